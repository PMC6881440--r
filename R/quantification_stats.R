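#' Specify a three-way contact focus
#'
#' A focus is the matrix neighbourhood at the intersection of two elements'
#' bins: cells whose bin centers lie within `radius` bp of both anchor bin
#' centers (closed predicate; with 1 kb bins and the default 2 kb radius this
#' is a 5x5 block). Counts in the focus measure how often the two elements
#' contact the viewpoint simultaneously at a single allele.
#'
#' @param name Focus label, e.g. "R2-R1-Hba".
#' @param pos_i,pos_j Genomic positions (bp) of the two anchor elements.
#' @param radius Radius in bp (default 2000).
#' @return A `focus_spec`.
#' @export
focus_spec <- function(name, pos_i, pos_j, radius = 2000L) {
  if (radius < 0) stop("radius must be >= 0")
  structure(list(name = name, pos_i = pos_i, pos_j = pos_j,
                 radius = as.integer(radius)),
            class = "focus_spec")
}

#' Focus cells as canonical (upper-triangle) index pairs
#' @noRd
.focus_cells <- function(m, focus) {
  grid <- m$grid
  bi <- position_to_bin(grid, focus$pos_i)
  bj <- position_to_bin(grid, focus$pos_j)
  if (is.na(bi) || is.na(bj)) stop("focus anchors outside the grid")
  ci <- grid$center[bi]; cj <- grid$center[bj]
  P <- which(abs(grid$center - ci) <= focus$radius)
  Q <- which(abs(grid$center - cj) <= focus$radius)
  cells <- expand.grid(p = P, q = Q)
  lo <- pmin(cells$p, cells$q); hi <- pmax(cells$p, cells$q)
  unique(cbind(lo, hi))  # block and its mirror counted once
}

#' Quantify a three-way contact focus
#'
#' Returns the counts in the focus block as a percentage of the total counts
#' in the matrix, where both numerator and denominator use one matrix
#' triangle (upper, including the diagonal) restricted to non-excluded
#' cells. The proportion is invariant under the matrix's global scaling.
#'
#' @param m A scaled `multiway_matrix`.
#' @param focus A `focus_spec`.
#' @return Proportion in percent.
#' @export
quantify_focus <- function(m, focus) {
  stopifnot(inherits(m, "multiway_matrix"), inherits(focus, "focus_spec"))
  cells <- .focus_cells(m, focus)
  vals <- m$values[cells]
  if (all(is.na(vals))) stop("focus block entirely excluded")
  total <- matrix_total(m)
  100 * sum(vals, na.rm = TRUE) / total
}

#' Compare focus proportions between two replicate groups
#'
#' Unpaired Student's t-test with pooled variance (df = n_a + n_b - 2) and a
#' two-tailed p-value; Welch's correction available via `var_equal = FALSE`.
#' Degenerate inputs follow a fixed contract: zero pooled variance with equal
#' means gives t = 0, p = 1; zero pooled variance with unequal means gives
#' p = 0 with a warning.
#'
#' @param props_a,props_b Per-replicate proportions (each length >= 2).
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return A `group_comparison`: list with `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(props_a, props_b, var_equal = TRUE) {
  n_a <- length(props_a); n_b <- length(props_b)
  if (n_a < 2L || n_b < 2L) stop("each group needs n >= 2")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  va <- stats::var(props_a); vb <- stats::var(props_b)
  sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
  if (sp2 == 0) {
    if (mean(props_a) == mean(props_b)) {
      t_stat <- 0; p <- 1; df <- n_a + n_b - 2
    } else {
      warning("zero pooled variance with unequal means")
      t_stat <- sign(mean(props_a) - mean(props_b)) * Inf
      p <- 0; df <- n_a + n_b - 2
    }
  } else {
    tt <- stats::t.test(props_a, props_b, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(t = t_stat, df = df, p = p,
                 mean_a = mean(props_a), mean_b = mean(props_b),
                 sem_a = sem(props_a), sem_b = sem(props_b),
                 n_a = n_a, n_b = n_b, var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: %.4g +/- %.4g (SEM, n=%d)\n", x$mean_a, x$sem_a,
              x$n_a))
  cat(sprintf("group B: %.4g +/- %.4g (SEM, n=%d)\n", x$mean_b, x$sem_b,
              x$n_b))
  cat(sprintf("%s t = %.4g, df = %.4g, two-tailed p = %.4g\n",
              if (x$var_equal) "pooled" else "Welch", x$t, x$df, x$p))
  invisible(x)
}

#' Quantify foci across replicate matrices and compare conditions
#'
#' @param matrices_a,matrices_b Lists of scaled `multiway_matrix` objects
#'   (one per replicate) for the two conditions.
#' @param foci List of `focus_spec` objects.
#' @param var_equal Passed to [compare_groups()].
#' @return A `focus_quantification` data.frame: one row per focus with
#'   per-replicate proportions (list-columns `props_a`, `props_b`), group
#'   means, SEMs, t and p.
#' @export
quantify_foci <- function(matrices_a, matrices_b, foci, var_equal = TRUE) {
  rows <- lapply(foci, function(fc) {
    pa <- vapply(matrices_a, quantify_focus, numeric(1), focus = fc)
    pb <- vapply(matrices_b, quantify_focus, numeric(1), focus = fc)
    cmp <- compare_groups(pa, pb, var_equal = var_equal)
    out <- data.frame(focus = fc$name, mean_a = cmp$mean_a,
                      mean_b = cmp$mean_b, sem_a = cmp$sem_a,
                      sem_b = cmp$sem_b, t = cmp$t, df = cmp$df, p = cmp$p,
                      stringsAsFactors = FALSE)
    out$props_a <- list(unname(pa))
    out$props_b <- list(unname(pb))
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("focus_quantification", "data.frame")
  out
}

#' Mean-filter smoothing of a contact matrix
#'
#' 2D mean filter over a (2h+1) x (2h+1) window, clipped at matrix edges:
#' each cell becomes the mean of the in-bounds, non-excluded cells in its
#' window. `h = 0` is the identity. Excluded (NA) cells stay NA.
#'
#' @param m A `multiway_matrix` or plain numeric matrix.
#' @param h Half-window size in bins.
#' @return Object of the same type with smoothed values.
#' @export
smooth_matrix <- function(m, h) {
  stopifnot(h >= 0)
  v <- if (inherits(m, "multiway_matrix")) m$values else m
  if (h == 0) return(m)
  n <- nrow(v)
  A <- v; A[is.na(A)] <- 0
  M <- matrix(as.numeric(!is.na(v)), n)
  PA <- matrix(0, n + 1L, n + 1L)
  PA[-1L, -1L] <- t(apply(apply(A, 2L, cumsum), 1L, cumsum))
  PM <- matrix(0, n + 1L, n + 1L)
  PM[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  wsum <- function(P)
    P[hi + 1L, hi + 1L, drop = FALSE] - P[lo, hi + 1L, drop = FALSE] -
    P[hi + 1L, lo, drop = FALSE] + P[lo, lo, drop = FALSE]
  S <- wsum(PA); C <- wsum(PM)
  out <- S / C
  out[C == 0] <- NA_real_
  out[is.na(v)] <- NA_real_
  if (inherits(m, "multiway_matrix")) {
    m$values <- out
    m
  } else out
}

#' Stratum-adjusted correlation coefficient between two matrices
#'
#' Both matrices are smoothed with half-window `h`, then cell pairs are
#' stratified by genomic distance `|i - j| * bin_size` up to `max_distance`.
#' Per stratum the Pearson correlation r_k is computed over paired
#' non-excluded cells, and the SCC is the weighted mean of the r_k with
#' weights `N_k * sqrt(var_a,k * var_b,k)`; strata with zero variance in
#' either matrix are skipped.
#'
#' @param a,b `multiway_matrix` objects on the same grid.
#' @param h Smoothing half-window in bins (default 10).
#' @param max_distance Maximum genomic distance in bp (default 100000).
#' @return SCC in `[-1, 1]`.
#' @export
scc <- function(a, b, h = 10L, max_distance = 100000L) {
  stopifnot(inherits(a, "multiway_matrix"), inherits(b, "multiway_matrix"))
  if (a$grid$n_bins != b$grid$n_bins ||
      a$grid$bin_size != b$grid$bin_size)
    stop("grid mismatch between matrices")
  if (max_distance < a$grid$bin_size)
    stop("max_distance must be at least one bin")
  A <- smooth_matrix(a$values, h)
  B <- smooth_matrix(b$values, h)
  n <- nrow(A)
  dmax <- min(floor(max_distance / a$grid$bin_size), n - 1L)
  num <- 0; den <- 0; usable <- 0L
  for (d in 0:dmax) {
    i <- seq_len(n - d); j <- i + d
    x <- A[cbind(i, j)]; y <- B[cbind(i, j)]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) next
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 || vy == 0) next
    r <- stats::cor(x, y)
    w <- length(x) * sqrt(vx * vy)
    num <- num + w * r
    den <- den + w
    usable <- usable + 1L
  }
  if (usable == 0L) stop("no usable strata for SCC")
  num / den
}

#' Pairwise SCC table across replicate matrices
#'
#' @param matrices Named list of `multiway_matrix` objects.
#' @param h,max_distance Passed to [scc()].
#' @return Data.frame with `a`, `b`, `scc` for every unordered pair.
#' @export
scc_table <- function(matrices, h = 10L, max_distance = 100000L) {
  nm <- names(matrices) %||% as.character(seq_along(matrices))
  pairs <- utils::combn(length(matrices), 2L)
  data.frame(a = nm[pairs[1L, ]], b = nm[pairs[2L, ]],
             scc = apply(pairs, 2L, function(pq)
               scc(matrices[[pq[1L]]], matrices[[pq[2L]]], h = h,
                   max_distance = max_distance)),
             stringsAsFactors = FALSE)
}
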