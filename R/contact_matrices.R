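#' Construct a multiway matrix object
#' @noRd
.new_multiway <- function(values, grid, viewpoint, state, excluded,
                          norm = list(), counters = list()) {
  structure(list(viewpoint = viewpoint, grid = grid, values = values,
                 state = state, excluded = excluded, norm = norm,
                 counters = counters),
            class = "multiway_matrix")
}

#' @export
print.multiway_matrix <- function(x, ...) {
  tot <- matrix_total(x)
  cat("<multiway_matrix>", x$state, "| viewpoint", x$viewpoint, "|",
      x$grid$n_bins, "x", x$grid$n_bins, "bins of", x$grid$bin_size, "bp |",
      sum(x$excluded), "excluded bins | triangle total",
      format(tot, digits = 6), "\n")
  invisible(x)
}

#' Plot a multiway contact matrix
#'
#' Simple heat-map rendering; excluded bins are left blank.
#'
#' @param x A `multiway_matrix`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @method plot multiway_matrix
#' @export
plot.multiway_matrix <- function(x, main = NULL, ...) {
  v <- x$values
  if (x$state == "differential") {
    lim <- max(abs(v), na.rm = TRUE)
    col <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
    graphics::image(x$grid$center, x$grid$center, v, col = col,
                    zlim = c(-lim, lim), xlab = "bp", ylab = "bp",
                    main = main %||% paste(x$viewpoint, x$state), ...)
  } else {
    col <- grDevices::colorRampPalette(c("white", "red", "black"))(101)
    graphics::image(x$grid$center, x$grid$center, v, col = col,
                    xlab = "bp", ylab = "bp",
                    main = main %||% paste(x$viewpoint, x$state), ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method as.matrix multiway_matrix
#' @export
as.matrix.multiway_matrix <- function(x, ...) x$values

#' Total of one matrix triangle (upper, including diagonal)
#'
#' The symmetric-storage-safe total: each unordered bin pair is counted once.
#'
#' @param m A `multiway_matrix` or plain matrix.
#' @return Numeric total over non-excluded cells.
#' @export
matrix_total <- function(m) {
  v <- if (inherits(m, "multiway_matrix")) m$values else m
  sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
}

#' Count multi-way reporter co-occurrences into a raw contact matrix
#'
#' Every read with k >= 2 reporters contributes its C(k,2) unordered reporter
#' pairs: each pair increments the cell of (bin(a), bin(b)) and its transpose
#' mirror by 1 (same-bin pairs increment the diagonal once). Reads with a
#' single reporter contribute nothing. Reporters are assigned to bins via
#' their fragment midpoint; pairs with a reporter outside the grid are
#' skipped and counted. Bins containing no restriction fragment carry an NA
#' sentinel (no count can occur there).
#'
#' @param reads `reporter_reads`, deduplicated and filtered, one viewpoint.
#' @param grid A `bin_grid`.
#' @param map The `fragment_map`.
#' @param vp Optional `viewpoint_spec`; records the viewpoint/proximity bins
#'   masked at normalization time.
#' @return A `multiway_matrix` in state "raw".
#' @export
count_multiway <- function(reads, grid, map, vp = NULL) {
  stopifnot(inherits(grid, "bin_grid"), inherits(map, "fragment_map"))
  f2b <- fragment_to_bin(map, grid)
  nb <- grid$n_bins
  U <- matrix(0, nb, nb)
  skipped <- 0L

  k <- lengths(reads$reporters)
  multi <- which(k >= 2L)
  if (length(multi)) {
    # group reads by multiplicity so pair expansion is vectorised per k
    for (kk in sort(unique(k[multi]))) {
      rows <- multi[k[multi] == kk]
      fr <- matrix(unlist(reads$reporters[rows], use.names = FALSE),
                   ncol = kk, byrow = TRUE)
      bn <- matrix(f2b$bin[fr + 1L], ncol = kk)
      pairs <- utils::combn(kk, 2L)
      for (p in seq_len(ncol(pairs))) {
        bi <- bn[, pairs[1L, p]]
        bj <- bn[, pairs[2L, p]]
        ok <- !is.na(bi) & !is.na(bj)
        skipped <- skipped + sum(!ok)
        lo <- pmin(bi[ok], bj[ok]); hi <- pmax(bi[ok], bj[ok])
        tab <- tabulate((hi - 1L) * nb + lo, nbins = nb * nb)
        U <- U + matrix(tab, nb, nb)
      }
    }
  }
  V <- U + t(U)
  diag(V) <- diag(U)
  excluded <- f2b$counts == 0L
  V[excluded, ] <- NA_real_
  V[, excluded] <- NA_real_

  vp_bins <- logical(nb)
  if (!is.null(vp)) {
    vfr <- vp$fragments
    win_lo <- min(map$fragments$start[vfr + 1L]) - vp$proximity_radius
    win_hi <- max(map$fragments$end[vfr + 1L]) + vp$proximity_radius
    vp_bins <- grid$end > win_lo & grid$start < win_hi
  }
  .new_multiway(V, grid, if (is.null(vp)) "unknown" else vp$name, "raw",
                excluded,
                norm = list(fragments_per_bin = f2b$counts,
                            vp_bins = vp_bins),
                counters = list(skipped_pairs = skipped))
}

#' Normalize and scale a raw multiway matrix
#'
#' Applies, in order: division by the total raw counts in the matrix
#' (sequencing-depth normalization); division by the fragment-density
#' correction `f_i * f_j / mean(f)^2`, where `f_i` is the number of
#' restriction fragments in bin i and the mean runs over non-excluded bins;
#' and a single global rescale so the mean over non-excluded cells equals
#' `target_mean` (default 100 normalized interactions per bin). The
#' viewpoint/proximity bins recorded at counting time are masked (NA) before
#' any total is computed, together with zero-fragment bins.
#'
#' @param m A `multiway_matrix` in state "raw".
#' @param fragments_per_bin Optional per-bin fragment counts; defaults to the
#'   counts recorded by [count_multiway()].
#' @param target_mean Mean value of non-excluded cells after scaling.
#' @return A `multiway_matrix` in state "scaled".
#' @export
normalize_matrix <- function(m, fragments_per_bin = NULL, target_mean = 100) {
  stopifnot(inherits(m, "multiway_matrix"))
  if (m$state != "raw") stop("normalize_matrix expects a raw matrix")
  f <- fragments_per_bin %||% m$norm$fragments_per_bin
  if (is.null(f)) stop("fragments_per_bin required")
  nb <- m$grid$n_bins
  stopifnot(length(f) == nb)
  excluded <- m$excluded | f == 0L | (m$norm$vp_bins %||% logical(nb))

  v <- m$values
  v[excluded, ] <- NA_real_
  v[, excluded] <- NA_real_
  total <- sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
  if (total == 0) stop("no contacts to normalize")
  mean_f <- mean(f[!excluded])
  corr <- outer(f, f) / mean_f^2
  v <- v / total / corr
  mu <- mean(v, na.rm = TRUE)
  v <- v * (target_mean / mu)
  .new_multiway(v, m$grid, m$viewpoint, "scaled", excluded,
                norm = list(raw_total = total, mean_f = mean_f,
                            target_mean = target_mean,
                            fragments_per_bin = f),
                counters = m$counters)
}

#' Differential multiway matrix between two conditions
#'
#' Cell-wise `a - b` on scaled matrices over the same grid; the union of the
#' two exclusion masks is applied. `differential_matrix(a, b)` equals
#' `-differential_matrix(b, a)`.
#'
#' @param a,b Scaled `multiway_matrix` objects on the same grid.
#' @return A `multiway_matrix` in state "differential" (signed values).
#' @export
differential_matrix <- function(a, b) {
  stopifnot(inherits(a, "multiway_matrix"), inherits(b, "multiway_matrix"))
  if (a$state != "scaled" || b$state != "scaled")
    stop("differential_matrix expects scaled matrices")
  if (a$grid$n_bins != b$grid$n_bins ||
      a$grid$bin_size != b$grid$bin_size ||
      a$grid$region_start != b$grid$region_start ||
      a$grid$region_end != b$grid$region_end)
    stop("grid mismatch between matrices")
  excluded <- a$excluded | b$excluded
  v <- a$values - b$values
  v[excluded, ] <- NA_real_
  v[, excluded] <- NA_real_
  .new_multiway(v, a$grid, a$viewpoint, "differential", excluded)
}

#' Positive part of a differential matrix
#'
#' The condition-specific gains: negative cells set to 0.
#'
#' @param m A differential `multiway_matrix`.
#' @return A `multiway_matrix` with non-negative values.
#' @export
positive_part <- function(m) {
  stopifnot(inherits(m, "multiway_matrix"), m$state == "differential")
  m$values <- pmax(m$values, 0)
  m
}

#' Element-wise mean of scaled replicate matrices
#'
#' @param matrices List of scaled `multiway_matrix` objects on one grid.
#' @return A `multiway_matrix` in state "scaled" (union exclusion mask).
#' @export
mean_matrix <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  excluded <- Reduce(`|`, lapply(matrices, `[[`, "excluded"))
  v <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  v[excluded, ] <- NA_real_
  v[, excluded] <- NA_real_
  .new_multiway(v, matrices[[1]]$grid, matrices[[1]]$viewpoint, "scaled",
                excluded)
}

#' Pairwise interaction profile from reporter reads
#'
#' Counts each reporter fragment once per read (all reads with >= 1
#' reporter), normalizes to 100,000 total interactions on the analyzed
#' chromosome, and applies a display scaling constant (default 0.01, i.e.
#' per-1000 units), recorded in the metadata.
#'
#' @param reads `reporter_reads` (mode "tri_capture"), or a data.frame with
#'   columns `fragment`, `count` of pre-tabulated pairwise reporter counts
#'   (mode "capture_c").
#' @param vp The `viewpoint_spec`.
#' @param map The `fragment_map`.
#' @param mode "tri_capture" or "capture_c".
#' @param display_scale Display scaling constant applied after
#'   normalization.
#' @return A `pairwise_profile`: data.frame with `fragment`, `start`, `end`,
#'   `count`, `normalized`, `scaled` over all fragments (excluded fragments
#'   absent), plus metadata attributes.
#' @export
pairwise_profile <- function(reads, vp, map,
                             mode = c("tri_capture", "capture_c"),
                             display_scale = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "fragment_map"))
  nfrag <- nrow(map$fragments)
  counts <- numeric(nfrag)
  if (mode == "tri_capture") {
    fr <- unlist(reads$reporters, use.names = FALSE)
    tab <- tabulate(fr + 1L, nbins = nfrag)
    counts <- as.numeric(tab)
  } else {
    counts[reads$fragment + 1L] <- reads$count
  }
  # excluded fragments never appear among filtered reporters; drop them from
  # the profile support anyway for the capture_c path
  excl <- c(vp$fragments, vp$excluded_fragments)
  counts[excl + 1L] <- 0
  total <- sum(counts)
  if (total == 0) stop("zero total interaction count")
  keep <- !(seq_len(nfrag) - 1L) %in% excl
  df <- data.frame(fragment = map$fragments$id[keep],
                   start = map$fragments$start[keep],
                   end = map$fragments$end[keep],
                   count = counts[keep],
                   normalized = counts[keep] * 1e5 / total)
  df$scaled <- df$normalized * display_scale
  structure(df, class = c("pairwise_profile", "data.frame"),
            viewpoint = vp$name, chrom = map$chrom, total = total,
            display_scale = display_scale)
}

#' Element-wise mean of replicate pairwise profiles
#'
#' @param profiles List of `pairwise_profile` objects on one fragment map.
#' @return A `pairwise_profile` whose count/normalized/scaled columns are the
#'   element-wise means.
#' @export
mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  out <- profiles[[1]]
  for (col in c("count", "normalized", "scaled")) {
    out[[col]] <- Reduce(`+`, lapply(profiles, `[[`, col)) / length(profiles)
  }
  out
}

#' Plot a pairwise interaction profile
#' @param x A `pairwise_profile`.
#' @param ... Passed to [graphics::plot()].
#' @method plot pairwise_profile
#' @export
plot.pairwise_profile <- function(x, ...) {
  graphics::plot((x$start + x$end) / 2, x$scaled, type = "h",
                 xlab = "bp", ylab = "scaled interactions",
                 main = attr(x, "viewpoint"), ...)
  invisible(x)
}

#' Independence-expectation matrix from a pairwise profile
#'
#' Builds the contact matrix expected if two reporters co-occurred
#' independently: the outer product of the binned pairwise profile, masked
#' and rescaled exactly like an observed scaled matrix. Comparing observed
#' focus values against this expectation separates hub-like enrichment from
#' mutually exclusive depletion.
#'
#' @param profile A `pairwise_profile`.
#' @param grid The `bin_grid`.
#' @param map The `fragment_map`.
#' @param like Optional scaled `multiway_matrix` whose exclusion mask is
#'   reused (recommended for like-for-like comparison).
#' @param target_mean Mean of non-excluded cells after scaling (default 100).
#' @return A `multiway_matrix` in state "scaled".
#' @export
independence_expectation <- function(profile, grid, map, like = NULL,
                                     target_mean = 100) {
  f2b <- fragment_to_bin(map, grid)
  nb <- grid$n_bins
  p <- numeric(nb)
  bins <- f2b$bin[profile$fragment + 1L]
  ok <- !is.na(bins)
  p_tab <- tapply(profile$normalized[ok], bins[ok], sum)
  p[as.integer(names(p_tab))] <- p_tab
  excluded <- if (!is.null(like)) like$excluded else f2b$counts == 0L
  # per-fragment rate per bin, so the outer product lives on the same
  # fragment-density-corrected scale as a normalized observed matrix
  p <- ifelse(f2b$counts > 0L, p / f2b$counts, 0)
  v <- outer(p, p)
  v[excluded, ] <- NA_real_
  v[, excluded] <- NA_real_
  if (all(is.na(v)) || sum(v, na.rm = TRUE) == 0)
    stop("profile carries no mass on non-excluded bins")
  v <- v * (target_mean / mean(v, na.rm = TRUE))
  .new_multiway(v, grid, attr(profile, "viewpoint"), "scaled", excluded)
}

#' Write a multiway matrix as dense TSV, triplet TSV and sidecar JSON
#'
#' @param m A `multiway_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.matrix.tsv`,
#'   `<prefix>.triplets.tsv` and `<prefix>.json`.
#' @param meta Extra metadata stored in the sidecar (e.g. config hash, seed).
#' @return Invisibly, the three paths.
#' @export
write_matrix <- function(m, prefix, meta = list()) {
  stopifnot(inherits(m, "multiway_matrix"))
  dense <- paste0(prefix, ".matrix.tsv")
  trip <- paste0(prefix, ".triplets.tsv")
  side <- paste0(prefix, ".json")
  vals <- format(m$values, digits = 10, trim = TRUE, scientific = FALSE)
  vals[is.na(m$values)] <- "NA"
  utils::write.table(vals, dense, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  idx <- which(!is.na(m$values) & m$values != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  tdf <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                    value = m$values[idx])
  tdf <- tdf[order(tdf$bin_i, tdf$bin_j), ]
  utils::write.table(tdf, trip, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- c(list(viewpoint = m$viewpoint, state = m$state,
                    chrom = m$grid$chrom,
                    region_start = m$grid$region_start,
                    region_end = m$grid$region_end,
                    bin_size = m$grid$bin_size,
                    excluded_bins = which(m$excluded) - 1L,
                    normalization = m$norm[setdiff(names(m$norm),
                                                   "fragments_per_bin")]),
               meta)
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(dense, trip, side))
}

#' Write a pairwise profile as bedGraph
#'
#' @param profile A `pairwise_profile`.
#' @param path Output path.
#' @param column Which value column to emit ("scaled", "normalized" or
#'   "count").
#' @export
write_profile_bedgraph <- function(profile, path, column = "scaled") {
  df <- data.frame(chrom = attr(profile, "chrom"), start = profile$start,
                   end = profile$end,
                   value = format(profile[[column]], digits = 10,
                                  trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
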