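# Independent brute-force oracles and shared fixtures.

# sliding-window digestion oracle: every window of width L compared to the
# site (overlap-tolerant by construction)
bf_digest <- function(seq, site, offset) {
  len <- nchar(seq); L <- nchar(site)
  b <- integer(0)
  if (len >= L) {
    i <- seq_len(len - L + 1L)
    hit <- substring(seq, i, i + L - 1L) == site
    b <- i[hit] - 1L + offset
  }
  b <- sort(unique(b[b > 0L & b < len]))
  data.frame(start = c(0L, b), end = c(b, len))
}

rc_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# double-loop mean-filter oracle
bf_smooth <- function(v, h) {
  n <- nrow(v)
  out <- v
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.na(v[i, j])) next
    win <- v[max(1, i - h):min(n, i + h), max(1, j - h):min(n, j + h)]
    out[i, j] <- mean(win, na.rm = TRUE)
  }
  out
}

# straight-line normalization reference (explicit double loop)
ref_normalize <- function(raw, f, excluded, target = 100) {
  n <- nrow(raw)
  v <- raw
  v[excluded, ] <- NA
  v[, excluded] <- NA
  tot <- sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
  fm <- mean(f[!excluded])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!is.na(v[i, j])) v[i, j] <- v[i, j] / tot / (f[i] * f[j] / fm^2)
  }
  v * target / mean(v, na.rm = TRUE)
}

# brute-force focus-proportion oracle with explicit distance predicate
bf_focus <- function(values, centers, ci, cj, radius) {
  n <- nrow(values)
  num <- 0; seen <- matrix(FALSE, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (abs(centers[p] - ci) <= radius && abs(centers[q] - cj) <= radius) {
      lo <- min(p, q); hi <- max(p, q)
      if (!seen[lo, hi]) {
        seen[lo, hi] <- TRUE
        if (!is.na(values[lo, hi])) num <- num + values[lo, hi]
      }
    }
  }
  den <- 0
  for (p in seq_len(n)) for (q in p:n) {
    if (!is.na(values[p, q])) den <- den + values[p, q]
  }
  100 * num / den
}

# direct-formula SCC reference on plain matrices
ref_scc <- function(A, B, bin_size, h, max_d) {
  A <- bf_smooth(A, h); B <- bf_smooth(B, h)
  n <- nrow(A)
  num <- 0; den <- 0
  for (d in 0:min(floor(max_d / bin_size), n - 1L)) {
    x <- c(); y <- c()
    for (i in seq_len(n - d)) {
      if (!is.na(A[i, i + d]) && !is.na(B[i, i + d])) {
        x <- c(x, A[i, i + d]); y <- c(y, B[i, i + d])
      }
    }
    if (length(x) < 2) next
    vx <- var(x); vy <- var(y)
    if (vx == 0 || vy == 0) next
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    w <- length(x) * sqrt(vx * vy)
    num <- num + w * r; den <- den + w
  }
  num / den
}

# hand-built multiway matrix (internal constructor) for toy cases
toy_matrix <- function(values, bin_size = 1000L, state = "scaled",
                       excluded = NULL) {
  n <- nrow(values)
  grid <- bin_grid("toy", 0L, n * bin_size, bin_size)
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  values[excluded, ] <- NA_real_
  values[, excluded] <- NA_real_
  tricontact:::.new_multiway(values, grid, "toy", state, excluded)
}

sym_random_matrix <- function(n, excluded_frac = 0) {
  v <- matrix(stats::rpois(n * n, 5), n, n)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  v <- v * 1.0
  excl <- rep(FALSE, n)
  if (excluded_frac > 0)
    excl[sample.int(n, max(1, round(n * excluded_frac)))] <- TRUE
  list(values = v, excluded = excl)
}

# shared simulation fixture: default locus, boundary deleted, NlaIII digest
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      loc <- locus_model()
      loc$boundary_active <- FALSE
      ref <- random_locus_sequence(loc, seed = 7)
      map <- digest_reference(ref, enzyme("NlaIII"), chrom = loc$chrom)
      vp <- viewpoint_from_locus(loc, map)
      grid <- bin_grid(loc$chrom, 0L, loc$region_length, 1000L)
      cache <<- list(loc = loc, ref = ref, map = map, vp = vp, grid = grid)
    }
    cache
  }
})

# one replicate through the analysis path, returning the scaled matrix
replicate_matrix <- function(fx, params, seed) {
  tr <- simulate_alleles(fx$loc, params, seed = seed)
  rd <- ligate_and_read(tr, fx$loc, fx$map, params, seed = seed + 500009L)
  rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
  list(reporters = rr,
       scaled = normalize_matrix(count_multiway(rr, fx$grid, fx$map,
                                                vp = fx$vp)))
}
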