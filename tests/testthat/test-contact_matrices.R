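mk_reporter_reads <- function(frs) {
  r <- data.frame(read_id = sprintf("r%d", seq_along(frs)),
                  left_end = 0L, right_end = 10L, stringsAsFactors = FALSE)
  r$reporters <- frs
  class(r) <- c("reporter_reads", "data.frame")
  r
}

test_that("multi-way counting increments every reporter pair once (mirrored)", {
  fx <- sim_fixture()
  f2b <- fragment_to_bin(fx$map, fx$grid)
  # three reporters in distinct bins -> C(3,2) = 3 mirrored cells
  frs <- which(!is.na(f2b$bin))[c(10, 60, 120)] - 1L
  bins <- f2b$bin[frs + 1L]
  m <- count_multiway(mk_reporter_reads(list(frs)), fx$grid, fx$map)
  expect_equal(matrix_total(m), 3)
  for (p in 1:2) for (q in (p + 1):3) {
    expect_equal(m$values[bins[p], bins[q]], 1)
    expect_equal(m$values[bins[q], bins[p]], 1)
  }
  # single-reporter reads contribute nothing
  m1 <- count_multiway(mk_reporter_reads(list(frs[1])), fx$grid, fx$map)
  expect_equal(matrix_total(m1), 0)
  # symmetry of raw storage
  v <- m$values
  expect_equal(v, t(v))
})

test_that("raw matrix total equals the pair-count enumeration over reads", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", seed = 1, reads_per_replicate = 2000)
  tr <- simulate_alleles(fx$loc, p, seed = 111)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 112)
  rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
  m <- count_multiway(rr, fx$grid, fx$map, vp = fx$vp)
  k <- lengths(rr$reporters)
  expect_equal(matrix_total(m), sum(choose(k[k >= 2], 2)))
  expect_equal(m$counters$skipped_pairs, 0L)
})

test_that("normalization fulfils its contract and matches the reference formula", {
  n <- 12L
  f <- rep(3L, n)
  raw <- matrix(5, n, n)
  m <- toy_matrix(raw, state = "raw")
  m$norm$fragments_per_bin <- f
  sc <- normalize_matrix(m)
  # uniform fragments + uniform raw counts -> every cell exactly 100
  expect_equal(unname(sc$values), matrix(100, n, n))
  expect_equal(mean(sc$values, na.rm = TRUE), 100, tolerance = 1e-12)

  set.seed(777)
  for (i in 1:10) {
    sr <- sym_random_matrix(15, excluded_frac = 0.15)
    f <- sample(0:5, 15, replace = TRUE)
    excl <- sr$excluded | f == 0L
    m <- toy_matrix(sr$values, state = "raw", excluded = excl)
    m$norm$fragments_per_bin <- f
    if (sum(m$values[upper.tri(m$values, diag = TRUE)], na.rm = TRUE) == 0)
      next
    sc <- normalize_matrix(m)
    # mean contract
    expect_equal(mean(sc$values, na.rm = TRUE), 100, tolerance = 1e-9)
    # straight-line double-loop reference
    ref <- ref_normalize(sr$values, f, excl)
    expect_equal(sc$values, ref, tolerance = 1e-12)
    # invariance under uniform doubling of raw counts
    m2 <- toy_matrix(sr$values * 2, state = "raw", excluded = excl)
    m2$norm$fragments_per_bin <- f
    expect_equal(normalize_matrix(m2)$values, sc$values, tolerance = 1e-12)
    # symmetry preserved
    expect_equal(sc$values, t(sc$values))
  }

  zero <- toy_matrix(matrix(0, 5, 5), state = "raw")
  zero$norm$fragments_per_bin <- rep(1L, 5)
  expect_error(normalize_matrix(zero), "no contacts")
})

test_that("differential matrices subtract cell-wise and are antisymmetric", {
  set.seed(888)
  a <- sym_random_matrix(10, 0.1)
  b <- sym_random_matrix(10, 0.1)
  ma <- toy_matrix(a$values, excluded = a$excluded)
  mb <- toy_matrix(b$values, excluded = b$excluded)
  d1 <- differential_matrix(ma, mb)
  d2 <- differential_matrix(mb, ma)
  expect_equal(d1$values, -d2$values)
  expect_equal(d1$excluded, ma$excluded | mb$excluded)
  self <- differential_matrix(ma, ma)
  expect_true(all(self$values[!is.na(self$values)] == 0))
  pos <- positive_part(d1)
  expect_true(all(pos$values[!is.na(pos$values)] >= 0))

  other <- toy_matrix(a$values[1:8, 1:8])
  expect_error(differential_matrix(ma, other), "grid mismatch")
})

test_that("pairwise profiles normalize to 100,000 and average across replicates", {
  fx <- sim_fixture()
  # all counts on one fragment
  fr <- 200L
  rr <- mk_reporter_reads(rep(list(fr), 7))
  prof <- pairwise_profile(rr, fx$vp, fx$map)
  expect_equal(prof$normalized[prof$fragment == fr], 1e5)
  expect_equal(prof$scaled[prof$fragment == fr], 1e5 * 0.01)
  expect_true(all(prof$normalized[prof$fragment != fr] == 0))
  expect_equal(sum(prof$normalized), 1e5)

  p <- topology_params(model = "hub", seed = 1, reads_per_replicate = 500)
  profs <- lapply(1:3, function(r) {
    tr <- simulate_alleles(fx$loc, p, replicate = r, seed = 120 + r)
    rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 130 + r)
    rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
    pairwise_profile(rr, fx$vp, fx$map)
  })
  for (pr in profs) expect_equal(sum(pr$normalized), 1e5)
  mp <- mean_profile(profs)
  expect_equal(mp$normalized,
               (profs[[1]]$normalized + profs[[2]]$normalized +
                  profs[[3]]$normalized) / 3)
  none <- mk_reporter_reads(list(fr))[0, ]
  expect_error(pairwise_profile(none, fx$vp, fx$map), "zero total")

  # capture_c mode accepts pre-tabulated pairwise counts
  pc <- pairwise_profile(data.frame(fragment = c(10L, 20L),
                                    count = c(3, 1)),
                         fx$vp, fx$map, mode = "capture_c")
  expect_equal(pc$normalized[pc$fragment == 10L], 75000)
})

test_that("viewpoint-proximity bins are masked at normalization, not at counting", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", seed = 1, reads_per_replicate = 1500)
  tr <- simulate_alleles(fx$loc, p, seed = 141)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 142)
  rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
  raw <- count_multiway(rr, fx$grid, fx$map, vp = fx$vp)
  sc <- normalize_matrix(raw)
  vp_bin <- position_to_bin(fx$grid, fx$loc$elements[[fx$loc$viewpoint]])
  expect_false(raw$excluded[vp_bin])        # raw: only zero-fragment bins
  expect_true(sc$excluded[vp_bin])          # scaled: proximity mask applied
  expect_true(all(is.na(sc$values[sc$excluded, ])))
  expect_equal(sc$values, t(sc$values))
})

test_that("scaled matrices separate hub enrichment from exclusive depletion", {
  fx <- sim_fixture()
  fc <- focus_spec("promoter-promoter", fx$loc$elements[["Mpg"]],
                   fx$loc$elements[["Hba"]])
  ratio <- function(model, seed) {
    p <- topology_params(model = model, seed = seed,
                         reads_per_replicate = 4000)
    tr <- simulate_alleles(fx$loc, p, seed = seed + 1)
    rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = seed + 2)
    rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
    sc <- normalize_matrix(count_multiway(rr, fx$grid, fx$map, vp = fx$vp))
    em <- independence_expectation(pairwise_profile(rr, fx$vp, fx$map),
                                   fx$grid, fx$map, like = sc)
    quantify_focus(sc, fc) / quantify_focus(em, fc)
  }
  expect_gt(ratio("hub", 2000), 1)
  expect_lt(ratio("exclusive", 3000), 1)
})

test_that("matrix writers emit dense, triplet and sidecar files that agree", {
  set.seed(999)
  a <- sym_random_matrix(8, 0.1)
  m <- toy_matrix(a$values, excluded = a$excluded)
  prefix <- file.path(withr::local_tempdir(), "mat")
  write_matrix(m, prefix, meta = list(seed = 1))
  dense <- as.matrix(utils::read.table(paste0(prefix, ".matrix.tsv"),
                                       sep = "\t"))
  dimnames(dense) <- NULL
  expect_equal(dense, m$values, tolerance = 1e-9)
  trip <- utils::read.table(paste0(prefix, ".triplets.tsv"), header = TRUE)
  expect_equal(trip$value,
               m$values[cbind(trip$bin_i + 1L, trip$bin_j + 1L)])
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  expect_equal(side$state, "scaled")
  expect_equal(sort(side$excluded_bins), which(m$excluded) - 1L)
  expect_equal(side$seed, 1L)
})
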