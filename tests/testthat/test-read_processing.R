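test_that("segment_and_map maps single-fragment reads and drops unmappable ones", {
  fx <- sim_fixture()
  fr <- 100L
  frag_seq <- substr(fx$ref, fx$map$fragments$start[fr + 1L] + 1L,
                     fx$map$fragments$end[fr + 1L])
  fq <- data.frame(name = c("a|a", "b|b"),
                   seq = c(frag_seq, strrep("N", 60)),
                   stringsAsFactors = FALSE)
  out <- segment_and_map(fq, fx$ref, fx$map, enzyme("NlaIII"))
  expect_equal(nrow(out), 1L)
  expect_equal(out$fragments[[1]], fr)
  expect_equal(attr(out, "stats")$dropped_reads, 1L)
  expect_error(segment_and_map(fq, NULL, fx$map, enzyme("NlaIII")),
               "reference")
})

test_that("render/segment round-trip recovers simulated fragment sets", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", duplication_rate = 0, seed = 1,
                       reads_per_replicate = 150)
  tr <- simulate_alleles(fx$loc, p, seed = 81)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 82)
  fq <- render_fastq(rd, fx$map, fx$ref, enzyme = enzyme("NlaIII"),
                     seed = 83)
  out <- segment_and_map(fq, fx$ref, fx$map, enzyme("NlaIII"))
  lens <- fx$map$fragments$end - fx$map$fragments$start
  # recovery is guaranteed for reads whose fragments all clear the minimum
  # mappable segment length; terminal fragments of the map lack a flanking
  # restriction site, so junction regeneration cannot reconstruct them
  nfrag <- nrow(fx$map$fragments)
  eligible <- vapply(rd$fragments, function(f)
    all(lens[f + 1L] >= 20L) && !any(f %in% c(0L, nfrag - 1L)), logical(1))
  got <- out$fragments[match(rd$read_id[eligible], out$read_id)]
  expect_true(all(mapply(identical, got, rd$fragments[eligible])))
  expect_gt(sum(eligible), 100)
})

test_that("reporter extraction applies every filter and is order-independent", {
  fx <- sim_fixture()
  vfr <- fx$vp$fragments
  far <- vfr + 60L
  oligo <- vfr + 80L
  vp2 <- viewpoint_spec(fx$vp$name, vfr, proximity_radius = 1000L,
                        excluded_fragments = oligo)
  mk <- function(frs) {
    r <- data.frame(read_id = sprintf("r%d", seq_along(frs)),
                    left_end = 0L, right_end = 10L,
                    stringsAsFactors = FALSE)
    r$fragments <- frs
    r
  }
  # radius 0 isolates the re-ligation adjacency filter from the bp-radius one
  vp0 <- viewpoint_spec(fx$vp$name, vfr, proximity_radius = 0L,
                        excluded_fragments = oligo)
  reads <- mk(list(vfr,                      # viewpoint only -> discarded
                   c(vfr, vfr + 1L, far),    # adjacent filtered, far kept
                   c(vfr, oligo),            # oligo-excluded -> reporterless
                   c(far, far + 1L),         # no viewpoint -> discarded
                   c(vfr, far)))
  rr <- extract_reporters(reads, vp0, fx$map)
  expect_equal(rr$read_id, c("r2", "r5"))
  expect_equal(rr$reporters, list(far, far))
  st <- attr(rr, "stats")
  expect_equal(st$no_viewpoint, 1L)
  expect_equal(st$adjacent_excluded_reporters, 1L)
  expect_equal(st$oligo_excluded_reporters, 1L)
  expect_equal(st$reporterless_reads, 2L)
  # with a 1 kb radius the adjacent fragment is instead claimed by the
  # proximity filter
  rr2 <- extract_reporters(reads, vp2, fx$map)
  expect_equal(attr(rr2, "stats")$proximity_excluded_reporters, 1L)
  expect_equal(attr(rr2, "stats")$adjacent_excluded_reporters, 0L)

  # order-independence: surviving reporters equal brute-force predicate
  # application regardless of filter order
  set.seed(555)
  nfrag <- nrow(fx$map$fragments)
  frs <- lapply(1:200, function(i)
    unique(c(if (runif(1) < 0.8) vfr,
             sample.int(nfrag, sample(0:4, 1)) - 1L)))
  reads <- mk(frs)
  rr <- extract_reporters(reads, vp2, fx$map)
  win_lo <- fx$map$fragments$start[vfr + 1L] - 1000L
  win_hi <- fx$map$fragments$end[vfr + 1L] + 1000L
  keep_pred <- function(f) {
    !(f %in% vfr) & !(f %in% oligo) & !(f %in% c(vfr - 1L, vfr + 1L)) &
      !(fx$map$fragments$end[f + 1L] > win_lo &
          fx$map$fragments$start[f + 1L] < win_hi)
  }
  oracle <- lapply(frs, function(f) if (any(f %in% vfr)) f[keep_pred(f)])
  oracle_ids <- which(lengths(oracle) > 0)
  expect_equal(rr$read_id, sprintf("r%d", oracle_ids))
  expect_equal(rr$reporters, unname(oracle[oracle_ids]))
})

test_that("extract_reporters is idempotent and monotone in the proximity radius", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", seed = 1, reads_per_replicate = 500)
  tr <- simulate_alleles(fx$loc, p, seed = 91)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 92)
  rr1 <- extract_reporters(rd, fx$vp, fx$map)
  back <- rr1
  back$fragments <- lapply(seq_len(nrow(rr1)), function(i)
    c(fx$vp$fragments, rr1$reporters[[i]]))
  rr2 <- extract_reporters(back, fx$vp, fx$map)
  expect_equal(rr2$reporters, rr1$reporters)
  expect_equal(rr2$read_id, rr1$read_id)

  n_surviving <- vapply(c(0L, 1000L, 5000L, 20000L), function(r) {
    vp <- viewpoint_spec(fx$vp$name, fx$vp$fragments, proximity_radius = r)
    sum(lengths(extract_reporters(rd, vp, fx$map)$reporters))
  }, numeric(1))
  expect_true(all(diff(n_surviving) <= 0))
})

test_that("duplicate removal follows the wobble-bin rule", {
  mk <- function(ids, frs, le, re) {
    r <- data.frame(read_id = ids, left_end = le, right_end = re,
                    stringsAsFactors = FALSE)
    r$reporters <- frs
    class(r) <- c("reporter_reads", "data.frame")
    r
  }
  # same fragments, ends within one wobble bin -> collapsed
  r <- mk(c("a", "b"), list(c(5L, 9L), c(9L, 5L)), c(12L, 13L), c(60L, 65L))
  out <- remove_duplicates(r, wobble = 6L)
  expect_equal(out$read_id, "a")
  expect_equal(attr(out, "stats")$collapsed, 1L)
  # same fragments, ends in different bins -> kept
  r <- mk(c("a", "b"), list(5L, 5L), c(11L, 13L), c(60L, 60L))
  expect_equal(nrow(remove_duplicates(r, wobble = 6L)), 2L)
  # wobble 0 requires exact end identity
  r <- mk(c("a", "b"), list(5L, 5L), c(12L, 12L), c(60L, 61L))
  expect_equal(nrow(remove_duplicates(r, wobble = 0L)), 2L)
  r <- mk(c("a", "b"), list(5L, 5L), c(12L, 12L), c(60L, 60L))
  expect_equal(nrow(remove_duplicates(r, wobble = 0L)), 1L)
  # idempotent
  out2 <- remove_duplicates(remove_duplicates(r, 6L), 6L)
  expect_equal(nrow(out2), 1L)
  expect_equal(attr(out2, "stats")$collapsed, 0L)
})

test_that("deduplication recovers distinct lineages on simulated duplicates", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", duplication_rate = 0.5, jitter = 0,
                       seed = 1, reads_per_replicate = 800)
  tr <- simulate_alleles(fx$loc, p, seed = 96)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 97)
  rr <- extract_reporters(rd, fx$vp, fx$map)
  out <- remove_duplicates(rr, wobble = 6L)
  expect_equal(nrow(out), length(unique(rr$lineage)))
})

test_that("multiplicity split partitions the surviving reads disjointly", {
  fx <- sim_fixture()
  p <- topology_params(model = "hub", seed = 1, reads_per_replicate = 600)
  tr <- simulate_alleles(fx$loc, p, seed = 93)
  rd <- ligate_and_read(tr, fx$loc, fx$map, p, seed = 94)
  rr <- remove_duplicates(extract_reporters(rd, fx$vp, fx$map))
  sp <- split_by_multiplicity(rr)
  expect_equal(nrow(sp$pairwise) + nrow(sp$multiway), nrow(rr))
  expect_equal(length(intersect(sp$pairwise$read_id, sp$multiway$read_id)),
               0L)
  expect_true(all(lengths(sp$pairwise$reporters) == 1L))
  expect_true(all(lengths(sp$multiway$reporters) >= 2L))
})
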