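#' Define a regulatory locus model for simulation
#'
#' Describes a toy single-TAD locus: a ~180 kb window containing a cluster of
#' enhancers and several gene promoters, a capture viewpoint, and a CTCF-like
#' boundary position separating the upstream promoters from the enhancer/
#' globin-gene block. The default layout mirrors an alpha-globin-like domain:
#' three upstream promoters (Snrnp25, Rhbdf1, Mpg), five clustered enhancers
#' (R1-R4, Rm) and the globin promoters (Hba) downstream, with the boundary
#' between Mpg and R1.
#'
#' @param region_length Locus span in bp (default 180000).
#' @param chrom Sequence name used throughout.
#' @param elements Named vector of element positions (bp within the region).
#' @param element_types Named character vector ("promoter"/"enhancer")
#'   matching `elements`.
#' @param viewpoint Name of the capture viewpoint element.
#' @param boundary_pos Boundary position in bp.
#' @param boundary_active Logical; TRUE models the intact boundary (contacts
#'   crossing it are attenuated), FALSE the boundary deletion.
#' @return A `locus_model`.
#' @export
locus_model <- function(region_length = 180000L,
                        chrom = "locusA",
                        elements = c(Snrnp25 = 20000, Rhbdf1 = 35000,
                                     Mpg = 50000, R1 = 72000, R2 = 78000,
                                     R3 = 82000, R4 = 86000, Rm = 90000,
                                     Hba = 110000),
                        element_types = c(Snrnp25 = "promoter",
                                          Rhbdf1 = "promoter",
                                          Mpg = "promoter",
                                          R1 = "enhancer", R2 = "enhancer",
                                          R3 = "enhancer", R4 = "enhancer",
                                          Rm = "enhancer",
                                          Hba = "promoter"),
                        viewpoint = "R2",
                        boundary_pos = 60000L,
                        boundary_active = TRUE) {
  if (is.null(names(elements)) || anyDuplicated(names(elements)))
    stop("elements must have unique names")
  if (any(elements < 0 | elements >= region_length))
    stop("all element positions must lie inside the region")
  if (!viewpoint %in% names(elements))
    stop("viewpoint must be a named element")
  element_types <- element_types[names(elements)]
  if (anyNA(element_types))
    stop("element_types must cover every element")
  structure(list(region_length = as.integer(region_length), chrom = chrom,
                 elements = elements, element_types = element_types,
                 viewpoint = viewpoint,
                 boundary_pos = as.integer(boundary_pos),
                 boundary_active = isTRUE(boundary_active)),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model>", x$chrom, sprintf("(%d bp),", x$region_length),
      length(x$elements), "elements, viewpoint", x$viewpoint,
      "| boundary", if (x$boundary_active) "intact" else "deleted",
      "at", x$boundary_pos, "\n")
  invisible(x)
}

#' Topology and sequencing parameters for the simulator
#'
#' @param model Interaction topology: "hub" (the viewpoint co-recruits
#'   several elements into one complex), "exclusive" (flip-flop: exactly one
#'   partner at a time) or "independent" (each element joins on its own).
#' @param p_complex Probability an allele forms a specific complex at all
#'   (otherwise it carries only distance-decay background contacts).
#' @param hub_size_dist Named probability vector over the number of elements
#'   co-recruited with the viewpoint under the hub model (names = k, k >= 2).
#' @param partner_weights Named non-negative recruitment weights per element
#'   (default: equal weight for every non-viewpoint element).
#' @param boundary_block Retention probability in (0, 1] for complexed
#'   contacts crossing the boundary when the boundary is active.
#' @param decay_exponent Power-law exponent for background contact decay with
#'   distance from the viewpoint (default 1, canonical 3C decay).
#' @param capture_prob Per-element probability that a complexed contact is
#'   captured into the sequenced concatemer.
#' @param background_dist Probability vector for the number of background
#'   reporter fragments per read (0, 1, 2, ...).
#' @param duplication_rate Probability a read is re-emitted as a PCR
#'   duplicate.
#' @param jitter Uniform sonication-end jitter (+/- bp) applied to duplicate
#'   copies; 0 gives byte-identical duplicate keys.
#' @param sonication_offset Maximum sonication-end offset from the viewpoint
#'   fragment (ends drawn uniformly from 0..offset-1 bp; default 700,
#'   a typical sonication fragment size).
#' @param join_scale Baseline join probability scale for the independent
#'   model: element e joins with probability
#'   `join_scale * w_e / max(w)`.
#' @param reads_per_replicate Alleles (= reads before duplication) per
#'   biological replicate.
#' @param n_replicates Biological replicates per condition (default 3).
#' @param seed Master seed; required for any simulation run.
#' @return A `topology_params` list.
#' @export
topology_params <- function(model = c("hub", "exclusive", "independent"),
                            p_complex = 0.5,
                            hub_size_dist = c("2" = 0.5, "3" = 0.3,
                                              "4" = 0.2),
                            partner_weights = NULL,
                            boundary_block = 0.2,
                            decay_exponent = 1,
                            capture_prob = 0.8,
                            background_dist = c(0.3, 0.5, 0.2),
                            duplication_rate = 0.1,
                            jitter = 3L,
                            sonication_offset = 700L,
                            join_scale = 0.5,
                            reads_per_replicate = 5000L,
                            n_replicates = 3L,
                            seed = NULL) {
  model <- match.arg(model)
  stopifnot(p_complex >= 0, p_complex <= 1,
            boundary_block >= 0, boundary_block <= 1,
            decay_exponent > 0,
            capture_prob >= 0, capture_prob <= 1,
            duplication_rate >= 0, duplication_rate <= 1,
            jitter >= 0, sonication_offset >= 1,
            reads_per_replicate >= 1, n_replicates >= 1)
  if (model == "hub") {
    ks <- as.integer(names(hub_size_dist))
    if (anyNA(ks) || any(ks < 2))
      stop("hub_size_dist support must be integers >= 2")
    if (abs(sum(hub_size_dist) - 1) > 1e-8)
      stop("hub_size_dist probabilities must sum to 1")
  }
  if (!is.null(partner_weights)) {
    if (any(partner_weights < 0) || all(partner_weights == 0))
      stop("partner_weights must be non-negative and not all zero")
  }
  structure(list(model = model, p_complex = p_complex,
                 hub_size_dist = hub_size_dist,
                 partner_weights = partner_weights,
                 boundary_block = boundary_block,
                 decay_exponent = decay_exponent,
                 capture_prob = capture_prob,
                 background_dist = background_dist,
                 duplication_rate = duplication_rate,
                 jitter = as.integer(jitter),
                 sonication_offset = as.integer(sonication_offset),
                 join_scale = join_scale,
                 reads_per_replicate = as.integer(reads_per_replicate),
                 n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "topology_params")
}

.partner_weights <- function(locus, params) {
  els <- setdiff(names(locus$elements), locus$viewpoint)
  w <- rep(1, length(els))
  names(w) <- els
  if (!is.null(params$partner_weights)) {
    shared <- intersect(names(params$partner_weights), els)
    w[] <- 0
    w[shared] <- params$partner_weights[shared]
    if (all(w == 0)) stop("partner_weights assign no weight to any partner")
  }
  w
}

.crosses_boundary <- function(locus, element_names) {
  b <- locus$boundary_pos
  vp_side <- locus$elements[[locus$viewpoint]] < b
  (locus$elements[element_names] < b) != vp_side
}

#' Simulate single-allele complex membership
#'
#' Generates the ground-truth complex composition of each allele under the
#' chosen topology. With probability `p_complex` an allele forms a complex:
#' hub -- the viewpoint plus k partners sampled without replacement by weight
#' (k from `hub_size_dist`); exclusive -- the viewpoint plus exactly one
#' weighted partner; independent -- each partner joins independently with a
#' weight-scaled probability. Complexed contacts crossing an active boundary
#' are then retained with probability `boundary_block`.
#'
#' @param locus A `locus_model` (its `boundary_active` flag is the condition
#'   proxy).
#' @param params A `topology_params`.
#' @param condition,replicate Labels recorded in the truth table.
#' @param n_alleles Number of alleles (defaults to `reads_per_replicate`).
#' @param seed Optional seed (set before any draw).
#' @return A data.frame of class `simulation_truth`: `allele`, `condition`,
#'   `replicate`, `model`, and list-column `members` (partner element names
#'   co-complexed with the viewpoint; empty for background-only alleles).
#' @export
simulate_alleles <- function(locus, params, condition = "deleted",
                             replicate = 1L,
                             n_alleles = params$reads_per_replicate,
                             seed = NULL) {
  stopifnot(inherits(locus, "locus_model"),
            inherits(params, "topology_params"))
  if (!is.null(seed)) set.seed(seed)
  w <- .partner_weights(locus, params)
  els <- names(w)
  n <- as.integer(n_alleles)

  members <- rep(list(character(0)), n)
  in_complex <- stats::runif(n) < params$p_complex
  idx <- which(in_complex)
  if (length(idx)) {
    if (params$model == "hub") {
      ks <- as.integer(names(params$hub_size_dist))
      if (any(ks < 2)) stop("hub_size_dist support must be >= 2")
      ks_drawn <- ks[sample.int(length(ks), length(idx), replace = TRUE,
                                prob = params$hub_size_dist)]
      ks_drawn <- pmin(ks_drawn, sum(w > 0))
      # Gumbel-key trick: top-k keys == weighted sampling w/o replacement
      keys <- matrix(log(w), nrow = length(idx), ncol = length(els),
                     byrow = TRUE) -
        log(-log(matrix(stats::runif(length(idx) * length(els)),
                        nrow = length(idx))))
      keys[, w == 0] <- -Inf
      ord <- apply(keys, 1L, order, decreasing = TRUE)
      members[idx] <- lapply(seq_along(idx), function(r)
        els[ord[seq_len(ks_drawn[r]), r]])
    } else if (params$model == "exclusive") {
      pick <- sample.int(length(els), length(idx), replace = TRUE, prob = w)
      members[idx] <- as.list(els[pick])
    } else { # independent
      p_join <- params$join_scale * w / max(w)
      joins <- matrix(stats::runif(length(idx) * length(els)),
                      nrow = length(idx)) <
        matrix(p_join, nrow = length(idx), ncol = length(els), byrow = TRUE)
      members[idx] <- lapply(seq_along(idx), function(r) els[joins[r, ]])
    }
    if (locus$boundary_active && params$boundary_block < 1) {
      crosses <- .crosses_boundary(locus, els)
      members[idx] <- lapply(members[idx], function(m) {
        cr <- crosses[m]
        keep <- !cr | stats::runif(length(m)) < params$boundary_block
        m[keep]
      })
    }
  }
  out <- data.frame(allele = seq_len(n), condition = condition,
                    replicate = as.integer(replicate),
                    model = params$model, stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("simulation_truth", "data.frame")
  out
}

#' Emit proximity-ligation concatemer reads from allele truth
#'
#' Each allele yields one read containing the viewpoint fragment, the
#' fragments of its complexed partners (each captured with `capture_prob`),
#' and 0..m background fragments drawn with probability proportional to
#' `(1 + distance to viewpoint)^(-decay_exponent)`. Fragment ids are
#' deduplicated within the read. Reads carry sonication outer ends around the
#' viewpoint fragment; with probability `duplication_rate` a read is
#' re-emitted as a PCR duplicate with ends jittered uniformly in
#' `+/- jitter` bp and the same duplicate-lineage id.
#'
#' @param truth A `simulation_truth` from [simulate_alleles()].
#' @param locus The `locus_model` used to generate it.
#' @param map A `fragment_map` of the locus reference.
#' @param params The `topology_params`.
#' @param seed Optional seed.
#' @return A data.frame of reads: `read_id`, `lineage`, `condition`,
#'   `replicate`, `left_end`, `right_end` and list-column `fragments`
#'   (sorted unique fragment ids, always including the viewpoint fragment).
#' @export
ligate_and_read <- function(truth, locus, map, params, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(map, "fragment_map"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  el_frag <- locate_fragment(map, locus$elements)
  names(el_frag) <- names(locus$elements)
  vp_frag <- el_frag[[locus$viewpoint]]
  vp_start <- map$fragments$start[vp_frag + 1L]
  vp_end <- map$fragments$end[vp_frag + 1L]
  vp_pos <- locus$elements[[locus$viewpoint]]

  # complexed partner fragments, captured per element
  mlen <- lengths(truth$members)
  long_read <- rep.int(seq_len(n), mlen)
  long_frag <- el_frag[unlist(truth$members, use.names = FALSE)]
  captured <- stats::runif(length(long_frag)) < params$capture_prob
  long_read <- long_read[captured]
  long_frag <- long_frag[captured]

  # background reporters: distance-decay draw over all non-viewpoint fragments
  mids <- (map$fragments$start + map$fragments$end) / 2
  bg_w <- (1 + abs(mids - vp_pos))^(-params$decay_exponent)
  bg_w[vp_frag + 1L] <- 0
  n_bg <- sample.int(length(params$background_dist), n, replace = TRUE,
                     prob = params$background_dist) - 1L
  tot_bg <- sum(n_bg)
  if (tot_bg > 0) {
    bg_frag <- sample.int(nrow(map$fragments), tot_bg, replace = TRUE,
                          prob = bg_w) - 1L
    long_read <- c(long_read, rep.int(seq_len(n), n_bg))
    long_frag <- c(long_frag, bg_frag)
  }

  dt <- data.table::data.table(read = c(seq_len(n), long_read),
                               frag = c(rep.int(vp_frag, n),
                                        as.integer(long_frag)))
  dt <- unique(dt)
  data.table::setorder(dt, read, frag)
  frag_list <- split(dt$frag, factor(dt$read, levels = seq_len(n)))
  names(frag_list) <- NULL

  left <- vp_start - sample.int(params$sonication_offset, n,
                                replace = TRUE) + 1L
  right <- vp_end + sample.int(params$sonication_offset, n,
                               replace = TRUE) - 1L
  ids <- sprintf("%s_rep%d_r%05d", truth$condition, truth$replicate,
                 truth$allele)
  reads <- data.frame(read_id = ids, lineage = ids,
                      condition = truth$condition,
                      replicate = truth$replicate,
                      left_end = left, right_end = right,
                      stringsAsFactors = FALSE)
  reads$fragments <- frag_list

  dup <- stats::runif(n) < params$duplication_rate
  if (any(dup)) {
    d <- reads[dup, , drop = FALSE]
    d$read_id <- paste0(d$read_id, "_dup")
    if (params$jitter > 0) {
      d$left_end <- d$left_end +
        sample.int(2L * params$jitter + 1L, nrow(d), replace = TRUE) -
        params$jitter - 1L
      d$right_end <- d$right_end +
        sample.int(2L * params$jitter + 1L, nrow(d), replace = TRUE) -
        params$jitter - 1L
    }
    reads <- rbind(reads, d)
    rownames(reads) <- NULL
  }
  reads
}

#' Render simulated reads as FASTQ records
#'
#' Concatenates each read's fragment sequences in random order and random
#' orientation into one concatemer. Ligation of sticky-ended restriction
#' fragments regenerates the recognition site at every junction, so junctions
#' are normalized to carry exactly one copy of the site (on the side implied
#' by the cut offset); in-silico re-digestion then recovers the original
#' fragments. Record names encode `read_id|lineage` so tests can join back
#' to the truth.
#'
#' @param reads Read table from [ligate_and_read()].
#' @param map The `fragment_map`.
#' @param sequence Reference sequence (character).
#' @param enzyme The `enzyme_spec` used for digestion (junction chemistry);
#'   default NlaIII.
#' @param read_length Optional trim length in bp; NULL keeps full concatemers.
#' @param seed Optional seed for the shuffle/orientation draws.
#' @return A data.frame with `name`, `seq`, `qual`.
#' @export
render_fastq <- function(reads, map, sequence, enzyme = NULL,
                         read_length = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(enzyme)) enzyme <- tricontact::enzyme("NlaIII")
  if (nrow(reads) == 0L)
    return(data.frame(name = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  frag_seq <- substring(sequence, map$fragments$start + 1L,
                        map$fragments$end)
  site <- enzyme$recognition_site
  L <- nchar(site)
  # cut downstream of the site (NlaIII): the site travels with the left
  # piece at each junction; cut upstream (DpnII): with the right piece
  left_carry <- enzyme$cut_offset * 2L >= L
  has_prefix <- function(s) substr(s, 1L, L) == site
  has_suffix <- function(s) substr(s, nchar(s) - L + 1L, nchar(s)) == site
  n_trunc <- 0L
  seqs <- vapply(seq_len(nrow(reads)), function(i) {
    fr <- reads$fragments[[i]]
    pieces <- frag_seq[fr + 1L]
    ord <- sample.int(length(pieces))
    pieces <- pieces[ord]
    flip <- stats::runif(length(pieces)) < 0.5
    if (any(flip))
      pieces[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(pieces[flip])))
    np <- length(pieces)
    if (np > 1L) {
      for (j in seq_len(np - 1L)) {  # normalize each ligation junction
        if (left_carry) {
          if (!has_suffix(pieces[j]))
            pieces[j] <- paste0(pieces[j], site)
          if (has_prefix(pieces[j + 1L]))
            pieces[j + 1L] <- substr(pieces[j + 1L], L + 1L,
                                     nchar(pieces[j + 1L]))
        } else {
          if (!has_prefix(pieces[j + 1L]))
            pieces[j + 1L] <- paste0(site, pieces[j + 1L])
          if (has_suffix(pieces[j]))
            pieces[j] <- substr(pieces[j], 1L, nchar(pieces[j]) - L)
        }
      }
    }
    s <- paste0(pieces, collapse = "")
    if (!is.null(read_length) && nchar(s) > read_length) {
      if (!read_length %in% cumsum(nchar(pieces)))
        n_trunc <<- n_trunc + 1L
      s <- substr(s, 1L, read_length)
    }
    s
  }, character(1))
  if (n_trunc > 0L)
    warning(n_trunc, " read(s) truncated mid-fragment by read_length")
  data.frame(name = paste0(reads$read_id, "|", reads$lineage),
             seq = seqs, qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#' @param fastq Data.frame with `name`, `seq`, `qual`.
#' @param path Output path; ".gz" suffix gzip-compresses.
#' @export
write_fastq <- function(fastq, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(fastq))
    writeLines(paste0("@", fastq$name, "\n", fastq$seq, "\n+\n", fastq$qual),
               con)
  invisible(path)
}

#' Read FASTQ records
#' @param path FASTQ path (optionally gzipped).
#' @return Data.frame with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  if (length(lines) == 0L)
    return(data.frame(name = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  i <- seq(1L, length(lines), by = 4L)
  data.frame(name = sub("^@", "", lines[i]), seq = lines[i + 1L],
             qual = lines[i + 3L], stringsAsFactors = FALSE)
}

#' Generate a random locus reference sequence
#'
#' Uniform-composition DNA used as the toy reference for simulation and
#' round-trip tests.
#'
#' @param locus A `locus_model` (provides length).
#' @param seed Seed for the base draw.
#' @return Character string of length `region_length`.
#' @export
random_locus_sequence <- function(locus, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), locus$region_length, replace = TRUE),
         collapse = "")
}

#' Simulate a full multi-replicate, two-condition experiment
#'
#' Runs [simulate_alleles()] and [ligate_and_read()] for each condition and
#' biological replicate. Conditions map onto the boundary state:
#' "intact" keeps the boundary active, "deleted" removes it. Per-replicate
#' seeds are derived reproducibly from the master seed.
#'
#' @param locus A `locus_model`.
#' @param params A `topology_params` with a non-NULL `seed`.
#' @param map A `fragment_map`.
#' @param conditions Character vector of condition names (subset of
#'   c("deleted", "intact")).
#' @param n_replicates Replicates per condition.
#' @return List with `truth` (row-bound truth tables) and `reads` (row-bound
#'   read tables).
#' @export
simulate_experiment <- function(locus, params, map,
                                conditions = c("deleted", "intact"),
                                n_replicates = params$n_replicates) {
  if (is.null(params$seed)) stop("params$seed is required for simulation")
  stopifnot(all(conditions %in% c("deleted", "intact")))
  set.seed(as.integer(params$seed))
  subseeds <- matrix(sample.int(2^30, length(conditions) * n_replicates * 2L),
                     ncol = 2L)
  truth_all <- list(); reads_all <- list(); k <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    loc <- locus
    loc$boundary_active <- identical(cond, "intact")
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      tr <- simulate_alleles(loc, params, condition = cond, replicate = r,
                             seed = subseeds[k, 1L])
      rd <- ligate_and_read(tr, loc, map, params, seed = subseeds[k, 2L])
      truth_all[[k]] <- tr
      reads_all[[k]] <- rd
    }
  }
  truth <- do.call(rbind, truth_all)
  class(truth) <- c("simulation_truth", "data.frame")
  list(truth = truth, reads = do.call(rbind, reads_all))
}

#' Write simulated reads as a fragment-list TSV
#'
#' Columns: read_id, lineage, condition, replicate, left_end, right_end,
#' fragments (comma-separated ids). This is also the pre-segmented input
#' format accepted by the processing stage.
#'
#' @param reads Read table.
#' @param path Output path.
#' @export
write_reads_tsv <- function(reads, path) {
  df <- reads
  df$fragments <- vapply(df$fragments, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment-list TSV written by [write_reads_tsv()]
#' @param path Input path.
#' @return Read table with list-column `fragments`.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(fragments = "character"))
  df$fragments <- lapply(strsplit(df$fragments, ","), as.integer)
  df
}

#' Write allele truth records as TSV
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- as.data.frame(truth)
  df$members <- vapply(df$members, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
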