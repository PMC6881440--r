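#' Viewpoint specification for reporter extraction
#'
#' @param name Viewpoint name.
#' @param fragments Integer id(s) of the viewpoint restriction fragment(s).
#' @param proximity_radius Exclusion radius in bp around the viewpoint
#'   fragment (default 1000); reporters on fragments overlapping the window
#'   are dominated by random polymer proximity and are removed.
#' @param excluded_fragments Fragment ids targeted by other capture
#'   oligonucleotides in a multiplexed design; reporters on them are removed.
#' @return A `viewpoint_spec`.
#' @export
viewpoint_spec <- function(name, fragments, proximity_radius = 1000L,
                           excluded_fragments = integer(0)) {
  fragments <- as.integer(fragments)
  excluded_fragments <- as.integer(excluded_fragments)
  if (proximity_radius < 0) stop("proximity_radius must be >= 0")
  if (length(intersect(fragments, excluded_fragments)))
    stop("viewpoint fragments cannot be in excluded_fragments")
  structure(list(name = name, fragments = fragments,
                 proximity_radius = as.integer(proximity_radius),
                 excluded_fragments = excluded_fragments),
            class = "viewpoint_spec")
}

#' Build a viewpoint spec from a locus element
#'
#' Convenience wrapper resolving an element position to its restriction
#' fragment.
#'
#' @param locus A `locus_model`.
#' @param map A `fragment_map`.
#' @param name Element name (default: the locus viewpoint).
#' @param ... Passed to [viewpoint_spec()].
#' @return A `viewpoint_spec`.
#' @export
viewpoint_from_locus <- function(locus, map, name = locus$viewpoint, ...) {
  viewpoint_spec(name, locate_fragment(map, locus$elements[[name]]), ...)
}

#' Segment concatemer reads and map them to restriction fragments
#'
#' Splits each read sequence in silico at every recognition-site occurrence
#' (cut offset applied), then locates each segment of at least
#' `min_segment_length` bp in the reference by exact match on either strand.
#' A uniquely matching segment is converted to a fragment id through the
#' midpoint of its match; ambiguous or unmatched segments are dropped and
#' counted. Reads in which no segment maps are dropped.
#'
#' @param fastq Data.frame with `name` and `seq` (see [read_fastq()]).
#' @param reference Reference sequence (character string).
#' @param map `fragment_map` of the reference.
#' @param enzyme The `enzyme_spec` used for digestion.
#' @param min_segment_length Minimum mappable segment length (default 20 bp).
#' @return Data.frame with `read_id`, `lineage` (parsed from names of the
#'   form "id|lineage", else equal to `read_id`) and list-column `fragments`
#'   (sorted unique ids); attribute `stats` counts dropped segments/reads.
#' @export
segment_and_map <- function(fastq, reference, map, enzyme,
                            min_segment_length = 20L) {
  if (missing(reference) || is.null(reference))
    stop("a reference sequence is required to map FASTQ segments")
  stopifnot(inherits(map, "fragment_map"), inherits(enzyme, "enzyme_spec"))
  ref <- Biostrings::DNAString(reference)
  site <- enzyme$recognition_site
  off <- enzyme$cut_offset
  pat <- paste0("(?=", site, ")")

  n_unmapped_seg <- 0L; n_dropped_reads <- 0L
  ids <- character(0); lineages <- character(0); frags <- list()
  for (i in seq_len(nrow(fastq))) {
    s <- toupper(fastq$seq[i])
    len <- nchar(s)
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    bounds <- if (hits[1] == -1L) integer(0) else
      as.integer(hits) - 1L + off
    bounds <- sort(unique(bounds[bounds > 0L & bounds < len]))
    starts <- c(0L, bounds); ends <- c(bounds, len)
    keep <- (ends - starts) >= min_segment_length
    fr <- integer(0)
    for (k in which(keep)) {
      seg <- Biostrings::DNAString(substr(s, starts[k] + 1L, ends[k]))
      m_f <- Biostrings::matchPattern(seg, ref)
      m_r <- Biostrings::matchPattern(Biostrings::reverseComplement(seg), ref)
      n_hits <- length(m_f) + length(m_r)
      if (n_hits != 1L) {
        n_unmapped_seg <- n_unmapped_seg + 1L
        next
      }
      rng <- if (length(m_f)) m_f else m_r
      mid <- (Biostrings::start(rng) - 1L + Biostrings::end(rng) - 1L) %/% 2L
      fr <- c(fr, locate_fragment(map, mid))
    }
    n_unmapped_seg <- n_unmapped_seg + sum(!keep)
    if (length(fr) == 0L) {
      n_dropped_reads <- n_dropped_reads + 1L
      next
    }
    nm <- strsplit(fastq$name[i], "|", fixed = TRUE)[[1]]
    ids <- c(ids, nm[1])
    lineages <- c(lineages, if (length(nm) > 1L) nm[2] else nm[1])
    frags[[length(frags) + 1L]] <- sort(unique(fr))
  }
  out <- data.frame(read_id = ids, lineage = lineages,
                    stringsAsFactors = FALSE)
  out$fragments <- frags
  attr(out, "stats") <- list(unmapped_segments = n_unmapped_seg,
                             dropped_reads = n_dropped_reads)
  out
}

#' Extract filtered reporter reads for a viewpoint
#'
#' Keeps only reads containing a viewpoint fragment, then removes from the
#' reporter set, in order: the viewpoint fragment(s) themselves; fragments
#' targeted by other capture oligos; fragments overlapping the proximity
#' window `[viewpoint_start - radius, viewpoint_end + radius)`; and fragments
#' immediately adjacent to a viewpoint fragment (re-ligation artefacts).
#' Reads left without reporters are discarded. The surviving set is
#' independent of the order in which the filters are applied.
#'
#' @param reads Read table with list-column `fragments` (from
#'   [ligate_and_read()], [segment_and_map()] or [read_reads_tsv()]).
#' @param vp A `viewpoint_spec`.
#' @param map The `fragment_map`.
#' @return A `reporter_reads` data.frame: original read columns plus
#'   `viewpoint` and list-column `reporters`; attribute `stats` holds the
#'   filtering funnel counts in application order.
#' @export
extract_reporters <- function(reads, vp, map) {
  stopifnot(inherits(vp, "viewpoint_spec"), inherits(map, "fragment_map"))
  vfr <- vp$fragments
  win_lo <- min(map$fragments$start[vfr + 1L]) - vp$proximity_radius
  win_hi <- max(map$fragments$end[vfr + 1L]) + vp$proximity_radius
  overlaps_win <- map$fragments$end > win_lo & map$fragments$start < win_hi
  adjacent <- unique(c(vfr - 1L, vfr + 1L))
  adjacent <- adjacent[adjacent >= 0L & adjacent < nrow(map$fragments) &
                         !adjacent %in% vfr]

  # long-format pass over all fragments at once
  nlen <- lengths(reads$fragments)
  ridx <- rep.int(seq_len(nrow(reads)), nlen)
  frag <- unlist(reads$fragments, use.names = FALSE)
  is_vp <- frag %in% vfr
  has_vp <- tabulate(ridx[is_vp], nbins = nrow(reads)) > 0L
  n_no_vp <- sum(!has_vp)

  live <- has_vp[ridx] & !is_vp
  drop_oligo <- live & frag %in% vp$excluded_fragments
  live <- live & !drop_oligo
  drop_prox <- live & overlaps_win[frag + 1L]
  live <- live & !drop_prox
  drop_adj <- live & frag %in% adjacent
  live <- live & !drop_adj
  n_oligo <- sum(drop_oligo); n_prox <- sum(drop_prox)
  n_adj <- sum(drop_adj)

  kept_rows <- which(has_vp)
  kept <- reads[kept_rows, , drop = FALSE]
  reporters <- unname(split(frag[live],
                            factor(ridx[live], levels = kept_rows)))
  n_rep <- lengths(reporters)
  n_reporterless <- sum(n_rep == 0L)
  out <- kept[n_rep > 0L, setdiff(names(kept), "fragments"), drop = FALSE]
  out$viewpoint <- vp$name
  out$reporters <- reporters[n_rep > 0L]
  rownames(out) <- NULL
  class(out) <- c("reporter_reads", "data.frame")
  attr(out, "stats") <- list(input_reads = nrow(reads),
                             no_viewpoint = n_no_vp,
                             oligo_excluded_reporters = n_oligo,
                             proximity_excluded_reporters = n_prox,
                             adjacent_excluded_reporters = n_adj,
                             reporterless_reads = n_reporterless,
                             surviving_reads = nrow(out))
  out
}

#' Remove PCR duplicates by fragment set and wobbly sonication ends
#'
#' Reads with identical sorted reporter fragment sets whose outer sonication
#' ends fall in the same `wobble`-bp genomic bin (fixed bins,
#' `floor(end / wobble)`) are collapsed to one; the read with the
#' lexicographically smallest id is kept. With `wobble = 0` ends must match
#' exactly.
#'
#' @param reads A `reporter_reads` table with `left_end`/`right_end`.
#' @param wobble Wobbly-end bin width in bp (default 6).
#' @return Deduplicated `reporter_reads`; attribute `stats` reports the
#'   number of collapsed reads.
#' @export
remove_duplicates <- function(reads, wobble = 6L) {
  stopifnot(wobble >= 0)
  if (nrow(reads) == 0L) {
    attr(reads, "stats") <- list(collapsed = 0L)
    return(reads)
  }
  fr_key <- vapply(reads$reporters, function(f)
    paste(sort(f), collapse = ","), character(1))
  lb <- if (wobble > 0) floor(reads$left_end / wobble) else reads$left_end
  rb <- if (wobble > 0) floor(reads$right_end / wobble) else reads$right_end
  key <- paste(fr_key, lb, rb, sep = "|")
  ord <- order(key, reads$read_id)
  first <- ord[!duplicated(key[ord])]
  out <- reads[sort(first), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reporter_reads", "data.frame")
  attr(out, "stats") <- list(collapsed = nrow(reads) - nrow(out))
  out
}

#' Split surviving reads by reporter multiplicity
#'
#' Pairwise-only reads (exactly 1 reporter) feed pairwise profiles; multi-way
#' reads (>= 2 reporters) feed the contact matrices. The two sets partition
#' the surviving reads.
#'
#' @param reads A `reporter_reads` table.
#' @return List with `pairwise` and `multiway` subsets.
#' @export
split_by_multiplicity <- function(reads) {
  k <- lengths(reads$reporters)
  list(pairwise = reads[k == 1L, , drop = FALSE],
       multiway = reads[k >= 2L, , drop = FALSE])
}

#' Write reporter reads as TSV
#' @param reads A `reporter_reads` table.
#' @param path Output path.
#' @export
write_reporters_tsv <- function(reads, path) {
  df <- as.data.frame(reads)
  df$reporters <- vapply(df$reporters, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
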