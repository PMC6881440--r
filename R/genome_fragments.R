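#' Restriction enzyme specification
#'
#' Defines the recognition site and cut offset used for in-silico digestion.
#' The cut offset is the number of base pairs from the start of the
#' recognition site at which the fragment boundary is placed: DpnII (^GATC)
#' cuts before the site (offset 0), NlaIII (CATG^) after it (offset 4).
#'
#' @param name Short identifier, e.g. "DpnII".
#' @param recognition_site Upper-case DNA string over \{A,C,G,T\}.
#' @param cut_offset Integer in `[0, nchar(recognition_site)]`.
#' @return An object of class `enzyme_spec`.
#' @export
#' @examples
#' enzyme_spec("DpnII", "GATC", 0)
enzyme_spec <- function(name, recognition_site, cut_offset) {
  if (!is.character(recognition_site) || nchar(recognition_site) == 0L)
    stop("recognition_site must be a non-empty DNA string")
  recognition_site <- toupper(recognition_site)
  if (grepl("[^ACGT]", recognition_site))
    stop("recognition_site may only contain A, C, G, T")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L ||
      cut_offset > nchar(recognition_site))
    stop("cut_offset must lie in [0, nchar(recognition_site)]")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' Look up a predefined restriction enzyme
#'
#' @param name One of "DpnII" or "NlaIII" (case-insensitive), the two
#'   four-cutters commonly used for Capture-C and Tri-C library preparation.
#' @return An `enzyme_spec`.
#' @export
enzyme <- function(name) {
  key <- tolower(name)
  presets <- list(
    dpnii  = list("DpnII",  "GATC", 0L),
    nlaiii = list("NlaIII", "CATG", 4L)
  )
  if (!key %in% names(presets))
    stop("unknown enzyme '", name, "'; use enzyme_spec() for custom enzymes")
  do.call(enzyme_spec, presets[[key]])
}

#' @export
print.enzyme_spec <- function(x, ...) {
  site <- x$recognition_site
  marked <- paste0(substr(site, 1, x$cut_offset), "^",
                   substr(site, x$cut_offset + 1, nchar(site)))
  cat("<enzyme_spec>", x$name, marked, "\n")
  invisible(x)
}

#' In-silico restriction digestion of a reference sequence
#'
#' Scans the forward strand for every (possibly overlapping) occurrence of the
#' recognition site and places a fragment boundary at `site_start + cut_offset`.
#' For palindromic sites (DpnII, NlaIII) this is strand-symmetric. `N` bases
#' never match a site. Coordinates are 0-based half-open.
#'
#' @param sequence DNA as a character string (or `Biostrings::DNAString`),
#'   alphabet \{A,C,G,T,N\}.
#' @param enzyme An `enzyme_spec`.
#' @param chrom Sequence name recorded in the map.
#' @return A `fragment_map`: list with `chrom`, `seqlen`, and `fragments`, a
#'   data.frame with columns `id` (0-based, coordinate-ordered), `start`, `end`
#'   (0-based half-open). Fragments tile the sequence without gaps or overlaps.
#' @export
#' @examples
#' m <- digest_reference("GGGATCCAGATCA", enzyme("DpnII"))
#' m$fragments
digest_reference <- function(sequence, enzyme, chrom = "seq") {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len == 0L) stop("sequence is empty")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may only contain A, C, G, T, N")
  stopifnot(inherits(enzyme, "enzyme_spec"))

  # lookahead regex finds overlapping site occurrences
  hits <- gregexpr(paste0("(?=", enzyme$recognition_site, ")"),
                   sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    bounds <- integer(0)
  } else {
    bounds <- as.integer(hits) - 1L + enzyme$cut_offset
    bounds <- sort(unique(bounds[bounds > 0L & bounds < len]))
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, len)
  structure(list(
    chrom = chrom,
    seqlen = len,
    fragments = data.frame(id = seq_along(starts) - 1L,
                           start = starts, end = ends)
  ), class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map>", x$chrom, ":", nrow(x$fragments), "fragments over",
      x$seqlen, "bp\n")
  print(utils::head(x$fragments, 5))
  if (nrow(x$fragments) > 5) cat("...\n")
  invisible(x)
}

#' Locate the fragment containing a position
#'
#' Binary-search lookup (via `findInterval`) of the unique fragment with
#' `start <= pos < end`. Vectorised over `pos`.
#'
#' @param map A `fragment_map`.
#' @param pos 0-based position(s), each in `[0, seqlen)`.
#' @return Integer fragment id(s).
#' @export
locate_fragment <- function(map, pos) {
  stopifnot(inherits(map, "fragment_map"))
  pos <- as.numeric(pos)
  if (any(pos < 0 | pos >= map$seqlen))
    stop("position out of range [0, ", map$seqlen, ")")
  findInterval(pos, map$fragments$start) - 1L
}

#' Define a bin grid over a region
#'
#' Bins partition `[region_start, region_end)` in `bin_size` steps; the last
#' bin is shortened if the region length is not a multiple of `bin_size`.
#'
#' @param chrom Sequence name.
#' @param region_start,region_end Region in 0-based bp.
#' @param bin_size Bin width in bp (default 1000, the working resolution for
#'   multi-way contact matrices).
#' @return A `bin_grid` with per-bin `start`, `end` and `center` vectors.
#' @export
bin_grid <- function(chrom, region_start, region_end, bin_size = 1000L) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) stop("bin_size must be > 0")
  if (region_end <= region_start) stop("region_end must exceed region_start")
  starts <- seq.int(region_start, region_end - 1L, by = bin_size)
  ends <- pmin(starts + bin_size, region_end)
  structure(list(chrom = chrom, region_start = region_start,
                 region_end = region_end, bin_size = bin_size,
                 start = starts, end = ends,
                 center = (starts + ends) / 2,
                 n_bins = length(starts)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid>", x$chrom, ":", sprintf("[%d,%d)", x$region_start,
      x$region_end), "in", x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Assign restriction fragments to bins
#'
#' Each fragment is assigned to the bin containing its midpoint
#' `floor((start + end) / 2)`; fragments whose midpoint falls outside the grid
#' are unassigned. The per-bin fragment count is the exposure used by the
#' fragment-density correction during matrix normalization.
#'
#' @param map A `fragment_map`.
#' @param grid A `bin_grid`.
#' @return List with `bin`: 1-based bin index per fragment (NA if outside the
#'   grid), and `counts`: fragments per bin (length `grid$n_bins`, may be 0).
#' @export
fragment_to_bin <- function(map, grid) {
  stopifnot(inherits(map, "fragment_map"), inherits(grid, "bin_grid"))
  mids <- (map$fragments$start + map$fragments$end) %/% 2L
  inside <- mids >= grid$region_start & mids < grid$region_end
  bin <- rep(NA_integer_, length(mids))
  bin[inside] <- findInterval(mids[inside], grid$start)
  list(bin = bin, counts = tabulate(bin[inside], nbins = grid$n_bins))
}

#' Map arbitrary positions to bins
#'
#' @param grid A `bin_grid`.
#' @param pos 0-based positions.
#' @return 1-based bin indices (NA outside the grid).
#' @export
position_to_bin <- function(grid, pos) {
  stopifnot(inherits(grid, "bin_grid"))
  out <- rep(NA_integer_, length(pos))
  inside <- pos >= grid$region_start & pos < grid$region_end
  out[inside] <- findInterval(pos[inside], grid$start)
  out
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file (may be multi-record).
#' @param chrom Record name to use; default the first record.
#' @return List with `chrom` and `sequence` (character).
#' @export
read_reference_fasta <- function(path, chrom = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  idx <- if (is.null(chrom)) 1L else match(chrom, nm)
  if (is.na(idx)) stop("record '", chrom, "' not found in ", path)
  list(chrom = nm[idx], sequence = as.character(seqs[[idx]]))
}

#' Write a fragment map as BED3+1
#'
#' Columns: chrom, start, end, fragment id (BED conventions, 0-based
#' half-open).
#'
#' @param map A `fragment_map`.
#' @param path Output file.
#' @export
write_fragment_map <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  df <- data.frame(chrom = map$chrom, start = map$fragments$start,
                   end = map$fragments$end, name = map$fragments$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment map from BED3+1
#'
#' The fragments must tile a contiguous region starting at 0; ids are
#' renumbered 0..n-1 in coordinate order.
#'
#' @param path BED file written by [write_fragment_map()].
#' @return A `fragment_map`.
#' @export
read_fragment_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "integer", "integer",
                                         "integer"))
  df <- df[order(df$start), ]
  if (df$start[1] != 0L || any(df$start[-1] != df$end[-nrow(df)]))
    stop("fragments do not tile the sequence from 0 without gaps/overlaps")
  structure(list(chrom = df$chrom[1], seqlen = df$end[nrow(df)],
                 fragments = data.frame(id = seq_len(nrow(df)) - 1L,
                                        start = df$start, end = df$end)),
            class = "fragment_map")
}

#' Write a bin grid as BED3+1 (name column = 0-based bin index)
#' @param grid A `bin_grid`.
#' @param path Output file.
#' @export
write_bin_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bin_grid"))
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   name = seq_len(grid$n_bins) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
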