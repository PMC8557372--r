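# Fragment -> insertion-site conversion and track IO.
#
# Tn5 transposition duplicates a 9-bp target site; the insertion-event center
# is recovered by shifting the fragment 5' end +4 bp on the forward strand and
# the 3' end (half-open) -5 bp on the reverse strand. Both shifted positions
# of one 9-bp duplication coincide.

#' Shift fragments to single-base insertion-event centers
#'
#' Applies the +4 (forward) / -5 (reverse, on the half-open end) shift to each
#' fragment, producing one '+' and one '-' insertion site per fragment.
#' Fragments shorter than 9 bp cannot span a full target-site duplication and
#' are rejected (counted, not fatal).
#'
#' @param fragments data frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return list with `sites` (aggregated insertion-site data frame) and
#'   `n_rejected` (fragments shorter than 9 bp).
#' @examples
#' f <- data.frame(contig = "c1", start = 100L, end = 200L)
#' shift_fragments(f)$sites  # pos 104 '+' and 195 '-'
#' @export
shift_fragments <- function(fragments) {
  stopifnot(all(c("contig", "start", "end") %in% names(fragments)))
  len <- fragments$end - fragments$start
  stopifnot(all(len > 0))
  keep <- len >= 9L
  n_rejected <- sum(!keep)
  f <- fragments[keep, , drop = FALSE]
  sites <- new_sites(
    contig = rep(f$contig, 2L),
    pos = c(f$start + 4L, f$end - 5L),
    strand = rep(c("+", "-"), each = nrow(f)),
    count = rep(1L, 2L * nrow(f))
  )
  list(sites = aggregate_sites(sites), n_rejected = n_rejected)
}

#' Fragment size distribution
#'
#' @param fragments fragment data frame.
#' @return data frame (`length`, `count`); empty for empty input.
#' @export
fragment_size_distribution <- function(fragments) {
  if (nrow(fragments) == 0)
    return(data.frame(length = integer(), count = integer()))
  tab <- table(fragments$end - fragments$start)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Write insertion sites as BED6 or bedGraph
#'
#' BED6 rows are `(contig, pos, pos+1, ., count, strand)`; bedGraph rows merge
#' strands to `(contig, pos, pos+1, summed count)`. A write/read round trip
#' reproduces the sites.
#'
#' @param sites insertion-site data frame, sorted by (contig, pos); unsorted
#'   input is sorted with a warning.
#' @param path output file.
#' @param format `"bed"` or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_insertion_track <- function(sites, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  ord <- order(sites$contig, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    warning("sites were not sorted by (contig, pos); sorting")
    sites <- sites[ord, , drop = FALSE]
  }
  if (format == "bedgraph") sites <- merge_site_strands(sites)
  gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = if (format == "bed") ifelse(sites$strand %in% c("+", "-"),
                                         sites$strand, "*") else "*",
    score = as.numeric(sites$count)
  )
  if (format == "bed") {
    rtracklayer::export(gr, path, format = "BED")
  } else {
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read insertion sites from BED6
#' @param path BED file written by [write_insertion_track()] (or compatible).
#' @return insertion-site data frame.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "*"
  score <- gr$score
  if (is.null(score)) score <- rep(1, length(gr))
  sort_sites(new_sites(
    contig = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = strand,
    count = as.integer(score)
  ))
}

#' Read a bedGraph track
#' @param path bedGraph file.
#' @return data frame (`contig`, `start`, `end`, `value`), 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#' @param df data frame (`contig`, `start`, `end`, `value`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = as.numeric(df$value))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read fragments from a BED3+ file
#' @param path BED file of fragment intervals.
#' @return fragment data frame (`contig`, `start`, `end`).
#' @export
read_fragments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_df(gr)
  out[order(out$contig, out$start, out$end), , drop = FALSE]
}

#' Write fragments as BED3
#' @param fragments fragment data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- as_granges(fragments)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED3 interval file
#' @param path BED file.
#' @return interval data frame (`contig`, `start`, `end`).
#' @export
read_bed3 <- function(path) {
  granges_to_df(rtracklayer::import(path, format = "BED"))
}
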