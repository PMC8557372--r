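# Genome container and interval primitives. Coordinates are 0-based half-open
# (BED convention) everywhere inside the package; 1-based formats are converted
# at the boundary.

new_genome <- function(seqs, blacklist = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  n_nonN <- vapply(seqs, function(s) {
    sum(!is.na(.base_code_table[utf8ToInt(s)]))
  }, integer(1))
  mappable <- sum(n_nonN)
  bl <- NULL
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    missing <- setdiff(unique(blacklist$contig), names(seqs))
    if (length(missing)) {
      warning("blacklist contigs absent from genome, skipped: ",
              paste(missing, collapse = ", "))
      blacklist <- blacklist[!blacklist$contig %in% missing, , drop = FALSE]
    }
    bl <- merge_intervals(blacklist)
    if (nrow(bl) > 0) {
      excl <- 0L
      for (i in seq_len(nrow(bl))) {
        s <- substr(seqs[[bl$contig[i]]], bl$start[i] + 1L, bl$end[i])
        excl <- excl + sum(!is.na(.base_code_table[utf8ToInt(s)]))
      }
      mappable <- mappable - excl
    }
  }
  structure(list(seq = seqs, contig_lengths = lens,
                 mappable_size = as.numeric(mappable), blacklist = bl),
            class = "tn5_genome")
}

#' Construct a genome from in-memory sequences
#'
#' @param seqs named character vector of contig sequences (uppercased on
#'   construction).
#' @param blacklist optional interval data frame excluded from the mappable
#'   size.
#' @return a `tn5_genome`.
#' @export
genome_from_seqs <- function(seqs, blacklist = NULL) {
  new_genome(seqs, blacklist = blacklist)
}

#' Load a genome from FASTA
#'
#' Sequences are uppercased on load. The mappable genome size is the number of
#' non-N bases, optionally minus non-N bases overlapping a blacklist (the
#' denominator of the expected-insertion formula).
#'
#' @param fasta_path path to a FASTA file.
#' @param blacklist optional interval data frame (`contig`, `start`, `end`,
#'   0-based half-open) of regions to exclude from the mappable size.
#' @return a `tn5_genome` object: named character sequences, per-contig
#'   lengths, `mappable_size`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTN"), fa)
#' g <- load_genome(fa)
#' g$mappable_size  # 4: N is not mappable
#' @export
load_genome <- function(fasta_path, blacklist = NULL) {
  ss <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                 error = function(e) stop("malformed FASTA: ",
                                          conditionMessage(e), call. = FALSE))
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  new_genome(seqs, blacklist = blacklist)
}

#' @export
print.tn5_genome <- function(x, ...) {
  cat("tn5_genome:", length(x$seq), "contig(s),",
      sum(x$contig_lengths), "bp,", x$mappable_size, "mappable bp\n")
  invisible(x)
}

genome_base_composition <- function(genome) {
  counts <- integer(4)
  for (s in genome$seq) {
    code <- .base_code_table[utf8ToInt(s)]
    counts <- counts + tabulate(code, nbins = 4L)
  }
  stats::setNames(counts / sum(counts), .BASES)
}

#' Extract fixed-width sequence windows centered on sites
#'
#' Windows containing N or falling off a contig end are returned as `NA`;
#' downstream encoders drop them (shape and PWM tables are undefined on N).
#'
#' @param genome a `tn5_genome`.
#' @param sites insertion-site data frame.
#' @param width odd window width in bp.
#' @return character vector of windows (NA where invalid), one per site row.
#' @export
site_windows <- function(genome, sites, width) {
  stopifnot(width %% 2 == 1)
  half <- (width - 1L) / 2L
  out <- rep(NA_character_, nrow(sites))
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    if (!ctg %in% names(genome$seq)) next
    L <- genome$contig_lengths[[ctg]]
    p <- sites$pos[idx]
    ok <- p - half >= 0 & p + half < L
    w <- rep(NA_character_, length(idx))
    w[ok] <- substring(genome$seq[[ctg]], p[ok] - half + 1L, p[ok] + half + 1L)
    w[!is.na(w) & grepl("[^ACGT]", w)] <- NA_character_
    out[idx] <- w
  }
  out
}

## ---- interval sets -------------------------------------------------------

as_granges <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals
#'
#' @param df interval data frame (`contig`, `start`, `end`, 0-based half-open).
#' @return merged, sorted interval data frame.
#' @export
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  granges_to_df(GenomicRanges::reduce(as_granges(df)))
}

#' Total merged length of an interval set
#' @param df interval data frame.
#' @return total bp after merging overlaps.
#' @export
interval_length <- function(df) {
  m <- merge_intervals(df)
  sum(as.numeric(m$end - m$start))
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$contig,
                         IRanges::IRanges(start = sites$pos + 1L, width = 1L))
}
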