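# Observed/expected insertion enrichment per genomic feature with chi-square
# goodness-of-fit and Benjamini-Hochberg FDR control.

#' Expected insertion count for a feature
#'
#' `E = merged feature length x (total insertion sites / mappable genome
#' size)` -- the uniform-insertion expectation.
#'
#' @param feature interval data frame; overlapping intervals are merged before
#'   measuring.
#' @param total_sites total insertion count genome-wide.
#' @param mappable_size mappable genome size in bp.
#' @return expected count (0 for a zero-length feature).
#' @export
expected_insertions <- function(feature, total_sites, mappable_size) {
  stopifnot(mappable_size > 0)
  len <- interval_length(feature)
  stopifnot(len <= mappable_size)
  len * total_sites / mappable_size
}

#' Observed insertion count inside a feature
#'
#' Counts strand-merged site counts at positions `p` with
#' `start <= p < end` in any merged interval (half-open convention).
#'
#' @param feature interval data frame.
#' @param sites insertion-site data frame.
#' @return integer total count.
#' @export
observed_insertions <- function(feature, sites) {
  if (nrow(feature) == 0 || nrow(sites) == 0) return(0L)
  m <- merge_intervals(feature)
  hits <- GenomicRanges::findOverlaps(sites_granges(sites), as_granges(m))
  sum(sites$count[unique(S4Vectors::queryHits(hits))])
}

.chisq_gof2 <- function(O, E, total, yates = FALSE) {
  o <- c(O, total - O)
  e <- c(E, total - E)
  d <- abs(o - e)
  if (yates) d <- pmax(0, d - 0.5)
  sum(d^2 / e)
}

#' Feature enrichment of Tn5 insertion
#'
#' For each feature, tests the (inside, outside) split of total insertions
#' against the uniform expectation with a two-cell chi-square goodness-of-fit
#' (df = 1), adjusts p-values across features by Benjamini-Hochberg, and
#' reports `log2(O/E)` (positive = enrichment, negative = depletion).
#'
#' @param features named list of interval data frames.
#' @param sites insertion-site data frame.
#' @param genome a `tn5_genome` (supplies the mappable size).
#' @param fdr significance threshold on the BH-adjusted q-value.
#' @param yates apply a continuity correction (off by default; intended use
#'   has large counts).
#' @param mappable_size optional override of `genome$mappable_size`.
#' @return data frame with `feature`, `O`, `E`, `log2_oe`, `chi2`, `p`, `q`,
#'   `significant`. Features with degenerate expectation (E = 0 or E = total)
#'   get NA statistics and are excluded from the FDR family.
#' @export
feature_enrichment <- function(features, sites, genome, fdr = 0.001,
                               yates = FALSE, mappable_size = NULL) {
  stopifnot(length(features) >= 1, !is.null(names(features)))
  M <- mappable_size %||% genome$mappable_size
  total <- sum(sites$count)
  res <- data.frame(feature = names(features),
                    O = NA_real_, E = NA_real_, log2_oe = NA_real_,
                    chi2 = NA_real_, p = NA_real_, q = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (i in seq_along(features)) {
    E <- expected_insertions(features[[i]], total, M)
    O <- observed_insertions(features[[i]], sites)
    res$O[i] <- O
    res$E[i] <- E
    if (E > 0 && O > 0) res$log2_oe[i] <- log2(O / E)
    if (E > 0 && total - E > 0) {
      chi2 <- .chisq_gof2(O, E, total, yates = yates)
      res$chi2[i] <- chi2
      res$p[i] <- pchisq(chi2, df = 1, lower.tail = FALSE)
    }
  }
  tested <- !is.na(res$p)
  res$q[tested] <- p.adjust(res$p[tested], method = "BH")
  res$significant[tested] <- res$q[tested] < fdr
  res
}

#' Sample-by-feature enrichment matrix with complete-linkage ordering
#'
#' Builds the `log2(O/E)` matrix across samples, masks non-significant cells
#' (NA), and clusters sample rows by complete linkage on Euclidean distance.
#' Clustering uses the unmasked values (distance on NA-holed rows is
#' undefined); masking applies to the returned display matrix.
#'
#' @param results named list of [feature_enrichment()] outputs, one per
#'   sample.
#' @return list with `matrix` (masked), `full` (unmasked), `order` (sample
#'   order), and `hclust` (NULL for a single sample).
#' @export
enrichment_matrix <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  feats <- results[[1]]$feature
  full <- t(vapply(results, function(r) {
    r$log2_oe[match(feats, r$feature)]
  }, numeric(length(feats))))
  colnames(full) <- feats
  rownames(full) <- names(results)
  masked <- full
  for (s in names(results)) {
    r <- results[[s]]
    sig <- r$significant[match(feats, r$feature)]
    masked[s, !(sig %in% TRUE)] <- NA
  }
  if (length(results) >= 2) {
    hc <- hclust(dist(full), method = "complete")
    ord <- rownames(full)[hc$order]
  } else {
    hc <- NULL
    ord <- rownames(full)
  }
  list(matrix = masked, full = full, order = ord, hclust = hc)
}

#' Write an enrichment table as TSV
#' @param res [feature_enrichment()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
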