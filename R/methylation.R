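# Context-dependent 9-mer procedure: tile the genome into 9-bp bins, classify
# bins by two-condition methylation into four groups, average insertion
# frequency per unique 9-mer, keep 9-mers shared by all four groups, and
# Z-scale per condition so insertion frequencies are comparable across
# conditions from different sources.

#' Tile the genome into 9-bp bins and annotate methylation and insertions
#'
#' Bin methylation is the unweighted mean percent methylation over covered
#' cytosines in the bin, per condition; bins with no covered cytosine get NA
#' (absent is distinct from 0: bisulfite coverage gaps must not masquerade as
#' unmethylated). Insertion counts are strand-merged sums of site counts per
#' bin (half-open membership). Bins containing N, or truncated at the contig
#' end, are dropped.
#'
#' @param genome a `tn5_genome`.
#' @param meth named list of two bedGraph-style per-cytosine percent tracks.
#' @param sites named list of two insertion-site data frames (same names).
#' @return data frame: `contig`, `start`, `end`, `ninemer`, `meth_<A>`,
#'   `meth_<B>`, `ins_<A>`, `ins_<B>` where A, B are the condition names.
#' @export
tile_and_annotate <- function(genome, meth, sites) {
  stopifnot(length(meth) == 2, length(sites) == 2,
            identical(names(meth), names(sites)),
            !is.null(names(meth)))
  conds <- names(meth)
  for (m in meth) {
    bad <- setdiff(unique(m$contig), names(genome$seq))
    if (length(bad)) stop("methylation track contig(s) not in genome: ",
                          paste(bad, collapse = ", "))
  }
  bins_list <- list()
  for (ctg in names(genome$seq)) {
    L <- genome$contig_lengths[[ctg]]
    n_bins <- L %/% 9L
    if (n_bins == 0) next
    start <- (seq_len(n_bins) - 1L) * 9L
    nin <- substring(genome$seq[[ctg]], start + 1L, start + 9L)
    ok <- !grepl("[^ACGT]", nin)
    b <- data.frame(contig = ctg, start = start[ok], end = start[ok] + 9L,
                    ninemer = nin[ok], stringsAsFactors = FALSE)
    for (cond in conds) {
      m <- meth[[cond]]
      m <- m[m$contig == ctg, , drop = FALSE]
      msum <- numeric(nrow(b)); mn <- integer(nrow(b))
      if (nrow(m) > 0) {
        bin_i <- match(m$start %/% 9L * 9L, b$start)
        keep <- !is.na(bin_i)
        agg_sum <- tapply(m$value[keep], bin_i[keep], sum)
        agg_n <- tapply(m$value[keep], bin_i[keep], length)
        msum[as.integer(names(agg_sum))] <- agg_sum
        mn[as.integer(names(agg_n))] <- agg_n
      }
      b[[paste0("meth_", cond)]] <- ifelse(mn > 0, msum / mn, NA_real_)
      s <- merge_site_strands(sites[[cond]][sites[[cond]]$contig == ctg, ,
                                            drop = FALSE])
      ins <- numeric(nrow(b))
      if (nrow(s) > 0) {
        bin_i <- match(s$pos %/% 9L * 9L, b$start)
        keep <- !is.na(bin_i)
        agg <- tapply(s$count[keep], bin_i[keep], sum)
        ins[as.integer(names(agg))] <- agg
      }
      b[[paste0("ins_", cond)]] <- ins
    }
    bins_list[[ctg]] <- b
  }
  out <- do.call(rbind, bins_list)
  rownames(out) <- NULL
  out
}

#' Classify bins into four methylation groups
#'
#' Using the two conditions' bin methylation means: `<A>-only` (> 0 in A,
#' = 0 in B), `<B>-only`, `Both` (> 0 in both), `None` (= 0 in both). Bins
#' with absent (NA) methylation in either condition are ineligible and
#' excluded.
#'
#' @param bins output of [tile_and_annotate()].
#' @return eligible bins with a `group` column.
#' @export
classify_groups <- function(bins) {
  mcols <- grep("^meth_", names(bins), value = TRUE)
  stopifnot(length(mcols) == 2)
  conds <- sub("^meth_", "", mcols)
  a <- bins[[mcols[1]]]
  b <- bins[[mcols[2]]]
  eligible <- !is.na(a) & !is.na(b)
  out <- bins[eligible, , drop = FALSE]
  a <- a[eligible]; b <- b[eligible]
  out$group <- ifelse(a > 0 & b > 0, "Both",
               ifelse(a > 0, paste0(conds[1], "-only"),
               ifelse(b > 0, paste0(conds[2], "-only"), "None")))
  rownames(out) <- NULL
  out
}

#' Per-9-mer insertion profile with shared filter and Z-scaling
#'
#' For each (9-mer, group, condition): the mean insertion frequency over all
#' bins carrying that 9-mer in that group. 9-mers absent from any of the four
#' groups are dropped (the shared filter that equalizes sequence context
#' across groups). Z-scores are computed per condition across all retained
#' (9-mer, group) means, making conditions from different sources comparable.
#'
#' @param bins classified bins (see [classify_groups()]).
#' @return data frame `ninemer`, `group`, plus per condition `mean_<cond>`
#'   and `z_<cond>`; empty (with a warning) if no 9-mer survives the filter.
#' @export
ninemer_profile <- function(bins) {
  stopifnot("group" %in% names(bins))
  icols <- grep("^ins_", names(bins), value = TRUE)
  conds <- sub("^ins_", "", icols)
  groups <- c(grep("-only$", unique(bins$group), value = TRUE),
              "Both", "None")
  groups <- unique(groups)
  key <- paste(bins$ninemer, bins$group, sep = "\r")
  first <- !duplicated(key)
  prof <- data.frame(ninemer = bins$ninemer[first],
                     group = bins$group[first], stringsAsFactors = FALSE)
  prof_key <- paste(prof$ninemer, prof$group, sep = "\r")
  for (i in seq_along(conds)) {
    sums <- rowsum(bins[[icols[i]]], key)  # rownames sorted by key
    cnts <- as.vector(table(key))          # table is also key-sorted
    means <- sums[, 1] / cnts
    prof[[paste0("mean_", conds[i])]] <- means[match(prof_key, rownames(sums))]
  }
  # shared filter: keep 9-mers present in all four groups
  tab <- table(prof$ninemer)
  n_groups <- length(unique(bins$group))
  shared <- names(tab)[tab == 4L]
  if (n_groups < 4L || length(shared) == 0) {
    warning("no 9-mer occurs in all four groups")
    return(prof[0, , drop = FALSE])
  }
  prof <- prof[prof$ninemer %in% shared, , drop = FALSE]
  for (cond in conds) {
    v <- prof[[paste0("mean_", cond)]]
    prof[[paste0("z_", cond)]] <- as.numeric(scale(v))
  }
  rownames(prof) <- NULL
  prof
}

#' Trim distribution tails for boxplot export
#'
#' Drops the top and bottom 1% of values, the standard display rule for the
#' heavily skewed insertion-frequency distributions.
#'
#' @param x numeric vector.
#' @param frac tail fraction on each side.
#' @return trimmed vector.
#' @export
trim_outliers <- function(x, frac = 0.01) {
  q <- quantile(x, c(frac, 1 - frac), na.rm = TRUE, names = FALSE)
  x[x >= q[1] & x <= q[2]]
}

#' Stratify bins into 11 methylation levels
#'
#' Level 0 holds exactly-unmethylated bins (mean 0%); levels 1..10 are the
#' ten equal-width bins (0,10], (10,20], ..., (90,100]. Per level the
#' insertion-frequency distribution is summarized with boxplot statistics
#' (median, quartiles, 1.5 IQR whiskers).
#'
#' @param bins output of [tile_and_annotate()] (grouping not required).
#' @param condition condition name (matching the `meth_`/`ins_` suffixes).
#' @param n_levels number of levels (11; kept as an argument for symmetry).
#' @return data frame `level`, `n`, `median`, `q1`, `q3`, `lower`, `upper`;
#'   per-bin level assignments attached as attribute `assignments`.
#' @export
stratify_levels <- function(bins, condition, n_levels = 11L) {
  stopifnot(n_levels == 11L)
  m <- bins[[paste0("meth_", condition)]]
  ins <- bins[[paste0("ins_", condition)]]
  ok <- !is.na(m)
  m <- m[ok]; ins <- ins[ok]
  level <- ifelse(m == 0, 0L, pmin(10L, as.integer(ceiling(m / 10))))
  out <- data.frame(level = 0:10, n = 0L, median = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, lower = NA_real_, upper = NA_real_)
  for (l in 0:10) {
    v <- ins[level == l]
    out$n[l + 1] <- length(v)
    if (length(v) == 0) next
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    out$median[l + 1] <- qs[2]
    out$q1[l + 1] <- qs[1]
    out$q3[l + 1] <- qs[3]
    out$lower[l + 1] <- min(v[v >= qs[1] - 1.5 * iqr])
    out$upper[l + 1] <- max(v[v <= qs[3] + 1.5 * iqr])
  }
  attr(out, "assignments") <- data.frame(level = level, insertion = ins)
  out
}
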