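# k-mer bias model and single-base signal correction. The insertion rate of
# each (optionally masked) k-mer context is estimated genome-wide and the
# signal at each site is rescaled by mean rate / context rate, conserving the
# global signal total so downstream threshold semantics are unchanged.

#' Build a k-mer insertion-bias model
#'
#' For each masked k-mer `w` centered on a genome position:
#' `rate(w) = (site counts at positions with context w + pseudocount) /
#' (genome occurrences of w + pseudocount)`; `scale(w) = mean rate / rate(w)`.
#' Contexts are the '+'-strand k-mer centered at strand-merged positions;
#' positions whose k-mer spans a contig edge or contains N are excluded from
#' both numerator and denominator. Contexts are stored sparsely (observed
#' masked k-mers only), so large k with spaced masks stays tractable.
#'
#' @param sites insertion-site data frame.
#' @param genome a `tn5_genome`.
#' @param k odd context width (19 by default, matching the finding that a
#'   19-bp range affects Tn5 insertion).
#' @param mask string over `X` (informative) and `.` (ignored) of length `k`;
#'   default all informative.
#' @param pseudocount added to numerator and denominator (0.5 by default);
#'   with pseudocount 0 a context never observed at any site has an undefined
#'   scale and an error is raised.
#' @return a `tn5_bias_model`: `k`, `mask`, `scale` (named vector),
#'   `genome_counts`, `site_counts`, `mean_rate`, `pseudocount`.
#' @export
build_bias_model <- function(sites, genome, k = 19L, mask = NULL,
                             pseudocount = 0.5) {
  stopifnot(k %% 2 == 1)
  mask <- mask %||% strrep("X", k)
  stopifnot(nchar(mask) == k, grepl("^[X.]+$", mask))
  keep_off <- which(strsplit(mask, "")[[1]] == "X")
  if (length(keep_off) == 0) keep_off <- integer(0)
  half <- (k - 1L) %/% 2L

  genome_tab <- list()
  site_tab <- list()
  total_sites <- 0
  total_pos <- 0
  merged <- merge_site_strands(sites)
  for (ctg in names(genome$seq)) {
    s <- genome$seq[[ctg]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)  # 1-based k-mer starts; center = start+half
    ctx <- .masked_kmers(s, starts, keep_off)
    ok <- !is.na(ctx)
    genome_tab[[ctg]] <- table(ctx[ok])
    total_pos <- total_pos + sum(ok)
    sc <- merged[merged$contig == ctg, , drop = FALSE]
    if (nrow(sc) > 0) {
      st <- sc$pos - half + 1L  # k-mer start for each site center
      valid <- st >= 1L & st <= L - k + 1L
      sctx <- rep(NA_character_, nrow(sc))
      sctx[valid] <- .masked_kmers(s, st[valid], keep_off)
      vok <- !is.na(sctx)
      if (any(vok)) {
        site_tab[[ctg]] <- rowsum(as.numeric(sc$count[vok]), sctx[vok])
        total_sites <- total_sites + sum(sc$count[vok])
      }
    }
  }
  gcounts <- .sum_tables(genome_tab)
  scounts <- .sum_rowsums(site_tab)
  if (total_pos == 0 || total_sites == 0)
    stop("no valid positions or no sites with valid context")
  mean_rate <- total_sites / total_pos
  # scale for every context observed at a site
  ctxs <- names(scounts)
  gc <- gcounts[ctxs]
  gc[is.na(gc)] <- 0
  if (pseudocount == 0 && any(scounts == 0))
    stop("context with zero site observations and pseudocount 0")
  rate <- (scounts + pseudocount) / (gc + pseudocount)
  if (any(!is.finite(rate)))
    stop("undefined context rate; increase pseudocount")
  scale <- mean_rate / rate
  # also define scales for genome-only contexts (numerator = pseudocount)
  only_g <- setdiff(names(gcounts), ctxs)
  if (length(only_g) > 0 && pseudocount > 0) {
    rate_g <- pseudocount / (gcounts[only_g] + pseudocount)
    scale <- c(scale, mean_rate / rate_g)
  }
  structure(list(k = k, mask = mask, scale = scale,
                 genome_counts = gcounts, site_counts = scounts,
                 mean_rate = mean_rate, pseudocount = pseudocount),
            class = "tn5_bias_model")
}

# masked k-mer strings at the given 1-based starts of one contig sequence
# (NA where any informative position is non-ACGT)
.masked_kmers <- function(seq, starts, keep_off) {
  if (length(keep_off) == 0) return(rep(".", length(starts)))
  parts <- lapply(keep_off, function(o) substring(seq, starts + o - 1L,
                                                  starts + o - 1L))
  ctx <- do.call(paste0, parts)
  ctx[grepl("[^ACGT]", ctx)] <- NA_character_
  ctx
}

.sum_tables <- function(tabs) {
  all <- unlist(lapply(tabs, function(t) as.numeric(t)), use.names = FALSE)
  nms <- unlist(lapply(tabs, names), use.names = FALSE)
  out <- rowsum(all, nms)
  stats::setNames(out[, 1], rownames(out))
}

.sum_rowsums <- function(tabs) {
  all <- unlist(lapply(tabs, function(t) as.numeric(t[, 1])),
                use.names = FALSE)
  nms <- unlist(lapply(tabs, rownames), use.names = FALSE)
  if (length(all) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- rowsum(all, nms)
  stats::setNames(out[, 1], rownames(out))
}

#' @export
print.tn5_bias_model <- function(x, ...) {
  cat("tn5_bias_model: k =", x$k, "mask", x$mask, "-",
      length(x$scale), "contexts, mean rate", signif(x$mean_rate, 4), "\n")
  invisible(x)
}

#' Correct single-base insertion signal with a bias model
#'
#' The corrected value at each strand-merged site is
#' `raw count x scale(context)`, then the whole track is rescaled so the
#' corrected total equals the raw total (conservation). Sites whose context is
#' undefined (edge, N, or absent from the model) are emitted uncorrected and
#' counted in the `n_flagged` attribute.
#'
#' @param sites insertion-site data frame.
#' @param model a `tn5_bias_model`.
#' @param genome the `tn5_genome` the model was built on.
#' @return bedGraph-style data frame `contig`, `start`, `end`, `value`;
#'   attributes `n_flagged` and `rescale_factor`.
#' @export
correct_signal <- function(sites, model, genome) {
  merged <- merge_site_strands(sites)
  k <- model$k
  half <- (k - 1L) %/% 2L
  keep_off <- which(strsplit(model$mask, "")[[1]] == "X")
  fac <- rep(NA_real_, nrow(merged))
  for (ctg in unique(merged$contig)) {
    if (!ctg %in% names(genome$seq)) stop("contig not in genome: ", ctg)
    idx <- which(merged$contig == ctg)
    s <- genome$seq[[ctg]]
    L <- nchar(s)
    st <- merged$pos[idx] - half + 1L
    valid <- st >= 1L & st <= L - k + 1L
    ctx <- rep(NA_character_, length(idx))
    ctx[valid] <- .masked_kmers(s, st[valid], keep_off)
    fac[idx] <- model$scale[ctx]
  }
  if (all(is.na(fac)) && nrow(merged) > 0)
    stop("no site context found in the model; genome mismatch?")
  flagged <- is.na(fac)
  fac[flagged] <- 1
  value <- merged$count * fac
  raw_total <- sum(merged$count)
  rescale <- raw_total / sum(value)
  value <- value * rescale
  out <- data.frame(contig = merged$contig, start = merged$pos,
                    end = merged$pos + 1L, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "rescale_factor") <- rescale
  out
}

#' Partition two interval sets into shared and specific intervals
#'
#' An interval is shared if it overlaps the other set by at least 1 bp
#' (half-open coordinates: touching intervals do not overlap).
#'
#' @param a,b interval data frames.
#' @return list with `a_shared`, `a_specific`, `b_shared`, `b_specific`.
#' @export
compare_interval_sets <- function(a, b) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  a_hit <- GenomicRanges::countOverlaps(ga, gb, minoverlap = 1L) > 0
  b_hit <- GenomicRanges::countOverlaps(gb, ga, minoverlap = 1L) > 0
  list(a_shared = a[a_hit, , drop = FALSE],
       a_specific = a[!a_hit, , drop = FALSE],
       b_shared = b[b_hit, , drop = FALSE],
       b_specific = b[!b_hit, , drop = FALSE])
}

#' Write a bias-model scale table as TSV
#' @param model a `tn5_bias_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bias_model <- function(model, path) {
  ctx <- names(model$scale)
  df <- data.frame(context = ctx, scale = as.numeric(model$scale),
                   genome_count = as.numeric(model$genome_counts[ctx]),
                   site_count = as.numeric(model$site_counts[ctx]),
                   stringsAsFactors = FALSE)
  df$genome_count[is.na(df$genome_count)] <- 0
  df$site_count[is.na(df$site_count)] <- 0
  df <- df[order(df$context), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d mask=%s pseudocount=%g mean_rate=%.10g",
                     model$k, model$mask, model$pseudocount,
                     model$mean_rate), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
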