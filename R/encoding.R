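# Feature-vector assembly for the classification framework: per-position PWM
# score, DNA shape, k-mer one-hot and (optionally) per-position methylation
# blocks over 51-bp windows, min-max standardized to [0, 1].

#' Per-position PWM score vector
#'
#' Element j is the log2-odds of the observed base at position j under the
#' window-wide PWM -- summing the vector gives the full-window scan score.
#'
#' @param seqs character vector of windows, each of length `pwm$width`.
#' @param pwm a `tn5_pwm` whose width equals the window length.
#' @return numeric matrix n x width, columns `motif_<pos>`.
#' @export
encode_pwm_vector <- function(seqs, pwm) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  if (L != pwm$width)
    stop("window length ", L, " does not match PWM width ", pwm$width)
  n <- length(seqs)
  out <- matrix(NA_real_, n, L)
  for (j in seq_len(L)) {
    b <- .base_code_table[utf8ToInt(paste0(substr(seqs, j, j), collapse = ""))]
    out[, j] <- pwm$log_odds[cbind(b, j)]
  }
  colnames(out) <- paste0("motif_", seq_len(L))
  out
}

#' k-mer one-hot encoding
#'
#' One indicator block of size 4^k per start position: lengths 51x4 (mono),
#' 50x16 (di), 49x64 (tri) for 51-bp windows, with exactly one 1 per block.
#' Returned sparse.
#'
#' @param seqs character vector of equal-length N-free windows.
#' @param k 1, 2 or 3.
#' @return a `dgCMatrix`, columns `k<k>_<pos>_<kmer>`.
#' @export
encode_kmer <- function(seqs, k) {
  stopifnot(k %in% 1:3)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1, L >= k)
  n <- length(seqs)
  n_pos <- L - k + 1L
  width <- 4L^k
  # integer codes per window position
  codes <- matrix(.base_code_table[utf8ToInt(paste0(seqs, collapse = ""))],
                  nrow = n, ncol = L, byrow = TRUE)
  if (anyNA(codes)) stop("windows contain non-ACGT characters")
  j_idx <- integer(n * n_pos)
  for (s in seq_len(n_pos)) {
    idx <- codes[, s] - 1L
    if (k >= 2) idx <- idx * 4L + (codes[, s + 1L] - 1L)
    if (k >= 3) idx <- idx * 4L + (codes[, s + 2L] - 1L)
    j_idx[((s - 1L) * n + 1L):(s * n)] <- (s - 1L) * width + idx + 1L
  }
  m <- Matrix::sparseMatrix(i = rep(seq_len(n), n_pos), j = j_idx, x = 1,
                            dims = c(n, n_pos * width))
  km <- all_kmers(k)
  colnames(m) <- paste0("k", k, "_", rep(seq_len(n_pos), each = width),
                        "_", rep(km, n_pos))
  m
}

#' Sample random genomic control sites
#'
#' Uniform over positions whose centered window is in-bounds and N-free
#' (matching "random sites across the genome" as classifier controls).
#'
#' @param genome a `tn5_genome`.
#' @param n number of control sites.
#' @param width window width the controls must support.
#' @param seed integer seed.
#' @param exclude optional insertion-site data frame whose positions are
#'   avoided.
#' @return insertion-site data frame with count 1.
#' @export
sample_control_sites <- function(genome, n, width = 51L, seed = 1L,
                                 exclude = NULL) {
  half <- (width - 1L) %/% 2L
  with_seed(child_seed(seed, "controls"), {
    picked <- list()
    got <- 0L
    guard <- 0L
    while (got < n && guard < 50L) {
      guard <- guard + 1L
      need <- (n - got) * 2L + 10L
      ctg_i <- sample.int(length(genome$seq), need, replace = TRUE,
                          prob = genome$contig_lengths)
      ctg <- names(genome$seq)[ctg_i]
      pos <- floor(runif(need, half, genome$contig_lengths[ctg_i] - half))
      cand <- new_sites(contig = ctg, pos = as.integer(pos), strand = "+",
                        count = 1L)
      w <- site_windows(genome, cand, width)
      ok <- !is.na(w)
      if (!is.null(exclude)) {
        key <- paste(cand$contig, cand$pos)
        ok <- ok & !(key %in% paste(exclude$contig, exclude$pos))
      }
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) > 0) {
        picked[[guard]] <- cand
        got <- got + nrow(cand)
      }
    }
    out <- do.call(rbind, picked)
    if (nrow(out) < n) stop("could not sample ", n, " valid control sites")
    out <- out[!duplicated(paste(out$contig, out$pos)), , drop = FALSE]
    if (nrow(out) < n) out <- out  # duplicates rare; top up below if short
    while (nrow(out) < n) {
      extra <- sample.int(nrow(out), n - nrow(out), replace = TRUE)
      out <- rbind(out, out[extra, , drop = FALSE])
    }
    sort_sites(out[seq_len(n), , drop = FALSE])
  })
}

# Shuffle each window's characters independently (seeded): the
# shuffled-sequence negative control that destroys positional information
# while preserving composition.
shuffle_windows <- function(seqs, seed) {
  with_seed(child_seed(seed, "shuffle"), {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

.minmax_block <- function(x, bounds = NULL) {
  if (is.null(bounds)) {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
  } else {
    lo <- bounds$min
    hi <- bounds$max
  }
  span <- hi - lo
  degen <- span <= 0
  span[degen] <- 1
  out <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  out[, degen] <- 0
  list(x = out, bounds = list(min = lo, max = hi), n_degenerate = sum(degen))
}

#' Assemble a standardized feature matrix
#'
#' Builds the classifier input: rows are insertion sites (label 1) followed by
#' controls (label 0); columns are the requested feature blocks over the
#' centered window; every feature is min-max standardized to [0, 1] with
#' bounds from this matrix (or reused bounds for held-out data). Windows
#' containing N are dropped (with their labels).
#'
#' @param sites insertion-site data frame (label 1).
#' @param controls control-site data frame (label 0).
#' @param genome a `tn5_genome`.
#' @param blocks character vector from `"motif"`, `"shapes"`, `"kmer1"`,
#'   `"kmer2"`, `"kmer3"`, `"meth"`.
#' @param pwm a window-wide `tn5_pwm` (required for the motif block).
#' @param table a `tn5_shape_table` (required for the shapes block).
#' @param meth bedGraph-style percent-methylation data frame (required for the
#'   meth block; positions without a value encode 0).
#' @param window odd window width (51 by default).
#' @param shuffle_sequences shuffle each window's characters (negative
#'   control) before encoding.
#' @param seed seed for the sequence shuffle.
#' @param bounds standardization bounds from a training matrix, to apply to
#'   held-out data (default: computed from this matrix).
#' @return a `tn5_feature_matrix`: `x` (matrix or dgCMatrix), `labels`
#'   (0/1), `col_info` (block/param/position per column), `bounds`, `window`,
#'   `n_dropped`.
#' @export
assemble_matrix <- function(sites, controls, genome,
                            blocks = c("motif", "shapes"),
                            pwm = NULL, table = NULL, meth = NULL,
                            window = 51L, shuffle_sequences = FALSE,
                            seed = 1L, bounds = NULL) {
  stopifnot(window %% 2 == 1, length(blocks) >= 1)
  known <- c("motif", "shapes", "kmer1", "kmer2", "kmer3", "meth")
  stopifnot(all(blocks %in% known))
  all_sites <- rbind(sites[, c("contig", "pos", "strand", "count")],
                     controls[, c("contig", "pos", "strand", "count")])
  labels <- c(rep(1L, nrow(sites)), rep(0L, nrow(controls)))
  w <- site_windows(genome, all_sites, window)
  keep <- !is.na(w)
  n_dropped <- sum(!keep)
  w <- w[keep]
  labels <- labels[keep]
  kept_sites <- all_sites[keep, , drop = FALSE]
  if (shuffle_sequences) w <- shuffle_windows(w, seed)

  xs <- list()
  infos <- list()
  bnds <- list(min = numeric(0), max = numeric(0))
  n_degen <- 0L
  for (b in blocks) {
    if (b == "motif") {
      if (is.null(pwm)) stop("motif block requires a window-wide pwm")
      xb <- encode_pwm_vector(w, pwm)
      info <- data.frame(block = b, param = "motif",
                         position = seq_len(window))
    } else if (b == "shapes") {
      if (is.null(table)) stop("shapes block requires a shape table")
      xb <- encode_shape(w, table)
      info <- data.frame(block = b,
                         param = rep(shape_names(), each = window - 4L),
                         position = rep(seq_len(window - 4L) + 2L,
                                        length(shape_names())))
    } else if (b %in% c("kmer1", "kmer2", "kmer3")) {
      k <- as.integer(sub("kmer", "", b))
      xb <- encode_kmer(w, k)
      n_pos <- window - k + 1L
      info <- data.frame(block = b, param = paste0(k, "mer"),
                         position = rep(seq_len(n_pos), each = 4L^k))
    } else {  # meth
      if (is.null(meth)) stop("meth block requires a methylation track")
      xb <- .meth_window_matrix(kept_sites, meth, window)
      info <- data.frame(block = b, param = "meth",
                         position = seq_len(window))
    }
    blk_bounds <- if (!is.null(bounds)) {
      sel <- bounds$col_info$block == b
      list(min = bounds$min[sel], max = bounds$max[sel])
    } else NULL
    if (inherits(xb, "sparseMatrix")) {
      # one-hot: bounds are 0/1 analytically; empty columns are degenerate 0
      cmax <- as.numeric(diff(xb@p) > 0)
      if (!is.null(blk_bounds)) cmax <- blk_bounds$max
      bnds$min <- c(bnds$min, rep(0, ncol(xb)))
      bnds$max <- c(bnds$max, cmax)
      n_degen <- n_degen + sum(cmax == 0)
      xs[[b]] <- xb
    } else {
      st <- .minmax_block(xb, blk_bounds)
      bnds$min <- c(bnds$min, st$bounds$min)
      bnds$max <- c(bnds$max, st$bounds$max)
      n_degen <- n_degen + st$n_degenerate
      xs[[b]] <- st$x
    }
    infos[[b]] <- info
  }
  sparse <- any(vapply(xs, function(m) inherits(m, "sparseMatrix"),
                       logical(1)))
  x <- if (sparse) do.call(cbind, lapply(xs, function(m)
         as(m, "CsparseMatrix"))) else do.call(cbind, xs)
  col_info <- do.call(rbind, infos)
  rownames(col_info) <- NULL
  if (n_degen > 0)
    warning(n_degen, " zero-variance feature(s) mapped to 0")
  out <- list(x = x, labels = labels, col_info = col_info,
              bounds = list(min = bnds$min, max = bnds$max,
                            col_info = col_info),
              window = window, n_dropped = n_dropped)
  class(out) <- "tn5_feature_matrix"
  out
}

# per-position percent methylation within the window (0 where no value)
.meth_window_matrix <- function(sites, meth, window) {
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(sites), window)
  for (ctg in unique(sites$contig)) {
    idx <- which(sites$contig == ctg)
    m <- meth[meth$contig == ctg, , drop = FALSE]
    if (nrow(m) == 0) next
    mv <- stats::setNames(m$value, m$start)
    for (j in seq_len(window)) {
      p <- sites$pos[idx] + (j - half - 1L)
      v <- mv[as.character(p)]
      v[is.na(v)] <- 0
      out[idx, j] <- v
    }
  }
  colnames(out) <- paste0("meth_", seq_len(window))
  out
}

#' @export
print.tn5_feature_matrix <- function(x, ...) {
  cat("tn5_feature_matrix:", nrow(x$x), "rows x", ncol(x$x), "features;",
      sum(x$labels == 1), "sites /", sum(x$labels == 0), "controls;",
      x$n_dropped, "windows dropped\n")
  invisible(x)
}
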