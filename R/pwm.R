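# PWM construction from center-aligned insertion windows and genome scanning
# with exact p-values. Because windows are center-aligned at insertion sites,
# positional frequency counting replaces de novo motif discovery: there is no
# alignment step to perform.

#' Construct a PWM object
#'
#' @param probs 4 x w column-stochastic matrix, rows in ACGT order.
#' @param background length-4 background probabilities.
#' @param pseudocount pseudocount used when the matrix was estimated.
#' @return a `tn5_pwm`: `width`, `probs`, `background`, `pseudocount`,
#'   `log_odds` (log2(prob/background)).
#' @export
new_pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == 4, all(abs(colSums(probs) - 1) < 1e-9),
            length(background) == 4, abs(sum(background) - 1) < 1e-9,
            pseudocount >= 0)
  rownames(probs) <- .BASES
  background <- stats::setNames(as.numeric(background), .BASES)
  structure(list(width = ncol(probs), probs = probs, background = background,
                 pseudocount = pseudocount,
                 log_odds = log2(probs / background)),
            class = "tn5_pwm")
}

#' @export
print.tn5_pwm <- function(x, ...) {
  cat("tn5_pwm: width", x$width, "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm a `tn5_pwm`.
#' @return character consensus (column argmax).
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm a `tn5_pwm`.
#' @return a `tn5_pwm` for the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[4:1, pwm$width:1, drop = FALSE]
  new_pwm(probs, background = pwm$background[4:1],
          pseudocount = pwm$pseudocount)
}

#' Select insertion sites evidenced by paired fragments
#'
#' Two adjacent fragments whose coordinates overlap by exactly the 9-bp
#' target-site duplication (`left end - right start = 9`) evidence one
#' insertion event seen from both sides; the event center is
#' `right start + 4` (equivalently `left end - 5`). Every matching
#' (left, right) pair contributes one event; duplicates merge into counts.
#'
#' @param fragments fragment data frame sorted by (contig, start).
#' @return insertion-site data frame ('+' strand, merged counts).
#' @export
paired_fragment_sites <- function(fragments) {
  out <- list()
  for (ctg in unique(fragments$contig)) {
    f <- fragments[fragments$contig == ctg, , drop = FALSE]
    ends <- table(f$end)
    starts <- table(f$start)
    e <- as.integer(names(ends))
    match_start <- match(as.character(e - 9L), names(starts))
    ok <- !is.na(match_start)
    if (!any(ok)) next
    out[[ctg]] <- new_sites(
      contig = ctg,
      pos = e[ok] - 5L,
      strand = "+",
      count = as.integer(ends[ok]) * as.integer(starts[match_start[ok]])
    )
  }
  if (length(out) == 0) return(new_sites())
  sort_sites(do.call(rbind, out))
}

#' Subsample insertion sites
#'
#' Uniform without-replacement sample of distinct site rows; the standard
#' protocol samples 500 000 paired-fragment sites per sample.
#'
#' @param sites insertion-site data frame.
#' @param n sample size; if it exceeds the available distinct sites, all are
#'   returned with a warning.
#' @param seed integer seed.
#' @return sampled sites, sorted.
#' @export
subsample_sites <- function(sites, n = 500000L, seed = 1L) {
  stopifnot(n > 0)
  if (n >= nrow(sites)) {
    if (n > nrow(sites))
      warning("requested ", n, " sites but only ", nrow(sites),
              " available; returning all")
    return(sort_sites(sites))
  }
  idx <- with_seed(child_seed(seed, "subsample"),
                   sample.int(nrow(sites), n))
  sort_sites(sites[idx, , drop = FALSE])
}

#' Build a PWM from windows centered at insertion sites
#'
#' Positional base frequencies over fixed-width windows centered at each site.
#' Sites on the '-' strand contribute the reverse complement of their window;
#' '+' and strand-merged sites contribute the forward window. Windows
#' containing N or off-contig are dropped (reported in the error on underflow).
#'
#' @param sites insertion-site data frame; each site is weighted by its count.
#' @param genome a `tn5_genome`.
#' @param window odd window width (19 bp for the core motif view, 51 bp for
#'   the classifier's motif vector).
#' @param pseudocount added per cell before normalizing.
#' @param background background probabilities; defaults to the genome base
#'   composition.
#' @return a `tn5_pwm` of width `window`.
#' @export
build_pwm <- function(sites, genome, window = 19L, pseudocount = 1,
                      background = NULL) {
  stopifnot(window %% 2 == 1)
  w <- site_windows(genome, sites, window)
  minus <- sites$strand == "-" & !is.na(w)
  if (any(minus)) w[minus] <- revcomp(w[minus])
  keep <- !is.na(w)
  n_kept <- sum(keep)
  if (n_kept < 100)
    stop("only ", n_kept, " N-free in-bounds windows (need >= 100); dropped ",
         sum(!keep), " of ", length(w))
  w <- w[keep]
  wt <- sites$count[keep]
  counts <- matrix(0, nrow = 4, ncol = window, dimnames = list(.BASES, NULL))
  codes <- matrix(0L, nrow = length(w), ncol = window)
  for (j in seq_len(window)) {
    codes[, j] <- .base_code_table[utf8ToInt(paste0(substr(w, j, j),
                                                    collapse = ""))]
  }
  for (j in seq_len(window)) {
    counts[, j] <- vapply(1:4, function(b) sum(wt[codes[, j] == b]),
                          numeric(1))
  }
  n <- sum(wt)
  probs <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  bg <- background %||% genome_base_composition(genome)
  new_pwm(probs, background = bg, pseudocount = pseudocount)
}

## ---- exact score distribution --------------------------------------------

# Discretize per-cell log2-odds to an integer grid of the given grain and
# compute the exact distribution of the window score under the iid background
# by dynamic programming (one convolution per column).
pwm_score_distribution <- function(pwm, grain_frac = 1e-4) {
  lo <- pwm$log_odds
  col_max <- apply(lo, 2, max)
  col_min <- apply(lo, 2, min)
  score_range <- sum(col_max) - sum(col_min)
  if (score_range <= 0) score_range <- 1
  grain <- score_range * grain_frac
  I <- round(lo / grain)
  mins <- apply(I, 2, min)
  maxs <- apply(I, 2, max)
  lo_tot <- sum(mins)
  hi_tot <- sum(maxs)
  n_cells <- hi_tot - lo_tot + 1L
  dist <- numeric(n_cells)
  # running distribution over partial sums, offset so index 1 = current min
  cur <- 1
  cur_min <- 0L
  bg <- pwm$background
  for (j in seq_len(pwm$width)) {
    width_new <- length(cur) + (maxs[j] - mins[j])
    nxt <- numeric(width_new)
    for (b in 1:4) {
      sh <- I[b, j] - mins[j]
      nxt[(1 + sh):(length(cur) + sh)] <-
        nxt[(1 + sh):(length(cur) + sh)] + bg[b] * cur
    }
    cur <- nxt
    cur_min <- cur_min + mins[j]
  }
  stopifnot(cur_min == lo_tot, length(cur) == n_cells)
  tail_p <- rev(cumsum(rev(cur)))
  list(I = I, grain = grain, min_total = lo_tot, max_total = hi_tot,
       probs = cur, tail_p = tail_p, total_mass = sum(cur))
}

# p-value of an integer score under the precomputed distribution
.tail_lookup <- function(dist, int_scores) {
  idx <- int_scores - dist$min_total + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(dist$tail_p)] <- length(dist$tail_p)
  p <- dist$tail_p[idx]
  # scores above the maximum achievable have probability 0
  p[int_scores > dist$max_total] <- 0
  pmin(p, 1)
}

# Integer and float scores at every window start of one contig for one
# orientation's integer matrix; NA where the window has N or leaves the contig.
.scan_scores <- function(code, I, lo) {
  w <- ncol(I)
  L <- length(code)
  n_pos <- L - w + 1L
  if (n_pos < 1L) return(list(int = integer(0), flt = numeric(0)))
  s_int <- integer(n_pos)
  s_flt <- numeric(n_pos)
  valid <- rep(TRUE, n_pos)
  for (j in seq_len(w)) {
    b <- code[j:(j + n_pos - 1L)]
    bad <- is.na(b)
    valid <- valid & !bad
    b[bad] <- 1L
    s_int <- s_int + I[cbind(b, j)]
    s_flt <- s_flt + lo[cbind(b, j)]
  }
  s_int[!valid] <- NA_integer_
  s_flt[!valid] <- NA_real_
  list(int = s_int, flt = s_flt)
}

#' Scan a genome with a PWM using exact p-values
#'
#' Scores every window on both strands with the log2-odds score; per-hit
#' p-values are exact tail probabilities of the score under the iid background
#' model, computed by dynamic programming on a discretized score grid
#' (FIMO-style semantics). q-values are Benjamini-Hochberg over all scanned
#' windows; hits with `q < q_threshold` are returned, overlapping same-strand
#' hits all retained.
#'
#' @param pwm a `tn5_pwm`, width <= 30 (exact-p DP bound).
#' @param genome a `tn5_genome`.
#' @param q_threshold q-value cutoff (paper protocol: 0.001).
#' @param grain_frac discretization grain as a fraction of the score range.
#' @param both_strands scan the reverse strand too.
#' @return data frame `contig`, `start`, `end`, `strand`, `score`, `p`, `q`,
#'   sorted by position; attribute `n_scanned` records the BH family size.
#' @export
scan_pwm <- function(pwm, genome, q_threshold = 0.001, grain_frac = 1e-4,
                     both_strands = TRUE) {
  if (pwm$width > 30)
    stop("PWM width ", pwm$width,
         " exceeds the exact-p bound (30); use a coarser grain / shorter PWM")
  dist <- pwm_score_distribution(pwm, grain_frac)
  strands <- if (both_strands) c("+", "-") else "+"
  rc <- if (both_strands) pwm_revcomp(pwm) else NULL
  dist_rc <- if (both_strands) pwm_score_distribution(rc, grain_frac) else NULL
  rows <- list()
  for (ctg in names(genome$seq)) {
    code <- base_codes(genome$seq[[ctg]])
    for (st in strands) {
      d <- if (st == "+") dist else dist_rc
      lo <- if (st == "+") pwm$log_odds else rc$log_odds
      sc <- .scan_scores(code, d$I, lo)
      ok <- which(!is.na(sc$int))
      if (length(ok) == 0) next
      rows[[paste(ctg, st)]] <- data.frame(
        contig = ctg, start = ok - 1L, end = ok - 1L + pwm$width,
        strand = st, score = sc$flt[ok],
        p = .tail_lookup(d, sc$int[ok]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p = numeric(), q = numeric())
    attr(out, "n_scanned") <- 0L
    return(out)
  }
  all <- do.call(rbind, rows)
  n_scanned <- nrow(all)
  all$q <- p.adjust(all$p, method = "BH")
  hits <- all[all$q < q_threshold, , drop = FALSE]
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_scanned") <- n_scanned
  hits
}

#' Insertion / motif usage taxonomy
#'
#' A site is "inside" if its position lies within any hit interval
#' (strand-agnostic, half-open); a hit is "used" if at least one site lies
#' within it. Fractions are over distinct sites and distinct hits.
#'
#' @param sites insertion-site data frame.
#' @param hits [scan_pwm()] output.
#' @return list `frac_insert_inside`, `frac_insert_outside`,
#'   `frac_motif_used`, `frac_motif_unused` (the latter two NA when there are
#'   no hits).
#' @export
usage_summary <- function(sites, hits) {
  if (nrow(hits) == 0)
    return(list(frac_insert_inside = 0, frac_insert_outside = 1,
                frac_motif_used = NA_real_, frac_motif_unused = NA_real_))
  hit_gr <- GenomicRanges::GRanges(hits$contig,
                                   IRanges::IRanges(hits$start + 1L,
                                                    hits$end))
  ov <- GenomicRanges::findOverlaps(sites_granges(sites), hit_gr)
  inside <- length(unique(S4Vectors::queryHits(ov))) / nrow(sites)
  used <- length(unique(S4Vectors::subjectHits(ov))) / nrow(hits)
  list(frac_insert_inside = inside, frac_insert_outside = 1 - inside,
       frac_motif_used = used, frac_motif_unused = 1 - used)
}

## ---- MEME minimal format ---------------------------------------------------

#' Write a PWM in MEME minimal motif format
#' @param pwm a `tn5_pwm`.
#' @param path output file.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_pwm_meme <- function(pwm, path, name = "Tn5") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", .BASES, pwm$background), collapse = " "), "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 0 E= 0",
            pwm$width),
    apply(pwm$probs, 2, function(col) paste(sprintf("%.6f", col),
                                            collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from MEME minimal motif format
#' @param path MEME minimal-format file with one motif.
#' @return a `tn5_pwm`.
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  bg <- rep(0.25, 4)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  mat_i <- grep("^letter-probability matrix", lines)
  stopifnot(length(mat_i) >= 1)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mat_i[1]]))
  rows <- lines[(mat_i[1] + 1L):(mat_i[1] + w)]
  pm <- vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4))  # 4 x w, rows ACGT
  # renormalize against 6-digit rounding so columns are exactly stochastic
  pm <- sweep(pm, 2, colSums(pm), "/")
  dimnames(pm) <- NULL
  new_pwm(pm, background = bg / sum(bg), pseudocount = 0)
}
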