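# Synthetic genomes and insertion events with planted, known preference
# structure. Every downstream stage is validated by recovering the planted
# parameters from the sampled sites.

#' Simulation configuration
#'
#' The per-position insertion propensity is
#' `exp(motif_weight * s_pwm(i) + sum(dinuc_weights over the 19-bp window) +
#' methylation_effect * meth(i)/100)`, where `s_pwm` is the natural-log odds
#' score of the planted PWM centered at `i` and the 19-bp context mirrors the
#' empirical finding that a 19-bp range around the duplication affects Tn5
#' insertion.
#'
#' @param genome_length genome length in bp (>= 200).
#' @param base_composition named probabilities for A, C, G, T (sum to 1).
#' @param planted_pwm a `tn5_pwm` (see [default_planted_pwm()]) or NULL.
#' @param motif_weight log-scale multiplier on the PWM score. With
#'   `motif_weight = 1` and PWM background equal to the genome composition the
#'   column distributions of sampled windows equal the planted PWM columns, so
#'   PWM building recovers the planted matrix.
#' @param dinuc_weights 4x4 matrix of adjacent-pair weights (rows = first
#'   base, cols = second base, ACGT order) or NULL; the shape-proxy term,
#'   summed over the 18 steps of the 19-bp window.
#' @param methylation_effect multiplier on fractional methylation at the
#'   center position, or 0.
#' @param n_insertions number of insertion events to draw (>= 1).
#' @param n_planted_motifs number of consensus motif instances embedded in
#'   the simulated genome at non-overlapping positions. Real genomes carry
#'   abundant motif occurrences; an i.i.d. genome does not, so genome-wide
#'   scans on it (correctly) find nothing.
#' @param seed integer master seed; per-stage child seeds are derived from it.
#' @return a `tn5_sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       planted_pwm = NULL,
                       motif_weight = 0,
                       dinuc_weights = NULL,
                       methylation_effect = 0,
                       n_insertions = 10000L,
                       n_planted_motifs = 0L,
                       seed = 1L) {
  stopifnot(genome_length >= 200, n_insertions >= 1,
            abs(sum(base_composition) - 1) < 1e-9,
            length(base_composition) == 4)
  if (is.null(names(base_composition))) names(base_composition) <- .BASES
  stopifnot(is.finite(motif_weight), is.finite(methylation_effect))
  if (!is.null(dinuc_weights)) {
    stopifnot(is.matrix(dinuc_weights), all(dim(dinuc_weights) == c(4, 4)),
              all(is.finite(dinuc_weights)))
    dimnames(dinuc_weights) <- list(.BASES, .BASES)
  }
  structure(list(genome_length = as.integer(genome_length),
                 base_composition = base_composition[.BASES],
                 planted_pwm = planted_pwm,
                 motif_weight = motif_weight,
                 dinuc_weights = dinuc_weights,
                 methylation_effect = methylation_effect,
                 n_insertions = as.integer(n_insertions),
                 n_planted_motifs = as.integer(n_planted_motifs),
                 seed = as.integer(seed)),
            class = "tn5_sim_config")
}

#' A Tn5-like planted PWM
#'
#' A 9-bp matrix with G/C-favored edges and an A/T-rich center, loosely
#' shaped like the published Tn5 core motif; used as the default planted
#' signal in simulations and the demo pipeline.
#'
#' @param strength interpolation between uniform (0) and the full matrix (1).
#' @return a `tn5_pwm` of width 9.
#' @export
default_planted_pwm <- function(strength = 1) {
  consensus_like <- rbind(
    A = c(.10, .15, .40, .15, .55, .15, .40, .15, .10),
    C = c(.20, .55, .10, .15, .10, .15, .10, .15, .45),
    G = c(.45, .15, .10, .15, .10, .15, .10, .55, .20),
    T = c(.25, .15, .40, .55, .25, .55, .40, .15, .25)
  )
  probs <- strength * consensus_like + (1 - strength) * 0.25
  new_pwm(probs, background = rep(0.25, 4), pseudocount = 0)
}

#' Simulate an i.i.d. genome
#'
#' @param config a `tn5_sim_config`.
#' @param contig contig name.
#' @return a `tn5_genome` with one contig; deterministic given the seed.
#' @export
simulate_genome <- function(config, contig = "chrS") {
  stopifnot(inherits(config, "tn5_sim_config"))
  seq <- with_seed(child_seed(config$seed, "genome"), {
    bases <- sample(.BASES, config$genome_length, replace = TRUE,
                    prob = config$base_composition)
    if (config$n_planted_motifs > 0) {
      stopifnot(!is.null(config$planted_pwm))
      w <- config$planted_pwm$width
      slots <- floor(config$genome_length / (2L * w))
      stopifnot(config$n_planted_motifs <= slots)
      at <- sort(sample.int(slots, config$n_planted_motifs)) * 2L * w - w
      inst <- .BASES[apply(config$planted_pwm$probs, 2, which.max)]
      for (s in at) bases[(s + 1L):(s + w)] <- inst
    }
    paste(bases, collapse = "")
  })
  new_genome(stats::setNames(seq, contig))
}

# Natural-log PWM odds score at every center position of one contig code
# vector (NA outside valid range or at N-containing windows).
.pwm_center_scores <- function(code, pwm) {
  w <- pwm$width
  half <- (w - 1L) %/% 2L
  L <- length(code)
  lo <- log(pwm$probs / pwm$background)  # natural log for the energy model
  s <- numeric(L)
  valid <- rep(TRUE, L)
  for (j in seq_len(w)) {
    idx <- seq_len(L) + (j - 1L) - half
    ok <- idx >= 1L & idx <= L
    b <- rep(NA_integer_, L)
    b[ok] <- code[idx[ok]]
    bad <- is.na(b)
    valid <- valid & !bad
    b[bad] <- 1L
    s <- s + lo[cbind(b, j)]
  }
  s[!valid] <- NA_real_
  s
}

#' Simulate insertion events from planted preference
#'
#' Positions require a full 19-bp context window; insertions are drawn
#' multinomially (with replacement, so counts > 1 occur as in real pileups)
#' from the normalized propensity. All sites are emitted on the '+' strand:
#' the event center is intrinsically double-stranded and all counting
#' operations are strand-merged.
#'
#' @param genome a `tn5_genome` (single contig, as from [simulate_genome()]).
#' @param config a `tn5_sim_config`.
#' @param methylation optional bedGraph-style data frame of per-cytosine
#'   percent methylation (used when `methylation_effect != 0`).
#' @return list with `sites` (insertion-site data frame) and `truth` (list:
#'   normalized `propensity` vector over positions, `positions` (0-based),
#'   planted parameters, sampled counts).
#' @export
simulate_insertions <- function(genome, config, methylation = NULL) {
  stopifnot(inherits(genome, "tn5_genome"), inherits(config, "tn5_sim_config"))
  ctg <- names(genome$seq)[1]
  code <- base_codes(genome$seq[[ctg]])
  L <- length(code)
  win <- 19L
  half <- (win - 1L) %/% 2L
  stopifnot(L > win)
  pos0 <- seq.int(half, L - half - 1L)  # 0-based centers with full window
  energy <- numeric(length(pos0))
  valid <- rep(TRUE, length(pos0))

  # validity: full 19-bp window N-free
  for (off in -half:half) {
    b <- code[pos0 + 1L + off]
    valid <- valid & !is.na(b)
  }

  if (!is.null(config$planted_pwm) && config$motif_weight != 0) {
    s <- .pwm_center_scores(code, config$planted_pwm)[pos0 + 1L]
    s[is.na(s)] <- 0
    energy <- energy + config$motif_weight * s
  }
  if (!is.null(config$dinuc_weights)) {
    W <- config$dinuc_weights
    for (off in -half:(half - 1L)) {
      b1 <- code[pos0 + 1L + off]
      b2 <- code[pos0 + 2L + off]
      ok <- !is.na(b1) & !is.na(b2)
      add <- numeric(length(pos0))
      add[ok] <- W[cbind(b1[ok], b2[ok])]
      energy <- energy + add
    }
  }
  if (config$methylation_effect != 0 && !is.null(methylation)) {
    mv <- numeric(L)
    m <- methylation[methylation$contig == ctg, , drop = FALSE]
    if (nrow(m) > 0) mv[m$start + 1L] <- m$value
    energy <- energy + config$methylation_effect * mv[pos0 + 1L] / 100
  }

  prop <- exp(energy - max(energy[valid]))
  prop[!valid] <- 0
  if (all(prop == 0)) stop("all-zero insertion propensity")
  prop <- prop / sum(prop)

  counts <- with_seed(child_seed(config$seed, "insertions"), {
    as.vector(rmultinom(1, size = config$n_insertions, prob = prop))
  })
  hit <- counts > 0
  sites <- new_sites(contig = ctg, pos = pos0[hit], strand = "+",
                     count = counts[hit])
  truth <- list(propensity = prop, positions = pos0, contig = ctg,
                counts = counts, config = config)
  list(sites = sort_sites(sites), truth = truth)
}

#' Simulate per-cytosine percent methylation tracks
#'
#' Emits one track per condition; in two-condition mode, condition-specific
#' methylated blocks are laid out with configurable overlap so all four
#' context groups (A-only / B-only / Both / None) are populated.
#'
#' @param genome a `tn5_genome`.
#' @param config a `tn5_sim_config` (seed source).
#' @param n_conditions 1 or 2.
#' @param block_size width in bp of methylated blocks.
#' @param frac_only fraction of the genome covered by condition-exclusive
#'   methylated blocks (each condition).
#' @param frac_both fraction covered by blocks methylated in both conditions.
#' @return named list of bedGraph-style data frames (`contig`, `start`,
#'   `end`, `value` = percent methylation), one entry per cytosine.
#' @export
simulate_methylation <- function(genome, config, n_conditions = 2L,
                                 block_size = 450L, frac_only = 0.2,
                                 frac_both = 0.2) {
  stopifnot(inherits(genome, "tn5_genome"))
  ctg <- names(genome$seq)[1]
  code <- base_codes(genome$seq[[ctg]])
  c_pos <- which(code == 2L) - 1L  # 0-based cytosine positions
  if (length(c_pos) == 0) {
    warning("genome has no cytosines; empty methylation track")
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer(), value = numeric())
    return(stats::setNames(rep(list(empty), n_conditions),
                           paste0("cond", LETTERS[seq_len(n_conditions)])))
  }
  L <- genome$contig_lengths[[ctg]]
  n_blocks <- max(1L, floor(L / block_size))
  with_seed(child_seed(config$seed, "methylation"), {
    # assign non-overlapping blocks to roles: A-only, B-only, both, none
    roles <- sample(c("A", "B", "both", "none"), n_blocks, replace = TRUE,
                    prob = c(frac_only, frac_only, frac_both,
                             max(0, 1 - 2 * frac_only - frac_both)))
    block_of <- pmin(floor(c_pos / block_size) + 1L, n_blocks)
    role_of <- roles[block_of]
    levels_pct <- round(runif(length(c_pos), 20, 100), 1)
    tracks <- list()
    condA <- ifelse(role_of %in% c("A", "both"), levels_pct, 0)
    tracks$condA <- data.frame(contig = ctg, start = c_pos, end = c_pos + 1L,
                               value = condA, stringsAsFactors = FALSE)
    if (n_conditions >= 2L) {
      levels_pct2 <- round(runif(length(c_pos), 20, 100), 1)
      condB <- ifelse(role_of %in% c("B", "both"), levels_pct2, 0)
      tracks$condB <- data.frame(contig = ctg, start = c_pos,
                                 end = c_pos + 1L, value = condB,
                                 stringsAsFactors = FALSE)
    }
    tracks
  })
}

#' Expand insertion events to fragment pairs with exact 9-bp overlaps
#'
#' Each event at center `p` yields a left fragment ending at `p + 5` and a
#' right fragment starting at `p - 4`, so the two fragments overlap by exactly
#' the 9-bp target-site duplication and shift back to `p` under the +4/-5
#' rule. Fragment lengths are drawn from a unimodal log-normal (naked-DNA
#' fragmentation has no nucleosome periodicity).
#'
#' @param sites insertion-site data frame (counts expanded to events).
#' @param genome a `tn5_genome` (for clipping at contig ends).
#' @param seed integer seed for fragment lengths.
#' @param meanlog,sdlog log-normal parameters of fragment length.
#' @return fragment data frame sorted by (contig, start, end).
#' @export
sites_to_fragments <- function(sites, genome, seed = 1L,
                               meanlog = log(160), sdlog = 0.35) {
  idx <- rep(seq_len(nrow(sites)), sites$count)
  p <- sites$pos[idx]
  ctg <- sites$contig[idx]
  n <- length(p)
  with_seed(child_seed(seed, "fragments"), {
    len_l <- pmax(20L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    len_r <- pmax(20L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    Lmax <- genome$contig_lengths[ctg]
    left <- data.frame(contig = ctg,
                       start = pmax(0L, p + 5L - len_l),
                       end = p + 5L, stringsAsFactors = FALSE)
    right <- data.frame(contig = ctg,
                        start = p - 4L,
                        end = pmin(as.integer(Lmax), p - 4L + len_r),
                        stringsAsFactors = FALSE)
    out <- rbind(left, right)
    out <- out[out$start >= 0 & out$end - out$start >= 9, , drop = FALSE]
    out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a simulation truth record
#'
#' Structured-text export of all planted parameters and the propensity
#' summary, for provenance alongside FASTA/BED exports.
#'
#' @param truth the `truth` element of [simulate_insertions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cfg <- truth$config
  lines <- c(
    sprintf("contig\t%s", truth$contig),
    sprintf("n_insertions\t%d", cfg$n_insertions),
    sprintf("seed\t%d", cfg$seed),
    sprintf("motif_weight\t%g", cfg$motif_weight),
    sprintf("methylation_effect\t%g", cfg$methylation_effect),
    sprintf("base_composition\t%s",
            paste(sprintf("%s=%g", .BASES, cfg$base_composition),
                  collapse = ",")),
    sprintf("dinuc_weights\t%s",
            if (is.null(cfg$dinuc_weights)) "none"
            else paste(signif(as.vector(cfg$dinuc_weights), 6),
                       collapse = ",")),
    sprintf("planted_pwm\t%s",
            if (is.null(cfg$planted_pwm)) "none"
            else paste(signif(as.vector(cfg$planted_pwm$probs), 6),
                       collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
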