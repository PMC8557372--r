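# Shared fixtures, all generated in code.

toy_genome <- function(seq = "ACGTACGTACGT", name = "c1") {
  genome_from_seqs(stats::setNames(seq, name))
}

random_windows <- function(n, width = 51L, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

# uniform random PWM of a given width (columns renormalized)
random_pwm <- function(width, seed = 1L, background = rep(0.25, 4)) {
  with_seed(seed, {
    m <- matrix(stats::runif(4 * width, 0.05, 1), 4, width)
    new_pwm(sweep(m, 2, colSums(m), "/"), background = background,
            pseudocount = 1e-6)
  })
}

# a sharp 9-bp PWM for scan-oriented simulations
sharp_pwm9 <- function(cons = c("G", "C", "A", "T", "A", "T", "A", "G", "C"),
                       p_cons = 0.88) {
  m <- matrix((1 - p_cons) / 3, 4, 9,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(9)) m[cons[j], j] <- p_cons
  new_pwm(unname(m))
}

# centered dinucleotide weight matrix favoring CG and TA steps
cg_ta_dinuc <- function(scale = 1) {
  W <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  W["C", "G"] <- 1.2 * scale
  W["T", "A"] <- 1.0 * scale
  W - mean(W)
}
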