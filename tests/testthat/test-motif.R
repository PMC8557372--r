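test_that("paired-fragment sites require the exact 9-bp overlap", {
  f <- data.frame(contig = "c1",
                  start = c(100L, 191L), end = c(200L, 300L))
  s <- paired_fragment_sites(f)
  expect_equal(s$pos, 195L)  # = right start + 4 = left end - 5
  # overlap 8: no site
  f8 <- data.frame(contig = "c1", start = c(100L, 192L),
                   end = c(200L, 300L))
  expect_equal(nrow(paired_fragment_sites(f8)), 0L)
  # overlap 10: no site
  f10 <- data.frame(contig = "c1", start = c(100L, 190L),
                    end = c(200L, 300L))
  expect_equal(nrow(paired_fragment_sites(f10)), 0L)
  # three chained fragments -> two sites
  f3 <- data.frame(contig = "c1", start = c(0L, 91L, 191L),
                   end = c(100L, 200L, 300L))
  expect_equal(nrow(paired_fragment_sites(f3)), 2L)
})

test_that("paired sites are a subset of strand-merged shifted sites", {
  cfg <- sim_config(genome_length = 50000L, n_insertions = 3000L, seed = 12)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  fr <- sites_to_fragments(ins$sites, g, seed = 12)
  paired <- paired_fragment_sites(fr)
  shifted <- merge_site_strands(shift_fragments(fr)$sites)
  expect_gt(nrow(paired), 0)
  expect_true(all(paste(paired$contig, paired$pos) %in%
                    paste(shifted$contig, shifted$pos)))
})

test_that("subsampling is deterministic, uniform and bounded", {
  sites <- data.frame(contig = "c1", pos = 0:999, strand = "+", count = 1L)
  s1 <- subsample_sites(sites, 100, seed = 3)
  s2 <- subsample_sites(sites, 100, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100L)
  # n = all is the identity up to order
  expect_equal(subsample_sites(sites, 1000, seed = 1), sites,
               ignore_attr = TRUE)
  expect_warning(big <- subsample_sites(sites, 2000, seed = 1), "available")
  expect_equal(nrow(big), 1000L)
  expect_error(subsample_sites(sites, 0, seed = 1))
})

test_that("PWM building recovers degenerate and prior-only limits", {
  g <- toy_genome("TACGTACGTT")
  # four sites all with window "ACG" (positions 1, 5 are A of ACG)
  sites <- data.frame(contig = "c1", pos = c(2L, 2L, 6L, 6L), strand = "+",
                      count = 1L)
  pwm <- suppressWarnings(
    build_pwm(sites[rep(1:4, 30), ], g, window = 3, pseudocount = 0,
              background = rep(0.25, 4)))
  expect_equal(pwm$probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwm$probs[, 2], c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(pwm$probs[, 3], c(A = 0, C = 0, G = 1, T = 0))
  # minus-strand sites contribute the reverse complement window
  sites_m <- sites
  sites_m$strand <- "-"
  pwm_m <- build_pwm(sites_m[rep(1:4, 30), ], g, window = 3,
                     pseudocount = 0, background = rep(0.25, 4))
  expect_equal(pwm_consensus(pwm_m), "CGT")
  # too few windows errors
  expect_error(build_pwm(sites, g, window = 3), "100")
})

test_that("PWM building is invariant to input order", {
  cfg <- sim_config(genome_length = 20000L, n_insertions = 2000L, seed = 13)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  p1 <- build_pwm(ins$sites, g, window = 9)
  p2 <- build_pwm(ins$sites[rev(seq_len(nrow(ins$sites))), ], g, window = 9)
  expect_equal(p1$probs, p2$probs)
})

test_that("planted PWM is recovered from simulated sites", {
  truth <- default_planted_pwm()
  cfg <- sim_config(genome_length = 200000L, planted_pwm = truth,
                    motif_weight = 1, n_insertions = 50000L, seed = 14)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  est <- build_pwm(ins$sites, g, window = 9, pseudocount = 1,
                   background = rep(0.25, 4))
  tv <- colSums(abs(est$probs - truth$probs)) / 2
  expect_true(all(tv <= 0.05))
})

test_that("width-1 exact p-values match enumeration", {
  # log-odds (2,1,0,0) on uniform background: P(score >= 2) = 1/4
  probs <- matrix(c(4, 2, 1, 1) / 8, ncol = 1)
  pwm <- new_pwm(probs)
  d <- tn5prefer:::pwm_score_distribution(pwm, 1e-4)
  top <- round(max(pwm$log_odds) / d$grain)
  expect_equal(tn5prefer:::.tail_lookup(d, top), 0.25, tolerance = 1e-9)
  expect_equal(d$total_mass, 1, tolerance = 1e-9)
})

test_that("exact-p DP equals exhaustive enumeration for small widths", {
  for (w in 2:4) {
    pwm <- random_pwm(w, seed = w)
    d <- tn5prefer:::pwm_score_distribution(pwm, 1e-4)
    kmers <- tn5prefer:::all_kmers(w)
    int_scores <- vapply(kmers, function(s) {
      b <- tn5prefer:::base_codes(s)
      sum(d$I[cbind(b, seq_len(w))])
    }, numeric(1))
    # brute-force tail probability at each distinct integer score
    for (s in unique(int_scores)) {
      brute <- sum(0.25^w * (int_scores >= s))
      expect_equal(tn5prefer:::.tail_lookup(d, s), brute, tolerance = 1e-12)
    }
  }
})

test_that("scan returns consensus hits with minimal p and monotone p in score", {
  cfg <- sim_config(genome_length = 100000L, planted_pwm = sharp_pwm9(),
                    motif_weight = 1, n_insertions = 10000L,
                    n_planted_motifs = 1250L, seed = 15)
  g <- simulate_genome(cfg)
  pwm <- sharp_pwm9()
  hits <- scan_pwm(pwm, g, q_threshold = 0.001)
  expect_gt(nrow(hits), 0)
  expect_lte(max(hits$q), 0.001)
  # p monotone nonincreasing in score
  o <- order(hits$score)
  expect_true(all(diff(hits$p[o]) <= 1e-15))
  # consensus windows attain the maximal score
  cons <- pwm_consensus(pwm)
  top <- hits[which.min(hits$p), ]
  win <- substr(g$seq[[1]], top$start + 1, top$end)
  if (top$strand == "-") win <- tn5prefer:::revcomp(win)
  expect_identical(win, cons)
  expect_error(scan_pwm(random_pwm(31), g), "width")
})

test_that("usage summary classifies sites and hits by half-open overlap", {
  hits <- data.frame(contig = "c1", start = 10L, end = 19L, strand = "+",
                     score = 1, p = 1e-6, q = 1e-4)
  inside <- data.frame(contig = "c1", pos = 18L, strand = "*", count = 1L)
  at_end <- data.frame(contig = "c1", pos = 19L, strand = "*", count = 1L)
  u1 <- usage_summary(inside, hits)
  expect_equal(u1$frac_insert_inside, 1)
  expect_equal(u1$frac_motif_used, 1)
  u2 <- usage_summary(at_end, hits)
  expect_equal(u2$frac_insert_inside, 0)
  expect_equal(u2$frac_motif_used, 0)
  u0 <- usage_summary(inside, hits[0, ])
  expect_equal(u0$frac_insert_inside, 0)
  expect_true(is.na(u0$frac_motif_used))
})

test_that("strong-motif insertions fall inside motifs more than uniform null", {
  cfg <- sim_config(genome_length = 100000L,
                    planted_pwm = default_planted_pwm(),
                    motif_weight = 1, n_insertions = 20000L,
                    n_planted_motifs = 1250L, seed = 16)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  pwm <- build_pwm(ins$sites, g, window = 9)
  hits <- scan_pwm(pwm, g, q_threshold = 0.001)
  u <- usage_summary(merge_site_strands(ins$sites), hits)
  cfg0 <- sim_config(genome_length = 100000L,
                     planted_pwm = default_planted_pwm(),
                     motif_weight = 0, n_insertions = 20000L,
                     n_planted_motifs = 1250L, seed = 16)
  ins0 <- simulate_insertions(g, cfg0)
  u0 <- usage_summary(merge_site_strands(ins0$sites), hits)
  expect_gt(u$frac_insert_inside, u0$frac_insert_inside)
})

test_that("MEME minimal format round trips", {
  pwm <- random_pwm(9, seed = 17)
  f <- tempfile(fileext = ".meme")
  write_pwm_meme(pwm, f)
  back <- read_pwm_meme(f)
  expect_equal(back$width, 9)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5)
  expect_equal(back$background, pwm$background, tolerance = 1e-5)
})
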