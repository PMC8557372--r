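test_that("shape encoding matches a naive per-position lookup", {
  tab <- synthetic_shape_table()
  seqs <- random_windows(200, width = 51L, seed = 18)
  enc <- encode_shape(seqs, tab)
  expect_equal(dim(enc), c(200L, 14L * 47L))
  # naive oracle: explicit pentamer dictionary lookup, window by window
  for (i in c(1, 57, 200)) {
    for (sh in c("MGW", "Roll", "ProT")) {
      s <- tab$shapes[[sh]]
      naive <- vapply(1:47, function(c0) {
        p <- substr(seqs[i], c0, c0 + 4)
        if (s$class == "inter") (s$v1[[p]] + s$v2[[p]]) / 2 else s$v1[[p]]
      }, numeric(1))
      expect_equal(unname(enc[i, paste0(sh, "_", 3:49)]), naive)
    }
  }
})

test_that("single-pentamer window encodes to the table entry", {
  tab <- synthetic_shape_table()
  enc <- encode_shape("AAAAA", tab, shapes = "MGW")
  expect_equal(dim(enc), c(1L, 1L))
  expect_equal(unname(enc[1, 1]), unname(tab$shapes$MGW$v1[["AAAAA"]]))
})

test_that("table shuffling preserves the value multiset and is seeded", {
  tab <- synthetic_shape_table()
  sh1 <- shuffle_shape_table(tab, seed = 1)
  sh2 <- shuffle_shape_table(tab, seed = 1)
  sh3 <- shuffle_shape_table(tab, seed = 2)
  for (nm in shape_names()) {
    expect_equal(sort(unname(sh1$shapes[[nm]]$v1)),
                 sort(unname(tab$shapes[[nm]]$v1)))
    expect_identical(sh1$shapes[[nm]]$v1, sh2$shapes[[nm]]$v1)
  }
  # a permutation of 1024 values is essentially never the identity
  expect_false(identical(sh1$shapes$MGW$v1, tab$shapes$MGW$v1))
  expect_false(identical(sh1$shapes$MGW$v1, sh3$shapes$MGW$v1))
  # inter-shape v1/v2 move together: their pairing is preserved
  pair_orig <- paste(tab$shapes$Roll$v1, tab$shapes$Roll$v2)
  pair_shuf <- paste(sh1$shapes$Roll$v1, sh1$shapes$Roll$v2)
  expect_setequal(pair_shuf, pair_orig)
})

test_that("shape table TSV round trips", {
  tab <- synthetic_shape_table()
  f <- tempfile(fileext = ".tsv")
  write_shape_table(tab, f)
  back <- read_shape_table(f)
  expect_equal(back$shapes$MGW$v1, tab$shapes$MGW$v1, tolerance = 1e-12)
  expect_equal(back$shapes$Roll$v2, tab$shapes$Roll$v2, tolerance = 1e-12)
  expect_identical(back$shapes$Roll$class, "inter")
})

test_that("PWM vector encoding is per-position log-odds summing to scan score", {
  pwm <- random_pwm(51, seed = 19)
  seqs <- random_windows(20, width = 51L, seed = 19)
  enc <- encode_pwm_vector(seqs, pwm)
  expect_equal(dim(enc), c(20L, 51L))
  # uniform PWM: all zeros
  upwm <- new_pwm(matrix(0.25, 4, 51))
  expect_true(all(encode_pwm_vector(seqs, upwm) == 0))
  # consensus gets the column maxima
  cons <- pwm_consensus(pwm)
  expect_equal(unname(encode_pwm_vector(cons, pwm)[1, ]),
               unname(apply(pwm$log_odds, 2, max)))
  # row sums equal full-window scores (cross-module identity)
  d <- tn5prefer:::pwm_score_distribution(pwm, 1e-4)
  sc <- tn5prefer:::.scan_scores(tn5prefer:::base_codes(seqs[1]), d$I,
                                 pwm$log_odds)
  expect_equal(sum(enc[1, ]), sc$flt[1], tolerance = 1e-9)
  expect_error(encode_pwm_vector(seqs, random_pwm(9)), "width")
})

test_that("k-mer one-hot blocks have exactly one 1 per block and decode back", {
  seqs <- random_windows(30, width = 51L, seed = 20)
  for (k in 1:3) {
    m <- encode_kmer(seqs, k)
    n_pos <- 51L - k + 1L
    expect_equal(ncol(m), n_pos * 4L^k)
    expect_true(all(Matrix::rowSums(m) == n_pos))
    # block structure: one 1 in each positional block
    blocks <- rep(seq_len(n_pos), each = 4L^k)
    row1 <- as.numeric(m[1, ])
    expect_true(all(tapply(row1, blocks, sum) == 1))
    # decode
    on <- which(row1 == 1)
    kmers <- sub(".*_", "", colnames(m)[on])
    recon <- paste0(kmers[1],
                    paste(substr(kmers[-1], k, k), collapse = ""))
    expect_identical(recon, seqs[1])
  }
  expect_equal(encode_kmer("A", 1)[1, ], c(k1_1_A = 1, k1_1_C = 0,
                                           k1_1_G = 0, k1_1_T = 0))
})

test_that("feature matrices standardize to [0,1] and respect block layout", {
  cfg <- sim_config(genome_length = 30000L, n_insertions = 1500L, seed = 21)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  sites <- subsample_sites(ins$sites, 500, seed = 21)
  sites$count <- 1L
  controls <- sample_control_sites(g, 500, width = 51L, seed = 21)
  pwm <- build_pwm(sites, g, window = 51)
  tab <- synthetic_shape_table()
  fm <- assemble_matrix(sites, controls, g, blocks = c("motif", "shapes"),
                        pwm = pwm, table = tab)
  expect_s3_class(fm, "tn5_feature_matrix")
  expect_equal(ncol(fm$x), 51L + 658L)
  expect_equal(nrow(fm$x), 1000L - fm$n_dropped)
  expect_true(all(fm$x >= 0 & fm$x <= 1))
  cmin <- apply(fm$x, 2, min)
  cmax <- apply(fm$x, 2, max)
  nondegen <- fm$bounds$max > fm$bounds$min
  expect_true(all(abs(cmin[nondegen]) < 1e-12))
  expect_true(all(abs(cmax[nondegen] - 1) < 1e-12))
  # motif-only: 51 columns
  fm_m <- assemble_matrix(sites, controls, g, blocks = "motif", pwm = pwm)
  expect_equal(ncol(fm_m$x), 51L)
  # labels: sites then controls
  expect_equal(sum(fm$labels), nrow(sites) -
                 sum(is.na(site_windows(g, sites, 51L))))
})

test_that("encoding is pure: same window and table give identical vectors", {
  tab <- synthetic_shape_table()
  s <- random_windows(3, width = 51L, seed = 22)
  expect_identical(encode_shape(s, tab), encode_shape(s, tab))
})

test_that("planted dinucleotide signal carries more information in the di block", {
  W <- cg_ta_dinuc(1.2)
  cfg <- sim_config(genome_length = 200000L, dinuc_weights = W,
                    n_insertions = 20000L, seed = 23)
  g <- simulate_genome(cfg)
  ins <- simulate_insertions(g, cfg)
  sites <- subsample_sites(ins$sites, 4000, seed = 23)
  sites$count <- 1L
  controls <- sample_control_sites(g, 4000, width = 51L, seed = 23)
  w <- site_windows(g, rbind(sites, controls), 51L)
  y <- c(rep(1L, nrow(sites)), rep(0L, nrow(controls)))[!is.na(w)]
  w <- w[!is.na(w)]
  # plug-in MI between label and the k-mer category, averaged over positions
  mi_k <- function(k) {
    mean(vapply(seq_len(51L - k + 1L), function(pos) {
      tab <- table(substring(w, pos, pos + k - 1L), y)
      p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p)
      sum(ifelse(p > 0, p * log2(p / outer(px, py)), 0))
    }, numeric(1)))
  }
  expect_gt(mi_k(2), mi_k(1))
})
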