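# A small deterministic two-condition fixture with known bin structure.
meth_fixture <- function(seed = 40, genome_length = 120000L,
                         methylation_effect = 1.5) {
  cfg <- sim_config(genome_length = genome_length,
                    base_composition = c(A = 0.45, C = 0.05, G = 0.05,
                                         T = 0.45),
                    methylation_effect = methylation_effect,
                    n_insertions = 30000L, seed = seed)
  g <- simulate_genome(cfg)
  meth <- simulate_methylation(g, cfg)
  insA <- simulate_insertions(g, cfg, methylation = meth$condA)
  cfgB <- cfg
  cfgB$seed <- cfg$seed + 500L
  insB <- simulate_insertions(g, cfgB, methylation = meth$condB)
  bins <- tile_and_annotate(g, meth, list(condA = insA$sites,
                                          condB = insB$sites))
  list(genome = g, meth = meth, bins = bins)
}

test_that("bins average methylation per condition and count insertions half-open", {
  g <- toy_genome(paste0(strrep("A", 4), "C", strrep("A", 4),   # bin 1: C at 4
                         strrep("A", 2), "CC", strrep("A", 5),  # bin 2: C 11,12
                         strrep("A", 9)))                       # bin 3: no C
  meth <- list(
    condA = data.frame(contig = "c1", start = c(4L, 11L, 12L),
                       end = c(5L, 12L, 13L), value = c(80, 30, 50)),
    condB = data.frame(contig = "c1", start = c(4L, 11L, 12L),
                       end = c(5L, 12L, 13L), value = c(0, 0, 0))
  )
  sites <- list(
    condA = data.frame(contig = "c1", pos = c(0L, 8L, 9L, 17L, 18L),
                       strand = "+", count = c(1L, 1L, 2L, 1L, 5L)),
    condB = data.frame(contig = "c1", pos = 0L, strand = "+", count = 1L)
  )
  bins <- tile_and_annotate(g, meth, sites)
  expect_equal(nrow(bins), 3L)
  expect_equal(bins$meth_condA, c(80, 40, NA))
  expect_equal(bins$meth_condB, c(0, 0, NA))
  # half-open: pos 8 in bin 1, pos 9 in bin 2, pos 17 in bin 2, 18 in bin 3
  expect_equal(bins$ins_condA, c(2, 3, 5))
  expect_equal(bins$ninemer, c("AAAACAAAA", "AACCAAAAA", "AAAAAAAAA"))
  expect_error(tile_and_annotate(g, list(condA = data.frame(
    contig = "cX", start = 1L, end = 2L, value = 1), condB = meth$condB),
    sites), "contig")
})

test_that("group classification applies the four >0 / =0 definitions", {
  bins <- data.frame(contig = "c1", start = c(0, 9, 18, 27, 36),
                     end = c(9, 18, 27, 36, 45),
                     ninemer = strrep("A", 9),
                     meth_condA = c(40, 0, 12, 0, NA),
                     meth_condB = c(0, 0, 7, 33, 5),
                     ins_condA = 1, ins_condB = 1)
  cl <- classify_groups(bins)
  expect_equal(nrow(cl), 4L)  # NA row ineligible
  expect_equal(cl$group, c("condA-only", "None", "Both", "condB-only"))
  # swapping conditions swaps the -only labels and fixes Both/None
  bins_sw <- bins
  names(bins_sw)[names(bins_sw) == "meth_condA"] <- "tmp"
  names(bins_sw)[names(bins_sw) == "meth_condB"] <- "meth_condA"
  names(bins_sw)[names(bins_sw) == "tmp"] <- "meth_condB"
  bins_sw <- bins_sw[, names(bins)]
  cl_sw <- classify_groups(bins_sw)
  expect_equal(cl_sw$group, c("condB-only", "None", "Both", "condA-only"))
})

test_that("group labels partition eligible bins", {
  fx <- meth_fixture()
  cl <- classify_groups(fx$bins)
  eligible <- sum(!is.na(fx$bins$meth_condA) & !is.na(fx$bins$meth_condB))
  expect_equal(nrow(cl), eligible)
  expect_equal(sum(table(cl$group)), eligible)
  expect_setequal(unique(cl$group),
                  c("condA-only", "condB-only", "Both", "None"))
})

test_that("9mer profile averages, filters to shared 9mers and Z-scales", {
  fx <- meth_fixture()
  cl <- classify_groups(fx$bins)
  prof <- ninemer_profile(cl)
  expect_gt(nrow(prof), 0)
  # every retained 9mer appears in all four groups
  expect_true(all(table(prof$ninemer) == 4))
  # z-scores per condition have mean 0 and sd 1
  expect_lt(abs(mean(prof$z_condA)), 1e-9)
  expect_lt(abs(sd(prof$z_condA) - 1), 1e-9)
  expect_lt(abs(mean(prof$z_condB)), 1e-9)
  expect_lt(abs(sd(prof$z_condB) - 1), 1e-9)
  # hand-check one mean: pick a retained (ninemer, group) cell with >= 2 bins
  key <- paste(cl$ninemer, cl$group)
  retained <- key[cl$ninemer %in% prof$ninemer]
  pick <- names(which(table(retained) >= 2))[1]
  sel <- key == pick
  expect_equal(prof$mean_condA[paste(prof$ninemer, prof$group) == pick],
               mean(cl$ins_condA[sel]))
})

test_that("a 9mer absent from one group is dropped by the shared filter", {
  mk <- function(nm, grp) data.frame(contig = "c1", start = 0, end = 9,
                                     ninemer = nm, meth_condA = 1,
                                     meth_condB = 1, ins_condA = 1,
                                     ins_condB = 1, group = grp)
  groups <- c("condA-only", "condB-only", "Both", "None")
  bins <- do.call(rbind, c(lapply(groups, mk, nm = strrep("A", 9)),
                           lapply(groups[1:3], mk, nm = strrep("C", 9))))
  prof <- ninemer_profile(bins)
  expect_setequal(unique(prof$ninemer), strrep("A", 9))
})

test_that("11-level stratification uses {0} and ten (.,.] bins", {
  bins <- data.frame(contig = "c1", start = 0, end = 9, ninemer = "x",
                     meth_condA = c(0, 0.5, 10, 10.1, 100, NA),
                     ins_condA = c(1, 2, 3, 4, 5, 6))
  lv <- stratify_levels(bins, "condA")
  asg <- attr(lv, "assignments")
  expect_equal(asg$level, c(0L, 1L, 1L, 2L, 10L))
  expect_equal(lv$n[lv$level == 0], 1L)
  expect_equal(sum(lv$n), 5L)  # NA methylation excluded
})

test_that("planted methylation effect raises insertion in methylated levels", {
  fx <- meth_fixture(seed = 41, methylation_effect = 2)
  lv <- stratify_levels(fx$bins, "condA")
  asg <- attr(lv, "assignments")
  med0 <- median(asg$insertion[asg$level == 0])
  med_pos <- median(asg$insertion[asg$level > 0])
  expect_gt(med_pos, med0)
})

test_that("zero methylation effect shows no level trend across seeds", {
  rhos <- vapply(1:20, function(s) {
    fx <- meth_fixture(seed = 100 + s, genome_length = 45000L,
                       methylation_effect = 0)
    lv <- stratify_levels(fx$bins, "condA")
    ok <- lv$n > 0 & !is.na(lv$median)
    suppressWarnings(cor(lv$level[ok], lv$median[ok], method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.3)
})

test_that("outlier trimming removes the distribution tails", {
  x <- c(1:98, 1000, -1000)
  tr <- trim_outliers(x)
  expect_false(any(c(1000, -1000) %in% tr))
  expect_equal(length(tr), 98L)
})
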