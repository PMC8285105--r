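test_that("piRNA size selection keeps 23-29 nt inclusive", {
  r <- small_rna_reads("c1", 0:5, c(21, 22, 23, 26, 29, 31), "+")
  out <- filter_pirna(r)
  expect_equal(out$length, c(23, 26, 29))
  mixed <- small_rna_reads("c1", 0:3, c(21, 23, 29, 31), "+")
  expect_equal(filter_pirna(mixed)$length, c(23, 29))
})

test_that("strand split partitions and conserves reads", {
  r <- small_rna_reads("TRAM", c(0, 5, 9), 25, c("+", "-", "-"))
  sp <- split_by_strand(r)
  expect_equal(nrow(sp$sense), 1)
  expect_equal(nrow(sp$antisense), 2)
  expect_equal(nrow(sp$sense) + nrow(sp$antisense), nrow(r))
  e <- split_by_strand(r[0, ])
  expect_equal(nrow(e$sense) + nrow(e$antisense), 0)
})

test_that("window RPM normalizes counts by total mapped piRNA reads", {
  g <- toy_genome(c(c1 = 20000), "autosome")
  r <- small_rna_reads("c1", c(rep(1000, 50), rep(12000, 10)), 25, "+")
  w <- window_rpm(r, g, width = 5000, total = 2e6)
  expect_equal(w$rpm[1], 25)  # 50 reads / 2M reads * 1e6
  expect_equal(w$count[2], 0)
  expect_equal(sum(w$count), nrow(r))
  ## a single-window library: RPM = 1e6 * count / total
  r2 <- small_rna_reads("c1", rep(100, 7), 25, "+")
  w2 <- window_rpm(r2, g, width = 5000)
  expect_equal(w2$rpm[1], 1e6)
  expect_error(window_rpm(r[0, ], g), "> 0")
})

test_that("window-peak association groups by label and pericentric midpoint", {
  g <- toy_genome(c(c1 = 40000), "autosome",
                  pericentric = data.frame(chrom = "c1", start = 0,
                                           end = 12500))
  wins <- data.frame(chrom = "c1", start = seq(0, 35000, 5000),
                     end = seq(5000, 40000, 5000),
                     count = 1, rpm = c(50, 40, 10, 10, 8, 30, 1, 2))
  pk <- hn_peaks(c("c1", "c1"), c(1000, 26000), c(1200, 26200),
                 summit = c(1100, 26100), stage = "s3")
  pk$persistence <- c("persistent", "temporary")
  out <- associate_windows_peaks(wins, pk, g$pericentric)
  expect_equal(as.character(out$groups),
               c("persistent", "no_peak_pericentric", "no_peak_euchromatic",
                 "no_peak_euchromatic", "no_peak_euchromatic", "temporary",
                 "no_peak_euchromatic", "no_peak_euchromatic"))
  ## window [10000,15000) straddles the pericentric boundary at 12500:
  ## its midpoint 12500 lies outside [0,12500), so it is euchromatic
  expect_equal(unname(out$medians["persistent"]), 50)
  ## identical RPM everywhere: medians equal, tests uninformative
  wins2 <- wins; wins2$rpm <- 5
  out2 <- associate_windows_peaks(wins2, pk, g$pericentric)
  expect_true(all(out2$medians == 5))
  expect_true(all(out2$tests$p == 1))
})

test_that("per-family consensus piRNA coverage is mean per-position depth", {
  lib <- te_library(c("FAMA", "FAMB"), c(100, 200), "non_ltr")
  r <- small_rna_reads("FAMA", 0, 25, "+")
  out <- te_pirna_coverage(r, lib)
  expect_equal(out$sense[out$family == "FAMA"], 0.25)
  expect_equal(out$antisense[out$family == "FAMA"], 0)
  expect_equal(out$sense[out$family == "FAMB"], 0)
  ## two identical reads double the coverage
  out2 <- te_pirna_coverage(rbind(r, r), lib)
  expect_equal(out2$sense[1], 0.5)
  ## unknown targets are skipped with a warning
  bad <- small_rna_reads(c("FAMA", "NOPE"), 0, 25, "+")
  expect_warning(out3 <- te_pirna_coverage(bad, lib), "unknown")
  expect_equal(out3$n_sense[1], 1)
})

test_that("copy-number scaling divides normalized RNA by normalized DNA", {
  expect_equal(scaled_te_expression(100, 200, 50, 100), 1)
  expect_equal(scaled_te_expression(0, 200, 50, 100), 0)
  expect_true(is.na(scaled_te_expression(100, 0, 50, 100)))
  expect_error(scaled_te_expression(1, 1, 0, 1), "> 0")
  ## invariance to a common factor on RNA counts and the RNA normalizer
  x1 <- scaled_te_expression(c(10, 20), c(5, 5), 40, 10)
  x2 <- scaled_te_expression(c(30, 60), c(5, 5), 120, 10)
  expect_equal(x1, x2)
})

test_that("stage fold changes use the pseudocount-guarded ratio", {
  expect_equal(stage_fold_change(2, 2)$fold, 1)
  expect_equal(stage_fold_change(1, 2)$fold, 2.01 / 1.01)
  out <- stage_fold_change(c(1, 2, 4), c(2, 4, 8))
  expect_equal(out$group_mean, mean(out$fold))
})

test_that("sex inference thresholds the autosome:X coverage ratio", {
  g <- toy_genome(c(a1 = 3000, x1 = 2000), c("autosome", "X"))
  male <- coverage_track(list(a1 = rep(100, 3000), x1 = rep(50, 2000)), g)
  out <- infer_sex(male, g)
  expect_equal(out$ratio, 2)
  expect_equal(out$sex, "male")
  female <- coverage_track(list(a1 = rep(100, 3000), x1 = rep(100, 2000)), g)
  expect_equal(infer_sex(female, g)$sex, "female")
  ## ratio exactly at the threshold is called female (strict >)
  edge <- coverage_track(list(a1 = rep(150, 3000), x1 = rep(100, 2000)), g)
  expect_equal(infer_sex(edge, g)$ratio, 1.5)
  expect_equal(infer_sex(edge, g)$sex, "female")
  zero <- coverage_track(list(a1 = rep(100, 3000), x1 = rep(0, 2000)), g)
  expect_error(infer_sex(zero, g), "zero")
})

test_that("ATAC enrichment is the pseudocounted log2 ratio over DNA", {
  g <- toy_genome(c(a1 = 4000), "autosome")
  atac <- flat_track(g, 10, assay = "atac", sex = "male")
  dna <- flat_track(g, 10, assay = "dna", sex = "male")
  atac_n <- normalize_by_median(atac)
  dna_n <- normalize_by_median(dna)
  out <- atac_enrichment(atac_n, dna_n)
  expect_true(all(out$values$a1 == 0))
  ## 2x accessibility at a site, values well above the pseudocount (the
  ## doubled region is small enough not to move the window median)
  atac2 <- coverage_track(list(a1 = c(rep(20, 100), rep(10, 3900))), g,
                          assay = "atac", sex = "male")
  out2 <- atac_enrichment(normalize_by_median(atac2), dna_n)
  expect_equal(out2$values$a1[1], 1, tolerance = 0.05)
  ## sex mismatch and unnormalized inputs are errors
  dna_f <- flat_track(g, 10, assay = "dna", sex = "female")
  expect_error(atac_enrichment(atac_n, normalize_by_median(dna_f)),
               "sex")
  expect_error(atac_enrichment(atac, dna), "normalized")
})

test_that("rank-sum matches brute-force enumeration and handles scale", {
  expect_equal(rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(17)
  for (k in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    vals <- sample(1:100, n + m)
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(rank_sum(x, y)$p, brute_ranksum_p(x, y), tolerance = 1e-12)
  }
  ## large clearly-shifted samples under the normal approximation
  big <- rank_sum(rnorm(300), rnorm(300) + 2)
  expect_lt(big$p, 1e-6)
  expect_error(rank_sum(numeric(0), 1), "empty")
})

test_that("Pearson correlation and BH adjustment behave canonically", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(2, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
  set.seed(19)
  null <- pearson_r(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted piRNA rate differences are detected per family", {
  gen <- default_gen()
  truth <- gen$truth
  early <- truth$pirna$group == "early"
  hits <- 0
  n_rep <- 12
  for (k in seq_len(n_rep)) {
    sim <- simulate_pirna(truth, total_reads = 100000, seed = 3000 + k)
    counts <- table(factor(sim$consensus$target,
                           levels = truth$pirna$family))
    p <- rank_sum(as.numeric(counts[early]), as.numeric(counts[!early]))$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
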