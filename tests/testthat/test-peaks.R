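test_that("representative enrichment averages replicates, male-only on Y", {
  g <- toy_genome(c(a1 = 1000, y1 = 1000), c("autosome", "neoY"))
  mk <- function(a, y, sex) enrichment_track(
    list(a1 = rep(a, 1000), y1 = rep(y, 1000)), g, sex = sex)
  reps <- list(mk(1, 2, "male"), mk(3, 2, "male"), mk(5, 9, "female"))
  rep_tr <- representative_enrichment(reps)
  expect_equal(rep_tr$values$a1, rep(3, 1000))   # mean of 1,3,5
  expect_equal(rep_tr$values$y1, rep(2, 1000))   # male-only mean of 2,2
  # single replicate is returned as-is
  one <- representative_enrichment(reps[1])
  expect_equal(one$values, reps[[1]]$values)
  # neo-Y with no male replicate is an error
  expect_error(representative_enrichment(list(mk(1, 1, "female"))), "male")
})

test_that("replicate peaks merge only when strictly closer than 100 bp", {
  g99 <- hn_peaks(c("c1", "c1"), c(0, 199), c(100, 300),
                  summit = c(50, 250), enrich = c(1, 5))
  m99 <- merge_replicate_peaks(list(g99[1, ], g99[2, ]))
  expect_equal(nrow(m99), 1)      # gap 99 -> merged
  expect_equal(m99$start, 0)
  expect_equal(m99$end, 300)
  expect_equal(m99$summit, 250)   # summit of the higher-enrichment member
  g100 <- hn_peaks(c("c1", "c1"), c(0, 200), c(100, 300),
                   summit = c(50, 250), enrich = c(1, 5))
  m100 <- merge_replicate_peaks(list(g100[1, ], g100[2, ]))
  expect_equal(nrow(m100), 2)     # gap exactly 100 -> kept apart
  # single replicate passes through
  single <- merge_replicate_peaks(list(g99))
  expect_equal(nrow(single), 1)   # the two peaks of one list still merge
  expect_equal(nrow(merge_replicate_peaks(list(g100))), 2)
  # empty input allowed
  expect_equal(nrow(merge_replicate_peaks(list())), 0)
})

test_that("summit-window enrichment truncates at chromosome boundaries", {
  g <- toy_genome(c(c1 = 1000), "autosome")
  tr <- enr_track(g, list(c1 = rep(1.5, 1000)))
  pk <- hn_peaks("c1", 400, 600, summit = 500)
  expect_equal(peak_enrichment(pk, tr), 1.5)
  # asymmetric flanks average to the midpoint
  v <- c(rep(1, 500), rep(3, 500))
  tr2 <- enr_track(g, list(c1 = v))
  expect_equal(peak_enrichment(pk, tr2), 2)
  # summit at 20: window truncated to [0, 120), 120 bases
  pk2 <- hn_peaks("c1", 0, 60, summit = 20)
  tr3 <- enr_track(g, list(c1 = seq_len(1000)))
  expect_equal(peak_enrichment(pk2, tr3), mean(1:120))
})

test_that("the enrichment rule is a strict threshold", {
  expect_false(is_enriched(0.5))
  expect_true(is_enriched(0.51))
  expect_false(is_enriched(-1))
  expect_equal(is_enriched(c(0.4, 0.9), threshold = log2(1.5)),
               c(FALSE, TRUE))
})

test_that("phantom filtering partitions by alternative-mark enrichment", {
  g <- toy_genome(c(c1 = 10000), "autosome")
  pk <- hn_peaks(rep("c1", 5), seq(500, 8500, 2000),
                 seq(700, 8700, 2000), summit = seq(600, 8600, 2000))
  # two peaks planted as shared across marks
  shared <- data.frame(chrom = "c1", start = c(500, 2500),
                       end = c(700, 2700), value = 1.2)
  alt1 <- enr_with_sites(g, 0, shared)
  alt2 <- enr_with_sites(g, 0)
  out <- filter_phantom(pk, list(alt1, alt2))
  expect_equal(sum(out$specificity == "phantom"), 2)
  expect_equal(sum(out$specificity == "specific"), 3)
  expect_equal(which(out$specificity == "phantom"), c(1, 2))
  # partition conserves counts
  expect_equal(sum(table(out$specificity)), nrow(pk))
  # no alternative marks: everything specific
  out0 <- filter_phantom(pk, list())
  expect_true(all(out0$specificity == "specific"))
})

test_that("persistence is judged at the final stage with a strict rule", {
  g <- toy_genome(c(c1 = 4000), "autosome")
  pk <- hn_peaks(c("c1", "c1", "c1"), c(400, 1400, 2400),
                 c(600, 1600, 2600), summit = c(500, 1500, 2500),
                 stage = "s3")
  s7 <- enr_with_sites(g, 0, data.frame(
    chrom = "c1", start = c(400, 1400, 2400), end = c(600, 1600, 2600),
    value = c(1.4, 0.0, 0.5)))
  stages <- hn_stageset(list(s7 = s7))
  out <- classify_persistence(pk, stages)
  expect_equal(out$persistence, c("persistent", "temporary", "temporary"))
  expect_equal(sum(table(out$persistence)), nrow(pk))
  expect_error(classify_persistence(pk, hn_stageset(list(s3 = s7))), "s7")
})

test_that("novelty splits early stage 4 peaks by stage 3 enrichment", {
  g <- toy_genome(c(c1 = 4000), "autosome")
  pk <- hn_peaks(c("c1", "c1"), c(400, 1400), c(600, 1600),
                 summit = c(500, 1500), stage = "e4")
  s3 <- enr_with_sites(g, 0, data.frame(chrom = "c1", start = 400,
                                        end = 600, value = 0.9))
  out <- classify_novelty(pk, s3)
  expect_equal(out$novelty, c("old", "new"))
  expect_equal(sum(table(out$novelty)), nrow(pk))
})

test_that("pre-enrichment fractions count peaks passing the rule earlier", {
  g <- toy_genome(c(c1 = 22000), "autosome")
  pk <- hn_peaks(rep("c1", 10), seq(500, 18500, 2000) - 100,
                 seq(500, 18500, 2000) + 100,
                 summit = seq(500, 18500, 2000), stage = "s7")
  # 6 of 10 peaks pre-enriched at e4, none at s3
  e4 <- enr_with_sites(g, 0, data.frame(
    chrom = "c1", start = seq(500, 10500, 2000) - 150,
    end = seq(500, 10500, 2000) + 150, value = 2))
  s3 <- enr_with_sites(g, 0)
  stages <- hn_stageset(list(s3 = s3, e4 = e4))
  fr <- fraction_pre_enriched(pk, stages)
  expect_equal(unname(fr["s3"]), 0)
  expect_equal(unname(fr["e4"]), 0.6)
  # all enriched everywhere -> 1
  hi <- enr_with_sites(g, 2)
  fr1 <- fraction_pre_enriched(pk, hn_stageset(list(s3 = hi, e4 = hi)))
  expect_equal(unname(fr1), c(1, 1))
})

test_that("summit profiles sort rows by mean and bound the median", {
  g <- toy_genome(c(c1 = 10000), "autosome")
  flat <- enr_with_sites(g, 1.25)
  pk <- hn_peaks(c("c1", "c1"), c(2000, 6000), c(2200, 6200),
                 summit = c(2100, 6100), name = c("p1", "p2"))
  pr <- profile_around(pk, flat, flank = 200, n_boot = 50)
  expect_true(all(pr$median == 1.25))
  expect_true(all(pr$ci_lower == 1.25 & pr$ci_upper == 1.25))
  # triangular enrichment peaks at offset 0
  tri <- enr_with_sites(g, 0)
  tri$values$c1[2100 + 1 + (-300:300)] <- 2 * (1 - abs(-300:300) / 301)
  pr2 <- profile_around(pk[1, ], tri, flank = 200, n_boot = 10)
  expect_equal(pr2$offsets[which.max(pr2$median)], 0)
  # rows ordered by descending mean
  two <- enr_with_sites(g, 0, data.frame(
    chrom = "c1", start = c(1900, 5900), end = c(2300, 6300),
    value = c(1, 3)))
  pr3 <- profile_around(pk, two, flank = 100, n_boot = 10)
  expect_equal(rownames(pr3$matrix), c("p2", "p1"))
  expect_error(profile_around(pk[0, ], flat), "empty")
})

test_that("trajectories are invariant under peak reordering", {
  g <- toy_genome(c(c1 = 10000), "autosome")
  pk <- hn_peaks(rep("c1", 4), c(1000, 3000, 5000, 7000) - 100,
                 c(1000, 3000, 5000, 7000) + 100,
                 summit = c(1000, 3000, 5000, 7000))
  stages <- hn_stageset(list(
    s3 = enr_with_sites(g, 0.2), s5 = enr_with_sites(g, 0.8),
    s7 = enr_with_sites(g, 1.6)))
  tr <- trajectory(pk, stages, n_boot = 100)
  expect_equal(tr$stage, c("s3", "s5", "s7"))
  expect_equal(tr$median, c(0.2, 0.8, 1.6))
  tr2 <- trajectory(pk[c(3, 1, 4, 2), ], stages, n_boot = 100)
  expect_equal(tr2, tr)
  # single peak: trajectory is its own window means, degenerate CI
  tr1 <- trajectory(pk[1, ], stages, n_boot = 50)
  expect_equal(tr1$median, tr1$ci_lower)
  expect_equal(tr1$median, tr1$ci_upper)
})

test_that("peak annotation uses TE > microsatellite > gene precedence", {
  chroms <- data.frame(name = "c1", length = 10000, class = "autosome")
  ann <- data.frame(
    chrom = "c1", start = c(1000, 3000, 3050, 5000),
    end = c(1500, 3500, 3600, 5500),
    category = c("TE", "gene", "TE", "gene"),
    name = c("t1", "g1", "t2", "g2"), strand = "+")
  g <- hn_genome(chroms,
                 pericentric = data.frame(chrom = "c1", start = 0,
                                          end = 2000),
                 annotations = ann)
  pk <- hn_peaks(rep("c1", 3), c(1100, 3100, 8000), c(1300, 3300, 8200),
                 summit = c(1200, 3200, 8100))
  out <- annotate_peaks(pk, g)
  expect_equal(as.character(out$category), c("TE", "TE", "other"))
  expect_equal(out$fraction_pericentric, 1 / 3)
})

test_that("narrowPeak files round-trip through the reader", {
  pk <- hn_peaks(c("c1", "c2"), c(100, 5000), c(400, 5400),
                 summit = c(250, 5100), stage = "s3", enrich = c(2.5, 1.1))
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, path)
  back <- read_peaks(path, stage = "s3")
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$enrich, pk$enrich)
  expect_equal(back$stage, c("s3", "s3"))
})
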