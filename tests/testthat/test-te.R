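lib_tram <- te_library(
  name = c("TRAM", "TRAM_LTR", "LOA"),
  length = c(5000, 372, 4500),
  kind = c("ltr_internal", "ltr_terminal", "non_ltr"),
  partner = c("TRAM_LTR", "TRAM", NA))

test_that("RepeatMasker GFF parsing converts coordinates and categories", {
  gff <- c(
    "##gff-version 2",
    "c1\tRepeatMasker\tsimilarity\t101\t472\t.\t+\t.\tTarget \"Motif:TRAM\" 1 372",
    "c1\tRepeatMasker\tsimilarity\t1001\t1200\t.\t+\t.\tTarget \"Motif:(AGAT)n\" 1 200",
    "c1\tRepeatMasker\tsimilarity\t2001\t2400\t.\t-\t.\tTarget \"Motif:UNKNOWN_FAM\" 1 400",
    "c1\tRepeatMasker\tsimilarity\t3001\t3400\t.\t+\t.\tTarget \"Motif:TRAM\" 1 6000")
  path <- withr::local_tempfile(fileext = ".gff")
  writeLines(gff, path)
  expect_warning(ins <- parse_repeatmasker_gff(path, lib_tram), "skipped")
  expect_equal(nrow(ins), 2)
  expect_equal(attr(ins, "skipped"), 2)  # unknown family + bad span
  te <- ins[ins$category == "TE", ]
  expect_equal(te$start, 100)            # 1-based closed -> 0-based half-open
  expect_equal(te$end, 472)
  expect_equal(te$cons_start, 0)
  expect_equal(te$cons_end, 372)
  ms <- ins[ins$category == "microsatellite", ]
  expect_equal(ms$family, "(AGAT)n")
})

test_that("generated insertions round-trip through GFF", {
  gen <- default_gen()
  sub <- gen$insertions[1:25, ]
  path <- withr::local_tempfile(fileext = ".gff")
  write_repeatmasker_gff(sub, path)
  back <- parse_repeatmasker_gff(path, gen$library)
  expect_equal(back$chrom, sub$chrom)
  expect_equal(back$start, sub$start)
  expect_equal(back$end, sub$end)
  expect_equal(back$strand, sub$strand)
  expect_equal(back$family, sub$family)
  expect_equal(back$cons_start, sub$cons_start)
  expect_equal(back$cons_end, sub$cons_end)
})

test_that("consensus projection is strand-aware and identity on full spans", {
  g <- toy_genome(c(c1 = 2000), "autosome")
  lib <- te_library("FAMX", 100, "non_ltr")
  ## + strand, full consensus coverage, constant enrichment
  ins <- te_insertions("c1", 500, 600, "+", "FAMX", 0, 100)
  tr <- enr_with_sites(g, 0, data.frame(chrom = "c1", start = 500,
                                        end = 600, value = 2))
  mat <- project_to_consensus(ins, tr, lib)
  expect_equal(unname(mat[1, ]), rep(2, 100))
  ## identity round trip: row equals the genomic values
  v <- seq(0.1, 10, length.out = 100)
  tr2 <- enr_track(g, list(c1 = c(rep(0, 500), v, rep(0, 1400))))
  mat2 <- project_to_consensus(ins, tr2, lib)
  expect_equal(unname(mat2[1, ]), v)
  expect_equal(unname(consensus_profile(mat2)), v)
  ## reverse strand: ascending genomic values descend along the consensus
  ins_m <- te_insertions("c1", 500, 600, "-", "FAMX", 0, 100)
  mat3 <- project_to_consensus(ins_m, tr2, lib)
  expect_equal(unname(mat3[1, ]), rev(v))
  ## strand-reversal equivariance: flipping strand and genomic values
  ## leaves the consensus row unchanged
  tr_rev <- enr_track(g, list(c1 = c(rep(0, 500), rev(v), rep(0, 1400))))
  mat4 <- project_to_consensus(ins_m, tr_rev, lib)
  expect_equal(mat4[1, ], mat2[1, ])
  ## two insertions on disjoint consensus ranges
  ins2 <- te_insertions(c("c1", "c1"), c(500, 900), c(550, 950),
                        c("+", "+"), "FAMX", c(0, 50), c(50, 100))
  mat5 <- project_to_consensus(ins2, tr, lib)
  expect_equal(sum(!is.na(mat5)), 100)
  expect_true(all(is.na(mat5[rownames(mat5) == "c1:900-950(+)", 1:50])))
  expect_error(project_to_consensus(ins[0, ], tr, lib), "empty")
})

test_that("column means skip undefined cells and flag empty columns", {
  m <- matrix(c(1, 3, NA, 5, NA, NA), nrow = 2)
  out <- consensus_profile(m)
  expect_equal(out, c(2, 5, NA_real_))
})

test_that("LTR structure classification follows the gap rules", {
  lib <- lib_tram
  mk <- function(starts, ends, strands, fams) {
    te_insertions("c1", starts, ends, strands, fams,
                  cons_start = 0, cons_end = ifelse(fams == "TRAM", 5000, 372))
  }
  ## flanked within 10 bp on both sides, same strand -> full length
  full <- mk(c(1000, 1375, 5002), c(1372, 5000, 5374), "+",
             c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  out <- classify_ltr_structure(full, lib, "TRAM")
  expect_equal(out$structural_class, "full_length")
  ## upstream LTR 6000 bp away, downstream adjacent -> 5' truncated
  five <- mk(c(1000, 7372, 11000), c(1372, 11000, 11372), "+",
             c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  out5 <- classify_ltr_structure(five, lib, "TRAM")
  expect_equal(out5$structural_class, "five_prime_truncated")
  ## flanking LTRs on the opposite strand are not valid flanks
  anti <- mk(c(1000, 1375, 5002), c(1372, 5000, 5374), c("-", "+", "-"),
             c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  outa <- classify_ltr_structure(anti, lib, "TRAM")
  expect_equal(outa$structural_class, "other")
  ## gap exactly 10 counts as adjacent; gap 11 does not
  g10 <- mk(c(1000, 1382, 5010), c(1372, 5000, 5382), "+",
            c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  expect_equal(classify_ltr_structure(g10, lib, "TRAM")$structural_class,
               "full_length")
  g11 <- mk(c(1000, 1383, 5010), c(1372, 5000, 5382), "+",
            c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  expect_equal(classify_ltr_structure(g11, lib, "TRAM")$structural_class,
               "other")
  ## far boundary: 5000 is still "near" (-> other), 5001 is missing
  f5000 <- mk(c(1000, 6372, 11374), c(1372, 11372, 11746), "+",
              c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  expect_equal(classify_ltr_structure(f5000, lib, "TRAM")$structural_class,
               "other")
  f5001 <- mk(c(1000, 6373, 11375), c(1372, 11373, 11747), "+",
              c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  expect_equal(classify_ltr_structure(f5001, lib, "TRAM")$structural_class,
               "five_prime_truncated")
  ## strand-aware: on "-" the 5' side is genomic right
  minus <- mk(c(1000, 7372, 11005), c(1372, 11000, 11377), "-",
              c("TRAM_LTR", "TRAM", "TRAM_LTR"))
  expect_equal(classify_ltr_structure(minus, lib, "TRAM")$structural_class,
               "three_prime_truncated")
})

test_that("classification is exhaustive and mutually exclusive", {
  gen <- default_gen()
  out <- classify_ltr_structure(gen$insertions, gen$library, "TRAM")
  expect_false(anyNA(out$structural_class))
  expect_true(all(out$structural_class %in%
                    c("full_length", "five_prime_truncated",
                      "three_prime_truncated", "other")))
  expect_equal(nrow(out), sum(gen$insertions$family == "TRAM"))
})

test_that("truncation contrast averages the correct terminal kilobase", {
  g <- toy_genome(c(c1 = 30000), "autosome")
  ## enrichment 2 over the last 1 kb of the full-length internal only
  full <- te_insertions("c1", 1000, 6000, "+", "TRAM", 0, 5000)
  trunc <- te_insertions("c1", 11000, 15000, "+", "TRAM", 1000, 5000)
  tr <- enr_with_sites(g, 0, data.frame(chrom = "c1", start = 5000,
                                        end = 6000, value = 2))
  out <- truncation_contrast(full, trunc, list(s7 = tr), side = "five_prime")
  expect_equal(out$mean_full, 2)
  expect_equal(out$mean_truncated, 0)
  expect_equal(out$fold, 4)
  ## three-prime contrast uses the first kilobase
  tr2 <- enr_with_sites(g, 0, data.frame(chrom = "c1", start = 1000,
                                         end = 2000, value = 1))
  out2 <- truncation_contrast(full, trunc, list(s7 = tr2),
                              side = "three_prime")
  expect_equal(out2$mean_full, 1)
  ## internal shorter than 1 kb: averaged over its full length
  short <- te_insertions("c1", 20000, 20500, "+", "TRAM", 0, 500)
  tr3 <- enr_with_sites(g, 0, data.frame(chrom = "c1", start = 20000,
                                         end = 20500, value = 3))
  out3 <- truncation_contrast(full, short, list(s7 = tr3),
                              side = "five_prime")
  expect_equal(out3$mean_truncated, 3)
  ## identical groups: fold near 1, insignificant
  set.seed(9)
  noisy <- enr_track(g, list(c1 = rnorm(30000, 1, 0.1)))
  same <- te_insertions("c1", seq(1000, 19000, 2000), seq(1000, 19000, 2000) + 1500,
                        "+", "TRAM", 0, 1500)
  outn <- truncation_contrast(same[1:5, ], same[6:10, ], list(s7 = noisy),
                              side = "five_prime")
  expect_equal(outn$fold, 1, tolerance = 0.05)
  expect_gt(outn$p, 0.05)
  expect_error(truncation_contrast(full[0, ], trunc, list(s7 = tr)),
               "nonempty")
})

test_that("family copy counts split genome-wide and neo-Y insertions", {
  chroms <- data.frame(name = c("a1", "y1"), length = c(10000, 10000),
                       class = c("autosome", "neoY"))
  g <- hn_genome(chroms)
  ins <- te_insertions(c("a1", "y1", "y1", "a1", "a1"),
                       c(0, 0, 5000, 2000, 4000),
                       c(1000, 1000, 6000, 3000, 5000),
                       "+", c("F1", "F1", "F1", "F2", "F2"),
                       0, 1000)
  out <- family_copy_counts(ins, g, family_sets = list(hot = "F1"))
  expect_equal(out$counts$total, c(3, 2))
  expect_equal(out$counts$neoY, c(2, 0))
  expect_equal(out$tests$hot$fold_total, 1.5)
  # all-autosomal insertions have zero neo-Y counts
  auto <- ins[ins$chrom == "a1", ]
  out2 <- family_copy_counts(auto, g)
  expect_true(all(out2$counts$neoY == 0))
})

test_that("peak summits map to consensus positions through insertions", {
  lib <- te_library("FAMX", 100, "non_ltr")
  ins <- te_insertions("c1", 1000, 1100, "+", "FAMX", 0, 100)
  pk <- hn_peaks("c1", 1040, 1060, summit = 1050, name = "pk1")
  out <- te_peak_overlap(pk, ins, lib)
  expect_equal(out$per_family$n_peaks, 1)
  expect_equal(out$positions$cons_pos, 50)
  ## reverse strand mirrors the position
  ins_m <- te_insertions("c1", 1000, 1100, "-", "FAMX", 0, 100)
  out_m <- te_peak_overlap(pk, ins_m, lib)
  expect_equal(out_m$positions$cons_pos, 49)
  ## a peak outside every insertion stays unassigned
  pk2 <- hn_peaks("c1", 5000, 5100, summit = 5050)
  out2 <- te_peak_overlap(pk2, ins, lib)
  expect_equal(nrow(out2$positions), 0)
  expect_equal(out2$per_family$n_peaks, 0)
})
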