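## derive a deterministic sub-seed (kept below 2^31)
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Run the full analysis pipeline on a synthetic genome
#'
#' Generates the synthetic genome, simulates spike-in-distorted ChIP/input
#' pairs for every stage and replicate, normalizes them (median autosomal
#' + spike-in quantile-bin shift), calls and merges replicate peaks,
#' applies the developmental taxonomy (phantom filtering,
#' persistent/temporary, old/new), projects enrichment onto the TRAM
#' consensus, runs the LTR truncation contrast, associates piRNA windows
#' with peaks, and computes copy-number-scaled TE expression -- then
#' scores every classification against the planted truth.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed controlling every random draw.
#' @param outdir if non-`NULL`, a directory where all standard-format
#'   output files (bedGraph, narrowPeak, BED, TSV, JSON) are written.
#' @param n_boot bootstrap resamples for profile/trajectory CIs.
#' @param flank profile flank in bp.
#' @return A large named list of results; see the package vignette.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, outdir = NULL,
                         n_boot = 200, flank = 1000) {
  gen <- generate_genome(config, seed)
  genome <- gen$genome; lib <- gen$library
  insertions <- gen$insertions; truth <- gen$truth
  pseudo <- config$pseudo
  sexes <- config$replicate_sexes
  n_rep <- config$n_replicates

  ## ---- spike-in normalization ------------------------------------------
  sample_ids <- names(truth$spikein$distortions)
  spike_wins <- list()
  spike_pairs <- list()
  for (k in seq_along(sample_ids)) {
    sp <- simulate_spikein_pair(truth, sample_ids[k], subseed(seed, 7000 + k))
    spike_pairs[[sample_ids[k]]] <- sp
    spike_wins[[sample_ids[k]]] <-
      window_enrichment(sp$chip, sp$input, pseudo)
  }
  reference <- build_spikein_reference(spike_pairs, pseudo)
  shifts <- lapply(spike_wins, function(w)
    fit_quantile_shift(w$value, reference))

  ## ---- stage tracks, enrichment, per-replicate peak calls ---------------
  stage_tracks <- list()   # representative enrichment per stage
  rep_peaks <- list(s3 = list(), e4 = list())
  input_s3_male <- NULL
  for (stage in HN_STAGES) {
    reps <- list()
    for (r in seq_len(n_rep)) {
      sid <- paste0(stage, "_rep", r)
      tr <- simulate_stage_tracks(truth, stage, r, sexes[r],
                                  subseed(seed, 100 * match(stage, HN_STAGES) + r),
                                  distortion = truth$spikein$distortions[[sid]],
                                  genome = genome)
      if (stage == "s3" && sexes[r] == "male" && is.null(input_s3_male))
        input_s3_male <- tr$input
      enr <- enrichment(tr$chip, tr$input, pseudo)
      enr <- apply_shift(enr, shifts[[sid]])
      reps[[r]] <- enr
      if (stage %in% c("s3", "e4"))
        rep_peaks[[stage]][[r]] <- call_peaks_simple(enr, stage = stage)
    }
    stage_tracks[[stage]] <- representative_enrichment(reps, genome)
  }
  stages <- hn_stageset(stage_tracks)

  ## ---- alternative-mark tracks at stage 3 (phantom detection) -----------
  alt_marks <- c("H3", "H3K4me3", "H4K16ac")
  alt_tracks <- lapply(seq_along(alt_marks), function(k) {
    tr <- simulate_stage_tracks(truth, "s3", 1, "male",
                                subseed(seed, 9000 + k),
                                mark = alt_marks[k], genome = genome)
    enrichment(tr$chip, tr$input, pseudo)
  })
  names(alt_tracks) <- alt_marks

  ## ---- replicate merging and taxonomy -----------------------------------
  s3_merged <- merge_replicate_peaks(rep_peaks$s3, track = stage_tracks$s3)
  s3_merged$stage <- "s3"
  e4_merged <- merge_replicate_peaks(rep_peaks$e4, track = stage_tracks$e4)
  e4_merged$stage <- "e4"

  s3_all <- filter_phantom(s3_merged, alt_tracks)
  s3_specific <- s3_all[s3_all$specificity == "specific", , drop = FALSE]
  s3_specific <- classify_persistence(s3_specific, stages)
  e4_classified <- classify_novelty(e4_merged, stage_tracks$s3)

  ## score recovered labels against the planted truth
  truth_labels <- function(peaks) {
    m <- match_peaks_to_sites(peaks, truth)
    s <- truth$sites[m, , drop = FALSE]
    data.frame(matched = !is.na(m),
               phantom = s$phantom,
               temporary = s$temporary,
               onset_s3 = s$type %in% c("tram5", "sym_s3"))
  }
  t3 <- truth_labels(s3_all)
  phantom_acc <- mean((s3_all$specificity[t3$matched] == "phantom") ==
                        t3$phantom[t3$matched])
  t3s <- truth_labels(s3_specific)
  persistence_acc <- mean(
    (s3_specific$persistence[t3s$matched] == "temporary") ==
      t3s$temporary[t3s$matched])
  t4 <- truth_labels(e4_classified)
  novelty_acc <- mean((e4_classified$novelty[t4$matched] == "old") ==
                        t4$onset_s3[t4$matched])

  ## ---- profiles, trajectories, annotation --------------------------------
  traj <- trajectory(s3_specific, stages, n_boot = n_boot,
                     seed = subseed(seed, 11))
  prof <- profile_around(s3_specific, stage_tracks$s3, flank = flank,
                         n_boot = n_boot, seed = subseed(seed, 12))
  ann <- annotate_peaks(s3_specific, genome)
  s7_peaks <- call_peaks_simple(stage_tracks$s7, stage = "s7")
  pre_enriched <- fraction_pre_enriched(s7_peaks, stages,
                                        threshold = log2(1.5))

  ## ---- TE structure -------------------------------------------------------
  tram_name <- config$tram$name
  structure_cls <- classify_ltr_structure(insertions, lib, tram_name)
  full_ins <- structure_cls[structure_cls$structural_class == "full_length", ]
  five_ins <- structure_cls[
    structure_cls$structural_class == "five_prime_truncated", ]
  contrast <- truncation_contrast(full_ins, five_ins, stages$tracks,
                                  side = "five_prime")
  tram_internal <- insertions[insertions$family == tram_name, , drop = FALSE]
  cons_mat <- project_to_consensus(tram_internal, stage_tracks$s7, lib)
  cons_prof <- consensus_profile(cons_mat)
  overlap <- te_peak_overlap(s3_specific, insertions, lib)
  copy_counts <- family_copy_counts(
    insertions, genome,
    family_sets = list(early = truth$family_groups$early,
                       late = truth$family_groups$late))

  ## ---- piRNA association --------------------------------------------------
  pirna <- simulate_pirna(truth, seed = subseed(seed, 21))
  pir_filt <- filter_pirna(pirna$genomic)
  wins <- window_rpm(pir_filt, genome)
  assoc <- associate_windows_peaks(wins, s3_specific, genome$pericentric,
                                   label = "persistence")
  cons_filt <- filter_pirna(pirna$consensus)
  te_cov <- te_pirna_coverage(cons_filt, lib[lib$kind != "ltr_terminal", ,
                                             drop = FALSE])

  ## ---- expression ---------------------------------------------------------
  expr <- simulate_expression(truth, seed = subseed(seed, 22))
  fam <- expr$families
  scaled <- lapply(c("s2", "s4", "s5"), function(s) {
    scaled_te_expression(fam[[paste0("rna_", s)]], fam$dna_count,
                         expr$rna_normalizer, expr$dna_normalizer)
  })
  names(scaled) <- c("s2", "s4", "s5")
  fold_by_group <- vapply(c("early", "late", "none"), function(g) {
    sel <- fam$group == g
    stage_fold_change(scaled$s2[sel], scaled$s4[sel])$group_mean
  }, numeric(1))
  ## anti-sense piRNA abundance vs maternal expression, log scale
  cov_as <- te_cov$antisense[match(fam$family, te_cov$family)]
  ok <- !is.na(scaled$s2) & !is.na(cov_as)
  corr <- pearson_r(log2(cov_as[ok] + 0.01), log2(scaled$s2[ok] + 0.01))

  ## ---- sex inference and ATAC --------------------------------------------
  sex_call <- infer_sex(input_s3_male, genome)
  atac <- simulate_atac(truth, "s5", "male", subseed(seed, 31), genome)
  atac_enr <- atac_enrichment(normalize_by_median(atac$atac, genome),
                              normalize_by_median(atac$dna, genome))

  results <- list(
    genome = genome, library = lib, insertions = insertions, truth = truth,
    stages = stages, reference = reference, shifts = shifts,
    peaks = list(s3 = s3_all, s3_specific = s3_specific,
                 e4 = e4_classified, s7 = s7_peaks),
    accuracy = list(phantom = phantom_acc, persistence = persistence_acc,
                    novelty = novelty_acc),
    trajectory = traj, profile = prof, annotation = ann,
    fraction_pre_enriched = pre_enriched,
    structure = structure_cls, truncation = contrast,
    consensus_matrix = cons_mat, consensus_profile = cons_prof,
    te_peak_overlap = overlap, copy_counts = copy_counts,
    pirna_windows = wins, pirna_assoc = assoc, te_pirna = te_cov,
    expression = list(families = fam, scaled = scaled,
                      fold_by_group = fold_by_group,
                      pirna_corr = corr),
    sex_call = sex_call, atac = atac_enr)

  if (!is.null(outdir)) write_pipeline_outputs(results, outdir)
  results
}

## ATAC fragment coverage: accessibility decreases where H3K9me3 spreads
simulate_atac <- function(truth, stage, sex, seed, genome) {
  surf <- build_surface(truth, stage)
  dosage <- sex_dosage(genome, sex)
  depth <- truth$depth
  with_seed(seed, {
    atac_vals <- lapply(names(surf), function(chrom) {
      as.numeric(stats::rpois(length(surf[[chrom]]),
                              depth * dosage[[chrom]] *
                                2^(-0.5 * surf[[chrom]])))
    })
    names(atac_vals) <- names(surf)
    dna_vals <- lapply(names(surf), function(chrom) {
      as.numeric(stats::rpois(length(surf[[chrom]]),
                              depth * dosage[[chrom]]))
    })
    names(dna_vals) <- names(surf)
    list(atac = coverage_track(atac_vals, genome, sample_id = "atac",
                               stage = stage, assay = "atac", sex = sex),
         dna = coverage_track(dna_vals, genome, sample_id = "dna",
                              stage = stage, assay = "dna", sex = sex))
  })
}

#' Write all pipeline outputs in their documented formats
#'
#' Emits the chromosome table (TSV), pericentric regions (BED),
#' representative enrichment tracks (bedGraph), merged peak calls
#' (narrowPeak), taxonomy tables (TSV), trajectory/profile matrices (TSV),
#' the TRAM consensus matrix (TSV), structural classes (BED + class
#' column), the truncation contrast (TSV), piRNA reads (BED-like TSV),
#' window RPM (bedGraph), TE piRNA coverage and expression tables (TSV),
#' one fitted shift function (TSV), the ATAC enrichment track (bedGraph)
#' and the ground truth (JSON).
#'
#' @param results return value of [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_chrom_table(results$genome, fp("chromosomes.tsv"))
  write_bed(results$genome$pericentric, fp("pericentric.bed"))
  for (stage in names(results$stages$tracks))
    write_bedgraph(results$stages$tracks[[stage]],
                   fp(paste0("enrichment_", stage, ".bedgraph")))
  write_narrowpeak(results$peaks$s3, fp("peaks_s3.narrowPeak"))
  write_narrowpeak(results$peaks$e4, fp("peaks_e4.narrowPeak"))
  write_peaks(results$peaks$s3, fp("taxonomy_s3.tsv"))
  write_peaks(results$peaks$e4, fp("taxonomy_e4.tsv"))
  utils::write.table(results$trajectory, fp("trajectory.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$profile$matrix, fp("profile_s3.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  utils::write.table(results$consensus_matrix, fp("consensus_TRAM.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  st <- results$structure
  write_bed(data.frame(st$chrom, st$start, st$end,
                       st$structural_class),
            fp("ltr_structure.bed"))
  utils::write.table(results$truncation, fp("truncation_contrast.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$pirna_windows, fp("pirna_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$te_pirna, fp("te_pirna_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$expression$families, fp("expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_shift(results$shifts[[1]], fp("shift_s3_rep1.tsv"))
  write_bedgraph(results$atac, fp("atac_enrichment.bedgraph"))
  truth <- results$truth
  truth_out <- list(seed = truth$seed, sites = truth$sites,
                    insertions = truth$insertions,
                    family_groups = truth$family_groups,
                    distortions = truth$spikein$distortions,
                    pirna = truth$pirna, expression = truth$expression)
  jsonlite::write_json(truth_out, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
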