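#' Construct a peak table
#'
#' Summit-anchored intervals (0-based half-open) carrying stage of origin
#' and the developmental taxonomy labels. Labels start as `NA` and are only
#' set by the classifying operations.
#'
#' @param chrom,start,end interval coordinates.
#' @param summit absolute summit position (bp); `start <= summit < end`.
#' @param stage stage of origin, or `NA`.
#' @param name peak names (default `peak_1`, ...).
#' @param enrich optional per-peak signal value (e.g. MACS2 signalValue),
#'   used as the default score when merging replicate peaks.
#' @return data.frame of class `hn_peaks` with label columns `specificity`
#'   (`specific`/`phantom`), `persistence` (`persistent`/`temporary`) and
#'   `novelty` (`old`/`new`).
#' @export
hn_peaks <- function(chrom, start, end, summit = NULL,
                     stage = NA_character_, name = NULL, enrich = NA_real_) {
  n <- max(length(chrom), length(start))
  if (length(start) == 0) n <- 0
  if (is.null(summit)) summit <- floor((start + end) / 2)
  if (is.null(name)) name <- paste0("peak_", seq_len(n), recycle0 = TRUE)
  name <- rep(name, length.out = n)
  stage <- rep(stage, length.out = n)
  enrich <- rep(enrich, length.out = n)
  df <- data.frame(chrom = rep(as.character(chrom), length.out = n),
                   start = as.numeric(start),
                   end = as.numeric(end), summit = as.numeric(summit),
                   stage = stage, name = name, enrich = enrich,
                   specificity = rep(NA_character_, n),
                   persistence = rep(NA_character_, n),
                   novelty = rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$summit | df$summit >= df$end))
    stop("summit must satisfy start <= summit < end")
  class(df) <- c("hn_peaks", "data.frame")
  df
}

#' Read MACS2 narrowPeak (or BED) peak calls
#'
#' narrowPeak summits are `start + column 10`; BED files may carry an
#' optional 5th column with the absolute summit (defaulting to the
#' interval midpoint).
#'
#' @param path input path.
#' @param stage stage of origin to attach.
#' @param format `"narrowPeak"` or `"bed"`.
#' @return An `hn_peaks` table.
#' @export
read_peaks <- function(path, stage = NA_character_,
                       format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    if (ncol(tab) < 10) stop("narrowPeak requires 10 columns")
    hn_peaks(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
             summit = tab[[2]] + tab[[10]], stage = stage,
             name = as.character(tab[[4]]), enrich = tab[[7]])
  } else {
    summit <- if (ncol(tab) >= 5) tab[[5]] else NULL
    name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else NULL
    hn_peaks(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
             summit = summit, stage = stage, name = name)
  }
}

#' Write peaks with taxonomy labels as TSV
#' @param peaks an `hn_peaks`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' A stage set of representative enrichment tracks
#'
#' Ordered container mapping each developmental stage to its representative
#' enrichment track (and optionally the per-replicate tracks).
#'
#' @param tracks named list of `hn_enrichment`, names from
#'   `c("s3","e4","l4","s5","s7")` in any subset.
#' @param replicates optional named list (same names) of lists of
#'   per-replicate `hn_enrichment`.
#' @return An object of class `hn_stageset`.
#' @export
hn_stageset <- function(tracks, replicates = NULL) {
  if (!all(names(tracks) %in% HN_STAGES))
    stop("unknown stage name(s): ",
         paste(setdiff(names(tracks), HN_STAGES), collapse = ", "))
  ord <- intersect(HN_STAGES, names(tracks))
  structure(list(tracks = tracks[ord], replicates = replicates),
            class = "hn_stageset")
}

#' Average replicate enrichment into a representative track
#'
#' Per-base mean across replicates; on Y/neo-Y chromosomes only male
#' replicates contribute (female embryos carry no Y).
#'
#' @param replicates list of `hn_enrichment` with `sex` metadata.
#' @param genome genome model (defaults to the first replicate's).
#' @return The representative `hn_enrichment`.
#' @export
representative_enrichment <- function(replicates, genome = replicates[[1]]$genome) {
  if (length(replicates) == 0) stop("no replicates")
  cls <- chrom_class(genome)
  male <- vapply(replicates, function(t) identical(t$meta$sex, "male"), logical(1))
  values <- lapply(names(cls), function(chrom) {
    use <- replicates
    if (cls[[chrom]] %in% c("Y", "neoY")) {
      if (!any(male))
        stop("chromosome ", chrom, " (", cls[[chrom]],
             ") requires at least one male replicate")
      use <- replicates[male]
    }
    Reduce(`+`, lapply(use, function(t) t$values[[chrom]])) / length(use)
  })
  names(values) <- names(cls)
  first <- replicates[[1]]
  enrichment_track(values, genome,
                   chip_id = paste0("representative(",
                                    length(replicates), " reps)"),
                   input_id = first$meta$input_id,
                   pseudocount = first$meta$pseudocount,
                   spikein_normalized = first$meta$spikein_normalized,
                   stage = first$meta$stage, mark = first$meta$mark,
                   sex = "unknown")
}

#' Merge peak calls across replicates
#'
#' Peaks from different replicates whose end-to-start gap is strictly less
#' than 100 bp (0 if overlapping) are deemed the same peak; the merged
#' interval is the union span and the merged summit is the summit of the
#' member with the highest mean enrichment (from `track` if given,
#' otherwise the `enrich` column).
#'
#' @param peak_lists list of `hn_peaks` tables (one per replicate).
#' @param track optional `hn_enrichment` used to score members via
#'   [peak_enrichment()].
#' @param max_gap merge gap threshold (strictly less than; default 100).
#' @return The merged `hn_peaks`.
#' @export
merge_replicate_peaks <- function(peak_lists, track = NULL, max_gap = 100) {
  all_peaks <- do.call(rbind, lapply(peak_lists, as.data.frame))
  if (is.null(all_peaks) || nrow(all_peaks) == 0)
    return(hn_peaks(character(), numeric(), numeric()))
  score <- if (!is.null(track)) {
    pk <- all_peaks; class(pk) <- c("hn_peaks", "data.frame")
    peak_enrichment(pk, track)
  } else {
    s <- all_peaks$enrich
    s[is.na(s)] <- -Inf
    s
  }
  all_peaks$.score <- score
  merged <- lapply(split(all_peaks, all_peaks$chrom), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    run_end <- df$end[1]
    cluster <- integer(nrow(df))
    cluster[1] <- 1L
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] - run_end < max_gap) {
        cluster[i] <- cluster[i - 1]
      } else {
        cluster[i] <- cluster[i - 1] + 1L
      }
      run_end <- max(run_end, df$end[i])
      if (cluster[i] != cluster[i - 1]) run_end <- df$end[i]
    }
    do.call(rbind, lapply(split(df, cluster), function(cl) {
      best <- which.max(cl$.score)
      data.frame(chrom = cl$chrom[1], start = min(cl$start),
                 end = max(cl$end), summit = cl$summit[best],
                 stage = cl$stage[1], enrich = cl$.score[best],
                 stringsAsFactors = FALSE)
    }))
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  hn_peaks(merged$chrom, merged$start, merged$end, summit = merged$summit,
           stage = merged$stage, enrich = merged$enrich)
}

#' Mean enrichment around peak summits
#'
#' Arithmetic mean of the log2 enrichment over the half-open window
#' `[summit - halfwidth, summit + halfwidth)`, truncated at chromosome
#' boundaries.
#'
#' @param peaks an `hn_peaks` (vectorized over rows).
#' @param track an `hn_enrichment`.
#' @param halfwidth flank around the summit in bp (default 100).
#' @return Numeric vector of per-peak means.
#' @export
peak_enrichment <- function(peaks, track, halfwidth = 100) {
  len <- chrom_lengths(track$genome)
  vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    lo <- max(0, peaks$summit[i] - halfwidth)
    hi <- min(len[[chrom]], peaks$summit[i] + halfwidth)
    mean(track$values[[chrom]][(lo + 1):hi])
  }, numeric(1))
}

#' Enrichment rule
#'
#' A region is deemed enriched if its log2 enrichment exceeds the threshold
#' strictly (default log2 enrichment > 0.5).
#'
#' @param value log2 enrichment value(s).
#' @param threshold strict lower threshold (default 0.5).
#' @return Logical vector.
#' @export
is_enriched <- function(value, threshold = 0.5) {
  value > threshold
}

#' Separate mark-specific peaks from phantom peaks
#'
#' A peak is a phantom if it shows enrichment (per [is_enriched()]) in one
#' or more ChIP preparations against unrelated marks -- an artifact of
#' low-input ChIP rather than genuine signal.
#'
#' @param peaks an `hn_peaks`.
#' @param alt_tracks list of `hn_enrichment` for the alternative marks; an
#'   empty list labels every peak specific.
#' @param threshold enrichment threshold.
#' @param halfwidth summit window halfwidth.
#' @return The `hn_peaks` with `specificity` set; elements `specific` and
#'   `phantom` of `split_peaks()` recover the partition.
#' @export
filter_phantom <- function(peaks, alt_tracks, threshold = 0.5, halfwidth = 100) {
  phantom <- rep(FALSE, nrow(peaks))
  for (t in alt_tracks) {
    phantom <- phantom | is_enriched(peak_enrichment(peaks, t, halfwidth),
                                     threshold)
  }
  peaks$specificity <- ifelse(phantom, "phantom", "specific")
  peaks
}

#' Classify persistence of early peaks
#'
#' A peak is `temporary` if it is no longer enriched at the final stage
#' (stage 7) representative track, and `persistent` otherwise.
#'
#' @param peaks an `hn_peaks` (stage 3 peaks).
#' @param stages an `hn_stageset` containing an `s7` track.
#' @param threshold,halfwidth enrichment rule parameters.
#' @return The `hn_peaks` with `persistence` set.
#' @export
classify_persistence <- function(peaks, stages, threshold = 0.5, halfwidth = 100) {
  if (is.null(stages$tracks$s7)) stop("stage set has no s7 track")
  e <- peak_enrichment(peaks, stages$tracks$s7, halfwidth)
  peaks$persistence <- ifelse(is_enriched(e, threshold),
                              "persistent", "temporary")
  peaks
}

#' Classify novelty of early stage 4 peaks
#'
#' An early stage 4 peak is `old` if it already shows enrichment on the
#' stage 3 representative track, and `new` otherwise.
#'
#' @param peaks an `hn_peaks` (early stage 4 peaks).
#' @param stage3_track the stage 3 representative `hn_enrichment`.
#' @param threshold,halfwidth enrichment rule parameters.
#' @return The `hn_peaks` with `novelty` set.
#' @export
classify_novelty <- function(peaks, stage3_track, threshold = 0.5,
                             halfwidth = 100) {
  e <- peak_enrichment(peaks, stage3_track, halfwidth)
  peaks$novelty <- ifelse(is_enriched(e, threshold), "old", "new")
  peaks
}

#' Fraction of peaks already enriched at earlier stages
#'
#' For peaks of a given stage, the proportion that already pass the
#' enrichment rule on each earlier stage's representative track. The
#' threshold is configurable: 0.5 reproduces the operative log2 > 0.5 rule,
#' `log2(1.5)` the 1.5-fold variant.
#'
#' @param peaks an `hn_peaks` carrying a single `stage`.
#' @param stages an `hn_stageset`.
#' @param threshold enrichment threshold (log2 units).
#' @param halfwidth summit window halfwidth.
#' @return Named numeric vector of fractions, one per earlier stage.
#' @export
fraction_pre_enriched <- function(peaks, stages, threshold = 0.5,
                                  halfwidth = 100) {
  stage <- unique(peaks$stage)
  if (length(stage) != 1) stop("peaks must carry a single stage")
  earlier <- HN_STAGES[seq_len(match(stage, HN_STAGES) - 1)]
  earlier <- intersect(earlier, names(stages$tracks))
  vapply(earlier, function(s) {
    mean(is_enriched(peak_enrichment(peaks, stages$tracks[[s]], halfwidth),
                     threshold))
  }, numeric(1))
}

## percentile bootstrap CI of a column-wise statistic over rows
boot_ci <- function(mat, stat = function(col) stats::median(col, na.rm = TRUE),
                    n_boot = 1000, conf = 0.95, seed = 1L) {
  n <- nrow(mat)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      apply(mat[idx, , drop = FALSE], 2, stat)
    }, numeric(ncol(mat)))
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE)
}

#' Enrichment profile around peak summits
#'
#' Extracts per-base enrichment in a window around each summit, sorts rows
#' by descending mean enrichment, and returns the per-offset median with a
#' percentile-bootstrap 95% confidence band over peaks. Rows truncated at
#' chromosome boundaries are padded with `NA`, which is excluded from the
#' medians.
#'
#' @param peaks an `hn_peaks` (at least one row).
#' @param track an `hn_enrichment`.
#' @param flank flank size in bp (columns span offsets `-flank..+flank`).
#' @param n_boot bootstrap resamples for the confidence band.
#' @param conf confidence level.
#' @param seed bootstrap RNG seed.
#' @return list with `matrix` (rows sorted by mean, named by peak),
#'   `offsets`, `median`, `ci_lower`, `ci_upper`.
#' @export
profile_around <- function(peaks, track, flank = 1000, n_boot = 1000,
                           conf = 0.95, seed = 1L) {
  stopifnot(flank >= 1)
  if (nrow(peaks) == 0) stop("empty peak list")
  len <- chrom_lengths(track$genome)
  offsets <- -flank:flank
  mat <- t(vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    pos <- peaks$summit[i] + offsets
    ok <- pos >= 0 & pos < len[[chrom]]
    row <- rep(NA_real_, length(offsets))
    row[ok] <- track$values[[chrom]][pos[ok] + 1]
    row
  }, numeric(length(offsets))))
  rownames(mat) <- peaks$name
  ord <- order(rowMeans(mat, na.rm = TRUE), decreasing = TRUE)
  mat <- mat[ord, , drop = FALSE]
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  ci <- boot_ci(mat, n_boot = n_boot, conf = conf, seed = seed)
  list(matrix = mat, offsets = offsets, median = med,
       ci_lower = ci[1, ], ci_upper = ci[2, ])
}

#' Developmental trajectory of peak enrichment
#'
#' Median of the summit-window mean enrichment over peaks, per stage, with
#' a percentile-bootstrap confidence interval. Invariant under peak
#' reordering.
#'
#' @param peaks an `hn_peaks` (at least one row).
#' @param stages an `hn_stageset`.
#' @param halfwidth summit window halfwidth.
#' @param n_boot,conf,seed bootstrap parameters.
#' @return data.frame with `stage`, `median`, `ci_lower`, `ci_upper`.
#' @export
trajectory <- function(peaks, stages, halfwidth = 100, n_boot = 1000,
                       conf = 0.95, seed = 1L) {
  if (nrow(peaks) == 0) stop("empty peak list")
  per_stage <- vapply(stages$tracks, function(t) {
    peak_enrichment(peaks, t, halfwidth)
  }, numeric(nrow(peaks)))
  if (is.null(dim(per_stage)))
    per_stage <- matrix(per_stage, nrow = nrow(peaks),
                        dimnames = list(NULL, names(stages$tracks)))
  ci <- boot_ci(per_stage, n_boot = n_boot, conf = conf, seed = seed)
  data.frame(stage = colnames(per_stage),
             median = apply(per_stage, 2, stats::median),
             ci_lower = ci[1, ], ci_upper = ci[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate peaks by overlap category
#'
#' Assigns each peak the category of the annotations it overlaps, with
#' precedence TE > microsatellite > gene > other, and reports the fraction
#' of peak summits inside pericentric regions.
#'
#' @param peaks an `hn_peaks`.
#' @param genome an `hn_genome` with annotations loaded.
#' @return list with `category` (per-peak factor) and `fraction_pericentric`.
#' @export
annotate_peaks <- function(peaks, genome) {
  ann <- genome$annotations
  category <- rep("other", nrow(peaks))
  for (cat in c("gene", "microsatellite", "TE")) {
    sub <- ann[ann$category == cat, , drop = FALSE]
    hit <- overlaps_any(peaks$chrom, peaks$start, peaks$end,
                        sub$chrom, sub$start, sub$end)
    category[hit] <- cat
  }
  frac_peri <- if (nrow(peaks) == 0) NA_real_ else
    mean(point_in_regions(peaks$chrom, peaks$summit, genome$pericentric))
  list(category = factor(category,
                         levels = c("TE", "microsatellite", "gene", "other")),
       fraction_pericentric = frac_peri)
}
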