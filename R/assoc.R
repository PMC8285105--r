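#' Construct a small-RNA read table
#'
#' @param target chromosome or TE consensus name each read maps to.
#' @param start 0-based start position.
#' @param length read length in nt (> 0).
#' @param strand `"+"` or `"-"`.
#' @return data.frame of class `hn_smallrna`.
#' @export
small_rna_reads <- function(target, start, length, strand) {
  df <- data.frame(target = as.character(target), start = as.numeric(start),
                   length = as.numeric(length), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("read length must be > 0")
  class(df) <- c("hn_smallrna", "data.frame")
  df
}

#' Read / write small-RNA reads as BED-like TSV (target, start, length, strand)
#' @param path file path.
#' @export
read_small_rna <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  small_rna_reads(tab[[1]], tab[[2]], tab[[3]], tab[[4]])
}

#' @rdname read_small_rna
#' @param reads an `hn_smallrna`.
#' @export
write_small_rna <- function(reads, path) {
  utils::write.table(as.data.frame(reads), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' piRNA size selection
#'
#' Retains reads of piRNA length, 23--29 nt inclusive.
#'
#' @param reads an `hn_smallrna`.
#' @param min_len,max_len inclusive length bounds.
#' @return The filtered reads.
#' @export
filter_pirna <- function(reads, min_len = 23, max_len = 29) {
  reads[reads$length >= min_len & reads$length <= max_len, , drop = FALSE]
}

#' Split reads by mapping strand
#'
#' For reads mapped to a TE consensus, forward reads are sense and reverse
#' reads antisense.
#'
#' @param reads an `hn_smallrna`.
#' @return list with elements `sense` (`+`) and `antisense` (`-`).
#' @export
split_by_strand <- function(reads) {
  list(sense = reads[reads$strand == "+", , drop = FALSE],
       antisense = reads[reads$strand == "-", , drop = FALSE])
}

#' piRNA reads per million in genomic windows
#'
#' Tiles the genome with non-overlapping windows, assigns each read to the
#' window containing its start, and converts counts to RPM using the total
#' number of filtered mapped piRNA reads.
#'
#' @param reads an `hn_smallrna` mapped to genomic chromosomes (already
#'   size-filtered).
#' @param genome an `hn_genome`.
#' @param width window width in bp (default 5000).
#' @param total total 23--29 nt mapped reads for the RPM denominator
#'   (defaults to `nrow(reads)`).
#' @return data.frame with `chrom`, `start`, `end`, `count`, `rpm`.
#' @export
window_rpm <- function(reads, genome, width = 5000, total = nrow(reads)) {
  if (total <= 0) stop("total mapped piRNA read count must be > 0")
  len <- chrom_lengths(genome)
  unknown <- !(reads$target %in% names(len))
  if (any(unknown))
    stop("read(s) on chromosome absent from genome: ",
         paste(unique(reads$target[unknown]), collapse = ", "))
  out <- lapply(names(len), function(chrom) {
    n <- len[[chrom]]
    starts <- seq(0, n - 1, by = width)
    ends <- pmin(starts + width, n)
    sel <- reads$target == chrom
    win_idx <- floor(reads$start[sel] / width) + 1
    counts <- tabulate(win_idx, nbins = length(starts))
    data.frame(chrom = chrom, start = starts, end = ends, count = counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$rpm <- out$count / (total / 1e6)
  rownames(out) <- NULL
  out
}

#' Associate piRNA windows with peak taxonomy
#'
#' Groups genomic windows by whether they overlap a peak (split by the
#' peak's taxonomy label) and, for windows without peaks, by pericentric
#' versus euchromatic location (window midpoint rule). Reports per-group
#' median RPM and pairwise two-sided rank-sum tests.
#'
#' @param windows output of [window_rpm()].
#' @param peaks an `hn_peaks` with the relevant label column set.
#' @param pericentric data.frame of pericentric regions.
#' @param label which taxonomy label splits the peak-overlapping windows:
#'   `"persistence"` or `"novelty"`.
#' @return list with `groups` (per-window group factor), `medians` (named
#'   per-group median RPM) and `tests` (data.frame of pairwise rank-sum
#'   p-values; empty groups are skipped with a message).
#' @export
associate_windows_peaks <- function(windows, peaks, pericentric,
                                    label = c("persistence", "novelty")) {
  label <- match.arg(label)
  lv <- if (label == "persistence") c("persistent", "temporary")
        else c("old", "new")
  group <- rep(NA_character_, nrow(windows))
  ## windows overlapping a peak take the label of the strongest class
  for (l in rev(lv)) {
    sub <- peaks[!is.na(peaks[[label]]) & peaks[[label]] == l, , drop = FALSE]
    hit <- overlaps_any(windows$chrom, windows$start, windows$end,
                        sub$chrom, sub$start, sub$end)
    group[hit] <- l
  }
  ## unlabelled peaks still mark a window as peak-overlapping
  other <- peaks[is.na(peaks[[label]]), , drop = FALSE]
  hit <- is.na(group) & overlaps_any(windows$chrom, windows$start, windows$end,
                                     other$chrom, other$start, other$end)
  group[hit] <- "peak_unlabelled"
  mid <- floor((windows$start + windows$end) / 2)
  peri <- point_in_regions(windows$chrom, mid, pericentric)
  group[is.na(group)] <- ifelse(peri[is.na(group)],
                                "no_peak_pericentric", "no_peak_euchromatic")
  groups <- factor(group)
  medians <- tapply(windows$rpm, groups, stats::median)
  pairs <- utils::combn(levels(groups), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- windows$rpm[groups == pairs[1, k]]
    b <- windows$rpm[groups == pairs[2, k]]
    if (length(a) == 0 || length(b) == 0) {
      message("skipping test ", pairs[1, k], " vs ", pairs[2, k],
              ": empty group")
      return(NULL)
    }
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               p = rank_sum(a, b)$p, stringsAsFactors = FALSE)
  })
  list(groups = groups, medians = medians,
       tests = do.call(rbind, tests))
}

#' Mean sense/antisense piRNA coverage on TE consensus sequences
#'
#' Per family and strand, the mean per-position read coverage over the
#' consensus length (covered bases, truncated at the consensus end,
#' divided by the length). Reads with unknown targets are skipped with a
#' warning.
#'
#' @param reads an `hn_smallrna` mapped to consensus names.
#' @param library an `hn_te_library`.
#' @return data.frame with `family`, `sense`, `antisense` (mean coverage)
#'   and raw counts `n_sense`, `n_antisense`.
#' @export
te_pirna_coverage <- function(reads, library) {
  known <- reads$target %in% library$name
  if (any(!known))
    warning(sum(!known), " read(s) on unknown consensus target skipped")
  reads <- reads[known, , drop = FALSE]
  lens <- stats::setNames(library$length, library$name)
  covered <- pmin(reads$start + reads$length, lens[reads$target]) -
    pmax(reads$start, 0)
  covered <- pmax(covered, 0)
  per <- function(strand) {
    sel <- reads$strand == strand
    cov <- tapply(covered[sel], factor(reads$target[sel],
                                       levels = library$name), sum)
    cov[is.na(cov)] <- 0
    as.numeric(cov) / library$length
  }
  counts <- function(strand) {
    as.integer(table(factor(reads$target[reads$strand == strand],
                            levels = library$name)))
  }
  data.frame(family = library$name,
             sense = per("+"), antisense = per("-"),
             n_sense = counts("+"), n_antisense = counts("-"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Copy-number-scaled TE expression
#'
#' RNA counts are normalized by the median read count at autosomal genes,
#' DNA counts by the median autosomal coverage; the scaled expression is
#' the ratio of the two normalized counts. Families with zero DNA count
#' are reported missing (`NA`).
#'
#' @param rna_count,dna_count per-family counts (vectorized).
#' @param rna_normalizer median autosomal gene RNA count (> 0).
#' @param dna_normalizer median autosomal DNA coverage (> 0).
#' @return Numeric vector of scaled expression values.
#' @export
scaled_te_expression <- function(rna_count, dna_count, rna_normalizer,
                                 dna_normalizer) {
  if (rna_normalizer <= 0 || dna_normalizer <= 0)
    stop("normalizers must be > 0")
  out <- (rna_count / rna_normalizer) / (dna_count / dna_normalizer)
  out[dna_count == 0] <- NA_real_
  out
}

#' Fold change of scaled expression between stages
#'
#' Per-family ratio of stage-b to stage-a scaled expression, with a
#' pseudocount guard on both numerator and denominator; group summaries
#' are means of the per-family ratios.
#'
#' @param expr_a,expr_b per-family scaled expression at the two stages.
#' @param pseudo pseudocount (default 0.01).
#' @return list with `fold` (per-family) and `group_mean`.
#' @export
stage_fold_change <- function(expr_a, expr_b, pseudo = 0.01) {
  fold <- (expr_b + pseudo) / (expr_a + pseudo)
  list(fold = fold, group_mean = mean(fold, na.rm = TRUE))
}

#' Infer embryo sex from input DNA coverage
#'
#' Males carry one X, so the ratio of median autosomal to median X window
#' coverage is ~2 in males and ~1 in females; the call is male iff the
#' ratio strictly exceeds the threshold.
#'
#' @param track an `hn_track` (input or DNA-seq coverage).
#' @param genome genome model.
#' @param threshold ratio threshold (default 1.5, the midpoint).
#' @param width window width for the medians.
#' @return list with `sex` (`"male"`/`"female"`) and `ratio`.
#' @export
infer_sex <- function(track, genome = track$genome, threshold = 1.5,
                      width = 1000) {
  x_chroms <- genome$chromosomes$name[genome$chromosomes$class == "X"]
  if (length(x_chroms) == 0) stop("genome has no X chromosome")
  w <- window_means(track, width)
  xw <- w$value[w$chrom %in% x_chroms]
  if (length(xw) == 0 || stats::median(xw) == 0)
    stop("zero median X coverage")
  ratio <- median_autosomal(track, genome, width) / stats::median(xw)
  list(sex = if (ratio > threshold) "male" else "female", ratio = ratio)
}

#' ATAC enrichment over sex-matched DNA coverage
#'
#' Per-base log2 ratio of median-normalized ATAC fragment coverage to
#' sex-matched DNA-seq coverage (controls for copy number and for sex
#' chromosome dosage), with the standard 0.01 pseudocount.
#'
#' @param atac an `hn_track` of ATAC fragment coverage, median-normalized.
#' @param dna an `hn_track` of DNA-seq coverage, median-normalized, same
#'   sex.
#' @param pseudo pseudocount.
#' @return An `hn_enrichment`.
#' @export
atac_enrichment <- function(atac, dna, pseudo = 0.01) {
  if (!identical(atac$meta$sex, dna$meta$sex))
    stop("ATAC and DNA tracks have different sexes (",
         atac$meta$sex, " vs ", dna$meta$sex, ")")
  if (!isTRUE(atac$meta$normalized) || !isTRUE(dna$meta$normalized))
    stop("both tracks must be median-normalized first")
  if (!same_genome(atac, dna)) stop("tracks are on different genomes")
  values <- lapply(names(atac$values), function(chrom) {
    log2((atac$values[[chrom]] + pseudo) / (dna$values[[chrom]] + pseudo))
  })
  names(values) <- names(atac$values)
  enrichment_track(values, atac$genome,
                   chip_id = atac$meta$sample_id,
                   input_id = dna$meta$sample_id,
                   pseudocount = pseudo, stage = atac$meta$stage,
                   mark = "ATAC", sex = atac$meta$sex)
}
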