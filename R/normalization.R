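#' Construct a log2 enrichment track
#'
#' Per-base log2 enrichment derived from a ChIP/input pair (or ATAC/DNA
#' pair). Values are finite reals; the pseudocount guarantees a positive
#' denominator.
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param genome the `hn_genome`.
#' @param chip_id,input_id provenance sample ids.
#' @param pseudocount pseudocount used when forming the ratio.
#' @param spikein_normalized whether a spike-in shift has been applied.
#' @param stage,mark,sex metadata carried over from the ChIP sample.
#' @return An object of class `hn_enrichment`.
#' @export
enrichment_track <- function(values, genome, chip_id = NA_character_,
                             input_id = NA_character_, pseudocount = 0.01,
                             spikein_normalized = FALSE,
                             stage = NA_character_, mark = NA_character_,
                             sex = "unknown") {
  len <- chrom_lengths(genome)
  if (!setequal(names(values), names(len)))
    stop("enrichment chromosomes do not match genome")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (length(v) != len[[chrom]])
      stop("length mismatch on ", chrom)
    if (anyNA(v) || any(!is.finite(v)))
      stop("enrichment values must be finite on ", chrom)
  }
  structure(list(values = values[names(len)], genome = genome,
                 meta = list(chip_id = chip_id, input_id = input_id,
                             pseudocount = pseudocount,
                             spikein_normalized = spikein_normalized,
                             stage = stage, mark = mark, sex = sex)),
            class = "hn_enrichment")
}

#' @export
print.hn_enrichment <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Enrichment track log2(%s / %s) [stage=%s mark=%s%s]\n",
              m$chip_id, m$input_id, m$stage, m$mark,
              if (isTRUE(m$spikein_normalized)) " spike-in normalized" else ""))
  cat(" ", length(x$values), "chromosomes,",
      format(sum(lengths(x$values)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Normalize a coverage track by its median autosomal coverage
#'
#' Divides every per-base value by the median of the autosomal 1 kb window
#' means, normalizing for library size.
#'
#' @param track an `hn_track`.
#' @param genome genome model (defaults to the track's own).
#' @param width window width for the median.
#' @return The normalized `hn_track` (metadata flagged `normalized`).
#' @export
normalize_by_median <- function(track, genome = track$genome, width = 1000) {
  med <- median_autosomal(track, genome, width)
  if (med <= 0) stop("median autosomal coverage is zero (degenerate library)")
  track$values <- lapply(track$values, function(v) v / med)
  track$meta$normalized <- TRUE
  track
}

#' Per-base log2 enrichment of a ChIP track over its input
#'
#' Both tracks are divided by their median autosomal coverage, then the
#' per-site enrichment is
#' `(chip/chip_median + pseudo) / (input/input_median + pseudo)`,
#' stored as log2.
#'
#' @param chip,input `hn_track`s on the same genome.
#' @param pseudo pseudocount (default 0.01).
#' @param width window width for the medians.
#' @return An `hn_enrichment`.
#' @export
enrichment <- function(chip, input, pseudo = 0.01, width = 1000) {
  if (!same_genome(chip, input)) stop("chip and input are on different genomes")
  genome <- chip$genome
  cm <- median_autosomal(chip, genome, width)
  im <- median_autosomal(input, genome, width)
  if (cm <= 0 || im <= 0) stop("median autosomal coverage is zero")
  values <- lapply(names(chip$values), function(chrom) {
    log2((chip$values[[chrom]] / cm + pseudo) /
           (input$values[[chrom]] / im + pseudo))
  })
  names(values) <- names(chip$values)
  enrichment_track(values, genome,
                   chip_id = chip$meta$sample_id,
                   input_id = input$meta$sample_id,
                   pseudocount = pseudo,
                   stage = chip$meta$stage, mark = chip$meta$mark,
                   sex = chip$meta$sex)
}

#' Window-level log2 enrichment of a ChIP/input pair
#'
#' Window means of ChIP and input coverage fed through the pseudocount
#' enrichment formula after median-autosomal normalization; the windowed
#' form used for spike-in reference building and shift fitting.
#'
#' @param chip,input `hn_track`s on the same genome.
#' @param pseudo pseudocount.
#' @param width window width in bp.
#' @return data.frame with `chrom`, `start`, `end`, `value` (log2).
#' @export
window_enrichment <- function(chip, input, pseudo = 0.01, width = 1000) {
  if (!same_genome(chip, input)) stop("chip and input are on different genomes")
  cm <- median_autosomal(chip, chip$genome, width)
  im <- median_autosomal(input, input$genome, width)
  if (cm <= 0 || im <= 0) stop("median autosomal coverage is zero")
  wc <- window_means(chip, width)
  wi <- window_means(input, width)
  wc$value <- log2((wc$value / cm + pseudo) / (wi$value / im + pseudo))
  wc
}

#' Build the spike-in reference enrichment profile
#'
#' Computes window-level log2 enrichment for every spike-in ChIP/input pair
#' and averages across pairs, producing the reference each spike-in (and
#' hence each sample) is normalized towards.
#'
#' @param spikein_pairs list of `list(chip = , input = )` pairs of
#'   `hn_track`s on the spike-in genome.
#' @param pseudo pseudocount.
#' @param width window width (default 1000).
#' @return data.frame of class `hn_reference` with `chrom`, `start`, `end`,
#'   `value` (mean log2 enrichment per window).
#' @export
build_spikein_reference <- function(spikein_pairs, pseudo = 0.01, width = 1000) {
  if (length(spikein_pairs) == 0) stop("no spike-in pairs")
  mats <- lapply(spikein_pairs, function(p) {
    window_enrichment(p$chip, p$input, pseudo, width)
  })
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (nrow(m) != nrow(ref) || !all(m$chrom == ref$chrom & m$start == ref$start))
      stop("spike-in pairs are on different genomes/windowings")
  }
  ref$value <- rowMeans(do.call(cbind, lapply(mats, `[[`, "value")))
  class(ref) <- c("hn_reference", "data.frame")
  ref
}

#' Fit a quantile-bin shift function against the spike-in reference
#'
#' Both the spike-in sample's window enrichment values and the reference
#' values (aligned on the same windows) are cut into quantile bins of width
#' 0.1 percentile (1000 bins). The shift for a bin is the mean reference
#' value in the bin minus the mean spike-in value; bin boundaries are
#' recorded from the spike-in distribution. Empty bins (ties collapsing
#' quantiles, or fewer values than bins) inherit the nearest non-empty
#' bin's shift.
#'
#' @param spikein_values numeric vector of the sample's spike-in window log2
#'   enrichment values.
#' @param reference an `hn_reference` (or numeric vector) aligned on the
#'   same windows.
#' @param n_bins number of quantile bins (default 1000, i.e. 0.1-percentile
#'   bins).
#' @return An object of class `hn_shift` with fields `cuts` (internal bin
#'   boundaries, length `n_bins - 1`) and `shifts` (per-bin additive log2
#'   shift).
#' @export
fit_quantile_shift <- function(spikein_values, reference, n_bins = 1000) {
  ref <- if (is.data.frame(reference)) reference$value else reference
  v <- as.numeric(spikein_values)
  if (length(v) < 2) stop("need at least 2 windows to fit a shift function")
  if (length(ref) != length(v))
    stop("spike-in values and reference not aligned (different lengths)")
  n <- length(v)
  vs <- sort(v)
  rs <- sort(ref)
  ## rank i (1..n) -> quantile bin 1..n_bins
  bins <- floor((seq_len(n) - 1) * n_bins / n) + 1
  shift_raw <- tapply(rs - vs, bins, mean)
  occupied <- as.integer(names(shift_raw))
  shifts <- rep(NA_real_, n_bins)
  shifts[occupied] <- as.numeric(shift_raw)
  empty <- which(is.na(shifts))
  if (length(empty) > 0) {
    nearest <- vapply(empty, function(k) {
      occupied[which.min(abs(occupied - k))]
    }, numeric(1))
    shifts[empty] <- shifts[nearest]
  }
  ## internal cut points between consecutive bins, from the spike-in values:
  ## midpoint between the last value of bin k and the first value of bin k+1
  ## (last rank in bin k is ceiling(k * n / n_bins), from the bin formula)
  last_idx <- ceiling(seq_len(n_bins - 1) * n / n_bins)
  cuts <- ifelse(last_idx >= n, vs[n],
                 (vs[pmin(last_idx, n)] + vs[pmin(last_idx + 1, n)]) / 2)
  cuts <- cummax(cuts)
  structure(list(cuts = cuts, shifts = shifts, n_bins = n_bins),
            class = "hn_shift")
}

#' @export
print.hn_shift <- function(x, ...) {
  cat("Quantile-bin shift function:", x$n_bins, "bins; shift range [",
      round(min(x$shifts), 3), ",", round(max(x$shifts), 3), "] log2 units\n")
  invisible(x)
}

#' Evaluate a shift function at arbitrary log2 enrichment values
#'
#' Values below the lowest (above the highest) boundary receive the first
#' (last) bin's shift.
#'
#' @param fn an `hn_shift`.
#' @param x numeric vector of log2 enrichment values.
#' @return The per-value additive shift.
#' @export
shift_evaluate <- function(fn, x) {
  bin <- findInterval(x, fn$cuts) + 1L
  fn$shifts[bin]
}

#' Apply a spike-in shift function to a sample enrichment track
#'
#' Each per-base log2 value is incremented by the shift of the spike-in
#' quantile bin its value falls into. Applying a shift to an already
#' spike-in-normalized track is an error.
#'
#' @param sample an `hn_enrichment`.
#' @param fn an `hn_shift` fitted from the matching spike-in.
#' @return The shifted `hn_enrichment`, flagged `spikein_normalized`.
#' @export
apply_shift <- function(sample, fn) {
  if (isTRUE(sample$meta$spikein_normalized))
    stop("track is already spike-in normalized")
  sample$values <- lapply(sample$values, function(v) v + shift_evaluate(fn, v))
  sample$meta$spikein_normalized <- TRUE
  sample
}

#' Serialize / read a shift function as 2-column TSV
#'
#' Columns: upper boundary of each bin (the last bin's boundary written as
#' `Inf`) and the bin's shift.
#'
#' @param fn an `hn_shift`.
#' @param path output path.
#' @export
write_shift <- function(fn, path) {
  utils::write.table(
    data.frame(upper = c(fn$cuts, Inf), shift = fn$shifts),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_shift
#' @return `read_shift` returns the `hn_shift`.
#' @export
read_shift <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  structure(list(cuts = tab[[1]][-nrow(tab)], shifts = tab[[2]],
                 n_bins = nrow(tab)),
            class = "hn_shift")
}
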