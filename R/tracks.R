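#' Construct a coverage track
#'
#' Per-base, non-negative signal for one sample over the chromosomes of a
#' genome. Values are read (or fragment) counts per site before
#' normalization and real-valued after.
#'
#' @param values named list of numeric vectors, one per chromosome; each
#'   vector's length must equal the chromosome length.
#' @param genome the `hn_genome` the track lives on.
#' @param sample_id sample identifier.
#' @param stage one of `"s3","e4","l4","s5","s7"` or `NA`.
#' @param assay one of `"chip","input","atac","dna","rna"`.
#' @param mark antibody target for ChIP samples (e.g. `"H3K9me3"`).
#' @param replicate replicate identifier.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param normalized logical; `TRUE` once values have been divided by the
#'   median autosomal coverage.
#' @return An object of class `hn_track`.
#' @export
coverage_track <- function(values, genome, sample_id = "sample",
                           stage = NA_character_, assay = "chip",
                           mark = NA_character_, replicate = NA_character_,
                           sex = "unknown", normalized = FALSE) {
  stopifnot(is.list(values), !is.null(names(values)))
  len <- chrom_lengths(genome)
  if (!setequal(names(values), names(len)))
    stop("track chromosomes do not match genome")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (length(v) != len[[chrom]])
      stop("length of '", chrom, "' values (", length(v),
           ") != chromosome length (", len[[chrom]], ")")
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
      stop("coverage values must be finite and >= 0 on ", chrom)
  }
  if (!is.na(stage) && !stage %in% HN_STAGES)
    stop("unknown stage: ", stage)
  structure(list(values = values[names(len)], genome = genome,
                 meta = list(sample_id = sample_id, stage = stage,
                             assay = assay, mark = mark,
                             replicate = replicate, sex = sex,
                             normalized = normalized)),
            class = "hn_track")
}

#' @export
print.hn_track <- function(x, ...) {
  m <- x$meta
  cat("Coverage track", m$sample_id,
      sprintf("[assay=%s stage=%s mark=%s rep=%s sex=%s%s]\n",
              m$assay, m$stage, m$mark, m$replicate, m$sex,
              if (isTRUE(m$normalized)) " normalized" else ""))
  cat(" ", length(x$values), "chromosomes,",
      format(sum(lengths(x$values)), big.mark = ","), "bp\n")
  invisible(x)
}

same_genome <- function(a, b) {
  la <- chrom_lengths(a$genome); lb <- chrom_lengths(b$genome)
  setequal(names(la), names(lb)) && all(la[names(lb)] == lb)
}

#' Construct alignment records
#'
#' A light in-memory representation of aligned reads: one row per alignment.
#'
#' @param read_id character vector of read names.
#' @param target_name chromosome (or consensus) each read aligned to.
#' @param position 0-based leftmost aligned position.
#' @param aligned_length aligned length in bp (> 0).
#' @param strand `"+"` or `"-"`.
#' @param mapping_quality integer >= 0; 0 marks an ambiguous (tied) alignment.
#' @param pair_role `"single"`, `"mate1"` or `"mate2"`.
#' @return data.frame of class `hn_alignments`.
#' @export
alignment_records <- function(read_id, target_name, position, aligned_length,
                              strand = "+", mapping_quality = 60L,
                              pair_role = "single") {
  df <- data.frame(read_id = as.character(read_id),
                   target_name = as.character(target_name),
                   position = as.numeric(position),
                   aligned_length = as.numeric(aligned_length),
                   strand = strand,
                   mapping_quality = as.integer(mapping_quality),
                   pair_role = pair_role,
                   stringsAsFactors = FALSE)
  if (any(df$position < 0)) stop("position must be >= 0")
  if (any(df$aligned_length <= 0)) stop("aligned_length must be > 0")
  class(df) <- c("hn_alignments", "data.frame")
  df
}

#' Read alignment records from a SAM/BAM file
#'
#' Optional convenience for file-based input; requires the Rsamtools
#' package. Text SAM files are converted with [Rsamtools::asBam()] first.
#'
#' @param path path to a `.bam` or `.sam` file.
#' @return An `hn_alignments` data.frame (unmapped records dropped).
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignments() requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "mapq", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  flag <- b$flag[keep]
  role <- ifelse(bitwAnd(flag, 64L) > 0L, "mate1",
                 ifelse(bitwAnd(flag, 128L) > 0L, "mate2", "single"))
  alignment_records(read_id = b$qname[keep],
                    target_name = as.character(b$rname)[keep],
                    position = b$pos[keep] - 1,
                    aligned_length = b$qwidth[keep],
                    strand = as.character(b$strand)[keep],
                    mapping_quality = b$mapq[keep],
                    pair_role = role)
}

#' Partition alignments between sample and spike-in genomes
#'
#' Reads mapped jointly to the sample and spike-in reference are split by
#' target genome; ambiguous alignments (mapping quality 0, i.e. a tie
#' between the genomes in the combined mapping) are discarded and counted.
#'
#' @param records an `hn_alignments` data.frame.
#' @param sample_chroms character vector of sample-genome chromosome names.
#' @param spikein_chroms character vector of spike-in chromosome names;
#'   must be disjoint from `sample_chroms`.
#' @return list with elements `sample`, `spikein` (both `hn_alignments`) and
#'   `discarded` (count of ambiguous records).
#' @export
partition_spikein <- function(records, sample_chroms, spikein_chroms) {
  if (length(intersect(sample_chroms, spikein_chroms)) > 0)
    stop("sample and spike-in chromosome name sets overlap: ",
         paste(intersect(sample_chroms, spikein_chroms), collapse = ", "))
  known <- records$target_name %in% c(sample_chroms, spikein_chroms)
  if (!all(known))
    stop("record(s) with unknown target: ",
         paste(utils::head(records$read_id[!known], 5), collapse = ", "))
  ambiguous <- records$mapping_quality == 0L
  in_sample <- !ambiguous & records$target_name %in% sample_chroms
  in_spike <- !ambiguous & records$target_name %in% spikein_chroms
  list(sample = records[in_sample, , drop = FALSE],
       spikein = records[in_spike, , drop = FALSE],
       discarded = sum(ambiguous))
}

## add +1 over [start, end) (0-based half-open) to per-base vector via a
## difference array; starts/ends already clipped to [0, len]
add_intervals <- function(v, start, end) {
  n <- length(v)
  d <- numeric(n + 1)
  tab_s <- tabulate(start + 1L, nbins = n)
  tab_e <- tabulate(end + 1L, nbins = n + 1L)
  d[seq_len(n)] <- tab_s
  d <- d - tab_e
  v + cumsum(d[seq_len(n)])
}

#' Compute per-base coverage from alignment records
#'
#' In `read` mode each record adds 1 to every base it covers. In `fragment`
#' mode mate pairs sharing a `read_id` contribute 1 to every base spanned
#' by the full mate1-start to mate2-end fragment, once per pair (the
#' behaviour of `genomeCoverageBed -pc`).
#'
#' @param records an `hn_alignments` data.frame.
#' @param genome an `hn_genome`.
#' @param mode `"read"` or `"fragment"`.
#' @param ... metadata passed to [coverage_track()].
#' @return An `hn_track`.
#' @export
coverage_from_alignments <- function(records, genome, mode = c("read", "fragment"),
                                     ...) {
  mode <- match.arg(mode)
  len <- chrom_lengths(genome)
  unknown <- !(records$target_name %in% names(len))
  if (any(unknown))
    stop("record(s) on chromosome absent from genome: ",
         paste(unique(records$target_name[unknown]), collapse = ", "))
  if (mode == "read") {
    iv <- data.frame(chrom = records$target_name,
                     start = records$position,
                     end = records$position + records$aligned_length)
  } else {
    paired <- records$pair_role %in% c("mate1", "mate2")
    if (any(!paired))
      stop("fragment mode with unpaired record(s): ",
           paste(unique(records$read_id[!paired]), collapse = ", "))
    sp <- split(seq_len(nrow(records)), records$read_id)
    bad <- names(sp)[lengths(sp) != 2]
    if (length(bad) > 0)
      stop("fragment mode requires exactly one mate pair per read_id; bad: ",
           paste(utils::head(bad, 5), collapse = ", "))
    idx1 <- vapply(sp, `[`, numeric(1), 1)
    idx2 <- vapply(sp, `[`, numeric(1), 2)
    if (any(records$target_name[idx1] != records$target_name[idx2]))
      stop("mate pair on different chromosomes")
    iv <- data.frame(
      chrom = records$target_name[idx1],
      start = pmin(records$position[idx1], records$position[idx2]),
      end = pmax(records$position[idx1] + records$aligned_length[idx1],
                 records$position[idx2] + records$aligned_length[idx2]))
  }
  if (any(iv$end > len[iv$chrom]))
    stop("record extends past chromosome end")
  values <- lapply(names(len), function(chrom) {
    v <- numeric(len[[chrom]])
    sel <- iv$chrom == chrom
    if (any(sel)) v <- add_intervals(v, iv$start[sel], iv$end[sel])
    v
  })
  names(values) <- names(len)
  coverage_track(values, genome, ...)
}

#' Window means of a coverage or enrichment track
#'
#' Tiles each chromosome with non-overlapping windows from position 0 and
#' averages the per-base values in each window. The final partial window is
#' kept, averaged over its actual length.
#'
#' @param track an `hn_track` or `hn_enrichment`.
#' @param width window width in bp (default 1000).
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
window_means <- function(track, width = 1000) {
  stopifnot(width >= 1)
  out <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    n <- length(v)
    if (n == 0) return(NULL)
    starts <- seq(0, n - 1, by = width)
    ends <- pmin(starts + width, n)
    cs <- c(0, cumsum(v))
    data.frame(chrom = chrom, start = starts, end = ends,
               value = (cs[ends + 1] - cs[starts + 1]) / (ends - starts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  rownames(out) <- NULL
  out
}

#' Median autosomal window coverage
#'
#' Median of the 1 kb window means over autosomal windows; the library-size
#' normalizer used throughout.
#'
#' @param track an `hn_track`.
#' @param genome genome model (defaults to the track's own genome).
#' @param width window width in bp.
#' @return The median (even-length medians average the central pair).
#' @export
median_autosomal <- function(track, genome = track$genome, width = 1000) {
  auto <- autosome_names(genome)
  if (length(auto) == 0) stop("genome has no autosomes")
  w <- window_means(track, width)
  w <- w[w$chrom %in% auto, , drop = FALSE]
  if (nrow(w) == 0) stop("no autosomal windows")
  stats::median(w$value)
}

#' Write a track as bedGraph
#'
#' Four-column, 0-based half-open bedGraph; consecutive equal values are
#' run-length collapsed.
#'
#' @param track an `hn_track` or `hn_enrichment`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track_to_granges(track)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

track_to_granges <- function(track) {
  lvls <- names(track$values)
  parts <- lapply(lvls, function(chrom) {
    r <- rle(track$values[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    GenomicRanges::GRanges(factor(rep(chrom, length(starts)), levels = lvls),
                           IRanges::IRanges(starts, ends),
                           score = r$values)
  })
  do.call(c, parts)
}

#' Read a bedGraph file into a per-base track
#'
#' Positions not covered by any bedGraph interval get value 0.
#'
#' @param path bedGraph path.
#' @param genome an `hn_genome` providing chromosome lengths.
#' @param ... metadata passed to [coverage_track()] / enrichment constructor.
#' @param enrichment if `TRUE` return an `hn_enrichment` (values may be
#'   negative) instead of a coverage track.
#' @return An `hn_track` or `hn_enrichment`.
#' @export
read_bedgraph <- function(path, genome, ..., enrichment = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  len <- chrom_lengths(genome)
  values <- lapply(names(len), function(chrom) numeric(len[[chrom]]))
  names(values) <- names(len)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chroms %in% names(len)))
    stop("bedGraph chromosome absent from genome: ",
         paste(setdiff(unique(chroms), names(len)), collapse = ", "))
  starts <- GenomicRanges::start(gr)  # 1-based
  ends <- GenomicRanges::end(gr)
  score <- gr$score
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    w <- ends[sel] - starts[sel] + 1
    idx <- sequence(w) + rep(starts[sel] - 1, w)
    values[[chrom]][idx] <- rep(score[sel], w)
  }
  if (enrichment) {
    enrichment_track(values, genome, ...)
  } else {
    coverage_track(values, genome, ...)
  }
}
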