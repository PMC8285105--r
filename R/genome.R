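#' Developmental stages
#'
#' The five embryonic stages profiled, in developmental order: stage 3
#' (pre-MBT, syncytial), early stage 4, late stage 4, stage 5 (cellular
#' blastoderm) and stage 7 (gastrulation).
#'
#' @export
HN_STAGES <- c("s3", "e4", "l4", "s5", "s7")

#' Chromosome classes recognised by the genome model
#' @export
HN_CHROM_CLASSES <- c("autosome", "X", "Y", "neoY")

#' Construct a genome model
#'
#' A genome model holds the chromosome table (name, length, class), the
#' pericentric/heterochromatic regions, and interval annotations (TE
#' insertions, microsatellites, genes). All intervals are 0-based half-open.
#'
#' @param chromosomes data.frame with columns `name`, `length`, `class`
#'   (one of `"autosome"`, `"X"`, `"Y"`, `"neoY"`).
#' @param pericentric data.frame with columns `chrom`, `start`, `end`
#'   (may be empty).
#' @param annotations data.frame with columns `chrom`, `start`, `end`,
#'   `category` (e.g. `"TE"`, `"microsatellite"`, `"gene"`) and optionally
#'   `name`, `strand` (may be empty).
#' @return An object of class `hn_genome`.
#' @export
hn_genome <- function(chromosomes,
                      pericentric = empty_regions(),
                      annotations = empty_annotations()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "class") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  chromosomes$class <- as.character(chromosomes$class)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names")
  if (!all(chromosomes$class %in% HN_CHROM_CLASSES))
    stop("unknown chromosome class: ",
         paste(setdiff(chromosomes$class, HN_CHROM_CLASSES), collapse = ", "))
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  g <- structure(list(chromosomes = chromosomes,
                      pericentric = pericentric,
                      annotations = annotations),
                 class = "hn_genome")
  validate_regions(g, pericentric, "pericentric")
  validate_regions(g, annotations, "annotations")
  g
}

empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             category = character(), name = character(), strand = character(),
             stringsAsFactors = FALSE)
}

validate_regions <- function(genome, regions, what) {
  if (nrow(regions) == 0) return(invisible(TRUE))
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  len <- chrom_lengths(genome)
  bad <- !(regions$chrom %in% names(len))
  if (any(bad))
    stop(what, ": unknown chromosome ",
         paste(unique(regions$chrom[bad]), collapse = ", "))
  if (any(regions$start < 0 | regions$start >= regions$end |
            regions$end > len[regions$chrom]))
    stop(what, ": interval outside 0 <= start < end <= chromosome length")
  invisible(TRUE)
}

#' @export
print.hn_genome <- function(x, ...) {
  cat("Genome model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp\n")
  print(x$chromosomes, row.names = FALSE)
  cat(nrow(x$pericentric), "pericentric regions;",
      nrow(x$annotations), "annotations\n")
  invisible(x)
}

chrom_lengths <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}

chrom_class <- function(genome) {
  stats::setNames(genome$chromosomes$class, genome$chromosomes$name)
}

autosome_names <- function(genome) {
  genome$chromosomes$name[genome$chromosomes$class == "autosome"]
}

#' Read a chromosome table
#'
#' Reads a 3-column TSV (name, length, class) into a genome model.
#'
#' @param path path to the TSV file (no header).
#' @param pericentric_bed optional BED file of pericentric regions.
#' @return An `hn_genome`.
#' @export
read_chrom_table <- function(path, pericentric_bed = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "length", "class"),
                           stringsAsFactors = FALSE)
  peri <- if (is.null(pericentric_bed)) empty_regions() else read_bed(pericentric_bed)
  hn_genome(tab, pericentric = peri)
}

#' Write a chromosome table
#' @param genome an `hn_genome`.
#' @param path output TSV path.
#' @export
write_chrom_table <- function(genome, path) {
  utils::write.table(genome$chromosomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions (0-based half-open, first three columns)
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]), start = tab[[2]],
                    end = tab[[3]], stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  out
}

#' Write regions as BED
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   further columns, written as-is after the first three.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## any-overlap test of query intervals against subject intervals, per chrom;
## all intervals 0-based half-open
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  if (length(q_chrom) == 0) return(logical(0))
  if (length(s_chrom) == 0) return(rep(FALSE, length(q_chrom)))
  lvls <- unique(c(q_chrom, s_chrom))
  q <- GenomicRanges::GRanges(factor(q_chrom, levels = lvls),
                              IRanges::IRanges(q_start + 1, q_end))
  s <- GenomicRanges::GRanges(factor(s_chrom, levels = lvls),
                              IRanges::IRanges(s_start + 1, s_end))
  IRanges::overlapsAny(q, s)
}

## is a point (0-based) inside any region on the same chromosome?
point_in_regions <- function(chrom, pos, regions) {
  overlaps_any(chrom, pos, pos + 1, regions$chrom, regions$start, regions$end)
}
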