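#' Construct a TE consensus library
#'
#' One row per repeat-index entry. LTR retrotransposons have separate
#' internal and LTR entries linked through `partner`.
#'
#' @param name entry name (e.g. `"TRAM"`, `"TRAM_LTR"`).
#' @param length consensus length in bp (> 0).
#' @param kind one of `"ltr_internal"`, `"ltr_terminal"`, `"non_ltr"`,
#'   `"other"`.
#' @param partner for LTR families, the name of the matching internal/LTR
#'   entry (`NA` otherwise). Links must be symmetric.
#' @return data.frame of class `hn_te_library`.
#' @export
te_library <- function(name, length, kind, partner = NA_character_) {
  df <- data.frame(name = as.character(name), length = as.numeric(length),
                   kind = kind, partner = as.character(partner),
                   stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("consensus length must be > 0")
  if (anyDuplicated(df$name)) stop("duplicate library entry names")
  linked <- !is.na(df$partner)
  back <- df$partner[match(df$partner[linked], df$name)]
  if (any(is.na(back)) || any(back != df$name[linked]))
    stop("partner links must be symmetric")
  class(df) <- c("hn_te_library", "data.frame")
  df
}

#' Read / write a TE library table (TSV: name, length, kind, partner)
#' @param path file path.
#' @export
read_te_library <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  te_library(tab$name, tab$length, tab$kind, tab$partner)
}

#' @rdname read_te_library
#' @param library an `hn_te_library`.
#' @export
write_te_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a TE insertion table
#'
#' Genomic intervals (0-based half-open) with strand, repeat-index entry
#' (`family`), the matching consensus span, and a structural class set by
#' [classify_ltr_structure()].
#'
#' @param chrom,start,end,strand genomic interval.
#' @param family repeat-index entry name.
#' @param cons_start,cons_end 0-based half-open span on the consensus.
#' @param category `"TE"` or `"microsatellite"`.
#' @return data.frame of class `hn_insertions` with `structural_class`
#'   initialised to `NA`.
#' @export
te_insertions <- function(chrom, start, end, strand, family,
                          cons_start, cons_end, category = "TE") {
  n <- max(length(chrom), length(start))
  if (length(start) == 0) n <- 0
  df <- data.frame(chrom = rep(as.character(chrom), length.out = n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep(as.character(strand), length.out = n),
                   family = rep(as.character(family), length.out = n),
                   cons_start = as.numeric(cons_start),
                   cons_end = as.numeric(cons_end),
                   category = rep(category, length.out = n),
                   structural_class = rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  if (any(df$cons_start < 0 | df$cons_start >= df$cons_end))
    stop("consensus span must satisfy 0 <= start < end")
  class(df) <- c("hn_insertions", "data.frame")
  df
}

#' Parse a RepeatMasker-style GFF of TE insertions
#'
#' Reads the tab-separated GFF (1-based closed coordinates, converted to
#' 0-based half-open) and the `Target "Motif:NAME" a b` attribute giving
#' the consensus span. Entries whose motif matches `(motif)n` are labelled
#' microsatellites rather than TEs. Records whose family is absent from
#' the library, or whose consensus span exceeds the library length, are
#' skipped with a warning and counted in the `skipped` attribute.
#'
#' @param path GFF path.
#' @param library an `hn_te_library`; microsatellite motifs need no entry.
#' @return An `hn_insertions` table (attribute `skipped` = skip count).
#' @export
parse_repeatmasker_gff <- function(path, library) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- te_insertions(character(), numeric(), numeric(), character(),
                         character(), numeric(), numeric())
    attr(out, "skipped") <- 0L
    return(out)
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           quote = "", stringsAsFactors = FALSE)
  attrs <- tab[[9]]
  m <- regmatches(attrs, regexec(
    'Target[ =]"?(?:Motif:)?([^" ]+)"?\\s+(\\d+)\\s+(\\d+)', attrs))
  motif <- vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_,
                  character(1))
  t1 <- vapply(m, function(x) if (length(x) == 4) as.numeric(x[3]) else NA_real_,
               numeric(1))
  t2 <- vapply(m, function(x) if (length(x) == 4) as.numeric(x[4]) else NA_real_,
               numeric(1))
  is_microsat <- grepl("^\\(.+\\)n$", motif)
  known <- is_microsat | motif %in% library$name
  lib_len <- stats::setNames(library$length, library$name)
  bad_span <- !is_microsat & known &
    (t1 < 1 | t2 > lib_len[motif] | t1 > t2)
  bad_span[is.na(bad_span)] <- TRUE
  keep <- known & !bad_span & !is.na(motif)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(n_skip, " GFF record(s) skipped (unknown family or ",
            "consensus span outside library entry)")
  out <- te_insertions(
    chrom = tab[[1]][keep],
    start = tab[[4]][keep] - 1,       # 1-based closed -> 0-based half-open
    end = tab[[5]][keep],
    strand = tab[[7]][keep],
    family = motif[keep],
    cons_start = t1[keep] - 1,
    cons_end = t2[keep],
    category = ifelse(is_microsat[keep], "microsatellite", "TE"))
  attr(out, "skipped") <- n_skip
  out
}

#' Write insertions as a RepeatMasker-style GFF
#' @param insertions an `hn_insertions`.
#' @param path output path.
#' @export
write_repeatmasker_gff <- function(insertions, path) {
  lines <- sprintf(
    "%s\tRepeatMasker\tsimilarity\t%d\t%d\t.\t%s\t.\tTarget \"Motif:%s\" %d %d",
    insertions$chrom, as.integer(insertions$start + 1),
    as.integer(insertions$end), insertions$strand, insertions$family,
    as.integer(insertions$cons_start + 1), as.integer(insertions$cons_end))
  writeLines(c("##gff-version 2", lines), path)
  invisible(path)
}

## map consensus columns [cs, ce) of one insertion to genomic per-base
## values, strand-aware, with linear rescaling for indel length mismatch
consensus_row <- function(ins_start, ins_end, strand, cs, ce, genomic_values) {
  g <- genomic_values
  if (strand == "-") g <- rev(g)
  wc <- ce - cs
  wg <- length(g)
  ## nearest-position linear map: consensus offset j -> genomic index
  idx <- floor(((seq_len(wc) - 0.5) / wc) * wg) + 1
  g[pmin(pmax(idx, 1), wg)]
}

#' Project insertions of one family onto consensus coordinates
#'
#' Builds the insertion-by-consensus-position matrix of log2 enrichment:
#' each row is one genomic insertion lined up on the family consensus
#' (reverse-strand insertions reversed so columns always follow consensus
#' orientation), with linear position rescaling where the genomic and
#' consensus spans differ in length. Cells outside an insertion's aligned
#' span are `NA`. Rows are sorted by descending row mean.
#'
#' @param insertions an `hn_insertions`, all of one family.
#' @param track an `hn_enrichment`.
#' @param library an `hn_te_library` giving the consensus length.
#' @return matrix of class `hn_consensus_matrix` (attribute `family`).
#' @export
project_to_consensus <- function(insertions, track, library) {
  if (nrow(insertions) == 0) stop("empty insertion list")
  fam <- unique(insertions$family)
  if (length(fam) != 1) stop("insertions must all be of one family")
  L <- library$length[match(fam, library$name)]
  if (is.na(L)) stop("family not in library: ", fam)
  mat <- matrix(NA_real_, nrow = nrow(insertions), ncol = L)
  for (i in seq_len(nrow(insertions))) {
    chrom <- insertions$chrom[i]
    g <- track$values[[chrom]][(insertions$start[i] + 1):insertions$end[i]]
    cs <- insertions$cons_start[i]; ce <- insertions$cons_end[i]
    mat[i, (cs + 1):ce] <- consensus_row(insertions$start[i],
                                         insertions$end[i],
                                         insertions$strand[i], cs, ce, g)
  }
  rownames(mat) <- sprintf("%s:%d-%d(%s)", insertions$chrom,
                           insertions$start, insertions$end,
                           insertions$strand)
  ord <- order(rowMeans(mat, na.rm = TRUE), decreasing = TRUE)
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "family") <- fam
  class(mat) <- c("hn_consensus_matrix", class(mat))
  mat
}

#' Per-position mean enrichment over a consensus matrix
#'
#' Column means over defined cells; columns covered by no insertion are
#' `NA`.
#'
#' @param matrix an `hn_consensus_matrix` (or plain matrix).
#' @return Numeric vector, one value per consensus position.
#' @export
consensus_profile <- function(matrix) {
  if (nrow(matrix) < 1) stop("matrix has no rows")
  out <- colMeans(matrix, na.rm = TRUE)
  out[colSums(!is.na(matrix)) == 0] <- NA_real_
  out
}

#' Classify LTR insertion structure
#'
#' For each internal-sequence record of an LTR family, looks for
#' same-strand LTR records flanking it: both flanks within `max_gap`
#' (inclusive) make it `full_length`; a 5' flank (strand-aware) that is
#' missing or farther than `far` with an intact 3' flank makes it
#' `five_prime_truncated` (and mirrored for `three_prime_truncated`); any
#' other configuration is `other`. A single LTR may flank two internal
#' sequences (head-to-tail tandems).
#'
#' @param insertions an `hn_insertions` containing the family's internal
#'   and LTR records.
#' @param library an `hn_te_library` linking internal and LTR entries.
#' @param family the internal entry name (e.g. `"TRAM"`).
#' @param max_gap maximum flank gap in bp (inclusive; default 10).
#' @param far distance beyond which an LTR no longer rescues a side
#'   (strictly greater than; default 5000).
#' @return The internal-record rows with `structural_class` filled in.
#' @export
classify_ltr_structure <- function(insertions, library, family,
                                   max_gap = 10, far = 5000) {
  ltr_name <- library$partner[match(family, library$name)]
  if (is.na(ltr_name)) stop("family ", family, " has no LTR partner entry")
  internal <- insertions[insertions$family == family, , drop = FALSE]
  ltrs <- insertions[insertions$family == ltr_name, , drop = FALSE]
  if (nrow(internal) == 0) return(internal)
  side_status <- function(i, genomic_side) {
    ## genomic_side: "left" (upstream) or "right" (downstream)
    same <- ltrs$chrom == internal$chrom[i] & ltrs$strand == internal$strand[i]
    if (genomic_side == "left") {
      gaps <- internal$start[i] - ltrs$end[same]
    } else {
      gaps <- ltrs$start[same] - internal$end[i]
    }
    gaps <- gaps[gaps >= 0]
    if (length(gaps) == 0) return("missing")
    g <- min(gaps)
    if (g <= max_gap) "adjacent" else if (g > far) "missing" else "near"
  }
  cls <- vapply(seq_len(nrow(internal)), function(i) {
    left <- side_status(i, "left")
    right <- side_status(i, "right")
    ## strand-aware: for "+" the 5' side is genomic left; for "-" it is right
    if (internal$strand[i] == "+") {
      five <- left; three <- right
    } else {
      five <- right; three <- left
    }
    if (five == "adjacent" && three == "adjacent") "full_length"
    else if (five == "missing" && three == "adjacent") "five_prime_truncated"
    else if (three == "missing" && five == "adjacent") "three_prime_truncated"
    else "other"
  }, character(1))
  internal$structural_class <- cls
  internal
}

#' Terminal-window enrichment contrast between full-length and truncated
#' insertions
#'
#' For the 5'-truncation contrast each insertion's mean log2 enrichment is
#' taken over the last 1 kb of the internal sequence (3' LTR excluded);
#' for the 3'-truncation contrast over the first 1 kb (5' LTR excluded).
#' Windows are truncated to the internal-sequence length when shorter.
#' Per stage the fold difference of group means (linear scale) and a
#' two-sided rank-sum p-value are reported.
#'
#' @param full `hn_insertions` of full-length internal records.
#' @param truncated `hn_insertions` of the truncated internal records.
#' @param tracks named list of `hn_enrichment`, one per stage.
#' @param side `"five_prime"` or `"three_prime"` (which truncation class
#'   `truncated` holds).
#' @param terminal window size in bp (default 1000).
#' @return data.frame with one row per stage: `stage`, `mean_full`,
#'   `mean_truncated` (log2), `fold` (linear ratio of group means), `p`;
#'   attribute `values` keeps the per-insertion means.
#' @export
truncation_contrast <- function(full, truncated, tracks,
                                side = c("five_prime", "three_prime"),
                                terminal = 1000) {
  side <- match.arg(side)
  if (nrow(full) == 0 || nrow(truncated) == 0)
    stop("both insertion groups must be nonempty")
  terminal_window <- function(ins) {
    w <- pmin(terminal, ins$end - ins$start)
    ## last 1 kb of the element for the 5' contrast, first 1 kb for the 3'
    at_end <- (side == "five_prime") == (ins$strand == "+")
    lo <- ifelse(at_end, ins$end - w, ins$start)
    data.frame(chrom = ins$chrom, start = lo, end = lo + w)
  }
  mean_window <- function(win, track) {
    vapply(seq_len(nrow(win)), function(i) {
      mean(track$values[[win$chrom[i]]][(win$start[i] + 1):win$end[i]])
    }, numeric(1))
  }
  wf <- terminal_window(full)
  wt <- terminal_window(truncated)
  values <- list()
  rows <- lapply(names(tracks), function(stage) {
    mf <- mean_window(wf, tracks[[stage]])
    mt <- mean_window(wt, tracks[[stage]])
    values[[stage]] <<- list(full = mf, truncated = mt)
    rs <- rank_sum(mf, mt)
    data.frame(stage = stage, mean_full = mean(mf), mean_truncated = mean(mt),
               fold = 2^(mean(mf) - mean(mt)), p = rs$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "values") <- values
  out
}

#' Copy counts per family, genome-wide and on the neo-Y
#'
#' Counts insertions per family and on Y/neo-Y chromosomes, and compares
#' nominated family groups (e.g. stage 3 nucleating vs all) by rank-sum on
#' the per-family counts.
#'
#' @param insertions an `hn_insertions`.
#' @param genome an `hn_genome` (for chromosome classes).
#' @param family_sets named list of character vectors of family names; a
#'   rank-sum test is run for each set against the complement.
#' @return list with `counts` (data.frame `family`, `total`, `neoY`) and
#'   `tests` (per set: fold of mean neo-Y counts vs complement, p).
#' @export
family_copy_counts <- function(insertions, genome, family_sets = list()) {
  ins <- insertions[insertions$category == "TE", , drop = FALSE]
  cls <- chrom_class(genome)
  fams <- sort(unique(ins$family))
  on_y <- cls[ins$chrom] %in% c("Y", "neoY")
  counts <- data.frame(
    family = fams,
    total = as.integer(table(factor(ins$family, levels = fams))),
    neoY = as.integer(table(factor(ins$family[on_y], levels = fams))),
    stringsAsFactors = FALSE)
  tests <- lapply(family_sets, function(set) {
    in_set <- counts$family %in% set
    if (!any(in_set) || all(in_set)) return(NULL)
    list(fold_total = mean(counts$total[in_set]) / mean(counts$total[!in_set]),
         fold_neoY = mean(counts$neoY[in_set]) / mean(counts$neoY[!in_set]),
         p_total = rank_sum(counts$total[in_set], counts$total[!in_set])$p,
         p_neoY = rank_sum(counts$neoY[in_set], counts$neoY[!in_set])$p)
  })
  list(counts = counts, tests = tests)
}

#' Overlap of peaks with TE insertions, in consensus coordinates
#'
#' For each library family: the number of peaks whose summit falls inside
#' one of its insertions, and each such summit mapped to a consensus
#' position through the insertion's (strand-aware, linearly rescaled)
#' coordinate map.
#'
#' @param peaks an `hn_peaks`.
#' @param insertions an `hn_insertions`.
#' @param library an `hn_te_library`.
#' @return list with `per_family` (data.frame `family`, `n_peaks`) and
#'   `positions` (data.frame `peak`, `family`, `cons_pos`).
#' @export
te_peak_overlap <- function(peaks, insertions, library) {
  ins <- insertions[insertions$category == "TE", , drop = FALSE]
  pos <- list()
  for (i in seq_len(nrow(peaks))) {
    hit <- which(ins$chrom == peaks$chrom[i] &
                   ins$start <= peaks$summit[i] &
                   peaks$summit[i] < ins$end)
    for (j in hit) {
      off <- peaks$summit[i] - ins$start[j]
      wg <- ins$end[j] - ins$start[j]
      if (ins$strand[j] == "-") off <- wg - 1 - off
      wc <- ins$cons_end[j] - ins$cons_start[j]
      cons_pos <- ins$cons_start[j] + floor((off + 0.5) / wg * wc)
      pos[[length(pos) + 1]] <- data.frame(
        peak = peaks$name[i], family = ins$family[j], cons_pos = cons_pos,
        stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(pos) > 0) do.call(rbind, pos) else
    data.frame(peak = character(), family = character(), cons_pos = numeric())
  per_family <- data.frame(
    family = library$name,
    n_peaks = vapply(library$name, function(f) {
      length(unique(positions$peak[positions$family == f]))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_family = per_family, positions = positions)
}
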