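#' Default configuration for the synthetic genome
#'
#' The defaults define the simulated study conditions: a ~2.4 Mb genome
#' with two autosomes, an X and a repeat-rich neo-Y; pericentric regions;
#' an LTR family (TRAM-like) with planted full-length and truncated
#' copies; a second LTR family and non-LTR families split into early
#' (stage 3) nucleating, later (early stage 4) nucleating and
#' non-nucleating groups; standalone persistent, temporary, new and
#' phantom nucleation sites; per-sample spike-in distortions; piRNA rates
#' elevated at early-nucleating families; and a maternal + zygotic
#' expression model.
#'
#' @param ... named overrides of any default listed in the function
#'   definition.
#' @return A config list for [generate_genome()].
#' @export
sim_config <- function(...) {
  cfg <- list(
    chromosomes = data.frame(
      name = c("chr2", "chr3", "chrX", "chrY"),
      length = c(850000, 850000, 400000, 300000),
      class = c("autosome", "autosome", "X", "neoY"),
      stringsAsFactors = FALSE),
    pericentric = data.frame(
      chrom = c("chr2", "chr3", "chrX", "chrY"),
      start = c(0, 0, 0, 0),
      end = c(280000, 280000, 80000, 300000),
      stringsAsFactors = FALSE),
    depth = 30,
    pseudo = 0.01,
    n_replicates = 3,
    replicate_sexes = c("male", "male", "female"),
    amplitude = 2,
    sigma_shoulder = 50,
    ## enrichment rises across stages as heterochromatin matures
    stage_gain = c(0.8, 1, 1.15, 1.25, 1.3),
    ## fractional drop from the nucleation origin to the spreading front
    plateau_taper = 0.15,
    ## LTR families: internal + LTR consensus entries
    tram = list(name = "TRAM", ltr = "TRAM_LTR", internal_len = 5000,
                ltr_len = 372, n_full = 40, n_five = 5, n_three = 5),
    gypsy = list(name = "GYPSY7", ltr = "GYPSY7_LTR", internal_len = 4000,
                 ltr_len = 300, n_full = 8),
    ltr_cassette_gap = 5100,  # keeps same-family LTRs of neighbours > 5 kb away
    ## non-LTR named families
    loa_len = 4500, n_loa = 6,
    r1_len = 3000, n_r1 = 6,
    ## extra non-LTR families by nucleation group
    n_extra_early = 19, n_extra_late = 19, n_extra_none = 18,
    insertions_per_early = 3, insertions_per_other = 2,
    extra_len_range = c(1500, 3000),
    ## standalone nucleation sites
    n_standalone_persistent = 20, n_temporary = 10, n_new_e4 = 20,
    n_phantom = 10,
    ## other annotations
    n_microsat = 30, microsat_motif = "AGAT",
    n_genes = 60, gene_len = 2000,
    ## spreading half-widths (bp) per stage s3, e4, l4, s5, s7
    hw_standalone_s3 = c(70, 150, 300, 600, 1000),
    hw_standalone_e4 = c(0, 70, 150, 300, 600),
    hw_tram5 = c(70, 300, 1000, 2500, 5500),
    hw_gypsy5 = c(0, 70, 300, 1000, 2500),
    decay_temporary = c(1, 0.5, 0.25, 0.1, 0),
    ## spike-in: large enough that the 0.1-percentile quantile bins hold
    ## several 1 kb windows each
    spikein_length = 4000000,
    ## per-sample pull-down distortion: slopes on log2 enrichment
    ## (background stays put, enriched regions compress or stretch --
    ## a constant offset would be removed by median normalization)
    distortion_levels = c(0.7, 0.85, 1, 1.15, 1.3),
    ## piRNA (rates are relative weights per kb of insertion sequence)
    pirna = list(rate_early = 10, rate_late = 2, rate_none = 1,
                 sense_frac = 0.7, total_reads = 200000),
    ## expression model
    expression = list(
      fold_s4 = c(early = 1.41, late = 1.01, none = 0.97),
      fold_s5 = c(early = 2.0, late = 2.5, none = 2.0),
      base_mean_log2 = 6, pirna_slope = 0.5, noise_sd = 1.1,
      dna_depth = 100, gene_mean = 200))
  over <- list(...)
  if (length(over) > 0) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

## greedy placement of items into regions; items is a data.frame with
## columns width and min_gap; returns chrom/start per item (input order)
place_items <- function(regions, items) {
  n <- nrow(items)
  chrom <- character(n); start <- numeric(n)
  order_idx <- sample.int(n)
  ri <- 1
  cursor <- regions$start[1]
  for (k in order_idx) {
    placed <- FALSE
    while (ri <= nrow(regions)) {
      gap <- items$min_gap[k] + floor(stats::runif(1, 0, 300))
      pos <- cursor + gap
      if (pos + items$width[k] <= regions$end[ri]) {
        chrom[k] <- regions$chrom[ri]
        start[k] <- pos
        cursor <- pos + items$width[k]
        placed <- TRUE
        break
      }
      ri <- ri + 1
      if (ri <= nrow(regions)) cursor <- regions$start[ri]
    }
    if (!placed)
      stop("infeasible placement: genome too small for configured insertions")
  }
  data.frame(chrom = chrom, start = start)
}

## genomic complement of the pericentric regions, per chromosome
arm_regions <- function(chroms, pericentric) {
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    name <- chroms$name[i]; L <- chroms$length[i]
    peri <- pericentric[pericentric$chrom == name, , drop = FALSE]
    if (nrow(peri) == 0)
      return(data.frame(chrom = name, start = 0, end = L))
    peri <- peri[order(peri$start), ]
    starts <- c(0, peri$end); ends <- c(peri$start, L)
    keep <- ends - starts > 0
    data.frame(chrom = rep(name, sum(keep)), start = starts[keep],
               end = ends[keep])
  })
  do.call(rbind, out)
}

## build the parts (LTR/internal records) of one LTR cassette
## cls: full_length / five_prime_truncated / three_prime_truncated
## special: NA, "boundary" (gaps exactly 10), "far" (far LTR at 5001),
##          "tandem" (two full-length sharing the middle LTR)
ltr_cassette <- function(fam, cls, strand, special = NA) {
  il <- fam$internal_len; ll <- fam$ltr_len
  g <- function() if (identical(special, "boundary")) 10 else sample(0:10, 1)
  int_part <- function(cs, ce)
    list(entry = fam$name, width = ce - cs, cons = c(cs, ce), class = cls)
  ltr_part <- function()
    list(entry = fam$ltr, width = ll, cons = c(0, ll), class = NA)
  gap_part <- function(w) list(entry = NA, width = w)
  parts <- switch(
    cls,
    full_length = if (identical(special, "tandem")) {
      list(ltr_part(), gap_part(g()), int_part(0, il), gap_part(g()),
           ltr_part(), gap_part(g()), int_part(0, il), gap_part(g()),
           ltr_part())
    } else {
      list(ltr_part(), gap_part(g()), int_part(0, il), gap_part(g()),
           ltr_part())
    },
    five_prime_truncated = {
      trunc <- int_part(1000, il)  # 5' kb of the internal lost too
      core <- list(trunc, gap_part(g()), ltr_part())
      if (identical(special, "far"))
        core <- c(list(ltr_part(), gap_part(5001)), core)
      core
    },
    three_prime_truncated = {
      trunc <- int_part(0, il - 1000)
      core <- list(ltr_part(), gap_part(g()), trunc)
      if (identical(special, "far"))
        core <- c(core, list(gap_part(5001), ltr_part()))
      core
    })
  ## for "-" strand the 5' end of the element is genomic right: mirror
  if (strand == "-") parts <- rev(parts)
  parts
}

cassette_width <- function(parts) sum(vapply(parts, `[[`, numeric(1), "width"))

## expand placed cassettes into insertion records
cassette_records <- function(parts, chrom, start, strand) {
  out <- list()
  pos <- start
  for (p in parts) {
    if (!is.na(p$entry)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = pos + p$width, strand = strand,
        family = p$entry, cons_start = p$cons[1], cons_end = p$cons[2],
        category = "TE",
        planted_class = if (is.null(p$class)) NA_character_ else p$class,
        stringsAsFactors = FALSE)
    }
    pos <- pos + p$width
  }
  do.call(rbind, out)
}

#' Generate the synthetic genome, TE library, insertions and ground truth
#'
#' Deterministic given the seed. Plants the configured counts of
#' full-length and truncated LTR insertions (flank gaps at most 10 bp for
#' full length; far LTRs at 5001 bp; one head-to-tail tandem), the
#' nucleation/phantom/temporary sites, the spike-in enrichment surface and
#' per-sample distortions, per-family piRNA rates and the expression model.
#'
#' @param config a [sim_config()] list.
#' @param seed integer RNG seed.
#' @return list with `genome` (`hn_genome`), `library` (`hn_te_library`),
#'   `insertions` (`hn_insertions`), and `truth` (class `hn_truth`).
#' @export
generate_genome <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, generate_genome_impl(config, seed))
}

generate_genome_impl <- function(config, seed) {
  chroms <- config$chromosomes
  if (sum(chroms$class == "autosome") < 2 || !any(chroms$class == "X"))
    stop("config requires >= 2 autosomes and an X chromosome")
  peri <- config$pericentric
  arms <- arm_regions(chroms, peri)

  ## ---- TE library -------------------------------------------------------
  extra_n <- config$n_extra_early + config$n_extra_late + config$n_extra_none
  extra_names <- if (extra_n > 0) sprintf("FAM%02d", seq_len(extra_n)) else character()
  extra_lens <- if (extra_n > 0)
    floor(stats::runif(extra_n, config$extra_len_range[1],
                       config$extra_len_range[2])) else numeric()
  lib <- te_library(
    name = c(config$tram$name, config$tram$ltr, config$gypsy$name,
             config$gypsy$ltr, "LOA", "R1", extra_names),
    length = c(config$tram$internal_len, config$tram$ltr_len,
               config$gypsy$internal_len, config$gypsy$ltr_len,
               config$loa_len, config$r1_len, extra_lens),
    kind = c("ltr_internal", "ltr_terminal", "ltr_internal", "ltr_terminal",
             "non_ltr", "non_ltr", rep("non_ltr", extra_n)),
    partner = c(config$tram$ltr, config$tram$name, config$gypsy$ltr,
                config$gypsy$name, rep(NA_character_, 2 + extra_n)))

  groups <- list(
    early = c(config$tram$name, "LOA",
              extra_names[seq_len(config$n_extra_early)]),
    late = c(config$gypsy$name, "R1",
             extra_names[config$n_extra_early + seq_len(config$n_extra_late)]),
    none = extra_names[config$n_extra_early + config$n_extra_late +
                         seq_len(config$n_extra_none)])

  ## ---- pericentric items: LTR cassettes + early-family insertions -------
  tram <- config$tram
  cassettes <- list()
  add_cassette <- function(cls, special = NA) {
    strand <- sample(c("+", "-"), 1)
    parts <- ltr_cassette(tram, cls, strand, special)
    cassettes[[length(cassettes) + 1]] <<-
      list(parts = parts, strand = strand, min_gap = config$ltr_cassette_gap)
  }
  if (tram$n_full >= 3) {
    add_cassette("full_length", "tandem")   # counts as two full-length copies
    add_cassette("full_length", "boundary") # flank gaps exactly 10 bp
    for (i in seq_len(tram$n_full - 3)) add_cassette("full_length")
  } else {
    for (i in seq_len(tram$n_full)) add_cassette("full_length")
  }
  if (tram$n_five >= 1) {
    add_cassette("five_prime_truncated", "far")  # 5' LTR 5001 bp away
    for (i in seq_len(max(0, tram$n_five - 1)))
      add_cassette("five_prime_truncated")
  }
  if (tram$n_three >= 1) {
    add_cassette("three_prime_truncated", "far")
    for (i in seq_len(max(0, tram$n_three - 1)))
      add_cassette("three_prime_truncated")
  }
  for (i in seq_len(config$gypsy$n_full)) {
    strand <- sample(c("+", "-"), 1)
    parts <- ltr_cassette(config$gypsy, "full_length", strand)
    cassettes[[length(cassettes) + 1]] <-
      list(parts = parts, strand = strand, min_gap = config$ltr_cassette_gap)
  }

  simple_item <- function(entry, len, zone, cons = NULL) {
    if (is.null(cons)) cons <- c(0, len)
    list(entry = entry, width = cons[2] - cons[1], cons = cons, zone = zone)
  }
  lib_len <- stats::setNames(lib$length, lib$name)
  rand_span <- function(len) {
    if (stats::runif(1) < 0.7) return(c(0, len))
    w <- floor(stats::runif(1, max(800, len / 3), len))
    s <- floor(stats::runif(1, 0, len - w))
    c(s, s + w)
  }
  simple_items <- list()
  add_simple <- function(entry, zone) {
    simple_items[[length(simple_items) + 1]] <<-
      simple_item(entry, lib_len[[entry]], zone, rand_span(lib_len[[entry]]))
  }
  for (i in seq_len(config$n_loa)) add_simple("LOA", if (i <= 3) "peri" else "arm")
  for (i in seq_len(config$n_r1)) add_simple("R1", "arm")
  for (f in groups$early[-(1:2)])
    for (i in seq_len(config$insertions_per_early)) add_simple(f, "peri")
  for (f in groups$late[-(1:2)])
    for (i in seq_len(config$insertions_per_other)) add_simple(f, "arm")
  for (f in groups$none)
    for (i in seq_len(config$insertions_per_other)) add_simple(f, "arm")

  ## place pericentric items (cassettes + peri simple items)
  peri_items <- data.frame(
    width = c(vapply(cassettes, function(cst) cassette_width(cst$parts),
                     numeric(1)),
              vapply(Filter(function(x) x$zone == "peri", simple_items),
                     `[[`, numeric(1), "width")),
    min_gap = c(vapply(cassettes, `[[`, numeric(1), "min_gap"),
                rep(300, sum(vapply(simple_items, `[[`, character(1),
                                    "zone") == "peri"))))
  peri_regions <- peri[sample.int(nrow(peri)), , drop = FALSE]
  peri_pos <- place_items(peri_regions, peri_items)

  n_cass <- length(cassettes)
  ins_list <- list()
  for (i in seq_len(n_cass)) {
    ins_list[[length(ins_list) + 1]] <- cassette_records(
      cassettes[[i]]$parts, peri_pos$chrom[i], peri_pos$start[i],
      cassettes[[i]]$strand)
  }
  peri_simple <- Filter(function(x) x$zone == "peri", simple_items)
  for (j in seq_along(peri_simple)) {
    it <- peri_simple[[j]]
    k <- n_cass + j
    ins_list[[length(ins_list) + 1]] <- data.frame(
      chrom = peri_pos$chrom[k], start = peri_pos$start[k],
      end = peri_pos$start[k] + it$width,
      strand = sample(c("+", "-"), 1), family = it$entry,
      cons_start = it$cons[1], cons_end = it$cons[2], category = "TE",
      planted_class = NA_character_, stringsAsFactors = FALSE)
  }

  ## place arm items: simple insertions, microsatellites, genes
  arm_simple <- Filter(function(x) x$zone == "arm", simple_items)
  ms_lens <- if (config$n_microsat > 0)
    4 * floor(stats::runif(config$n_microsat, 30, 100)) else numeric()
  arm_widths <- c(vapply(arm_simple, `[[`, numeric(1), "width"), ms_lens,
                  rep(config$gene_len, config$n_genes))
  arm_items <- data.frame(width = arm_widths,
                          min_gap = rep(300, length(arm_widths)))
  arm_regions_shuffled <- arms[sample.int(nrow(arms)), , drop = FALSE]
  arm_pos <- place_items(arm_regions_shuffled, arm_items)
  for (j in seq_along(arm_simple)) {
    it <- arm_simple[[j]]
    ins_list[[length(ins_list) + 1]] <- data.frame(
      chrom = arm_pos$chrom[j], start = arm_pos$start[j],
      end = arm_pos$start[j] + it$width,
      strand = sample(c("+", "-"), 1), family = it$entry,
      cons_start = it$cons[1], cons_end = it$cons[2], category = "TE",
      planted_class = NA_character_, stringsAsFactors = FALSE)
  }
  n_as <- length(arm_simple)
  for (j in seq_len(config$n_microsat)) {
    k <- n_as + j
    ins_list[[length(ins_list) + 1]] <- data.frame(
      chrom = arm_pos$chrom[k], start = arm_pos$start[k],
      end = arm_pos$start[k] + ms_lens[j], strand = "+",
      family = sprintf("(%s)n", config$microsat_motif),
      cons_start = 0, cons_end = ms_lens[j], category = "microsatellite",
      planted_class = NA_character_, stringsAsFactors = FALSE)
  }
  genes <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (config$n_genes > 0) {
    idx <- n_as + config$n_microsat + seq_len(config$n_genes)
    genes <- data.frame(chrom = arm_pos$chrom[idx], start = arm_pos$start[idx],
                        end = arm_pos$start[idx] + config$gene_len,
                        stringsAsFactors = FALSE)
  }
  ins_all <- do.call(rbind, ins_list)
  if (is.null(ins_all))
    ins_all <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          family = character(), cons_start = numeric(),
                          cons_end = numeric(), category = character(),
                          planted_class = character(),
                          stringsAsFactors = FALSE)
  insertions <- te_insertions(ins_all$chrom, ins_all$start, ins_all$end,
                              ins_all$strand, ins_all$family,
                              ins_all$cons_start, ins_all$cons_end,
                              category = ins_all$category)

  ## ---- nucleation sites -------------------------------------------------
  sites <- list()
  add_site <- function(chrom, pos, type, role, family = NA_character_,
                       dir = 0L, phantom = FALSE, temporary = FALSE) {
    sites[[length(sites) + 1]] <<- data.frame(
      chrom = chrom, pos = pos, type = type, role = role, family = family,
      dir = dir, phantom = phantom, temporary = temporary,
      amplitude = config$amplitude, stringsAsFactors = FALSE)
  }
  ## sites at the 5' junction of full-length LTR internals, spreading into
  ## the element body
  internal_recs <- ins_all[!is.na(ins_all$planted_class) &
                             ins_all$planted_class == "full_length", ,
                           drop = FALSE]
  for (i in seq_len(nrow(internal_recs))) {
    r <- internal_recs[i, ]
    type <- if (r$family == tram$name) "tram5" else "gypsy5"
    if (r$strand == "+") add_site(r$chrom, r$start, type, "te5", r$family, 1L)
    else add_site(r$chrom, r$end - 1, type, "te5", r$family, -1L)
  }
  ## one symmetric site per insertion of early/late non-LTR families
  nonltr_early <- setdiff(groups$early, tram$name)
  nonltr_late <- setdiff(groups$late, config$gypsy$name)
  for (i in seq_len(nrow(ins_all))) {
    r <- ins_all[i, ]
    if (r$category != "TE") next
    mid <- floor((r$start + r$end) / 2)
    if (r$family %in% nonltr_early)
      add_site(r$chrom, mid, "sym_s3", "family_early", r$family)
    else if (r$family %in% nonltr_late)
      add_site(r$chrom, mid, "sym_e4", "family_late", r$family)
  }
  ## standalone sites in annotation-free arm space, >= 3 kb apart
  occupied <- rbind(
    data.frame(chrom = ins_all$chrom, pos = (ins_all$start + ins_all$end) / 2,
               halfwidth = (ins_all$end - ins_all$start) / 2 + 3000),
    data.frame(chrom = genes$chrom, pos = (genes$start + genes$end) / 2,
               halfwidth = (genes$end - genes$start) / 2 + 1000))
  draw_standalone <- function(n, type, role, phantom = FALSE,
                              temporary = FALSE) {
    placed <- 0; tries <- 0
    while (placed < n && tries < n * 400) {
      tries <- tries + 1
      ri <- sample.int(nrow(arms), 1)
      pos <- floor(stats::runif(1, arms$start[ri] + 2000, arms$end[ri] - 2000))
      chrom <- arms$chrom[ri]
      near <- occupied$chrom == chrom & abs(occupied$pos - pos) < occupied$halfwidth
      if (any(near)) next
      add_site(chrom, pos, type, role, phantom = phantom,
               temporary = temporary)
      occupied <<- rbind(occupied, data.frame(chrom = chrom, pos = pos,
                                              halfwidth = 3000))
      placed <- placed + 1
    }
    if (placed < n)
      stop("infeasible placement: could not place standalone sites")
  }
  draw_standalone(config$n_standalone_persistent, "sym_s3", "standalone")
  draw_standalone(config$n_temporary, "sym_s3", "temporary", temporary = TRUE)
  draw_standalone(config$n_new_e4, "sym_e4", "new_e4")
  draw_standalone(config$n_phantom, "sym_s3", "phantom", phantom = TRUE)
  sites <- do.call(rbind, sites)
  if (is.null(sites))
    sites <- data.frame(chrom = character(), pos = numeric(),
                        type = character(), role = character(),
                        family = character(), dir = integer(),
                        phantom = logical(), temporary = logical(),
                        amplitude = numeric(), stringsAsFactors = FALSE)

  ## ---- spike-in ---------------------------------------------------------
  spike_genome <- hn_genome(data.frame(
    name = "spike_1", length = config$spikein_length, class = "autosome",
    stringsAsFactors = FALSE))
  n_win <- ceiling(config$spikein_length / 1000)
  enriched <- stats::runif(n_win) < 0.3
  win_vals <- ifelse(enriched, stats::rnorm(n_win, 2.5, 1),
                     stats::rnorm(n_win, 0, 0.6))
  spike_surface <- rep(win_vals, each = 1000)[seq_len(config$spikein_length)]
  ## balanced per-sample distortions (additive log2 offsets), mean 0 across
  ## the H3K9me3 samples; alt-mark samples are undistorted
  n_chip <- length(HN_STAGES) * config$n_replicates
  levels_rep <- rep(config$distortion_levels,
                    length.out = n_chip)
  distortions <- lapply(sample(levels_rep),
                        function(s) list(slope = s, offset = 0))
  names(distortions) <- as.vector(t(outer(HN_STAGES,
                                          seq_len(config$n_replicates),
                                          function(s, r) paste0(s, "_rep", r))))

  ## ---- piRNA rates and expression model ---------------------------------
  group_of <- function(fam) {
    base <- c(stats::setNames(tram$name, tram$ltr),
              stats::setNames(config$gypsy$name, config$gypsy$ltr))
    fam <- ifelse(fam %in% names(base), base[fam], fam)
    ifelse(fam %in% groups$early, "early",
           ifelse(fam %in% groups$late, "late", "none"))
  }
  fam_names <- c(tram$name, config$gypsy$name, "LOA", "R1", extra_names)
  fam_group <- group_of(fam_names)
  rates <- c(early = config$pirna$rate_early, late = config$pirna$rate_late,
             none = config$pirna$rate_none)[fam_group]
  pirna_rates <- data.frame(family = fam_names, group = fam_group,
                            rate_per_kb = as.numeric(rates),
                            stringsAsFactors = FALSE)
  ex <- config$expression
  lr <- log2(pirna_rates$rate_per_kb)
  level_log2 <- ex$base_mean_log2 - ex$pirna_slope * (lr - mean(lr)) +
    stats::rnorm(length(fam_names), 0, ex$noise_sd)
  expression_model <- data.frame(
    family = fam_names, group = fam_group,
    level = 2^level_log2,
    fold_s4 = as.numeric(ex$fold_s4[fam_group]),
    fold_s5 = as.numeric(ex$fold_s5[fam_group]),
    stringsAsFactors = FALSE)

  genome <- hn_genome(
    chroms,
    pericentric = peri,
    annotations = rbind(
      data.frame(chrom = ins_all$chrom, start = ins_all$start,
                 end = ins_all$end,
                 category = ifelse(ins_all$category == "TE", "TE",
                                   "microsatellite"),
                 name = ins_all$family, strand = ins_all$strand,
                 stringsAsFactors = FALSE),
      data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                 category = rep("gene", nrow(genes)),
                 name = sprintf("gene_%d", seq_len(nrow(genes))),
                 strand = rep("+", nrow(genes)), stringsAsFactors = FALSE)))

  truth <- structure(list(
    seed = seed, config = config, sites = sites,
    insertions = ins_all, family_groups = groups,
    spikein = list(genome = spike_genome, surface = spike_surface,
                   distortions = distortions),
    pirna = pirna_rates, expression = expression_model,
    depth = config$depth), class = "hn_truth")
  list(genome = genome, library = lib, insertions = insertions, truth = truth)
}

#' @export
print.hn_truth <- function(x, ...) {
  cat("Synthetic ground truth: seed", x$seed, "\n")
  cat(" ", nrow(x$sites), "nucleation sites (",
      sum(x$sites$phantom), "phantom,", sum(x$sites$temporary),
      "temporary )\n")
  cat(" ", nrow(x$insertions), "planted repeat records,",
      nrow(x$pirna), "families\n")
  invisible(x)
}

## stage-specific left/right half-widths and amplitude multiplier of a site
site_kernel_params <- function(site, stage_idx, config) {
  hw <- switch(site$type,
               tram5 = config$hw_tram5[stage_idx],
               gypsy5 = config$hw_gypsy5[stage_idx],
               sym_s3 = config$hw_standalone_s3[stage_idx],
               sym_e4 = config$hw_standalone_e4[stage_idx],
               stop("unknown site type: ", site$type))
  if (site$type %in% c("tram5", "gypsy5")) {
    back <- min(70, hw)
    if (site$dir >= 0) c(back, hw) else c(hw, back)
  } else {
    c(hw, hw)
  }
}

## planted per-base log2 enrichment surface for one stage and mark
## (phantom sites contribute to every mark; real sites to H3K9me3 only)
build_surface <- function(truth, stage, mark = "H3K9me3") {
  config <- truth$config
  stage_idx <- match(stage, HN_STAGES)
  if (is.na(stage_idx)) stop("unknown stage: ", stage)
  sigma <- config$sigma_shoulder
  lens <- stats::setNames(config$chromosomes$length,
                          config$chromosomes$name)
  surf <- lapply(lens, function(L) numeric(L))
  taper <- config$plateau_taper
  gain <- config$stage_gain[stage_idx]
  for (i in seq_len(nrow(truth$sites))) {
    site <- truth$sites[i, ]
    if (!site$phantom && mark != "H3K9me3") next
    amp <- site$amplitude * gain
    if (site$temporary) amp <- amp * config$decay_temporary[stage_idx]
    hw <- site_kernel_params(site, stage_idx, config)
    if (amp <= 0 || max(hw) <= 0) next
    lo <- max(0, site$pos - hw[1] - 4 * sigma)
    hi <- min(lens[[site$chrom]] - 1, site$pos + hw[2] + 4 * sigma)
    d <- (lo:hi) - site$pos
    side_hw <- ifelse(d < 0, hw[1], hw[2])
    beyond <- pmax(0, abs(d) - side_hw)
    ## apex at the nucleation origin, tapering toward the spreading front
    frac <- pmin(1, abs(d) / pmax(side_hw, 1))
    kern <- amp * (1 - taper * frac) * exp(-beyond^2 / (2 * sigma^2))
    idx <- (lo:hi) + 1
    surf[[site$chrom]][idx] <- pmax(surf[[site$chrom]][idx], kern)
  }
  surf
}

## monotone warp of a log2 enrichment surface by a sample's pull-down
## distortion: numeric = additive offset; list(slope, offset) = affine
warp_enrichment <- function(E, distortion) {
  if (is.null(distortion)) return(E)
  if (is.numeric(distortion)) return(E + distortion)
  slope <- if (is.null(distortion$slope)) 1 else distortion$slope
  offset <- if (is.null(distortion$offset)) 0 else distortion$offset
  if (slope <= 0) stop("distortion slope must be positive (monotone warp)")
  slope * E + offset
}

## coverage-rate multiplier per chromosome for a given sex
sex_dosage <- function(genome, sex) {
  cls <- chrom_class(genome)
  vapply(cls, function(cl) {
    if (cl == "autosome") 1
    else if (cl == "X") { if (sex == "male") 0.5 else 1 }
    else { if (sex == "male") 0.5 else 0 }  # Y / neoY
  }, numeric(1))
}

#' Simulate a ChIP/input coverage pair for one stage and replicate
#'
#' Input coverage is Poisson at the base depth (scaled by sex-specific
#' chromosome dosage); ChIP coverage is Poisson at
#' `depth * 2^E(x)` where `E(x)` is the planted log2 enrichment surface at
#' that stage (optionally warped by the sample's pull-down distortion,
#' which the spike-in normalization is meant to undo). For marks other
#' than H3K9me3 only phantom sites contribute.
#'
#' @param truth an `hn_truth` from [generate_genome()].
#' @param stage one of `"s3","e4","l4","s5","s7"`.
#' @param replicate replicate id (integer or string).
#' @param sex `"male"` or `"female"`.
#' @param seed RNG seed.
#' @param mark mark being ChIPed.
#' @param distortion pull-down distortion of enrichment for this sample:
#'   a number (additive log2 offset) or `list(slope, offset)` for an
#'   affine monotone warp (default none).
#' @param genome the `hn_genome` (re-derivable from the truth config).
#' @return list with `chip` and `input` (`hn_track`s).
#' @export
simulate_stage_tracks <- function(truth, stage, replicate, sex, seed,
                                  mark = "H3K9me3", distortion = NULL,
                                  genome = NULL) {
  if (!stage %in% HN_STAGES) stop("unknown stage: ", stage)
  if (is.null(genome))
    genome <- hn_genome(truth$config$chromosomes,
                        pericentric = truth$config$pericentric)
  depth <- truth$depth
  surf <- build_surface(truth, stage, mark)
  dosage <- sex_dosage(genome, sex)
  sid <- paste0(stage, "_rep", replicate)
  with_seed(seed, {
    chip_vals <- lapply(names(surf), function(chrom) {
      rate <- depth * dosage[[chrom]] *
        2^warp_enrichment(surf[[chrom]], distortion)
      as.numeric(stats::rpois(length(rate), rate))
    })
    names(chip_vals) <- names(surf)
    input_vals <- lapply(names(surf), function(chrom) {
      as.numeric(stats::rpois(lengths(surf)[[chrom]],
                              depth * dosage[[chrom]]))
    })
    names(input_vals) <- names(surf)
    list(chip = coverage_track(chip_vals, genome,
                               sample_id = paste0(mark, "_", sid),
                               stage = stage, assay = "chip", mark = mark,
                               replicate = as.character(replicate), sex = sex),
         input = coverage_track(input_vals, genome,
                                sample_id = paste0("input_", sid),
                                stage = stage, assay = "input",
                                replicate = as.character(replicate),
                                sex = sex))
  })
}

#' Simulate a spike-in ChIP/input pair for one sample
#'
#' All samples share the same spike-in genome and enrichment surface; each
#' sample's surface is warped by its own distortion before Poisson
#' sampling, so the quantile-bin normalization must recover and undo a
#' known shift.
#'
#' @param truth an `hn_truth`.
#' @param sample_id key into `truth$spikein$distortions` (e.g.
#'   `"s3_rep1"`); ignored when `distortion` is given directly.
#' @param seed RNG seed.
#' @param distortion override: a number (additive log2 offset) or
#'   `list(slope, offset)`.
#' @return list with `chip`, `input` (`hn_track`s on the spike-in genome)
#'   and `distortion`.
#' @export
simulate_spikein_pair <- function(truth, sample_id, seed, distortion = NULL) {
  if (is.null(distortion)) {
    distortion <- truth$spikein$distortions[[sample_id]]
    if (is.null(distortion))
      stop("no distortion recorded for sample ", sample_id)
  }
  genome <- truth$spikein$genome
  depth <- truth$depth
  E <- warp_enrichment(truth$spikein$surface, distortion)
  with_seed(seed, {
    chip <- as.numeric(stats::rpois(length(E), depth * 2^E))
    input <- as.numeric(stats::rpois(length(E), depth))
    list(chip = coverage_track(list(spike_1 = chip), genome,
                               sample_id = paste0("spike_chip_", sample_id),
                               assay = "chip"),
         input = coverage_track(list(spike_1 = input), genome,
                                sample_id = paste0("spike_input_", sample_id),
                                assay = "input"),
         distortion = distortion)
  })
}

#' Simulate maternally deposited piRNA reads
#'
#' Read counts per family follow a multinomial with weights proportional
#' to the family's planted rate times its genomic insertion length; read
#' lengths put 90% of mass uniformly on 23--29 nt (the rest on
#' 21,22,30,31); strands follow the configured sense fraction. Genomic
#' reads fall uniformly within insertions of the family; a matching
#' consensus-mapped read set is drawn on the family consensus.
#'
#' @param truth an `hn_truth`.
#' @param total_reads total read count (defaults to the configured value).
#' @param seed RNG seed.
#' @return list with `genomic` and `consensus` (`hn_smallrna` tables).
#' @export
simulate_pirna <- function(truth, total_reads = NULL, seed = 1L) {
  if (is.null(total_reads)) total_reads <- truth$config$pirna$total_reads
  stopifnot(total_reads > 0)
  cfg <- truth$config
  ins <- truth$insertions[truth$insertions$category == "TE", , drop = FALSE]
  ## map LTR entries to their family group for rate lookup
  ent2fam <- c(stats::setNames(cfg$tram$name, cfg$tram$ltr),
               stats::setNames(cfg$gypsy$name, cfg$gypsy$ltr))
  fam_of <- ifelse(ins$family %in% names(ent2fam),
                   ent2fam[ins$family], ins$family)
  rates <- stats::setNames(truth$pirna$rate_per_kb, truth$pirna$family)
  ins_weight <- rates[fam_of] * (ins$end - ins$start) / 1000
  lens <- stats::setNames(truth$config$chromosomes$length,
                          truth$config$chromosomes$name)
  len_pool <- c(21, 22, 23:29, 30, 31)
  len_prob <- c(0.025, 0.025, rep(0.9 / 7, 7), 0.025, 0.025)
  lib_len <- c(stats::setNames(cfg$tram$internal_len, cfg$tram$name),
               stats::setNames(cfg$gypsy$internal_len, cfg$gypsy$name))
  fam_len <- stats::setNames(
    vapply(truth$pirna$family, function(f) {
      if (f %in% names(lib_len)) lib_len[[f]] else
        max(ins$end[fam_of == f] - ins$start[fam_of == f], 100)
    }, numeric(1)), truth$pirna$family)
  with_seed(seed, {
    ins_idx <- sample.int(nrow(ins), total_reads, replace = TRUE,
                          prob = ins_weight)
    rl <- sample(len_pool, total_reads, replace = TRUE, prob = len_prob)
    strand <- ifelse(stats::runif(total_reads) < cfg$pirna$sense_frac,
                     "+", "-")
    width <- ins$end[ins_idx] - ins$start[ins_idx]
    off <- floor(stats::runif(total_reads) * pmax(1, width - rl))
    genomic <- small_rna_reads(target = ins$chrom[ins_idx],
                               start = ins$start[ins_idx] + off,
                               length = rl, strand = strand)
    fam <- fam_of[ins_idx]
    cl <- fam_len[fam]
    cons_start <- floor(stats::runif(total_reads) * pmax(1, cl - rl))
    consensus <- small_rna_reads(target = fam, start = cons_start,
                                 length = rl, strand = strand)
    list(genomic = genomic, consensus = consensus)
  })
}

#' Simulate maternal + zygotic TE expression and DNA counts
#'
#' Maternal baseline counts at the stage 2 equivalent are Poisson around
#' `level * copies`; zygotic induction multiplies the rate by the
#' family's planted fold from its onset stage; DNA counts are Poisson
#' around copy number times the DNA depth. Autosomal gene counts for the
#' RNA normalizer are Poisson around the configured gene mean.
#'
#' @param truth an `hn_truth`.
#' @param stages expression stages to emit (default `c("s2","s4","s5")`).
#' @param seed RNG seed.
#' @return list with `families` (per-family counts and scaled expression
#'   inputs), `gene_counts`, `rna_normalizer`, `dna_normalizer`.
#' @export
simulate_expression <- function(truth, stages = c("s2", "s4", "s5"),
                                seed = 1L) {
  cfg <- truth$config
  ex <- cfg$expression
  ins <- truth$insertions[truth$insertions$category == "TE", , drop = FALSE]
  ent2fam <- c(stats::setNames(cfg$tram$name, cfg$tram$ltr),
               stats::setNames(cfg$gypsy$name, cfg$gypsy$ltr))
  fam_of <- ifelse(ins$family %in% names(ent2fam),
                   ent2fam[ins$family], ins$family)
  copies <- as.integer(table(factor(fam_of, levels = truth$expression$family)))
  em <- truth$expression
  with_seed(seed, {
    out <- data.frame(family = em$family, group = em$group, copies = copies,
                      stringsAsFactors = FALSE)
    out$dna_count <- stats::rpois(nrow(out), copies * ex$dna_depth)
    cum_fold <- stats::setNames(rep(1, nrow(out)), em$family)
    for (s in stages) {
      if (s == "s4") cum_fold <- cum_fold * em$fold_s4
      if (s == "s5") cum_fold <- cum_fold * em$fold_s5
      out[[paste0("rna_", s)]] <-
        stats::rpois(nrow(out), em$level * copies * cum_fold)
    }
    gene_counts <- stats::rpois(cfg$n_genes, ex$gene_mean)
    list(families = out, gene_counts = gene_counts,
         rna_normalizer = stats::median(gene_counts),
         dna_normalizer = ex$dna_depth)
  })
}

#' Naive threshold peak caller for synthetic tracks
#'
#' A stand-in for an external peak caller used only to generate peak-call
#' fixtures from simulated tracks: smooths the per-base enrichment with a
#' running mean, takes runs above the threshold, merges nearby runs and
#' reports the smoothed maximum as the summit.
#'
#' @param track an `hn_enrichment`.
#' @param threshold log2 enrichment call threshold (default 1.0).
#' @param smooth running-mean width in bp (odd; default 51).
#' @param min_width minimum peak width (default 50).
#' @param merge_gap merge runs closer than this many bp (default 100).
#' @param stage stage label to attach.
#' @return An `hn_peaks`.
#' @export
call_peaks_simple <- function(track, threshold = 1.0, smooth = 51,
                              min_width = 50, merge_gap = 100,
                              stage = NA_character_) {
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    sm <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2))
    sm[is.na(sm)] <- 0
    r <- rle(sm > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
    if (nrow(runs) == 0) next
    ## merge runs separated by < merge_gap
    keep_start <- runs$start[1]; merged <- list()
    cur_end <- runs$end[1]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - cur_end < merge_gap) {
        cur_end <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- c(keep_start, cur_end)
        keep_start <- runs$start[i]; cur_end <- runs$end[i]
      }
    }
    merged[[length(merged) + 1]] <- c(keep_start, cur_end)
    for (m in merged) {
      if (m[2] - m[1] < min_width) next
      seg <- sm[(m[1] + 1):m[2]]
      summit <- m[1] + which.max(seg) - 1
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = m[1], end = m[2], summit = summit,
        enrich = mean(v[(m[1] + 1):m[2]]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(hn_peaks(character(), numeric(), numeric(), stage = stage))
  df <- do.call(rbind, out)
  hn_peaks(df$chrom, df$start, df$end, summit = df$summit, stage = stage,
           enrich = df$enrich)
}

#' Write peaks in MACS2 narrowPeak format
#'
#' @param peaks an `hn_peaks`.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name,
                   as.integer(pmax(0, round(100 * peaks$enrich))), ".",
                   ifelse(is.na(peaks$enrich), 0, peaks$enrich), -1, -1,
                   as.integer(peaks$summit - peaks$start))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Match peaks to planted nucleation sites
#'
#' Assigns each peak the nearest planted site on the same chromosome
#' within `max_dist` of its summit (`NA` if none), for scoring recovered
#' taxonomy labels against the truth.
#'
#' @param peaks an `hn_peaks`.
#' @param truth an `hn_truth`.
#' @param max_dist maximum summit-to-site distance (default 500 bp).
#' @return Integer vector of row indices into `truth$sites` (NA = no match).
#' @export
match_peaks_to_sites <- function(peaks, truth, max_dist = 500) {
  sites <- truth$sites
  vapply(seq_len(nrow(peaks)), function(i) {
    sel <- which(sites$chrom == peaks$chrom[i])
    if (length(sel) == 0) return(NA_integer_)
    d <- abs(sites$pos[sel] - peaks$summit[i])
    j <- which.min(d)
    if (d[j] <= max_dist) sel[j] else NA_integer_
  }, integer(1))
}
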