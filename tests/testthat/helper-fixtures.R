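## shared fixtures, built once per test run

.hn_cache <- new.env(parent = emptyenv())

## small genome for unit tests; lengths chosen so 1 kb windows are exact
toy_genome <- function(lengths = c(a1 = 3000, a2 = 3000, x1 = 2000),
                       classes = c("autosome", "autosome", "X"),
                       pericentric = NULL) {
  g <- data.frame(name = names(lengths), length = as.numeric(lengths),
                  class = classes, stringsAsFactors = FALSE)
  if (is.null(pericentric))
    pericentric <- data.frame(chrom = character(), start = numeric(),
                              end = numeric())
  hn_genome(g, pericentric = pericentric)
}

## coverage track with one constant value everywhere
flat_track <- function(genome, value, ...) {
  len <- genome$chromosomes$length
  values <- lapply(len, function(L) rep(value, L))
  names(values) <- genome$chromosomes$name
  coverage_track(values, genome, ...)
}

## enrichment track from explicit per-chromosome vectors
enr_track <- function(genome, values, ...) {
  enrichment_track(values, genome, ...)
}

## enrichment track constant everywhere except given (chrom, pos0, value)
enr_with_sites <- function(genome, background = 0, sites = NULL, ...) {
  len <- genome$chromosomes$length
  values <- lapply(len, function(L) rep(background, L))
  names(values) <- genome$chromosomes$name
  if (!is.null(sites)) {
    for (i in seq_len(nrow(sites))) {
      idx <- (sites$start[i] + 1):sites$end[i]
      values[[sites$chrom[i]]][idx] <- sites$value[i]
    }
  }
  enrichment_track(values, genome, ...)
}

## default synthetic genome, generated once
default_gen <- function() {
  if (is.null(.hn_cache$gen))
    .hn_cache$gen <- generate_genome(sim_config(), seed = 1)
  .hn_cache$gen
}

## spike-in fixture: reference from three undistorted pairs plus one
## undistorted sample pair, all on the default truth
spike_fixture <- function() {
  if (is.null(.hn_cache$spike)) {
    truth <- default_gen()$truth
    no_warp <- list(slope = 1, offset = 0)
    pairs <- lapply(1:3, function(k)
      simulate_spikein_pair(truth, NULL, 500 + k, distortion = no_warp))
    reference <- build_spikein_reference(pairs)
    sample_pair <- simulate_spikein_pair(truth, NULL, 991,
                                         distortion = no_warp)
    w0 <- window_enrichment(sample_pair$chip, sample_pair$input)
    .hn_cache$spike <- list(truth = truth, reference = reference, w0 = w0)
  }
  .hn_cache$spike
}

## full default pipeline run (with outputs), shared across test files
pipeline_fixture <- function() {
  if (is.null(.hn_cache$pipe)) {
    outdir <- file.path(tempdir(), "hetnuc-pipeline-fixture")
    t0 <- Sys.time()
    res <- run_pipeline(sim_config(), seed = 1, outdir = outdir)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .hn_cache$pipe <- list(res = res, outdir = outdir, elapsed = elapsed)
  }
  .hn_cache$pipe
}

## independent brute-force oracle for the per-site enrichment formula:
## plain loops, no shared code with the implementation
brute_enrichment <- function(chip_values, input_values, auto_names,
                             width = 1000, pseudo = 0.01) {
  win_means <- function(values) {
    out <- numeric(0)
    for (chrom in auto_names) {
      v <- values[[chrom]]
      i <- 1
      while (i <= length(v)) {
        j <- min(i + width - 1, length(v))
        out <- c(out, sum(v[i:j]) / (j - i + 1))
        i <- j + 1
      }
    }
    out
  }
  med <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  cm <- med(win_means(chip_values))
  im <- med(win_means(input_values))
  out <- list()
  for (chrom in names(chip_values)) {
    res <- numeric(length(chip_values[[chrom]]))
    for (i in seq_along(res)) {
      res[i] <- log2((chip_values[[chrom]][i] / cm + pseudo) /
                       (input_values[[chrom]][i] / im + pseudo))
    }
    out[[chrom]] <- res
  }
  out
}

## independent brute-force two-sided rank-sum p: enumerate every assignment
## of ranks to the x-sample
brute_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
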