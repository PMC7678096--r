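# shared fixture builders and independent oracles

# small uniform-bin track on one or more chromosomes
make_track <- function(values, bin_size = 10L, chrom = "chr1",
                       probability = FALSE) {
  n <- length(values)
  chrom <- rep_len(chrom, n)
  start <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                         function(i) (seq_along(i) - 1L) * bin_size),
                  use.names = FALSE)
  # reorder into chromosome blocks
  ord <- order(match(chrom, unique(chrom)))
  f <- if (probability) probability_track else coverage_track
  f(chrom[ord], start, start + bin_size, values[ord], bin_size = bin_size)
}

# random coverage track with a random number of chromosomes
random_track <- function(n_bins, bin_size = 10L, max_chroms = 3L,
                         probability = FALSE) {
  n_chrom <- sample.int(max_chroms, 1L)
  chrom <- sort(sample.int(n_chrom, n_bins, replace = TRUE))
  values <- if (probability) runif(n_bins) else rpois(n_bins, 4)
  make_track(values, bin_size, paste0("chr", chrom), probability)
}

# brute-force sliding median: the independent oracle for sliding_median()
naive_sliding_median <- function(values, half_width) {
  L <- length(values)
  vapply(seq_len(L), function(i) {
    w <- sort(values[max(1L, i - half_width):min(L, i + half_width)])
    m <- length(w)
    if (m %% 2L == 1L) w[(m + 1L) / 2] else (w[m / 2] + w[m / 2 + 1L]) / 2
  }, numeric(1L))
}
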