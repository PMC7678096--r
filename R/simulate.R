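#' Specify a synthetic coverage track
#'
#' Describes a single-chromosome coverage track with a known
#' signal/background structure: a flat or Poisson-noise background at
#' `background_rate` plus rectangular (boxcar) peaks. Peak regions must be
#' sparse — total peak width below 50% of the chromosome — mirroring the
#' assumption under which the sliding-window median is a valid background
#' estimator; the generator enforces it so simulated fixtures cannot
#' silently violate the estimator's premise.
#'
#' @param chrom_length_bp chromosome length in bp.
#' @param bin_size bin width in bp.
#' @param background_rate mean background read depth (>= 0).
#' @param noise_model `"constant"` (bins take exactly their mean value;
#'   useful for exact-value tests) or `"poisson"` (read-depth counts drawn
#'   from Poisson distributions).
#' @param peaks data.frame with columns `start_bp`, `width_bp`, `height`:
#'   non-overlapping boxcar peaks inside the chromosome. `NULL` for none.
#' @param seed integer seed making generation deterministic.
#' @param chrom chromosome name used in generated tracks.
#' @return A `synthetic_track_spec` list.
#' @export
synthetic_track_spec <- function(chrom_length_bp, bin_size = 10L,
                                 background_rate = 5,
                                 noise_model = c("constant", "poisson"),
                                 peaks = NULL, seed = 1L, chrom = "chrS") {
  noise_model <- match.arg(noise_model)
  chrom_length_bp <- as.integer(chrom_length_bp)
  bin_size <- as.integer(bin_size)
  stopifnot(chrom_length_bp > 0L, bin_size > 0L,
            is.finite(background_rate), background_rate >= 0)
  if (is.null(peaks))
    peaks <- data.frame(start_bp = integer(), width_bp = integer(),
                        height = numeric())
  stopifnot(all(c("start_bp", "width_bp", "height") %in% names(peaks)))
  peaks <- peaks[order(peaks$start_bp), , drop = FALSE]
  if (nrow(peaks)) {
    if (any(peaks$width_bp <= 0) || any(peaks$height < 0))
      stop("peak widths must be > 0 and heights >= 0", call. = FALSE)
    if (any(peaks$start_bp < 0) ||
        any(peaks$start_bp + peaks$width_bp > chrom_length_bp))
      stop("peaks must lie within the chromosome", call. = FALSE)
    ends <- peaks$start_bp + peaks$width_bp
    if (nrow(peaks) > 1L && any(peaks$start_bp[-1L] < ends[-nrow(peaks)]))
      stop("overlapping peaks", call. = FALSE)
    if (sum(peaks$width_bp) >= chrom_length_bp / 2)
      stop("total peak width must stay below 50% of the chromosome ",
           "(sparse-signal assumption of the median background estimator)",
           call. = FALSE)
  }
  structure(list(chrom_length_bp = chrom_length_bp, bin_size = bin_size,
                 background_rate = as.numeric(background_rate),
                 noise_model = noise_model, peaks = peaks,
                 seed = as.integer(seed), chrom = chrom),
            class = "synthetic_track_spec")
}

# runs the generator's RNG in an isolated stream so callers' RNG state is
# untouched and a fixed seed gives bit-identical tracks
with_track_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic coverage track
#'
#' Realises a [synthetic_track_spec] as a [coverage_track]. Each bin's mean
#' depth is `background_rate`, plus the peak `height` inside a peak (a bin
#' counts as inside a peak when its midpoint falls in the peak interval).
#' Under the `"constant"` model bins take exactly their mean; under
#' `"poisson"` each bin is an independent Poisson draw with that mean, so
#' values are integer read-depth counts. Generation is deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec a [synthetic_track_spec].
#' @return A [coverage_track].
#' @examples
#' spec <- synthetic_track_spec(5000, bin_size = 10, background_rate = 5,
#'                              peaks = data.frame(start_bp = 1000,
#'                                                 width_bp = 200,
#'                                                 height = 45))
#' tr <- generate_track(spec)
#' range(tr$value)
#' @export
generate_track <- function(spec) {
  stopifnot(inherits(spec, "synthetic_track_spec"))
  start <- seq.int(0L, spec$chrom_length_bp - 1L, by = spec$bin_size)
  end <- pmin(start + spec$bin_size, spec$chrom_length_bp)
  mid <- (start + end) / 2
  mean_depth <- rep(spec$background_rate, length(start))
  for (p in seq_len(nrow(spec$peaks))) {
    s <- spec$peaks$start_bp[p]
    inside <- mid >= s & mid < s + spec$peaks$width_bp[p]
    mean_depth[inside] <- mean_depth[inside] + spec$peaks$height[p]
  }
  value <- switch(spec$noise_model,
                  constant = mean_depth,
                  poisson = with_track_seed(spec$seed,
                                            stats::rpois(length(mean_depth),
                                                         mean_depth)))
  coverage_track(rep(spec$chrom, length(start)), start, end, value,
                 bin_size = spec$bin_size)
}

#' Generate replicate synthetic tracks
#'
#' Produces `n_reps` tracks sharing the spec's peak locations and heights
#' but with independent noise draws per replicate (one seed each),
#' emulating replicates of the same experiment. Under the `"constant"`
#' model all replicates are identical.
#'
#' @param spec a [synthetic_track_spec].
#' @param n_reps number of replicates (>= 2).
#' @param seeds integer vector of length `n_reps`, one seed per replicate;
#'   duplicated seeds trigger a warning (replicates would be identical).
#' @return A list of `n_reps` [coverage_track]s.
#' @export
generate_replicates <- function(spec, n_reps,
                                seeds = spec$seed + seq_len(n_reps) - 1L) {
  stopifnot(inherits(spec, "synthetic_track_spec"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 2L)
    stop("n_reps must be >= 2", call. = FALSE)
  if (length(seeds) != n_reps)
    stop("need exactly one seed per replicate", call. = FALSE)
  if (anyDuplicated(seeds))
    warning("duplicate seeds: some replicates will be identical",
            call. = FALSE)
  lapply(seeds, function(s) {
    spec$seed <- as.integer(s)
    generate_track(spec)
  })
}
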