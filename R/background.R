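#' Background-estimation parameters
#'
#' Bundles the three tunables of the sliding-window-median background
#' estimator: the window size in bp, the multiplier applied to the windowed
#' median, and the small positive value substituted where the scaled median
#' is zero (so the noise estimate can always serve as a divisor).
#'
#' Defaults are the method's standard settings: a 10 kb window, background
#' taken as 2x the windowed median, and 0.1 replacing zeros.
#'
#' @param window_bp sliding-window size in bp (> 0).
#' @param median_multiplier scale factor applied to the windowed median (> 0).
#' @param zero_replacement value substituted when the scaled median is 0 (> 0).
#' @return A `calculator_config` list.
#' @export
calculator_config <- function(window_bp = 10000L, median_multiplier = 2,
                              zero_replacement = 0.1) {
  window_bp <- as.integer(window_bp)
  if (is.na(window_bp) || window_bp <= 0L)
    stop("window_bp must be a positive integer", call. = FALSE)
  if (!is.finite(median_multiplier) || median_multiplier <= 0)
    stop("median_multiplier must be > 0", call. = FALSE)
  if (!is.finite(zero_replacement) || zero_replacement <= 0)
    stop("zero_replacement must be > 0", call. = FALSE)
  structure(list(window_bp = window_bp,
                 median_multiplier = as.numeric(median_multiplier),
                 zero_replacement = as.numeric(zero_replacement)),
            class = "calculator_config")
}

#' @export
print.calculator_config <- function(x, ...) {
  cat(sprintf(paste0("<calculator config: window %d bp, ",
                     "%g x median, zero replacement %g>\n"),
              x$window_bp, x$median_multiplier, x$zero_replacement))
  invisible(x)
}

#' Sliding-window median
#'
#' For each position i returns the median of
#' `values[max(1, i - half_width) .. min(L, i + half_width)]`: a window
#' straddling the position, truncated at the sequence boundaries (no padding
#' or wraparound). Even-count windows — which arise only near the
#' boundaries — use the mean of the two central order statistics, the
#' conventional sample median.
#'
#' Interior positions (full odd windows of 2*half_width + 1 values) are
#' computed by [stats::runmed]'s running-median algorithm, so the whole pass
#' is O(L log w); the truncated boundary windows are computed directly.
#'
#' @param values non-empty numeric vector.
#' @param half_width number of neighbours taken on each side (>= 0).
#' @return Numeric vector of the same length as `values`.
#' @export
sliding_median <- function(values, half_width) {
  L <- length(values)
  if (L == 0L) stop("values must be non-empty", call. = FALSE)
  half_width <- as.integer(half_width)
  if (is.na(half_width) || half_width < 0L)
    stop("half_width must be >= 0", call. = FALSE)
  if (half_width == 0L) return(as.numeric(values))
  k <- 2L * half_width + 1L
  edge_median <- function(i) {
    w <- sort(values[max(1L, i - half_width):min(L, i + half_width)])
    m <- length(w)
    if (m %% 2L == 1L) w[(m + 1L) %/% 2L] else (w[m %/% 2L] + w[m %/% 2L + 1L]) / 2
  }
  if (k > L) return(vapply(seq_len(L), edge_median, numeric(1L)))
  out <- as.numeric(stats::runmed(values, k, endrule = "keep"))
  edges <- c(seq_len(half_width), seq.int(L - half_width + 1L, L))
  out[edges] <- vapply(edges, edge_median, numeric(1L))
  out
}

#' Estimate per-bin background noise
#'
#' Estimates the local background noise n_i of a coverage track as
#' `median_multiplier` times the sliding-window median of coverage, computed
#' per chromosome (windows never span chromosome boundaries). Any scaled
#' median equal to 0 is replaced by `zero_replacement`, so every n_i is
#' strictly positive and safe to divide by. The estimator assumes signal
#' regions are sparse along the genome, so the windowed median reflects
#' background rather than signal.
#'
#' The window is specified in bp and converted to a per-side half-width of
#' `floor(window_bp / (2 * bin_size))` bins, symmetric about each position.
#'
#' @param track a valid [coverage_track].
#' @param config a [calculator_config].
#' @return A `background_track` (a `genomic_track`) whose bins align
#'   one-to-one with `track` and whose values are the strictly positive n_i.
#' @export
estimate_background <- function(track, config = calculator_config()) {
  validate_track(track)
  stopifnot(inherits(config, "calculator_config"))
  if (nrow(track) == 0L)
    return(structure(track, class = c("background_track", "genomic_track",
                                      "data.frame")))
  bs <- bin_size(track)
  if (config$window_bp < bs)
    stop("window smaller than one bin (window_bp = ", config$window_bp,
         ", bin_size = ", bs, ")", call. = FALSE)
  half_width <- config$window_bp %/% (2L * bs)
  n <- track$value
  for (idx in split_chrom(track))
    n[idx] <- config$median_multiplier * sliding_median(track$value[idx],
                                                        half_width)
  n[n == 0] <- config$zero_replacement
  out <- new_track(track$chrom, track$start, track$end, n, bs,
                   "background_track", chrom_order = chrom_order(track))
  out
}
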