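#' Complement of the minimum Bayes' factor
#'
#' The minimum Bayes' factor exp(-z^2/2) is the strongest Bayes-factor
#' evidence against a null hypothesis attainable from a z-statistic. With
#' z = r/n — read depth over local background noise — its complement
#'
#'   p = 1 - exp(-(r/n)^2 / 2)
#'
#' maps coverage onto \[0, 1) as a probability of true signal given the
#' background. It is used here purely as a calibration with a positive
#' monotonic relation to the input: no hypothesis-testing machinery is
#' attached. `p = 0` exactly when `r = 0`, and p approaches 1 as r/n grows.
#'
#' @param r non-negative read depth(s).
#' @param n strictly positive background noise estimate(s); recycled
#'   against `r`.
#' @return Probabilities in \[0, 1), same length as `r`.
#' @examples
#' cmbf(0, 1)        # 0
#' cmbf(5, 5)        # z = 1: 1 - exp(-1/2) ~= 0.3935
#' cmbf(50, 5)       # z = 10: ~= 1
#' @export
cmbf <- function(r, n) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("r must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(n)) || any(n <= 0))
    stop("n must be finite and > 0 (apply zero replacement upstream)",
         call. = FALSE)
  z <- r / n
  1 - exp(-z^2 / 2)
}

#' Transform a coverage track to a cMBF probability track
#'
#' The calculator stage of the pipeline: estimates the per-bin background
#' n_i with [estimate_background()] and applies [cmbf()] bin by bin, giving
#' a per-position probability of true signal. Output bins align exactly with
#' the input bins; runtime is linear in bin count times window size.
#'
#' @param track a valid [coverage_track].
#' @param config a [calculator_config]; the defaults are the method's
#'   standard settings (10 kb window, 2x median, zero replacement 0.1).
#' @param source_label provenance string attached to the result (used by the
#'   CLI for logging); defaults to a deparse of the input.
#' @return A [probability_track] with attribute `source`.
#' @examples
#' tr <- coverage_track("chr1", seq(0L, 90L, 10L), seq(10L, 100L, 10L),
#'                      c(rep(5, 4), 50, 50, rep(5, 4)))
#' p <- calculate_track(tr, calculator_config(window_bp = 100))
#' round(p$value, 4)
#' @export
calculate_track <- function(track, config = calculator_config(),
                            source_label = deparse(substitute(track))) {
  bg <- estimate_background(track, config)
  out <- new_track(track$chrom, track$start, track$end,
                   cmbf(track$value, if (nrow(track)) bg$value else numeric()),
                   bin_size(track), "probability_track",
                   chrom_order = chrom_order(track))
  attr(out, "source") <- as.character(source_label)[1L]
  out
}
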