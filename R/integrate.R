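#' Integrate two probability tracks by joint probability
#'
#' Combines two cMBF probability tracks into one: on every bin with
#' identical coordinates in both tracks the integrated value is the joint
#' probability P_i = p_a,i * p_b,i. The tracks are expected to share a
#' common genome-wide bin grid; bins present in only one track are handled
#' per `missing_policy`:
#'
#' * `"error"` (default) — abort, naming the first offending bin; silent
#'   coercion would hide upstream mistakes on genome-wide grids;
#' * `"treat-as-zero"` — the missing value is taken as 0, so P_i = 0;
#' * `"intersect"` — the bin is dropped.
#'
#' Bins that overlap between the tracks without sharing boundaries indicate
#' different bin grids and are always an error instructing the user to
#' [rebin()]. Input values outside \[0, 1\] are a hard error, not clamped:
#' they indicate raw coverage was passed instead of a probability track.
#'
#' @param a,b [probability_track]s on a common bin grid.
#' @param missing_policy one of `"error"`, `"treat-as-zero"`, `"intersect"`.
#' @return A [probability_track]; every value is `<=` the corresponding
#'   value in each input.
#' @examples
#' pa <- probability_track("chr1", 0L, 10L, 0.5)
#' pb <- probability_track("chr1", 0L, 10L, 0.5)
#' integrate_pair(pa, pb)$value  # 0.25
#' @export
integrate_pair <- function(a, b, missing_policy = c("error", "treat-as-zero",
                                                    "intersect")) {
  missing_policy <- match.arg(missing_policy)
  check_probability(a, "first")
  check_probability(b, "second")
  key_a <- paste(a$chrom, a$start, a$end)
  key_b <- paste(b$chrom, b$start, b$end)
  ia <- match(key_a, key_b)
  only_a <- is.na(ia)
  only_b <- !(key_b %in% key_a)
  if (any(only_a)) check_grid_compatible(a, b, which(only_a))
  if (any(only_b)) check_grid_compatible(b, a, which(only_b))
  if ((any(only_a) || any(only_b)) && missing_policy == "error") {
    off <- if (any(only_a)) a[which(only_a)[1L], ] else b[which(only_b)[1L], ]
    stop("bin ", off$chrom, ":", off$start, "-", off$end,
         " is present in only one track (missing_policy = \"error\")",
         call. = FALSE)
  }
  chrom <- a$chrom; start <- a$start; end <- a$end
  value <- a$value * ifelse(only_a, 0, b$value[ia])
  if (missing_policy == "intersect") {
    keep <- !only_a
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    value <- value[keep]
  } else if (any(only_b)) {
    # treat-as-zero: bins unique to b enter the union with P = 0
    chrom <- c(chrom, b$chrom[only_b])
    start <- c(start, b$start[only_b])
    end <- c(end, b$end[only_b])
    value <- c(value, rep(0, sum(only_b)))
  }
  co <- unique(c(chrom_order(a), chrom_order(b)))
  ord <- order(match(chrom, co), start)
  out <- new_track(chrom[ord], start[ord], end[ord], value[ord],
                   bin_size(a), "probability_track", chrom_order = co)
  validate_track(out)
  out
}

check_probability <- function(track, which_one) {
  validate_track(track)
  if (nrow(track) && (any(track$value < 0) || any(track$value > 1)))
    stop("values of the ", which_one, " track are outside [0, 1]; ",
         "integrate cMBF probability tracks, not raw coverage",
         call. = FALSE)
}

# bins of `x` at `idx` have no coordinate-identical partner in `y`; if any of
# them overlaps a `y` bin the two tracks are on different grids -> error
check_grid_compatible <- function(x, y, idx) {
  for (ch in unique(x$chrom[idx])) {
    yb <- y[y$chrom == ch, ]
    if (nrow(yb) == 0L) next
    xi <- idx[x$chrom[idx] == ch]
    # a y bin overlaps x bin i iff y$start < x$end[i] and y$end > x$start[i]
    j <- findInterval(x$start[xi], yb$end) + 1L
    hit <- j <= nrow(yb) & yb$start[j] < x$end[xi]
    if (any(hit)) {
      i <- xi[which(hit)[1L]]
      stop("bin grids are misaligned near ", x$chrom[i], ":", x$start[i],
           "-", x$end[i], "; rebin the tracks to a common grid first",
           call. = FALSE)
    }
  }
}

#' Integrate several probability tracks
#'
#' Left-fold of [integrate_pair()] over the list: sequential dual-input
#' joint-probability calculations, valid because the operation is
#' commutative and associative, so the result is independent of input order
#' (up to floating-point rounding in the last ulp).
#'
#' @param tracks list of at least two [probability_track]s.
#' @inheritParams integrate_pair
#' @return A [probability_track].
#' @export
integrate_many <- function(tracks, missing_policy = c("error", "treat-as-zero",
                                                      "intersect")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.list(tracks) || length(tracks) < 2L)
    stop("need at least 2 tracks to integrate", call. = FALSE)
  Reduce(function(a, b) integrate_pair(a, b, missing_policy), tracks)
}

#' Calculate and integrate coverage tracks in one step
#'
#' Convenience composition of the full pipeline: each coverage track is
#' transformed to a cMBF probability track with [calculate_track()], then
#' the probability tracks are folded into one with [integrate_many()].
#'
#' @param tracks list of at least two [coverage_track]s with equal bin size.
#' @param config a [calculator_config] shared by all calculator runs.
#' @inheritParams integrate_pair
#' @return A [probability_track].
#' @export
integrate_coverage <- function(tracks, config = calculator_config(),
                               missing_policy = c("error", "treat-as-zero",
                                                  "intersect")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.list(tracks) || length(tracks) < 2L)
    stop("need at least 2 tracks to integrate", call. = FALSE)
  sizes <- unique(vapply(tracks, bin_size, integer(1L)))
  if (length(sizes[!is.na(sizes)]) > 1L)
    stop("tracks have mixed bin sizes (", paste(sizes, collapse = ", "),
         "); rebin to a common grid first", call. = FALSE)
  probs <- lapply(seq_along(tracks), function(i)
    calculate_track(tracks[[i]], config, source_label = paste0("track", i)))
  integrate_many(probs, missing_policy)
}
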