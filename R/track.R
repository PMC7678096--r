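#' Genomic signal track containers
#'
#' A genomic track is a data.frame with columns `chrom`, `start`, `end`,
#' `value` holding sorted, non-overlapping fixed-width bins (the last bin of
#' a chromosome may be shorter, as coverage tools emit at chromosome ends).
#' Coordinates are 0-based half-open, the BED convention. Two subclasses
#' share this structure:
#'
#' * `coverage_track` — `value` is a non-negative read depth `r_i`;
#' * `probability_track` — `value` is a probability in \[0, 1\], either a
#'   single-track cMBF `p_i` or an integrated joint probability `P_i`.
#'
#' The bin width is carried in attribute `bin_size` and chromosome order
#' (order of first appearance, no karyotype sorting) in `chrom_order`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open bin coordinates (bp).
#' @param value numeric vector of bin values.
#' @param bin_size uniform bin width in bp; inferred as the modal width when
#'   `NULL`.
#' @return An object of class `coverage_track` or `probability_track`
#'   (both inherit from `genomic_track` and `data.frame`).
#' @examples
#' tr <- coverage_track("chr1", c(0L, 10L, 20L), c(10L, 20L, 30L), c(1, 2, 3))
#' tr
#' summary(tr)
#' @name genomic_track
NULL

new_track <- function(chrom, start, end, value, bin_size, subclass,
                      chrom_order = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (is.null(chrom_order)) chrom_order <- unique(df$chrom)
  structure(df,
            bin_size = as.integer(bin_size),
            chrom_order = chrom_order,
            class = c(subclass, "genomic_track", "data.frame"))
}

infer_bin_size <- function(start, end) {
  if (length(start) == 0L) return(NA_integer_)
  widths <- end - start
  tab <- tabulate(match(widths, unique(widths)))
  as.integer(unique(widths)[which.max(tab)])
}

#' @rdname genomic_track
#' @export
coverage_track <- function(chrom, start, end, value, bin_size = NULL) {
  if (is.null(bin_size)) bin_size <- infer_bin_size(start, end)
  tr <- new_track(chrom, start, end, value, bin_size, "coverage_track")
  validate_track(tr)
  tr
}

#' @rdname genomic_track
#' @export
probability_track <- function(chrom, start, end, value, bin_size = NULL) {
  if (is.null(bin_size)) bin_size <- infer_bin_size(start, end)
  tr <- new_track(chrom, start, end, value, bin_size, "probability_track")
  validate_track(tr)
  tr
}

#' Validate track invariants
#'
#' Checks sortedness, non-overlap within chromosomes, coordinate sanity and
#' the value range appropriate to the track class (non-negative for coverage,
#' \[0, 1\] for probability tracks). Called by every constructor and by the
#' BED reader; exported so pipelines can re-validate externally produced
#' objects.
#'
#' @param track a `genomic_track`.
#' @return `track`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_track <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("chrom", "start", "end", "value") %in% names(track)))
  if (nrow(track) == 0L) return(invisible(track))
  if (any(track$start < 0L)) stop("negative start coordinate", call. = FALSE)
  if (any(track$end <= track$start))
    stop("bin with end <= start", call. = FALSE)
  if (any(!is.finite(track$value)))
    stop("non-finite bin value", call. = FALSE)
  if (any(track$value < 0))
    stop("negative bin value", call. = FALSE)
  if (inherits(track, "probability_track") && any(track$value > 1))
    stop("probability track has values > 1", call. = FALSE)
  # sorted by chromosome order of appearance, then start; non-overlapping
  ord <- chrom_order(track)
  ci <- match(track$chrom, ord)
  if (is.unsorted(ci)) stop("chromosome blocks are interleaved", call. = FALSE)
  same <- ci[-1L] == ci[-length(ci)]
  if (any(same & track$start[-1L] < track$start[-nrow(track)]))
    stop("bins not sorted by start within a chromosome", call. = FALSE)
  if (any(same & track$start[-1L] < track$end[-nrow(track)]))
    stop("overlapping bins within a chromosome", call. = FALSE)
  invisible(track)
}

#' @rdname genomic_track
#' @param x,object,track a track object.
#' @export
bin_size <- function(track) attr(track, "bin_size", exact = TRUE)

#' @rdname genomic_track
#' @export
chrom_order <- function(track) {
  co <- attr(track, "chrom_order", exact = TRUE)
  if (is.null(co)) unique(track$chrom) else co
}

# indices of each chromosome's bins, in track order
split_chrom <- function(track) {
  split(seq_len(nrow(track)), factor(track$chrom, levels = chrom_order(track)))
}

#' @rdname genomic_track
#' @param ... passed on to further methods.
#' @export
print.genomic_track <- function(x, ...) {
  kind <- if (inherits(x, "probability_track")) "probability" else "coverage"
  cat(sprintf("<%s track: %d bins, bin size %s bp, %d chromosome(s)>\n",
              kind, nrow(x),
              ifelse(is.na(bin_size(x)), "?", bin_size(x)),
              length(chrom_order(x))))
  if (nrow(x) > 0L) {
    show <- utils::head(as.data.frame(x), 6L)
    print(show, row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... %d more bins\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' @rdname genomic_track
#' @export
summary.genomic_track <- function(object, ...) {
  co <- chrom_order(object)
  per <- vapply(split_chrom(object), length, integer(1L))
  out <- list(bins = nrow(object), bin_size = bin_size(object),
              chromosomes = co, bins_per_chrom = per,
              value_summary = summary(object$value))
  class(out) <- "summary.genomic_track"
  out
}

#' @export
print.summary.genomic_track <- function(x, ...) {
  cat(sprintf("Track: %d bins of %s bp on %d chromosome(s)\n",
              x$bins, ifelse(is.na(x$bin_size), "?", x$bin_size),
              length(x$chromosomes)))
  cat("Bins per chromosome:\n")
  print(x$bins_per_chrom)
  cat("Values:\n")
  print(x$value_summary)
  invisible(x)
}

#' @rdname genomic_track
#' @param chrom_plot chromosome to plot; defaults to the first in the track.
#' @export
plot.genomic_track <- function(x, chrom_plot = chrom_order(x)[1L], ...) {
  sel <- x$chrom == chrom_plot
  if (!any(sel)) stop("no bins on chromosome ", chrom_plot, call. = FALSE)
  mid <- (x$start[sel] + x$end[sel]) / 2
  ylab <- if (inherits(x, "probability_track")) "probability" else "coverage"
  graphics::plot(mid, x$value[sel], type = "s", xlab = paste0(chrom_plot, " (bp)"),
                 ylab = ylab, ...)
  invisible(x)
}
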