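#' Read a 4-column coverage BED file
#'
#' Reads a tab/whitespace-delimited BED dialect with fields chrom, start,
#' end, value — the format emitted by `bedtools genomecov -bg`, `bedtools
#' coverage` and similar depth tools. Coordinates are 0-based half-open.
#' Lines starting with `track`, `browser` or `#` are skipped. The fourth
#' field is parsed as a real number so the same reader serves read-depth and
#' probability tracks. Records are validated (coordinates, value range,
#' overlap) and sorted per chromosome if needed (with a notice); chromosome
#' order of first appearance is preserved.
#'
#' @param path path to an existing BED file.
#' @param probability if `TRUE`, return a `probability_track` (values checked
#'   to lie in \[0, 1\]); otherwise a `coverage_track`.
#' @return A [coverage_track] (or [probability_track]) whose `bin_size` is
#'   the modal bin width in the file; an empty file yields a zero-bin track.
#' @seealso [write_bed()], [write_bedgraph()]
#' @export
read_coverage_bed <- function(path, probability = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  subclass <- if (probability) "probability_track" else "coverage_track"
  if (length(lines) == 0L)
    return(new_track(character(), integer(), integer(), numeric(),
                     NA_integer_, subclass))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("line ", lineno[which(nf < 4L)[1L]],
         ": expected at least 4 fields, found ", nf[which(nf < 4L)[1L]],
         call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 4L)))
  bad <- function(test, what) {
    i <- which(test)
    if (length(i))
      stop("line ", lineno[i[1L]], ": ", what, call. = FALSE)
  }
  bad(is.na(start) | start != floor(start), "start is not an integer")
  bad(is.na(end) | end != floor(end), "end is not an integer")
  bad(start < 0, "negative start coordinate")
  bad(end <= start, "end must exceed start")
  bad(is.na(value), "value is not numeric")
  bad(value < 0, "negative value")
  co <- unique(chrom)
  ci <- match(chrom, co)
  ord <- order(ci, start)
  if (is.unsorted(ord)) {
    message("read_coverage_bed: records were not sorted; sorting per chromosome")
    chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
    value <- value[ord]
  }
  tr <- new_track(chrom, start, end, value,
                  infer_bin_size(start, end), subclass, chrom_order = co)
  validate_track(tr)
  tr
}

#' Write a track as a 4-column BED file
#'
#' Writes one tab-delimited `chrom start end value` line per bin. A
#' write-then-read round trip reproduces the track exactly up to the value
#' formatting precision.
#'
#' @param track a valid [coverage_track] or [probability_track].
#' @param path output path.
#' @param precision decimal places for the value field (default 6;
#'   probabilities below 10^-6 are indistinguishable from 0 downstream).
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path, precision = 6L) {
  validate_track(track)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(track) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                       formatC(track$value, format = "f",
                               digits = as.integer(precision))), con)
  invisible(path)
}

#' Write a track as a bedGraph file
#'
#' Emits a `track type=bedGraph name=<track_name>` header followed by
#' 4-column records, suitable for genome-browser display (conversion to
#' BigWig is left to external tools). With `merge = TRUE`, runs of adjacent
#' bins (contiguous coordinates, same chromosome) carrying the same
#' formatted value are collapsed into single records.
#'
#' @inheritParams write_bed
#' @param track_name name placed in the bedGraph track header.
#' @param merge collapse adjacent equal-valued bins into one record?
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, track_name = "cmbftrack",
                           merge = FALSE, precision = 6L) {
  validate_track(track)
  chrom <- track$chrom; start <- track$start; end <- track$end
  val <- formatC(track$value, format = "f", digits = as.integer(precision))
  if (merge && nrow(track) > 1L) {
    n <- nrow(track)
    newrun <- c(TRUE, !(chrom[-1L] == chrom[-n] & start[-1L] == end[-n] &
                          val[-1L] == val[-n]))
    run <- cumsum(newrun)
    first <- which(newrun)
    last <- c(first[-1L] - 1L, n)
    chrom <- chrom[first]; start <- start[first]; end <- end[last]
    val <- val[first]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", track_name), con)
  if (length(chrom) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end, val), con)
  invisible(path)
}

#' Aggregate a track to coarser bins
#'
#' Re-bins a track to a coarser uniform grid; each output bin's value is the
#' arithmetic mean of the input bins it covers (a partial trailing group
#' averages the available bins), so the width-weighted mean over any whole
#' region is preserved. `new_bin_size` must be a positive multiple of the
#' current bin size.
#'
#' @param track a [coverage_track].
#' @param new_bin_size target bin width in bp.
#' @return A track of the same class on the coarser grid.
#' @export
rebin <- function(track, new_bin_size) {
  bs <- bin_size(track)
  new_bin_size <- as.integer(new_bin_size)
  if (is.na(bs)) stop("track has no bins to rebin", call. = FALSE)
  if (new_bin_size <= 0L || new_bin_size %% bs != 0L)
    stop("new_bin_size must be a positive multiple of the track bin size (",
         bs, " bp)", call. = FALSE)
  if (new_bin_size == bs) return(track)
  fac <- new_bin_size %/% bs
  subclass <- class(track)[1L]
  pieces <- lapply(split_chrom(track), function(idx) {
    n <- length(idx)
    grp <- (seq_len(n) - 1L) %/% fac
    first <- idx[!duplicated(grp)]
    last <- idx[rev(!duplicated(rev(grp)))]
    sums <- rowsum(track$value[idx], grp, reorder = FALSE)[, 1L]
    counts <- rowsum(rep(1, n), grp, reorder = FALSE)[, 1L]
    data.frame(chrom = track$chrom[first],
               start = track$start[first],
               end = track$end[last],
               value = unname(sums / counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  tr <- new_track(out$chrom, out$start, out$end, out$value, new_bin_size,
                  subclass, chrom_order = chrom_order(track))
  validate_track(tr)
  tr
}
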