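#' Sonogram feature extraction
#'
#' A sonogram is a `channels x bins` matrix of spike counts obtained by
#' counting events over non-overlapping fixed-length time windows. It is
#' the image representation fed to the convolutional network, and can be
#' re-expanded into Poisson input rates for the spiking twin.
#'
#' @name sonogram
NULL

#' Bin a spike train into a sonogram
#'
#' Bins are half-open `[k*w, (k+1)*w)` with the final boundary closed, so
#' an event exactly at the end of the interval lands in the last bin and no
#' event is ever dropped. `merged_abs` counts every event regardless of
#' polarity in a single plane (row sums equal the total event count);
#' `two_plane` stacks positive-event counts over negative-event counts as
#' `2 * channels` rows.
#'
#' @param st A [spike_train()].
#' @param n_bins Number of time bins (>= 1).
#' @param polarity_mode `"merged_abs"` (default) or `"two_plane"`.
#' @return A `sonogram` object: integer `counts` matrix, `bin_width`
#'   (seconds), `duration`, `polarity_mode`.
#' @export
time_bin <- function(st, n_bins, polarity_mode = c("merged_abs", "two_plane")) {
  stopifnot(inherits(st, "spike_train"))
  polarity_mode <- match.arg(polarity_mode)
  if (n_bins < 1L) stop("`n_bins` must be a positive integer")
  bw <- st$duration / n_bins
  n_rows <- if (polarity_mode == "two_plane") 2L * st$n_channels else st$n_channels
  counts <- matrix(0L, nrow = n_rows, ncol = n_bins)
  if (n_events(st) > 0L) {
    bins <- raster_bin(st$times, bw, n_bins)
    rows <- if (polarity_mode == "two_plane") {
      st$channels + ifelse(st$polarities > 0L, 0L, st$n_channels)
    } else {
      st$channels
    }
    for (k in seq_along(bins)) {
      counts[rows[k], bins[k]] <- counts[rows[k], bins[k]] + 1L
    }
  }
  structure(
    list(counts = counts, bin_width = bw, duration = st$duration,
         polarity_mode = polarity_mode),
    class = "sonogram"
  )
}

#' @export
print.sonogram <- function(x, ...) {
  cat(sprintf("<sonogram> %d x %d (%s), bin width %.4g s, %d events\n",
              nrow(x$counts), ncol(x$counts), x$polarity_mode,
              x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Convert a sonogram into Poisson input rates
#'
#' Linearly rescales counts by the global (whole-sonogram) maximum so that
#' the densest cell maps to `max_rate` Hz and inter-channel intensity
#' ratios are preserved. An all-zero sonogram maps to all-zero rates.
#'
#' @param s A [time_bin()] sonogram.
#' @param max_rate Peak input rate in Hz.
#' @return Numeric rate matrix of the same shape as `s$counts`.
#' @export
sonogram_to_rates <- function(s, max_rate = 500) {
  stopifnot(inherits(s, "sonogram"), max_rate >= 0)
  m <- max(s$counts)
  if (m == 0) return(matrix(0, nrow = nrow(s$counts), ncol = ncol(s$counts)))
  max_rate * s$counts / m
}

#' Render a sonogram as a grayscale PNG
#'
#' One pixel per cell: rows are channels, columns are time bins, intensity
#' proportional to count (the maximum count maps to white).
#'
#' @param s A [time_bin()] sonogram.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_sonogram <- function(s, path) {
  stopifnot(inherits(s, "sonogram"))
  m <- max(s$counts)
  img <- if (m == 0) s$counts * 0 else s$counts / m
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write a sonogram counts matrix as CSV
#' @param s A [time_bin()] sonogram.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sonogram_csv <- function(s, path) {
  stopifnot(inherits(s, "sonogram"))
  utils::write.table(s$counts, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
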