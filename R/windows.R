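#' Sliding-window specification
#'
#' Windows are anchored at coordinate 0 and use 0-based half-open
#' `[start, end)` intervals internally. The scan defaults follow the common
#' 20-kb window / 10-kb step convention.
#'
#' @param size Window size in bp (default 20000).
#' @param step Step in bp (default 10000); must satisfy `0 < step <= size`.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(size = 20000, step = 10000) {
  size <- as.integer(size); step <- as.integer(step)
  if (is.na(size) || size <= 0L) stop("window size must be positive", call. = FALSE)
  if (is.na(step) || step <= 0L || step > size) {
    stop("step must satisfy 0 < step <= size", call. = FALSE)
  }
  structure(list(size = size, step = step), class = "window_spec")
}

## window grid covering [0, chrom_len): starts at multiples of step,
## last window is the first whose start reaches the final position
make_windows <- function(chrom, chrom_len, spec) {
  starts <- seq.int(0L, max(0L, as.integer(ceiling(chrom_len / spec$step) - 1L)) * spec$step,
                    by = spec$step)
  starts <- starts[starts < chrom_len]
  tibble::tibble(chrom = chrom, start = starts, end = starts + spec$size)
}

## assign each position (1-based bp) to every window covering it; returns
## a list: for window i, integer indices of sites inside [start, end)
window_site_index <- function(pos, windows) {
  p0 <- pos - 1L  # 0-based coordinate of the SNP
  lapply(seq_len(nrow(windows)), function(i) {
    which(p0 >= windows$start[i] & p0 < windows$end[i])
  })
}

new_windowed_track <- function(chrom, start, end, n_snps, value, stat) {
  out <- tibble::tibble(chrom = chrom, start = as.integer(start),
                        end = as.integer(end),
                        n_snps = as.integer(n_snps), value = as.double(value))
  attr(out, "stat") <- stat
  class(out) <- c("windowed_track", class(out))
  out
}

track_stat <- function(track) attr(track, "stat") %||% "value"

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    stop("window grids do not match", call. = FALSE)
  }
  invisible(TRUE)
}

#' Z-transform a windowed track
#'
#' Standardizes the track genome-wide: `(x - mean) / sd` over all
#' non-missing windows, with the sample (n-1) standard deviation.
#' Missing windows stay missing.
#'
#' @param track A windowed track tibble (`value` column).
#' @return The track with `value` replaced by its Z-score.
#' @export
z_transform <- function(track) {
  v <- track$value
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-missing windows", call. = FALSE)
  s <- stats::sd(v[ok])
  if (!is.finite(s) || s == 0) stop("zero variance: cannot Z-transform", call. = FALSE)
  track$value <- (v - mean(v[ok])) / s
  attr(track, "stat") <- paste0("Z(", track_stat(track), ")")
  track
}

## merge selected window rows (0-based half-open) into bookended regions
merge_windows_to_regions <- function(windows, selected, evidence) {
  w <- windows[selected, , drop = FALSE]
  if (nrow(w) == 0L) return(candidate_regions())
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  out <- list()
  cur <- w[1, ]
  if (nrow(w) > 1) for (i in 2:nrow(w)) {
    if (w$chrom[i] == cur$chrom && w$start[i] <= cur$end) {
      cur$end <- max(cur$end, w$end[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- w[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  m <- dplyr::bind_rows(out)
  candidate_regions(m$chrom, m$start, m$end, evidence = evidence)
}

## strict empirical quantile threshold: values strictly above the
## q-quantile (type 7) are selected; ties at the threshold excluded
strictly_above_quantile <- function(x, q) {
  thr <- stats::quantile(x, q, na.rm = TRUE, names = FALSE, type = 7)
  !is.na(x) & x > thr
}
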