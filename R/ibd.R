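#' Detect IBD segments by exact haplotype matching
#'
#' Self-contained stand-in for a probabilistic IBD caller, intended for
#' error-free (simulated) data: reports every maximal inter-sample
#' haplotype match with at most `max_mismatch` discordant SNPs spanning at
#' least `min_length_bp`. Segment boundaries are placed at the midpoint
#' between the last matching and first mismatching SNP (chromosome ends
#' extend to 0 and `chrom_len`). Within-sample pairs are excluded.
#' Missing alleles count as mismatches. For real data, read an external
#' caller's output with [read_ibd_segments()].
#'
#' @param panel A phased [hap_panel()].
#' @param min_length_bp Minimum segment span (default 1e5).
#' @param max_mismatch Allowed discordant SNPs inside a segment (default 0).
#' @param samples1,samples2 Optional sample sets; only pairs with one
#'   member in each set are scanned (default: all inter-sample pairs).
#' @param chrom_len Chromosome length (default: last SNP position).
#' @return An `ibd_segments` tibble (0-based half-open coordinates).
#' @export
detect_ibd_segments <- function(panel, min_length_bp = 1e5, max_mismatch = 0,
                                samples1 = NULL, samples2 = NULL,
                                chrom_len = max(panel$pos)) {
  require_phased(panel, "IBD detection")
  H <- panel$alleles
  pos <- panel$pos
  S <- length(pos)
  ## midpoints: boundary of a run ending at site i / starting at site i
  left_bound <- c(0, floor((pos[-S] + pos[-1]) / 2))       # before site i
  right_bound <- c(floor((pos[-S] + pos[-1]) / 2), chrom_len)  # after site i
  if (is.null(samples1)) samples1 <- panel$samples
  if (is.null(samples2)) samples2 <- panel$samples
  rows_of <- function(s) list(r = c(2L * match(s, panel$samples) - 1L,
                                    2L * match(s, panel$samples)))
  out <- vector("list", 2000L); nout <- 0L
  seen <- new.env(parent = emptyenv())
  for (s1 in samples1) {
    i1 <- match(s1, panel$samples)
    for (s2 in samples2) {
      if (s1 == s2) next
      key <- paste(sort(c(s1, s2)), collapse = "\r")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      i2 <- match(s2, panel$samples)
      for (h1 in 1:2) for (h2 in 1:2) {
        segs <- match_runs_cpp(H[2L * i1 - 2L + h1, ], H[2L * i2 - 2L + h2, ],
                               as.integer(max_mismatch))
        for (k in seq_len(nrow(segs))) {
          st <- left_bound[segs[k, 1]]
          en <- right_bound[segs[k, 2]]
          if (en - st >= min_length_bp) {
            nout <- nout + 1L
            if (nout > length(out)) out <- c(out, vector("list", length(out)))
            out[[nout]] <- c(i1 = i1, h1 = h1, i2 = i2, h2 = h2, st = st, en = en)
          }
        }
      }
    }
  }
  if (nout == 0L) {
    return(ibd_segments(character(), integer(), character(), integer(),
                        character(), numeric(), numeric()))
  }
  m <- do.call(rbind, out[seq_len(nout)])
  ibd_segments(panel$samples[m[, "i1"]], m[, "h1"],
               panel$samples[m[, "i2"]], m[, "h2"],
               panel$chrom, m[, "st"], m[, "en"],
               length_cm = NA_real_)
}

#' Per-window normalized IBD sharing (nIBD)
#'
#' Counts the IBD tracks between one cultivar and any donor that overlap
#' each window, divided by the number of donors. Each segment is counted
#' once in every window it overlaps. `count = "donors"` counts distinct
#' sharing donors instead of tracks.
#'
#' @param segments An `ibd_segments` tibble.
#' @param cultivar Sample id (must not be a donor).
#' @param donors Character vector of donor sample ids.
#' @param spec Window grid (default 10 kb / 5 kb).
#' @param chrom_len Chromosome length in bp.
#' @param chrom Chromosome name for the track.
#' @param count `"tracks"` (default) or `"donors"`.
#' @return A windowed track (`stat = "nibd"`).
#' @export
nibd <- function(segments, cultivar, donors, spec = window_spec(10000, 5000),
                 chrom_len, chrom = "chr1", count = c("tracks", "donors")) {
  count <- match.arg(count)
  if (!length(donors)) stop("donors must be non-empty", call. = FALSE)
  if (cultivar %in% donors) stop("cultivar cannot be one of the donors", call. = FALSE)
  windows <- make_windows(chrom, chrom_len, spec)
  sel <- (segments$sample1 == cultivar & segments$sample2 %in% donors) |
    (segments$sample2 == cultivar & segments$sample1 %in% donors)
  seg <- segments[sel, , drop = FALSE]
  vals <- nibd_window_counts(seg, windows, cultivar, count) / length(donors)
  new_windowed_track(windows$chrom, windows$start, windows$end,
                     0L, vals, "nibd")
}

nibd_window_counts <- function(seg, windows, cultivar, count) {
  nw <- nrow(windows)
  if (count == "tracks") {
    counts <- numeric(nw)
    for (k in seq_len(nrow(seg))) {
      hit <- windows$start < seg$end[k] & windows$end > seg$start[k]
      counts[hit] <- counts[hit] + 1
    }
    counts
  } else {
    donor_of <- ifelse(seg$sample1 == cultivar, seg$sample2, seg$sample1)
    per_donor <- matrix(FALSE, nw, length(unique(donor_of)),
                        dimnames = list(NULL, unique(donor_of)))
    for (k in seq_len(nrow(seg))) {
      hit <- windows$start < seg$end[k] & windows$end > seg$start[k]
      per_donor[hit, donor_of[k]] <- TRUE
    }
    rowSums(per_donor)
  }
}

#' Relative IBD (rIBD) track
#'
#' For each cultivar, `rIBD = nIBD_IL - nIBD_PL` per window; the track
#' value is the mean over cultivars, and `z` is its genome-wide
#' standardization (n-1 sd). Accepts either a phased panel (segments are
#' detected with [detect_ibd_segments()]) or a precomputed `ibd_segments`
#' tibble.
#'
#' @param x A [hap_panel()] or `ibd_segments` tibble.
#' @param cultivars Recipient group sample ids.
#' @param donors_il,donors_pl The two donor groups (disjoint from each
#'   other and from `cultivars`).
#' @param spec Window grid (default 10 kb / 5 kb).
#' @param chrom_len Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param count Track- or donor-counting (see [nibd()]).
#' @param min_length_bp,max_mismatch Passed to [detect_ibd_segments()]
#'   when `x` is a panel.
#' @return Tibble of class `ribd_track`: `chrom`, `start`, `end`, `ribd`
#'   (group mean), `z`; per-cultivar values in attribute `per_cultivar`.
#' @export
ribd_track <- function(x, cultivars, donors_il, donors_pl,
                       spec = window_spec(10000, 5000),
                       chrom_len = NULL, chrom = NULL,
                       count = c("tracks", "donors"),
                       min_length_bp = 1e5, max_mismatch = 0) {
  count <- match.arg(count)
  if (length(intersect(donors_il, donors_pl)) ||
      length(intersect(cultivars, c(donors_il, donors_pl)))) {
    stop("cultivars and donor groups must be disjoint", call. = FALSE)
  }
  if (inherits(x, "hap_panel")) {
    if (is.null(chrom_len)) chrom_len <- max(x$pos)
    if (is.null(chrom)) chrom <- x$chrom
    segments <- detect_ibd_segments(x, min_length_bp, max_mismatch,
                                    samples1 = cultivars,
                                    samples2 = c(donors_il, donors_pl),
                                    chrom_len = chrom_len)
  } else {
    segments <- x
    if (is.null(chrom_len)) chrom_len <- max(segments$end)
    if (is.null(chrom)) chrom <- segments$chrom[1] %||% "chr1"
  }
  windows <- make_windows(chrom, chrom_len, spec)
  per <- vapply(cultivars, function(cv) {
    il <- nibd(segments, cv, donors_il, spec, chrom_len, chrom, count)$value
    pl <- nibd(segments, cv, donors_pl, spec, chrom_len, chrom, count)$value
    il - pl
  }, numeric(nrow(windows)))
  mean_ribd <- rowMeans(per)
  s <- stats::sd(mean_ribd)
  if (!is.finite(s) || s == 0) stop("zero variance of window means", call. = FALSE)
  z <- (mean_ribd - mean(mean_ribd)) / s
  out <- tibble::tibble(chrom = windows$chrom, start = windows$start,
                        end = windows$end, ribd = mean_ribd, z = z)
  attr(out, "per_cultivar") <- per
  class(out) <- c("ribd_track", class(out))
  out
}

#' Putative introgressed regions from an rIBD track
#'
#' Windows with `z > z_threshold` merged into regions (tag `"ribd"`).
#'
#' @param track A [ribd_track()].
#' @param z_threshold Z-score threshold (default 2).
#' @return A [candidate_regions()] tibble.
#' @export
introgression_regions <- function(track, z_threshold = 2) {
  merge_windows_to_regions(track[, c("chrom", "start", "end")],
                           !is.na(track$z) & track$z > z_threshold, "ribd")
}
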