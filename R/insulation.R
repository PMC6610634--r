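#' Insulation scores
#'
#' Crane-style sliding-square insulation: the raw score at bin i is the mean
#' of the unmasked contact values in the square of bins
#' `[i - w, i) x (i, i + w]` with `w = square_size_bp / bin_size`, i.e. the
#' contacts passing across bin i within `square_size_bp`. Scores are
#' undefined (NA) within `w` bins of the chromosome ends, at masked bins,
#' and where more than half of the window cells are masked. Normalized
#' scores are `log2(raw / iqrMean)` where `iqrMean` is the mean of the raw
#' scores lying within the interquartile range of the chromosome's raw
#' scores (robust chromosome-level normalization; low normalized scores mark
#' strong insulation, i.e. domain boundaries).
#'
#' @param m A balanced [contact_matrix()] (typically 100-kb bins).
#' @param square_size_bp Side of the sliding square (default 500 kb).
#' @param delta_span_bp Span of the boundary-detection delta vector
#'   (default 400 kb); stored for [call_boundaries()].
#' @return An `insulation_track`: `raw`, `normalized`, parameters, binning.
#' @export
insulation_score <- function(m, square_size_bp = 500e3,
                             delta_span_bp = 400e3) {
  bs <- m$binning$bin_size_bp
  n <- m$binning$n_bins
  w <- as.integer(round(square_size_bp / bs))
  if (w < 1) stop("square smaller than one bin")
  if (2 * w + 1 > n) stop("square larger than chromosome")
  v <- m$values
  un <- !m$mask
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n || !un[i]) next
    rows <- (i - w):(i - 1)
    cols <- (i + 1):(i + w)
    cell_ok <- outer(un[rows], un[cols], "&")
    if (mean(cell_ok) <= 0.5) next
    vals <- v[rows, cols, drop = FALSE][cell_ok]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    mu <- mean(vals)
    raw[i] <- if (mu > 0) mu else NA_real_
  }
  q <- stats::quantile(raw, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  inside <- raw[!is.na(raw) & raw >= q[1] & raw <= q[2]]
  iqr_mean <- mean(inside)
  normalized <- log2(raw / iqr_mean)
  structure(list(binning = m$binning, raw = raw, normalized = normalized,
                 iqr_mean = iqr_mean,
                 params = list(square_size_bp = square_size_bp,
                               delta_span_bp = delta_span_bp)),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("<insulation_track> %s: %d bins scored (square %g kb, delta %g kb)\n",
              x$binning$chrom, sum(!is.na(x$normalized)),
              x$params$square_size_bp / 1e3, x$params$delta_span_bp / 1e3))
  invisible(x)
}

#' Delta vector of an insulation track
#'
#' `delta[i] = mean(normalized over (i, i+d]) - mean(normalized over
#' [i-d, i))` with `d = delta_span_bp / bin_size`. Negative-to-positive zero
#' crossings of the delta vector sit at insulation minima (boundaries).
#'
#' @param track An `insulation_track`.
#' @return Numeric delta vector (NA where either side has no scored bin).
#' @export
insulation_delta <- function(track) {
  ns <- track$normalized
  n <- length(ns)
  d <- as.integer(round(track$params$delta_span_bp / track$binning$bin_size_bp))
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i + 1 > n || i - 1 < 1) next
    right <- ns[(i + 1):min(i + d, n)]
    left <- ns[max(1, i - d):(i - 1)]
    r <- mean(right, na.rm = TRUE)
    l <- mean(left, na.rm = TRUE)
    if (is.nan(r) || is.nan(l)) next
    delta[i] <- r - l
  }
  delta
}

#' Call insulation boundaries
#'
#' Boundaries are placed at negative-to-positive zero crossings of the delta
#' vector (at the crossing, the bin with the lower normalized insulation
#' score is reported). Boundary strength is the amplitude of the delta
#' swing: (nearest local delta maximum after the crossing) minus (nearest
#' local delta minimum before it). Calls with strength <= `noise_threshold`
#' are dropped (the default 0 keeps everything, mirroring `-nt 0`).
#'
#' @param track An `insulation_track`.
#' @param noise_threshold Minimum strength retained (default 0).
#' @return Data frame: `bin`, `strength`, `score` (normalized insulation at
#'   the boundary bin).
#' @export
call_boundaries <- function(track, noise_threshold = 0) {
  delta <- insulation_delta(track)
  ns <- track$normalized
  idx <- which(!is.na(delta))
  calls <- list()
  if (length(idx) >= 2) {
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      if (j != i + 1) next
      if (!(delta[i] < 0 && delta[j] >= 0)) next
      # boundary bin: the insulation minimum at the crossing
      cand <- c(i, j)
      sc <- ns[cand]
      b <- cand[which.min(ifelse(is.na(sc), Inf, sc))]
      # walk left to the local delta minimum
      lo <- i
      while (lo - 1 >= 1 && !is.na(delta[lo - 1]) && delta[lo - 1] <= delta[lo])
        lo <- lo - 1
      # walk right to the local delta maximum
      hi <- j
      while (hi + 1 <= length(delta) && !is.na(delta[hi + 1]) &&
             delta[hi + 1] >= delta[hi])
        hi <- hi + 1
      strength <- delta[hi] - delta[lo]
      calls[[length(calls) + 1]] <-
        data.frame(bin = b, strength = strength, score = ns[b])
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(bin = integer(0), strength = numeric(0),
                         score = numeric(0))
  out[out$strength > noise_threshold, , drop = FALSE]
}

#' Compare insulation scores between two region sets
#'
#' Scores each region by the minimum normalized insulation score over the
#' bins it overlaps (boundaries are insulation minima) and compares the two
#' score sets with a Wilcoxon rank-sum test. Used e.g. to ask whether TAD
#' boundaries at S1/S2 compartment borders insulate more strongly than the
#' other TAD boundaries.
#'
#' @param track An `insulation_track`.
#' @param set_a,set_b Region data frames (see [region()]).
#' @param alternative Passed to [stats::wilcox.test()] ("two.sided",
#'   "less", "greater"; "less" asks whether set_a scores are lower, i.e.
#'   stronger insulation).
#' @return List: `statistic`, `p.value`, `scores_a`, `scores_b`.
#' @export
compare_boundary_sets <- function(track, set_a, set_b,
                                  alternative = "two.sided") {
  score_regions <- function(set) {
    vapply(seq_len(nrow(set)), function(k) {
      bins <- bins_in_region(track$binning, set$start[k], set$end[k])
      sc <- track$normalized[bins]
      sc <- sc[!is.na(sc)]
      if (!length(sc)) NA_real_ else min(sc)
    }, 0)
  }
  a <- score_regions(set_a); a <- a[!is.na(a)]
  b <- score_regions(set_b); b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("each region set must map to at least one scored bin")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       scores_a = a, scores_b = b)
}

#' Fraction of compartment borders coinciding with boundaries
#'
#' For each border between adjacent compartment segments, asks whether a
#' boundary region (e.g. a TAD boundary) lies within `slack_bins` bins of
#' it. The analogous published observation is that most S1/S2 borders
#' coincide with TAD boundaries.
#'
#' @param segments A `compartment_segments`.
#' @param boundaries Region data frame of boundary elements.
#' @param slack_bins Matching window in bins (default 1).
#' @return List: `fraction`, `n_borders`, `matches` (data frame of border
#'   bin and matched boundary index, NA when unmatched).
#' @export
border_boundary_overlap <- function(segments, boundaries, slack_bins = 1) {
  seg <- segments$segments
  if (nrow(seg) < 2)
    return(list(fraction = NA_real_, n_borders = 0L,
                matches = data.frame(border_bin = integer(0),
                                     boundary = integer(0))))
  border_bins <- seg$start_bin[-1]
  bbins <- lapply(seq_len(nrow(boundaries)), function(k)
    bins_in_region(segments$binning, boundaries$start[k], boundaries$end[k]))
  match_idx <- vapply(border_bins, function(b) {
    hit <- which(vapply(bbins, function(bb)
      length(bb) && min(abs(bb - b)) <= slack_bins, TRUE))
    if (length(hit)) hit[1] else NA_integer_
  }, 1L)
  list(fraction = mean(!is.na(match_idx)),
       n_borders = length(border_bins),
       matches = data.frame(border_bin = border_bins, boundary = match_idx))
}
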