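#' Cumulative integral of a coverage track
#'
#' Returns a vectorized function `I(x)` giving the integral of the
#' piecewise-constant signal over `[0, x)`; uncovered bases contribute 0.
#' Backbone of window smoothing, scaling, densities, and binning.
#'
#' @param track A [coverage_track()].
#' @return Function of a numeric vector of positions.
#' @export
track_integral <- function(track) {
  s <- track$start; e <- track$end; v <- track$value
  cum0 <- c(0, cumsum(v * (e - s)))
  function(x) {
    i <- findInterval(x, s)
    out <- numeric(length(x))
    pos <- i > 0
    ii <- i[pos]
    out[pos] <- cum0[ii] + v[ii] * pmax(0, pmin(x[pos], e[ii]) - s[ii])
    out
  }
}

#' Signal value at positions
#' @param track A [coverage_track()].
#' @param x 0-based positions.
#' @export
track_value_at <- function(track, x) {
  i <- findInterval(x, track$start)
  out <- numeric(length(x))
  pos <- i > 0 & x < track$end[pmax(i, 1)]
  out[pos] <- track$value[i[pos]]
  out
}

#' Sliding-window smoothing of a coverage track
#'
#' Mean signal in windows of `window_bp` centered every `step_bp`
#' (the CHART/ChIP convention of 1-kb windows recorded every 500 bp).
#' Bases beyond the chromosome/track extent count as 0 within a window.
#'
#' @param track A [coverage_track()].
#' @param window_bp Window width (>= step).
#' @param step_bp Recording step.
#' @param extent_bp Extent to cover (default: end of last interval).
#' @return A smoothed [coverage_track()] piecewise-constant at `step_bp`.
#' @export
smooth_windows <- function(track, window_bp = 1000, step_bp = 500,
                           extent_bp = NULL) {
  if (window_bp < step_bp) stop("window must be >= step")
  if (is.null(extent_bp))
    extent_bp <- if (nrow(track)) max(track$end) else 0
  if (extent_bp <= 0) return(coverage_track(attr(track, "chrom")))
  I <- track_integral(track)
  k <- seq_len(ceiling(extent_bp / step_bp)) - 1
  centers <- (k + 0.5) * step_bp
  vals <- (I(centers + window_bp / 2) - I(pmax(centers - window_bp / 2, 0))) /
    window_bp
  coverage_track(attr(track, "chrom"), k * step_bp, (k + 1) * step_bp, vals,
                 norm = attr(track, "norm"))
}

#' Fragments-per-million normalization
#'
#' Scales a track so its total signal mass equals 1e6 (per-million
#' convention for coverage made from read counts).
#'
#' @param track A [coverage_track()].
#' @export
fpm_normalize <- function(track) {
  I <- track_integral(track)
  total <- I(max(track$end))
  if (total <= 0) stop("cannot fpm-normalize a track with zero mass")
  out <- coverage_track(attr(track, "chrom"), track$start, track$end,
                        track$value * 1e6 / total, norm = "fpm")
  out
}

#' Scale a track to match a reference's signal mass over a region
#'
#' Multiplies `target` by `(integral of reference over region) / (integral
#' of target over region)` — the chromosome-sum equalization used to make
#' Xist coverage comparable between genotypes before computing delta tracks.
#'
#' @param target,reference [coverage_track()]s.
#' @param start,end Region over which sums are equalized (0-based
#'   half-open); defaults to the union extent of both tracks.
#' @return Scaled copy of `target` (norm tag "scaled").
#' @export
scale_to_reference <- function(target, reference, start = 0, end = NULL) {
  if (is.null(end)) end <- max(c(target$end, reference$end, 1))
  It <- track_integral(target)(c(start, end))
  Ir <- track_integral(reference)(c(start, end))
  st <- It[2] - It[1]; sr <- Ir[2] - Ir[1]
  if (st == 0) stop("target has zero signal over the scaling region")
  coverage_track(attr(target, "chrom"), target$start, target$end,
                 target$value * (sr / st), norm = "scaled")
}

#' Pointwise difference of two coverage tracks
#'
#' `a - b` over the union of the two tracks' breakpoints (the delta tracks
#' used to contrast mutant and wild-type Xist / H3K27me3 / H2AK119ub
#' profiles). Adjacent intervals with equal values are merged; zero-valued
#' stretches are kept only inside the covered extent.
#'
#' @param a,b [coverage_track()]s on the same chromosome.
#' @return A [coverage_track()].
#' @export
delta_track <- function(a, b) {
  if (!identical(attr(a, "chrom"), attr(b, "chrom")))
    stop("tracks are on different chromosomes")
  bp <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(bp) < 2) return(coverage_track(attr(a, "chrom")))
  s <- bp[-length(bp)]; e <- bp[-1]
  va <- track_value_at(a, s)
  vb <- track_value_at(b, s)
  v <- va - vb
  # merge adjacent equal-valued intervals (runs are contiguous by construction)
  keep <- c(TRUE, v[-1] != v[-length(v)] | s[-1] != e[-length(e)])
  idx <- which(keep)
  starts <- s[idx]
  ends <- e[c(idx[-1] - 1L, length(e))]
  coverage_track(attr(a, "chrom"), starts, ends, v[idx],
                 norm = "input_subtracted")
}

#' Mean signal density over regions
#'
#' Per-bp mean signal over each region (genic / intergenic density
#' computations).
#'
#' @param track A [coverage_track()].
#' @param regions Region data frame.
#' @return Numeric vector of densities, one per region.
#' @export
region_density <- function(track, regions) {
  I <- track_integral(track)
  (I(regions$end) - I(regions$start)) / (regions$end - regions$start)
}

#' Bin a coverage track
#'
#' Length-weighted mean signal per bin of `binning` (resolution-independent
#' density; bins, not sums).
#'
#' @param track A [coverage_track()].
#' @param binning A [genome_binning()].
#' @return Numeric vector of per-bin values (a binned signal).
#' @export
bin_track <- function(track, binning) {
  I <- track_integral(track)
  i <- seq_len(binning$n_bins)
  (I(bin_end(binning, i)) - I(bin_start(binning, i))) / bin_widths(binning)
}

#' Compare binned densities between S1 and S2 compartments
#'
#' Partitions per-bin values (typically a delta track binned at 200 kb) by
#' compartment sign and runs an unpaired Wilcoxon rank-sum test, with
#' box-plot summaries (median, quartiles, 1.5 IQR whiskers) per compartment.
#' Positive-sign bins are the S1 (Xist-rich) compartment under the package's
#' orientation convention.
#'
#' @param values Numeric per-bin signal.
#' @param labels Per-bin compartment labels ("+" / "-", NA ignored), e.g.
#'   from [segments_to_labels()].
#' @param alternative Sidedness; "greater" asks whether S1 (+) bins exceed
#'   S2 (-) bins.
#' @return List: `statistic`, `p.value`, `s1`, `s2` (values), `box` (summary
#'   data frame); NULL test with a warning when a compartment is empty.
#' @export
s1s2_density_test <- function(values, labels, alternative = "greater") {
  if (length(values) != length(labels))
    stop("values and labels must have equal length")
  ok <- !is.na(values) & !is.na(labels)
  s1 <- values[ok & labels == "+"]
  s2 <- values[ok & labels == "-"]
  if (!length(s1) || !length(s2)) {
    warning("all bins fall in one compartment; test skipped")
    return(list(statistic = NA_real_, p.value = NA_real_, s1 = s1, s2 = s2,
                box = NULL))
  }
  wt <- suppressWarnings(stats::wilcox.test(s1, s2,
                                            alternative = alternative))
  box1 <- grDevices::boxplot.stats(s1)$stats
  box2 <- grDevices::boxplot.stats(s2)$stats
  box <- data.frame(compartment = c("S1", "S2"),
                    lower_whisker = c(box1[1], box2[1]),
                    q1 = c(box1[2], box2[2]),
                    median = c(box1[3], box2[3]),
                    q3 = c(box1[4], box2[4]),
                    upper_whisker = c(box1[5], box2[5]),
                    n = c(length(s1), length(s2)))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       s1 = s1, s2 = s2, box = box)
}

#' Summit-centered metaprofile
#'
#' Average signal in a window of `2 * flank_bp` centered at each summit
#' (e.g. 20-kb regions around H2AK119ub peak summits), sampled at `step_bp`
#' resolution. Summits closer than `flank_bp` to the chromosome start (or
#' `chrom_length_bp` end, when given) are dropped and counted.
#'
#' @param track A [coverage_track()].
#' @param summits Region data frame whose `start` is the summit position.
#' @param flank_bp Half-window (default 10 kb).
#' @param step_bp Sampling step (default 100 bp).
#' @param chrom_length_bp Optional chromosome length for right-edge drops.
#' @return List: `profile` (summits x positions matrix), `mean_curve`,
#'   `positions` (window-relative bp, centers of steps), `n_dropped`.
#' @export
summit_metaprofile <- function(track, summits, flank_bp = 10e3,
                               step_bp = 100, chrom_length_bp = NULL) {
  pos <- summits$start
  drop <- pos < flank_bp
  if (!is.null(chrom_length_bp)) drop <- drop | pos + flank_bp > chrom_length_bp
  n_dropped <- sum(drop)
  pos <- pos[!drop]
  offsets <- seq(-flank_bp, flank_bp - step_bp, by = step_bp)
  I <- track_integral(track)
  prof <- matrix(NA_real_, length(pos), length(offsets))
  for (k in seq_along(pos)) {
    starts <- pos[k] + offsets
    prof[k, ] <- (I(starts + step_bp) - I(starts)) / step_bp
  }
  list(profile = prof,
       mean_curve = if (nrow(prof)) colMeans(prof) else rep(NA_real_, length(offsets)),
       positions = offsets + step_bp / 2,
       n_dropped = n_dropped)
}
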