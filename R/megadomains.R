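#' Inter-megadomain interaction fraction
#'
#' The fraction of long-range chromatin interactions (bin-pair distance
#' greater than `span_threshold_bp`, by default 10 Mb, roughly twice the
#' largest X-linked TAD) that span the Dxz4 megadomain boundary (73 Mb on
#' mm9 by default). Computed on depth-corrected raw-count maps at 200-kb
#' resolution; depth-matching between samples is the caller's
#' responsibility (see [downsample()]).
#'
#' A pair (i < j) is long-range iff `(j - i) * bin_size > span_threshold_bp`
#' and crossing iff `bin_start(i) < boundary_bp <= bin_start(j)` — the bin
#' containing the boundary belongs to the proximal side, the first bin
#' starting at or beyond the boundary to the distal (telomeric) side.
#' By default counts are contact-weighted sums; `weighted = FALSE` counts
#' distinct bin pairs instead.
#'
#' @param m A [contact_matrix()].
#' @param boundary_bp Megadomain boundary position (default 73e6, mm9 Dxz4).
#' @param span_threshold_bp Minimum pair span (default 10e6).
#' @param weighted Contact-weighted (default) or pair-counted.
#' @return A `megadomain_stat`: `n_long_range`, `n_crossing`, `fraction`.
#' @export
inter_megadomain_fraction <- function(m, boundary_bp = 73e6,
                                      span_threshold_bp = 10e6,
                                      weighted = TRUE) {
  b <- m$binning
  if (boundary_bp <= 0 || boundary_bp >= b$chrom_length_bp)
    stop("megadomain boundary outside chromosome")
  n <- b$n_bins
  v <- m$values
  un <- !m$mask
  ii <- row(v); jj <- col(v)
  starts_i <- bin_start(b, ii); starts_j <- bin_start(b, jj)
  longr <- jj > ii & (jj - ii) * b$bin_size_bp > span_threshold_bp &
    outer(un, un) & !is.na(v)
  crossing <- longr & starts_i < boundary_bp & starts_j >= boundary_bp
  wt <- if (weighted) v else (v != 0) * 1
  n_long <- sum(wt[longr], na.rm = TRUE)
  n_cross <- sum(wt[crossing], na.rm = TRUE)
  frac <- if (n_long > 0) n_cross / n_long else {
    warning("no long-range contacts; fraction is NA")
    NA_real_
  }
  structure(list(boundary_bp = boundary_bp,
                 span_threshold_bp = span_threshold_bp,
                 weighted = weighted,
                 n_long_range = n_long, n_crossing = n_cross,
                 fraction = frac),
            class = "megadomain_stat")
}

#' @export
print.megadomain_stat <- function(x, ...) {
  cat(sprintf(
    "<megadomain_stat> boundary %.1f Mb, span > %.0f Mb: %.2f%% inter-megadomain\n",
    x$boundary_bp / 1e6, x$span_threshold_bp / 1e6, 100 * x$fraction))
  invisible(x)
}

#' Compare inter-megadomain fractions between two groups of replicates
#'
#' Welch unpaired t test on the replicate-level fractions, with per-group
#' mean and standard deviation (the published comparisons are one-sided,
#' unpaired t tests on two replicates per condition, shown as mean +/- s.d.
#' bar plots).
#'
#' @param group_a,group_b Lists of `megadomain_stat` (or numeric fractions).
#' @param alternative "two.sided", "less", or "greater" (direction of
#'   group_a relative to group_b).
#' @return List: `t`, `p.value`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_fractions <- function(group_a, group_b, alternative = "two.sided") {
  as_frac <- function(g) {
    if (is.numeric(g)) g
    else vapply(g, function(s) s$fraction, 0)
  }
  a <- as_frac(group_a); b <- as_frac(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per group")
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b))
}
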