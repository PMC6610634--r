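# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain double loops, sharing no code with the
# package internals they check.

make_binning <- function(n, bin = 1e5, chrom = "chrT")
  genome_binning(chrom, n * bin, bin)

random_symmetric <- function(n, lo = 0.5, hi = 5) {
  v <- matrix(stats::runif(n * n, lo, hi), n)
  (v + t(v)) / 2
}

# textbook ICE: explicit bias vector iteration
bf_ice <- function(v, n_iter = 400) {
  target <- mean(v)
  b <- rep(1, nrow(v))
  for (it in seq_len(n_iter)) {
    w <- v / outer(b, b)
    s <- rowSums(w)
    b <- b * (s / mean(s))
  }
  w <- v / outer(b, b)
  w * target / mean(w)
}

# per-diagonal O/E by explicit loops
bf_oe <- function(v) {
  n <- nrow(v)
  out <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d)) vals <- c(vals, v[i, i + d])
    e <- mean(vals, na.rm = TRUE)
    for (i in 1:(n - d)) {
      out[i, i + d] <- if (!is.na(e) && e > 0) v[i, i + d] / e else NA
      out[i + d, i] <- out[i, i + d]
    }
  }
  out
}

# pairwise Pearson with self-column exclusion, by loops
bf_pearson <- function(v, mask) {
  n <- nrow(v)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (mask[i] || mask[j]) next
    if (i == j) { out[i, j] <- 1; next }
    cols <- setdiff(which(!mask), c(i, j))
    x <- v[i, cols]; y <- v[j, cols]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      out[i, j] <- stats::cor(x[ok], y[ok])
  }
  out
}

# insulation raw/normalized scores by explicit double loop
bf_insulation <- function(v, mask, bin_size, square_bp = 500e3) {
  n <- nrow(v)
  w <- round(square_bp / bin_size)
  raw <- rep(NA_real_, n)
  for (i in 1:n) {
    if (i - w < 1 || i + w > n || mask[i]) next
    vals <- c(); n_ok <- 0; n_tot <- 0
    for (r in (i - w):(i - 1)) for (cc in (i + 1):(i + w)) {
      n_tot <- n_tot + 1
      if (!mask[r] && !mask[cc]) {
        n_ok <- n_ok + 1
        if (!is.na(v[r, cc])) vals <- c(vals, v[r, cc])
      }
    }
    if (n_ok / n_tot > 0.5 && length(vals) > 0 && mean(vals) > 0)
      raw[i] <- mean(vals)
  }
  q <- stats::quantile(raw, c(0.25, 0.75), na.rm = TRUE)
  im <- mean(raw[!is.na(raw) & raw >= q[1] & raw <= q[2]])
  list(raw = raw, normalized = log2(raw / im))
}

# delta vector + boundary bins by loops (same definitions, independent code)
bf_boundaries <- function(normalized, delta_bp, bin_size) {
  n <- length(normalized)
  d <- round(delta_bp / bin_size)
  delta <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    rs <- c(); ls <- c()
    for (k in 1:d) {
      if (i + k <= n && !is.na(normalized[i + k])) rs <- c(rs, normalized[i + k])
      if (i - k >= 1 && !is.na(normalized[i - k])) ls <- c(ls, normalized[i - k])
    }
    if (length(rs) && length(ls)) delta[i] <- mean(rs) - mean(ls)
  }
  bins <- c(); strengths <- c()
  for (i in 1:(n - 1)) {
    if (is.na(delta[i]) || is.na(delta[i + 1])) next
    if (delta[i] < 0 && delta[i + 1] >= 0) {
      sc <- normalized[c(i, i + 1)]
      sc[is.na(sc)] <- Inf
      bins <- c(bins, c(i, i + 1)[which.min(sc)])
      lo <- i
      while (lo - 1 >= 1 && !is.na(delta[lo - 1]) && delta[lo - 1] <= delta[lo])
        lo <- lo - 1
      hi <- i + 1
      while (hi + 1 <= n && !is.na(delta[hi + 1]) && delta[hi + 1] >= delta[hi])
        hi <- hi + 1
      strengths <- c(strengths, delta[hi] - delta[lo])
    }
  }
  list(delta = delta, bins = bins, strengths = strengths)
}

# exhaustive O(n^2) inter-megadomain counting
bf_megadomain <- function(v, mask, bin_size, boundary_bp, span_bp,
                          weighted = TRUE) {
  n <- nrow(v)
  n_long <- 0; n_cross <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (mask[i] || mask[j] || is.na(v[i, j])) next
    if ((j - i) * bin_size <= span_bp) next
    wt <- if (weighted) v[i, j] else as.numeric(v[i, j] != 0)
    n_long <- n_long + wt
    si <- (i - 1) * bin_size; sj <- (j - 1) * bin_size
    if (si < boundary_bp && sj >= boundary_bp) n_cross <- n_cross + wt
  }
  n_cross / n_long
}

# hand-applied classification cascade on a small table (per-gene loops)
bf_cascade <- function(table, control, baseline_condition = "WT_DMSO") {
  genes <- sort(unique(table$gene_id))
  out <- character(length(genes))
  for (k in seq_along(genes)) {
    g <- table[table$gene_id == genes[k], ]
    ctl <- control[control$gene_id == genes[k], ]
    if (any(g$fpkm <= 0)) { out[k] <- "excluded"; next }
    if (any(g$mus_reads + g$cas_reads < 13)) { out[k] <- "excluded"; next }
    ctl_pm <- 100 * ctl$mus_reads / (ctl$mus_reads + ctl$cas_reads)
    if (any(!is.na(ctl_pm) & ctl_pm > 9.09)) { out[k] <- "excluded"; next }
    wt <- g[g$condition == baseline_condition, ]
    esc <- any(wt$mus_reads / wt$cas_reads > 0.1, na.rm = TRUE)
    out[k] <- if (esc) "escapee" else "subject_to_XCI"
  }
  stats::setNames(out, genes)
}
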