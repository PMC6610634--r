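#' Mask low-coverage bins
#'
#' Marks as unmappable the bins whose raw marginal (row sum) falls in the
#' bottom `quantile` of bins, mirroring the practice of excluding the bottom
#' ~14% of bins by read coverage before iterative correction. Exactly
#' `ceiling(quantile * n_bins)` lowest-marginal bins are masked (ties broken
#' by lower bin index); all-zero bins are always masked. Idempotent: values
#' are left in place, only the mask is set.
#'
#' @param m A [contact_matrix()] (unbalanced).
#' @param quantile Fraction of bins to mask, in `[0, 1)`. Default 0.14.
#' @return The matrix with its mask updated.
#' @export
mask_low_coverage <- function(m, quantile = 0.14) {
  if (quantile < 0 || quantile >= 1) stop("quantile must be in [0, 1)")
  if (m$balanced) stop("mask_low_coverage expects an unbalanced matrix")
  marg <- rowSums(m$values, na.rm = TRUE)
  n <- m$binning$n_bins
  k <- ceiling(quantile * n - 1e-9)  # guard FP noise in quantile * n
  mask <- m$mask | marg == 0
  if (k > 0) {
    ord <- order(marg, seq_len(n))  # ties broken by lower index
    mask[ord[seq_len(k)]] <- TRUE
  }
  m$mask <- mask
  m
}

#' Down-sample a contact matrix to a target depth
#'
#' Samples individual contacts without replacement (jointly multivariate
#' hypergeometric over cells), so that the total contact count equals
#' `target_total` exactly. Used to match sequencing depth between samples
#' before comparing Pearson maps or megadomain statistics.
#'
#' @param m A [contact_matrix()] with integer counts.
#' @param target_total Desired total (<= current total).
#' @param seed RNG seed (required for reproducibility).
#' @return The down-sampled matrix; `metadata$downsample_seed` records the
#'   seed.
#' @export
downsample <- function(m, target_total, seed) {
  v <- m$values
  ut <- upper.tri(v, diag = TRUE)
  cnt <- v[ut]
  if (any(cnt != round(cnt), na.rm = TRUE))
    stop("downsample requires integer counts")
  cnt[is.na(cnt)] <- 0
  total <- sum(cnt)
  if (target_total > total) stop("target_total exceeds current total")
  if (target_total == total) return(m)
  new_cnt <- numeric(length(cnt))
  if (target_total > 0) {
    nz <- which(cnt > 0)
    cum <- cumsum(cnt[nz])
    picks <- withr::with_seed(seed, sort(sample.int(total, target_total)))
    cell <- findInterval(picks - 1, cum) + 1L  # which nonzero cell
    tb <- tabulate(cell, nbins = length(nz))
    new_cnt[nz] <- tb
  }
  out <- matrix(0, nrow(v), ncol(v))
  out[ut] <- new_cnt
  out <- out + t(out) - diag(diag(out), nrow(v))
  m$values <- out
  m$metadata$downsample_seed <- seed
  m$metadata$downsample_target <- target_total
  m
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Classic Imakaev-style bias iteration: bin biases are updated from the
#' current marginals until the coefficient of variation of the unmasked
#' marginals falls below `tol`. The result is rescaled so that the mean of
#' the unmasked entries is unchanged. Masked rows/columns are set to `NA`.
#'
#' @param m A masked [contact_matrix()].
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the marginal CV (default 1e-6).
#' @return Balanced matrix; `metadata$ice_iterations` holds the iteration
#'   count and `metadata$ice_converged` the convergence flag. Non-convergence
#'   raises a warning.
#' @export
ice_balance <- function(m, max_iter = 200, tol = 1e-6) {
  un <- !m$mask
  if (!any(un)) stop("all bins are masked; cannot balance")
  W <- m$values[un, un, drop = FALSE]
  W[is.na(W)] <- 0
  target_mean <- mean(W)
  b <- rep(1, nrow(W))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(W)
    if (all(s == 0)) stop("balancing degenerate: all unmasked rows are zero")
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0  # single unmasked bin
    if (cv < tol) { converged <- TRUE; break }
    ds <- s / mean(s)
    ds[ds == 0] <- 1
    b <- b * ds
    W <- W / outer(ds, ds)
  }
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations (CV = %.3g)",
                    max_iter, stats::sd(rowSums(W)) / mean(rowSums(W))))
  W <- W * (target_mean / mean(W))
  out <- matrix(NA_real_, m$binning$n_bins, m$binning$n_bins)
  out[un, un] <- W
  m$values <- out
  m$balanced <- TRUE
  m$metadata$ice_iterations <- iter
  m$metadata$ice_converged <- converged
  m$metadata$ice_bias <- b
  m
}

#' Observed/expected normalization
#'
#' Divides each entry by the mean of its diagonal (same genomic distance)
#' computed over unmasked pairs, removing the distance-decay signal so the
#' compartment checkerboard becomes visible. Diagonals with expected 0 give
#' `NA`.
#'
#' @param m A balanced [contact_matrix()].
#' @return O/E matrix (`metadata$oe = TRUE`).
#' @export
observed_over_expected <- function(m) {
  n <- m$binning$n_bins
  un <- !m$mask
  v <- m$values
  d <- abs(row(v) - col(v))
  ok <- outer(un, un) & !is.na(v)
  sums <- rowsum(ifelse(ok, v, 0)[TRUE], d[TRUE], reorder = TRUE)
  cnts <- rowsum(as.numeric(ok)[TRUE], d[TRUE], reorder = TRUE)
  expd <- rep(NA_real_, n)
  dd <- as.integer(rownames(sums)) + 1L
  expd[dd] <- ifelse(cnts > 0, sums / cnts, NA_real_)
  E <- matrix(expd[d + 1L], n, n)
  oe <- ifelse(ok & !is.na(E) & E > 0, v / E, NA_real_)
  oe[!outer(un, un)] <- NA_real_
  m$values <- oe
  m$metadata$oe <- TRUE
  m
}

#' Pearson correlation map
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the O/E
#' matrix, computed pairwise-complete over unmasked columns and excluding
#' columns i and j themselves (so the self-contact and the i-j contact do
#' not inflate the correlation). Pairs with fewer than 3 complete columns or
#' zero variance give `NA`. Implemented with BLAS-level sufficient
#' statistics after row-centering (Pearson is shift-invariant), so full
#' chromosomes at 100-kb bins are handled in seconds.
#'
#' @param oe An observed/expected [contact_matrix()].
#' @return A `correlation_map` (values in `[-1, 1]`, `NA` at masked bins,
#'   diagonal 1 for unmasked bins).
#' @export
pearson_map <- function(oe) {
  n <- oe$binning$n_bins
  un <- !oe$mask
  A <- oe$values
  V <- matrix(0, n, n)
  V[un, un] <- 1
  V[is.na(A)] <- 0
  X <- ifelse(V == 1, A, 0)
  # center rows by their valid-entry means (shift-invariance of Pearson)
  rn <- rowSums(V)
  rmean <- ifelse(rn > 0, rowSums(X) / rn, 0)
  X <- (X - rmean) * V
  dV <- diag(V); dX <- diag(X)
  tX <- t(X); tV <- t(V)
  N <- tcrossprod(V)
  Sx <- tcrossprod(X, V)
  Sxx <- tcrossprod(X * X, V)
  Sxy <- tcrossprod(X)
  Sy <- t(Sx); Syy <- t(Sxx)
  # remove the two self-columns i and j from each pair's sums
  W1 <- dV * tV                 # W1[i,j] = V[i,i] * V[j,i]
  W2 <- t(t(V) * dV)            # W2[i,j] = V[i,j] * V[j,j]
  Np <- N - W1 - W2
  Sxp <- Sx - dX * W1 - X * W2
  Syp <- Sy - tX * W1 - t(t(W2) * dX)
  Sxxp <- Sxx - dX^2 * W1 - X^2 * W2
  Syyp <- Syy - tX^2 * W1 - t(t(W2) * dX^2)
  Sxyp <- Sxy - dX * (tX * W1) - t(t(X * W2) * dX)
  num <- Np * Sxyp - Sxp * Syp
  vx <- Np * Sxxp - Sxp^2
  vy <- Np * Syyp - Syp^2
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  scale2 <- pmax(abs(vx), abs(vy), 1)
  r <- ifelse(Np >= 3 & vx > 1e-12 * scale2 & vy > 1e-12 * scale2,
              num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  r[!un, ] <- NA_real_
  r[, !un] <- NA_real_
  diag(r)[un] <- 1
  structure(list(values = r, binning = oe$binning, mask = oe$mask,
                 metadata = oe$metadata),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %s: %d bins, %d masked\n",
              x$binning$chrom, x$binning$n_bins, sum(x$mask)))
  invisible(x)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts within blocks of `factor` consecutive bins, e.g. to go from
#' 100-kb bins (compartment calling, insulation) to 200-kb bins (Pearson
#' maps, megadomain statistic). A coarse bin is masked when more than half
#' of its constituent fine bins are masked.
#'
#' @param m A raw-count [contact_matrix()].
#' @param factor Integer aggregation factor (>= 2).
#' @return A `contact_matrix` at `bin_size * factor`.
#' @export
coarsen_matrix <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 2)
  if (m$balanced) stop("coarsen raw counts, not balanced matrices")
  n <- m$binning$n_bins
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  ng <- max(grp)
  G <- matrix(0, n, ng)
  G[cbind(seq_len(n), grp)] <- 1
  vals <- t(G) %*% ifelse(is.na(m$values), 0, m$values) %*% G
  # block sums count each within-block off-diagonal pair twice; restore the
  # once-per-pair convention on the coarse diagonal
  fine_diag <- as.vector(tapply(diag(m$values), grp, sum))
  diag(vals) <- (diag(vals) + fine_diag) / 2
  mask <- as.vector(tapply(m$mask, grp, function(z) mean(z) > 0.5))
  bin2 <- genome_binning(m$binning$chrom, m$binning$chrom_length_bp,
                         m$binning$bin_size_bp * factor)
  contact_matrix(vals, bin2, allele = m$allele, mask = mask,
                 metadata = m$metadata)
}
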