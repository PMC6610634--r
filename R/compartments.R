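#' Eigenvector compartment analysis
#'
#' PC1 and PC2 are the leading eigenvectors of the Pearson correlation map
#' restricted to unmasked bins. On the active X (and autosomes) PC1 tracks
#' the A/B checkerboard; on the SMCHD1-deficient Xi it tracks the S1/S2
#' compartments while PC2 captures the two megadomains (which PC captures
#' which structure is sample-dependent and is not automated here: both PCs
#' are returned with their reference correlations and callers select, see
#' [select_pc()]).
#'
#' Each PC's sign is fixed so its Pearson correlation with `reference`
#' (an S1/A-like binned track, e.g. Xist or H3K27me3 density) is >= 0; by
#' that convention positive PC values mark the Xist-rich S1 (or active A)
#' compartment.
#'
#' @param corr A `correlation_map` from [pearson_map()].
#' @param reference Numeric per-bin signal used to orient signs (NA allowed).
#' @param reference_name Label recorded in the profile.
#' @return A `compartment_profile`: `pc1`, `pc2` (NA at masked bins, unit
#'   norm over unmasked bins), `explained_variance`, `reference_correlation`.
#' @export
compute_compartments <- function(corr, reference,
                                 reference_name = deparse(substitute(reference))) {
  n <- corr$binning$n_bins
  un <- !corr$mask & apply(corr$values, 1, function(z) any(!is.na(z)))
  if (sum(un) < 10) stop("need at least 10 unmasked bins for PCA")
  if (length(reference) != n) stop("reference length must equal n_bins")
  if (all(is.na(reference[un]))) stop("reference is all-NA on unmasked bins")
  C <- corr$values[un, un, drop = FALSE]
  C[is.na(C)] <- 0
  diag(C) <- 1
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  expl <- e$values[1:2] / sum(ev)
  pcs <- matrix(NA_real_, n, 2)
  pcs[un, ] <- e$vectors[, 1:2]
  refcor <- numeric(2)
  for (k in 1:2) {
    ok <- !is.na(pcs[, k]) & !is.na(reference)
    r <- suppressWarnings(stats::cor(pcs[ok, k], reference[ok]))
    if (is.na(r)) r <- 0
    if (r < 0) { pcs[, k] <- -pcs[, k]; r <- -r }
    if (r < 0.05)
      warning(sprintf("PC%d orientation unreliable (|r| = %.3f with reference)",
                      k, r))
    refcor[k] <- r
  }
  structure(list(binning = corr$binning, pc1 = pcs[, 1], pc2 = pcs[, 2],
                 mask = !un,
                 explained_variance = stats::setNames(expl, c("pc1", "pc2")),
                 reference_correlation = stats::setNames(refcor, c("pc1", "pc2")),
                 orientation_reference = reference_name),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf(
    "<compartment_profile> %s: %d bins; PC1 %.1f%% var (r_ref = %.2f), PC2 %.1f%% (r_ref = %.2f)\n",
    x$binning$chrom, x$binning$n_bins,
    100 * x$explained_variance[1], x$reference_correlation[1],
    100 * x$explained_variance[2], x$reference_correlation[2]))
  invisible(x)
}

#' Select the PC that tracks a structure of interest
#'
#' Returns "pc1" or "pc2", whichever correlates more strongly (in absolute
#' value) with the orientation reference.
#'
#' @param profile A `compartment_profile`.
#' @export
select_pc <- function(profile) {
  names(which.max(abs(profile$reference_correlation)))
}

#' Permutation null for PC1 explained variance
#'
#' Tests whether a chromosome has any compartment structure. The raw contact
#' matrix is permuted within each diagonal (preserving the distance-decay
#' profile and marginal noise while destroying positional coherence) and the
#' full pipeline — iterative correction, observed/expected, Pearson map,
#' eigendecomposition — is re-run on each permutation, so the null band
#' carries the same balancing noise as the observed value (ICE on a noisy
#' matrix alone inflates PC1 slightly; running it inside the null accounts
#' for that). On a compartment-less chromosome (the WT Xi) the observed PC1
#' explained variance falls inside the permutation band.
#'
#' @param m A masked, unbalanced [contact_matrix()].
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return List: `observed`, `null` (vector of length `n_perm`),
#'   `p.value` (upper-tail, with the +1 correction).
#' @export
pc1_variance_null <- function(m, n_perm = 100, seed = 1) {
  if (m$balanced) stop("pc1_variance_null expects the raw masked matrix")
  ev1 <- function(mm) {
    pm <- pearson_map(observed_over_expected(
      suppressWarnings(ice_balance(mm))))
    un <- !pm$mask & apply(pm$values, 1, function(z) any(!is.na(z)))
    C <- pm$values[un, un, drop = FALSE]
    C[is.na(C)] <- 0
    diag(C) <- 1
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ev[1] / sum(pmax(ev, 0))
  }
  observed <- ev1(m)
  n <- m$binning$n_bins
  v <- m$values
  un <- !m$mask
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- v
    for (d in seq_len(n - 1)) {
      ii <- seq_len(n - d)
      idx <- cbind(ii, ii + d)
      vals <- v[idx]
      ok <- !is.na(vals) & un[idx[, 1]] & un[idx[, 2]]
      if (sum(ok) > 1) vals[ok] <- sample(vals[ok])
      p[idx] <- vals
      p[idx[, 2:1, drop = FALSE]] <- vals
    }
    pm2 <- m
    pm2$values <- p
    ev1(pm2)
  }, 0))
  list(observed = observed, null = null,
       p.value = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' Call compartment segments from PC sign runs
#'
#' Segments are maximal runs of constant PC sign over unmasked bins.
#' Interior masked bins do not break a run when the flanking signs agree;
#' when they disagree, the boundary is placed at the midpoint of the masked
#' gap. Runs shorter than `min_run_bins` are merged into the longer
#' neighbouring run (so single-bin noise flips do not inflate the
#' compartment count).
#'
#' @param profile A `compartment_profile` (typically at 100-kb bins).
#' @param which "pc1" or "pc2".
#' @param min_run_bins Minimum run length kept as its own segment.
#' @return A `compartment_segments` object: data frame of
#'   (start_bin, end_bin, sign) plus `n_compartments` and `mean_size_bp`.
#' @export
call_segments <- function(profile, which = c("pc1", "pc2"), min_run_bins = 3) {
  which <- match.arg(which)
  pc <- profile[[which]]
  n <- length(pc)
  s <- ifelse(is.na(pc), NA, ifelse(pc >= 0, 1L, -1L))
  scored <- which(!is.na(s))
  if (!length(scored)) {
    return(structure(list(segments = data.frame(start_bin = integer(0),
                                                end_bin = integer(0),
                                                sign = character(0)),
                          n_compartments = 0L, mean_size_bp = NA_real_,
                          binning = profile$binning, which = which),
                     class = "compartment_segments"))
  }
  lo <- min(scored); hi <- max(scored)
  s <- s[lo:hi]
  # bridge interior NA gaps
  nas <- is.na(s)
  if (any(nas)) {
    r <- rle(nas)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      left <- s[a - 1L]; right <- s[b + 1L]
      if (left == right) s[a:b] <- left
      else {
        mid <- a + (b - a) %/% 2L
        if (a <= mid) s[a:mid] <- left
        if (mid + 1L <= b) s[(mid + 1L):b] <- right
      }
    }
  }
  # merge short runs into the longer neighbour, shortest first
  repeat {
    r <- rle(s)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run_bins)
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
    right_len <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
    take <- if (left_len >= right_len) r$values[k - 1L] else r$values[k + 1L]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    s[starts[k]:ends[k]] <- take
  }
  r <- rle(s)
  ends <- cumsum(r$lengths) + lo - 1L
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_bin = starts, end_bin = ends,
                    sign = ifelse(r$values > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  sizes <- bin_end(profile$binning, seg$end_bin) -
    bin_start(profile$binning, seg$start_bin)
  structure(list(segments = seg, n_compartments = nrow(seg),
                 mean_size_bp = mean(sizes), binning = profile$binning,
                 which = which),
            class = "compartment_segments")
}

#' @export
print.compartment_segments <- function(x, ...) {
  cat(sprintf("<compartment_segments> %d segments (%s), mean size %.2f Mb\n",
              x$n_compartments, x$which, x$mean_size_bp / 1e6))
  invisible(x)
}

#' Per-bin compartment labels from segments
#'
#' Projects segment signs onto an arbitrary binning (bin midpoints decide
#' membership), e.g. 100-kb segments onto the 200-kb bins used for density
#' comparisons.
#'
#' @param segments A `compartment_segments`.
#' @param binning Target [genome_binning()] (default: the segments' own).
#' @return Character vector per target bin: "+", "-", or NA outside segments.
#' @export
segments_to_labels <- function(segments, binning = segments$binning) {
  out <- rep(NA_character_, binning$n_bins)
  mids <- (bin_start(binning, seq_len(binning$n_bins)) +
             bin_end(binning, seq_len(binning$n_bins))) / 2
  src <- segments$binning
  for (k in seq_len(nrow(segments$segments))) {
    seg <- segments$segments[k, ]
    a <- bin_start(src, seg$start_bin)
    b <- bin_end(src, seg$end_bin)
    out[mids >= a & mids < b] <- seg$sign
  }
  out
}

#' Correlate a compartment profile with a binned feature
#'
#' Pearson correlation between a PC and a binned chromatin feature (Xist,
#' H3K27me3, H2AK119ub density...), over bins unmasked in both.
#'
#' @param profile A `compartment_profile`.
#' @param feature Numeric per-bin signal.
#' @param which "pc1" or "pc2".
#' @return List with `r` and `n` (bins used).
#' @export
correlate_with_feature <- function(profile, feature, which = "pc1") {
  pc <- profile[[which]]
  if (length(feature) != length(pc))
    stop("feature binning does not match profile")
  ok <- !is.na(pc) & !is.na(feature)
  list(r = stats::cor(pc[ok], feature[ok]), n = sum(ok))
}

#' Hierarchical clustering of compartment profiles
#'
#' Agglomerative clustering of PC profiles across samples, with Euclidean or
#' Pearson-correlation distance; bins that are NA in any profile are dropped
#' listwise.
#'
#' @param profiles Named list of `compartment_profile`s on a shared binning.
#' @param distance "euclidean" or "pearson" (1 - r).
#' @param linkage Passed to [stats::hclust()] (default "complete").
#' @param which "pc1" or "pc2".
#' @return An `hclust` tree.
#' @export
cluster_profiles <- function(profiles, distance = c("euclidean", "pearson"),
                             linkage = "complete", which = "pc1") {
  distance <- match.arg(distance)
  if (length(profiles) < 2) stop("need at least 2 profiles")
  M <- do.call(rbind, lapply(profiles, `[[`, which))
  if (is.null(rownames(M))) rownames(M) <- names(profiles)
  keep <- colSums(is.na(M)) == 0
  M <- M[, keep, drop = FALSE]
  d <- if (distance == "euclidean") stats::dist(M)
       else stats::as.dist(1 - stats::cor(t(M)))
  stats::hclust(d, method = linkage)
}
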