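#' Ground-truth Xi architecture for simulation
#'
#' Defines the planted chromosome architecture for one of four regimes of
#' the inactive/active X:
#' \describe{
#'   \item{WT_Xi}{compartment-less: no S1/S2 contrast (epsilon = 0),
#'     megadomains partially obscured (delta = 0.2);}
#'   \item{SMCHD1_KO}{re-emergent S1/S2 compartments (epsilon = 0.4) on top
#'     of megadomains (delta = 0.2);}
#'   \item{XIST_KO}{de-compartmentalized with sharpened megadomains
#'     (epsilon = 0, delta = 0.6);}
#'   \item{Xa}{A/B checkerboard, no megadomains (epsilon = 0.4,
#'     delta = 0).}
#' }
#' Compartment labels form `n_segments` contiguous alternating runs whose
#' lengths are drawn with uniform 10-40 relative weights and rescaled to
#' tile the chromosome; a 166-Mb chromosome with 25 segments mimics the
#' scale of the re-emergent S1/S2 compartments. A fraction of bins
#' (default 14%, matching the bottom-coverage mask) is unmappable; the two
#' bins flanking the megadomain boundary are never masked so the megadomain
#' statistic stays well-defined.
#'
#' @param chrom_length_bp Chromosome length (default 166 Mb, ~ mm9 chrX).
#' @param bin_size_bp Bin size (default 100 kb, the calling resolution).
#' @param regime One of "WT_Xi", "SMCHD1_KO", "XIST_KO", "Xa".
#' @param n_segments Planted compartment count (default 25).
#' @param megadomain_boundary_bp Default 73e6 (Dxz4, mm9).
#' @param decay_exponent Distance-decay exponent (default 1).
#' @param compartment_strength epsilon >= 0; same-compartment pairs get
#'   mean x (1 + epsilon). Default set by regime.
#' @param megadomain_strength delta in [0, 1]; boundary-crossing pairs get
#'   mean x (1 - delta). Default set by regime.
#' @param unmappable_fraction Fraction of bins masked (default 0.14).
#' @param read_depth Expected total contacts (default 5e6).
#' @param seed RNG seed (identical seed => identical truth and simulations).
#' @return An `architecture_truth` object.
#' @export
architecture_truth <- function(chrom_length_bp = 166e6, bin_size_bp = 100e3,
                               regime = c("SMCHD1_KO", "WT_Xi", "XIST_KO", "Xa"),
                               n_segments = 25,
                               megadomain_boundary_bp = 73e6,
                               decay_exponent = 1,
                               compartment_strength = NULL,
                               megadomain_strength = NULL,
                               unmappable_fraction = 0.14,
                               read_depth = 5e6, seed = 1) {
  regime <- match.arg(regime)
  defaults <- list(WT_Xi = c(eps = 0, delta = 0.2),
                   SMCHD1_KO = c(eps = 0.4, delta = 0.2),
                   XIST_KO = c(eps = 0, delta = 0.6),
                   Xa = c(eps = 0.4, delta = 0))[[regime]]
  eps <- if (is.null(compartment_strength)) defaults[["eps"]]
         else compartment_strength
  delta <- if (is.null(megadomain_strength)) defaults[["delta"]]
           else megadomain_strength
  if (eps < 0) stop("compartment strength must be >= 0")
  if (delta < 0 || delta > 1) stop("megadomain strength must be in [0, 1]")
  if (unmappable_fraction < 0 || unmappable_fraction >= 1)
    stop("unmappable fraction must be in [0, 1)")
  binning <- genome_binning("chrX", chrom_length_bp, bin_size_bp)
  n <- binning$n_bins
  withr::with_seed(seed, {
    w <- stats::runif(n_segments, 10, 40)
    lens <- floor(w / sum(w) * n)
    rem <- n - sum(lens)
    if (rem > 0) {
      extra <- order(w / sum(w) * n - lens, decreasing = TRUE)[seq_len(rem)]
      lens[extra] <- lens[extra] + 1L
    }
    lens <- lens[lens > 0]
    labels <- rep(rep(c("S1", "S2"), length.out = length(lens)), lens)
    boundary_bin <- bin_of(binning, megadomain_boundary_bp - 1)
    protected <- unique(pmin(pmax(c(boundary_bin, boundary_bin + 1L), 1L), n))
    k <- floor(unmappable_fraction * n)
    pool <- setdiff(seq_len(n), protected)
    masked_bins <- sort(sample(pool, min(k, length(pool))))
  })
  mask <- rep(FALSE, n)
  mask[masked_bins] <- TRUE
  structure(list(binning = binning, regime = regime, labels = labels,
                 mask = mask,
                 megadomain_boundary_bp = megadomain_boundary_bp,
                 decay_exponent = decay_exponent,
                 compartment_strength = eps, megadomain_strength = delta,
                 unmappable_fraction = unmappable_fraction,
                 read_depth = read_depth, seed = seed),
            class = "architecture_truth")
}

#' Simulate an allele-tagged contact matrix with planted structure
#'
#' Expected contacts for an unmasked pair (i, j) follow a power-law
#' distance decay in bin units modulated by the planted structure:
#' `mu(i,j) = C * (|i - j| + 1)^(-alpha) * (1 + eps * same_compartment) *
#' (1 - delta * crosses_boundary)`, with `C` chosen so the expected total
#' equals `read_depth` (the classic contact-probability scaling
#' P(s) ~ s^-1 at the analysis bin size). Counts are independent Poisson
#' draws per pair; masked bins are zeroed.
#'
#' @param truth An [architecture_truth()].
#' @param allele Allele tag for the matrix (default "mus", the Xi).
#' @return A [contact_matrix()] with `metadata$truth_regime` etc.
#' @export
simulate_contact_matrix <- function(truth, allele = "mus") {
  b <- truth$binning
  n <- b$n_bins
  if (n < 20) stop("need at least 20 bins")
  same <- outer(truth$labels, truth$labels, "==")
  starts <- bin_start(b, seq_len(n))
  cross <- outer(starts < truth$megadomain_boundary_bp,
                 starts >= truth$megadomain_boundary_bp) |
    outer(starts >= truth$megadomain_boundary_bp,
          starts < truth$megadomain_boundary_bp)
  idx <- seq_len(n)
  d_bins <- abs(outer(idx, idx, "-"))
  mu <- (d_bins + 1)^(-truth$decay_exponent) *
    (1 + truth$compartment_strength * same) *
    (1 - truth$megadomain_strength * cross)
  if (any(mu < 0)) stop("negative expected contacts; check strengths")
  un <- !truth$mask
  ut <- upper.tri(mu, diag = TRUE) & outer(un, un)
  mu_ut <- mu[ut]
  mu_ut <- mu_ut * (truth$read_depth / sum(mu_ut))
  counts <- withr::with_seed(truth$seed + 1L,
                             stats::rpois(length(mu_ut), mu_ut))
  v <- matrix(0, n, n)
  v[ut] <- counts
  v <- v + t(v) - diag(diag(v), n)
  v[truth$mask, ] <- 0
  v[, truth$mask] <- 0
  contact_matrix(v, b, allele = allele, mask = truth$mask,
                 metadata = list(truth_regime = truth$regime,
                                 seed = truth$seed,
                                 read_depth = truth$read_depth))
}

#' Simulate a coverage track following the planted compartments
#'
#' Per-step signal mean is `base * (1 + enrichment_S1)` inside S1 bins and
#' `base` elsewhere, plus Gaussian noise — the synthetic analogue of Xist
#' CHART or H3K27me3/H2AK119ub ChIP coverage, whose densities track the
#' S1/S2 compartments. Rendered as a bedGraph-style track at `step_bp`
#' resolution (default 500 bp). Negative draws are clipped at 0.
#'
#' @param truth An [architecture_truth()].
#' @param enrichment_S1 Relative S1 enrichment (0 = no structure).
#' @param noise_sd Gaussian noise s.d. (same units as `base`).
#' @param base Baseline signal level (default 1).
#' @param step_bp Rendering step (default 500).
#' @param seed RNG seed (default the truth's seed; pass different seeds for
#'   replicate tracks).
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(truth, enrichment_S1 = 0.5, noise_sd = 0.2,
                              base = 1, step_bp = 500, seed = truth$seed) {
  len <- truth$binning$chrom_length_bp
  starts <- seq(0, len - 1, by = step_bp)
  ends <- pmin(starts + step_bp, len)
  bin_idx <- bin_of(truth$binning, starts)
  mean_val <- base * (1 + enrichment_S1 * (truth$labels[bin_idx] == "S1"))
  vals <- withr::with_seed(seed + 2L,
                           stats::rnorm(length(starts), mean_val, noise_sd))
  coverage_track(truth$binning$chrom, starts, ends, pmax(vals, 0))
}

#' Ground-truth allelic expression program
#'
#' Plants per-gene XCI status and reactivation for the 2x2 design
#' (WT/Smchd1-null x DMSO/Aza, two clones per condition):
#' escapees keep `escapee_ratio` Xi/Xa expression everywhere; subject genes
#' are silenced to `silenced_ratio`; a planted subset of subject genes is
#' reactivated (`reactivation_fold` times the silenced ratio) under the
#' combined-perturbation condition `KO_Aza`. Class labels I/II/III are
#' attached to subject genes with reactivated genes enriched in Class I. A
#' fraction of genes is planted as miscalled SNPs: they show spurious mus
#' signal in the pure-cas control samples.
#'
#' @param n_genes Number of genes (default 100).
#' @param prop_escapee,prop_reactivated,prop_miscalled Planted proportions
#'   (defaults 0.1, 0.2, 0.05).
#' @param silenced_ratio Xi/Xa for silenced genes (default 0.01).
#' @param escapee_ratio Xi/Xa for escapees (default 0.3).
#' @param reactivation_fold Multiplier on the silenced ratio under KO_Aza
#'   (default 5).
#' @param condition_effects Named multipliers on the silenced ratio for
#'   subject genes per condition (default: none for WT_DMSO and KO_DMSO is
#'   mild, demethylation alone gives a mild global release, and the
#'   combined perturbation a stronger one; planted reactivated genes get
#'   `reactivation_fold` under KO_Aza instead). Escapees are unaffected by
#'   treatment.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param mean_expression Log-normal location of Xa counts (default 800,
#'   the scale of allele-assignable exonic reads for a mid-expressed gene
#'   in a 50M-read library).
#' @param clones_per_condition Default 2.
#' @param seed RNG seed.
#' @return An `expression_truth` object.
#' @export
expression_truth <- function(n_genes = 100, prop_escapee = 0.1,
                             prop_reactivated = 0.2, prop_miscalled = 0.05,
                             silenced_ratio = 0.01, escapee_ratio = 0.3,
                             reactivation_fold = 5,
                             condition_effects = c(WT_DMSO = 1, WT_Aza = 1.4,
                                                   KO_DMSO = 1.2, KO_Aza = 2),
                             dispersion = 0.1,
                             mean_expression = 800,
                             clones_per_condition = 2, seed = 1) {
  conditions <- c("WT_DMSO", "WT_Aza", "KO_DMSO", "KO_Aza")
  stopifnot(all(conditions %in% names(condition_effects)))
  withr::with_seed(seed, {
    gene_id <- sprintf("gene%03d", seq_len(n_genes))
    gene_length_bp <- round(stats::runif(n_genes, 2e3, 5e4))
    xa_mean <- round(stats::rlnorm(n_genes, log(mean_expression), 0.4))
    xa_mean <- pmax(xa_mean, 50)
    n_esc <- round(prop_escapee * n_genes)
    n_mis <- round(prop_miscalled * n_genes)
    roles <- rep("subject", n_genes)
    idx <- sample.int(n_genes)
    roles[idx[seq_len(n_esc)]] <- "escapee"
    if (n_mis > 0)
      roles[idx[n_esc + seq_len(n_mis)]] <- "miscalled"
    subj <- which(roles == "subject")
    n_rea <- round(prop_reactivated * length(subj))
    reactivated <- rep(FALSE, n_genes)
    reactivated[sample(subj, n_rea)] <- TRUE
    silencing_ratio <- ifelse(roles == "escapee",
                              stats::runif(n_genes, escapee_ratio * 0.8,
                                           escapee_ratio * 1.5),
                              silenced_ratio)
    class_label <- rep(NA_character_, n_genes)
    class_label[subj] <- sample(c("II", "III"), length(subj), replace = TRUE)
    class_label[reactivated] <- "I"
    n_extra_I <- max(0, round(0.2 * length(subj)) - sum(reactivated))
    stable_subj <- setdiff(subj, which(reactivated))
    if (n_extra_I > 0 && length(stable_subj))
      class_label[sample(stable_subj, min(n_extra_I, length(stable_subj)))] <- "I"
  })
  structure(list(gene_id = gene_id, gene_length_bp = gene_length_bp,
                 xa_mean = xa_mean, role = roles,
                 silencing_ratio = silencing_ratio,
                 reactivated = reactivated, class_label = class_label,
                 reactivation_fold = reactivation_fold,
                 condition_effects = condition_effects,
                 dispersion = dispersion, conditions = conditions,
                 clones_per_condition = clones_per_condition, seed = seed),
            class = "expression_truth")
}

# Gamma-Poisson with a per-sample gene-expression factor shared by the two
# alleles: each allele's marginal is NB(mu, dispersion), but the allelic
# ratio carries only the count-limited (binomial-scale) noise, as in real
# allele-specific RNA-seq where biological expression variation moves both
# alleles together.
rcounts_shared <- function(mus_mu, cas_mu, dispersion) {
  n <- length(mus_mu)
  f <- if (dispersion > 0)
    stats::rgamma(n, shape = 1 / dispersion, scale = dispersion)
  else rep(1, n)
  list(mus = stats::rpois(n, pmax(f * mus_mu, 0)),
       cas = stats::rpois(n, pmax(f * cas_mu, 0)))
}

#' Simulate an allele-resolved gene count table
#'
#' Draws cas (Xa) counts from a negative binomial around each gene's Xa
#' mean, and mus (Xi) counts around `Xa mean x silencing ratio x
#' reactivation multiplier` for the sample's condition. FPKM is derived
#' from the counts and gene length assuming a 50M-read library where
#' one third of exonic reads are allele-assignable. `noiseless = TRUE`
#' replaces sampling by rounded means (for exact cascade-recovery checks).
#'
#' @param truth An [expression_truth()].
#' @param noiseless Deterministic counts instead of NB draws.
#' @return List: `table` (the design samples), `control` (two pure-cas
#'   background samples for the miscalled-SNP filter), `truth`.
#' @export
simulate_allelic_counts <- function(truth, noiseless = FALSE) {
  ng <- length(truth$gene_id)
  rows <- list()
  draw2 <- function(mus_mu, cas_mu) {
    if (noiseless) list(mus = round(mus_mu), cas = round(cas_mu))
    else rcounts_shared(mus_mu, cas_mu, truth$dispersion)
  }
  sim <- withr::with_seed(truth$seed + 3L, {
    for (cond in truth$conditions) {
      for (cl in seq_len(truth$clones_per_condition)) {
        mult <- rep(truth$condition_effects[[cond]], length(truth$gene_id))
        mult[truth$role == "escapee"] <- 1
        mult[truth$reactivated & cond == "KO_Aza"] <- truth$reactivation_fold
        mus_mu <- truth$xa_mean * truth$silencing_ratio * mult
        cnt <- draw2(mus_mu, truth$xa_mean)
        cas <- cnt$cas
        mus <- cnt$mus
        total <- round((mus + cas) * 3)
        fpkm <- total / (truth$gene_length_bp / 1e3) / 50
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = truth$gene_id,
          gene_length_bp = truth$gene_length_bp,
          sample_id = sprintf("%s_c%d", cond, cl),
          condition = cond, clone = sprintf("clone%d", cl),
          mus_reads = mus, cas_reads = cas, fpkm = fpkm,
          stringsAsFactors = FALSE)
      }
    }
    # pure-cas controls: mus signal only at planted miscalled-SNP genes
    ctl <- list()
    for (k in 1:2) {
      mis_mu <- ifelse(truth$role == "miscalled", truth$xa_mean * 0.15, 0)
      cnt <- draw2(mis_mu, truth$xa_mean)
      cas <- cnt$cas
      mus <- cnt$mus
      total <- round((mus + cas) * 3)
      fpkm <- total / (truth$gene_length_bp / 1e3) / 50
      ctl[[k]] <- data.frame(
        gene_id = truth$gene_id, gene_length_bp = truth$gene_length_bp,
        sample_id = sprintf("cas_control_%d", k),
        condition = "cas_control", clone = sprintf("ctl%d", k),
        mus_reads = mus, cas_reads = cas, fpkm = fpkm,
        stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), control = do.call(rbind, ctl))
  })
  list(table = validate_allelic_table(sim$table),
       control = validate_allelic_table(sim$control),
       truth = truth)
}
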