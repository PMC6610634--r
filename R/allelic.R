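#' Percent maternal (mus / Xi) expression
#'
#' `%mus = 100 * mus / (mus + cas)` — the percentage of mus-specific
#' (inactive-X) reads among all allele-assignable reads of a gene; NA when
#' no allele-specific reads are present. 1 mus read against 10 cas reads
#' gives 9.09%, the threshold used to flag miscalled SNPs.
#'
#' @param mus_reads,cas_reads Non-negative integer vectors.
#' @return Numeric vector in `[0, 100]`, NA where both counts are 0.
#' @export
percent_mus <- function(mus_reads, cas_reads) {
  if (any(mus_reads < 0) || any(cas_reads < 0))
    stop("read counts must be non-negative")
  tot <- mus_reads + cas_reads
  ifelse(tot > 0, 100 * mus_reads / tot, NA_real_)
}

#' Classify X-linked genes by allelic expression
#'
#' Applies the fixed classification cascade to an allelic gene table:
#' \enumerate{
#'   \item active: FPKM > 0 in all samples;
#'   \item allele-assessable: at least `min_allelic_reads` (default 13)
#'     allele-specific reads (mus + cas) in every sample;
#'   \item miscalled-SNP filter: genes with %mus strictly greater than
#'     `miscall_threshold` (default 9.09%) in any sample of the pure-cas
#'     control table are excluded (their Xi signal is an annotation
#'     artifact);
#'   \item escapee: Xi expression (mus/cas within a clone) strictly greater
#'     than `escape_ratio` (default 0.1, i.e. Xi > 10% of Xa) in at least
#'     one baseline (WT) sample;
#'   \item subject to XCI: the remaining active, assessable genes.
#' }
#' Each excluded gene is annotated with the first filter it failed.
#'
#' @param table Allelic gene table (see [read_allelic_table()]).
#' @param control_table Optional pure-cas background table with the same
#'   columns; when missing the miscalled-SNP filter is skipped with a
#'   warning.
#' @param baseline_condition Condition naming the WT clones used for the
#'   escapee rule (default "WT_DMSO").
#' @param min_allelic_reads,miscall_threshold,escape_ratio Cascade
#'   thresholds (defaults 13 reads inclusive, 9.09% strict, 0.1 strict).
#' @return A `gene_classification`: per-gene data frame (`genes`), the
#'   gene x sample %mus matrix (`pmus`), sample annotation (`samples`), and
#'   `summary` counts.
#' @export
classify_genes <- function(table, control_table = NULL,
                           baseline_condition = "WT_DMSO",
                           min_allelic_reads = 13,
                           miscall_threshold = 9.09,
                           escape_ratio = 0.1) {
  table <- validate_allelic_table(table)
  genes <- sort(unique(table$gene_id))
  samples <- sort(unique(table$sample_id))
  get_mat <- function(col) {
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(table$gene_id, genes), match(table$sample_id, samples))] <-
      table[[col]]
    if (anyNA(m)) stop("gene missing from a sample")
    m
  }
  fpkm <- get_mat("fpkm")
  mus <- get_mat("mus_reads")
  cas <- get_mat("cas_reads")
  pmus <- matrix(percent_mus(mus, cas), nrow(mus), ncol(mus),
                 dimnames = dimnames(mus))
  samp_info <- unique(table[, c("sample_id", "condition", "clone")])
  samp_info <- samp_info[match(samples, samp_info$sample_id), ]

  is_active <- apply(fpkm > 0, 1, all)
  is_assessable <- apply(mus + cas >= min_allelic_reads, 1, all)

  is_miscalled <- rep(FALSE, length(genes))
  if (is.null(control_table)) {
    warning("no control table supplied; miscalled-SNP filter skipped")
  } else {
    ctl <- validate_allelic_table(control_table)
    ctl_pm <- percent_mus(ctl$mus_reads, ctl$cas_reads)
    bad <- unique(ctl$gene_id[!is.na(ctl_pm) & ctl_pm > miscall_threshold])
    is_miscalled <- genes %in% bad
  }

  base_samples <- samp_info$sample_id[samp_info$condition == baseline_condition]
  if (!length(base_samples))
    stop(sprintf("no samples with baseline condition '%s'", baseline_condition))
  xi_over_xa <- mus[, base_samples, drop = FALSE] /
    cas[, base_samples, drop = FALSE]
  is_escapee <- apply(xi_over_xa, 1, function(z)
    any(!is.nan(z) & z > escape_ratio))

  status <- rep("excluded", length(genes))
  failed <- rep(NA_character_, length(genes))
  failed[!is_active] <- "inactive"
  failed[is_active & !is_assessable] <- "not_assessable"
  failed[is_active & is_assessable & is_miscalled] <- "miscalled_snp"
  pass <- is_active & is_assessable & !is_miscalled
  status[pass & is_escapee] <- "escapee"
  status[pass & !is_escapee] <- "subject_to_XCI"

  structure(list(
    genes = data.frame(gene_id = genes, is_active = is_active,
                       is_assessable = is_assessable,
                       is_miscalled_snp = is_miscalled,
                       status = status, failed_filter = failed,
                       stringsAsFactors = FALSE, row.names = NULL),
    pmus = pmus, samples = samp_info,
    params = list(baseline_condition = baseline_condition,
                  min_allelic_reads = min_allelic_reads,
                  miscall_threshold = miscall_threshold,
                  escape_ratio = escape_ratio),
    summary = c(n_genes = length(genes), n_active = sum(is_active),
                n_assessable = sum(is_active & is_assessable),
                n_miscalled = sum(is_active & is_assessable & is_miscalled),
                n_escapee = sum(status == "escapee"),
                n_subject = sum(status == "subject_to_XCI"))),
    class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<gene_classification> %d genes: %d active, %d assessable, %d miscalled, %d escapees, %d subject to XCI\n",
    s["n_genes"], s["n_active"], s["n_assessable"], s["n_miscalled"],
    s["n_escapee"], s["n_subject"]))
  invisible(x)
}

group_mean_pmus <- function(cls, sample_ids, genes = NULL) {
  if (is.null(genes))
    genes <- cls$genes$gene_id[cls$genes$status == "subject_to_XCI"]
  m <- cls$pmus[genes, sample_ids, drop = FALSE]
  rowMeans(m, na.rm = TRUE)
}

#' Call reactivated genes
#'
#' A subject-to-XCI gene is called reactivated when its mean %mus across
#' test-condition clones is (1) at least `fold` times the mean across
#' baseline clones and (2) greater with one-sided Welch t-test p <
#' `p_cutoff`. Default thresholds: 3-fold and p < 0.1, the criteria for
#' calling Xi reactivation under combined Smchd1 loss + demethylation
#' (baseline WT_DMSO vs test KO_Aza). A baseline mean of exactly 0
#' satisfies the fold criterion whenever the test mean is positive. With
#' zero within-group variance the t test degenerates; the call then rests
#' on the mean difference alone.
#'
#' @param cls A `gene_classification`.
#' @param baseline_condition,test_condition Condition labels.
#' @param fold Fold-change threshold (default 3, inclusive).
#' @param p_cutoff One-sided p-value cutoff (default 0.1, strict).
#' @return Data frame per subject gene: means, fold, p, `reactivated`.
#' @export
call_reactivated <- function(cls, baseline_condition = "WT_DMSO",
                             test_condition = "KO_Aza",
                             fold = 3, p_cutoff = 0.1) {
  si <- cls$samples
  base_s <- si$sample_id[si$condition == baseline_condition]
  test_s <- si$sample_id[si$condition == test_condition]
  if (length(base_s) < 2 || length(test_s) < 2)
    stop("need >= 2 clones per condition")
  genes <- cls$genes$gene_id[cls$genes$status == "subject_to_XCI"]
  res <- lapply(genes, function(g) {
    b <- cls$pmus[g, base_s]; tvals <- cls$pmus[g, test_s]
    b[is.na(b)] <- 0; tvals[is.na(tvals)] <- 0
    mb <- mean(b); mt <- mean(tvals)
    fold_ok <- if (mb == 0) mt > 0 else mt >= fold * mb
    p <- tryCatch(
      stats::t.test(tvals, b, alternative = "greater")$p.value,
      error = function(e) if (mt > mb) 0 else 1)
    data.frame(gene_id = g, mean_baseline = mb, mean_test = mt,
               fold = if (mb > 0) mt / mb else if (mt > 0) Inf else NA_real_,
               p.value = p,
               reactivated = fold_ok && p < p_cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cumulative-distribution comparison of %mus between sample groups
#'
#' Per-gene mean %mus is computed within each group over subject-to-XCI
#' genes (clone averaging); groups are compared with a Wilcoxon test and
#' cumulative distribution plot (CDP) coordinates are returned. The paired
#' comparison uses the Wilcoxon signed-rank test on per-gene differences
#' (the standard paired analogue; identical groups give p = 1 under the
#' zero-difference normal approximation, or NA when no test is possible).
#' `naive_paired_ranksum = TRUE` forces a rank-sum test on the paired
#' samples instead.
#'
#' @param cls A `gene_classification`.
#' @param group_a,group_b Sample-id vectors.
#' @param paired Paired (signed-rank) or unpaired (rank-sum) comparison.
#' @param alternative Sidedness of group_a relative to group_b ("less"
#'   asks whether group_a %mus is shifted below group_b).
#' @param genes Optional gene subset (default: subject-to-XCI genes).
#' @param naive_paired_ranksum Use a plain rank-sum test even when paired.
#' @return List: `statistic`, `p.value`, `values_a`, `values_b`, `cdp_a`,
#'   `cdp_b` (step-function coordinates).
#' @export
compare_cdp <- function(cls, group_a, group_b, paired = TRUE,
                        alternative = "less", genes = NULL,
                        naive_paired_ranksum = FALSE) {
  a <- group_mean_pmus(cls, group_a, genes)
  b <- group_mean_pmus(cls, group_b, genes)
  ok <- if (paired) !is.na(a) & !is.na(b) else TRUE
  if (paired) { a <- a[ok]; b <- b[ok] } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  wt <- tryCatch(
    suppressWarnings(stats::wilcox.test(
      a, b, paired = paired && !naive_paired_ranksum,
      alternative = alternative)),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  cdp <- function(x) {
    x <- sort(x)
    data.frame(pmus = x, F = seq_along(x) / length(x))
  }
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       values_a = a, values_b = b, cdp_a = cdp(a), cdp_b = cdp(b))
}

#' Class-I enrichment among subject-to-XCI genes
#'
#' Intersects an external gene-class annotation (Class I = genes requiring
#' SMCHD1 for de novo silencing) with the subject-to-XCI set and compares
#' the %mus distributions of Class I vs non-Class I subject genes with an
#' unpaired one-sided rank-sum test (Class I genes are the ones prone to
#' reactivation).
#'
#' @param cls A `gene_classification`.
#' @param class_annotation Data frame with `gene_id` and `class_label`
#'   (labels "I", "II", "III", "unclassified").
#' @param sample_ids Samples whose mean %mus is compared.
#' @param class_of_interest Default "I".
#' @param alternative Default "greater" (Class I shifted up).
#' @return List: intersection counts, test statistic and p-value, values.
#' @export
class_enrichment <- function(cls, class_annotation, sample_ids,
                             class_of_interest = "I",
                             alternative = "greater") {
  subj <- cls$genes$gene_id[cls$genes$status == "subject_to_XCI"]
  cl_genes <- class_annotation$gene_id[
    class_annotation$class_label == class_of_interest]
  inter <- intersect(subj, cl_genes)
  other <- setdiff(subj, cl_genes)
  counts <- c(n_subject = length(subj), n_class = length(cl_genes),
              n_intersection = length(inter), n_other = length(other))
  if (!length(inter)) {
    warning("class annotation disjoint from subject genes; test skipped")
    return(list(counts = counts, statistic = NA_real_, p.value = NA_real_,
                values_class = numeric(0), values_other = numeric(0)))
  }
  vi <- group_mean_pmus(cls, sample_ids, inter)
  vo <- group_mean_pmus(cls, sample_ids, other)
  wt <- suppressWarnings(stats::wilcox.test(vi, vo,
                                            alternative = alternative))
  list(counts = counts, statistic = unname(wt$statistic),
       p.value = wt$p.value, values_class = vi, values_other = vo)
}

#' Cluster samples on their %mus profiles
#'
#' Unsupervised hierarchical clustering of samples on the gene x sample
#' %mus matrix restricted to subject-to-XCI genes; with condition effects
#' larger than clone noise the tree groups clones of the same genotype and
#' treatment together.
#'
#' @param cls A `gene_classification`.
#' @param linkage Passed to [stats::hclust()].
#' @return An `hclust` tree over samples.
#' @export
cluster_samples <- function(cls, linkage = "complete") {
  if (ncol(cls$pmus) < 4) stop("need >= 4 samples")
  subj <- cls$genes$gene_id[cls$genes$status == "subject_to_XCI"]
  m <- cls$pmus[subj, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stats::hclust(stats::dist(t(m)), method = linkage)
}
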