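test_that("percent_mus matches its definition including the 9.09% landmark", {
  expect_equal(percent_mus(0, 10), 0)
  expect_equal(percent_mus(7, 7), 50)
  expect_equal(percent_mus(1, 10), 100 / 11)       # 9.0909..., the
  expect_gt(percent_mus(1, 10), 9.09)              # miscall threshold value
  expect_true(is.na(percent_mus(0, 0)))
  expect_error(percent_mus(-1, 3), "non-negative")
})

test_that("the classification cascade matches a hand-applied oracle on the fixture", {
  fx <- make_fixture()
  cls <- classify_genes(fx$table, fx$control)
  oracle <- bf_cascade(fx$table, fx$control)
  got <- stats::setNames(cls$genes$status, cls$genes$gene_id)
  expect_equal(got[names(oracle)], oracle)
  # branch-by-branch expectations
  expect_equal(got[["inactive"]], "excluded")
  expect_equal(cls$genes$failed_filter[cls$genes$gene_id == "inactive"],
               "inactive")
  expect_equal(got[["thin"]], "excluded")
  expect_equal(got[["boundary13"]], "subject_to_XCI")  # 13 reads inclusive
  expect_equal(got[["miscalled"]], "excluded")
  expect_equal(got[["escapee11"]], "escapee")          # 11% > 10%, one clone
  expect_equal(got[["ratio10"]], "subject_to_XCI")     # exactly 10%: strict
  # statuses partition the active & assessable set
  expect_equal(unname(cls$summary["n_escapee"] + cls$summary["n_subject"] +
                        cls$summary["n_miscalled"]),
               unname(cls$summary["n_assessable"]))
  # missing gene in a sample is fatal
  bad <- fx$table[-1, ]
  expect_error(classify_genes(bad, fx$control), "every sample")
  # no control: filter skipped with warning
  expect_warning(cls2 <- classify_genes(fx$table), "control")
  # without the control filter the spurious mus signal mimics escape
  expect_equal(cls2$genes$status[cls2$genes$gene_id == "miscalled"],
               "escapee")
})

test_that("reactivation calls follow the 3-fold + one-sided p < 0.1 rule", {
  fx <- make_fixture()
  cls <- classify_genes(fx$table, fx$control)
  rea <- call_reactivated(cls)
  r <- stats::setNames(rea$reactivated, rea$gene_id)
  expect_true(r[["reactivated"]])      # fold 3.5, p ~ 0.01
  expect_false(r[["fold29"]])          # below the fold threshold
  expect_true(r[["from_zero"]])        # baseline 0, test > 0 convention
  expect_false(r[["clean_subject"]])
  frow <- rea[rea$gene_id == "reactivated", ]
  expect_equal(frow$fold, 3.5)
  expect_lt(frow$p.value, 0.1)
  expect_equal(rea$fold[rea$gene_id == "from_zero"], Inf)
})

test_that("the cascade recovers noiseless synthetic truth exactly", {
  tr <- expression_truth(n_genes = 120, seed = 77)
  sim <- simulate_allelic_counts(tr, noiseless = TRUE)
  cls <- classify_genes(sim$table, sim$control)
  status <- stats::setNames(cls$genes$status, cls$genes$gene_id)[tr$gene_id]
  expect_true(all(status[tr$role == "escapee"] == "escapee"))
  expect_true(all(status[tr$role == "miscalled"] == "excluded"))
  expect_true(all(status[tr$role == "subject"] == "subject_to_XCI"))
  rea <- call_reactivated(cls)
  expect_equal(sort(rea$gene_id[rea$reactivated]),
               sort(tr$gene_id[tr$reactivated]))
})

test_that("CDP comparisons match manual rank computations and shift rightward", {
  fx <- make_fixture()
  cls <- classify_genes(fx$table, fx$control)
  # identical groups, paired: zero differences -> NA by convention
  same <- compare_cdp(cls, c("WT_DMSO_c1", "WT_DMSO_c2"),
                      c("WT_DMSO_c1", "WT_DMSO_c2"), paired = TRUE)
  expect_true(is.na(same$p.value) || same$p.value == 1)
  # constructed unpaired shift: statistic equals the rank-sum formula
  set.seed(41)
  a <- round(stats::runif(50, 1, 40), 3)
  b <- a + 5
  w <- stats::wilcox.test(a, b, alternative = "less")
  ranks <- rank(c(a, b))
  W_manual <- sum(ranks[1:50]) - 50 * 51 / 2
  expect_equal(unname(w$statistic), W_manual)
  # through the package on a synthetic table: KO_Aza shifts %mus upward
  tr <- expression_truth(n_genes = 150, seed = 78)
  sim <- simulate_allelic_counts(tr)
  cls2 <- classify_genes(sim$table, sim$control)
  cd <- compare_cdp(cls2, c("WT_DMSO_c1", "WT_DMSO_c2"),
                    c("KO_Aza_c1", "KO_Aza_c2"), paired = TRUE,
                    alternative = "less")
  expect_lt(cd$p.value, 0.05)
  expect_lt(stats::median(cd$values_a), stats::median(cd$values_b))
  expect_equal(max(cd$cdp_a$F), 1)
})

test_that("class intersection counts and enrichment test work on a planted annotation", {
  # mock classification shaped like the published numbers:
  # 216 subject genes, 126 Class I genes, 79 in the intersection
  genes <- sprintf("g%03d", 1:400)
  subj <- genes[1:216]
  class1 <- c(genes[1:79], genes[301:347])  # 79 in subject + 47 outside
  pm <- matrix(2, 400, 2, dimnames = list(genes, c("s1", "s2")))
  pm[1:79, ] <- 8  # Class I subject genes reactivate more
  cls <- structure(list(
    genes = data.frame(gene_id = genes,
                       status = ifelse(genes %in% subj, "subject_to_XCI",
                                       "excluded")),
    pmus = pm,
    samples = data.frame(sample_id = c("s1", "s2"),
                         condition = "KO_Aza", clone = c("c1", "c2"))),
    class = "gene_classification")
  ann <- data.frame(gene_id = class1, class_label = "I")
  res <- class_enrichment(cls, ann, c("s1", "s2"))
  expect_equal(unname(res$counts["n_subject"]), 216L)
  expect_equal(unname(res$counts["n_class"]), 126L)
  expect_equal(unname(res$counts["n_intersection"]), 79L)
  expect_equal(unname(res$counts["n_other"]), 137L)
  expect_lt(res$p.value, 0.05)
  # disjoint annotation: skipped with warning
  ann2 <- data.frame(gene_id = genes[390:400], class_label = "I")
  expect_warning(res2 <- class_enrichment(cls, ann2, c("s1", "s2")),
                 "disjoint")
  expect_true(is.na(res2$p.value))
})

test_that("sample clustering recovers planted condition groups and ignores order", {
  set.seed(43)
  conds <- rep(c("WT_DMSO", "WT_Aza", "KO_DMSO", "KO_Aza"), each = 2)
  eff <- rep(c(0, 10, 20, 40), each = 2)
  ng <- 60
  pm <- sapply(seq_along(conds), function(k)
    pmax(stats::rnorm(ng, 2 + eff[k], 1), 0))
  dimnames(pm) <- list(sprintf("g%02d", 1:ng), sprintf("s%d_%s", 1:8, conds))
  cls <- structure(list(
    genes = data.frame(gene_id = rownames(pm), status = "subject_to_XCI"),
    pmus = pm,
    samples = data.frame(sample_id = colnames(pm), condition = conds,
                         clone = rep(c("c1", "c2"), 4))),
    class = "gene_classification")
  hc <- cluster_samples(cls)
  grp <- stats::cutree(hc, k = 4)
  expect_equal(length(unique(tapply(grp, conds, function(z)
    paste(sort(unique(z)), collapse = ",")))), 4)
  expect_true(all(tapply(grp, conds, function(z) length(unique(z))) == 1))
  # permuting sample order leaves the tree topology unchanged
  perm <- c(5, 1, 7, 3, 8, 2, 6, 4)
  cls2 <- cls
  cls2$pmus <- pm[, perm]
  cls2$samples <- cls$samples[perm, ]
  hc2 <- cluster_samples(cls2)
  d1 <- as.matrix(stats::cophenetic(hc))
  d2 <- as.matrix(stats::cophenetic(hc2))
  expect_equal(d1[colnames(pm), colnames(pm)], d2[colnames(pm), colnames(pm)])
})
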