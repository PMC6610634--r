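#' Default pipeline configuration
#'
#' The bundled demo configuration: a 120-Mb synthetic chromosome analysed
#' end to end (simulate, balance, compartments, insulation, megadomains,
#' coverage deltas, allelic classification) for a compartment-less WT_Xi
#' regime and an S1/S2-restored SMCHD1_KO regime. All thresholds carry the
#' analysis defaults (14% mask, 3-bin minimum run, 73-Mb boundary, 10-Mb
#' span, 3-fold + p < 0.1 reactivation rule).
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return Config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    chrom_length_bp = 120e6,
    bin_size_bp = 100e3,
    pearson_bin_factor = 2,          # Pearson/megadomain at 200 kb
    regimes = c("WT_Xi", "SMCHD1_KO"),
    n_segments = 25,
    read_depth = 2e6,
    megadomain_boundary_bp = 73e6,
    mask_quantile = 0.14,
    min_run_bins = 3,
    span_threshold_bp = 10e6,
    coverage = list(enrichment_S1 = 0.5, noise_sd = 0.2),
    counts = list(n_genes = 100, reactivation_fold = 5, dispersion = 0.1),
    reactivation = list(fold = 3, p_cutoff = 0.1)
  )
}

#' Run the full synthetic Xi-architecture pipeline
#'
#' Orchestrates simulate -> balance -> compartments -> insulation ->
#' megadomains -> coverage tracks -> allelic classification from a single
#' declarative config, writing per-stage TSV/bedGraph/BED outputs and a
#' JSON report. Re-running with the same config produces byte-identical
#' outputs (every random stage is seeded from `config$seed`).
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same fields.
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly; written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("xifold_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config(seed = config$seed %||% 1)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  report <- list(config = config, config_md5 = cfg_hash,
                 package_version = as.character(utils::packageVersion("xifold")),
                 regimes = list())

  for (ri in seq_along(config$regimes)) {
    regime <- config$regimes[[ri]]
    truth <- architecture_truth(
      chrom_length_bp = config$chrom_length_bp,
      bin_size_bp = config$bin_size_bp,
      regime = regime, n_segments = config$n_segments,
      megadomain_boundary_bp = config$megadomain_boundary_bp,
      read_depth = config$read_depth,
      seed = config$seed + 10 * ri)
    m100 <- simulate_contact_matrix(truth)
    m200 <- coarsen_matrix(m100, config$pearson_bin_factor)

    m100 <- mask_low_coverage(m100, config$mask_quantile)
    m200 <- mask_low_coverage(m200, config$mask_quantile)
    ice100 <- ice_balance(m100)
    ice200 <- ice_balance(m200)

    # orientation reference: an Xist-like coverage track for this regime
    xist_like <- simulate_coverage(truth,
                                   enrichment_S1 = config$coverage$enrichment_S1,
                                   noise_sd = config$coverage$noise_sd,
                                   seed = truth$seed)
    ref100 <- bin_track(xist_like, m100$binning)
    ref200 <- bin_track(xist_like, m200$binning)

    corr200 <- pearson_map(observed_over_expected(ice200))
    prof200 <- suppressWarnings(
      compute_compartments(corr200, ref200, "xist_like"))
    corr100 <- pearson_map(observed_over_expected(ice100))
    prof100 <- suppressWarnings(
      compute_compartments(corr100, ref100, "xist_like"))
    pc_used <- select_pc(prof100)
    segs <- call_segments(prof100, pc_used, config$min_run_bins)

    ins <- insulation_score(ice100)
    bnd <- call_boundaries(ins)
    bnd_regions <- if (nrow(bnd)) {
      region(truth$binning$chrom,
             bin_start(truth$binning, bnd$bin),
             bin_end(truth$binning, bnd$bin),
             sprintf("boundary%03d", seq_len(nrow(bnd))),
             category = "TAD_boundary")
    } else region("chr", 0, 1)[0, ]
    overlap <- border_boundary_overlap(segs, bnd_regions, slack_bins = 1)

    mg <- inter_megadomain_fraction(m200,
                                    boundary_bp = config$megadomain_boundary_bp,
                                    span_threshold_bp = config$span_threshold_bp)

    # coverage chain: regime track vs a structure-less baseline track
    wt_cov <- simulate_coverage(truth, enrichment_S1 = 0,
                                noise_sd = config$coverage$noise_sd,
                                seed = truth$seed + 100)
    scaled_wt <- scale_to_reference(wt_cov, xist_like)
    dlt <- delta_track(xist_like, scaled_wt)
    dlt_binned <- bin_track(dlt, m200$binning)
    labels200 <- segments_to_labels(segs, m200$binning)
    s1s2 <- tryCatch(s1s2_density_test(dlt_binned, labels200),
                     warning = function(w) NULL)

    tag <- sprintf("%02d_%s", ri, regime)
    write_bed(data.frame(chrom = truth$binning$chrom,
                         start = bin_start(truth$binning, segs$segments$start_bin),
                         end = bin_end(truth$binning, segs$segments$end_bin),
                         name = segs$segments$sign, strand = "."),
              file.path(out_dir, paste0(tag, "_segments.bed")))
    ins_ok <- !is.na(ins$normalized)
    write_bedgraph(coverage_track(truth$binning$chrom,
                                  bin_start(truth$binning, which(ins_ok)),
                                  bin_end(truth$binning, which(ins_ok)),
                                  ins$normalized[ins_ok]),
                   file.path(out_dir, paste0(tag, "_insulation.bedGraph")))
    pc <- prof100[[pc_used]]
    pc_ok <- !is.na(pc)
    write_bedgraph(coverage_track(truth$binning$chrom,
                                  bin_start(truth$binning, which(pc_ok)),
                                  bin_end(truth$binning, which(pc_ok)),
                                  pc[pc_ok]),
                   file.path(out_dir, paste0(tag, "_", pc_used, ".bedGraph")))

    report$regimes[[regime]] <- list(
      seed = truth$seed,
      pc_used = pc_used,
      n_compartments = segs$n_compartments,
      mean_size_mb = segs$mean_size_bp / 1e6,
      explained_variance = as.list(prof100$explained_variance),
      reference_correlation = as.list(prof100$reference_correlation),
      n_boundaries = nrow(bnd),
      border_boundary_overlap = overlap$fraction,
      inter_megadomain_fraction = mg$fraction,
      s1s2_delta_p = if (is.null(s1s2)) NA else s1s2$p.value)
  }

  # allelic-expression arm
  etruth <- expression_truth(n_genes = config$counts$n_genes,
                             reactivation_fold = config$counts$reactivation_fold,
                             dispersion = config$counts$dispersion,
                             seed = config$seed + 1000)
  sim <- simulate_allelic_counts(etruth)
  cls <- classify_genes(sim$table, sim$control)
  rea <- call_reactivated(cls, fold = config$reactivation$fold,
                          p_cutoff = config$reactivation$p_cutoff)
  si <- cls$samples
  cdp <- compare_cdp(cls,
                     si$sample_id[si$condition == "WT_DMSO"],
                     si$sample_id[si$condition == "KO_Aza"],
                     paired = TRUE, alternative = "less")
  utils::write.table(merge(cls$genes, rea[, c("gene_id", "reactivated")],
                           all.x = TRUE),
                     file.path(out_dir, "gene_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$classification <- c(as.list(cls$summary),
                             list(n_reactivated = sum(rea$reactivated),
                                  cdp_p_WT_vs_KOAza = cdp$p.value))

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
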