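# End-to-end pipeline driver: simulate -> DEA -> GR-eQTL (combined, female,
# male) -> interaction -> meQTL -> enrichment -> TSPS, with a
# machine-readable summary.

#' Pipeline configuration
#'
#' Bundles stage toggles, thresholds and the master seed. Every threshold
#' defaults to the reference analysis value: FDR 0.05, |log2FC| 0.2, cis
#' window 1 Mb, clump r2 0.2, proxy r2 0.6. `n_perm` defaults to a
#' desk-scale 1000 permutations per probe (the reference design used
#' 500,000; raise it for production runs).
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param fdr significance threshold used throughout.
#' @param abs_logfc_min fold-change threshold for the DEA summary.
#' @param window cis window in bp.
#' @param clump_r2 tag clumping threshold.
#' @param proxy_r2 proxy substitution threshold.
#' @param n_perm maxT permutations per probe.
#' @param n_sets MAF-matched null sets for enrichment.
#' @param tsps_effect log-odds per score SD for the simulated case/control
#'   phenotype in the TSPS stage.
#' @param strata strata to analyse.
#' @param seed master seed (overrides `sim$seed`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), fdr = 0.05,
                            abs_logfc_min = 0.2, window = 1e6,
                            clump_r2 = 0.2, proxy_r2 = 0.6, n_perm = 1000,
                            n_sets = 200, tsps_effect = 0.5,
                            strata = c("all", "female", "male"),
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, fdr = fdr, abs_logfc_min = abs_logfc_min,
                 window = window, clump_r2 = clump_r2, proxy_r2 = proxy_r2,
                 n_perm = n_perm, n_sets = n_sets,
                 tsps_effect = tsps_effect, strata = strata,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the whole synthetic analysis pipeline
#'
#' Executes simulate -> paired DEA (combined, per-sex, sex-effect) ->
#' GR-eQTL with the two-stage correction per stratum -> sex-by-genotype
#' interaction scan on the stratified etranscripts -> per-sex meQTL and
#' eSNP/meSNP overlap -> MAF-matched annotation enrichment -> TSPS
#' derivation, scoring and case/control association. Writes per-stage TSVs
#' and a JSON summary when `out_dir` is given; byte-identical summaries
#' under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return the summary list, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  genotypes <- simulate_genotypes(sim)
  covariates <- simulate_covariates(sim)
  probe_table <- make_probe_table(genotypes, sim)
  truth <- make_truth_table(genotypes, sim, probe_table)
  expr <- simulate_expression(genotypes, covariates, truth, sim, probe_table)
  cpg_truth <- make_truth_table(
    genotypes, sim, make_probe_table(genotypes, sim, "cpg", "cpgs"))
  meth <- simulate_methylation(genotypes, covariates, cpg_truth, sim)

  dea <- list(
    combined = fit_dea(expr, covariates, "combined"),
    female = fit_dea(expr, covariates, "stratified", "female"),
    male = fit_dea(expr, covariates, "stratified", "male"),
    sex_effect = fit_dea(expr, covariates, "sex_effect"))
  fc <- threshold_fc(dea$combined, config$fdr, config$abs_logfc_min)
  sexes <- compare_sexes(dea$female, dea$male, config$fdr)

  delta <- compute_delta(expr)
  eqtl <- lapply(stats::setNames(config$strata, config$strata), function(s)
    map_cis_qtl(delta, genotypes, covariates, stratum = s,
                n_perm = config$n_perm,
                seed = child_seed(config$seed, paste0("eqtl:", s)),
                window = config$window, r2_max = config$clump_r2,
                q_max = config$fdr))

  sig_pairs <- unique(rbind(
    eqtl$female$significant[, c("snp_id", "probe_id")],
    eqtl$male$significant[, c("snp_id", "probe_id")]))
  interaction <- if (nrow(sig_pairs) > 0)
    interaction_scan(delta, genotypes, covariates, sig_pairs) else NULL

  meqtl <- lapply(c(female = "female", male = "male"), function(s)
    scan_meqtl(meth, genotypes, covariates, stratum = s,
               q_max = config$fdr))
  me_overlap <- lapply(c(female = "female", male = "male"), function(s)
    overlap_eqtl_meqtl(eqtl[[s]]$significant$snp_id, meqtl[[s]]$mesnps))

  fixture <- make_annotation_fixtures(
    genotypes$snp_table, enriched_fraction = 0.5, background_fraction = 0.1,
    seed = child_seed(config$seed, "annotation"),
    targets = unique(eqtl$female$significant$snp_id))
  enrich <- if (length(fixture$targets) > 0)
    maf_matched_enrichment(
      genotypes$snp_table[genotypes$snp_table$snp_id %in% fixture$targets, ],
      genotypes$snp_table, list(fixture = fixture$intervals),
      n_sets = config$n_sets,
      seed = child_seed(config$seed, "enrichment")) else NULL

  tsps <- lapply(c(female = "female", male = "male"), function(s) {
    sig <- eqtl[[s]]$significant
    if (nrow(sig) == 0) return(NULL)
    w <- derive_weights(sig, genotypes$snp_table, stratum = s)
    compute_tsps(genotypes, w)
  })
  tsps_assoc <- NULL
  if (!is.null(tsps$female)) {
    pheno <- simulate_case_control(tsps$female, config$tsps_effect, 0.5,
                                   child_seed(config$seed, "phenotype"))
    idx <- list(female = covariates$sex == 1L, male = covariates$sex == 0L)
    tsps_assoc <- lapply(c(female = "female", male = "male"), function(s) {
      sc <- tsps$female[idx[[s]], , drop = FALSE]
      associate_tsps(sc, pheno[sc$sample_id])
    })
  }

  planted <- paste(truth$snp_id, truth$probe_id)
  recovered_in <- function(res) {
    if (nrow(res$significant) == 0) return(0L)
    bins <- res$bins
    hits <- vapply(seq_len(nrow(truth)), function(i) {
      bin <- bins$bin_id[match(truth$snp_id[i], bins$snp_id)]
      if (is.na(bin)) return(FALSE)
      tag <- bins$tag_id[match(truth$snp_id[i], bins$snp_id)]
      any(res$significant$snp_id == tag &
            res$significant$probe_id == truth$probe_id[i])
    }, logical(1))
    sum(hits)
  }

  summary <- list(
    seed = config$seed,
    n_samples = sim$n_individuals,
    n_snps = sim$n_snps,
    n_probes = sim$n_probes,
    dea = list(
      n_significant_combined = fc$n_significant,
      n_pass_fc = fc$n_pass_fc,
      pct_fc = fc$pct_fc,
      n_significant_female = sum(dea$female$q <= config$fdr),
      n_significant_male = sum(dea$male$q <= config$fdr),
      concordance = sexes$concordance,
      membership = as.list(sexes$membership)),
    eqtl = lapply(eqtl, function(e) list(
      n_records = nrow(e$records),
      n_bins = max(e$bins$bin_id, 0),
      n_tags = sum(e$bins$is_tag),
      n_significant = nrow(e$significant),
      n_significant_etranscripts = length(unique(e$significant$probe_id)),
      n_significant_tag_esnps = length(unique(e$significant$snp_id)))),
    truth_recovery = lapply(eqtl, function(e)
      list(n_planted = nrow(truth), n_recovered = recovered_in(e))),
    interaction = if (!is.null(interaction))
      list(n_tested = nrow(interaction),
           n_nominal = sum(interaction$p < 0.05)) else NULL,
    meqtl = lapply(meqtl, function(m) list(
      n_significant = nrow(m$significant),
      n_mesnps = length(m$mesnps))),
    meqtl_overlap = me_overlap,
    enrichment = if (!is.null(enrich))
      list(fold = enrich$fold[1], p_enrich = enrich$p_enrich[1]) else NULL,
    tsps = if (!is.null(tsps_assoc)) lapply(tsps_assoc, function(a)
      list(estimate = a$estimate, p = a$p, r2 = a$r2)) else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_table_tsv(covariates, file.path(out_dir, "covariates.tsv"))
    write_table_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_matrix_tsv(expr$baseline, file.path(out_dir, "expr_baseline.tsv"),
                     "probe_id")
    write_matrix_tsv(expr$post, file.path(out_dir, "expr_post.tsv"),
                     "probe_id")
    for (nm in names(dea))
      write_table_tsv(dea[[nm]], file.path(out_dir,
                                           paste0("dea_", nm, ".tsv")))
    for (nm in names(eqtl)) {
      write_table_tsv(eqtl[[nm]]$records,
                      file.path(out_dir, paste0("eqtl_", nm, ".tsv")))
      write_table_tsv(eqtl[[nm]]$bins,
                      file.path(out_dir, paste0("bins_", nm, ".tsv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
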