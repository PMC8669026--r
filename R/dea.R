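# Paired differential GR-response expression analysis: combined,
# sex-stratified and sex-effect models, BH FDR, fold-change thresholding and
# between-sex concordance summaries.

#' Per-sample expression change after stimulation
#'
#' The default `difference` dialect computes post minus baseline; both
#' matrices are on a log2-like normalized scale, so the difference is a log2
#' fold change. The `standardized` dialect additionally divides each probe's
#' change by its baseline standard deviation.
#'
#' @param expr an `expression_pair`.
#' @param dialect `"difference"` (default) or `"standardized"`.
#' @return an object of class `delta_expression`: list with `delta`
#'   (probes x samples), `dialect`, `probe_table`.
#' @export
compute_delta <- function(expr, dialect = c("difference", "standardized")) {
  dialect <- match.arg(dialect)
  b <- expr$baseline
  p <- expr$post
  if (!identical(dim(b), dim(p)))
    stop("baseline and post matrices have different shapes")
  if (!identical(colnames(b), colnames(p))) {
    unmatched <- union(setdiff(colnames(b), colnames(p)),
                       setdiff(colnames(p), colnames(b)))
    stop("sample mismatch between baseline and post: ",
         paste(unmatched, collapse = ", "))
  }
  d <- p - b
  if (dialect == "standardized") {
    sds <- apply(b, 1, stats::sd)
    if (any(sds == 0)) stop("zero baseline SD; cannot standardize")
    d <- d / sds
  }
  structure(list(delta = d, dialect = dialect,
                 probe_table = expr$probe_table),
            class = "delta_expression")
}

# Covariate design for the DEA/eQTL models: intercept + requested columns.
.dea_design <- function(covariates, cols) {
  covariates <- drop_constant_cols(covariates[, c("sample_id", cols),
                                              drop = FALSE],
                                   keep = "sample_id")
  cols <- setdiff(names(covariates), "sample_id")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[, cols, drop = FALSE]))
  rownames(X) <- covariates$sample_id
  X
}

.covariate_cols <- function(covariates) {
  setdiff(names(covariates), c("sample_id", "sex"))
}

#' Fit the differential GR-response expression models
#'
#' Three per-probe least-squares models:
#' * `combined`: long-format paired model of expression on a post-stimulation
#'   indicator (`dex`), controlling for sex, age, BMI, case status and the
#'   surrogate covariates; the reported coefficient is `dex`.
#' * `stratified`: the same model fit within one sex, omitting the sex
#'   covariate.
#' * `sex_effect`: the per-sample change regressed on sex plus the same
#'   covariates; the reported coefficient is `sex`.
#'
#' The paired model is plain OLS with a per-sample stimulation indicator (no
#' per-subject effect), matching the model formula as printed;
#' `subject_effect = TRUE` adds per-subject fixed effects for sensitivity
#' analysis. BH adjustment is applied over all probes within the run.
#'
#' @param expr an `expression_pair`.
#' @param covariates covariate table with `sample_id`, `sex`, `age`, `bmi`,
#'   `status` and surrogate columns.
#' @param model `"combined"`, `"stratified"` or `"sex_effect"`.
#' @param stratum `"all"`, `"female"` or `"male"` (stratified model only).
#' @param dialect delta dialect forwarded to [compute_delta()].
#' @param subject_effect add per-subject fixed effects to the paired model.
#' @return an object of class `differential_result`: data.frame with
#'   `probe_id`, `stratum`, `estimate`, `se`, `t`, `p`, `q` (BH), `log2fc`
#'   (per-probe mean change within the stratum).
#' @export
fit_dea <- function(expr, covariates,
                    model = c("combined", "stratified", "sex_effect"),
                    stratum = c("all", "female", "male"),
                    dialect = c("difference", "standardized"),
                    subject_effect = FALSE) {
  model <- match.arg(model)
  stratum <- match.arg(stratum)
  dialect <- match.arg(dialect)
  if (model == "combined") stratum <- "all"
  if (model == "sex_effect") stratum <- "all"
  keep <- switch(stratum, all = rep(TRUE, nrow(covariates)),
                 female = covariates$sex == 1L, male = covariates$sex == 0L)
  cov_s <- covariates[keep, , drop = FALSE]
  cols <- .covariate_cols(covariates)
  if (model != "stratified") cols <- c("sex", cols)
  if (nrow(cov_s) < length(cols) + 3L)
    stop("stratum '", stratum, "' has only ", nrow(cov_s),
         " samples; need at least ", length(cols) + 3L)
  label <- if (model == "sex_effect") "sex-effect" else stratum
  if (model == "sex_effect") {
    d <- compute_delta(expr, dialect)
    Y <- d$delta[, cov_s$sample_id, drop = FALSE]
    X <- .dea_design(cov_s, cols)
    fit <- fit_ols_rows(Y, X, "sex")
    log2fc <- rowMeans(expr$post[, cov_s$sample_id, drop = FALSE] -
                         expr$baseline[, cov_s$sample_id, drop = FALSE])
  } else {
    b <- expr$baseline[, cov_s$sample_id, drop = FALSE]
    p <- expr$post[, cov_s$sample_id, drop = FALSE]
    Y <- cbind(b, p)
    Xc <- .dea_design(cov_s, cols)
    X <- rbind(Xc, Xc)
    X <- cbind(X[, 1, drop = FALSE],
               dex = rep(c(0, 1), each = nrow(Xc)),
               X[, -1, drop = FALSE])
    if (subject_effect) {
      subj <- factor(rep(cov_s$sample_id, 2))
      S <- stats::model.matrix(~ subj)[, -1, drop = FALSE]
      X <- cbind(X, S)
    }
    rownames(X) <- NULL
    colnames(Y) <- NULL
    fit <- fit_ols_rows(Y, X, "dex")
    log2fc <- rowMeans(p - b)
  }
  out <- data.frame(probe_id = rownames(expr$baseline), stratum = label,
                    estimate = fit$estimate, se = fit$se, t = fit$t,
                    p = fit$p, q = stats::p.adjust(fit$p, "BH"),
                    log2fc = log2fc, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Apply FDR and fold-change thresholds to a differential result
#'
#' Selects probes with `q <= q_max` and `|log2FC| >= abs_logfc_min` and
#' reports the percentage of the q-significant probes that pass the
#' fold-change filter, rounded half-up to one decimal.
#'
#' @param result a `differential_result`.
#' @param q_max FDR threshold (default 0.05).
#' @param abs_logfc_min absolute log2 fold-change threshold (default 0.2).
#' @return list with `subset` (passing rows), `n_significant`, `n_pass_fc`,
#'   `pct_fc` (NaN with a warning when nothing is q-significant).
#' @export
threshold_fc <- function(result, q_max = 0.05, abs_logfc_min = 0.2) {
  sig <- result[!is.na(result$q) & result$q <= q_max, , drop = FALSE]
  pass <- sig[abs(sig$log2fc) >= abs_logfc_min, , drop = FALSE]
  pct <- if (nrow(sig) == 0) {
    warning("no q-significant probes; percentage undefined")
    NaN
  } else round_half_up(100 * nrow(pass) / nrow(sig), 1)
  list(subset = pass, n_significant = nrow(sig), n_pass_fc = nrow(pass),
       pct_fc = pct)
}

#' Between-sex concordance of differential results
#'
#' Compares the female and male stratified results over shared probes:
#' sign-concordance fraction among probes significant in either stratum, a
#' Wilcoxon rank-sum test comparing the absolute log2 fold changes of
#' female-significant versus male-significant probes, a per-probe scatter
#' table, and upset-style membership counts.
#'
#' @param female,male `differential_result` objects for the two strata.
#' @param q_max significance threshold used for memberships (default 0.05).
#' @return list with `concordance`, `wilcoxon_p`, `scatter` (probe table
#'   with both estimates and memberships), and `membership` (named counts
#'   `female_only`, `male_only`, `both`, `neither`).
#' @export
compare_sexes <- function(female, male, q_max = 0.05) {
  shared <- intersect(female$probe_id, male$probe_id)
  if (length(shared) == 0) stop("no shared probes between strata")
  f <- female[match(shared, female$probe_id), ]
  m <- male[match(shared, male$probe_id), ]
  sig_f <- f$q <= q_max
  sig_m <- m$q <= q_max
  either <- sig_f | sig_m
  concordance <- if (any(either))
    mean(sign(f$log2fc[either]) == sign(m$log2fc[either])) else NA_real_
  wilcoxon_p <- if (any(sig_f) && any(sig_m))
    suppressWarnings(stats::wilcox.test(abs(f$log2fc[sig_f]),
                                        abs(m$log2fc[sig_m]))$p.value)
  else NA_real_
  membership <- c(female_only = sum(sig_f & !sig_m),
                  male_only = sum(!sig_f & sig_m),
                  both = sum(sig_f & sig_m),
                  neither = sum(!sig_f & !sig_m))
  scatter <- data.frame(probe_id = shared,
                        log2fc_female = f$log2fc, log2fc_male = m$log2fc,
                        q_female = f$q, q_male = m$q,
                        significant_female = sig_f, significant_male = sig_m,
                        stringsAsFactors = FALSE)
  list(concordance = concordance, wilcoxon_p = wilcoxon_p,
       scatter = scatter, membership = membership)
}
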