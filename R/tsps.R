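# Transcriptional sensitivity profile score (TSPS): sensitive-allele coding
# from eQTL effects, proxy-SNP substitution, weighted dosage scoring with
# per-association correction, and association with phenotypes.

#' Derive TSPS weights from significant GR-eQTL records
#'
#' The sensitive allele is the allele associated with the larger absolute
#' expression change upon stimulation: the dosage-counted (alt) allele when
#' the eQTL coefficient is positive, the other (ref) allele when negative.
#' The weight is the absolute coefficient. An eSNP regulating k transcripts
#' contributes k rows (one per eQTL association). Zero-coefficient
#' associations are dropped with a warning.
#'
#' @param records significant tag eQTL records with `snp_id`, `probe_id`,
#'   `beta`.
#' @param snp_table SNP table with `snp_id`, `ref`, `alt` (and ideally
#'   `alt_freq`, used for proxy allele alignment).
#' @param stratum label stored with the weights (`"female"` / `"male"`).
#' @return data.frame of class `tsps_weights` with `snp_id`, `transcript`,
#'   `sensitive_allele`, `weight`, `stratum`.
#' @export
derive_weights <- function(records, snp_table, stratum = NA_character_) {
  zero <- records$beta == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " association(s) with beta = 0")
    records <- records[!zero, , drop = FALSE]
  }
  idx <- match(records$snp_id, snp_table$snp_id)
  if (anyNA(idx))
    stop("records reference SNPs absent from snp_table: ",
         paste(utils::head(records$snp_id[is.na(idx)], 5), collapse = ", "))
  out <- data.frame(
    snp_id = records$snp_id,
    transcript = records$probe_id,
    sensitive_allele = ifelse(records$beta > 0, snp_table$alt[idx],
                              snp_table$ref[idx]),
    weight = abs(records$beta),
    stratum = stratum, stringsAsFactors = FALSE)
  class(out) <- c("tsps_weights", "data.frame")
  out
}

#' Substitute proxy SNPs for weights unavailable in a test cohort
#'
#' Each weight SNP absent from `available_snps` is replaced by the
#' available SNP with the highest r-squared above `r2_min`; otherwise the
#' association is dropped. Allele orientation is propagated through the
#' signed LD correlation when the LD table has an `r` column; otherwise it
#' falls back to allele-frequency matching via `snp_table$alt_freq`, and as
#' a last resort keeps the original orientation with a warning (a logged
#' caveat, since phase is then unknown).
#'
#' @param weights a [derive_weights()] table.
#' @param available_snps character vector of SNP ids present in the test
#'   cohort.
#' @param ld data.frame with `snp_a`, `snp_b`, `r2`, optional signed `r`.
#' @param snp_table SNP table covering originals and proxies (`snp_id`,
#'   `ref`, `alt`, optionally `alt_freq`).
#' @param r2_min proxy threshold, strict (default 0.6).
#' @return the weights table with proxies substituted, a `proxy_for`
#'   column, and `attr(, "report")` = named counts
#'   `(n_direct, n_proxy, n_dropped)`.
#' @export
substitute_proxies <- function(weights, available_snps, ld,
                               snp_table = NULL, r2_min = 0.6) {
  weights$proxy_for <- NA_character_
  direct <- weights$snp_id %in% available_snps
  keep <- rep(TRUE, nrow(weights))
  n_proxy <- 0L
  freq_warned <- FALSE
  for (i in which(!direct)) {
    snp <- weights$snp_id[i]
    cand <- ld[(ld$snp_a == snp & ld$snp_b %in% available_snps) |
                 (ld$snp_b == snp & ld$snp_a %in% available_snps), ,
               drop = FALSE]
    cand <- cand[cand$r2 > r2_min, , drop = FALSE]
    if (nrow(cand) == 0) { keep[i] <- FALSE; next }
    best <- cand[order(-cand$r2, cand$snp_a, cand$snp_b)[1], , drop = FALSE]
    proxy <- if (best$snp_a == snp) best$snp_b else best$snp_a
    n_proxy <- n_proxy + 1L
    orig <- weights$snp_id[i]
    sens_is_alt <- !is.null(snp_table) &&
      weights$sensitive_allele[i] ==
      snp_table$alt[match(orig, snp_table$snp_id)]
    if ("r" %in% names(ld) && !is.na(best$r)) {
      # signed correlation of alt dosages: r > 0 means the proxy's alt
      # allele tracks the original's alt allele
      proxy_sens_alt <- if (best$r > 0) sens_is_alt else !sens_is_alt
    } else if (!is.null(snp_table) && "alt_freq" %in% names(snp_table)) {
      f_orig <- snp_table$alt_freq[match(orig, snp_table$snp_id)]
      f_sens <- if (sens_is_alt) f_orig else 1 - f_orig
      f_proxy_alt <- snp_table$alt_freq[match(proxy, snp_table$snp_id)]
      proxy_sens_alt <- abs(f_proxy_alt - f_sens) <=
        abs((1 - f_proxy_alt) - f_sens)
    } else {
      if (!freq_warned) {
        warning("no signed LD or allele frequencies; keeping original ",
                "allele orientation for proxies")
        freq_warned <- TRUE
      }
      proxy_sens_alt <- sens_is_alt
    }
    if (!is.null(snp_table)) {
      pr <- match(proxy, snp_table$snp_id)
      weights$sensitive_allele[i] <- if (proxy_sens_alt)
        snp_table$alt[pr] else snp_table$ref[pr]
    }
    weights$proxy_for[i] <- orig
    weights$snp_id[i] <- proxy
  }
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- c(n_direct = sum(direct),
                           n_proxy = n_proxy,
                           n_dropped = sum(!keep))
  out
}

#' Compute per-individual transcriptional sensitivity profile scores
#'
#' `score_i = sum over associations of (sensitive-allele dosage_i x weight)`
#' divided by the number of associations (the default correction for the
#' number of SNPs; `normalize = "snps"` divides by the number of unique
#' SNPs instead). The sensitive-allele dosage is the stored dosage when the
#' sensitive allele is the counted (alt) allele and `2 - dosage` otherwise.
#' A higher score denotes more alleles associated with a larger
#' GR-stimulated transcriptional response.
#'
#' @param genotypes a `genotype_matrix` containing every weight SNP.
#' @param weights a [derive_weights()] (possibly proxy-substituted) table.
#' @param normalize `"associations"` (default) or `"snps"`.
#' @return data.frame of class `score_vector` with `sample_id`, `score`,
#'   and attributes `n_associations`, `n_snps`.
#' @export
compute_tsps <- function(genotypes, weights,
                         normalize = c("associations", "snps")) {
  normalize <- match.arg(normalize)
  missing <- setdiff(weights$snp_id, colnames(genotypes$dosages))
  if (length(missing) > 0)
    stop("weight SNPs missing from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dos <- genotypes$dosages[, weights$snp_id, drop = FALSE]
  if (anyNA(dos)) stop("missing dosages; impute upstream")
  alt <- genotypes$snp_table$alt[match(weights$snp_id,
                                       genotypes$snp_table$snp_id)]
  sens_is_alt <- weights$sensitive_allele == alt
  sdos <- sweep(dos, 2, ifelse(sens_is_alt, 0, 2), function(d, k)
    abs(k - d))
  denom <- if (normalize == "associations") nrow(weights)
  else length(unique(weights$snp_id))
  score <- as.numeric(sdos %*% weights$weight) / denom
  out <- data.frame(sample_id = rownames(dos), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "n_associations") <- nrow(weights)
  attr(out, "n_snps") <- length(unique(weights$snp_id))
  class(out) <- c("score_vector", "data.frame")
  out
}

# Nagelkerke pseudo R-squared of a fitted binomial glm.
.nagelkerke <- function(fit) {
  n <- length(fit$y)
  cox <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  cox / (1 - exp(-fit$null.deviance / n))
}

#' Associate a TSPS with a phenotype
#'
#' Logistic regression for a binary case/control status, OLS for a
#' continuous symptom score, of the phenotype on the score plus optional
#' covariates. Reports the score coefficient, its SE and p, and the
#' variance explained (Nagelkerke pseudo R-squared for the binary case,
#' partial R-squared otherwise). Strata are analysed by subsetting the
#' inputs before the call.
#'
#' @param scores a [compute_tsps()] result (or numeric vector named by
#'   sample).
#' @param phenotype numeric vector named by sample id (binary 0/1 or
#'   continuous).
#' @param covariates optional covariate table (columns other than
#'   `sample_id` enter the model).
#' @return list with `estimate`, `se`, `p`, `r2`, `family`, `n`.
#' @export
associate_tsps <- function(scores, phenotype, covariates = NULL) {
  s <- if (is.data.frame(scores))
    stats::setNames(scores$score, scores$sample_id) else scores
  ids <- intersect(names(s), names(phenotype))
  if (length(ids) == 0) {
    if (length(s) == length(phenotype)) ids <- seq_along(s)
    else stop("no shared samples between scores and phenotype")
  }
  y <- phenotype[ids]
  x <- s[ids]
  if (stats::sd(x) == 0) stop("score is constant; coefficient undefined")
  df <- data.frame(y = y, score = x)
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$sample_id),
                     setdiff(names(covariates), "sample_id"), drop = FALSE]
    df <- cbind(df, cv)
  }
  binary <- all(y %in% c(0, 1))
  if (binary && length(unique(y)) < 2L)
    stop("binary phenotype has a single class")
  if (binary) {
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    co <- summary(fit)$coefficients["score", ]
    r2 <- .nagelkerke(fit)
  } else {
    fit <- stats::lm(y ~ ., data = df)
    co <- summary(fit)$coefficients["score", ]
    fit0 <- stats::lm(y ~ . - score, data = df)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(stats::residuals(fit0)^2)
  }
  list(estimate = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
       r2 = r2, family = if (binary) "binomial" else "gaussian",
       n = length(ids))
}

#' Associate a TSPS with multiple symptom items
#'
#' Runs [associate_tsps()] over every column of an item matrix and attaches
#' BH-adjusted q values across items (nominal p values are reported
#' alongside).
#'
#' @param scores a [compute_tsps()] result.
#' @param items data.frame/matrix of item scores (columns = items), rows
#'   named by sample id.
#' @param covariates optional covariate table.
#' @return data.frame with `item`, `estimate`, `se`, `p`, `q`.
#' @export
associate_tsps_items <- function(scores, items, covariates = NULL) {
  rows <- lapply(colnames(items), function(it) {
    ph <- stats::setNames(items[, it], rownames(items))
    a <- associate_tsps(scores, ph, covariates)
    data.frame(item = it, estimate = a$estimate, se = a$se, p = a$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}
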