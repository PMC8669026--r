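# Synthetic-data module: genotypes with block LD, paired expression,
# methylation, covariates, annotation fixtures and case/control phenotypes
# with known ground truth.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort. Defaults emulate the
#' design the pipeline targets: a few hundred adults sampled at baseline and
#' three hours after 1.5 mg oral dexamethasone, imputed genotype dosages
#' filtered at MAF >= 5%, and sex-specific cis effects on the expression
#' change (a female-specific effect of 0.5 expression units per dosage unit
#' by default, none in males).
#'
#' @param n_individuals number of individuals.
#' @param sex_ratio fraction of females in `[0, 1]` (female coded 1, male 0).
#' @param n_snps number of SNPs.
#' @param n_probes number of expression probes (also used for CpGs).
#' @param maf_range length-2 target minor-allele-frequency range, within
#'   `[0.05, 0.5]` (variants below 5% MAF are excluded upstream by design).
#' @param ld_block_size SNPs per LD block.
#' @param ld_r2 target squared within-block dosage correlation in `[0, 1]`.
#' @param n_true_eqtls number of planted cis effects.
#' @param beta_gr_female,beta_gr_male planted effect sizes (expression units
#'   per dosage unit) on the post-minus-baseline change, per sex.
#' @param dex_effect_sd SD of the per-probe dexamethasone shift.
#' @param noise_sd residual SD on the normalized-expression scale.
#' @param n_surrogates number of surrogate covariates (3 by default).
#' @param seed master integer seed; fully determines all outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 289, sex_ratio = 93 / 289,
                       n_snps = 2000, n_probes = 300,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_r2 = 0.8, n_true_eqtls = 30,
                       beta_gr_female = 0.5, beta_gr_male = 0,
                       dex_effect_sd = 0.3, noise_sd = 0.3,
                       n_surrogates = 3, seed = 1L) {
  counts <- c(n_individuals = n_individuals, n_snps = n_snps,
              n_probes = n_probes, ld_block_size = ld_block_size)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12)
    stop("maf_range must be within [0.05, 0.5]")
  if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must be in [0, 1]")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (n_true_eqtls < 0 || n_surrogates < 0) stop("counts must be nonnegative")
  structure(list(n_individuals = as.integer(n_individuals),
                 sex_ratio = sex_ratio, n_snps = as.integer(n_snps),
                 n_probes = as.integer(n_probes), maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
                 n_true_eqtls = as.integer(n_true_eqtls),
                 beta_gr_female = beta_gr_female, beta_gr_male = beta_gr_male,
                 dex_effect_sd = dex_effect_sd, noise_sd = noise_sd,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(Z1 > t, Z2 > t) under a bivariate standard normal with correlation rho.
.binorm_upper <- function(rho, t) {
  if (rho >= 0.99999) return(stats::pnorm(t, lower.tail = FALSE))
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((rho * z - t) / sqrt(1 - rho^2)),
    lower = t, upper = Inf, rel.tol = 1e-9)$value
}

# Latent within-block correlation such that thresholded allele indicators at
# frequency `maf` realize a phi (hence dosage) correlation of sqrt(target_r2).
# Discretization attenuates correlation, so the latent value exceeds the
# target; solved numerically per block at its mean target MAF.
.latent_rho <- function(target_r2, maf) {
  if (target_r2 <= 0) return(0)
  target_phi <- sqrt(target_r2)
  t <- stats::qnorm(1 - maf)
  phi <- function(rho)
    (.binorm_upper(rho, t) - maf^2) / (maf * (1 - maf)) - target_phi
  upper <- 0.99995
  if (phi(upper) < 0) return(upper)
  stats::uniroot(phi, c(1e-8, upper), tol = 1e-7)$root
}

#' Simulate LD-structured genotype dosages
#'
#' Haplotype alleles are drawn from a latent equicorrelated Gaussian per LD
#' block and thresholded at the Hardy-Weinberg quantile of each SNP's target
#' MAF; the two haplotypes are summed into dosages in `{0, 1, 2}`. SNPs in
#' different blocks are independent. The latent correlation is calibrated so
#' the realized dosage r-squared matches `ld_r2` despite discretization.
#' Blocks alternate between two chromosomes; positions are strictly
#' increasing within a chromosome (5 kb SNP spacing, 50 kb between blocks).
#'
#' @param config a [sim_config()].
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (individuals x SNPs, dimnames set) and `snp_table` (`snp_id`, `chrom`,
#'   `pos` 1-based, `ref`, `alt`, `alt_freq`, observed folded `maf`, `block`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genotypes"), {
    n <- config$n_individuals
    m <- config$n_snps
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]
    chrom <- ifelse(block %% 2L == 1L, "chr1", "chr2")
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      b <- block[idx]
      block_no <- cumsum(c(0L, diff(b) != 0L))
      pos[idx] <- 100000L + seq_along(idx) * 5000L + block_no * 50000L
    }
    maf_target <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    dos <- matrix(0L, n, m)
    for (bi in unique(block)) {
      idx <- which(block == bi)
      rho <- .latent_rho(config$ld_r2, mean(maf_target[idx]))
      thr <- stats::qnorm(1 - maf_target[idx])
      acc <- matrix(0L, n, length(idx))
      for (hap in 1:2) {
        shared <- stats::rnorm(n)
        z <- sqrt(rho) * shared +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(idx)), n)
        acc <- acc + (t(t(z) > thr)) * 1L
      }
      dos[, idx] <- acc
    }
    alt_freq <- colMeans(dos) / 2
    snp_id <- sprintf("snp%05d", seq_len(m))
    dimnames(dos) <- list(sprintf("S%04d", seq_len(n)), snp_id)
    snp_table <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      ref = "A", alt = "G", alt_freq = alt_freq,
      maf = pmin(alt_freq, 1 - alt_freq), block = block,
      stringsAsFactors = FALSE)
    structure(list(dosages = dos, snp_table = snp_table),
              class = "genotype_matrix")
  })
}

#' Simulate the covariate table
#'
#' One row per sample: `sex` (female = 1, male = 0; the stratification label
#' used throughout), `age` in years, `bmi` in kg/m2, `status` (case = 1),
#' and `n_surrogates` continuous surrogate covariates standing in for
#' cellular heterogeneity and batch.
#'
#' @param config a [sim_config()].
#' @return a data.frame with `sample_id` and covariate columns, no missing
#'   values.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "covariates"), {
    n <- config$n_individuals
    n_f <- round(n * config$sex_ratio)
    sex <- sample(c(rep(1L, n_f), rep(0L, n - n_f)))
    cov <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      sex = sex,
      age = round(pmax(18, stats::rnorm(n, 43, 13)), 1),
      bmi = round(pmax(16, stats::rnorm(n, 25, 4)), 1),
      status = stats::rbinom(n, 1L, 0.45),
      stringsAsFactors = FALSE)
    if (config$n_surrogates > 0) {
      sv <- matrix(stats::rnorm(n * config$n_surrogates), n)
      colnames(sv) <- paste0("sv", seq_len(config$n_surrogates))
      cov <- cbind(cov, as.data.frame(sv))
    }
    cov
  })
}

#' Place expression probes along the simulated genome
#'
#' Probe positions are locus midpoints, one locus per probe, drawn uniformly
#' over the span of each chromosome's SNPs. Deterministic given the config
#' seed, so every caller reconstructs the same table.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param config the matching [sim_config()].
#' @param prefix feature id prefix (`"probe"` or `"cpg"`).
#' @param stream child seed stream label.
#' @return data.frame with `probe_id`, `chrom`, `pos` (1-based).
#' @export
make_probe_table <- function(genotypes, config, prefix = "probe",
                             stream = "probes") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, stream), {
    st <- genotypes$snp_table
    np <- config$n_probes
    chrs <- unique(st$chrom)
    chr <- sample(chrs, np, replace = TRUE)
    pos <- integer(np)
    for (ch in chrs) {
      k <- sum(chr == ch)
      if (k == 0) next
      rng <- range(st$pos[st$chrom == ch])
      pos[chr == ch] <- as.integer(round(stats::runif(k, rng[1], rng[2])))
    }
    ord <- order(chr, pos)
    data.frame(probe_id = sprintf("%s%04d", prefix, seq_len(np)),
               chrom = chr[ord], pos = pos[ord], stringsAsFactors = FALSE)
  })
}

#' Build the ground-truth table of planted cis effects
#'
#' Chooses `n_true_eqtls` distinct features, each paired with one SNP within
#' 1 Mb, and records the planted female and male effect sizes. `acts_on`
#' says whether the effect enters the baseline level or the
#' post-minus-baseline change.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param config the matching [sim_config()].
#' @param probe_table feature table; defaults to [make_probe_table()].
#' @param acts_on `"delta"` (default) or `"baseline"`.
#' @return data.frame with `snp_id`, `probe_id`, `beta_female`, `beta_male`,
#'   `acts_on`.
#' @export
make_truth_table <- function(genotypes, config,
                             probe_table = make_probe_table(genotypes, config),
                             acts_on = c("delta", "baseline")) {
  acts_on <- match.arg(acts_on)
  if (config$n_true_eqtls == 0)
    return(data.frame(snp_id = character(), probe_id = character(),
                      beta_female = numeric(), beta_male = numeric(),
                      acts_on = character(), stringsAsFactors = FALSE))
  with_seed(child_seed(config$seed, "truth"), {
    pairs <- enumerate_cis_pairs(genotypes$snp_table, probe_table)
    eligible <- unique(pairs$probe_id)
    if (length(eligible) < config$n_true_eqtls)
      stop("fewer probes with cis SNPs (", length(eligible),
           ") than n_true_eqtls (", config$n_true_eqtls, ")")
    probes <- sample(eligible, config$n_true_eqtls)
    snp <- vapply(probes, function(p) {
      cand <- pairs$snp_id[pairs$probe_id == p]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    data.frame(snp_id = unname(snp), probe_id = probes,
               beta_female = config$beta_gr_female,
               beta_male = config$beta_gr_male,
               acts_on = acts_on, stringsAsFactors = FALSE, row.names = NULL)
  })
}

.check_truth <- function(truth, snp_ids, feature_ids) {
  bad_snp <- !(truth$snp_id %in% snp_ids)
  bad_probe <- !(truth$probe_id %in% feature_ids)
  if (any(bad_snp | bad_probe)) {
    i <- which(bad_snp | bad_probe)[1]
    stop("truth entry ", i, " references unknown ",
         if (bad_snp[i]) paste0("SNP '", truth$snp_id[i], "'")
         else paste0("feature '", truth$probe_id[i], "'"))
  }
}

# Per-sample genetic effect for one truth row, chosen by each sample's sex.
.genetic_effect <- function(truth_row, dosages, sex) {
  b <- ifelse(sex == 1L, truth_row$beta_female, truth_row$beta_male)
  b * dosages[, truth_row$snp_id]
}

# Centered/scaled covariate design used by the generative models (constant
# columns are centered only, so all-equal covariates contribute nothing).
.gen_design <- function(covariates) {
  num <- covariates[, setdiff(names(covariates), "sample_id"), drop = FALSE]
  X <- vapply(num, function(x) {
    s <- stats::sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  }, numeric(nrow(num)))
  matrix(X, nrow = nrow(num), dimnames = list(covariates$sample_id,
                                              colnames(num)))
}

#' Simulate paired baseline / post-dexamethasone expression
#'
#' Baseline is probe intercept + per-probe covariate effects +
#' baseline-acting genetic effects + Gaussian noise; post adds a per-probe
#' dexamethasone shift (SD `dex_effect_sd`) and the sex-specific
#' delta-acting genetic effects from the truth table, with independent
#' noise. Values are on an already-normalized log2-like scale. The realized
#' per-probe shift is attached as `attr(, "dex_shift")` for
#' parameter-recovery checks.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param covariates a [simulate_covariates()] table (same samples).
#' @param truth a [make_truth_table()] table (may be empty).
#' @param config the matching [sim_config()].
#' @param probe_table feature table; defaults to [make_probe_table()].
#' @return an object of class `expression_pair`: list with `baseline` and
#'   `post` (probes x samples) and `probe_table`.
#' @export
simulate_expression <- function(genotypes, covariates, truth, config,
                                probe_table = make_probe_table(genotypes,
                                                               config)) {
  stopifnot(inherits(config, "sim_config"))
  .check_truth(truth, genotypes$snp_table$snp_id, probe_table$probe_id)
  with_seed(child_seed(config$seed, "expression"), {
    n <- nrow(covariates)
    np <- nrow(probe_table)
    X <- .gen_design(covariates)
    mu <- stats::rnorm(np, 8, 1.5)
    coefs <- matrix(stats::rnorm(np * ncol(X), 0, 0.1), np)
    signal <- matrix(mu, np, n) + coefs %*% t(X)
    dimnames(signal) <- list(probe_table$probe_id, covariates$sample_id)
    for (i in seq_len(nrow(truth)))
      if (truth$acts_on[i] == "baseline")
        signal[truth$probe_id[i], ] <- signal[truth$probe_id[i], ] +
          .genetic_effect(truth[i, ], genotypes$dosages, covariates$sex)
    dex_shift <- stats::rnorm(np, 0, config$dex_effect_sd)
    names(dex_shift) <- probe_table$probe_id
    post_signal <- signal + dex_shift
    for (i in seq_len(nrow(truth)))
      if (truth$acts_on[i] == "delta")
        post_signal[truth$probe_id[i], ] <- post_signal[truth$probe_id[i], ] +
          .genetic_effect(truth[i, ], genotypes$dosages, covariates$sex)
    baseline <- signal + matrix(stats::rnorm(np * n, 0, config$noise_sd), np)
    post <- post_signal + matrix(stats::rnorm(np * n, 0, config$noise_sd), np)
    structure(list(baseline = baseline, post = post,
                   probe_table = probe_table),
              class = "expression_pair", dex_shift = dex_shift)
  })
}

#' Simulate CpG methylation beta values
#'
#' A linear model on the logit scale (CpG intercept + covariate effects +
#' genetic effects from the truth table + Gaussian noise) mapped through the
#' inverse logit, so all betas lie strictly in (0, 1). Truth `beta_*` values
#' are on the logit scale; `probe_id` must reference CpG ids.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param covariates a [simulate_covariates()] table.
#' @param truth truth table referencing CpG ids (may be empty).
#' @param config the matching [sim_config()].
#' @param cpg_table CpG table; defaults to a `"cpgs"`-stream
#'   [make_probe_table()] with prefix `"cpg"`.
#' @return an object of class `methylation_matrix`: list with `betas`
#'   (CpGs x samples, values in (0, 1)) and `cpg_table`.
#' @export
simulate_methylation <- function(genotypes, covariates, truth, config,
                                 cpg_table = make_probe_table(
                                   genotypes, config, prefix = "cpg",
                                   stream = "cpgs")) {
  stopifnot(inherits(config, "sim_config"))
  .check_truth(truth, genotypes$snp_table$snp_id, cpg_table$probe_id)
  with_seed(child_seed(config$seed, "methylation"), {
    n <- nrow(covariates)
    nc <- nrow(cpg_table)
    X <- .gen_design(covariates)
    mu <- stats::rnorm(nc, 0, 1.5)
    coefs <- matrix(stats::rnorm(nc * ncol(X), 0, 0.05), nc)
    lo <- matrix(mu, nc, n) + coefs %*% t(X)
    dimnames(lo) <- list(cpg_table$probe_id, covariates$sample_id)
    for (i in seq_len(nrow(truth)))
      lo[truth$probe_id[i], ] <- lo[truth$probe_id[i], ] +
        .genetic_effect(truth[i, ], genotypes$dosages, covariates$sex)
    lo <- lo + matrix(stats::rnorm(nc * n, 0, config$noise_sd), nc)
    structure(list(betas = stats::plogis(lo),
                   cpg_table = stats::setNames(cpg_table, c("cpg_id", "chrom",
                                                            "pos"))),
              class = "methylation_matrix")
  })
}

#' Construct an annotation interval fixture with known enrichment
#'
#' Emits a BED-convention interval set (0-based, half-open) plus a
#' designated target SNP subset such that the expected in-interval fraction
#' is `enriched_fraction` for targets and `background_fraction` for the
#' rest. A 51-bp interval is laid over each covered SNP; with >= 500 bp SNP
#' spacing no interval reaches a neighbouring SNP, so construction fractions
#' translate directly into downstream fold enrichments.
#'
#' @param snp_table SNP table (`snp_id`, `chrom`, `pos` 1-based).
#' @param enriched_fraction coverage probability for target SNPs, in
#'   `[0, 1]`.
#' @param background_fraction coverage probability for the rest, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param targets optional character vector of target SNP ids; by default a
#'   random 10% of `snp_table`.
#' @return list with `intervals` (data.frame `chrom`, `start`, `end`,
#'   `name`) and `targets` (character).
#' @export
make_annotation_fixtures <- function(snp_table, enriched_fraction,
                                     background_fraction, seed,
                                     targets = NULL) {
  if (enriched_fraction < 0 || enriched_fraction > 1 ||
      background_fraction < 0 || background_fraction > 1)
    stop("fractions must be in [0, 1]")
  with_seed(seed, {
    if (is.null(targets))
      targets <- sample(snp_table$snp_id,
                        max(1L, round(0.1 * nrow(snp_table))))
    is_target <- snp_table$snp_id %in% targets
    covered <- stats::runif(nrow(snp_table)) <
      ifelse(is_target, enriched_fraction, background_fraction)
    iv <- data.frame(chrom = snp_table$chrom[covered],
                     start = snp_table$pos[covered] - 26L,
                     end = snp_table$pos[covered] + 25L,
                     name = "fixture", stringsAsFactors = FALSE)
    iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    list(intervals = iv, targets = targets)
  })
}

#' Simulate a case/control phenotype from a score
#'
#' Bernoulli draws from a logistic model on the standardized score:
#' `logit P(case) = qlogis(base_rate) + effect * z(score)`.
#'
#' @param scores numeric score vector or a [compute_tsps()] result.
#' @param effect log-odds per score SD.
#' @param base_rate baseline case rate, strictly inside (0, 1).
#' @param seed integer seed.
#' @return integer 0/1 phenotype vector (named if scores were named).
#' @export
simulate_case_control <- function(scores, effect, base_rate, seed) {
  if (is.data.frame(scores)) {
    s <- stats::setNames(scores$score, scores$sample_id)
  } else s <- scores
  if (base_rate <= 0 || base_rate >= 1) stop("base_rate must be in (0, 1)")
  z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  with_seed(seed, {
    p <- stats::plogis(stats::qlogis(base_rate) + effect * z)
    stats::setNames(stats::rbinom(length(s), 1L, p), names(s))
  })
}
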