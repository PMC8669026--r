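# Synthetic-data generators: determinism, allele-frequency and LD targets,
# and ground-truth recovery by independent oracles.

test_that("identical config and seed give bitwise-identical outputs", {
  cfg <- small_config(seed = 9)
  a <- small_cohort(cfg)
  b <- small_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$expr$baseline, b$expr$baseline)
  expect_identical(a$expr$post, b$expr$post)
  expect_identical(a$truth, b$truth)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(maf_range = c(0.01, 0.4)), "maf_range")
  expect_error(sim_config(ld_r2 = 1.5), "ld_r2")
  expect_error(sim_config(n_individuals = 0), "positive")
})

test_that("symmetric MAF gives mean dosage near 1", {
  cfg <- sim_config(n_individuals = 10000, n_snps = 12, n_probes = 5,
                    maf_range = c(0.5, 0.5), ld_block_size = 4, ld_r2 = 0,
                    seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(colMeans(g$dosages) - 1) < 0.03))
})

test_that("zero ld_r2 gives independent SNPs within blocks", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 20, n_probes = 5,
                    ld_block_size = 10, ld_r2 = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  r2 <- unlist(lapply(unique(g$snp_table$block), function(b) {
    cc <- cor(g$dosages[, g$snp_table$block == b])^2
    cc[upper.tri(cc)]
  }))
  expect_lt(mean(r2), 0.02)
})

test_that("within-block dosage r2 recovers the ld_r2 target", {
  # empirical-correlation oracle at matched MAFs (r2 between unequal-MAF
  # binary variables is capped below the latent target)
  cfg <- sim_config(n_individuals = 5000, n_snps = 20, n_probes = 5,
                    ld_block_size = 5, ld_r2 = 0.8,
                    maf_range = c(0.3, 0.3), seed = 7)
  g <- simulate_genotypes(cfg)
  r2 <- unlist(lapply(unique(g$snp_table$block), function(b) {
    cc <- cor(g$dosages[, g$snp_table$block == b])^2
    cc[upper.tri(cc)]
  }))
  expect_lt(abs(mean(r2) - 0.8), 0.1)
})

test_that("unlinked genotype frequencies respect Hardy-Weinberg", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 10, n_probes = 5,
                    ld_block_size = 1, ld_r2 = 0, maf_range = c(0.2, 0.4),
                    seed = 11)
  g <- simulate_genotypes(cfg)
  pvals <- vapply(seq_len(cfg$n_snps), function(j) {
    d <- g$dosages[, j]
    q <- mean(d) / 2
    expected <- 5000 * c((1 - q)^2, 2 * q * (1 - q), q^2)
    observed <- tabulate(d + 1L, 3L)
    suppressWarnings(chisq.test(observed, p = expected / sum(expected)))$p.value
  }, numeric(1))
  expect_gt(min(pvals), 1e-4)
})

test_that("truth entries referencing unknown ids are rejected by name", {
  co <- small_cohort()
  bad <- co$truth
  bad$snp_id[1] <- "nope"
  expect_error(
    simulate_expression(co$genotypes, co$covariates, bad, co$cfg, co$probes),
    "nope")
})

test_that("null generator gives near-zero expression change", {
  cfg <- small_config(n_true_eqtls = 0, dex_effect_sd = 0, seed = 21,
                      n_individuals = 300)
  co <- small_cohort(cfg)
  d <- co$expr$post - co$expr$baseline
  # delta noise SD is sqrt(2) * noise_sd; per-probe mean has SE ~ 0.025
  expect_true(all(abs(rowMeans(d)) < 0.1))
})

test_that("per-probe mean change recovers the dexamethasone shift", {
  cfg <- small_config(n_individuals = 2000, n_true_eqtls = 0,
                      noise_sd = 0.1, dex_effect_sd = 1, seed = 23)
  co <- small_cohort(cfg)
  shift <- attr(co$expr, "dex_shift")
  d <- rowMeans(co$expr$post - co$expr$baseline)
  expect_true(all(abs(d - shift[names(d)]) < 0.01))
})

test_that("independent OLS oracle recovers sex-specific planted effects", {
  cfg <- small_config(n_individuals = 2000, n_true_eqtls = 1,
                      beta_gr_female = 0.5, beta_gr_male = 0, seed = 31)
  co <- small_cohort(cfg)
  d <- co$expr$post - co$expr$baseline
  tr <- co$truth[1, ]
  for (sx in c(1L, 0L)) {
    ids <- co$covariates$sample_id[co$covariates$sex == sx]
    fit <- lm(d[tr$probe_id, ids] ~ co$genotypes$dosages[ids, tr$snp_id])
    truth_beta <- if (sx == 1L) 0.5 else 0
    expect_lt(abs(coef(fit)[2] - truth_beta), 0.05)
  }
})

test_that("planted effects are recovered within 3 SE across many seeds", {
  ok <- vapply(1:100, function(s) {
    cfg <- small_config(n_individuals = 250, n_snps = 20, n_probes = 8,
                        n_true_eqtls = 1, beta_gr_female = 0.5,
                        beta_gr_male = 0.5, seed = 1000 + s)
    co <- small_cohort(cfg)
    d <- co$expr$post - co$expr$baseline
    tr <- co$truth[1, ]
    fit <- summary(lm(d[tr$probe_id, co$covariates$sample_id] ~
                        co$genotypes$dosages[co$covariates$sample_id,
                                             tr$snp_id]))$coefficients
    abs(fit[2, 1] - 0.5) <= 3 * fit[2, 2]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("methylation betas stay in (0,1) and recover planted effects", {
  cfg <- small_config(n_individuals = 2000, n_true_eqtls = 2,
                      beta_gr_female = 1, beta_gr_male = 1, seed = 41)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  cpgs <- make_probe_table(g, cfg, prefix = "cpg", stream = "cpgs")
  truth <- make_truth_table(g, cfg, cpgs)
  meth <- simulate_methylation(g, cov, truth, cfg, cpgs)
  expect_true(all(meth$betas > 0 & meth$betas < 1))
  tr <- truth[1, ]
  fit <- summary(lm(meth$betas[tr$probe_id, cov$sample_id] ~
                      g$dosages[cov$sample_id, tr$snp_id]))$coefficients
  expect_gt(fit[2, 1], 0)       # logit beta = +1 implies positive slope
  expect_lt(fit[2, 4], 1e-6)
  # null CpGs: dosage slopes centered on zero
  null_cpg <- setdiff(rownames(meth$betas), truth$probe_id)[1:5]
  slopes <- vapply(null_cpg, function(cg)
    coef(lm(meth$betas[cg, cov$sample_id] ~
              g$dosages[cov$sample_id, tr$snp_id]))[2], numeric(1))
  expect_lt(abs(mean(slopes)), 0.01)
})

test_that("degenerate methylation (no effects, no noise) is constant", {
  cfg <- small_config(n_individuals = 50, n_true_eqtls = 0, noise_sd = 0,
                      seed = 43)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  cov$age <- 40; cov$bmi <- 25; cov$status <- 0L
  cov[grep("^sv", names(cov))] <- 0
  cov$sex <- 0L
  truth <- make_truth_table(g, sim_config(n_true_eqtls = 0, seed = 1))
  meth <- simulate_methylation(g, cov, truth, cfg)
  expect_true(all(apply(meth$betas, 1, sd) < 1e-12))
})

test_that("annotation fixtures realize their construction fractions", {
  co <- small_cohort(small_config(n_snps = 200, seed = 51))
  st <- co$genotypes$snp_table
  fx <- make_annotation_fixtures(st, enriched_fraction = 0,
                                 background_fraction = 0.1, seed = 2)
  tgt <- st[st$snp_id %in% fx$targets, ]
  expect_identical(interval_overlap(tgt, fx$intervals)$n_inside, 0L)
  fx2 <- make_annotation_fixtures(st, enriched_fraction = 1,
                                  background_fraction = 0, seed = 2)
  tgt2 <- st[st$snp_id %in% fx2$targets, ]
  expect_identical(interval_overlap(tgt2, fx2$intervals)$n_inside,
                   nrow(tgt2))
  expect_error(make_annotation_fixtures(st, 1.2, 0.1, 1), "fractions")
})

test_that("case/control simulation matches its logistic model", {
  s <- rnorm(4000)
  y0 <- simulate_case_control(s, effect = 0, base_rate = 0.3, seed = 5)
  expect_lt(abs(mean(y0) - 0.3), 0.03)
  expect_gt(summary(glm(y0 ~ s, family = binomial()))$coefficients[2, 4],
            0.01)
  # saturating effect: status = indicator(score above median)
  yinf <- simulate_case_control(s, effect = 1e8, base_rate = 0.5, seed = 5)
  expect_gt(mean(yinf == (s > median(s))), 0.99)
  expect_error(simulate_case_control(s, 1, base_rate = 0, seed = 1),
               "base_rate")
})
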