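# cis pairing, residualization, nominal scan, maxT permutations, clumping
# and the probe-level FDR stage.

test_that("cis window boundary is 1 Mb inclusive", {
  st <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                   pos = c(1000001L, 1000002L))
  pt <- data.frame(probe_id = "p", chrom = "chr1", pos = 1L)
  pr <- enumerate_cis_pairs(st, pt)
  expect_identical(pr$snp_id, "a")
  expect_identical(pr$distance, 1000000L)
})

test_that("chromosome name mismatch is reported", {
  st <- data.frame(snp_id = "a", chrom = "chr1", pos = 1L)
  pt <- data.frame(probe_id = "p", chrom = "1", pos = 1L)
  expect_error(enumerate_cis_pairs(st, pt), "chr1")
})

test_that("pairing equals a brute-force double loop", {
  set.seed(5)
  st <- data.frame(snp_id = sprintf("s%03d", 1:200),
                   chrom = sample(c("chr1", "chr2"), 200, TRUE),
                   pos = sample.int(3e6, 200))
  pt <- data.frame(probe_id = sprintf("p%02d", 1:50),
                   chrom = sample(c("chr1", "chr2"), 50, TRUE),
                   pos = sample.int(3e6, 50))
  got <- enumerate_cis_pairs(st, pt)
  want <- do.call(rbind, lapply(seq_len(50), function(i)
    do.call(rbind, lapply(seq_len(200), function(j) {
      if (st$chrom[j] == pt$chrom[i] && abs(st$pos[j] - pt$pos[i]) <= 1e6)
        data.frame(snp_id = st$snp_id[j], probe_id = pt$probe_id[i])
      else NULL
    }))))
  key <- function(d) sort(paste(d$snp_id, d$probe_id))
  expect_identical(key(got), key(want))
  expect_false(any(duplicated(paste(got$snp_id, got$probe_id))))
})

test_that("make_phenotype residuals match a QR oracle and are centered", {
  co <- small_cohort(small_config(n_probes = 50, seed = 81))
  d <- compute_delta(co$expr)
  phen <- make_phenotype(d, co$covariates, "all")
  expect_lt(max(abs(rowMeans(phen))), 1e-10)
  cv <- co$covariates
  for (pb in rownames(phen)[1:10]) {
    oracle <- residuals(lm(d$delta[pb, cv$sample_id] ~ sex + age + bmi +
                             status + sv1 + sv2 + sv3, data = cv))
    expect_equal(unname(phen[pb, ]), unname(oracle), tolerance = 1e-10)
  }
  # phenotype exactly linear in a covariate leaves ~zero residuals
  lin <- matrix(2 * cv$age + 1, 1, nrow(cv),
                dimnames = list("f1", cv$sample_id))
  expect_lt(max(abs(make_phenotype(lin, cv, "all"))), 1e-8)
})

test_that("collinear covariates are reported by name", {
  co <- small_cohort()
  cv <- co$covariates
  cv$age2 <- 2 * cv$age
  d <- compute_delta(co$expr)
  expect_error(
    make_phenotype(d, cv, "all",
                   covariate_cols = c("age", "age2", "bmi")),
    "age2")
})

test_that("scan_cis recovers an injected slope and matches lm", {
  set.seed(91)
  n <- 500
  g <- manual_genotypes(matrix(rbinom(n * 3, 2, 0.3), n, 3))
  y <- 0.4 * g$dosages[, 2] + rnorm(n, 0, 0.2)
  phen <- matrix(y - mean(y), 1, n,
                 dimnames = list("p1", rownames(g$dosages)))
  pairing <- data.frame(snp_id = colnames(g$dosages), probe_id = "p1")
  rec <- scan_cis(phen, g, pairing)
  expect_lt(abs(rec$beta[rec$snp_id == "s02"] - 0.4), 0.08)
  for (j in 1:3) {
    fit <- summary(lm(phen[1, ] ~ g$dosages[, j]))$coefficients
    expect_equal(rec$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(rec$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("scan_cis p values are uniform for permuted genotypes", {
  set.seed(93)
  n <- 100
  g <- manual_genotypes(matrix(rbinom(n * 2000, 2, 0.3), n, 2000),
                        pos = seq_len(2000) * 10L)
  y <- rnorm(n)
  phen <- matrix(y, 1, n, dimnames = list("p1", rownames(g$dosages)))
  pairing <- data.frame(snp_id = colnames(g$dosages), probe_id = "p1")
  rec <- scan_cis(phen, g, pairing)
  expect_gt(ks.test(rec$p, "punif")$p.value, 0.01)
})

test_that("duplicated SNP columns give identical records; monomorphic drop", {
  set.seed(95)
  n <- 80
  dos <- cbind(a = rbinom(n, 2, 0.4), b = 0L)
  dos <- cbind(dos, c = dos[, "a"])
  g <- manual_genotypes(dos)
  phen <- matrix(rnorm(n), 1, n,
                 dimnames = list("p1", rownames(g$dosages)))
  pairing <- data.frame(snp_id = c("a", "b", "c"), probe_id = "p1")
  expect_message(rec <- scan_cis(phen, g, pairing), "monomorphic")
  expect_false("b" %in% rec$snp_id)
  expect_equal(rec$beta[rec$snp_id == "a"], rec$beta[rec$snp_id == "c"])
  expect_equal(rec$p[rec$snp_id == "a"], rec$p[rec$snp_id == "c"])
})

test_that("maxT adjusted p dominates the empirical p and is deterministic", {
  set.seed(97)
  n <- 60
  G <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  y <- rnorm(n) + 0.4 * G[, 3]
  a1 <- maxt_adjust(y, G, n_perm = 300, seed = 42)
  a2 <- maxt_adjust(y, G, n_perm = 300, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1$maxt_p >= a1$emp_p))
  expect_true(all(a1$emp_p > 0 & a1$maxt_p <= 1))
  expect_error(maxt_adjust(y, G, n_perm = 50), "at least 100")
})

test_that("maxT is invariant to SNP column order", {
  set.seed(99)
  n <- 50
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  y <- rnorm(n)
  a <- maxt_adjust(y, G, n_perm = 200, seed = 7)
  b <- maxt_adjust(y, G[, c(3, 1, 4, 2)], n_perm = 200, seed = 7)
  expect_equal(a[match(b$snp_id, a$snp_id), ], b, ignore_attr = TRUE)
})

test_that("single-SNP probes have maxT p equal to empirical p", {
  set.seed(101)
  n <- 40
  G <- matrix(rbinom(n, 2, 0.3), n, 1, dimnames = list(NULL, "s1"))
  a <- maxt_adjust(rnorm(n), G, n_perm = 500, seed = 3)
  expect_identical(a$emp_p, a$maxt_p)
})

test_that("exhaustive enumeration matches a per-permutation lm oracle", {
  # small version (6 samples); the full 8-sample check lives in the
  # acceptance suite
  set.seed(103)
  n <- 6
  G <- matrix(c(0, 1, 2, 0, 1, 2, 2, 1, 0, 1, 0, 2), n, 2,
              dimnames = list(NULL, c("s1", "s2")))
  y <- c(0.3, -1.2, 2.1, 0.4, -0.8, 1.5)
  a <- maxt_adjust(y, G, seed = 1, exhaustive = TRUE)
  P <- grqtl:::all_permutations(n)
  tstat <- function(yy, g) {
    f <- summary(lm(yy ~ g))$coefficients
    abs(f[2, 3])
  }
  obs <- vapply(1:2, function(j) tstat(y, G[, j]), numeric(1))
  tp <- apply(P, 1, function(pr)
    vapply(1:2, function(j) tstat(y[pr], G[, j]), numeric(1)))
  for (j in 1:2) {
    emp <- mean(tp[j, ] >= obs[j] - 1e-9)
    mxt <- mean(apply(tp, 2, max) >= obs[j] - 1e-9)
    expect_equal(a$emp_p[j], emp)
    expect_equal(a$maxt_p[j], mxt)
  }
})

test_that("clumping: independent SNPs each become their own tag", {
  set.seed(105)
  n <- 2000
  g <- manual_genotypes(matrix(rbinom(n * 6, 2, 0.3), n, 6))
  rec <- data.frame(snp_id = colnames(g$dosages), p = runif(6))
  bins <- clump_and_bin(rec, g)
  expect_true(all(bins$is_tag))
})

test_that("clumping: perfect LD collapses to one bin tagged by the best p", {
  set.seed(107)
  base <- rbinom(300, 2, 0.4)
  dos <- matrix(rep(base, 5), 300, 5)
  g <- manual_genotypes(dos)
  rec <- data.frame(snp_id = colnames(g$dosages),
                    p = c(0.4, 0.01, 0.2, 0.9, 0.5))
  bins <- clump_and_bin(rec, g)
  expect_equal(length(unique(bins$bin_id)), 1)
  expect_true(all(bins$tag_id == "s02"))
})

test_that("handcrafted two-block structure matches a greedy oracle", {
  set.seed(109)
  n <- 400
  b1 <- rbinom(n, 2, 0.3)
  b2 <- rbinom(n, 2, 0.4)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  dos <- cbind(a1 = b1, a2 = flip(b1, 15), a3 = flip(b1, 20),
               b1 = b2, b2 = flip(b2, 10), b3 = flip(b2, 25))
  g <- manual_genotypes(dos)
  rec <- data.frame(snp_id = colnames(dos), p = c(0.05, 0.01, 0.3,
                                                  0.2, 0.02, 0.6))
  bins <- clump_and_bin(rec, g)
  # independent greedy oracle
  r2 <- cor(dos)^2
  p <- rec$p
  names(p) <- rec$snp_id
  left <- names(sort(p))
  oracle <- list()
  while (length(left) > 0) {
    tag <- left[1]
    members <- left[r2[tag, left] > 0.2]
    oracle[[tag]] <- union(tag, members)
    left <- setdiff(left, oracle[[tag]])
  }
  for (tag in names(oracle))
    expect_setequal(bins$snp_id[bins$tag_id == tag], oracle[[tag]])
})

test_that("probe-level BH matches a hand oracle and flags significance", {
  g <- manual_genotypes(matrix(rbinom(300 * 10, 2, 0.3), 300, 10))
  rec <- data.frame(snp_id = colnames(g$dosages),
                    probe_id = "p1", p = seq(0.001, 0.01, by = 0.001),
                    maxt_p = seq(0.001, 0.01, by = 0.001))
  bins <- clump_and_bin(rec, g)
  out <- probe_level_fdr(rec, bins)
  expect_equal(sort(out$tags$q), sort(bh_oracle(rec$maxt_p)),
               tolerance = 1e-12)
  # all p = 1: nothing significant
  rec1 <- transform(rec, p = 1, maxt_p = 1)
  out1 <- probe_level_fdr(rec1, clump_and_bin(rec1, g))
  expect_equal(nrow(out1$significant), 0)
  # single tag at p = 0.04: q = 0.04, significant
  rec2 <- rec[1, ]
  rec2$p <- rec2$maxt_p <- 0.04
  out2 <- probe_level_fdr(rec2, clump_and_bin(rec2, g))
  expect_equal(out2$tags$q, 0.04)
  expect_equal(nrow(out2$significant), 1)
})

test_that("interaction scan recovers the sex-difference coefficient", {
  cfg <- small_config(n_individuals = 1000, n_true_eqtls = 1,
                      beta_gr_female = 0.5, beta_gr_male = 0, seed = 111)
  co <- small_cohort(cfg)
  d <- compute_delta(co$expr)
  pairing <- co$truth[, c("snp_id", "probe_id")]
  res <- interaction_scan(d, co$genotypes, co$covariates, pairing)
  # female = 1 coding: interaction = beta_female - beta_male = +0.5
  expect_lt(abs(res$estimate - 0.5), 0.1)
  expect_lt(res$p, 0.001)
  cv_f <- co$covariates[co$covariates$sex == 1, ]
  expect_error(interaction_scan(d, co$genotypes, cv_f, pairing), "both sexes")
})

test_that("interaction p values are calibrated when sexes share the effect", {
  cfg <- small_config(n_individuals = 400, n_probes = 40, n_true_eqtls = 10,
                      beta_gr_female = 0.4, beta_gr_male = 0.4, seed = 113)
  co <- small_cohort(cfg)
  d <- compute_delta(co$expr)
  res <- interaction_scan(d, co$genotypes, co$covariates,
                          co$truth[, c("snp_id", "probe_id")])
  expect_gt(min(res$p), 1e-3)   # no spurious strong interactions
})

test_that("meQTL scan finds planted effects with BH-only correction", {
  cfg <- small_config(n_individuals = 400, n_true_eqtls = 2,
                      beta_gr_female = 1.2, beta_gr_male = 1.2, seed = 115)
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  cpgs <- make_probe_table(g, cfg, prefix = "cpg", stream = "cpgs")
  truth <- make_truth_table(g, cfg, cpgs)
  meth <- simulate_methylation(g, cov, truth, cfg, cpgs)
  res <- scan_meqtl(meth, g, cov, stratum = "all")
  expect_true(all(c("q") %in% names(res$records)))
  key <- paste(res$significant$snp_id, res$significant$probe_id)
  expect_true(all(paste(truth$snp_id, truth$probe_id) %in% key))
})

test_that("eQTL/meQTL overlap counts intersections per stratum", {
  tags <- sprintf("rs%03d", 1:601)
  mesnps <- c(tags[1:317], sprintf("xx%03d", 1:50))
  ov <- overlap_eqtl_meqtl(tags, mesnps)
  expect_equal(ov$n_overlap, 317)
  expect_equal(ov$n_tags, 601)
  expect_equal(overlap_eqtl_meqtl(tags, character(0))$n_overlap, 0)
  expect_equal(overlap_eqtl_meqtl(tags, tags)$n_overlap, 601)
})
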