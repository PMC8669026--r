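# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

small_config <- function(seed = 1L, ...) {
  args <- list(n_individuals = 120, sex_ratio = 0.5, n_snps = 40,
               n_probes = 15, ld_block_size = 5, ld_r2 = 0.5,
               maf_range = c(0.2, 0.4), n_true_eqtls = 3,
               beta_gr_female = 0.5, beta_gr_male = 0, noise_sd = 0.3,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

small_cohort <- function(cfg = small_config()) {
  g <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  probes <- make_probe_table(g, cfg)
  truth <- make_truth_table(g, cfg, probes)
  expr <- simulate_expression(g, cov, truth, cfg, probes)
  list(cfg = cfg, genotypes = g, covariates = cov, probes = probes,
       truth = truth, expr = expr)
}

# Minimal hand-built genotype_matrix from an explicit dosage matrix.
manual_genotypes <- function(dos, chrom = "chr1",
                             pos = seq_len(ncol(dos)) * 1000L) {
  colnames(dos) <- colnames(dos) %||% sprintf("s%02d", seq_len(ncol(dos)))
  rownames(dos) <- rownames(dos) %||% sprintf("I%03d", seq_len(nrow(dos)))
  af <- colMeans(dos) / 2
  structure(list(
    dosages = dos,
    snp_table = data.frame(snp_id = colnames(dos), chrom = chrom, pos = pos,
                           ref = "A", alt = "G", alt_freq = af,
                           maf = pmin(af, 1 - af),
                           stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BH oracle: direct double loop over candidate thresholds.
bh_oracle <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi - 1e-15], function(t)
      n * t / sum(p <= t + 1e-15), numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Exact two-sided Fisher p by summation over the hypergeometric support.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  dens <- dhyper(lo:hi, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
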