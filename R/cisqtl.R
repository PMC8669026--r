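# cis-eQTL / cis-meQTL mapping with the two-stage multiple-testing
# correction: per-probe Westfall-Young maxT permutations, greedy LD clumping
# into tag-SNP bins, probe-level BH on tag records.

#' Enumerate cis SNP-feature pairs
#'
#' All and only pairs on the same chromosome with
#' `|snp_pos - probe_pos| <= window` (1-based inclusive; the 1 Mb default
#' means a distance of exactly 1,000,000 is paired).
#'
#' @param snp_table data.frame with `snp_id`, `chrom`, `pos`.
#' @param probe_table data.frame with `probe_id`, `chrom`, `pos`.
#' @param window cis window in bp (default 1e6).
#' @return data.frame with `snp_id`, `probe_id`, `distance` (signed,
#'   snp - probe); no duplicates.
#' @export
enumerate_cis_pairs <- function(snp_table, probe_table, window = 1e6) {
  shared <- intersect(unique(snp_table$chrom), unique(probe_table$chrom))
  if (length(shared) == 0)
    stop("no shared chromosome names between tables; SNP chromosomes: ",
         paste(unique(snp_table$chrom), collapse = ", "),
         "; probe chromosomes: ",
         paste(unique(probe_table$chrom), collapse = ", "))
  out <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    ch <- shared[k]
    s <- snp_table[snp_table$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    p <- probe_table[probe_table$chrom == ch, , drop = FALSE]
    lo <- findInterval(p$pos - window - 0.5, s$pos) + 1L
    hi <- findInterval(p$pos + window + 0.5, s$pos)
    keep <- hi >= lo
    if (!any(keep)) next
    idx <- which(keep)
    reps <- hi[idx] - lo[idx] + 1L
    si <- unlist(lapply(idx, function(i) lo[i]:hi[i]))
    out[[k]] <- data.frame(
      snp_id = s$snp_id[si],
      probe_id = rep(p$probe_id[idx], reps),
      distance = s$pos[si] - rep(p$pos[idx], reps),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), probe_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Residualize phenotypes on covariates
#'
#' Regresses every feature on the covariate design (with intercept) and
#' returns the residuals, which serve as the phenotype in the cis scans.
#' For the combined eQTL run the sex covariate is included; stratified runs
#' omit it and subset to the stratum's samples.
#'
#' @param phenotype a `delta_expression`, `methylation_matrix`, or a plain
#'   features x samples matrix with sample-id column names.
#' @param covariates covariate table.
#' @param stratum `"all"`, `"female"` or `"male"`.
#' @param covariate_cols covariate columns to regress out; default all
#'   non-id columns except `sex`, with `sex` added for `stratum = "all"`.
#' @return residual matrix (features x stratum samples), zero mean per
#'   feature, with attribute `stratum`.
#' @export
make_phenotype <- function(phenotype, covariates,
                           stratum = c("all", "female", "male"),
                           covariate_cols = NULL) {
  stratum <- match.arg(stratum)
  Y <- if (inherits(phenotype, "delta_expression")) phenotype$delta
  else if (inherits(phenotype, "methylation_matrix")) phenotype$betas
  else phenotype
  keep <- switch(stratum, all = rep(TRUE, nrow(covariates)),
                 female = covariates$sex == 1L, male = covariates$sex == 0L)
  cov_s <- covariates[keep, , drop = FALSE]
  if (is.null(covariate_cols)) {
    covariate_cols <- .covariate_cols(covariates)
    if (stratum == "all") covariate_cols <- c("sex", covariate_cols)
  }
  Y <- Y[, cov_s$sample_id, drop = FALSE]
  cov_s2 <- drop_constant_cols(cov_s[, c("sample_id", covariate_cols),
                                     drop = FALSE], keep = "sample_id")
  cols <- setdiff(names(cov_s2), "sample_id")
  X <- cbind(`(Intercept)` = 1, as.matrix(cov_s2[, cols, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  resid <- t(qr.resid(qx, t(Y)))
  dimnames(resid) <- dimnames(Y)
  attr(resid, "stratum") <- stratum
  resid
}

# Align a residual phenotype matrix and dosages on shared samples.
.align_samples <- function(phen, dosages) {
  samples <- colnames(phen)
  if (is.null(samples) || is.null(rownames(dosages)))
    stop("phenotype columns and dosage rows must carry sample ids")
  if (!all(samples %in% rownames(dosages)))
    stop("samples missing from genotype matrix: ",
         paste(utils::head(setdiff(samples, rownames(dosages)), 5),
               collapse = ", "))
  dosages[samples, , drop = FALSE]
}

#' Nominal cis association scan
#'
#' Per-pair OLS of the residual phenotype on allele dosage (slope, SE,
#' two-sided t-test p). Covariates are assumed already removed by
#' [make_phenotype()]. SNPs monomorphic within the analysed samples are
#' dropped with a message.
#'
#' @param phen residual phenotype matrix (features x samples).
#' @param genotypes a `genotype_matrix`.
#' @param pairing an [enumerate_cis_pairs()] table.
#' @return data.frame with `snp_id`, `probe_id`, `beta`, `se`, `t`, `p`.
#' @export
scan_cis <- function(phen, genotypes, pairing) {
  if (nrow(pairing) == 0) stop("empty cis pairing")
  dos <- .align_samples(phen, genotypes$dosages)
  n <- nrow(dos)
  gvar <- apply(dos, 2, stats::var)
  mono <- names(gvar)[gvar == 0]
  if (length(mono) > 0 && any(pairing$snp_id %in% mono)) {
    message("dropping ", sum(pairing$snp_id %in% mono),
            " pair(s) with monomorphic SNPs")
    pairing <- pairing[!(pairing$snp_id %in% mono), , drop = FALSE]
  }
  if (nrow(pairing) == 0) stop("no polymorphic cis pairs left")
  out <- vector("list", length(unique(pairing$probe_id)))
  names(out) <- unique(pairing$probe_id)
  for (pb in names(out)) {
    snps <- pairing$snp_id[pairing$probe_id == pb]
    y <- phen[pb, ]
    yc <- y - mean(y)
    G <- dos[, snps, drop = FALSE]
    Gc <- sweep(G, 2, colMeans(G))
    ss_g <- colSums(Gc^2)
    ss_y <- sum(yc^2)
    beta <- as.numeric(crossprod(Gc, yc)) / ss_g
    sigma2 <- pmax(ss_y - beta^2 * ss_g, 0) / (n - 2)
    se <- sqrt(sigma2 / ss_g)
    tval <- beta / se
    out[[pb]] <- data.frame(snp_id = snps, probe_id = pb, beta = beta,
                            se = se, t = tval,
                            p = 2 * stats::pt(-abs(tval), n - 2),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Westfall-Young maxT permutation correction for one cis region
#'
#' The phenotype vector is shuffled jointly across all SNPs of the probe,
#' preserving the LD structure of the genotypes. For each SNP,
#' `empirical p = (1 + #permutations with |t| >= observed |t|) / (1 + n_perm)`
#' and the maxT-adjusted p uses the maximum |t| over the probe's SNPs per
#' permutation, controlling family-wise error within the cis region. With
#' `exhaustive = TRUE` all `n!` phenotype orders are enumerated instead and
#' the p values are exact proportions over the full permutation group
#' (identity included). Since |t| is monotone in |r| at fixed sample size,
#' comparisons are made on |r| with a 1e-12 tolerance so exact permutation
#' ties count consistently.
#'
#' @param y residual phenotype vector for the probe.
#' @param G dosage matrix (samples x SNPs of the probe), column names = SNP
#'   ids.
#' @param n_perm number of random permutations (>= 100; desk-scale default
#'   10,000, larger values available by configuration).
#' @param seed integer seed; same seed gives identical p values.
#' @param exhaustive enumerate all permutations (sample sizes <= 9 only).
#' @return data.frame with `snp_id`, `t_obs`, `emp_p`, `maxt_p`; always
#'   `maxt_p >= emp_p`.
#' @export
maxt_adjust <- function(y, G, n_perm = 10000, seed = 1L, exhaustive = FALSE) {
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) >= 1)
  if (!exhaustive && n_perm < 100) stop("n_perm must be at least 100")
  if (exhaustive && n > 9) stop("exhaustive enumeration limited to n <= 9")
  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  Gc <- sweep(G, 2, colMeans(G))
  ss_g <- colSums(Gc^2)
  if (any(ss_g == 0)) stop("monomorphic SNP column in maxt_adjust")
  r_obs <- as.numeric(crossprod(Gc, yc)) / sqrt(ss_g * ss_y)
  t_obs <- r_obs * sqrt((n - 2) / pmax(1 - r_obs^2, .Machine$double.eps))
  if (exhaustive) {
    P <- all_permutations(n)
    Yp <- matrix(yc[t(P)], nrow = n)          # n x n! of permuted phenotypes
  } else {
    Yp <- with_seed(seed, {
      matrix(yc[replicate(n_perm, sample.int(n))], nrow = n)
    })
  }
  Rp <- abs(crossprod(Gc, Yp) / sqrt(ss_g %o% rep(ss_y, ncol(Yp))))
  tol <- 1e-12
  thresh <- abs(r_obs) - tol
  emp_ct <- rowSums(Rp >= thresh)
  mx <- Rp[1, ]
  if (nrow(Rp) > 1) for (k in 2:nrow(Rp)) mx <- pmax(mx, Rp[k, ])
  maxt_ct <- vapply(thresh, function(th) sum(mx >= th), numeric(1))
  denom <- if (exhaustive) ncol(Yp) else n_perm + 1
  num_off <- if (exhaustive) 0 else 1
  data.frame(snp_id = colnames(G) %||% paste0("snp", seq_along(r_obs)),
             t_obs = t_obs,
             emp_p = (num_off + emp_ct) / denom,
             maxt_p = (num_off + maxt_ct) / denom,
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping into tag-SNP bins
#'
#' SNP-level records are reduced to one row per SNP (best p). Greedily by
#' ascending p (ties broken by chromosome, position, then id), the best
#' remaining SNP becomes a tag and every unassigned SNP with dosage
#' `r^2 > r2_max` and distance `< window` on the same chromosome joins its
#' bin. Distinct tags are therefore pairwise correlated at `r^2 <= r2_max`.
#'
#' @param records association records with `snp_id` and `p` (and optionally
#'   `maxt_p`, preferred for ordering when present).
#' @param genotypes a `genotype_matrix` providing dosages and positions.
#' @param r2_max clumping threshold (default 0.2).
#' @param window clumping distance in bp (default 1e6, strict `<`).
#' @return data.frame with one row per SNP: `snp_id`, `chrom`, `pos`, `p`,
#'   `tag_id`, `bin_id`, `is_tag`. Empty input gives an empty table.
#' @export
clump_and_bin <- function(records, genotypes, r2_max = 0.2, window = 1e6) {
  if (nrow(records) == 0)
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), p = numeric(), tag_id = character(),
                      bin_id = integer(), is_tag = logical(),
                      stringsAsFactors = FALSE))
  pcol <- if ("maxt_p" %in% names(records) &&
              !all(is.na(records$maxt_p))) "maxt_p" else "p"
  agg <- stats::aggregate(records[[pcol]],
                          by = list(snp_id = records$snp_id), FUN = min)
  names(agg)[2] <- "p"
  st <- genotypes$snp_table
  agg <- merge(agg, st[, c("snp_id", "chrom", "pos")], by = "snp_id")
  agg <- agg[order(agg$p, agg$chrom, agg$pos, agg$snp_id), , drop = FALSE]
  dos <- genotypes$dosages[, agg$snp_id, drop = FALSE]
  m <- nrow(agg)
  tag_id <- character(m)
  bin_id <- integer(m)
  assigned <- logical(m)
  bin <- 0L
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    bin <- bin + 1L
    members <- i
    cand <- which(!assigned & agg$chrom == agg$chrom[i] &
                    abs(agg$pos - agg$pos[i]) < window)
    cand <- setdiff(cand, i)
    if (length(cand) > 0) {
      r2 <- as.numeric(stats::cor(dos[, i], dos[, cand, drop = FALSE]))^2
      members <- c(members, cand[r2 > r2_max])
    }
    tag_id[members] <- agg$snp_id[i]
    bin_id[members] <- bin
    assigned[members] <- TRUE
  }
  out <- data.frame(snp_id = agg$snp_id, chrom = agg$chrom, pos = agg$pos,
                    p = agg$p, tag_id = tag_id, bin_id = bin_id,
                    is_tag = tag_id == agg$snp_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Probe-level BH correction over tag records
#'
#' Benjamini-Hochberg over the maxT-adjusted p values of tag-SNP records
#' pooled across probes within one analysis; the FDR analogue Q < `q_max`
#' defines the significant set.
#'
#' @param records association records carrying `maxt_p` (or `p`).
#' @param bins a [clump_and_bin()] table for the same analysis.
#' @param q_max significance threshold (default 0.05).
#' @return list with `tags` (tag records with `q` and `bin_id` attached) and
#'   `significant` (subset with `q < q_max`).
#' @export
probe_level_fdr <- function(records, bins, q_max = 0.05) {
  tag_snps <- bins$snp_id[bins$is_tag]
  tags <- records[records$snp_id %in% tag_snps, , drop = FALSE]
  pcol <- if ("maxt_p" %in% names(tags) && !all(is.na(tags$maxt_p)))
    "maxt_p" else "p"
  tags$q <- stats::p.adjust(tags[[pcol]], "BH")
  tags$bin_id <- bins$bin_id[match(tags$snp_id, bins$snp_id)]
  rownames(tags) <- NULL
  list(tags = tags, significant = tags[tags$q < q_max, , drop = FALSE])
}

#' Full cis-QTL analysis for one stratum
#'
#' Runs the whole two-stage procedure: residualize the phenotype on
#' covariates, nominal cis scan, per-probe maxT permutations (one child seed
#' stream per probe), greedy LD clumping, and probe-level BH on tags.
#'
#' @param phenotype a `delta_expression`, `methylation_matrix`, or matrix;
#'   for eQTLs pass the expression change, for baseline eQTLs the baseline
#'   matrix.
#' @param genotypes a `genotype_matrix`.
#' @param covariates covariate table.
#' @param feature_table feature positions (`probe_id`, `chrom`, `pos`);
#'   inferred from the phenotype object when possible.
#' @param stratum `"all"`, `"female"` or `"male"`.
#' @param n_perm permutations per probe (default 10,000 at desk scale; the
#'   reference design uses 500,000).
#' @param seed master seed for the permutation streams.
#' @param window cis window (default 1e6).
#' @param r2_max clump threshold (default 0.2).
#' @param q_max tag-level significance threshold (default 0.05).
#' @param covariate_cols forwarded to [make_phenotype()].
#' @return list with `records` (nominal + `emp_p`, `maxt_p`), `bins`,
#'   `tags`, `significant`, `stratum`.
#' @export
map_cis_qtl <- function(phenotype, genotypes, covariates,
                        feature_table = NULL,
                        stratum = c("all", "female", "male"),
                        n_perm = 10000, seed = 1L, window = 1e6,
                        r2_max = 0.2, q_max = 0.05, covariate_cols = NULL) {
  stratum <- match.arg(stratum)
  if (is.null(feature_table)) {
    feature_table <- if (inherits(phenotype, "delta_expression"))
      phenotype$probe_table
    else if (inherits(phenotype, "methylation_matrix"))
      stats::setNames(phenotype$cpg_table, c("probe_id", "chrom", "pos"))
    else stop("feature_table required for a plain matrix phenotype")
  }
  phen <- make_phenotype(phenotype, covariates, stratum, covariate_cols)
  pairing <- enumerate_cis_pairs(genotypes$snp_table, feature_table, window)
  pairing <- pairing[pairing$probe_id %in% rownames(phen), , drop = FALSE]
  records <- scan_cis(phen, genotypes, pairing)
  dos <- .align_samples(phen, genotypes$dosages)
  adj <- lapply(unique(records$probe_id), function(pb) {
    snps <- records$snp_id[records$probe_id == pb]
    a <- maxt_adjust(phen[pb, ], dos[, snps, drop = FALSE], n_perm = n_perm,
                     seed = child_seed(seed, paste0("maxt:", pb)))
    a$probe_id <- pb
    a
  })
  adj <- do.call(rbind, adj)
  idx <- match(paste(records$snp_id, records$probe_id),
               paste(adj$snp_id, adj$probe_id))
  records$emp_p <- adj$emp_p[idx]
  records$maxt_p <- adj$maxt_p[idx]
  bins <- clump_and_bin(records, genotypes, r2_max = r2_max, window = window)
  fdr <- probe_level_fdr(records, bins, q_max = q_max)
  list(records = records, bins = bins, tags = fdr$tags,
       significant = fdr$significant, stratum = stratum)
}

#' Sex-by-genotype interaction scan
#'
#' For each cis pair, OLS of the expression change on sex, dosage, their
#' interaction, and the covariates; reports the interaction coefficient.
#' Intended for pairs restricted to the sex-stratified etranscripts.
#'
#' @param delta a `delta_expression`.
#' @param genotypes a `genotype_matrix`.
#' @param covariates covariate table (both sexes required).
#' @param pairing an [enumerate_cis_pairs()] table (typically restricted).
#' @return data.frame with `snp_id`, `probe_id`, `estimate` (interaction),
#'   `se`, `t`, `p`. Zero-variance genotypes are dropped with a message.
#' @export
interaction_scan <- function(delta, genotypes, covariates, pairing) {
  if (length(unique(covariates$sex)) < 2L)
    stop("interaction scan requires both sexes")
  Y <- delta$delta[, covariates$sample_id, drop = FALSE]
  dos <- genotypes$dosages[covariates$sample_id, , drop = FALSE]
  cols <- .covariate_cols(covariates)
  Xc <- .dea_design(covariates, cols)
  out <- vector("list", nrow(pairing))
  dropped <- 0L
  for (i in seq_len(nrow(pairing))) {
    g <- dos[, pairing$snp_id[i]]
    if (stats::var(g) == 0) { dropped <- dropped + 1L; next }
    X <- cbind(Xc[, 1, drop = FALSE], sex = covariates$sex, snp = g,
               `sex:snp` = covariates$sex * g, Xc[, -1, drop = FALSE])
    fit <- fit_ols_rows(Y[pairing$probe_id[i], , drop = FALSE], X, "sex:snp")
    out[[i]] <- data.frame(snp_id = pairing$snp_id[i],
                           probe_id = pairing$probe_id[i],
                           estimate = fit$estimate, se = fit$se, t = fit$t,
                           p = fit$p, stringsAsFactors = FALSE)
  }
  if (dropped > 0) message("dropped ", dropped, " zero-variance pair(s)")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable pairs")
  rownames(res) <- NULL
  res
}

#' cis-meQTL scan with genome-wide BH correction
#'
#' Reuses the cis machinery on methylation beta values but, matching the
#' reference meQTL design, applies BH at 5% FDR over all nominal tests with
#' no permutation stage. Covariates default to age and the surrogate (cell)
#' columns.
#'
#' @param methylation a `methylation_matrix`.
#' @param genotypes a `genotype_matrix`.
#' @param covariates covariate table.
#' @param stratum `"all"`, `"female"` or `"male"`.
#' @param window cis window (default 1e6).
#' @param q_max FDR threshold (default 0.05).
#' @param covariate_cols covariates to residualize on; default age + sv*.
#' @return list with `records` (with `q`), `significant` records, and
#'   `mesnps` (unique significant SNP ids).
#' @export
scan_meqtl <- function(methylation, genotypes, covariates,
                       stratum = c("all", "female", "male"), window = 1e6,
                       q_max = 0.05, covariate_cols = NULL) {
  stratum <- match.arg(stratum)
  if (is.null(covariate_cols))
    covariate_cols <- c("age", grep("^sv", names(covariates), value = TRUE))
  cpg_table <- stats::setNames(methylation$cpg_table,
                               c("probe_id", "chrom", "pos"))
  phen <- make_phenotype(methylation, covariates, stratum, covariate_cols)
  pairing <- enumerate_cis_pairs(genotypes$snp_table, cpg_table, window)
  records <- scan_cis(phen, genotypes, pairing)
  records$q <- stats::p.adjust(records$p, "BH")
  sig <- records[records$q < q_max, , drop = FALSE]
  list(records = records, significant = sig,
       mesnps = unique(sig$snp_id))
}

#' Overlap of tag eSNPs with significant meSNPs
#'
#' Counts how many tag eSNPs are also significant methylation-QTL SNPs.
#'
#' @param tag_esnps character vector of tag eSNP ids (one stratum).
#' @param mesnps character vector of significant meSNP ids.
#' @return list with `n_overlap`, `n_tags`, `fraction`.
#' @export
overlap_eqtl_meqtl <- function(tag_esnps, mesnps) {
  tag_esnps <- unique(tag_esnps)
  n <- length(tag_esnps)
  k <- sum(tag_esnps %in% mesnps)
  list(n_overlap = k, n_tags = n,
       fraction = if (n > 0) k / n else NaN)
}
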