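# Genomic-region annotation, interval overlap, MAF-matched permutation
# enrichment and gene-set overlap tests.
#
# Coordinate conventions: SNP/feature tables are 1-based (VCF convention);
# interval sets are BED 0-based half-open. A SNP at 1-based position p lies
# inside [start, end) iff start <= p - 1 < end; the conversion happens once,
# at GRanges construction.

.snp_granges <- function(snp_table) {
  GenomicRanges::GRanges(snp_table$chrom,
                         IRanges::IRanges(snp_table$pos, width = 1L))
}

.bed_granges <- function(intervals) {
  if (nrow(intervals) == 0)
    return(GenomicRanges::GRanges())
  if (any(intervals$start >= intervals$end))
    stop("interval with start >= end")
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1L,
                                          intervals$end))
}

# SNPs of snp_table falling inside any interval of the set.
.snps_inside <- function(snp_table, intervals) {
  if (nrow(snp_table) == 0) return(logical(0))
  hits <- GenomicRanges::countOverlaps(.snp_granges(snp_table),
                                       .bed_granges(intervals))
  hits > 0
}

#' Count SNPs inside an interval set
#'
#' A SNP at 1-based position p is inside a BED interval `[start, end)` iff
#' `start <= p - 1 < end`. The percentage is rounded half-up to two
#' decimals.
#'
#' @param snp_table SNP table (`snp_id`, `chrom`, `pos`).
#' @param intervals interval data.frame (`chrom`, `start`, `end`).
#' @return list with `n_inside`, `n_total`, `pct`, `inside` (SNP ids).
#' @export
interval_overlap <- function(snp_table, intervals) {
  inside <- .snps_inside(snp_table, intervals)
  n <- nrow(snp_table)
  list(n_inside = sum(inside), n_total = n,
       pct = if (n > 0) round_half_up(100 * sum(inside) / n, 2) else NaN,
       inside = snp_table$snp_id[inside])
}

#' Assign SNPs to genomic region categories
#'
#' Each SNP gets exactly one category by precedence
#' `promoter > utr5 > exon > intron > utr3 > downstream > distal_intergenic`;
#' SNPs on chromosomes absent from the gene model are `unannotated`. When
#' the SNP table carries a `stratum` column, a stratum x category count
#' table and a per-category two-sided Fisher exact test (female vs male,
#' in/out of category) are returned as well.
#'
#' @param snp_table SNP table, optionally with a `stratum` column
#'   (`"female"` / `"male"`).
#' @param gene_model data.frame (`chrom`, `start`, `end`, `feature`) with
#'   BED coordinates and features among the precedence classes.
#' @return list with `per_snp` (`snp_id`, `category`), `counts`
#'   (stratum x category, when strata present), `percent` (row percentages,
#'   half-up to one decimal), `tests` (per-category Fisher results).
#' @export
annotate_regions <- function(snp_table, gene_model) {
  precedence <- c("promoter", "utr5", "exon", "intron", "utr3", "downstream")
  category <- rep("distal_intergenic", nrow(snp_table))
  model_chroms <- unique(gene_model$chrom)
  category[!(snp_table$chrom %in% model_chroms)] <- "unannotated"
  for (feat in rev(precedence)) {
    iv <- gene_model[gene_model$feature == feat, , drop = FALSE]
    if (nrow(iv) == 0) next
    category[.snps_inside(snp_table, iv)] <- feat
  }
  per_snp <- data.frame(snp_id = snp_table$snp_id, category = category,
                        stringsAsFactors = FALSE)
  out <- list(per_snp = per_snp, counts = NULL, percent = NULL, tests = NULL)
  if ("stratum" %in% names(snp_table)) {
    lev <- c(precedence, "distal_intergenic", "unannotated")
    tab <- table(stratum = snp_table$stratum,
                 category = factor(category, levels = lev))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    out$counts <- tab
    out$percent <- round_half_up(100 * prop.table(tab, 1), 1)
    if (all(c("female", "male") %in% rownames(tab))) {
      tests <- lapply(colnames(tab), function(cat) {
        m <- rbind(female = c(tab["female", cat],
                              sum(tab["female", ]) - tab["female", cat]),
                   male = c(tab["male", cat],
                            sum(tab["male", ]) - tab["male", cat]))
        ft <- stats::fisher.test(m)
        data.frame(category = cat, odds_ratio = unname(ft$estimate),
                   p = ft$p.value, stringsAsFactors = FALSE)
      })
      out$tests <- do.call(rbind, tests)
    }
  }
  out
}

# Observed overlap of a target SNP set against one label: either an
# interval data.frame or a character vector of SNP ids (e.g., GWAS risk
# SNPs at nominal p < 0.05).
.label_overlap <- function(snp_table, ids, label) {
  sub <- snp_table[match(ids, snp_table$snp_id), , drop = FALSE]
  if (is.data.frame(label)) sum(.snps_inside(sub, label))
  else sum(ids %in% label)
}

#' MAF-matched permutation enrichment
#'
#' Compares the overlap of a target SNP set with each label (an annotation
#' interval set or a GWAS SNP id set) against `n_sets` null SNP sets drawn
#' from a background pool. Null sets are sampled without replacement within
#' folded-MAF bins so every null set's binned MAF histogram equals the
#' target's exactly; targets are removed from the pool before sampling.
#' Empirical p values get the +1/+1 correction; BH is applied across labels
#' on the enrichment p.
#'
#' @param targets target SNP table (`snp_id`, `chrom`, `pos`, `maf`), e.g.
#'   tag GR-eSNPs of one stratum.
#' @param pool background SNP table (same columns), e.g. baseline tag
#'   eSNPs; may contain the targets.
#' @param labels named list; each element an interval data.frame or a
#'   character vector of SNP ids.
#' @param n_sets number of null sets (default 1000).
#' @param maf_bin_width folded-MAF bin width (default 0.05).
#' @param seed integer seed; the draw is deterministic given it.
#' @return data.frame (class `enrichment_result`) with one row per label:
#'   `label`, `observed`, `n_target`, `null_mean`, `null_sd`, `fold`
#'   (observed / null mean), `p_enrich`, `p_deplete`, `fdr` (BH on
#'   `p_enrich`), `n_sets`; all null draws are kept in
#'   `attr(, "null_draws")`.
#' @export
maf_matched_enrichment <- function(targets, pool, labels, n_sets = 1000,
                                   maf_bin_width = 0.05, seed = 1L) {
  stopifnot(length(labels) > 0, !is.null(names(labels)))
  pool <- pool[!(pool$snp_id %in% targets$snp_id), , drop = FALSE]
  breaks <- seq(0, 0.5 + maf_bin_width, by = maf_bin_width)
  tbin <- cut(targets$maf, breaks, right = FALSE, include.lowest = TRUE)
  pbin <- cut(pool$maf, breaks, right = FALSE, include.lowest = TRUE)
  need <- table(tbin)
  have <- table(pbin)[names(need)]
  short <- need > 0 & (is.na(have) | have < need)
  if (any(short))
    stop("background pool too small in MAF bin(s): ",
         paste(names(need)[short], collapse = ", "))
  bins_used <- names(need)[need > 0]
  pool_by_bin <- split(pool$snp_id, pbin)
  null_sets <- with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      unlist(lapply(bins_used, function(b) {
        ids <- pool_by_bin[[b]]
        ids[sample.int(length(ids), need[b])]
      }), use.names = FALSE)
    })
  })
  all_snps <- rbind(targets, pool)
  rows <- lapply(names(labels), function(lab) {
    obs <- .label_overlap(all_snps, targets$snp_id, labels[[lab]])
    null <- vapply(null_sets, function(ids)
      .label_overlap(all_snps, ids, labels[[lab]]), numeric(1))
    data.frame(label = lab, observed = obs, n_target = nrow(targets),
               null_mean = mean(null), null_sd = stats::sd(null),
               fold = if (mean(null) > 0) obs / mean(null) else NaN,
               p_enrich = (1 + sum(null >= obs)) / (1 + n_sets),
               p_deplete = (1 + sum(null <= obs)) / (1 + n_sets),
               n_sets = n_sets, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_enrich, "BH")
  null_mat <- do.call(rbind, lapply(names(labels), function(lab)
    vapply(null_sets, function(ids)
      .label_overlap(all_snps, ids, labels[[lab]]), numeric(1))))
  rownames(null_mat) <- names(labels)
  attr(out, "null_draws") <- null_mat
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Sample odds ratio of a 2x2 table with Haldane-Anscombe 0.5 correction for
# zero cells; returns list(or, haldane flag).
.sample_or <- function(a, b, c, d) {
  if (a == 0 && (b > 0 || c > 0)) return(list(or = 0, haldane = FALSE))
  if (b == 0 && d == 0) return(list(or = 1, haldane = FALSE))
  if (any(c(a, b, c, d) == 0)) {
    return(list(or = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
                haldane = TRUE))
  }
  list(or = (a * d) / (b * c), haldane = FALSE)
}

#' Gene-set overlap enrichment with a declared universe
#'
#' Builds the 2x2 in/out table of two gene sets over a shared universe and
#' reports the Jaccard index, the Fisher exact odds ratio and two-sided p.
#' Infinite sample odds ratios are replaced by the Haldane-Anscombe
#' corrected value and flagged. When a background set is supplied (e.g.
#' baseline etranscripts), a second Fisher test compares the A-overlap with
#' the background-overlap.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe character vector of gene ids, or a single integer size.
#' @param background optional character vector (same universe).
#' @return list with `n_a`, `n_b`, `n_universe`, `intersection`, `jaccard`,
#'   `odds_ratio`, `haldane`, `p`, and (with background) `background_p` and
#'   `background_odds_ratio`.
#' @export
geneset_overlap_enrichment <- function(setA, setB, universe,
                                       background = NULL) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
    if (length(union(setA, setB)) > N)
      stop("sets exceed the declared universe size")
  } else {
    N <- length(unique(universe))
    out_of <- union(setdiff(setA, universe), setdiff(setB, universe))
    if (length(out_of) > 0)
      stop("sets exceed the universe: ",
           paste(utils::head(out_of, 5), collapse = ", "))
  }
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- N - a - b - c
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
  or <- .sample_or(a, b, c, d)
  un <- a + b + c
  res <- list(n_a = length(setA), n_b = length(setB), n_universe = N,
              intersection = a,
              jaccard = if (un > 0) a / un else NaN,
              odds_ratio = or$or, haldane = or$haldane, p = p)
  if (!is.null(background)) {
    background <- unique(background)
    bg_in <- length(intersect(background, setB))
    m <- matrix(c(a, b, bg_in, length(background) - bg_in), 2, byrow = TRUE)
    ft <- stats::fisher.test(m)
    res$background_p <- ft$p.value
    res$background_odds_ratio <- unname(ft$estimate)
  }
  res
}

#' Over-representation test against term-to-gene maps
#'
#' One-sided hypergeometric enrichment p and sample odds ratio per term;
#' nominal p values are reported with no cross-term correction (terms are
#' highly dependent). Empty terms are skipped with a warning.
#'
#' @param hits character vector of hit genes (subset of the universe).
#' @param terms named list of character vectors (term -> genes), or a
#'   data.frame with columns `term`, `gene`.
#' @param universe character vector of gene ids or a single integer size.
#' @return data.frame with `term`, `n_term`, `n_hits_in_term`,
#'   `odds_ratio`, `p`.
#' @export
overrepresentation_test <- function(hits, terms, universe) {
  if (is.data.frame(terms)) terms <- split(terms$gene, terms$term)
  hits <- unique(hits)
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
  } else {
    N <- length(unique(universe))
    if (length(setdiff(hits, universe)) > 0)
      stop("hits exceed the universe")
    terms <- lapply(terms, intersect, y = universe)
  }
  n <- length(hits)
  rows <- lapply(names(terms), function(tm) {
    genes <- unique(terms[[tm]])
    K <- length(genes)
    if (K == 0) {
      warning("skipping empty term '", tm, "'")
      return(NULL)
    }
    k <- length(intersect(hits, genes))
    or <- .sample_or(k, n - k, K - k, N - K - (n - k))
    data.frame(term = tm, n_term = K, n_hits_in_term = k,
               odds_ratio = or$or,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), n_term = integer(),
                      n_hits_in_term = integer(), odds_ratio = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
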