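# Readers and writers for the typed tables. TSV round-trips are lossless;
# SNP/feature tables are 1-based (VCF convention), BED files 0-based
# half-open.

#' @rdname io_tsv
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Generic TSV table IO
#'
#' Thin wrappers around [data.table::fread()] / [data.table::fwrite()] used
#' for covariate, truth, weight and record tables.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_table_tsv` returns a data.frame; `write_table_tsv` the
#'   path, invisibly.
#' @name io_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Genotype matrix TSV IO
#'
#' One row per SNP: the SNP metadata columns followed by one dosage column
#' per sample.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @return `read_genotypes` returns a `genotype_matrix`.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- cbind(genotypes$snp_table,
              as.data.frame(t(genotypes$dosages)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta_cols <- intersect(c("snp_id", "chrom", "pos", "ref", "alt",
                           "alt_freq", "maf", "block"), names(df))
  st <- df[, meta_cols, drop = FALSE]
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dos) <- st$snp_id
  structure(list(dosages = dos, snp_table = st), class = "genotype_matrix")
}

#' Feature matrix TSV IO
#'
#' Rows are features (probes or CpGs), columns samples; the first column
#' holds the feature id.
#'
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @param id_col name of the id column (default `feature_id`).
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' BED interval IO
#'
#' Reads 3+-column BED (0-based, half-open); `track`/`browser`/comment
#' lines are tolerated. Malformed rows (fewer than 3 fields, non-numeric or
#' `start >= end` coordinates) are rejected with their line number.
#'
#' @param path file path.
#' @param label optional label attached as a `name` column when the file
#'   has none.
#' @return data.frame with `chrom`, `start`, `end` (+ `name` if present).
#' @export
read_bed <- function(path, label = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines[keep], "\t|[ ]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0)
    stop("malformed BED row at line ", lineno[bad[1]],
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("malformed BED row at line ", lineno[bad[1]],
         ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop("invalid BED interval at line ", lineno[bad[1]],
         ": start >= end")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  nm <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
               character(1))
  if (!all(is.na(nm))) out$name <- nm
  else if (!is.null(label)) out$name <- label
  out
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` (+ optional
#'   `name`).
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present (continuous dosages), otherwise
#' counts alt alleles in `GT` (`0/1` and `0|1` both give 1).
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  has_ds <- any(grepl("\\bDS\\b", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  snp_id <- ifelse(is.na(fx$ID) | fx$ID == ".",
                   paste0(fx$CHROM, ":", fx$POS), fx$ID)
  dos <- t(ds)
  colnames(dos) <- snp_id
  af <- colMeans(dos, na.rm = TRUE) / 2
  st <- data.frame(snp_id = snp_id, chrom = fx$CHROM,
                   pos = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
                   alt_freq = af, maf = pmin(af, 1 - af),
                   stringsAsFactors = FALSE)
  structure(list(dosages = dos, snp_table = st), class = "genotype_matrix")
}

#' Write a minimal VCF with GT from rounded dosages
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  st <- genotypes$snp_table
  dos <- round(genotypes$dosages)
  gt <- apply(dos, 1, function(d) c("0/0", "0/1", "1/1")[d + 1L])
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosages)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(st)), function(i)
    paste(c(st$chrom[i], st$pos[i], st$snp_id[i], st$ref[i], st$alt[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
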