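# Genotype container and PLINK / TSV input-output.
#
# Dosages count allele1 (the A1 / effect allele, bim column 5) throughout the
# package. PRS weights attach to the effect allele, so this convention matters
# everywhere scores are computed.

#' Construct a genotype matrix object
#'
#' The central data container: an `n x m` additive dosage matrix (values 0, 1,
#' 2 or `NA`, counting copies of `allele1`) together with per-variant and
#' per-sample metadata.
#'
#' @param dosages integer/numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `variant_id`, `chromosome`,
#'   `position_bp` (1-based), `allele1` (counted/effect allele), `allele2`.
#' @param samples data.frame with columns `sample_id` and optionally `sex`
#'   (1/2/NA), `age`, `region_label`, `cluster_label`, `subpopulation_truth`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  req_v <- c("variant_id", "chromosome", "position_bp", "allele1", "allele2")
  missing_v <- setdiff(req_v, names(variants))
  if (length(missing_v)) {
    stop("variants is missing column(s): ", paste(missing_v, collapse = ", "))
  }
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
  for (col in c("sex", "age", "region_label", "cluster_label", "subpopulation_truth")) {
    if (!col %in% names(samples)) samples[[col]] <- rep(NA, nrow(samples))
  }
  if (nrow(dosages) != nrow(samples)) {
    stop("dosage rows (", nrow(dosages), ") != number of samples (", nrow(samples), ")")
  }
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage columns (", ncol(dosages), ") != number of variants (", nrow(variants), ")")
  }
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (nrow(variants) > 0 && any(variants$position_bp < 1, na.rm = TRUE)) {
    stop("position_bp must be >= 1")
  }
  if (nrow(variants) > 0 && any(variants$allele1 == variants$allele2)) {
    stop("allele1 must differ from allele2")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(samples$sample_id, variants$variant_id)
  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  if (!all(is.na(x$samples$subpopulation_truth))) {
    cat("  subpopulations:", paste(names(table(x$samples$subpopulation_truth)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants logical, integer or character index vectors.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosages)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$dosages)) else variants
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, x$variants$variant_id)
  genotype_matrix(
    x$dosages[si, vi, drop = FALSE],
    x$variants[vi, , drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

# 256 x 4 decode table: byte value -> four dosages (lowest-order pair first).
# 2-bit codes: 00 = hom allele1 (dosage 2), 01 = missing, 10 = het, 11 = hom allele2.
.bed_decode_table <- function() {
  codes <- c(2, NA, 1, 0)
  tbl <- matrix(NA_real_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tbl[b + 1, k] <- codes[(v %% 4) + 1]
      v <- v %/% 4
    }
  }
  tbl
}

.bed_code_of_dosage <- function(d) {
  # dosage -> 2-bit code
  out <- integer(length(d))
  out[is.na(d)] <- 1L
  out[!is.na(d) & d == 2] <- 0L
  out[!is.na(d) & d == 1] <- 2L
  out[!is.na(d) & d == 0] <- 3L
  out
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes the SNP-major binary bed format (magic bytes `0x6C 0x1B`, mode
#' `0x01`). Dosages count allele1 (bim column 5).
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read. Alternatively
#'   pass explicit paths via `bed`, `bim`, `fam`.
#' @param bed,bim,fam explicit file paths (override `prefix`).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed)) bed <- paste0(prefix, ".bed")
    if (is.null(bim)) bim <- paste0(prefix, ".bim")
    if (is.null(fam)) fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)

  bim_df <- utils::read.table(bim, header = FALSE, colClasses = "character",
                              col.names = c("chromosome", "variant_id", "cm",
                                            "position_bp", "allele1", "allele2"))
  bim_df$position_bp <- as.integer(bim_df$position_bp)
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character",
                              col.names = c("fid", "sample_id", "pat", "mat",
                                            "sex", "pheno"))
  sex <- suppressWarnings(as.integer(fam_df$sex))
  sex[!sex %in% c(1L, 2L)] <- NA_integer_

  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("bad magic bytes: not a PLINK bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major (mode 0x01) bed files supported")
  bpv <- if (n > 0) ceiling(n / 4) else 0L
  expected <- 3 + bpv * m
  if (length(raw) != expected) {
    stop("bed file size mismatch (corrupt?): got ", length(raw),
         " bytes, expected ", expected, " for ", n, " samples x ", m, " variants")
  }
  dos <- matrix(NA_real_, nrow = n, ncol = m)
  if (m > 0 && n > 0) {
    tbl <- .bed_decode_table()
    payload <- as.integer(raw[-(1:3)])
    dim(payload) <- c(bpv, m)
    for (j in seq_len(m)) {
      vals <- tbl[payload[, j] + 1L, , drop = FALSE]  # bpv x 4
      dos[, j] <- as.vector(t(vals))[seq_len(n)]
    }
  }
  variants <- data.frame(
    variant_id = bim_df$variant_id, chromosome = bim_df$chromosome,
    position_bp = bim_df$position_bp, allele1 = bim_df$allele1,
    allele2 = bim_df$allele2, stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = fam_df$sample_id, sex = sex,
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}

#' Write a genotype matrix as a PLINK bed/bim/fam fileset
#'
#' Bit-exact round trip with [read_plink()]. Missing sex is written as 0 per
#' the fam convention; phenotype column is written as -9.
#'
#' @param x a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- nrow(x$dosages); m <- ncol(x$dosages)
  v <- x$variants
  bim <- data.frame(chr = v$chromosome, id = v$variant_id,
                    cm = rep(0, m), pos = v$position_bp,
                    a1 = v$allele1, a2 = v$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sex <- x$samples$sex
  sex[is.na(sex)] <- 0
  fam <- data.frame(fid = x$samples$sample_id, iid = x$samples$sample_id,
                    pat = rep(0, n), mat = rep(0, n), sex = sex,
                    pheno = rep(-9, n))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0 && n > 0) {
    bpv <- ceiling(n / 4)
    pad <- bpv * 4 - n
    mult <- c(1L, 4L, 16L, 64L)
    for (j in seq_len(m)) {
      codes <- c(.bed_code_of_dosage(x$dosages[, j]), integer(pad))
      dim(codes) <- c(4, bpv)
      bytes <- as.integer(colSums(codes * mult))
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read genotypes from a VCF file (optional, biallelic GT only)
#'
#' Thin adapter over the \pkg{vcfR} package. Dosages count the ALT allele
#' (mapped to `allele1`). Multiallelic records are rejected.
#'
#' @param path VCF file (may be bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the optional 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multiallelic records not supported; split or filter the VCF first")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(
    variant_id = ids, chromosome = fix[, "CHROM"],
    position_bp = as.integer(fix[, "POS"]),
    allele1 = fix[, "ALT"], allele2 = fix[, "REF"], stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, samples)
}

#' Read a phenotype/covariate table from TSV
#'
#' Requires a header with a `sample_id` column. All other columns must be
#' numeric (use `NA` for missing); a value that fails numeric parsing raises
#' an error naming the column.
#'
#' @param path TSV file.
#' @return data.frame with `sample_id` (character) and numeric columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("phenotype TSV needs a 'sample_id' header column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in phenotype table")
  for (col in setdiff(names(df), "sample_id")) {
    vals <- df[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- !is.na(vals) & is.na(num)
    if (any(bad)) {
      stop("non-numeric value in column '", col, "': ", vals[which(bad)[1]])
    }
    df[[col]] <- num
  }
  df
}

#' Write a phenotype/covariate table to TSV
#'
#' @param df data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_phenotypes <- function(df, path) {
  stopifnot("sample_id" %in% names(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
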