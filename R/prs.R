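# Clumping-and-thresholding PRS construction, scoring, rank-inverse-normal
# transformation, variance explained, and Haseman-Elston heritability.

#' Greedy LD clumping and p-value thresholding
#'
#' Variants with discovery p-value below `p_threshold` are sorted by
#' ascending p (ties broken by genomic position, then variant id). The best
#' remaining variant becomes an index variant; every remaining variant on
#' the same chromosome within `clump_window_bp` of it (endpoints inclusive)
#' AND with r^2 >= `clump_r2` against it in the LD reference is removed.
#' Index variants form the score model, weighted by their discovery betas.
#'
#' @param assoc an `assoc_result` from the discovery group.
#' @param ld_reference a [genotype_matrix()] used for r^2 (conventionally the
#'   discovery genotypes, avoiding validation leakage); must contain the
#'   associated variants.
#' @param p_threshold retain variants with `p < p_threshold`
#'   (default 5.0e-6).
#' @param clump_window_bp clump window (default 1,000,000 bp).
#' @param clump_r2 r^2 threshold (default 0.1).
#' @return `prs_model` data.frame: `variant_id, chromosome, position_bp,
#'   effect_allele, weight, p_discovery`, with the parameters as attributes.
#'   An empty model (no variant passes) is valid.
#' @export
clump_and_threshold <- function(assoc, ld_reference, p_threshold = 5e-6,
                                clump_window_bp = 1e6, clump_r2 = 0.1) {
  stopifnot(inherits(ld_reference, "genotype_matrix"))
  ok <- !is.na(assoc$p_value) & assoc$p_value < p_threshold
  if ("flagged" %in% names(assoc)) ok <- ok & !assoc$flagged
  cand <- assoc[ok, , drop = FALSE]
  cand <- cand[order(cand$p_value, cand$position_bp, cand$variant_id), , drop = FALSE]
  ref_idx <- match(cand$variant_id, ld_reference$variants$variant_id)
  if (anyNA(ref_idx)) {
    stop("variant(s) absent from the LD reference: ",
         paste(utils::head(cand$variant_id[is.na(ref_idx)], 5), collapse = ", "))
  }
  kept <- integer(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    later <- which(alive)
    later <- later[later > i]
    if (!length(later)) break
    same_chr <- cand$chromosome[later] == cand$chromosome[i]
    near <- same_chr &
      abs(cand$position_bp[later] - cand$position_bp[i]) <= clump_window_bp
    for (j in later[near]) {
      r2 <- suppressWarnings(
        pairwise_r2(ld_reference, ref_idx[i], ref_idx[j])
      )
      if (r2 >= clump_r2) alive[j] <- FALSE
    }
  }
  model <- data.frame(
    variant_id = cand$variant_id[kept], chromosome = cand$chromosome[kept],
    position_bp = cand$position_bp[kept],
    effect_allele = cand$effect_allele[kept], weight = cand$beta[kept],
    p_discovery = cand$p_value[kept], stringsAsFactors = FALSE
  )
  attr(model, "params") <- list(p_threshold = p_threshold,
                                clump_window_bp = clump_window_bp,
                                clump_r2 = clump_r2)
  class(model) <- c("prs_model", "data.frame")
  model
}

#' Score individuals with a PRS model
#'
#' Weighted allelic sum `sum_j weight_j * dosage_j(effect allele)`. When the
#' model's effect allele equals the cohort's `allele2`, the dosage is flipped
#' (`2 - g`); variants matching in neither orientation are dropped with a
#' warning. A missing dosage is mean-imputed as `2 * (effect-allele
#' frequency in the scored group)`.
#'
#' @param genotypes a [genotype_matrix()] of the samples to score.
#' @param model a `prs_model` (possibly empty, giving all-zero scores).
#' @return data.frame `sample_id, raw_score`.
#' @export
score_prs <- function(genotypes, model) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  out <- data.frame(sample_id = genotypes$samples$sample_id,
                    raw_score = numeric(n), stringsAsFactors = FALSE)
  if (nrow(model) == 0) return(out)
  idx <- match(model$variant_id, genotypes$variants$variant_id)
  if (anyNA(idx)) {
    warning("model variant(s) absent from genotypes, dropped: ",
            paste(model$variant_id[is.na(idx)], collapse = ", "))
  }
  score <- numeric(n)
  for (k in seq_len(nrow(model))) {
    j <- idx[k]
    if (is.na(j)) next
    a1 <- genotypes$variants$allele1[j]
    a2 <- genotypes$variants$allele2[j]
    ea <- model$effect_allele[k]
    g <- genotypes$dosages[, j]
    if (ea == a1) {
      # as stored
    } else if (ea == a2) {
      g <- 2 - g
    } else {
      warning("effect allele ", ea, " matches neither allele of ",
              model$variant_id[k], "; variant dropped")
      next
    }
    if (anyNA(g)) {
      ea_freq <- mean(g, na.rm = TRUE) / 2
      g[is.na(g)] <- 2 * ea_freq
    }
    score <- score + model$weight[k] * g
  }
  out$raw_score <- score
  out
}

#' Rank-based inverse normal transformation
#'
#' Blom offset: `qnorm((rank - 0.375) / (n + 0.25))`, average ranks for
#' ties, `NA` preserved. A constant vector returns all zeros with a warning.
#'
#' @param values numeric vector (n >= 2 non-missing).
#' @return transformed vector, mean approximately 0 and SD approximately 1.
#' @export
rank_normalize <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  if (length(unique(values[ok])) == 1) {
    warning("constant input: rank normalization returns zeros")
    out[ok] <- 0
    return(out)
  }
  r <- .rank_avg(values[ok])
  out[ok] <- stats::qnorm((r - 0.375) / (n + 0.25))
  out
}

#' Incremental variance explained by a PRS
#'
#' Difference in adjusted R-squared between the full linear model
#' `phenotype ~ PRS + covariates` and the nested model
#' `phenotype ~ covariates`. May be slightly negative by the adjustment;
#' returned as-is.
#'
#' @param phenotype numeric vector.
#' @param prs numeric vector (same samples).
#' @param covariates matrix/data.frame or NULL.
#' @return delta adjusted R-squared (scalar).
#' @export
variance_explained <- function(phenotype, prs, covariates = NULL) {
  stopifnot(length(phenotype) == length(prs))
  keep <- !is.na(phenotype) & !is.na(prs)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- phenotype[keep]
  Z <- .check_covariates(if (is.null(C)) NULL else C[keep, , drop = FALSE],
                         sum(keep))
  Xfull <- cbind(Z, prs = prs[keep])
  if (qr(Xfull)$rank < ncol(Xfull)) stop("full model design is rank deficient")
  adj_r2 <- function(X) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    n <- length(y)
    1 - (rss / (n - fit$rank)) / (tss / (n - 1))
  }
  adj_r2(Xfull) - adj_r2(Z)
}

#' Haseman-Elston regression heritability
#'
#' Regresses the products `y_i y_j` of the standardized phenotype on the
#' off-diagonal entries `A_ij` of the genetic relationship matrix
#' `A = X X' / m` (X the standardized genotypes). The slope estimates the
#' narrow-sense heritability captured by the genotyped variants. The
#' reported estimate is clipped to `[0, 1]`; the raw slope is kept in the
#' result.
#'
#' @param genotypes a [genotype_matrix()], a standardized list from
#'   [standardize_genotypes()], or a pre-computed GRM passed via `grm`.
#' @param phenotype numeric vector.
#' @param grm optional n x n GRM (overrides `genotypes`).
#' @return list with `h2` (clipped), `h2_raw`, `intercept`, `n`, `m`.
#' @export
he_regression_h2 <- function(genotypes, phenotype, grm = NULL) {
  if (is.null(grm)) {
    std <- if (inherits(genotypes, "genotype_matrix")) standardize_genotypes(genotypes)
           else if (is.matrix(genotypes)) list(x = genotypes)
           else genotypes
    m <- ncol(std$x)
    grm <- tcrossprod(std$x) / m
  } else {
    m <- NA_integer_
  }
  n <- nrow(grm)
  stopifnot(length(phenotype) == n)
  keep <- !is.na(phenotype)
  grm <- grm[keep, keep, drop = FALSE]
  y <- phenotype[keep]
  n <- length(y)
  y <- (y - mean(y)) / stats::sd(y)
  ut <- upper.tri(grm)
  a <- grm[ut]
  yy <- tcrossprod(y)[ut]
  sxx <- sum((a - mean(a))^2)
  slope <- sum((a - mean(a)) * (yy - mean(yy))) / sxx
  list(h2 = min(max(slope, 0), 1), h2_raw = slope,
       intercept = mean(yy) - slope * mean(a), n = n, m = m)
}

#' Write a PRS model to TSV
#' @param model a `prs_model`.
#' @param path output path.
#' @export
write_prs_model <- function(model, path) {
  utils::write.table(model, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
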