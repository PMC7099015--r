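# Discovery/validation split and per-variant covariate-adjusted association.

#' Cluster-stratified random half split
#'
#' Randomly halves the cohort into discovery and validation groups with
#' approximately equal representation of every cluster: within each cluster
#' label the two groups differ in size by at most one. Deterministic given
#' the seed.
#'
#' @param sample_ids character vector.
#' @param cluster_labels vector of the same length (the stratification
#'   variable).
#' @param seed integer seed.
#' @return data.frame `sample_id, cluster_label, group` with
#'   `group` in `{"discovery", "validation"}`.
#' @export
split_cohort <- function(sample_ids, cluster_labels, seed) {
  stopifnot(length(sample_ids) == length(cluster_labels))
  set.seed(derive_seed(seed, "split_cohort"))
  group <- character(length(sample_ids))
  for (cl in unique(cluster_labels)) {
    idx <- which(cluster_labels == cl)
    idx <- idx[sample.int(length(idx))]
    half <- floor(length(idx) / 2)
    group[idx[seq_len(half)]] <- "discovery"
    group[idx[setdiff(seq_along(idx), seq_len(half))]] <- "validation"
  }
  data.frame(sample_id = sample_ids, cluster_label = cluster_labels,
             group = group, stringsAsFactors = FALSE)
}

# Validate the covariate matrix (plus intercept) and name collinear columns.
.check_covariates <- function(C, n) {
  if (is.null(C)) return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "intercept")))
  C <- as.matrix(C)
  if (is.null(colnames(C))) colnames(C) <- paste0("covar", seq_len(ncol(C)))
  Z <- cbind(intercept = 1, C)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Z
}

#' Per-variant linear association with covariate adjustment
#'
#' Ordinary least squares of the phenotype on each variant's dosage plus the
#' covariates (intercept added), with a t-test on the dosage coefficient.
#' Samples with missing phenotype or covariates are dropped (complete case);
#' samples with a missing dosage are dropped per variant. When no dosage is
#' missing, all variants are fitted at once by residualizing both sides on
#' the covariates (numerically identical to per-variant OLS).
#'
#' @param genotypes a [genotype_matrix()] (or dosage matrix).
#' @param phenotype numeric vector, length n.
#' @param covariates numeric matrix/data.frame of covariates (no intercept
#'   column), or NULL.
#' @param trait_name recorded in the result.
#' @return `assoc_result` data.frame: `variant_id, chromosome, position_bp,
#'   effect_allele, other_allele, beta, se, stat, p_value, n_used, model`.
#' @export
linear_assoc <- function(genotypes, phenotype, covariates = NULL,
                         trait_name = "trait") {
  gm <- inherits(genotypes, "genotype_matrix")
  d <- if (gm) genotypes$dosages else as.matrix(genotypes)
  n_all <- nrow(d)
  stopifnot(length(phenotype) == n_all)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(phenotype)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (sum(keep) < 3) stop("fewer than 3 samples with complete phenotype/covariates")
  d <- d[keep, , drop = FALSE]
  y <- phenotype[keep]
  Z <- .check_covariates(if (is.null(C)) NULL else C[keep, , drop = FALSE], sum(keep))
  n <- length(y)
  p_cov <- ncol(Z)
  m <- ncol(d)

  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  n_used <- rep(n, m)

  if (!anyNA(d)) {
    Q <- qr.Q(qr(Z))
    ys <- y - Q %*% crossprod(Q, y)
    Gs <- d - Q %*% crossprod(Q, d)
    Sjj <- colSums(Gs^2)
    ok <- Sjj > n * .Machine$double.eps
    Sxy <- as.vector(crossprod(Gs, ys))
    beta[ok] <- Sxy[ok] / Sjj[ok]
    yss <- sum(ys^2)
    df <- n - p_cov - 1
    rss <- pmax(yss - beta^2 * Sjj, 0)
    se[ok] <- sqrt(rss[ok] / df / Sjj[ok])
    zero_se <- !is.na(se) & se == 0
    tstat[ok] <- beta[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(-abs(tstat[ok]), df)
    tstat[zero_se] <- NA_real_
    pval[zero_se] <- NA_real_
  } else {
    for (j in seq_len(m)) {
      g <- d[, j]
      okr <- !is.na(g)
      if (sum(okr) <= p_cov + 1 || stats::var(g[okr]) == 0) next
      fit <- stats::lm.fit(cbind(Z[okr, , drop = FALSE], g = g[okr]), y[okr])
      co <- fit$coefficients["g"]
      res <- fit$residuals
      df <- sum(okr) - fit$rank
      XtX_inv_gg <- chol2inv(qr.R(fit$qr))[fit$rank, fit$rank]
      s2 <- sum(res^2) / df
      beta[j] <- co
      se[j] <- sqrt(s2 * XtX_inv_gg)
      tstat[j] <- co / se[j]
      pval[j] <- 2 * stats::pt(-abs(tstat[j]), df)
      n_used[j] <- sum(okr)
    }
  }
  vinfo <- if (gm) genotypes$variants else data.frame(
    variant_id = paste0("v", seq_len(m)), chromosome = "1",
    position_bp = seq_len(m), allele1 = "A", allele2 = "G",
    stringsAsFactors = FALSE)
  out <- data.frame(
    variant_id = vinfo$variant_id, chromosome = vinfo$chromosome,
    position_bp = vinfo$position_bp, effect_allele = vinfo$allele1,
    other_allele = vinfo$allele2, beta = beta, se = se, stat = tstat,
    p_value = pval, n_used = n_used, model = "linear",
    trait_name = trait_name, stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-variant logistic association with covariate adjustment
#'
#' Logistic regression (IRLS via `glm.fit`, max 25 iterations) of the binary
#' phenotype on dosage plus covariates, Wald test on the dosage coefficient.
#' Non-convergence and (quasi-)separation are flagged per variant with
#' `p_value = NA` so flagged variants never enter a PRS.
#'
#' @inheritParams linear_assoc
#' @param min_per_class minimum cases and controls required.
#' @return `assoc_result` data.frame with an extra logical column `flagged`.
#' @export
logistic_assoc <- function(genotypes, phenotype, covariates = NULL,
                           trait_name = "trait", min_per_class = 10) {
  gm <- inherits(genotypes, "genotype_matrix")
  d <- if (gm) genotypes$dosages else as.matrix(genotypes)
  stopifnot(length(phenotype) == nrow(d))
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(phenotype)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (sum(keep) < 3) stop("fewer than 3 samples with complete phenotype/covariates")
  d <- d[keep, , drop = FALSE]
  y <- phenotype[keep]
  if (!all(y %in% c(0, 1))) stop("binary phenotype must be coded 0/1")
  if (sum(y == 1) < min_per_class || sum(y == 0) < min_per_class) {
    stop("need at least ", min_per_class, " samples per class")
  }
  Z <- .check_covariates(if (is.null(C)) NULL else C[keep, , drop = FALSE], sum(keep))
  m <- ncol(d)
  beta <- se <- zstat <- pval <- rep(NA_real_, m)
  n_used <- integer(m)
  flagged <- logical(m)
  ctrl <- stats::glm.control(maxit = 25, epsilon = 1e-8)
  for (j in seq_len(m)) {
    g <- d[, j]
    okr <- !is.na(g)
    n_used[j] <- sum(okr)
    if (n_used[j] < ncol(Z) + 2 || stats::var(g[okr]) == 0) {
      flagged[j] <- TRUE
      next
    }
    X <- cbind(Z[okr, , drop = FALSE], g = g[okr])
    fit <- suppressWarnings(
      stats::glm.fit(X, y[okr], family = stats::binomial(), control = ctrl)
    )
    mu <- fit$fitted.values
    sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
    co <- fit$coefficients["g"]
    if (!fit$converged || is.na(co) || sep || abs(co) > 15) {
      flagged[j] <- TRUE
      next
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(W))
    cov_gg <- tryCatch(chol2inv(chol(XtWX))[ncol(X), ncol(X)],
                       error = function(e) NA_real_)
    if (is.na(cov_gg) || cov_gg <= 0 || sqrt(cov_gg) > 100) {
      flagged[j] <- TRUE
      next
    }
    beta[j] <- co
    se[j] <- sqrt(cov_gg)
    zstat[j] <- co / se[j]
    pval[j] <- 2 * stats::pnorm(-abs(zstat[j]))
  }
  vinfo <- if (gm) genotypes$variants else data.frame(
    variant_id = paste0("v", seq_len(m)), chromosome = "1",
    position_bp = seq_len(m), allele1 = "A", allele2 = "G",
    stringsAsFactors = FALSE)
  out <- data.frame(
    variant_id = vinfo$variant_id, chromosome = vinfo$chromosome,
    position_bp = vinfo$position_bp, effect_allele = vinfo$allele1,
    other_allele = vinfo$allele2, beta = beta, se = se, stat = zstat,
    p_value = pval, n_used = n_used, model = "logistic",
    trait_name = trait_name, flagged = flagged, stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Genomic inflation factor lambda
#'
#' Median association chi-squared statistic (1 df, from the p-values)
#' divided by its null expectation 0.4549364. Residual stratification
#' inflates lambda above 1.
#'
#' @param assoc an `assoc_result` or a numeric vector of p-values.
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(assoc) {
  p <- if (is.data.frame(assoc)) assoc$p_value else assoc
  p <- p[!is.na(p)]
  if (length(p) < 100) stop("need at least 100 variants for lambda")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write association results as a summary-statistics TSV
#'
#' @param assoc an `assoc_result`.
#' @param path output TSV.
#' @export
write_sumstats <- function(assoc, path) {
  cols <- c("variant_id", "chromosome", "position_bp", "effect_allele",
            "other_allele", "beta", "se", "p_value", "n_used")
  utils::write.table(assoc[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
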