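# Per-trait PRS differentiation statistics: delta normalized PRS, delta
# normalized phenotype, the BIAS statistic, the confounder-correlation scan,
# and the phenome-wide orchestration.

#' Covariate-adjusted phenotype normalization
#'
#' Residuals of the phenotype regressed on intercept + sex + age + age^2,
#' then rank-inverse-normal transformed ([rank_normalize()]). Intended to be
#' applied within the validation group. Near-constant residuals trigger a
#' warning (the normalized output is then driven by numerical noise).
#'
#' @param phenotype numeric vector (quantitative trait).
#' @param sex,age covariate vectors.
#' @return normalized vector (mean ~ 0, SD ~ 1), NA preserved.
#' @export
normalize_phenotype <- function(phenotype, sex, age) {
  stopifnot(length(phenotype) == length(sex), length(phenotype) == length(age))
  keep <- !is.na(phenotype) & !is.na(sex) & !is.na(age)
  if (!any(keep)) stop("no complete cases: all phenotype/covariate values missing")
  out <- rep(NA_real_, length(phenotype))
  X <- cbind(1, sex[keep], age[keep], age[keep]^2)
  res <- stats::lm.fit(X, phenotype[keep])$residuals
  if (stats::sd(res) < 1e-10 * max(stats::sd(phenotype[keep]), 1)) {
    warning("near-constant residuals after covariate adjustment")
  }
  out[keep] <- rank_normalize(res)
  out
}

#' Per-trait delta statistics between mainland and non-mainland groups
#'
#' `delta_prs   = mean(normalized PRS | non-mainland) - mean(normalized PRS | mainland)` and
#' `delta_pheno` analogously on the normalized phenotype. For binary traits
#' pass the raw 0/1 phenotype with `binary = TRUE`: the phenotype side is
#' then the prevalence difference between the groups.
#'
#' @param normalized_prs numeric vector (rank-normalized within the scored
#'   group).
#' @param normalized_pheno numeric vector (normalized phenotype, or raw 0/1
#'   if `binary`).
#' @param cluster_labels vector assigning each sample to a group.
#' @param mainland,nonmainland the two group labels; `nonmainland = NULL`
#'   means every label other than `mainland`.
#' @param binary treat the phenotype side as prevalence.
#' @param trait_name recorded in the report.
#' @return `delta_report` one-row data.frame: `trait_name, delta_prs,
#'   delta_pheno, bias, sign_concordant, n_mainland, n_nonmainland`.
#' @export
delta_statistics <- function(normalized_prs, normalized_pheno, cluster_labels,
                             mainland = "mainland", nonmainland = NULL,
                             binary = FALSE, trait_name = "trait") {
  n <- length(cluster_labels)
  stopifnot(length(normalized_prs) == n, length(normalized_pheno) == n)
  is_main <- cluster_labels == mainland
  is_non <- if (is.null(nonmainland)) !is_main else cluster_labels == nonmainland
  if (!any(is_main) || !any(is_non)) stop("both groups must be non-empty")
  gmean <- function(v, g) mean(v[g], na.rm = TRUE)
  delta_prs <- gmean(normalized_prs, is_non) - gmean(normalized_prs, is_main)
  delta_pheno <- gmean(normalized_pheno, is_non) - gmean(normalized_pheno, is_main)
  out <- data.frame(
    trait_name = trait_name, delta_prs = delta_prs, delta_pheno = delta_pheno,
    bias = abs(delta_prs - delta_pheno),
    sign_concordant = (delta_prs * delta_pheno) > 0,
    n_mainland = sum(is_main), n_nonmainland = sum(is_non),
    binary = binary, stringsAsFactors = FALSE
  )
  class(out) <- c("delta_report", "data.frame")
  out
}

#' Per-trait BIAS statistic
#'
#' `bias = |delta_prs - delta_pheno|`: the absolute difference between the
#' PRS group difference and the phenotypic group difference, both on their
#' normalized scales.
#'
#' @param delta a `delta_report` row (or any list with `delta_prs`,
#'   `delta_pheno`).
#' @return nonnegative scalar.
#' @export
bias_statistic <- function(delta) {
  abs(delta$delta_prs - delta$delta_pheno)
}

#' Correlation scan of per-trait bias against candidate confounders
#'
#' Pearson correlation (two-sided test, no multiplicity adjustment) of the
#' per-trait BIAS against each numeric confounder column across traits.
#' Distributional confounders (age/sex composition) are descriptive and
#' should be summarized separately, not tested.
#'
#' @param bias numeric vector of per-trait BIAS values (>= 3 traits).
#' @param confounders data.frame of numeric columns, one row per trait
#'   (e.g. discovery h2, |h2 difference between groups|, variance explained,
#'   |variance-explained difference|, number of model SNPs).
#' @return data.frame `confounder, r, p_value, n` (r = NA for constant
#'   columns).
#' @export
confounder_scan <- function(bias, confounders) {
  confounders <- as.data.frame(confounders)
  if (length(bias) < 3) stop("need at least 3 traits for the confounder scan")
  stopifnot(nrow(confounders) == length(bias))
  rows <- lapply(names(confounders), function(cn) {
    x <- confounders[[cn]]
    ok <- !is.na(x) & !is.na(bias)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(bias[ok]) == 0) {
      return(data.frame(confounder = cn, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(bias[ok], x[ok], method = "pearson")
    data.frame(confounder = cn, r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Build the GWAS covariate matrix: sex, age, age^2, optional PC scores,
# cluster indicator (1 = non-mainland).
.gwas_covariates <- function(samples, cluster_labels, mainland, pcs = NULL) {
  C <- cbind(sex = samples$sex, age = samples$age, age2 = samples$age^2)
  if (!is.null(pcs) && ncol(pcs) > 0) {
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    C <- cbind(C, pcs)
  }
  cbind(C, nonmainland = as.numeric(cluster_labels != mainland))
}

#' Phenome-wide PRS differentiation scan
#'
#' Orchestrates, for every trait over one shared cluster-stratified
#' discovery/validation split: discovery GWAS (linear or logistic) adjusted
#' for sex, age, age^2, `n_pcs` discovery-fit principal components and the
#' mainland/non-mainland indicator; clumping + thresholding against the
#' discovery genotypes; scoring and rank normalization of the PRS within the
#' validation group; phenotype normalization within the validation group
#' (prevalence for binary traits); and the per-trait delta/BIAS statistics
#' with the incremental variance explained by the PRS. Trait-level failures
#' are caught and logged, and the scan continues.
#'
#' @param genotypes a [genotype_matrix()] for the full cohort.
#' @param pheno data.frame with `sample_id`, `sex`, `age` and one column per
#'   trait (same sample order as `genotypes`).
#' @param trait_names character vector of trait columns in `pheno`.
#' @param cluster_labels per-sample cluster labels.
#' @param mainland label of the mainland (reference) cluster; all other
#'   labels count as non-mainland.
#' @param seed master seed (split and any stochastic stage derive from it).
#' @param n_pcs principal components used as GWAS covariates (fitted on the
#'   discovery split only, projected onto validation).
#' @param binary_traits subset of `trait_names` treated as 0/1 traits.
#' @param p_threshold,clump_window_bp,clump_r2 PRS construction parameters.
#' @param compute_confounders also estimate per-trait Haseman-Elston
#'   heritability (whole discovery group and per cluster) and per-cluster
#'   variance explained — the inputs of [confounder_scan()]. Adds O(n^2 m)
#'   work per scan.
#' @return list with `deltas` (one row per successful trait, including
#'   `variance_explained` and `n_model_snps`), `overall` (Pearson r/p of
#'   delta_prs vs delta_pheno across traits, plus the same restricted to
#'   traits with variance explained > 1%), `confounders` (correlation table
#'   or NULL), `confounder_values`, `split`, `failures` (named character
#'   vector of error messages).
#' @export
phenome_scan <- function(genotypes, pheno, trait_names, cluster_labels,
                         mainland = NULL, seed = 1L, n_pcs = 5,
                         binary_traits = character(),
                         p_threshold = 5e-6, clump_window_bp = 1e6,
                         clump_r2 = 0.1, compute_confounders = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  sm <- genotypes$samples
  stopifnot(identical(pheno$sample_id, sm$sample_id))
  if (is.null(mainland)) {
    mainland <- names(which.max(table(cluster_labels)))
  }
  split <- split_cohort(sm$sample_id, cluster_labels, seed)
  is_disc <- split$group == "discovery"
  g_disc <- subset_genotypes(genotypes, samples = which(is_disc))
  g_val <- subset_genotypes(genotypes, samples = which(!is_disc))

  # drop variants monomorphic in the discovery split from association/PCA
  p_disc <- .col_freq(g_disc$dosages)
  poly <- !is.na(p_disc) & p_disc > 0 & p_disc < 1
  g_disc <- subset_genotypes(g_disc, variants = which(poly))
  g_val_assoc <- subset_genotypes(g_val, variants = which(poly))

  pcs_disc <- pcs_val <- NULL
  if (n_pcs > 0) {
    std_disc <- standardize_genotypes(g_disc)
    pca <- genotype_pca(std_disc, k = n_pcs)
    pcs_disc <- pca$scores
    pcs_val <- pca_project(pca, g_val_assoc)
  }
  cl_disc <- cluster_labels[is_disc]
  cl_val <- cluster_labels[!is_disc]
  C_disc <- .gwas_covariates(pheno[is_disc, ], cl_disc, mainland, pcs_disc)
  C_val <- .gwas_covariates(pheno[!is_disc, ], cl_val, mainland, pcs_val)

  grm_disc <- grm_main <- grm_non <- NULL
  if (compute_confounders) {
    std_disc <- standardize_genotypes(g_disc)
    grm_disc <- tcrossprod(std_disc$x) / ncol(std_disc$x)
    im <- cl_disc == mainland
    grm_main <- grm_disc[im, im]
    grm_non <- grm_disc[!im, !im]
  }

  delta_rows <- list()
  conf_rows <- list()
  failures <- character(0)
  for (tn in trait_names) {
    res <- tryCatch({
      y <- pheno[[tn]]
      if (is.null(y)) stop("trait column not found")
      is_binary <- tn %in% binary_traits
      y_disc <- y[is_disc]
      assoc <- if (is_binary) {
        logistic_assoc(g_disc, y_disc, C_disc, trait_name = tn)
      } else {
        linear_assoc(g_disc, y_disc, C_disc, trait_name = tn)
      }
      model <- clump_and_threshold(assoc, g_disc, p_threshold = p_threshold,
                                   clump_window_bp = clump_window_bp,
                                   clump_r2 = clump_r2)
      raw <- score_prs(g_val_assoc, model)$raw_score
      norm_prs <- if (nrow(model) > 0) {
        suppressWarnings(rank_normalize(raw))
      } else {
        rep(0, length(raw))
      }
      y_val <- y[!is_disc]
      norm_pheno <- if (is_binary) y_val else {
        normalize_phenotype(y_val, pheno$sex[!is_disc], pheno$age[!is_disc])
      }
      dr <- delta_statistics(norm_prs, norm_pheno, cl_val,
                             mainland = mainland, binary = is_binary,
                             trait_name = tn)
      ve <- tryCatch(
        variance_explained(if (is_binary) y_val else norm_pheno,
                           norm_prs, C_val),
        error = function(e) NA_real_)
      dr$variance_explained <- ve
      dr$n_model_snps <- nrow(model)
      if (compute_confounders) {
        im_val <- cl_val == mainland
        h2_all <- he_regression_h2(NULL, y_disc, grm = grm_disc)$h2
        h2_m <- he_regression_h2(NULL, y_disc[cl_disc == mainland], grm = grm_main)$h2
        h2_n <- he_regression_h2(NULL, y_disc[cl_disc != mainland], grm = grm_non)$h2
        ve_m <- tryCatch(variance_explained(norm_pheno[im_val], norm_prs[im_val],
                                            C_val[im_val, colnames(C_val) != "nonmainland"]),
                         error = function(e) NA_real_)
        ve_n <- tryCatch(variance_explained(norm_pheno[!im_val], norm_prs[!im_val],
                                            C_val[!im_val, colnames(C_val) != "nonmainland"]),
                         error = function(e) NA_real_)
        conf_rows[[tn]] <- data.frame(
          trait_name = tn, h2_discovery = h2_all,
          h2_group_absdiff = abs(h2_m - h2_n),
          variance_explained = ve,
          variance_explained_absdiff = abs(ve_m - ve_n),
          n_model_snps = nrow(model), stringsAsFactors = FALSE
        )
      }
      dr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[tn] <- conditionMessage(res)
    } else {
      delta_rows[[tn]] <- res
    }
  }
  deltas <- if (length(delta_rows)) do.call(rbind, delta_rows) else NULL
  overall <- NULL
  if (!is.null(deltas) && nrow(deltas) >= 3) {
    ct <- stats::cor.test(deltas$delta_prs, deltas$delta_pheno)
    overall <- list(r = unname(ct$estimate), p_value = ct$p.value,
                    n_traits = nrow(deltas))
    informative <- !is.na(deltas$variance_explained) &
      deltas$variance_explained > 0.01
    if (sum(informative) >= 3) {
      ct2 <- stats::cor.test(deltas$delta_prs[informative],
                             deltas$delta_pheno[informative])
      overall$r_restricted <- unname(ct2$estimate)
      overall$p_restricted <- ct2$p.value
      overall$n_restricted <- sum(informative)
    }
  }
  confounders <- NULL
  conf_values <- if (length(conf_rows)) do.call(rbind, conf_rows) else NULL
  if (!is.null(conf_values) && nrow(conf_values) >= 3) {
    confounders <- confounder_scan(
      deltas$bias[match(conf_values$trait_name, deltas$trait_name)],
      conf_values[, setdiff(names(conf_values), "trait_name")]
    )
  }
  list(deltas = deltas, overall = overall, confounders = confounders,
       confounder_values = conf_values, split = split, failures = failures)
}

#' Run one scenario replicate end-to-end
#'
#' Generates a preset cohort ([scenario_preset()]), simulates its trait(s),
#' and runs [phenome_scan()] with the mainland/non-mainland indicator
#' included as a GWAS covariate. Cluster labels are taken from the
#' simulation truth by default (`cluster_from = "truth"`), which isolates
#' the score-bias machinery from cluster estimation; `"pca"` assigns them
#' with 2-means on PC1/PC2 instead.
#'
#' @param name preset name passed to [scenario_preset()].
#' @param seed replicate seed (drives cohort, traits and split).
#' @param n_pcs PCs used as GWAS covariates.
#' @param cluster_from `"truth"` or `"pca"`.
#' @return the [phenome_scan()] result, with the cohort's delta report in
#'   `$deltas`.
#' @export
run_scenario_replicate <- function(name, seed, n_pcs = 5,
                                   cluster_from = c("truth", "pca")) {
  cluster_from <- match.arg(cluster_from)
  sc <- scenario_preset(name, seed = seed)
  freqs <- sample_subpop_frequencies(sc$config)
  geno <- simulate_genotypes(freqs, sc$config)
  pheno <- NULL
  binary <- character(0)
  for (tr in sc$traits) {
    tp <- if (tr$type == "binary") {
      binary <- c(binary, tr$trait_name)
      simulate_binary_trait(geno, tr, seed = seed)
    } else {
      simulate_quantitative_trait(geno, tr, seed = seed)
    }
    pheno <- if (is.null(pheno)) tp else cbind(pheno, tp[tr$trait_name])
  }
  clusters <- if (cluster_from == "truth") {
    geno$samples$subpopulation_truth
  } else {
    emb <- embed_genotypes(geno, method = "pca", n_pcs = 2,
                           seed = derive_seed(seed, "embed"))
    assign_clusters(emb, k_clusters = 2, seed = derive_seed(seed, "kmeans"))
  }
  phenome_scan(geno, pheno,
               trait_names = vapply(sc$traits, `[[`, "", "trait_name"),
               cluster_labels = clusters, mainland = NULL, seed = seed,
               n_pcs = n_pcs, binary_traits = binary)
}
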