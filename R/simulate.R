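# Synthetic structured-cohort generator.
#
# The island model: subpopulation allele frequencies drift from a shared
# ancestral frequency via Balding-Nichols Beta steps, p' ~ Beta(p(1-F)/F,
# (1-p)(1-F)/F), so Var(p') = F * p * (1-p). Drift paths are hierarchical:
# subpopulations that share a prefix of their F path share the corresponding
# draws, which models a large "mainland" group and smaller insular groups that
# split off from it.

#' Build a simulation configuration
#'
#' @param seed integer master seed for the cohort.
#' @param m_variants number of variants.
#' @param subpopulations list of `list(name=, n_samples=, fst_path=)`; each
#'   `fst_path` is a vector of drift coefficients `F` in `[0, 1)` applied
#'   hierarchically from the ancestral population. Equal path prefixes share
#'   drift draws.
#' @param ancestral_freq_range ancestral frequencies drawn Uniform(low, high).
#' @param n_chromosomes number of chromosomes variants are laid out on
#'   (contiguous blocks).
#' @param spacing_bp base-pair spacing between adjacent variants.
#' @return `sim_config` object.
#' @export
sim_config <- function(seed, m_variants, subpopulations,
                       ancestral_freq_range = c(0.05, 0.95),
                       n_chromosomes = 10, spacing_bp = 50000) {
  stopifnot(m_variants >= 1, length(ancestral_freq_range) == 2)
  lo <- ancestral_freq_range[1]; hi <- ancestral_freq_range[2]
  if (!(lo > 0 && hi < 1 && lo < hi)) stop("ancestral_freq_range must satisfy 0 < low < high < 1")
  for (sp in subpopulations) {
    if (is.null(sp$name) || is.null(sp$n_samples) || is.null(sp$fst_path)) {
      stop("each subpopulation needs name, n_samples, fst_path")
    }
    if (sp$n_samples < 1) stop("n_samples must be >= 1")
    if (length(sp$fst_path) < 1) stop("fst_path needs at least one drift step (use 0 for none)")
    if (any(sp$fst_path < 0 | sp$fst_path >= 1)) stop("all F must be in [0, 1); F = 1 rejected")
  }
  if (anyDuplicated(vapply(subpopulations, `[[`, "", "name"))) stop("duplicate subpopulation names")
  structure(
    list(seed = as.integer(seed), m_variants = as.integer(m_variants),
         subpopulations = subpopulations,
         ancestral_freq_range = c(lo, hi),
         n_chromosomes = as.integer(n_chromosomes),
         spacing_bp = as.integer(spacing_bp)),
    class = "sim_config"
  )
}

# One Balding-Nichols drift step for a vector of frequencies.
.bn_drift <- function(p, f, eps = 1e-3) {
  if (f == 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  q <- stats::rbeta(length(p), a, b)
  pmin(pmax(q, eps), 1 - eps)
}

#' Sample per-subpopulation allele frequencies under hierarchical drift
#'
#' Ancestral frequencies are Uniform over `ancestral_freq_range`; each entry
#' of a subpopulation's `fst_path` applies a Balding-Nichols Beta step.
#' Internal path steps are shared: subpopulations with identical path
#' prefixes share those drift draws exactly, which is how a common
#' intermediate ancestor is expressed. The final (leaf) step is always a
#' subpopulation's own independent draw — so two subpopulations each with
#' path `c(0.01)` are two independent islands at F = 0.01 — except that an
#' `F = 0` leaf copies its parent unchanged (two subpopulations sharing a
#' prefix and ending in `F = 0` are therefore identical). Drifted
#' frequencies are clipped to `(0.001, 0.999)` so no variant becomes
#' monomorphic by construction.
#'
#' @param config a [sim_config()].
#' @return matrix `m_variants x (1 + n_subpop)`; first column `ancestral`,
#'   remaining columns named by subpopulation.
#' @export
sample_subpop_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_variants
  set.seed(derive_seed(config$seed, "ancestral_freq"))
  p0 <- stats::runif(m, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  # internal nodes cached by the F-path prefix; draws seeded per node so
  # traversal order cannot matter
  cache <- new.env(parent = emptyenv())
  node_freq <- function(path) {
    if (length(path) == 0) return(p0)
    key <- paste(format(path, digits = 15), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    parent <- node_freq(path[-length(path)])
    f <- path[length(path)]
    set.seed(derive_seed(config$seed, paste0("drift|", key)))
    out <- .bn_drift(parent, f)
    cache[[key]] <- out
    out
  }
  leaf_freq <- function(sp) {
    path <- sp$fst_path
    parent <- node_freq(path[-length(path)])
    f <- path[length(path)]
    if (f == 0) return(parent)
    set.seed(derive_seed(config$seed, paste0("leaf|", sp$name)))
    .bn_drift(parent, f)
  }
  cols <- lapply(config$subpopulations, leaf_freq)
  freqs <- cbind(ancestral = p0, do.call(cbind, cols))
  colnames(freqs) <- c("ancestral", vapply(config$subpopulations, `[[`, "", "name"))
  freqs
}

#' Simulate genotypes for a structured cohort
#'
#' Within each subpopulation, dosages are Hardy-Weinberg `Binomial(2, p)`
#' draws at that subpopulation's frequencies. Sample covariates follow the
#' defaults age ~ Uniform(30, 80) years and sex ~ Bernoulli(0.5) (coded 1/2).
#' The generating subpopulation is recorded in `subpopulation_truth` and, as
#' the recruitment-region analog, in `region_label`.
#'
#' @param freqs frequency matrix from [sample_subpop_frequencies()].
#' @param config the matching [sim_config()].
#' @return A [genotype_matrix()] with attribute `freqs` (the frequency matrix).
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_variants
  subs <- config$subpopulations
  n_total <- sum(vapply(subs, `[[`, 0, "n_samples"))

  set.seed(derive_seed(config$seed, "genotypes"))
  blocks <- vector("list", length(subs))
  for (k in seq_along(subs)) {
    n_k <- subs[[k]]$n_samples
    p_k <- pmin(pmax(freqs[, subs[[k]]$name], 1e-3), 1 - 1e-3)
    g <- stats::rbinom(n_k * m, 2L, rep(p_k, each = n_k))
    blocks[[k]] <- matrix(g, nrow = n_k, ncol = m)
  }
  dos <- do.call(rbind, blocks)

  # chromosome layout: contiguous equal blocks
  per_chr <- ceiling(m / config$n_chromosomes)
  chr <- rep(seq_len(config$n_chromosomes), each = per_chr)[seq_len(m)]
  idx_in_chr <- stats::ave(seq_len(m), chr, FUN = seq_along)
  variants <- data.frame(
    variant_id = sprintf("var%06d", seq_len(m)),
    chromosome = as.character(chr),
    position_bp = idx_in_chr * config$spacing_bp,
    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE
  )
  set.seed(derive_seed(config$seed, "covariates"))
  samples <- data.frame(
    sample_id = sprintf("ind%06d", seq_len(n_total)),
    sex = stats::rbinom(n_total, 1, 0.5) + 1L,
    age = round(stats::runif(n_total, 30, 80), 1),
    region_label = rep(vapply(subs, `[[`, "", "name"),
                       vapply(subs, `[[`, 0, "n_samples")),
    cluster_label = NA_character_,
    subpopulation_truth = rep(vapply(subs, `[[`, "", "name"),
                              vapply(subs, `[[`, 0, "n_samples")),
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dos, variants, samples)
  attr(g, "freqs") <- freqs
  g
}

#' Define a polygenic trait model
#'
#' Effects are defined on genotypes standardized by the *ancestral* frequency,
#' `g_std = (g - 2 p0) / sqrt(2 p0 (1 - p0))`, so allele-frequency drift
#' between subpopulations induces true mean differences in genetic value —
#' the mechanism that makes PRS deviations real rather than artefactual.
#' Effect magnitudes are `sqrt(h2 / m_causal)` so that the genetic variance on
#' the ancestral scale equals `h2`; residual noise is `N(0, 1 - h2)`.
#'
#' @param trait_name name of the trait column.
#' @param type `"quantitative"` or `"binary"`.
#' @param m_causal number of causal variants.
#' @param h2 narrow-sense heritability in `[0, 1]` (liability scale for
#'   binary traits).
#' @param env_offset named vector of per-subpopulation mean shifts, phenotype
#'   (or liability) SD units; unnamed subpopulations get 0.
#' @param prevalence binary traits only, in (0, 1).
#' @param covariate_effects list with `sex`, `age`, `age2` coefficients
#'   (applied to sex in {1,2} and centered age).
#' @param genetic_shift `"random"` (effect signs random) or
#'   `"negative"`/`"positive"`: orient each causal effect so the second
#'   subpopulation's true genetic mean is shifted in that direction relative
#'   to the first (used by the scenario presets).
#' @param beta optional explicit per-causal effect sizes (overrides
#'   `h2`-derived magnitudes).
#' @return `trait_model` object.
#' @export
trait_model <- function(trait_name, type = c("quantitative", "binary"),
                        m_causal, h2, env_offset = NULL, prevalence = NULL,
                        covariate_effects = list(sex = 0, age = 0, age2 = 0),
                        genetic_shift = c("random", "negative", "positive"),
                        beta = NULL) {
  type <- match.arg(type)
  genetic_shift <- match.arg(genetic_shift)
  stopifnot(h2 >= 0, h2 <= 1, m_causal >= 0)
  if (type == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1) {
      stop("binary traits need prevalence in (0, 1)")
    }
  }
  if (!is.null(beta) && length(beta) != m_causal) stop("beta must have length m_causal")
  ce <- list(sex = 0, age = 0, age2 = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(
    list(trait_name = trait_name, type = type, m_causal = as.integer(m_causal),
         h2 = h2, env_offset = env_offset, prevalence = prevalence,
         covariate_effects = ce, genetic_shift = genetic_shift, beta = beta),
    class = "trait_model"
  )
}

# Shared machinery: realized liability-scale value (genetic + covariates +
# offset + noise), plus the truth bookkeeping.
.simulate_liability <- function(genotypes, trait, seed) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(trait, "trait_model"))
  freqs <- attr(genotypes, "freqs")
  if (is.null(freqs)) stop("genotypes lack the simulator's frequency attribute")
  m <- ncol(genotypes$dosages)
  n <- nrow(genotypes$dosages)
  if (trait$m_causal > m) stop("m_causal exceeds the number of variants")
  has_cov <- any(unlist(trait$covariate_effects) != 0)
  if (trait$h2 == 1 && has_cov) {
    stop("h2 = 1 leaves no residual variance for covariate effects (variance bookkeeping)")
  }

  set.seed(derive_seed(seed, paste0("trait_causal|", trait$trait_name)))
  causal <- sort(sample.int(m, trait$m_causal))
  p0 <- freqs[causal, "ancestral", drop = TRUE]
  sd0 <- sqrt(2 * p0 * (1 - p0))

  if (!is.null(trait$beta)) {
    beta <- trait$beta
  } else {
    mag <- if (trait$m_causal > 0) sqrt(trait$h2 / trait$m_causal) else numeric(0)
    set.seed(derive_seed(seed, paste0("trait_sign|", trait$trait_name)))
    sgn <- sample(c(-1, 1), trait$m_causal, replace = TRUE)
    if (trait$genetic_shift != "random") {
      sp_names <- setdiff(colnames(freqs), "ancestral")
      if (length(sp_names) < 2) stop("directional genetic_shift needs >= 2 subpopulations")
      dfreq <- freqs[causal, sp_names[2]] - freqs[causal, sp_names[1]]
      want <- if (trait$genetic_shift == "negative") -1 else 1
      sgn <- ifelse(dfreq == 0, sgn, want * sign(dfreq))
    }
    beta <- mag * sgn
  }

  gs <- sweep(sweep(genotypes$dosages[, causal, drop = FALSE], 2, 2 * p0, "-"),
              2, sd0, "/")
  gs[is.na(gs)] <- 0
  gvalue <- if (trait$m_causal > 0) as.vector(gs %*% beta) else numeric(n)

  sm <- genotypes$samples
  cov_term <- trait$covariate_effects$sex * sm$sex +
    trait$covariate_effects$age * (sm$age - mean(sm$age)) +
    trait$covariate_effects$age2 * (sm$age - mean(sm$age))^2

  offset <- rep(0, n)
  if (!is.null(trait$env_offset)) {
    idx <- match(sm$subpopulation_truth, names(trait$env_offset))
    offset <- ifelse(is.na(idx), 0, unname(trait$env_offset)[idx])
  }
  set.seed(derive_seed(seed, paste0("trait_noise|", trait$trait_name)))
  e <- stats::rnorm(n, 0, sqrt(1 - trait$h2))
  list(liability0 = gvalue + cov_term + e,  # offset-free
       offset = offset, gvalue = gvalue, beta = beta, causal = causal)
}

#' Simulate a quantitative trait
#'
#' `y = sum(beta_j g_std_j) + covariate terms + env_offset[subpop] + e` with
#' `e ~ N(0, 1 - h2)`.
#'
#' @param genotypes a simulated [genotype_matrix()] (needs its `freqs`
#'   attribute).
#' @param trait a [trait_model()].
#' @param seed integer seed.
#' @return data.frame `sample_id, sex, age, <trait_name>` with attribute
#'   `truth` (causal indices, effects, per-sample genetic values,
#'   subpopulation) for parameter-recovery tests.
#' @export
simulate_quantitative_trait <- function(genotypes, trait, seed) {
  if (trait$type != "quantitative") stop("trait model is not quantitative")
  parts <- .simulate_liability(genotypes, trait, seed)
  sm <- genotypes$samples
  out <- data.frame(sample_id = sm$sample_id, sex = sm$sex, age = sm$age,
                    stringsAsFactors = FALSE)
  out[[trait$trait_name]] <- parts$liability0 + parts$offset
  attr(out, "truth") <- list(causal = parts$causal, beta = parts$beta,
                             genetic_value = parts$gvalue,
                             subpopulation = sm$subpopulation_truth)
  out
}

#' Simulate a binary (liability-threshold) trait
#'
#' The liability is the quantitative construction above; an individual is a
#' case iff `liability0 + offset > qnorm(1 - prevalence)`, with the threshold
#' computed on the offset-free liability scale, so per-subpopulation offsets
#' shift subpopulation prevalence. The closed-form prevalence in a
#' subpopulation with offset `d` is `1 - pnorm(qnorm(1 - prev) - d)` (exact
#' when covariate effects are zero, so the offset-free liability is standard
#' normal).
#'
#' @inheritParams simulate_quantitative_trait
#' @return data.frame as in [simulate_quantitative_trait()], trait column in
#'   {0, 1}.
#' @export
simulate_binary_trait <- function(genotypes, trait, seed) {
  if (trait$type != "binary") stop("trait model is not binary")
  parts <- .simulate_liability(genotypes, trait, seed)
  thr <- stats::qnorm(1 - trait$prevalence)
  y <- as.integer(parts$liability0 + parts$offset > thr)
  if (all(y == 0L) || all(y == 1L)) {
    warning("degenerate binary trait: all samples are ",
            if (all(y == 1L)) "cases" else "controls")
  }
  sm <- genotypes$samples
  out <- data.frame(sample_id = sm$sample_id, sex = sm$sex, age = sm$age,
                    stringsAsFactors = FALSE)
  out[[trait$trait_name]] <- y
  attr(out, "truth") <- list(causal = parts$causal, beta = parts$beta,
                             genetic_value = parts$gvalue,
                             liability = parts$liability0 + parts$offset,
                             subpopulation = sm$subpopulation_truth)
  out
}

#' Preset simulation scenarios
#'
#' Three named scenarios of a two-cluster cohort (one large mainland-like
#' subpopulation, one smaller insular one that drifted further):
#' \describe{
#'   \item{height_like}{true genetic mean shift in the insular group and its
#'     environmental offset have the same (negative) sign, so the PRS
#'     deviation and phenotype deviation are expected to be sign-concordant.}
#'   \item{bmi_like}{genetic shift negative but environmental offset positive
#'     and larger in magnitude (a rapid environment-driven reversal), so the
#'     deviations are expected to be sign-discordant.}
#'   \item{null}{both groups share the full drift path (identical allele
#'     frequencies) and there is no offset; both deltas are expected near 0.}
#' }
#'
#' @param name one of `"height_like"`, `"bmi_like"`, `"null"`.
#' @param seed master seed for the cohort configuration.
#' @param n_scale multiplier on the default subpopulation sample sizes
#'   (1800 mainland + 600 non-mainland); useful for quick smoke runs.
#' @return list with elements `config` (a [sim_config()]) and `traits`
#'   (list of [trait_model()]).
#' @export
scenario_preset <- function(name, seed = 1L, n_scale = 1) {
  presets <- c("height_like", "bmi_like", "null")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ", paste(presets, collapse = ", "))
  }
  n_main <- max(20L, as.integer(round(1800 * n_scale)))
  n_non <- max(10L, as.integer(round(600 * n_scale)))
  if (name == "null") {
    subpops <- list(
      list(name = "mainland", n_samples = n_main, fst_path = c(0.005, 0)),
      list(name = "nonmainland", n_samples = n_non, fst_path = c(0.005, 0))
    )
  } else {
    subpops <- list(
      list(name = "mainland", n_samples = n_main, fst_path = c(0.002)),
      list(name = "nonmainland", n_samples = n_non, fst_path = c(0.002, 0.01))
    )
  }
  config <- sim_config(seed = seed, m_variants = 2000, subpopulations = subpops,
                       n_chromosomes = 20, spacing_bp = 200000)
  base_cov <- list(sex = 0.1, age = 0.005, age2 = 0)
  trait <- switch(
    name,
    height_like = trait_model("height_like", "quantitative", m_causal = 20,
                              h2 = 0.5,
                              env_offset = c(mainland = 0, nonmainland = -0.3),
                              covariate_effects = base_cov,
                              genetic_shift = "negative"),
    bmi_like = trait_model("bmi_like", "quantitative", m_causal = 20,
                           h2 = 0.5,
                           env_offset = c(mainland = 0, nonmainland = 0.8),
                           covariate_effects = base_cov,
                           genetic_shift = "negative"),
    null = trait_model("null_trait", "quantitative", m_causal = 20, h2 = 0.5,
                       covariate_effects = base_cov)
  )
  list(config = config, traits = list(trait))
}

#' Hudson's Fst estimator between two groups
#'
#' Ratio-of-means Hudson estimator on per-variant allele frequencies:
#' numerator `(p1 - p2)^2 - p1 q1 / (n1 - 1) - p2 q2 / (n2 - 1)`, denominator
#' `p1 q2 + p2 q1`, averaged over variants before taking the ratio.
#'
#' @param genotypes a [genotype_matrix()].
#' @param groups factor/character vector of length n with exactly two levels.
#' @return Fst estimate (scalar).
#' @export
hudson_fst <- function(genotypes, groups) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("hudson_fst needs exactly two groups")
  d1 <- genotypes$dosages[g == levels(g)[1], , drop = FALSE]
  d2 <- genotypes$dosages[g == levels(g)[2], , drop = FALSE]
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- .col_freq(d1); p2 <- .col_freq(d2)
  keep <- n1 > 1 & n2 > 1 & !is.na(p1) & !is.na(p2)
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
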