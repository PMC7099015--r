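# Variant and sample quality control: exact Hardy-Weinberg test, per-variant
# filters, windowed LD pruning, and method-of-moments relatedness (PI_HAT).

#' Default QC thresholds
#'
#' Variant filters: call rate >= 0.99, exact HWE p >= 1e-6, heterozygote
#' count >= 5, MAF >= 0.01. Relatedness: PI_HAT <= 0.125. LD pruning:
#' 50-variant windows stepped by 5, r^2 threshold 0.2.
#'
#' @param min_call_rate,hwe_p_min,min_het_count,min_maf,pi_hat_max variant and
#'   sample-pair filter thresholds.
#' @param prune_window_snps,prune_step_snps,prune_r2 LD-pruning parameters.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(min_call_rate = 0.99, hwe_p_min = 1e-6,
                          min_het_count = 5, min_maf = 0.01,
                          pi_hat_max = 0.125, prune_window_snps = 50,
                          prune_step_snps = 5, prune_r2 = 0.2) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, hwe_p_min >= 0,
            hwe_p_min <= 1, min_het_count >= 0, min_maf >= 0, min_maf <= 0.5,
            pi_hat_max >= 0, pi_hat_max <= 1, prune_window_snps >= 2,
            prune_step_snps >= 1, prune_r2 >= 0, prune_r2 <= 1)
  list(min_call_rate = min_call_rate, hwe_p_min = hwe_p_min,
       min_het_count = min_het_count, min_maf = min_maf,
       pi_hat_max = pi_hat_max, prune_window_snps = prune_window_snps,
       prune_step_snps = prune_step_snps, prune_r2 = prune_r2)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the p-value is the sum of the probabilities of all heterozygote
#' configurations whose conditional probability does not exceed that of the
#' observed configuration (plain tail sum, no mid-p). Probabilities are
#' computed by the standard recurrence over het counts of the same parity.
#' A monomorphic variant returns p = 1.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("at least one genotyped sample required")
  n_a <- 2 * n_hom1 + n_het          # count of allele "1"
  n_b <- 2 * n_hom2 + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)           # monomorphic
  # possible het counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # recurse downward from the largest possible het count in log space
  # (ratios toward the mode can overflow a double for large n):
  # P(h-2)/P(h) = h(h-1) / (4 (hom1+1)(hom2+1)) with hom counts taken at h
  i0 <- length(hets)
  logp <- numeric(i0)
  if (i0 >= 2) for (i in i0:2) {
    h <- hets[i]
    hom1 <- (n_a - h) / 2
    hom2 <- (n_b - h) / 2
    logp[i - 1] <- logp[i] + log(h) + log(h - 1) -
      log(4) - log(hom1 + 1) - log(hom2 + 1)
  }
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts: het count has wrong parity")
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

#' Per-variant quality control
#'
#' A variant fails iff call rate < `min_call_rate`, exact HWE p <
#' `hwe_p_min`, heterozygote count < `min_het_count`, or MAF < `min_maf`
#' (MAF on non-missing dosages). Each excluded variant is annotated with
#' every rule it fails, so the filter set is order-free and idempotent.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @return data.frame: `variant_id, call_rate, maf, het_count, hwe_p, pass,
#'   fail_rules` (comma-separated rule names, "" when passing).
#' @export
variant_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  het <- colSums(d == 1, na.rm = TRUE)
  hom1 <- colSums(d == 2, na.rm = TRUE)
  hom2 <- colSums(d == 0, na.rm = TRUE)
  p1 <- (2 * hom1 + het) / (2 * pmax(hom1 + het + hom2, 1))
  maf <- pmin(p1, 1 - p1)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (hom1[j] + het[j] + hom2[j] == 0) return(NA_real_)
    hwe_exact_test(hom1[j], het[j], hom2[j])
  }, numeric(1))
  rules <- cbind(
    call_rate = call_rate < thresholds$min_call_rate,
    hwe = !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min,
    het_count = het < thresholds$min_het_count,
    maf = maf < thresholds$min_maf
  )
  fail_rules <- apply(rules, 1, function(r) paste(colnames(rules)[r], collapse = ","))
  data.frame(
    variant_id = genotypes$variants$variant_id,
    call_rate = call_rate, maf = maf, het_count = het, hwe_p = hwe_p,
    pass = fail_rules == "", fail_rules = fail_rules,
    stringsAsFactors = FALSE
  )
}

#' Pairwise genotypic r-squared between two variants
#'
#' Squared Pearson correlation of dosage vectors over jointly non-missing
#' samples (composite LD). A zero-variance vector yields r^2 = 0 with a
#' warning (treated as unlinked for pruning).
#'
#' @param genotypes a [genotype_matrix()].
#' @param i,j variant indices or ids.
#' @return r^2 in `[0, 1]`.
#' @export
pairwise_r2 <- function(genotypes, i, j) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.character(i)) i <- match(i, genotypes$variants$variant_id)
  if (is.character(j)) j <- match(j, genotypes$variants$variant_id)
  gi <- genotypes$dosages[, i]
  gj <- genotypes$dosages[, j]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  if (length(gi) < 2 || stats::var(gi) == 0 || stats::var(gj) == 0) {
    warning("zero dosage variance among jointly non-missing samples; r2 set to 0")
    return(0)
  }
  stats::cor(gi, gj)^2
}

# r^2 matrix for a dosage submatrix (pairwise-complete); zero-variance columns
# give 0 against everything.
.r2_matrix <- function(d) {
  suppressWarnings(r <- stats::cor(d, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r^2
}

#' Windowed LD pruning
#'
#' PLINK-style `--indep-pairwise` analog: slide a window of
#' `prune_window_snps` variants advanced by `prune_step_snps` along each
#' chromosome (variants in position order); within a window, while any
#' surviving pair has r^2 > `prune_r2`, remove one variant of the
#' worst-offending pair — the one with lower MAF, ties broken by removing the
#' later position. Deterministic and position-order stable.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @return character vector of pruned-in (surviving) variant ids, in position
#'   order.
#' @export
ld_prune <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  d <- genotypes$dosages
  p <- .col_freq(d)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, nrow(v))
  ord <- order(v$chromosome, v$position_bp)
  win <- thresholds$prune_window_snps
  step <- thresholds$prune_step_snps
  for (chr in unique(v$chromosome[ord])) {
    idx <- ord[v$chromosome[ord] == chr]   # position-sorted indices on chr
    m_c <- length(idx)
    starts <- seq(1, max(1, m_c), by = step)
    for (s in starts) {
      w <- idx[s:min(s + win - 1, m_c)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      r2 <- .r2_matrix(d[, w, drop = FALSE])
      diag(r2) <- 0
      while (TRUE) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[worst[1], worst[2]] <= thresholds$prune_r2) break
        a <- w[worst[1]]; b <- w[worst[2]]
        drop_v <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else if (v$position_bp[a] > v$position_bp[b]) a else b
        keep[drop_v] <- FALSE
        di <- match(drop_v, w)
        r2[di, ] <- 0; r2[, di] <- 0
      }
      if (s + win - 1 >= m_c) break
    }
  }
  v$variant_id[ord][keep[ord]]
}

# Per-variant expected IBS-state probabilities given allele frequency p,
# conditional on IBD state (method-of-moments, no finite-sample correction).
.ibs_expectations <- function(p) {
  q <- 1 - p
  list(
    e0_ibd0 = 2 * p^2 * q^2,
    e1_ibd0 = 4 * p^3 * q + 4 * p * q^3,
    e2_ibd0 = p^4 + q^4 + 4 * p^2 * q^2,
    e1_ibd1 = 2 * p^2 * q + 2 * p * q^2,
    e2_ibd1 = p^3 + q^3 + p^2 * q + p * q^2
  )
}

#' Method-of-moments PI_HAT between two samples
#'
#' Counts IBS states (IBS = 2 - |g_i - g_j|) over jointly non-missing
#' variants, compares them with their allele-frequency expectations under
#' IBD = 0/1/2, solves the moment equations for P(IBD = k), truncates the
#' probabilities to `[0, 1]` and renormalizes. `PI_HAT = P(IBD=2) +
#' 0.5 P(IBD=1)`. Intended for LD-pruned variants; sample allele frequencies
#' are used unless `freqs` is given.
#'
#' @param genotypes a [genotype_matrix()] (ideally pruned variants).
#' @param sample_i,sample_j sample indices or ids.
#' @param freqs optional per-variant allele1 frequencies.
#' @param min_overlap below this many jointly non-missing variants the
#'   estimate is flagged low-confidence (attribute `low_confidence`).
#' @return PI_HAT estimate in `[0, 1]`.
#' @export
pi_hat <- function(genotypes, sample_i, sample_j, freqs = NULL,
                   min_overlap = 100) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.character(sample_i)) sample_i <- match(sample_i, genotypes$samples$sample_id)
  if (is.character(sample_j)) sample_j <- match(sample_j, genotypes$samples$sample_id)
  gi <- genotypes$dosages[sample_i, ]
  gj <- genotypes$dosages[sample_j, ]
  if (is.null(freqs)) freqs <- .col_freq(genotypes$dosages)
  ok <- !is.na(gi) & !is.na(gj) & !is.na(freqs) & freqs > 0 & freqs < 1
  gi <- gi[ok]; gj <- gj[ok]; p <- freqs[ok]
  m <- length(gi)
  low_conf <- m < min_overlap
  ibs <- 2 - abs(gi - gj)
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
  e <- .ibs_expectations(p)
  E0_0 <- sum(e$e0_ibd0); E1_0 <- sum(e$e1_ibd0); E2_0 <- sum(e$e2_ibd0)
  E1_1 <- sum(e$e1_ibd1); E2_1 <- sum(e$e2_ibd1)
  p0 <- n0 / E0_0
  p1 <- (n1 - p0 * E1_0) / E1_1
  p2 <- (n2 - p0 * E2_0 - p1 * E2_1) / m
  pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
  if (sum(pr) == 0) pr <- c(1, 0, 0) else pr <- pr / sum(pr)
  out <- pr[3] + 0.5 * pr[2]
  attr(out, "low_confidence") <- low_conf
  out
}

#' All-pairs PI_HAT table
#'
#' @param genotypes a [genotype_matrix()] (pruned variants recommended).
#' @param freqs optional allele frequencies (defaults to sample estimates).
#' @return data.frame `sample_i, sample_j, pi_hat` over unordered pairs.
#' @export
pi_hat_all <- function(genotypes, freqs = NULL) {
  n <- nrow(genotypes$dosages)
  if (is.null(freqs)) freqs <- .col_freq(genotypes$dosages)
  pairs <- utils::combn(n, 2)
  ph <- vapply(seq_len(ncol(pairs)), function(k) {
    as.numeric(pi_hat(genotypes, pairs[1, k], pairs[2, k], freqs = freqs))
  }, numeric(1))
  data.frame(sample_i = genotypes$samples$sample_id[pairs[1, ]],
             sample_j = genotypes$samples$sample_id[pairs[2, ]],
             pi_hat = ph, stringsAsFactors = FALSE)
}

#' Greedy relatedness filtering
#'
#' Iteratively drops the individual appearing in the most sample pairs with
#' `PI_HAT > pi_hat_max` until no flagged pair remains (ties broken by
#' sample id for determinism).
#'
#' @param pihat_table data.frame from [pi_hat_all()].
#' @param pi_hat_max relatedness threshold (default 0.125).
#' @return character vector of sample ids to remove (possibly empty).
#' @export
relatedness_filter <- function(pihat_table, pi_hat_max = 0.125) {
  flagged <- pihat_table[pihat_table$pi_hat > pi_hat_max, , drop = FALSE]
  drop <- character(0)
  while (nrow(flagged) > 0) {
    counts <- sort(table(c(flagged$sample_i, flagged$sample_j)), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    victim <- sort(top)[1]
    drop <- c(drop, victim)
    flagged <- flagged[flagged$sample_i != victim & flagged$sample_j != victim, , drop = FALSE]
  }
  drop
}
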