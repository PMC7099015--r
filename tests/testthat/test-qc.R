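# Variant QC, exact HWE, LD pruning, relatedness.

# Independent HWE oracle: enumerate every heterozygote configuration with the
# observed allele counts via log-factorials (no recurrence).
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  if (min(n_a, n_b) == 0) return(1)
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  loglik <- vapply(hets, function(h) {
    h1 <- (n_a - h) / 2
    h2 <- (n_b - h) / 2
    lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) + h * log(2)
  }, numeric(1))
  pr <- exp(loglik - max(loglik))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

test_that("exact HWE test matches the enumeration oracle on spot checks", {
  expect_equal(hwe_exact_test(10, 10, 10), hwe_oracle(10, 10, 10), tolerance = 1e-12)
  # most extreme all-het configuration: p equals its own tail mass
  expect_equal(hwe_exact_test(0, 20, 0), hwe_oracle(0, 20, 0), tolerance = 1e-12)
  expect_identical(hwe_exact_test(30, 0, 0), 1)  # monomorphic
  expect_identical(hwe_exact_test(0, 0, 12), 1)
  for (trip in list(c(1, 0, 1), c(5, 1, 5), c(0, 1, 0), c(2, 7, 50))) {
    expect_equal(hwe_exact_test(trip[1], trip[2], trip[3]),
                 hwe_oracle(trip[1], trip[2], trip[3]), tolerance = 1e-12)
  }
})

test_that("variant_qc trips each rule exactly once on a constructed fixture", {
  # 5 variants x 100 samples: one fails each rule, one passes everything
  n <- 100
  hw <- function(p) rbinom(n, 2, p)
  set.seed(5)
  good <- hw(0.4)
  low_call <- hw(0.4); low_call[1:3] <- NA                # call rate 0.97
  low_maf <- c(rep(1, 1), rep(0, n - 1))                  # MAF 0.005, het 1
  few_het <- c(rep(2, 50), rep(0, 50))                    # 0 hets, HWE-awful
  hwe_bad <- rep(1, n)                                    # extreme het excess
  d <- cbind(good, low_call, low_maf, few_het, hwe_bad)
  g <- genotype_matrix(
    d, data.frame(variant_id = colnames(d), chromosome = "1",
                  position_bp = 1:5 * 1e6, allele1 = "A", allele2 = "G"),
    data.frame(sample_id = sprintf("s%03d", 1:n)))
  rep <- variant_qc(g, qc_thresholds(hwe_p_min = 1e-6))
  expect_true(rep$pass[rep$variant_id == "good"])
  expect_match(rep$fail_rules[rep$variant_id == "low_call"], "call_rate")
  expect_match(rep$fail_rules[rep$variant_id == "low_maf"], "maf")
  expect_match(rep$fail_rules[rep$variant_id == "few_het"], "het_count")
  expect_match(rep$fail_rules[rep$variant_id == "few_het"], "hwe")
  expect_equal(sum(!rep$pass), 4)
  # idempotence / rule-order independence: re-running on the survivors keeps them
  g2 <- subset_genotypes(g, variants = which(rep$pass))
  expect_true(all(variant_qc(g2, qc_thresholds(hwe_p_min = 1e-6))$pass))
})

test_that("pairwise r2 is 1 for duplicated and flipped variants, ~0 for independent", {
  g <- make_toy_genotypes(10000, 2, seed = 11)
  d <- cbind(g$dosages[, 1], g$dosages[, 1], 2 - g$dosages[, 1], g$dosages[, 2])
  gg <- genotype_matrix(
    d, data.frame(variant_id = paste0("v", 1:4), chromosome = "1",
                  position_bp = 1:4, allele1 = "A", allele2 = "G"),
    g$samples)
  expect_equal(pairwise_r2(gg, 1, 2), 1)
  expect_equal(pairwise_r2(gg, 1, 3), 1)  # orientation flip leaves r2 invariant
  expect_lt(pairwise_r2(gg, 1, 4), 0.01)
  # zero variance -> 0 with warning
  d0 <- cbind(rep(1, 5), c(0, 1, 2, 1, 0))
  g0 <- genotype_matrix(
    d0, data.frame(variant_id = c("c1", "c2"), chromosome = "1",
                   position_bp = 1:2, allele1 = "A", allele2 = "G"),
    data.frame(sample_id = paste0("x", 1:5)))
  expect_warning(r0 <- pairwise_r2(g0, 1, 2), "zero")
  expect_identical(r0, 0)
})

test_that("ld_prune keeps exactly one of a fully correlated trio and is the identity on unlinked variants", {
  g <- make_toy_genotypes(500, 1, seed = 13)
  v1 <- g$dosages[, 1]
  d <- cbind(v1, v1, 2 - v1)
  trio <- genotype_matrix(
    d, data.frame(variant_id = paste0("t", 1:3), chromosome = "1",
                  position_bp = c(1000, 2000, 3000), allele1 = "A", allele2 = "G"),
    g$samples)
  expect_length(ld_prune(trio), 1)

  ind <- make_toy_genotypes(800, 30, seed = 17)
  expect_identical(ld_prune(ind), ind$variants$variant_id)
})

test_that("pruned-in set satisfies the pairwise constraint and removals were justified", {
  # brute-force property checker over random LD-structured instances
  for (seed in 1:6) {
    set.seed(seed * 100)
    n <- 300
    base <- make_toy_genotypes(n, 12, seed = seed * 100 + 1)
    # duplicate some variants with noise to create LD blocks
    d <- base$dosages
    for (k in 1:8) {
      src <- sample(ncol(d), 1)
      noisy <- d[, src]
      flip <- runif(n) < 0.12
      noisy[flip] <- sample(0:2, sum(flip), replace = TRUE)
      d <- cbind(d, noisy)
    }
    m <- ncol(d)
    g <- genotype_matrix(
      d, data.frame(variant_id = sprintf("r%02d", 1:m), chromosome = "1",
                    position_bp = sample(1:1e6, m),
                    allele1 = "A", allele2 = "G"),
      base$samples)
    th <- qc_thresholds(prune_window_snps = 10, prune_step_snps = 3, prune_r2 = 0.2)
    kept <- ld_prune(g, th)
    idx <- match(kept, g$variants$variant_id)
    pos_order <- order(g$variants$chromosome[idx], g$variants$position_bp[idx])
    expect_identical(idx, idx[pos_order])  # position-order stable
    expect_identical(kept, ld_prune(g, th))  # deterministic
    # surviving set: no pair guaranteed to share a window exceeds the
    # threshold (ranks differing by <= window - step always co-occur)
    sorted <- order(g$variants$position_bp)
    keep_sorted <- sorted[sorted %in% idx]
    rank_of <- match(keep_sorted, sorted)
    r2full <- suppressWarnings(cor(g$dosages[, sorted]))^2
    for (a in seq_along(keep_sorted)) {
      for (b in seq_along(keep_sorted)) {
        if (b <= a) next
        if (rank_of[b] - rank_of[a] <= th$prune_window_snps - th$prune_step_snps) {
          expect_lte(r2full[rank_of[a], rank_of[b]], th$prune_r2 + 1e-12)
        }
      }
    }
    # every removed variant had a violating partner somewhere in its window
    removed <- setdiff(seq_len(m), idx)
    for (rm in removed) {
      rk <- match(rm, sorted)
      win <- r2full[rk, max(1, rk - th$prune_window_snps + 1):
                        min(m, rk + th$prune_window_snps - 1)]
      expect_gt(sort(win, decreasing = TRUE)[2], th$prune_r2)
    }
  }
})

test_that("pi_hat hits its limiting values: duplicate ~1, unrelated ~0, parent-offspring ~0.5", {
  g <- make_toy_genotypes(40, 5000, seed = 19, freq_range = c(0.15, 0.85))
  d <- g$dosages
  # append a duplicate of sample 1 and a synthetic child of samples 1 and 2
  p <- colMeans(d) / 2
  child <- rbinom(ncol(d), 1, d[1, ] / 2) + rbinom(ncol(d), 1, p)  # one allele from parent 1
  d2 <- rbind(d, d[1, ], child)
  g2 <- genotype_matrix(
    d2, g$variants,
    data.frame(sample_id = c(g$samples$sample_id, "dup1", "child")))
  n <- nrow(d2)
  expect_gte(as.numeric(pi_hat(g2, 1, n - 1)), 0.95)       # duplicate
  expect_lt(abs(as.numeric(pi_hat(g2, 1, 2))), 0.05)       # unrelated
  po <- as.numeric(pi_hat(g2, 1, n))
  expect_lt(abs(po - 0.5), 0.05)                            # parent-offspring
  # symmetry
  expect_equal(as.numeric(pi_hat(g2, 3, 7)), as.numeric(pi_hat(g2, 7, 3)))
})

test_that("relatedness_filter greedily breaks all flagged pairs", {
  tab <- data.frame(sample_i = c("a", "a", "b", "c"),
                    sample_j = c("b", "c", "c", "d"),
                    pi_hat = c(0.6, 0.3, 0.2, 0.4))
  drop <- relatedness_filter(tab, pi_hat_max = 0.125)
  left <- tab[!(tab$sample_i %in% drop | tab$sample_j %in% drop), ]
  expect_equal(nrow(left), 0)
  expect_true("c" %in% drop)  # c appears in most pairs -> removed first
})
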