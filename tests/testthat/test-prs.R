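# Clumping + thresholding, scoring, rank normalization, variance explained,
# Haseman-Elston heritability.

# Brute-force reference for the greedy clumping rule, working directly on a
# precomputed r2 matrix.
clump_oracle <- function(tbl, r2mat, p_threshold, window_bp, r2_thresh) {
  tbl <- tbl[!is.na(tbl$p_value) & tbl$p_value < p_threshold, , drop = FALSE]
  tbl <- tbl[order(tbl$p_value, tbl$position_bp, tbl$variant_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(tbl) > 0) {
    top <- tbl[1, ]
    kept <- c(kept, top$variant_id)
    tbl <- tbl[-1, , drop = FALSE]
    if (nrow(tbl) == 0) break
    drop <- tbl$chromosome == top$chromosome &
      abs(tbl$position_bp - top$position_bp) <= window_bp &
      r2mat[top$variant_id, tbl$variant_id] >= r2_thresh
    tbl <- tbl[!drop, , drop = FALSE]
  }
  kept
}

make_clump_instance <- function(seed, m_max = 15, n = 40) {
  set.seed(seed)
  m <- sample(3:m_max, 1)
  base <- make_toy_genotypes(n, m, seed = seed + 5000)
  d <- base$dosages
  # correlate some columns to create nontrivial r2
  for (k in seq_len(m %/% 3)) {
    a <- sample(m, 2)
    mix <- runif(n) < 0.7
    d[mix, a[1]] <- d[mix, a[2]]
  }
  g <- genotype_matrix(
    d, data.frame(variant_id = sprintf("c%02d", 1:m),
                  chromosome = as.character(sample(1:2, m, replace = TRUE)),
                  position_bp = sample(1:3e6, m),
                  allele1 = "A", allele2 = "G"),
    base$samples)
  assoc <- data.frame(
    variant_id = g$variants$variant_id, chromosome = g$variants$chromosome,
    position_bp = g$variants$position_bp, effect_allele = "A",
    other_allele = "G", beta = rnorm(m),
    p_value = 10^(-runif(m, 0, 9)), stringsAsFactors = FALSE)
  list(g = g, assoc = assoc)
}

test_that("clumping keeps the stronger variant of a correlated nearby pair", {
  n <- 400
  set.seed(1)
  v1 <- rbinom(n, 2, 0.5)
  v2 <- v1; swap <- runif(n) < 0.25
  v2[swap] <- rbinom(sum(swap), 2, 0.5)
  stopifnot(cor(v1, v2)^2 > 0.3)
  g <- genotype_matrix(
    cbind(v1, v2),
    data.frame(variant_id = c("a", "b"), chromosome = "1",
               position_bp = c(1.0e6, 1.5e6), allele1 = "A", allele2 = "G"),
    data.frame(sample_id = paste0("s", 1:n)))
  assoc <- data.frame(variant_id = c("a", "b"), chromosome = "1",
                      position_bp = c(1.0e6, 1.5e6), effect_allele = "A",
                      other_allele = "G", beta = c(0.2, 0.15),
                      p_value = c(1e-8, 1e-7), stringsAsFactors = FALSE)
  m1 <- clump_and_threshold(assoc, g)
  expect_identical(m1$variant_id, "a")
  # uncorrelated pair at the same distance: both retained
  g2 <- make_toy_genotypes(n, 2, seed = 2)
  g2$variants$position_bp <- c(1.0e6, 1.5e6)
  assoc2 <- assoc
  assoc2$variant_id <- g2$variants$variant_id
  stopifnot(cor(g2$dosages[, 1], g2$dosages[, 2])^2 < 0.1)
  m2 <- clump_and_threshold(assoc2, g2)
  expect_equal(nrow(m2), 2)
  # no variant passing the threshold -> valid empty model
  assoc3 <- assoc2; assoc3$p_value <- c(1e-3, 1e-4)
  expect_equal(nrow(clump_and_threshold(assoc3, g2)), 0)
})

test_that("clumping matches the brute-force greedy reference on random instances", {
  for (seed in 1:60) {
    inst <- make_clump_instance(seed)
    r2 <- suppressWarnings(cor(inst$g$dosages))^2
    dimnames(r2) <- list(inst$g$variants$variant_id, inst$g$variants$variant_id)
    got <- clump_and_threshold(inst$assoc, inst$g, p_threshold = 1e-3,
                               clump_window_bp = 5e5, clump_r2 = 0.2)
    want <- clump_oracle(inst$assoc, r2, 1e-3, 5e5, 0.2)
    expect_identical(got$variant_id, want)
    # retained-set invariant
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got)) {
        if (got$chromosome[a] == got$chromosome[b] &&
            abs(got$position_bp[a] - got$position_bp[b]) <= 5e5) {
          expect_lt(r2[got$variant_id[a], got$variant_id[b]], 0.2)
        }
      }
    }
  }
})

test_that("clumping is invariant under input row permutation", {
  inst <- make_clump_instance(99)
  base <- clump_and_threshold(inst$assoc, inst$g, p_threshold = 1e-2)
  set.seed(1)
  perm <- clump_and_threshold(inst$assoc[sample(nrow(inst$assoc)), ],
                              inst$g, p_threshold = 1e-2)
  expect_identical(base$variant_id, perm$variant_id)
})

test_that("scoring: weighted allelic sum, orientation invariance, linearity", {
  g <- make_toy_genotypes(5, 3, seed = 3)
  g$dosages[1, 1] <- 2
  model <- data.frame(variant_id = "v0001", chromosome = "1", position_bp = 1000,
                      effect_allele = "A", weight = 0.5, p_discovery = 1e-8,
                      stringsAsFactors = FALSE)
  sc <- score_prs(g, model)
  expect_equal(sc$raw_score[1], 1.0)  # dosage 2 x weight 0.5
  # flipped encoding of the same variant gives identical scores
  gf <- g
  gf$dosages[, 1] <- 2 - gf$dosages[, 1]
  gf$variants$allele1[1] <- "G"; gf$variants$allele2[1] <- "A"
  expect_equal(score_prs(gf, model)$raw_score, sc$raw_score)
  # empty model -> zeros
  expect_equal(score_prs(g, model[0, ])$raw_score, rep(0, 5))
  # linearity in weights
  m2 <- model; m2$weight <- 1.2
  madd <- model; madd$weight <- model$weight + m2$weight
  expect_equal(score_prs(g, madd)$raw_score,
               score_prs(g, model)$raw_score + score_prs(g, m2)$raw_score)
  # unmatched alleles dropped with warning
  mbad <- model; mbad$effect_allele <- "T"
  expect_warning(sbad <- score_prs(g, mbad), "neither")
  expect_equal(sbad$raw_score, rep(0, 5))
})

test_that("missing dosages are mean-imputed with the effect-allele frequency", {
  d <- matrix(c(0, 2, 2, NA), ncol = 1)
  g <- genotype_matrix(
    d, data.frame(variant_id = "v1", chromosome = "1", position_bp = 1,
                  allele1 = "A", allele2 = "G"),
    data.frame(sample_id = paste0("s", 1:4)))
  model <- data.frame(variant_id = "v1", chromosome = "1", position_bp = 1,
                      effect_allele = "A", weight = 1, p_discovery = 1e-8,
                      stringsAsFactors = FALSE)
  sc <- score_prs(g, model)
  expect_equal(sc$raw_score[4], mean(c(0, 2, 2)))  # 2 * freq
})

test_that("rank normalization matches the Blom closed form and its invariants", {
  got <- rank_normalize(c(5, 1, 3))
  want <- qnorm((c(3, 1, 2) - 0.375) / 3.25)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[3], 0, tolerance = 1e-12)
  expect_equal(got[1], 0.8694, tolerance = 1e-3)
  # invariance under monotone transforms
  set.seed(4)
  x <- rnorm(500)
  expect_equal(rank_normalize(exp(2 * x)), rank_normalize(x))
  # idempotence on distinct values
  expect_equal(rank_normalize(rank_normalize(x)), rank_normalize(x))
  # moments at n = 1e4
  z <- rank_normalize(rnorm(1e4))
  expect_lt(abs(mean(z)), 1e-12)
  expect_gt(sd(z), 0.95); expect_lt(sd(z), 1.05)
  # ties get average ranks; constant input warns and returns zeros
  expect_equal(rank_normalize(c(1, 1, 2))[1], rank_normalize(c(1, 1, 2))[2])
  expect_warning(zc <- rank_normalize(rep(3, 5)), "constant")
  expect_equal(zc, rep(0, 5))
  # NA preserved
  expect_true(is.na(rank_normalize(c(1, NA, 3))[2]))
})

test_that("variance explained: null PRS ~0, perfect PRS ~1, recovers h2 from a full model", {
  set.seed(5)
  y <- rnorm(2000)
  expect_lt(abs(variance_explained(y, rnorm(2000))), 0.01)
  expect_equal(variance_explained(y, y), 1, tolerance = 1e-10)
  # h2 = 0.5 trait, oracle score built from the true genetic values
  g <- make_two_pop_cohort(seed = 6, n_each = 1500, m = 500, f = 0.005)
  tr <- trait_model("t", "quantitative", m_causal = 50, h2 = 0.5)
  ph <- simulate_quantitative_trait(g, tr, seed = 7)
  truth <- attr(ph, "truth")
  ve <- variance_explained(ph$t, truth$genetic_value)
  expect_gt(ve, 0.42); expect_lt(ve, 0.55)
})

test_that("Haseman-Elston regression recovers simulated heritability", {
  g <- make_two_pop_cohort(seed = 8, n_each = 500, m = 2000, f = 0.003)
  std <- standardize_genotypes(g)
  grm <- tcrossprod(std$x) / ncol(std$x)
  set.seed(42)
  h2_hat <- replicate(5, {
    tr <- trait_model("t", "quantitative", m_causal = 100, h2 = 0.5)
    ph <- simulate_quantitative_trait(g, tr, seed = sample.int(1e6, 1))
    he_regression_h2(NULL, ph$t, grm = grm)$h2_raw
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.12)
  # null and permutation null
  set.seed(9)
  y0 <- rnorm(1000)
  expect_lt(abs(he_regression_h2(NULL, y0, grm = grm)$h2_raw), 0.15)
  tr <- trait_model("t", "quantitative", m_causal = 100, h2 = 0.6)
  ph <- simulate_quantitative_trait(g, tr, seed = 10)
  yperm <- sample(ph$t)
  expect_lt(abs(he_regression_h2(NULL, yperm, grm = grm)$h2_raw), 0.15)
})
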