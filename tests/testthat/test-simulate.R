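# Balding-Nichols cohort simulator: drift moments, Hardy-Weinberg draws,
# trait construction, presets.

test_that("F = 0 drift copies the ancestral frequencies exactly", {
  cfg <- sim_config(seed = 3, m_variants = 200, subpopulations = list(
    list(name = "A", n_samples = 5, fst_path = 0)
  ))
  fr <- sample_subpop_frequencies(cfg)
  expect_identical(fr[, "A"], fr[, "ancestral"])
})

test_that("Beta drift step has variance F p (1 - p)", {
  set.seed(42)
  draws <- strataprs:::.bn_drift(rep(0.5, 1e5), f = 0.01)
  expect_equal(mean(draws), 0.5, tolerance = 0.005)
  # target variance 0.01 * 0.25 = 0.0025; Monte-Carlo error << 10%
  expect_gt(var(draws), 0.00225)
  expect_lt(var(draws), 0.00275)
})

test_that("shared prefixes with F = 0 leaves give identical subpopulations", {
  cfg <- sim_config(seed = 7, m_variants = 500, subpopulations = list(
    list(name = "A", n_samples = 5, fst_path = c(0.05, 0)),
    list(name = "B", n_samples = 5, fst_path = c(0.05, 0))
  ))
  fr <- sample_subpop_frequencies(cfg)
  expect_identical(fr[, "A"], fr[, "B"])
  expect_false(identical(fr[, "A"], fr[, "ancestral"]))

  # nonzero leaves from the same prefix drift independently
  cfg2 <- sim_config(seed = 7, m_variants = 500, subpopulations = list(
    list(name = "A", n_samples = 5, fst_path = c(0.05, 0.01)),
    list(name = "B", n_samples = 5, fst_path = c(0.05, 0.01))
  ))
  fr2 <- sample_subpop_frequencies(cfg2)
  expect_false(identical(fr2[, "A"], fr2[, "B"]))
})

test_that("same seed and config give a bit-identical cohort", {
  cfg <- sim_config(seed = 11, m_variants = 300, subpopulations = list(
    list(name = "A", n_samples = 40, fst_path = 0.02),
    list(name = "B", n_samples = 20, fst_path = 0.02)
  ))
  g1 <- simulate_genotypes(sample_subpop_frequencies(cfg), cfg)
  g2 <- simulate_genotypes(sample_subpop_frequencies(cfg), cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$samples, g2$samples)
})

test_that("within-subpopulation genotypes are Hardy-Weinberg at nominal rates", {
  g <- make_two_pop_cohort(seed = 19, n_each = 200, m = 1000, f = 0.01)
  dA <- subset_genotypes(g, samples = g$samples$subpopulation_truth == "A")
  qc <- variant_qc(dA, qc_thresholds(min_call_rate = 0, min_het_count = 0,
                                     min_maf = 0, hwe_p_min = 0))
  # exact-test p-values are conservative; rejection at 0.05 should not exceed
  # the nominal rate by much
  expect_lt(mean(qc$hwe_p < 0.05, na.rm = TRUE), 0.07)
})

test_that("quantitative trait limits: h2 = 0 and h2 = 1", {
  g <- make_two_pop_cohort(seed = 23, n_each = 1000, m = 400, f = 0.005)
  t0 <- trait_model("null_h2", "quantitative", m_causal = 50, h2 = 0)
  p0 <- simulate_quantitative_trait(g, t0, seed = 1)
  tr0 <- attr(p0, "truth")
  expect_equal(tr0$genetic_value, rep(0, 2000))
  # phenotype uncorrelated with genotype anywhere: |r| < 0.08 at n = 2000
  r_max <- max(abs(cor(p0$null_h2, g$dosages[, 1:20])))
  expect_lt(r_max, 0.08)

  t1 <- trait_model("full_h2", "quantitative", m_causal = 50, h2 = 1)
  p1 <- simulate_quantitative_trait(g, t1, seed = 1)
  tr1 <- attr(p1, "truth")
  ratio <- var(tr1$genetic_value) / var(p1$full_h2)
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  expect_error(
    simulate_quantitative_trait(
      g, trait_model("bad", "quantitative", 10, h2 = 1,
                     covariate_effects = list(sex = 0.5)), seed = 1),
    "variance bookkeeping")
})

test_that("environmental offsets shift subpopulation means as configured", {
  g <- make_two_pop_cohort(seed = 29, n_each = 1000, m = 200, f = 0.005)
  tr <- trait_model("offset_trait", "quantitative", m_causal = 0, h2 = 0,
                    env_offset = c(A = 0, B = 0.5))
  ph <- simulate_quantitative_trait(g, tr, seed = 2)
  truth <- attr(ph, "truth")
  dmean <- mean(ph$offset_trait[truth$subpopulation == "B"]) -
    mean(ph$offset_trait[truth$subpopulation == "A"])
  expect_lt(abs(dmean - 0.5), 0.1)
})

test_that("true between-group genetic difference matches the frequency table", {
  cfg <- sim_config(seed = 31, m_variants = 600, subpopulations = list(
    list(name = "A", n_samples = 1500, fst_path = 0.02),
    list(name = "B", n_samples = 1500, fst_path = 0.02)
  ))
  fr <- sample_subpop_frequencies(cfg)
  g <- simulate_genotypes(fr, cfg)
  tr <- trait_model("gshift", "quantitative", m_causal = 80, h2 = 0.6)
  ph <- simulate_quantitative_trait(g, tr, seed = 3)
  truth <- attr(ph, "truth")
  p0 <- fr[truth$causal, "ancestral"]
  expected <- sum(truth$beta * 2 * (fr[truth$causal, "B"] - fr[truth$causal, "A"]) /
                    sqrt(2 * p0 * (1 - p0)))
  observed <- mean(truth$genetic_value[truth$subpopulation == "B"]) -
    mean(truth$genetic_value[truth$subpopulation == "A"])
  # sampling error of each group mean is ~ sqrt(h2/n)
  expect_lt(abs(observed - expected), 4 * sqrt(0.6 / 1500) * sqrt(2))
})

test_that("binary traits hit their target prevalence", {
  g <- make_two_pop_cohort(seed = 37, n_each = 1000, m = 200, f = 0.005)
  tb <- trait_model("d50", "binary", m_causal = 0, h2 = 0, prevalence = 0.5)
  yb <- simulate_binary_trait(g, tb, seed = 4)
  expect_lt(abs(mean(yb$d50) - 0.5), 0.03)

  g5 <- make_two_pop_cohort(seed = 38, n_each = 2500, m = 200, f = 0.005)
  tb2 <- trait_model("d10", "binary", m_causal = 20, h2 = 0.3, prevalence = 0.1)
  yb2 <- simulate_binary_trait(g5, tb2, seed = 5)
  expect_lt(abs(mean(yb2$d10) - 0.1), 0.02)
})

test_that("a liability offset shifts prevalence by the normal-tail closed form", {
  g <- make_two_pop_cohort(seed = 41, n_each = 2500, m = 200, f = 0.005)
  tb <- trait_model("dof", "binary", m_causal = 0, h2 = 0, prevalence = 0.1,
                    env_offset = c(A = 0, B = 1))
  yb <- simulate_binary_trait(g, tb, seed = 6)
  sp <- attr(yb, "truth")$subpopulation
  prevB <- mean(yb$dof[sp == "B"])
  expect_lt(abs(prevB - (1 - pnorm(qnorm(0.9) - 1))), 0.035)  # target ~0.386
  expect_lt(abs(mean(yb$dof[sp == "A"]) - 0.1), 0.02)
})

test_that("degenerate binary output is flagged", {
  g <- make_two_pop_cohort(seed = 43, n_each = 20, m = 50, f = 0.005)
  tb <- trait_model("rare", "binary", m_causal = 0, h2 = 0, prevalence = 0.001)
  expect_warning(simulate_binary_trait(g, tb, seed = 7), "degenerate")
})

test_that("unknown preset names are rejected; presets carry their designs", {
  expect_error(scenario_preset("weight_like"), "unknown preset")
  hl <- scenario_preset("height_like")
  expect_identical(hl$traits[[1]]$genetic_shift, "negative")
  off <- hl$traits[[1]]$env_offset
  expect_lt(off[["nonmainland"]], 0)
  bl <- scenario_preset("bmi_like")
  expect_gt(bl$traits[[1]]$env_offset[["nonmainland"]], 0)
  nl <- scenario_preset("null")
  expect_null(nl$traits[[1]]$env_offset)
})

test_that("hudson_fst recovers the simulated differentiation (small scale)", {
  g <- make_two_pop_cohort(seed = 47, n_each = 400, m = 8000, f = 0.01)
  fst <- hudson_fst(g, g$samples$subpopulation_truth)
  expect_gt(fst, 0.007)
  expect_lt(fst, 0.013)
})
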