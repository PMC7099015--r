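# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures on disk.

# Random genotype_matrix: HWE draws at uniform frequencies, optional missing.
make_toy_genotypes <- function(n, m, seed = 1, miss_rate = 0,
                               freq_range = c(0.1, 0.9), chromosome = NULL,
                               position_bp = NULL) {
  set.seed(seed)
  p <- runif(m, freq_range[1], freq_range[2])
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss_rate > 0) d[runif(n * m) < miss_rate] <- NA
  if (is.null(chromosome)) chromosome <- rep("1", m)
  if (is.null(position_bp)) position_bp <- seq_len(m) * 1000
  genotype_matrix(
    d,
    data.frame(variant_id = sprintf("v%04d", seq_len(m)),
               chromosome = chromosome, position_bp = position_bp,
               allele1 = "A", allele2 = "G", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%04d", seq_len(n)),
               sex = rbinom(n, 1, 0.5) + 1, age = runif(n, 30, 80),
               stringsAsFactors = FALSE)
  )
}

# Two-island cohort straight from the simulator.
make_two_pop_cohort <- function(seed, n_each = 300, m = 3000, f = 0.01) {
  cfg <- sim_config(
    seed = seed, m_variants = m,
    subpopulations = list(
      list(name = "A", n_samples = n_each, fst_path = f),
      list(name = "B", n_samples = n_each, fst_path = f)
    )
  )
  simulate_genotypes(sample_subpop_frequencies(cfg), cfg)
}
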