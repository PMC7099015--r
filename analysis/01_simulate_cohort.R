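#!/usr/bin/env Rscript
# Simulate the study cohort: a large mainland-like subpopulation and a
# smaller insular one that drifted further from the shared ancestor, with a
# height-like trait (genetic and environmental deviations of the same sign)
# and a BMI-like trait (environmental reversal). Writes the cohort as a
# PLINK fileset plus phenotype and truth tables under results/cohort/.

library(strataprs)

seed <- 2026
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_preset("height_like", seed = seed)
freqs <- sample_subpop_frequencies(sc$config)
geno <- simulate_genotypes(freqs, sc$config)
message("cohort: ", nrow(geno$dosages), " samples x ", ncol(geno$dosages),
        " variants; subpopulations: ",
        paste(names(table(geno$samples$subpopulation_truth)), collapse = ", "))

traits <- list(
  scenario_preset("height_like", seed = seed)$traits[[1]],
  scenario_preset("bmi_like", seed = seed)$traits[[1]]
)
pheno <- NULL
truth_rows <- list()
for (tr in traits) {
  tp <- simulate_quantitative_trait(geno, tr, seed = seed)
  truth <- attr(tp, "truth")
  truth_rows[[tr$trait_name]] <- data.frame(
    trait_name = tr$trait_name,
    variant_id = geno$variants$variant_id[truth$causal],
    beta = truth$beta)
  pheno <- if (is.null(pheno)) tp else cbind(pheno, tp[tr$trait_name])
}

write_plink(geno, file.path(out, "cohort"))
write_phenotypes(pheno, file.path(out, "phenotypes.tsv"))
write.table(data.frame(sample_id = geno$samples$sample_id,
                       subpopulation = geno$samples$subpopulation_truth,
                       region_label = geno$samples$region_label),
            file.path(out, "sample_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, truth_rows), file.path(out, "causal_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fst <- hudson_fst(geno, geno$samples$subpopulation_truth)
message(sprintf("realized Hudson Fst between subpopulations: %.4f", fst))
message("wrote PLINK trio + phenotype/truth TSVs under ", out)
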