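#!/usr/bin/env Rscript
# Detect the cohort's population structure from genotypes alone: variant QC,
# LD pruning, PCA of the standardized pruned matrix, k-means cluster
# assignment, and Cohen's kappa between assigned clusters and the simulated
# recruitment-region labels. Reads results/cohort/, writes results/structure/.

library(strataprs)

seed <- 2026
cohort_dir <- "results/cohort"
out <- "results/structure"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geno <- read_plink(file.path(cohort_dir, "cohort"))
truth <- read.delim(file.path(cohort_dir, "sample_truth.tsv"))
stopifnot(identical(geno$samples$sample_id, truth$sample_id))

th <- qc_thresholds()
qc <- variant_qc(geno, th)
message("variant QC: ", sum(!qc$pass), " of ", nrow(qc), " variants removed (",
        paste(names(table(qc$fail_rules[!qc$pass])), collapse = "; "), ")")
geno_qc <- subset_genotypes(geno, variants = which(qc$pass))

pruned <- ld_prune(geno_qc, th)
message("LD pruning: ", length(pruned), " pruned-in variants")
geno_pruned <- subset_genotypes(geno_qc, variants = pruned)

emb <- embed_genotypes(geno_pruned, method = "pca", n_pcs = 10, seed = seed)
clusters <- assign_clusters(emb, k_clusters = 2, seed = seed)
kap <- cohens_kappa(clusters, truth$region_label)
message(sprintf("cluster vs region kappa = %.3f (p = %.3g, %s)",
                kap$kappa, kap$p_value, kap$p_method))

write.table(data.frame(sample_id = geno$samples$sample_id,
                       dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
                       cluster = clusters, region = truth$region_label),
            file.path(out, "coords.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(qc, file.path(out, "variant_qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(pruned, file.path(out, "pruned_in_variants.txt"))
yaml::write_yaml(list(kappa = kap$kappa, p_value = kap$p_value,
                      mapping = as.list(kap$mapping)),
                 file.path(out, "kappa.yaml"))
message("wrote coordinates, QC report and kappa summary under ", out)
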