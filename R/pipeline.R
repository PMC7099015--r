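# End-to-end orchestration: configuration, staging, logging, manifest.

#' Build or load a run configuration
#'
#' A run configuration holds the master seed, the simulation scenario (a
#' preset name), QC thresholds, structure parameters, GWAS and PRS
#' parameters. It can be round-tripped through YAML. Every stochastic stage
#' derives its seed deterministically from `master_seed` and the stage name
#' via [derive_seed()], so adding a stage never perturbs earlier stages.
#'
#' @param master_seed integer.
#' @param scenario preset name (see [scenario_preset()]).
#' @param qc list overriding [qc_thresholds()] entries.
#' @param structure list: `method` (embedding), `n_pcs`, `k_clusters`.
#' @param gwas list: `n_pcs` (covariate PCs).
#' @param prs list: `p_threshold`, `clump_window_bp`, `clump_r2`.
#' @param scenario_n_scale multiplier on the preset cohort size (see
#'   [scenario_preset()]); 1 is the full study condition.
#' @return `run_config` list.
#' @export
run_config <- function(master_seed = 1L, scenario = "height_like",
                       qc = list(), structure = list(), gwas = list(),
                       prs = list(), scenario_n_scale = 1) {
  known <- list(
    qc = names(qc_thresholds()),
    structure = c("method", "n_pcs", "k_clusters"),
    gwas = c("n_pcs"),
    prs = c("p_threshold", "clump_window_bp", "clump_r2")
  )
  for (blk in names(known)) {
    extra <- setdiff(names(get(blk)), known[[blk]])
    if (length(extra)) {
      stop("unknown key(s) in '", blk, "' block: ", paste(extra, collapse = ", "))
    }
  }
  qc_full <- utils::modifyList(qc_thresholds(), qc)
  st <- utils::modifyList(list(method = "pca", n_pcs = 10, k_clusters = 2), structure)
  gw <- utils::modifyList(list(n_pcs = 5), gwas)
  pr <- utils::modifyList(list(p_threshold = 5e-6, clump_window_bp = 1e6,
                               clump_r2 = 0.1), prs)
  structure(
    list(master_seed = as.integer(master_seed), scenario = scenario,
         scenario_n_scale = scenario_n_scale,
         qc = qc_full, structure = st, gwas = gw, prs = pr),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file with top-level keys matching [run_config()]
#'   arguments.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("master_seed", "scenario", "qc", "structure", "gwas", "prs",
             "scenario_n_scale")
  extra <- setdiff(names(y), known)
  if (length(extra)) stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(run_config, y)
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulation-to-bias pipeline
#'
#' simulate -> variant QC -> LD pruning -> PCA/embedding -> cluster
#' assignment -> kappa against the simulated region labels -> stratified
#' split -> per-trait GWAS -> PRS -> delta/bias statistics. All tables are
#' written as TSV under `out_dir` together with a `manifest.yaml` recording
#' seeds, stage timings and filter counts. Re-running with the same
#' configuration reproduces the outputs byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_full_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  log_msg <- function(...) message("[strataprs] ", ...)

  s <- tic()
  sc <- scenario_preset(config$scenario,
                        seed = derive_seed(config$master_seed, "simulate"),
                        n_scale = config$scenario_n_scale)
  freqs <- sample_subpop_frequencies(sc$config)
  geno <- simulate_genotypes(freqs, sc$config)
  pheno <- NULL
  binary <- character(0)
  for (tr in sc$traits) {
    tp <- if (tr$type == "binary") {
      binary <- c(binary, tr$trait_name)
      simulate_binary_trait(geno, tr, seed = derive_seed(config$master_seed, "traits"))
    } else {
      simulate_quantitative_trait(geno, tr, seed = derive_seed(config$master_seed, "traits"))
    }
    pheno <- if (is.null(pheno)) tp else cbind(pheno, tp[tr$trait_name])
  }
  timings$simulate <- tic() - s
  log_msg("simulated ", nrow(geno$dosages), " samples x ", ncol(geno$dosages),
          " variants, ", length(sc$traits), " trait(s)")

  s <- tic()
  qc_rep <- variant_qc(geno, config$qc)
  geno_qc <- subset_genotypes(geno, variants = which(qc_rep$pass))
  pruned_ids <- ld_prune(geno_qc, config$qc)
  geno_pruned <- subset_genotypes(geno_qc, variants = pruned_ids)
  timings$qc <- tic() - s
  log_msg("variant QC: ", sum(!qc_rep$pass), " removed, ", sum(qc_rep$pass),
          " kept; pruning kept ", length(pruned_ids))

  s <- tic()
  emb <- embed_genotypes(geno_pruned, method = config$structure$method,
                         n_pcs = config$structure$n_pcs,
                         seed = derive_seed(config$master_seed, "embed"))
  clusters <- assign_clusters(emb, config$structure$k_clusters,
                              seed = derive_seed(config$master_seed, "cluster"))
  kap <- cohens_kappa(clusters, geno$samples$region_label)
  timings$structure <- tic() - s
  log_msg(sprintf("cluster vs region kappa = %.3f (p = %.3g)", kap$kappa, kap$p_value))

  s <- tic()
  scan <- phenome_scan(
    geno_qc, pheno,
    trait_names = vapply(sc$traits, `[[`, "", "trait_name"),
    cluster_labels = clusters, mainland = NULL,
    seed = derive_seed(config$master_seed, "scan"),
    n_pcs = config$gwas$n_pcs, binary_traits = binary,
    p_threshold = config$prs$p_threshold,
    clump_window_bp = config$prs$clump_window_bp,
    clump_r2 = config$prs$clump_r2
  )
  timings$scan <- tic() - s

  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(qc_rep, "variant_qc.tsv")
  wr(data.frame(sample_id = geno$samples$sample_id,
                dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
                cluster = clusters,
                region_label = geno$samples$region_label), "coords.tsv")
  wr(scan$split, "split.tsv")
  if (!is.null(scan$deltas)) wr(scan$deltas, "deltas.tsv")
  if (!is.null(scan$confounders)) wr(scan$confounders, "confounder_corr.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("strataprs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$master_seed,
    scenario = config$scenario,
    n_samples = nrow(geno$dosages),
    n_variants = ncol(geno$dosages),
    n_variants_qc = sum(qc_rep$pass),
    n_variants_pruned_in = length(pruned_ids),
    kappa_cluster_vs_region = kap$kappa,
    timings_sec = lapply(timings, function(x) round(x, 2)),
    total_sec = round(tic() - t0, 2)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(genotypes = geno, qc = qc_rep, pruned = pruned_ids,
                 embedding = emb, clusters = clusters, kappa = kap,
                 scan = scan, manifest = manifest))
}
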