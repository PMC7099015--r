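# Population-structure detection: standardized-genotype PCA, 2-D embedding
# adapters (t-SNE/UMAP via optional packages), k-means cluster assignment and
# Cohen's kappa cluster-vs-label correspondence.

#' Standardize genotype dosages
#'
#' Column j is transformed as `(g - 2 p_j) / sqrt(2 p_j (1 - p_j))` with
#' `p_j` the sample allele frequency of allele1 (the classical
#' variance-normalized convention for genotype PCA; the sample frequency is
#' used without a posterior adjustment). Missing dosages are mean-imputed to
#' 0 after centering. Monomorphic columns are an error — remove them with
#' [variant_qc()] first.
#'
#' @param genotypes a [genotype_matrix()] or a raw dosage matrix.
#' @return list with `x` (n x m standardized matrix), `p` (frequencies used),
#'   `center`, `scale`.
#' @export
standardize_genotypes <- function(genotypes) {
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  p <- .col_freq(d)
  if (any(is.na(p) | p == 0 | p == 1)) {
    stop("monomorphic (or all-missing) variant(s) present; run variant_qc first: ",
         paste(utils::head(which(is.na(p) | p == 0 | p == 1), 5), collapse = ", "))
  }
  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  x <- sweep(sweep(d, 2, ctr, "-"), 2, scl, "/")
  x[is.na(x)] <- 0
  list(x = x, p = p, center = ctr, scale = scl)
}

#' Principal component analysis of standardized genotypes
#'
#' Top-k eigendecomposition of the n x n sample covariance `X X' / m` of the
#' standardized matrix. Deterministic up to component sign; the sign is fixed
#' by making the largest-magnitude loading of each component positive.
#'
#' @param std output of [standardize_genotypes()] (or a pre-standardized
#'   matrix).
#' @param k number of components.
#' @return `pca_result`: list with `scores` (n x k, columns are `U d`),
#'   `eigenvalues` (of the covariance, nonincreasing), `loadings` (m x k),
#'   `p`, `center`, `scale` (standardization used), `total_variance`
#'   (trace of the covariance).
#' @export
genotype_pca <- function(std, k = 10) {
  if (is.matrix(std)) std <- list(x = std, p = NULL, center = NULL, scale = NULL)
  x <- std$x
  n <- nrow(x); m <- ncol(x)
  if (k > min(n, m)) stop("k = ", k, " exceeds min(n, m) = ", min(n, m))
  K <- tcrossprod(x) / m
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(k)], 0)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  d_svd <- sqrt(lam * m)
  scores <- sweep(U, 2, d_svd, "*")
  loadings <- crossprod(x, U)
  loadings <- sweep(loadings, 2, ifelse(d_svd > 0, d_svd, 1), "/")
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, eigenvalues = lam, loadings = loadings,
         p = std$p, center = std$center, scale = std$scale,
         total_variance = sum(diag(K))),
    class = "pca_result"
  )
}

#' Project new samples onto fitted principal components
#'
#' Standardizes the new dosages with the frequencies stored in the fit and
#' multiplies by the loadings. Used to carry discovery-fit PCs onto
#' validation samples without refitting.
#'
#' @param pca a `pca_result` fitted with frequency bookkeeping.
#' @param genotypes a [genotype_matrix()] (same variants, same order).
#' @return n_new x k score matrix.
#' @export
pca_project <- function(pca, genotypes) {
  if (is.null(pca$center)) stop("pca_result lacks standardization bookkeeping")
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else as.matrix(genotypes)
  if (ncol(d) != nrow(pca$loadings)) stop("variant count mismatch with the PCA fit")
  x <- sweep(sweep(d, 2, pca$center, "-"), 2, pca$scale, "/")
  x[is.na(x)] <- 0
  x %*% pca$loadings
}

#' Two-dimensional embedding of genotype data
#'
#' Adapter over five methods: `pca` (first two PCs), `tsne`, `pca_tsne`,
#' `umap`, `pca_umap`. The `pca_*` variants first reduce to `n_pcs`
#' principal components (default 50). t-SNE and UMAP call the optional
#' \pkg{Rtsne} / \pkg{uwot} packages with `n_components = 2` and otherwise
#' default parameters; if the package is absent an informative error names
#' it. The genotype input is never modified.
#'
#' @param genotypes a [genotype_matrix()], standardized list, or matrix.
#' @param method one of `"pca"`, `"tsne"`, `"pca_tsne"`, `"umap"`,
#'   `"pca_umap"`.
#' @param n_pcs PCs for the `pca_*` variants (and for `method = "pca"`, of
#'   which the first two are returned).
#' @param seed RNG seed for the stochastic methods.
#' @return `embedding_result`: list with `coords` (n x 2), `method`,
#'   `params`.
#' @export
embed_genotypes <- function(genotypes,
                            method = c("pca", "tsne", "pca_tsne", "umap", "pca_umap"),
                            n_pcs = 50, seed = 1L) {
  method <- match.arg(method)
  std <- if (inherits(genotypes, "genotype_matrix")) standardize_genotypes(genotypes)
         else if (is.matrix(genotypes)) list(x = genotypes)
         else genotypes
  need_pca <- method %in% c("pca", "pca_tsne", "pca_umap")
  base <- if (need_pca) {
    k <- min(n_pcs, nrow(std$x), ncol(std$x))
    genotype_pca(std, k = k)$scores
  } else {
    std$x
  }
  coords <- switch(
    method,
    pca = base[, 1:2, drop = FALSE],
    tsne = , pca_tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE)) {
        stop("method '", method, "' requires the optional 'Rtsne' package")
      }
      set.seed(seed)
      Rtsne::Rtsne(base, dims = 2, pca = FALSE, check_duplicates = FALSE)$Y
    },
    umap = , pca_umap = {
      if (!requireNamespace("uwot", quietly = TRUE)) {
        stop("method '", method, "' requires the optional 'uwot' package")
      }
      set.seed(seed)
      uwot::umap(base, n_components = 2)
    }
  )
  if (!all(is.finite(coords))) stop("embedding produced non-finite coordinates")
  structure(
    list(coords = coords, method = method,
         params = list(n_pcs = if (need_pca) n_pcs else NA_integer_, seed = seed)),
    class = "embedding_result"
  )
}

#' Assign clusters on a 2-D embedding
#'
#' k-means with 10 restarts at a fixed seed; cluster labels are renamed
#' `"cluster1", "cluster2", ...` by descending cluster size (ties by original
#' k-means index), so the largest cluster — the mainland analog — is always
#' `cluster1`.
#'
#' @param embedding an `embedding_result`, or an n x d coordinate matrix.
#' @param k_clusters number of clusters.
#' @param seed RNG seed.
#' @return character vector of cluster labels, length n.
#' @export
assign_clusters <- function(embedding, k_clusters, seed = 1L) {
  coords <- if (inherits(embedding, "embedding_result")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (k_clusters < 1) stop("k_clusters must be >= 1")
  if (k_clusters > n) stop("k_clusters exceeds the number of samples")
  if (k_clusters == 1) return(rep("cluster1", n))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k_clusters, nstart = 10, iter.max = 100)
  sizes <- tabulate(km$cluster, nbins = k_clusters)
  new_name <- integer(k_clusters)
  new_name[order(-sizes, seq_len(k_clusters))] <- seq_len(k_clusters)
  paste0("cluster", new_name[km$cluster])
}

# Core kappa on integer-coded labels with majority-vote mapping of a-levels
# onto b-levels. Returns the kappa value only (used by the permutation loop).
.kappa_mapped <- function(a, b, ka, kb, b_tot) {
  tab <- matrix(tabulate(a + ka * (b - 1L), nbins = ka * kb), nrow = ka)
  # majority vote per a-level; ties -> tied b category with smallest overall
  # count in b (prefers distinct mappings), then lowest index
  map <- integer(ka)
  for (i in seq_len(ka)) {
    row <- tab[i, ]
    cand <- which(row == max(row))
    if (length(cand) > 1) cand <- cand[order(b_tot[cand], cand)]
    map[i] <- cand[1]
  }
  n <- length(a)
  mapped <- map[a]
  p_o <- sum(mapped == b) / n
  ma <- tabulate(mapped, nbins = kb) / n
  mb <- b_tot / n
  p_e <- sum(ma * mb)
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Cohen's kappa agreement between a clustering and reference labels
#'
#' Cluster labels in `labels_a` are first mapped onto the categories of
#' `labels_b` by majority vote (ties resolved toward the tied reference
#' category with the smallest overall count, which favors distinct
#' mappings); kappa is then `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' marginal products. The p-value is one-sided (agreement greater than
#' chance): a large-sample normal approximation for `n >= 200`, otherwise a
#' permutation test (default 10,000 permutations, mapping re-derived per
#' permutation).
#'
#' @param labels_a cluster labels (character/factor).
#' @param labels_b reference labels.
#' @param n_perm permutations for the small-sample p-value.
#' @param force_permutation use the permutation p-value regardless of n.
#' @param seed RNG seed for permutations.
#' @return list with `kappa`, `p_value`, `p_method`, `table` (contingency,
#'   rows = mapped clusters), `mapping` (named character vector).
#' @export
cohens_kappa <- function(labels_a, labels_b, n_perm = 10000,
                         force_permutation = FALSE, seed = 1L) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  fa <- factor(labels_a); fb <- factor(labels_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    warning("constant labels: kappa undefined")
    return(list(kappa = NA_real_, p_value = NA_real_, p_method = "none",
                table = table(labels_a, labels_b), mapping = NULL))
  }
  a <- as.integer(fa); b <- as.integer(fb)
  ka <- nlevels(fa); kb <- nlevels(fb)
  b_tot <- tabulate(b, nbins = kb)
  kap <- .kappa_mapped(a, b, ka, kb, b_tot)

  # mapping reported to the user (recomputed as in .kappa_mapped)
  tab <- matrix(tabulate(a + ka * (b - 1L), nbins = ka * kb), nrow = ka,
                dimnames = list(levels(fa), levels(fb)))
  map <- vapply(seq_len(ka), function(i) {
    cand <- which(tab[i, ] == max(tab[i, ]))
    if (length(cand) > 1) cand <- cand[order(b_tot[cand], cand)]
    levels(fb)[cand[1]]
  }, character(1))
  names(map) <- levels(fa)

  if (n >= 200 && !force_permutation) {
    mapped <- match(map[a], levels(fb))
    pm <- tabulate(mapped, nbins = kb) / n
    pb <- b_tot / n
    p_e <- sum(pm * pb)
    # Fleiss large-sample null variance of kappa
    var0 <- (p_e + p_e^2 - sum(pm * pb * (pm + pb))) / (n * (1 - p_e)^2)
    z <- kap / sqrt(max(var0, .Machine$double.eps))
    p <- stats::pnorm(z, lower.tail = FALSE)
    p_method <- "normal"
  } else {
    set.seed(seed)
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      kp <- .kappa_mapped(a, b[sample.int(n)], ka, kb, b_tot)
      if (!is.na(kp) && kp >= kap) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    p_method <- "permutation"
  }
  list(kappa = kap, p_value = p, p_method = p_method,
       table = table(mapped_cluster = map[a], reference = labels_b),
       mapping = map)
}
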