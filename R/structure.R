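#' Impute missing dosages and center/scale the genotype matrix
#'
#' Missing dosages are replaced by the locus mean; columns are then
#' centered and, by default, scaled by `sqrt(p(1 - p))` where `p` is the
#' mean alternate-allele frequency — the binomial standardization usual in
#' genotype PCA outlier scans. Columns with zero variance after imputation
#' are dropped (logged in attribute `"dropped"`). Observed entries are
#' never altered by imputation.
#'
#' @param x a [geno] object
#' @param scale divide each column by `sqrt(p(1-p))` (default `TRUE`)
#' @return A numeric matrix (individuals x loci) with attribute
#'   `"dropped"` listing zero-variance locus ids.
#' @export
impute_and_scale <- function(x, scale = TRUE) {
  stopifnot(inherits(x, "geno"))
  d <- x$dosage
  typed <- colSums(!is.na(d))
  if (any(typed < 2))
    abort("each locus must be typed in at least 2 individuals")
  mu <- colMeans(d, na.rm = TRUE)
  m <- matrix(as.numeric(d), nrow(d), ncol(d), dimnames = dimnames(d))
  idx <- which(is.na(m))
  if (length(idx)) m[idx] <- mu[(idx - 1) %/% nrow(m) + 1]
  keep <- apply(m, 2, var) > 0
  dropped <- colnames(m)[!keep]
  if (length(dropped))
    inform(sprintf("dropped %d zero-variance loci after imputation",
                   length(dropped)))
  m <- m[, keep, drop = FALSE]
  mu <- mu[keep]
  m <- sweep(m, 2, colMeans(m))
  if (scale) {
    p <- mu / 2
    s <- sqrt(p * (1 - p))
    s[s == 0] <- 1
    m <- sweep(m, 2, s, "/")
  }
  attr(m, "dropped") <- dropped
  m
}

#' Principal components analysis of genotypes
#'
#' SVD-based PCA of the imputed, centered (optionally binomially scaled)
#' genotype matrix; deterministic up to axis sign. All clonefire results
#' are invariant to those signs.
#'
#' @param m numeric matrix from [impute_and_scale()] (or a [geno], which
#'   is imputed with defaults first)
#' @param n_components number of components to retain
#' @return A list of class `geno_pca`: `scores` (individuals x
#'   components), `explained` (variance fractions, non-increasing),
#'   `loadings` (loci x components), `sdev` (all singular-value sds),
#'   `center_ids` (locus ids retained).
#' @export
pca_genotypes <- function(m, n_components = 10) {
  if (inherits(m, "geno")) m <- impute_and_scale(m)
  n <- nrow(m)
  max_comp <- min(n - 1, ncol(m))
  if (n_components > max_comp)
    abort(sprintf("n_components must be <= %d", max_comp))
  sv <- svd(m, nu = n_components, nv = n_components)
  var_all <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  loadings <- sv$v
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores,
                 explained = var_all[seq_len(n_components)],
                 explained_all = var_all,
                 loadings = loadings, sdev = sv$d / sqrt(max(1, n - 1)),
                 center_ids = colnames(m)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d individuals, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained)))
  invisible(x)
}

#' @rdname pca_genotypes
#' @param x a `geno_pca`
#' @param ... unused
#' @export
tidy.geno_pca <- function(x, ...) {
  as_tibble(x$scores) %>%
    mutate(sample_id = rownames(x$scores), .before = 1)
}

#' @rdname pca_genotypes
#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         explained = sum(x$explained),
         explained_pc1 = x$explained[1])
}

#' Hierarchical clustering of individual genotypes
#'
#' Agglomerative clustering on the Euclidean distance between imputed
#' genotype rows. Complete linkage by default (`"average"` and `"ward.D2"`
#' available); distances can be computed on the unscaled imputed matrix
#' via `scale = FALSE`.
#'
#' @param x a [geno] object or a matrix from [impute_and_scale()]
#' @param linkage linkage method passed to [stats::hclust()]
#' @param scale passed to [impute_and_scale()] when `x` is a [geno]
#' @param k optional number of clusters to cut into
#' @return A list of class `geno_hclust`: `hclust` (the tree), `dist`
#'   (a `pairwise_matrix` of kind `"euclidean"`), and `labels` (cut
#'   labels, when `k` given).
#' @export
hierarchical_clustering <- function(x, linkage = c("complete", "average", "ward.D2"),
                                    scale = TRUE, k = NULL) {
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "geno")) impute_and_scale(x, scale = scale) else x
  if (nrow(m) < 2) abort("need at least 2 individuals")
  dd <- dist(m)
  hc <- hclust(dd, method = linkage)
  dm <- as.matrix(dd)
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  structure(list(hclust = hc,
                 dist = pairwise_matrix(dm, "euclidean"),
                 labels = labels, linkage = linkage),
            class = "geno_hclust")
}

#' Serialize a dendrogram to Newick
#'
#' @param x a `geno_hclust` (or plain `hclust`)
#' @param path optional file to write to
#' @return The Newick string, invisibly when written to file.
#' @export
as_newick <- function(x, path = NULL) {
  hc <- if (inherits(x, "geno_hclust")) x$hclust else x
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Hard cluster assignment from principal components
#'
#' Seeded k-means (`nstart = 10`) on the leading PCs stands in for
#' model-based admixture clustering: at near-fixed differentiation the
#' hard assignments coincide, and hard labels are all downstream analyses
#' consume. Soft memberships are heuristic inverse-distance weights, not
#' model posteriors.
#'
#' @param pca a `geno_pca` (or a score matrix)
#' @param k number of clusters
#' @param n_pcs number of leading PCs to cluster on (default: all in
#'   `pca`)
#' @param samples optional sample tibble (with `site_id`) used to attach
#'   per-site modal labels
#' @param nstart k-means restarts (default 10)
#' @return A list of class `cluster_assignment`: `assignments` tibble
#'   (`sample_id`, `cluster`, membership columns `m1..mK`), `site_modal`
#'   tibble when `samples` given, and the `kmeans` fit.
#' @export
assign_clusters <- function(pca, k, n_pcs = NULL, samples = NULL, nstart = 10) {
  scores <- if (inherits(pca, "geno_pca")) pca$scores else pca
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(scores)) abort("k exceeds the number of individuals")
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  if (k == 1) {
    km <- NULL
    hard <- rep(1L, nrow(scores))
    memb <- matrix(1, nrow(scores), 1)
  } else {
    km <- kmeans(scores, centers = k, nstart = nstart)
    hard <- km$cluster
    dmat <- vapply(seq_len(k), function(j)
      sqrt(rowSums(sweep(scores, 2, km$centers[j, ])^2)),
      numeric(nrow(scores)))
    inv <- 1 / pmax(dmat, 1e-12)
    memb <- inv / rowSums(inv)
  }
  colnames(memb) <- paste0("m", seq_len(k))
  assignments <- tibble(sample_id = rownames(scores),
                        cluster = as.integer(hard)) %>%
    dplyr::bind_cols(as_tibble(memb))
  site_modal <- NULL
  if (!is.null(samples)) {
    site_modal <- left_join(assignments, samples, by = "sample_id") %>%
      group_by(site_id = .data$site_id) %>%
      summarise(site_cluster = modal_label(.data$cluster), .groups = "drop")
  }
  structure(list(assignments = assignments, site_modal = site_modal,
                 k = k, kmeans = km),
            class = "cluster_assignment")
}

# most common label; ties broken by the smallest label for determinism
modal_label <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  as.integer(names(tab)[1])
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> K = %d; sizes: %s\n", x$k,
              paste(table(x$assignments$cluster), collapse = ", ")))
  invisible(x)
}

#' @rdname assign_clusters
#' @param x a `cluster_assignment`
#' @param ... unused
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignments

#' Choose the number of clusters by silhouette against a permutation null
#'
#' Runs [assign_clusters()] over a range of K and reports the mean
#' silhouette width (on the PC scores) plus within-cluster sum of squares
#' for each K. Even unclustered point clouds yield moderate silhouettes,
#' so each K's silhouette is compared against a null reference built by
#' independently permuting each score column (which preserves the
#' marginals but destroys any joint clustering, in the spirit of the gap
#' statistic). A K is a structure candidate only when its silhouette
#' exceeds the maximum of `n_null` permuted replicates; the selected K
#' maximizes silhouette among candidates. When no K qualifies the data
#' are reported as unstructured and K = 1 is selected.
#'
#' @param pca a `geno_pca`
#' @param k_range candidate K values (default `1:8`)
#' @param n_pcs leading PCs to use
#' @param n_null permuted null replicates per K (default 20)
#' @return A list of class `k_selection`: `k` (the choice),
#'   `no_structure` flag, and `diagnostics` tibble (`k`, `silhouette`,
#'   `sil_null_max`, `tot_withinss`).
#' @export
select_k <- function(pca, k_range = 1:8, n_pcs = NULL, n_null = 20) {
  if (!length(k_range)) abort("empty K range")
  scores <- pca$scores
  if (!is.null(n_pcs)) scores <- scores[, seq_len(n_pcs), drop = FALSE]
  k_range <- sort(unique(as.integer(k_range)))
  sil_of <- function(m, k) {
    lab <- assign_clusters(m, k)$assignments$cluster
    mean(cluster::silhouette(lab, dist(m))[, 3])
  }
  diag_tbl <- purrr::map_dfr(k_range, function(k) {
    asg <- assign_clusters(scores, k)
    if (k >= 2 && k < nrow(scores)) {
      sil <- mean(cluster::silhouette(asg$assignments$cluster,
                                      dist(scores))[, 3])
      sil_null <- max(vapply(seq_len(n_null), function(b) {
        perm <- apply(scores, 2, sample)
        rownames(perm) <- rownames(scores)
        sil_of(perm, k)
      }, numeric(1)))
    } else {
      sil <- sil_null <- NA_real_
    }
    tw <- if (k >= 2) asg$kmeans$tot.withinss else
      sum(sweep(scores, 2, colMeans(scores))^2)
    tibble(k = k, silhouette = sil, sil_null_max = sil_null,
           tot_withinss = tw)
  })
  cand <- filter(diag_tbl, !is.na(.data$silhouette),
                 .data$silhouette > .data$sil_null_max)
  if (nrow(cand)) {
    k_best <- cand$k[which.max(cand$silhouette)]
    no_structure <- FALSE
  } else {
    k_best <- if (1 %in% k_range) 1L else k_range[1]
    no_structure <- TRUE
  }
  structure(list(k = k_best, no_structure = no_structure,
                 diagnostics = diag_tbl),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> K = %d%s\n", x$k,
              if (x$no_structure) " (no structure detected)" else ""))
  print(as.data.frame(x$diagnostics), row.names = FALSE)
  invisible(x)
}
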