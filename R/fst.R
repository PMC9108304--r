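#' Symmetric pairwise matrix container
#'
#' Thin S3 wrapper around a labelled symmetric matrix, tagging what it
#' holds (`fst_site`, `geo_km`, `kinship`, `euclidean`). `tidy()` returns
#' the lower triangle as a long tibble.
#'
#' @param values symmetric numeric matrix with dimnames
#' @param kind one of `"fst_site"`, `"geo_km"`, `"kinship"`, `"euclidean"`
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, kind) {
  kind <- match.arg(kind, c("fst_site", "geo_km", "kinship", "euclidean"))
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE)))
    abort("`values` must be symmetric")
  structure(list(ids = rownames(values), values = values, kind = kind),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix: %s> %d ids\n", x$kind, length(x$ids)))
  print(x$values[seq_len(min(6, nrow(x$values))),
                 seq_len(min(6, ncol(x$values)))])
  invisible(x)
}

#' @rdname pairwise_matrix
#' @param x a `pairwise_matrix`
#' @param ... unused
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  lt <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble(id_a = x$ids[lt[, 2]], id_b = x$ids[lt[, 1]],
         value = x$values[lt], kind = x$kind)
}

# Weir & Cockerham (1984) variance components a, b, c for one biallelic
# locus over r groups. n: typed counts per group; p: alt freqs; h: observed
# het fractions. Returns c(a, b, c); all zero for loci monomorphic overall.
wc_components <- function(n, p, h) {
  use <- n > 0
  n <- n[use]; p <- p[use]; h <- h[use]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (pbar == 0 || pbar == 1) return(c(a = 0, b = 0, c = 0))
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

group_locus_counts <- function(x, g) {
  groups <- unique(g)
  n <- p <- h <- matrix(0, length(groups), ncol(x$dosage),
                        dimnames = list(groups, colnames(x$dosage)))
  for (gg in groups) {
    d <- x$dosage[g == gg, , drop = FALSE]
    n[gg, ] <- colSums(!is.na(d))
    p[gg, ] <- colMeans(d, na.rm = TRUE) / 2
    h[gg, ] <- colMeans(d == 1L, na.rm = TRUE)
  }
  p[is.nan(p)] <- 0; h[is.nan(h)] <- 0
  list(groups = groups, n = n, p = p, h = h)
}

#' Multi-locus Weir-Cockerham theta between two or more groups
#'
#' The 1984 variance-component estimator of F_ST as a ratio of sums over
#' loci, `theta = sum(a) / sum(a + b + c)`, with per-locus sample sizes
#' taken from typed counts (standard unequal-n formulation). Negative
#' estimates are legitimate and are not truncated. Loci monomorphic across
#' the compared groups contribute nothing and are skipped, as are loci with
#' fewer than 2 groups typed.
#'
#' @param x a [geno] object
#' @param grouping see [sample_groups()]
#' @return A single numeric theta.
#' @export
wc_theta <- function(x, grouping = "site_id") {
  g <- sample_groups(x, grouping)
  cnt <- group_locus_counts(x, g)
  comp <- vapply(seq_len(ncol(cnt$n)), function(l)
    wc_components(cnt$n[, l], cnt$p[, l], cnt$h[, l]), numeric(3))
  ok <- colSums(is.na(comp)) == 0 & colSums(comp) != 0
  if (!any(ok)) return(NA_real_)
  sum(comp[1, ok]) / sum(colSums(comp[, ok, drop = FALSE]))
}

#' Pairwise Weir-Cockerham F_ST between all groups
#'
#' @param x a [geno] object
#' @param grouping see [sample_groups()]; default treats each site as a
#'   population
#' @param min_n pairs where either group has fewer than `min_n` typed
#'   individuals overall are left `NA` (default 2)
#' @return A `pairwise_matrix` of kind `"fst_site"`, zero diagonal;
#'   undefined entries are `NA`.
#' @export
pairwise_fst <- function(x, grouping = "site_id", min_n = 2) {
  g <- sample_groups(x, grouping)
  groups <- unique(g)
  k <- length(groups)
  if (k < 2) abort("need at least two groups")
  m <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(m) <- 0
  sizes <- table(g)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (sizes[[groups[i]]] < min_n || sizes[[groups[j]]] < min_n) next
    sub <- geno_subset(x, samples = g %in% groups[c(i, j)])
    m[i, j] <- m[j, i] <- wc_theta(sub, g[g %in% groups[c(i, j)]])
  }
  pairwise_matrix(m, "fst_site")
}

#' Mantel test between two pairwise matrices
#'
#' Pearson correlation of the lower triangles, with significance from
#' simultaneous row/column permutations of the second matrix. One-tailed
#' for positive association:
#' `p = (1 + #permuted r >= observed r) / (n_perm + 1)`.
#'
#' @param m1,m2 `pairwise_matrix` objects (or plain symmetric matrices)
#'   with identical ids in identical order
#' @param n_perm number of permutations (default 9999, minimum 99)
#' @return A tibble with `r`, `p_value`, `n_perm`, `n_ids`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999) {
  v1 <- if (inherits(m1, "pairwise_matrix")) m1$values else m1
  v2 <- if (inherits(m2, "pairwise_matrix")) m2$values else m2
  if (!identical(rownames(v1), rownames(v2)))
    abort("matrices must share ids in the same order")
  if (n_perm < 99) abort("n_perm must be >= 99")
  lt <- lower.tri(v1)
  keep <- !is.na(v1[lt]) & !is.na(v2[lt])
  x1 <- v1[lt][keep]
  if (sd(v1[lt][keep]) == 0 || sd(v2[lt][keep]) == 0)
    abort("constant matrix: Mantel r undefined")
  r_obs <- cor(v1[lt][keep], v2[lt][keep])
  n <- nrow(v1)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    vp <- v2[perm, perm]
    ok <- !is.na(v1[lt]) & !is.na(vp[lt])
    rp <- cor(v1[lt][ok], vp[lt][ok])
    if (!is.na(rp) && rp >= r_obs) hits <- hits + 1L
  }
  tibble(r = r_obs, p_value = (1 + hits) / (n_perm + 1),
         n_perm = as.integer(n_perm), n_ids = n)
}

#' Great-circle distance matrix between sites or samples
#'
#' Haversine distances (sphere radius 6371 km) between the mean coordinates
#' of each group.
#'
#' @param samples tibble with `longitude`, `latitude` and the grouping
#'   column (a [geno]'s `$samples`, or any data frame)
#' @param grouping column to aggregate coordinates over (default
#'   `"site_id"`)
#' @return A `pairwise_matrix` of kind `"geo_km"` in kilometres.
#' @export
geographic_distance <- function(samples, grouping = "site_id") {
  if (inherits(samples, "geno")) samples <- samples$samples
  need <- c(grouping, "longitude", "latitude")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  if (anyNA(samples$longitude) || anyNA(samples$latitude))
    abort("missing coordinates")
  pts <- samples %>%
    group_by(id = .data[[grouping]]) %>%
    summarise(longitude = mean(.data$longitude),
              latitude = mean(.data$latitude), .groups = "drop")
  m <- geosphere::distm(as.matrix(pts[, c("longitude", "latitude")]),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371))
  dimnames(m) <- list(pts$id, pts$id)
  pairwise_matrix(m, "geo_km")
}
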