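# Fit dosage ~ design for every locus at once via one QR of the shared
# design; returns per-coefficient estimates, SEs, z (t) statistics and the
# unscaled inverse crossproduct for block Wald tests.
fit_all_loci <- function(design, X) {
  qrD <- qr(design)
  if (qrD$rank < ncol(design))
    abort("design matrix is rank deficient")
  B <- qr.coef(qrD, X)
  res <- X - design %*% B
  df <- nrow(design) - ncol(design)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  list(B = B, se = se, z = B / se, sigma2 = sigma2,
       XtXinv = XtXinv, df = df)
}

# median-based genomic inflation factor of a chi-square statistic
inflation_lambda <- function(stat, df) {
  median(stat, na.rm = TRUE) / qchisq(0.5, df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (wraps [stats::p.adjust()]).
#'
#' @param p vector of p-values in \[0, 1\]
#' @return A vector of q-values, `q >= p` elementwise.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) abort("empty p-value list")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Principal-component outlier scan
#'
#' Regresses every locus on the `k` leading principal components of the
#' imputed, scaled genotype matrix, collects the per-component z-scores,
#' and flags loci whose z-vector is an outlier by (robust) Mahalanobis
#' distance. Each z column is median-centered and MAD-standardized before
#' the empirical covariance is taken (`robust = FALSE` uses plain
#' mean/covariance). The squared distances are calibrated by the genomic
#' inflation factor `lambda = median(D2) / qchisq(0.5, k)`; p-values come
#' from the chi-square with `k` degrees of freedom on `D2 / lambda`, and
#' q-values from Benjamini-Hochberg. A locus is an outlier when
#' `q < 0.05`.
#'
#' @param x a [geno] object
#' @param k number of principal components capturing background structure
#'   (default 3)
#' @param robust MAD-standardize z-scores before the covariance
#'   (default `TRUE`)
#' @return An `outlier_scan` tibble: `locus_id`, `method`, `covariate`,
#'   `statistic` (Mahalanobis D2), `p_value`, `q_value`, `is_outlier`;
#'   attribute `"lambda"` holds the inflation factor. Constant loci are
#'   excluded.
#' @export
pc_outlier_scan <- function(x, k = 3, robust = TRUE) {
  stopifnot(inherits(x, "geno"))
  if (k < 1) abort("k must be >= 1")
  m <- impute_and_scale(x)
  pca <- pca_genotypes(m, n_components = k)
  design <- cbind(1, pca$scores)
  fit <- fit_all_loci(design, m)
  z <- t(fit$z[-1, , drop = FALSE])     # loci x k
  if (robust) {
    med <- apply(z, 2, median)
    madv <- apply(z, 2, function(v) median(abs(v - median(v)))) * 1.4826
    zs <- sweep(sweep(z, 2, med), 2, madv, "/")
    d2 <- stats::mahalanobis(zs, center = rep(0, k), cov = cov(zs))
  } else {
    d2 <- stats::mahalanobis(z, center = colMeans(z), cov = cov(z))
  }
  lambda <- inflation_lambda(d2, k)
  p <- pchisq(d2 / lambda, df = k, lower.tail = FALSE)
  q <- bh_qvalues(p)
  out <- tibble(locus_id = colnames(m), method = "pc_scan",
                covariate = "none", statistic = d2, p_value = p,
                q_value = q, is_outlier = q < 0.05)
  class(out) <- c("outlier_scan", class(out))
  attr(out, "lambda") <- lambda
  attr(out, "k") <- k
  out
}

#' Build the environmental design for the latent-factor scan
#'
#' @param samples sample tibble with `fire_category` and `longitude`
#' @param clusters optional per-sample cluster labels (integer/factor);
#'   coded as K-1 dummy columns against the first level
#' @return A numeric matrix with columns `fire` (1 = burnt), `longitude`
#'   (z-scored) and `clusterX` dummies; rows align with `samples`.
#' @export
env_matrix <- function(samples, clusters = NULL) {
  if (inherits(samples, "geno")) samples <- samples$samples
  if (anyNA(samples$fire_category) || anyNA(samples$longitude))
    abort("environment variables must be complete")
  fire <- as.numeric(samples$fire_category == "burnt")
  lon <- samples$longitude - mean(samples$longitude)
  if (sd(lon) > 0) lon <- lon / sd(lon)
  E <- cbind(fire = fire, longitude = lon)
  if (!is.null(clusters)) {
    f <- factor(clusters)
    if (nlevels(f) > 1) {
      dm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(dm) <- paste0("cluster", levels(f)[-1])
      E <- cbind(E, dm)
    }
  }
  rownames(E) <- samples$sample_id
  E
}

#' Latent-factor environmental association scan
#'
#' A two-step ridge-free approximation to latent-factor mixed models for
#' genotype-environment association: (1) latent factors `U` are the
#' leading left singular vectors of the genotype matrix after the
#' environmental design (plus intercept) has been projected out, so they
#' capture structure not explained by the environment; (2) each locus is
#' fit by least squares on `env + U`, and the per-covariate z-statistics
#' are genomic-inflation calibrated and BH-adjusted, covariate by
#' covariate. Cluster membership enters as a dummy block tested jointly
#' (Wald chi-square with K-1 degrees of freedom).
#'
#' @param x a [geno] object
#' @param env matrix from [env_matrix()], rows aligned with samples. Dummy
#'   blocks to be tested jointly must share a column-name prefix
#'   `"cluster"`.
#' @param k number of latent factors (default 5)
#' @return An `outlier_scan` tibble with one row per locus and covariate
#'   (`fire`, `longitude`, `cluster` when present); `statistic` is the
#'   calibrated chi-square. Attribute `"lambda"` is a named vector of
#'   per-covariate inflation factors.
#' @export
latent_factor_scan <- function(x, env, k = 5) {
  stopifnot(inherits(x, "geno"))
  if (k < 0) abort("k must be >= 0")
  if (nrow(env) != nrow(x$dosage)) abort("env rows must align with samples")
  E1 <- cbind(`(Intercept)` = 1, env)
  qe <- qr(E1)
  if (qe$rank < ncol(E1)) {
    piv <- qe$pivot[seq(qe$rank + 1, ncol(E1))]
    abort(sprintf("environment design is rank deficient (columns: %s)",
                  paste(colnames(E1)[piv], collapse = ", ")))
  }
  m <- impute_and_scale(x)
  U <- NULL
  if (k > 0) {
    resid <- m - E1 %*% qr.coef(qe, m)
    sv <- svd(resid, nu = min(k, nrow(m) - ncol(E1)), nv = 0)
    U <- sv$u
    colnames(U) <- paste0("U", seq_len(ncol(U)))
  }
  design <- cbind(E1, U)
  fit <- fit_all_loci(design, m)

  cn <- colnames(design)
  dummy_cols <- grep("^cluster", cn)
  simple <- setdiff(colnames(env), cn[dummy_cols])
  lambdas <- c()
  rows <- list()
  for (v in simple) {
    chi <- fit$z[v, ]^2
    lam <- inflation_lambda(chi, 1)
    p <- pchisq(chi / lam, df = 1, lower.tail = FALSE)
    q <- bh_qvalues(p)
    lambdas[v] <- lam
    rows[[v]] <- tibble(locus_id = colnames(m), method = "lfa_scan",
                        covariate = v, statistic = chi / lam, p_value = p,
                        q_value = q, is_outlier = q < 0.05)
  }
  if (length(dummy_cols)) {
    Vb <- fit$XtXinv[dummy_cols, dummy_cols, drop = FALSE]
    Vbinv <- solve(Vb)
    Bb <- fit$B[dummy_cols, , drop = FALSE]
    wald <- colSums((Vbinv %*% Bb) * Bb) / fit$sigma2
    dfb <- length(dummy_cols)
    lam <- inflation_lambda(wald, dfb)
    p <- pchisq(wald / lam, df = dfb, lower.tail = FALSE)
    q <- bh_qvalues(p)
    lambdas["cluster"] <- lam
    rows[["cluster"]] <- tibble(locus_id = colnames(m), method = "lfa_scan",
                                covariate = "cluster",
                                statistic = wald / lam, p_value = p,
                                q_value = q, is_outlier = q < 0.05)
  }
  out <- bind_rows(rows)
  class(out) <- c("outlier_scan", class(out))
  attr(out, "lambda") <- lambdas
  attr(out, "k") <- k
  out
}

#' Split loci into neutral and putatively selected panels
#'
#' Loci flagged by either scan form the non-neutral (putatively adaptive)
#' panel; the complement is the neutral panel used by all structure,
#' diversity and kinship analyses. Optionally re-applies the stage-2
#' quality filters to the neutral panel, logging both the pre- and
#' post-refilter counts.
#'
#' @param x the [geno] the scans were run on
#' @param outliers an `outlier_scan` tibble (or several, row-bound), or a
#'   character vector of locus ids
#' @param refilter_thresholds optional [filter_thresholds()]; when given,
#'   [filter_stage2()] is re-applied to the neutral panel
#' @return A list with `neutral` and `non_neutral` [geno] objects,
#'   `counts` tibble, and (when refiltered) `refilter_report`.
#' @export
split_panels <- function(x, outliers, refilter_thresholds = NULL) {
  stopifnot(inherits(x, "geno"))
  ids <- if (is.character(outliers)) outliers else
    unique(outliers$locus_id[outliers$is_outlier])
  ids <- intersect(ids, x$loci$locus_id)
  neutral <- geno_subset(x, loci = setdiff(x$loci$locus_id, ids))
  non_neutral <- geno_subset(x, loci = ids)
  counts <- tibble(panel = c("input", "non_neutral", "neutral"),
                   n_loci = c(ncol(x$dosage), ncol(non_neutral$dosage),
                              ncol(neutral$dosage)))
  refilter_report <- NULL
  if (!is.null(refilter_thresholds) && ncol(neutral$dosage) > 0) {
    s2 <- filter_stage2(neutral, refilter_thresholds)
    refilter_report <- s2$report
    neutral <- s2$genotypes
    counts <- bind_rows(counts, tibble(panel = "neutral_refiltered",
                                       n_loci = ncol(neutral$dosage)))
  }
  list(neutral = neutral, non_neutral = non_neutral, counts = counts,
       refilter_report = refilter_report)
}
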