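#' Assemble the site- and individual-level modelling tables
#'
#' Joins per-site allelic richness, modal cluster label and asexuality
#' rate, and per-individual heterozygosity with individual cluster labels,
#' into the tables the fire-by-cluster models consume. Ranger-managed
#' sites are excluded from the modelling tables (their replication and
#' management regime differ) but retained in the `descriptive` element.
#' Sites missing any component are listed in `excluded` with a warning.
#'
#' @param x a [geno] with attached sample metadata
#' @param clusters a `cluster_assignment` from [assign_clusters()] run
#'   with `samples = x$samples`
#' @param richness output of [allelic_richness()] grouped by site
#' @param rates output of [asexuality_rates()]
#' @return A list of class `model_table`: `sites` (burnt/unburnt site rows:
#'   `site_id`, `location_id`, `fire_category`, `site_K`,
#'   `allelic_richness`, `prop_clones`), `individuals` (`sample_id`,
#'   `site_id`, `fire_category`, `individual_K`, `heterozygosity`),
#'   `descriptive` (all sites incl. ranger), `excluded`.
#' @export
build_model_table <- function(x, clusters, richness, rates) {
  stopifnot(inherits(x, "geno"), inherits(clusters, "cluster_assignment"))
  if (is.null(clusters$site_modal))
    abort("run assign_clusters() with `samples` so site modal labels exist")
  site_info <- distinct(x$samples, .data$site_id, .data$location_id,
                        .data$fire_category)
  site_rates <- rates %>% filter(.data$scope == "site") %>%
    select(site_id = "scope_id", prop_clones = "rate")
  sites <- site_info %>%
    left_join(clusters$site_modal, by = "site_id") %>%
    left_join(rename(richness, site_id = "group")[, c("site_id", "allelic_richness")],
              by = "site_id") %>%
    left_join(site_rates, by = "site_id") %>%
    rename(site_K = "site_cluster")
  incomplete <- sites %>%
    filter(is.na(.data$site_K) | is.na(.data$allelic_richness) |
             is.na(.data$prop_clones))
  if (nrow(incomplete))
    warn(sprintf("sites missing components, excluded: %s",
                 paste(incomplete$site_id, collapse = ", ")))
  complete <- dplyr::anti_join(sites, incomplete, by = "site_id")
  het <- individual_heterozygosity(x)
  individuals <- x$samples %>%
    select("sample_id", "site_id", "location_id", "fire_category") %>%
    left_join(het[, c("sample_id", "heterozygosity")], by = "sample_id") %>%
    left_join(clusters$assignments[, c("sample_id", "cluster")],
              by = "sample_id") %>%
    rename(individual_K = "cluster")
  structure(list(
    sites = filter(complete, .data$fire_category %in% c("burnt", "unburnt")),
    individuals = filter(individuals,
                         .data$fire_category %in% c("burnt", "unburnt")),
    descriptive = complete,
    excluded = incomplete
  ), class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf("<model_table> %d model sites, %d individuals (%d descriptive sites)\n",
              nrow(x$sites), nrow(x$individuals), nrow(x$descriptive)))
  invisible(x)
}

# treatment-coded factors with unburnt / K1 as reference
model_factors <- function(df, k_col) {
  df$fire_category <- factor(df$fire_category, levels = c("unburnt", "burnt"))
  df$K <- factor(df[[k_col]])
  df
}

new_fire_model <- function(response, family, coefs, term_tests, aliased,
                           fit, notes = character()) {
  structure(list(response = response, family = family, coefs = coefs,
                 term_tests = term_tests, aliased = aliased, fit = fit,
                 notes = notes),
            class = "fire_model")
}

#' @export
print.fire_model <- function(x, ...) {
  cat(sprintf("<fire_model: %s (%s)>\n", x$response, x$family))
  print(as.data.frame(x$coefs), row.names = FALSE, digits = 3)
  cat("term tests:\n")
  print(as.data.frame(x$term_tests), row.names = FALSE, digits = 3)
  if (length(x$aliased))
    cat("aliased (empty design cells):", paste(x$aliased, collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @rdname fit_richness_ols
#' @param x a `fire_model`
#' @param ... unused
#' @export
tidy.fire_model <- function(x, ...) x$coefs

#' @rdname fit_richness_ols
#' @export
glance.fire_model <- function(x, ...) {
  tibble(response = x$response, family = x$family,
         n_terms = nrow(x$coefs), n_aliased = length(x$aliased))
}

# nested-model layouts for Type II term tests; collapses to the
# fire-only comparison when the cluster factor has a single level
term_layout <- function(df) {
  if (nlevels(df$K) >= 2) {
    list(
      fire_category = c("K", "fire_category + K"),
      K = c("fire_category", "fire_category + K"),
      `fire_category:K` = c("fire_category + K", "fire_category * K")
    )
  } else {
    list(fire_category = c("1", "fire_category"))
  }
}

model_rhs <- function(df) {
  if (nlevels(df$K) >= 2) "fire_category * K" else "fire_category"
}

# Type II term tests by nested-model F comparisons on lm fits
type2_terms <- function(df, response) {
  forms <- term_layout(df)
  purrr::map_dfr(names(forms), function(term) {
    small <- lm(stats::reformulate(forms[[term]][1], response), data = df)
    big <- lm(stats::reformulate(forms[[term]][2], response), data = df)
    a <- anova(small, big)
    tibble(term = term, statistic = a$F[2], df = a$Df[2],
           df_resid = a$Res.Df[2], p_value = a$`Pr(>F)`[2])
  })
}

# Type II Wald F-tests under a supplied covariance estimator: the
# coefficients the bigger model adds are tested jointly against zero
robust_type2 <- function(df, response, vc_fun, df_denom) {
  forms <- term_layout(df)
  purrr::map_dfr(names(forms), function(term) {
    small <- lm(stats::reformulate(forms[[term]][1], response), data = df)
    big <- lm(stats::reformulate(forms[[term]][2], response), data = df)
    cf <- coef(big)
    added <- setdiff(names(cf)[!is.na(cf)],
                     names(coef(small))[!is.na(coef(small))])
    if (!length(added))
      return(tibble(term = term, statistic = NA_real_, df = 0L,
                    df_resid = df_denom, p_value = NA_real_))
    V <- vc_fun(big)
    b <- cf[added]
    stat <- drop(t(b) %*% solve(V[added, added, drop = FALSE]) %*% b) /
      length(added)
    tibble(term = term, statistic = stat, df = length(added),
           df_resid = df_denom,
           p_value = pf(stat, length(added), df_denom, lower.tail = FALSE))
  })
}

#' Linear model of site-level allelic richness on fire category x cluster
#'
#' OLS of allelic richness on `fire_category * K` with treatment coding
#' (reference: unburnt, cluster 1). Design cells that are structurally
#' empty (a cluster observed only burnt, say) produce aliased interaction
#' coefficients; these are reported as aliased, never estimated. Term
#' p-values are Type II nested-model F-tests, which are invariant to term
#' order.
#'
#' @param table the `sites` tibble of a [build_model_table()] (or any data
#'   frame with the response, `fire_category` and the cluster column)
#' @param response column to model (default `"allelic_richness"`)
#' @param k_col cluster label column (default `"site_K"`)
#' @return A `fire_model` with `coefs`, `term_tests`, `aliased`.
#' @export
fit_richness_ols <- function(table, response = "allelic_richness",
                             k_col = "site_K") {
  df <- model_factors(as_tibble(table), k_col)
  fit <- lm(stats::reformulate(model_rhs(df), response), data = df)
  if (stats::df.residual(fit) < 2) abort("fewer than 2 residual df: fit refused")
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  sm <- summary(fit)$coefficients
  coefs <- tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                  std_error = unname(sm[, 2]), p_value = unname(sm[, 4]))
  new_fire_model(response, "ols", coefs, type2_terms(df, response),
                 aliased, fit)
}

#' Cluster-robust linear model of individual heterozygosity
#'
#' The same fixed-effect mean model as [fit_richness_ols()]
#' (`fire_category * K`) fit by OLS on individual rows, with standard
#' errors clustered on site (CR sandwich estimator) to absorb the
#' within-site correlation a site random intercept would model. Point
#' estimates equal the random-intercept model's fixed effects under the
#' same mean structure; inference is conservative. With a single site the
#' fit falls back to classical OLS with a warning.
#'
#' @param table the `individuals` tibble of a [build_model_table()]
#' @param response column to model (default `"heterozygosity"`)
#' @param k_col cluster label column (default `"individual_K"`)
#' @param cluster_col column defining the error clusters (default
#'   `"site_id"`)
#' @return A `fire_model` of family `ols_cluster_robust` (or `ols` on
#'   fallback).
#' @export
fit_heterozygosity_model <- function(table, response = "heterozygosity",
                                     k_col = "individual_K",
                                     cluster_col = "site_id") {
  df <- model_factors(as_tibble(table), k_col)
  fit <- lm(stats::reformulate(model_rhs(df), response), data = df)
  if (stats::df.residual(fit) < 2) abort("fewer than 2 residual df: fit refused")
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  n_clusters <- length(unique(df[[cluster_col]]))
  if (n_clusters < 2) {
    warn("single cluster: falling back to classical OLS standard errors")
    sm <- summary(fit)$coefficients
    coefs <- tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                    std_error = unname(sm[, 2]), p_value = unname(sm[, 4]))
    return(new_fire_model(response, "ols", coefs,
                          type2_terms(df, response), aliased, fit,
                          notes = "single-site data: classical OLS"))
  }
  vc <- sandwich::vcovCL(fit, cluster = df[[cluster_col]])
  ct <- lmtest::coeftest(fit, vcov. = vc, df = n_clusters - 1)
  coefs <- tibble(term = rownames(ct), estimate = unname(ct[, 1]),
                  std_error = unname(ct[, 2]), p_value = unname(ct[, 4]))
  # Type II Wald comparisons under the clustered covariance
  vfun <- function(m) sandwich::vcovCL(m, cluster = df[[cluster_col]])
  term_tests <- robust_type2(df, response, vfun, df_denom = n_clusters - 1)
  new_fire_model(response, "ols_cluster_robust", coefs, term_tests,
                 aliased, fit,
                 notes = sprintf("site-clustered (CR) standard errors, %d clusters",
                                 n_clusters))
}

#' Beta regression of the site-level proportion of clones
#'
#' Logit-link beta regression with constant precision, fit by maximum
#' likelihood, of the within-site asexuality rate on
#' `fire_category * K`. Boundary proportions are first compressed to the
#' open interval by `y' = (y (N - 1) + 0.5) / N` with `N` the number of
#' sites, the standard transformation for boundary-inclusive proportion
#' data. Coefficient p-values and term tests are Wald (interaction block
#' from the full model, main-effect blocks from the additive model, so
#' tests are order-invariant). With only factor covariates no smooth
#' structure exists, so the model is a plain beta GLM.
#'
#' @param table the `sites` tibble of a [build_model_table()]
#' @param response proportion column (default `"prop_clones"`)
#' @param k_col cluster label column (default `"site_K"`)
#' @param max_iter optimizer iteration cap (default 200)
#' @return A `fire_model` of family `beta_logit`; `fit` carries the
#'   coefficients, the precision `phi` and the log-likelihood.
#' @export
fit_clonality_beta <- function(table, response = "prop_clones",
                               k_col = "site_K", max_iter = 200) {
  df <- model_factors(as_tibble(table), k_col)
  y <- df[[response]]
  if (any(y < 0 | y > 1)) abort("proportions must lie in [0, 1]")
  n <- length(y)
  y <- (y * (n - 1) + 0.5) / n
  fit_block <- function(formula_rhs) {
    X_full <- model.matrix(stats::reformulate(formula_rhs), df)
    qrX <- qr(X_full)
    aliased <- if (qrX$rank < ncol(X_full))
      colnames(X_full)[qrX$pivot[-seq_len(qrX$rank)]] else character()
    X <- X_full[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    start_beta <- qr.coef(qr(X), stats::qlogis(y))
    par0 <- c(start_beta, log_phi = log(5))
    negll <- function(par) {
      mu <- stats::plogis(X %*% par[seq_len(ncol(X))])
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      phi <- exp(par[length(par)])
      -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    }
    opt <- optim(par0, negll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = max_iter))
    if (opt$convergence != 0)
      abort(sprintf("beta regression did not converge in %d iterations (code %d): %s",
                    max_iter, opt$convergence, opt$message %||% "no message"))
    vc <- tryCatch(solve(opt$hessian), error = function(e) {
      matrix(NA_real_, length(par0), length(par0))
    })
    k <- ncol(X)
    list(beta = setNames(opt$par[seq_len(k)], colnames(X)),
         se = sqrt(pmax(diag(vc)[seq_len(k)], 0)),
         vcov = vc[seq_len(k), seq_len(k), drop = FALSE],
         phi = exp(opt$par[k + 1]), loglik = -opt$value,
         aliased = aliased, X = X)
  }
  full <- fit_block(model_rhs(df))
  coefs <- tibble(term = names(full$beta), estimate = unname(full$beta),
                  std_error = unname(full$se),
                  p_value = unname(2 * pnorm(-abs(full$beta / full$se))))
  wald_block <- function(blk, pattern) {
    idx <- grep(pattern, names(blk$beta))
    if (!length(idx)) return(tibble(statistic = NA_real_, df = 0L,
                                    p_value = NA_real_))
    b <- blk$beta[idx]
    V <- blk$vcov[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V) %*% b)
    tibble(statistic = stat, df = length(idx),
           p_value = pchisq(stat, length(idx), lower.tail = FALSE))
  }
  additive <- if (nlevels(df$K) >= 2) fit_block("fire_category + K") else full
  term_tests <- bind_rows(
    mutate(wald_block(additive, "^fire_categoryburnt$"),
           term = "fire_category", .before = 1),
    mutate(wald_block(additive, "^K[^:]+$"), term = "K", .before = 1),
    mutate(wald_block(full, ":"), term = "fire_category:K", .before = 1)
  )
  new_fire_model(response, "beta_logit", coefs, term_tests, full$aliased,
                 full[c("beta", "se", "phi", "loglik")])
}

#' Fitted means of a beta-logit fire model
#'
#' @param object a `fire_model` of family `beta_logit`
#' @param newdata data frame with `fire_category` and the cluster column
#'   used at fit time (factor levels must match)
#' @param k_col cluster column name (default `"site_K"`)
#' @param ... unused
#' @return Numeric vector of fitted mean proportions, always in (0, 1).
#' @export
predict.fire_model <- function(object, newdata, k_col = "site_K", ...) {
  if (object$family != "beta_logit")
    return(stats::predict(object$fit, newdata = newdata))
  df <- model_factors(as_tibble(newdata), k_col)
  X <- model.matrix(stats::reformulate(model_rhs(df)), df)
  b <- object$fit$beta
  X <- X[, names(b), drop = FALSE]
  stats::plogis(drop(X %*% b))
}
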