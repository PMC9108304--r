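site_table <- function(fire, K, y, name = "allelic_richness") {
  tb <- tibble::tibble(site_id = sprintf("s%02d", seq_along(fire)),
                       fire_category = fire, site_K = K)
  tb[[name]] <- y
  tb
}

test_that("noiseless OLS recovers the generating coefficients exactly", {
  fire <- rep(c("unburnt", "burnt"), each = 6)
  K <- rep(c(1, 2, 3), 4)
  mu <- 1 + 0.5 * (fire == "burnt") + 0.3 * (K == 2) - 0.2 * (K == 3) +
    0.7 * (fire == "burnt" & K == 3)
  fit <- suppressWarnings(fit_richness_ols(site_table(fire, K, mu)))
  est <- setNames(fit$coefs$estimate, fit$coefs$term)
  expect_equal(unname(est["(Intercept)"]), 1, tolerance = 1e-10)
  expect_equal(unname(est["fire_categoryburnt"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(est["K2"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(est["fire_categoryburnt:K3"]), 0.7, tolerance = 1e-10)
  expect_length(fit$aliased, 0)
})

test_that("balanced 2x2 interaction equals the cell-mean contrast", {
  set.seed(300)
  fire <- rep(c("unburnt", "burnt"), each = 8)
  K <- rep(rep(c(1, 2), each = 4), 2)
  y <- rnorm(16)
  fit <- fit_richness_ols(site_table(fire, K, y))
  cm <- tapply(y, list(fire, K), mean)
  contrast <- cm["burnt", "2"] - cm["burnt", "1"] -
    cm["unburnt", "2"] + cm["unburnt", "1"]
  est <- setNames(fit$coefs$estimate, fit$coefs$term)
  expect_equal(unname(est["fire_categoryburnt:K2"]), contrast,
               tolerance = 1e-10)
})

test_that("structurally empty design cells are reported aliased", {
  set.seed(301)
  # K2 exists only at burnt sites
  fire <- c(rep("unburnt", 6), rep("burnt", 9))
  K <- c(rep(c(1, 3), 3), rep(c(1, 2, 3), 3))
  fit <- fit_richness_ols(site_table(fire, K, rnorm(15)))
  expect_true("fire_categoryburnt:K2" %in% fit$aliased)
  expect_false("fire_categoryburnt:K2" %in% fit$coefs$term)
  expect_true(all(c("fire_category", "K", "fire_category:K") %in%
                    fit$term_tests$term))
})

test_that("tiny designs are refused rather than overfit", {
  fire <- c("unburnt", "burnt", "unburnt", "burnt")
  K <- c(1, 1, 2, 2)
  expect_error(fit_richness_ols(site_table(fire, K, rnorm(4))), "residual df")
})

test_that("cluster-robust SEs collapse to classical ones without site effects", {
  set.seed(302)
  n_site <- 12; per <- 6
  df <- tibble::tibble(
    site_id = rep(sprintf("s%02d", 1:n_site), each = per),
    fire_category = rep(rep(c("burnt", "unburnt"), each = per), n_site / 2),
    individual_K = rep(rep(c(1, 2), times = per / 2), n_site),
    heterozygosity = rnorm(n_site * per))
  fit <- fit_heterozygosity_model(df)
  ols <- lm(heterozygosity ~ fire_category * K,
            data = dplyr::mutate(df,
                                 fire_category = factor(fire_category,
                                                        c("unburnt", "burnt")),
                                 K = factor(individual_K)))
  ratio <- fit$coefs$std_error / summary(ols)$coefficients[, 2]
  expect_true(all(ratio > 0.6 & ratio < 1.6))
  expect_equal(unname(fit$coefs$estimate), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("strong site intercepts inflate robust SEs for between-site terms", {
  set.seed(303)
  n_site <- 16; per <- 8
  site <- rep(sprintf("s%02d", 1:n_site), each = per)
  fire <- rep(rep(c("burnt", "unburnt"), each = per), n_site / 2)
  site_eff <- rep(rnorm(n_site, sd = 2), each = per)
  df <- tibble::tibble(site_id = site, fire_category = fire,
                       individual_K = 1,
                       heterozygosity = site_eff + rnorm(n_site * per, sd = 0.3))
  fit <- fit_heterozygosity_model(df)
  ols <- lm(heterozygosity ~ factor(fire_category, c("unburnt", "burnt")),
            data = df)
  robust_fire <- fit$coefs$std_error[fit$coefs$term == "fire_categoryburnt"]
  classical_fire <- summary(ols)$coefficients[2, 2]
  expect_gt(robust_fire, classical_fire)
})

test_that("beta regression keeps means in (0,1) and survives boundary data", {
  fire <- rep(c("unburnt", "burnt"), each = 8)
  K <- rep(rep(c(1, 2), each = 4), 2)
  tb <- site_table(fire, K, rep(0, 16), name = "prop_clones")
  fit <- fit_clonality_beta(tb)
  mu <- predict(fit, tb)
  expect_true(all(mu > 0 & mu < 1))
  tb2 <- site_table(fire, K, c(rep(0, 8), rep(1, 8)), name = "prop_clones")
  fit2 <- fit_clonality_beta(tb2)
  expect_true(all(predict(fit2, tb2) > 0 & predict(fit2, tb2) < 1))
  expect_error(fit_clonality_beta(site_table(fire, K, rep(1.5, 16),
                                             name = "prop_clones")),
               "0, 1")
})

test_that("beta regression recovers known coefficients within 2 SE mostly", {
  set.seed(304)
  fire <- rep(c("unburnt", "burnt"), each = 20)
  K <- rep(rep(c(1, 2), each = 10), 2)
  X <- cbind(1, fire == "burnt", K == 2, (fire == "burnt") & (K == 2))
  beta_true <- c(-0.5, 1.0, -0.8, 0.6)
  phi_true <- 30
  hits <- 0; total <- 0
  for (r in 1:20) {
    mu <- stats::plogis(X %*% beta_true)
    y <- rbeta(40, mu * phi_true, (1 - mu) * phi_true)
    fit <- fit_clonality_beta(site_table(fire, K, y, name = "prop_clones"))
    est <- setNames(fit$coefs$estimate, fit$coefs$term)
    se <- setNames(fit$coefs$std_error, fit$coefs$term)
    terms <- c("(Intercept)", "fire_categoryburnt", "K2",
               "fire_categoryburnt:K2")
    hits <- hits + sum(abs(est[terms] - beta_true) <= 2 * se[terms])
    total <- total + 4
  }
  expect_gte(hits / total, 0.9)
})

test_that("the model table assembles, excludes ranger sites, lists gaps", {
  ds <- simulate_dataset(sim_config(n_loci = 500, clonal_fraction = 0.3,
                                    seed = 310))
  g <- ds$genotypes
  pca <- pca_genotypes(g, n_components = 3)
  asg <- assign_clusters(pca, 3, samples = g$samples)
  rich <- allelic_richness(g, "site_id")
  kin <- kinship_matrix(filter_stage1(g)$genotypes, min_loci = 50)
  rates <- asexuality_rates(kin, g$samples)
  mt <- build_model_table(g, asg, rich, rates)
  expect_equal(nrow(mt$sites), 16)          # 8 paired roadside locations
  expect_equal(nrow(mt$descriptive), 19)    # + 3 ranger sites
  expect_false(any(mt$sites$fire_category == "ranger"))
  expect_true(all(c("site_K", "allelic_richness", "prop_clones") %in%
                    names(mt$sites)))
  expect_equal(nrow(mt$individuals), 80)
  # drop one site's richness: it must be listed and excluded
  rich2 <- rich[rich$group != "loc01_b", ]
  expect_warning(mt2 <- build_model_table(g, asg, rich2, rates), "loc01_b")
  expect_equal(nrow(mt2$sites), 15)
})

test_that("an end-to-end fire effect on clonality is detectable", {
  ds <- simulate_dataset(sim_config(
    clonal_fraction = c(burnt = 0.6, unburnt = 0.1, ranger = 0.1),
    n_loci = 1500, include_ranger = FALSE, seed = 311))
  g <- ds$genotypes
  pca <- pca_genotypes(g, n_components = 3)
  asg <- assign_clusters(pca, 3, samples = g$samples)
  rich <- allelic_richness(g, "site_id")
  kin <- kinship_matrix(g, min_loci = 50)
  rates <- asexuality_rates(kin, g$samples)
  mt <- build_model_table(g, asg, rich, rates)
  fit <- fit_clonality_beta(mt$sites)
  tt <- fit$term_tests
  expect_lt(tt$p_value[tt$term == "fire_category"], 0.05)
})
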