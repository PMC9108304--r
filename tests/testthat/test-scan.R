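null_geno <- function(n = 100, L = 2000, seed = 91) {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  make_geno(hwe_genotypes(n, p))
}

test_that("BH q-values match hand arithmetic and the step-up oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(92)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_qvalues(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_qvalues(numeric(0)), "empty")
  expect_error(bh_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("the PC scan is calibrated on neutral data", {
  g <- null_geno(n = 100, L = 3000, seed = 93)
  scan <- pc_outlier_scan(g, k = 3)
  expect_lte(mean(scan$is_outlier), 0.05 * 1.2)
  expect_equal(attr(scan, "lambda"), 1, tolerance = 0.1)
  # empirical type-I at p < 0.05 near nominal after calibration
  expect_lt(abs(mean(scan$p_value < 0.05) - 0.05), 0.02)
})

test_that("a locus collinear with PC1 ranks first by Mahalanobis distance", {
  g <- null_geno(n = 80, L = 500, seed = 94)
  pca <- pca_genotypes(g, n_components = 1)
  planted <- as.integer(cut(pca$scores[, 1], 3)) - 1L
  d <- cbind(g$dosage, planted = planted)
  colnames(d) <- c(colnames(g$dosage), "planted")
  scan <- pc_outlier_scan(make_geno(d), k = 3)
  expect_equal(scan$locus_id[which.max(scan$statistic)], "planted")
  expect_true(scan$is_outlier[scan$locus_id == "planted"])
})

test_that("lambda is ~1 on exactly chi-square distributed statistics", {
  set.seed(95)
  d2 <- stats::rchisq(20000, df = 3)
  expect_equal(inflation_lambda <- median(d2) / qchisq(0.5, 3), 1,
               tolerance = 0.05)
})

test_that("the latent-factor scan recovers planted fire-associated loci", {
  set.seed(96)
  n <- 90; L <- 2000; n_hit <- 50
  fire <- rep(c(1, 0), each = n / 2)
  p <- runif(L, 0.05, 0.5)
  # sweep targets start rare and rise by 0.3 at burnt sites
  p[seq_len(n_hit)] <- runif(n_hit, 0.05, 0.2)
  g <- hwe_genotypes(n, p)
  for (j in seq_len(n_hit))
    g[fire == 1, j] <- rbinom(n / 2, 2, p[j] + 0.3)
  gm <- make_geno(g)
  samples <- gm$samples
  samples$fire_category <- ifelse(fire == 1, "burnt", "unburnt")
  samples$longitude <- runif(n, 133, 134)
  env <- env_matrix(samples)
  scan <- latent_factor_scan(gm, env, k = 5)
  planted_ids <- colnames(gm$dosage)[seq_len(n_hit)]
  fire_hits <- scan$locus_id[scan$covariate == "fire" & scan$is_outlier]
  power <- mean(planted_ids %in% fire_hits)
  expect_gt(power, 0.8)
  # null loci stay quiet
  null_flagged <- setdiff(fire_hits, planted_ids)
  expect_lte(length(null_flagged), 0.01 * L)
})

test_that("the latent-factor scan is quiet under the null", {
  g <- null_geno(n = 80, L = 2000, seed = 97)
  samples <- g$samples
  set.seed(98)
  samples$fire_category <- sample(c("burnt", "unburnt"), 80, TRUE)
  samples$longitude <- runif(80, 133, 134)
  scan <- latent_factor_scan(g, env_matrix(samples), k = 5)
  for (cv in unique(scan$covariate))
    expect_lte(sum(scan$is_outlier[scan$covariate == cv]), 0.005 * 2000)
})

test_that("the cluster covariate flags cultivar-differentiated loci", {
  ds <- simulate_dataset(sim_config(n_cultivars = 3, divergence = 0.9,
                                    clonal_fraction = 0, n_loci = 600,
                                    missing_rate = 0, include_ranger = FALSE,
                                    seed = 99))
  g <- ds$genotypes
  env <- env_matrix(g$samples, clusters = ds$truth$cultivar)
  scan <- latent_factor_scan(g, env, k = 2)
  cl <- dplyr::filter(scan, covariate == "cluster")
  expect_gt(sum(cl$is_outlier), 0)
  # flagged loci are more differentiated than unflagged ones
  theta_of <- function(ids) wc_theta(geno_subset(g, loci = ids),
                                     ds$truth$cultivar)
  expect_gt(theta_of(cl$locus_id[cl$is_outlier]),
            theta_of(cl$locus_id[!cl$is_outlier]))
})

test_that("a rank-deficient environment design fails loudly", {
  g <- null_geno(n = 30, L = 50, seed = 100)
  samples <- g$samples
  samples$fire_category <- rep(c("burnt", "unburnt"), 15)
  samples$longitude <- 133          # constant -> collinear with intercept
  expect_error(latent_factor_scan(g, env_matrix(samples), k = 2),
               "rank deficient.*longitude")
})

test_that("panel splitting conserves and unions correctly", {
  g <- null_geno(n = 20, L = 100, seed = 101)
  sp <- split_panels(g, character(0))
  expect_equal(ncol(sp$neutral$dosage), 100)
  expect_equal(ncol(sp$non_neutral$dosage), 0)
  # overlapping calls union
  sp2 <- split_panels(g, c("L0001", "L0002", "L0002", "L0003"))
  expect_equal(ncol(sp2$non_neutral$dosage), 3)
  expect_equal(ncol(sp2$neutral$dosage), 97)
  expect_equal(sum(sp2$counts$n_loci[sp2$counts$panel %in%
                                       c("neutral", "non_neutral")]), 100)
  # disjoint method calls of sizes a and b give a + b
  s1 <- tibble::tibble(locus_id = c("L0001", "L0002"), is_outlier = TRUE)
  s2 <- tibble::tibble(locus_id = c("L0003"), is_outlier = TRUE)
  sp3 <- split_panels(g, dplyr::bind_rows(s1, s2))
  expect_equal(ncol(sp3$non_neutral$dosage), 3)
})
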