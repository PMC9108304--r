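sim_pair <- function(relationship, L, seed, lo = 0.1, hi = 0.9) {
  set.seed(seed)
  p <- runif(L, lo, hi)
  a <- drop(hwe_genotypes(1, p))
  pair <- switch(
    relationship,
    clone = list(a, a),
    parent_offspring = {
      b <- drop(hwe_genotypes(1, p))
      list(a, mendelian_offspring(a, b))
    },
    full_sib = {
      b <- drop(hwe_genotypes(1, p))
      list(mendelian_offspring(a, b), mendelian_offspring(a, b))
    },
    half_sib = {
      b <- drop(hwe_genotypes(1, p))
      cc <- drop(hwe_genotypes(1, p))
      list(mendelian_offspring(a, b), mendelian_offspring(a, cc))
    },
    unrelated = list(a, drop(hwe_genotypes(1, p)))
  )
  list(a = pair[[1]], b = pair[[2]], p = p)
}

test_that("EM kinship hits the textbook values for canonical relationships", {
  expected <- c(clone = 0.5, parent_offspring = 0.25, full_sib = 0.25,
                half_sib = 0.125, unrelated = 0)
  for (rel in names(expected)) {
    pr <- sim_pair(rel, 10000, seed = 200 + match(rel, names(expected)))
    est <- ml_kinship_pair(pr$a, pr$b, pr$p)
    expect_lt(abs(est$phi - expected[[rel]]), 0.01)
  }
})

test_that("clone pairs stay identifiable through mild genotyping error", {
  pr <- sim_pair("clone", 5000, seed = 210)
  b <- pr$b
  flip <- sample(5000, 50)  # 1% discordance
  b[flip] <- vapply(b[flip], function(g) sample(setdiff(0:2, g), 1L), integer(1))
  est <- ml_kinship_pair(pr$a, b, pr$p)
  expect_gt(est$phi, 0.45)
  expect_lt(est$phi, 0.55)
})

test_that("the EM log-likelihood is monotone non-decreasing", {
  for (rel in c("clone", "full_sib", "unrelated")) {
    pr <- sim_pair(rel, 2000, seed = 220 + nchar(rel))
    est <- ml_kinship_pair(pr$a, pr$b, pr$p)
    trace <- attr(est, "loglik_trace")
    expect_gt(length(trace), 1)
    expect_true(all(diff(trace) >= -1e-8))
    if (rel == "clone") expect_true(est$converged)
  }
})

test_that("EM agrees with the method-of-moments estimator on non-inbred pairs", {
  for (seed in 230:234) {
    rel <- c("unrelated", "half_sib", "full_sib", "parent_offspring",
             "clone")[seed - 229]
    pr <- sim_pair(rel, 8000, seed = seed)
    em <- ml_kinship_pair(pr$a, pr$b, pr$p)$phi
    mom <- mom_kinship_pair(pr$a, pr$b, pr$p)
    expect_lt(abs(em - max(mom, 0)), 0.02)
  }
})

test_that("mode weights are a simplex and phi is bounded", {
  pr <- sim_pair("full_sib", 3000, seed = 240)
  est <- ml_kinship_pair(pr$a, pr$b, pr$p)
  expect_equal(est$k0 + est$k1 + est$k2, 1, tolerance = 1e-8)
  expect_true(all(c(est$k0, est$k1, est$k2) >= 0))
  expect_gte(est$phi, 0)
  expect_lte(est$phi, 0.5)
})

test_that("pairs with too few shared loci are refused, not guessed", {
  pr <- sim_pair("clone", 300, seed = 250)
  a <- pr$a; a[1:250] <- NA
  est <- ml_kinship_pair(a, pr$b, pr$p, min_loci = 100)
  expect_true(is.na(est$phi))
  expect_equal(est$n_loci_used, 50)
})

test_that("the kinship matrix flags exactly the planted clone pair", {
  set.seed(260)
  p <- runif(3000, 0.1, 0.9)
  a <- drop(hwe_genotypes(1, p))
  m <- rbind(a, a, drop(hwe_genotypes(1, p)))
  gm <- make_geno(m)
  kin <- kinship_matrix(gm, allele_freqs = p)
  expect_equal(sum(kin$pairs$phi > 0.45), 1)
  expect_identical(kin$matrix$values, t(kin$matrix$values))
  expect_equal(nrow(kin$pairs), 3)
})

test_that("asexuality rates reduce to combinatorial counts", {
  set.seed(270)
  p <- runif(2000, 0.1, 0.9)
  genet <- drop(hwe_genotypes(1, p))
  others <- hwe_genotypes(3, p)
  m <- rbind(genet, genet, others)      # 5 individuals, one clone pair
  gm <- make_geno(m)
  gm$samples$location_id <- "loc01"
  gm$samples$site_id <- "loc01_b"
  kin <- kinship_matrix(gm, allele_freqs = p)
  rates <- asexuality_rates(kin, gm$samples)
  site <- rates[rates$scope == "site", ]
  expect_equal(site$n_pairs, 10)
  expect_equal(site$rate, 1 / 10)
  # all clones of one genet: every rate is 1
  m2 <- rbind(genet, genet, genet)
  gm2 <- make_geno(m2)
  gm2$samples$location_id <- "loc01"; gm2$samples$site_id <- "loc01_b"
  r2 <- asexuality_rates(kinship_matrix(gm2, allele_freqs = p), gm2$samples)
  expect_true(all(r2$rate == 1))
})

test_that("fully outcrossed samples show near-zero asexuality rates", {
  ds <- simulate_dataset(sim_config(clonal_fraction = 0, n_loci = 3000,
                                    n_locations = 2, samples_per_site = 8,
                                    include_ranger = FALSE,
                                    missing_rate = 0, seed = 280))
  kin <- kinship_matrix(ds$genotypes)
  rates <- asexuality_rates(kin, ds$genotypes$samples)
  expect_lt(rates$rate[rates$scope == "dataset"], 0.001)
})

test_that("rates recover the simulator truth and order by spatial scale", {
  ds <- simulate_dataset(sim_config(clonal_fraction = 0.45, n_loci = 3000,
                                    n_locations = 2, samples_per_site = 20,
                                    include_ranger = FALSE, seed = 290))
  kin <- kinship_matrix(filter_stage1(ds$genotypes)$genotypes)
  rates <- asexuality_rates(kin, ds$genotypes$samples)
  truth <- true_clone_pair_rates(ds)
  est <- pooled_rates(rates)
  tru <- pooled_rates(dplyr::rename(truth, n_above = rate) %>%
                        dplyr::mutate(n_above = .data$n_above * .data$n_pairs))
  for (sc in c("dataset", "location", "site")) {
    expect_lt(abs(est$rate[est$scope == sc] - tru$rate[tru$scope == sc]), 0.05)
  }
  # clones only arise within sites, so the rate concentrates at fine scale
  expect_gte(est$rate[est$scope == "site"], est$rate[est$scope == "location"])
  expect_gte(est$rate[est$scope == "location"], est$rate[est$scope == "dataset"])
})
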