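base_loci <- function(ids, tags = paste0("t_", ids), cr = 1, rep_ = 0.99) {
  tibble::tibble(locus_id = ids, tag_id = tags, call_rate = cr,
                 reproducibility = rep_)
}

test_that("same-tag dedup keeps the highest call rate, ties break by id", {
  m <- cbind(c(0L, 1L, 2L, 0L), c(1L, 0L, 2L, 1L), c(0L, 1L, 1L, 2L))
  g <- make_geno(m, loci = base_loci(c("A", "B", "C"),
                                     tags = c("t1", "t1", "t2"),
                                     cr = c(0.7, 0.9, 1)))
  out <- filter_stage1(g)
  expect_setequal(out$genotypes$loci$locus_id, c("B", "C"))
  expect_equal(out$report$removed$tag_dedup, "A")
  # equal call rates: lexicographically smallest id survives
  g2 <- make_geno(m, loci = base_loci(c("Z", "Y", "C"),
                                      tags = c("t1", "t1", "t2")))
  out2 <- filter_stage1(g2)
  expect_true("Y" %in% out2$genotypes$loci$locus_id)
  expect_false("Z" %in% out2$genotypes$loci$locus_id)
})

test_that("monomorphic loci and strict call-rate boundary behave as printed", {
  m <- cbind(rep(0L, 10), rep(2L, 10), rbinom(10, 2, 0.5))
  m[1, 3] <- 1L  # guarantee polymorphism
  g <- make_geno(m, loci = base_loci(c("mono0", "mono2", "poly"),
                                     cr = c(1, 1, 1)))
  out <- filter_stage1(g)
  expect_identical(out$genotypes$loci$locus_id, "poly")
  # boundary: 0.49 removed, 0.50 kept (strict <)
  g2 <- make_geno(cbind(m[, 3], m[, 3] + 0L),
                  loci = base_loci(c("lo", "edge"), cr = c(0.49, 0.50)))
  out2 <- filter_stage1(g2)
  expect_identical(out2$genotypes$loci$locus_id, "edge")
})

test_that("stage-2 boundaries are strict for MAF, reproducibility and H_obs", {
  n <- 50
  maf_low <- c(rep(1L, 4), rep(0L, n - 4))        # maf 0.04 -> removed
  maf_edge <- c(rep(1L, 5), rep(0L, n - 5))       # maf 0.05 -> kept
  het_all <- rep(1L, n)                           # hobs 1 -> removed
  hobs_edge <- c(rep(1L, 40), rep(0L, 5), rep(2L, 5))  # hobs 0.80 -> kept
  normal <- rbinom(n, 2, 0.5)
  m <- cbind(maf_low, maf_edge, het_all, hobs_edge, normal)
  g <- make_geno(m, loci = base_loci(
    c("maf_low", "maf_edge", "het_all", "hobs_edge", "normal"),
    rep_ = c(0.99, 0.99, 0.99, 0.99, 0.99)))
  out <- filter_stage2(g)
  expect_setequal(out$genotypes$loci$locus_id,
                  c("maf_edge", "hobs_edge", "normal"))
  expect_equal(out$report$removed$maf, "maf_low")
  expect_equal(out$report$removed$paralog_hobs, "het_all")
  # reproducibility boundary
  g2 <- make_geno(cbind(normal, rbinom(n, 2, 0.5)),
                  loci = base_loci(c("lo", "edge"), rep_ = c(0.949, 0.95)))
  out2 <- filter_stage2(g2)
  expect_identical(out2$report$removed$reproducibility, "lo")
})

test_that("a planted-violation fixture yields exact attrition counts", {
  set.seed(99)
  n <- 50
  hwe <- function() rbinom(n, 2L, 0.5)
  filler <- replicate(8, hwe())
  dup <- hwe()
  m <- cbind(
    tag_a = hwe(), tag_b = hwe(), tag_c = hwe(),   # shared tag -> 2 removed
    mono1 = rep(0L, n), mono2 = rep(2L, n),        # 2 monomorphic
    cr1 = hwe(), cr2 = hwe(),                      # metadata call rate 0.4
    maf1 = c(rep(1L, 4), rep(0L, n - 4)),          # maf 0.04
    rep1 = hwe(),                                  # reproducibility 0.90
    hob1 = rep(1L, n),                             # hobs 1
    dupA = dup, dupB = dup,                        # r = 1 -> 1 removed
    filler)
  colnames(m) <- c("tag_a", "tag_b", "tag_c", "mono1", "mono2", "cr1", "cr2",
                   "maf1", "rep1", "hob1", "dupA", "dupB",
                   sprintf("fill%02d", 1:8))
  loci <- base_loci(colnames(m))
  loci$tag_id[1:3] <- "tshared"
  loci$call_rate <- 1
  loci$call_rate[1:3] <- c(0.9, 0.95, 0.8)   # tag_b survives dedup
  loci$call_rate[6:7] <- 0.4
  loci$reproducibility[9] <- 0.90
  g <- make_geno(m, loci = loci)
  out <- filter_cascade(g)
  ledger <- tidy(out$report)
  expect_equal(ledger$n_removed,
               c(tag_dedup = 2, monomorphic = 2, call_rate = 2, maf = 1,
                 reproducibility = 1, paralog_hobs = 1, ld_prune = 1),
               ignore_attr = TRUE)
  # ledger conservation across the cascade
  expect_equal(ledger$n_before[1] - sum(ledger$n_removed),
               ledger$n_after[nrow(ledger)])
  expect_true(all(ledger$n_after == dplyr::lead(ledger$n_before,
                                                default = ledger$n_after[7])))
  expect_setequal(out$report$removed$ld_prune, "dupB")
})

test_that("both filter stages are idempotent", {
  set.seed(12)
  ds <- simulate_dataset(sim_config(n_loci = 300, n_locations = 2,
                                    divergence = 0.3, seed = 8))
  s1 <- filter_stage1(ds$genotypes)
  s1b <- filter_stage1(s1$genotypes)
  expect_identical(s1b$genotypes$dosage, s1$genotypes$dosage)
  s2 <- filter_stage2(s1$genotypes)
  s2b <- filter_stage2(s2$genotypes)
  expect_identical(s2b$genotypes$dosage, s2$genotypes$dosage)
  expect_true(all(tidy(s1b$report)$n_removed == 0))
  expect_true(all(tidy(s2b$report)$n_removed == 0))
})

test_that("ld pruning is greedy, deterministic and call-rate aware", {
  set.seed(3)
  n <- 40
  a <- rbinom(n, 2L, 0.5)
  m <- cbind(a, a, a, rbinom(n, 2L, 0.5))
  colnames(m) <- c("d1", "d2", "d3", "ind")
  # three mutual duplicates -> exactly two removed, one survivor
  g <- make_geno(m, loci = base_loci(colnames(m)))
  out <- ld_prune(g, 0.75)
  expect_length(out$removed, 2)
  expect_setequal(out$removed, c("d2", "d3"))
  # lower call rate loses regardless of scan position
  loci <- base_loci(colnames(m))
  loci$call_rate <- c(0.6, 1, 1, 1)
  out2 <- ld_prune(make_geno(m, loci = loci), 0.75)
  expect_true("d1" %in% out2$removed)
  expect_length(setdiff(c("d1", "d2", "d3"), out2$removed), 1)
})

test_that("undefined correlations (too few shared samples) keep the pair", {
  m <- cbind(c(0L, 1L, 2L, NA, NA, NA), c(NA, NA, NA, 0L, 1L, 2L),
             c(0L, 2L, 0L, 2L, 0L, 2L))
  colnames(m) <- c("x", "y", "z")
  g <- make_geno(m)
  expect_warning(out <- ld_prune(g, 0.75), "undefined")
  expect_true(all(c("x", "y") %in% out$genotypes$loci$locus_id))
})

test_that("independent HWE loci are essentially never pruned", {
  set.seed(44)
  m <- matrix(rbinom(200 * 120, 2L, 0.5), nrow = 200)
  g <- make_geno(m)
  out <- ld_prune(g, 0.75)
  expect_length(out$removed, 0)
})
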