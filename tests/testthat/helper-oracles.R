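# Independent oracles and small constructors shared across tests.

make_geno <- function(m, loci = NULL, ...) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (!is.null(loci)) colnames(m) <- loci$locus_id
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%04d", seq_len(ncol(m)))
  if (is.null(loci)) geno(m, ...) else geno(m, loci = loci, ...)
}

# two-deme Balding-Nichols genotype set with truth labels
bn_two_demes <- function(n_per, L, d, maf = c(0.05, 0.5)) {
  p_anc <- runif(L, maf[1], maf[2])
  draw <- function() if (d == 0) p_anc else
    rbeta(L, p_anc * (1 - d) / d, (1 - p_anc) * (1 - d) / d)
  g <- rbind(hwe_genotypes(n_per, draw()), hwe_genotypes(n_per, draw()))
  list(geno = make_geno(g), groups = rep(c("a", "b"), each = n_per))
}

# brute-force Weir-Cockerham variance components for ONE locus, written
# straight from the defining moment equations, independent of the package's
# vectorized path
oracle_wc_single <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# exhaustive rarefaction oracle: enumerate every g-subset of the N allele
# copies and average the number of distinct alleles seen
oracle_rarefied_richness <- function(N, Na, g) {
  copies <- c(rep(1, Na), rep(2, N - Na))
  subs <- utils::combn(N, g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# hand Benjamini-Hochberg step-up with monotonicity
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# pooled asexuality rate per scope from the rates tibble
pooled_rates <- function(rates) {
  rates |>
    dplyr::group_by(scope) |>
    dplyr::summarise(rate = sum(n_above) / sum(n_pairs), .groups = "drop")
}
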