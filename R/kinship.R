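# Per-locus genotype-pair likelihoods under the three IBD modes for a
# non-inbred biallelic model. p = alternate-allele frequency. Returns 9 x L
# matrices indexed by combo code ga*3 + gb + 1.
ibd_mode_tables <- function(p) {
  q <- 1 - p
  Pg <- rbind(q^2, 2 * p * q, p^2)           # genotype probs, rows g = 0,1,2
  L <- length(p)
  L0 <- matrix(0, 9, L); L1 <- matrix(0, 9, L); L2 <- matrix(0, 9, L)
  code <- function(ga, gb) ga * 3 + gb + 1
  for (ga in 0:2) for (gb in 0:2) {
    i <- code(ga, gb)
    L0[i, ] <- Pg[ga + 1, ] * Pg[gb + 1, ]
    if (ga == gb) L2[i, ] <- Pg[ga + 1, ]
  }
  # one shared IBD allele: standard pair table
  L1[code(0, 0), ] <- q^3
  L1[code(0, 1), ] <- L1[code(1, 0), ] <- p * q^2
  L1[code(1, 1), ] <- p * q
  L1[code(1, 2), ] <- L1[code(2, 1), ] <- p^2 * q
  L1[code(2, 2), ] <- p^3
  list(L0 = L0, L1 = L1, L2 = L2)
}

# EM fit of the IBD-mode mixture (k0, k1, k2) for one pair given the three
# per-locus likelihood vectors. Likelihood contributions are floored to
# keep occasional discordant calls (genotyping error) from collapsing the
# likelihood to zero.
em_ibd <- function(l0, l1, l2, tol = 1e-6, max_iter = 500, floor = 1e-6) {
  l0 <- pmax(l0, floor); l1 <- pmax(l1, floor); l2 <- pmax(l2, floor)
  k <- c(1, 1, 1) / 3
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w0 <- k[1] * l0; w1 <- k[2] * l1; w2 <- k[3] * l2
    tot <- w0 + w1 + w2
    trace[it] <- sum(log(tot))
    k_new <- c(mean(w0 / tot), mean(w1 / tot), mean(w2 / tot))
    if (max(abs(k_new - k)) < tol) { k <- k_new; break }
    k <- k_new
  }
  list(k = k, loglik = trace[length(trace)], trace = trace, iterations = it)
}

#' Maximum-likelihood pairwise kinship for one pair
#'
#' Fits the non-inbred identity-by-descent model by EM: at each locus the
#' probability of the observed genotype pair is a mixture over the three
#' IBD modes (sharing 0, 1 or 2 alleles identical by descent) with weights
#' `(k0, k1, k2)`; the E-step computes per-locus posterior mode weights and
#' the M-step averages them. The kinship coefficient is
#' `phi = k2 / 2 + k1 / 4`: 0.5 for clones, 0.25 for full sibs or
#' parent-offspring, 0 for unrelated pairs. Convergence when every mode
#' weight moves less than `tol`, or after `max_iter` iterations.
#'
#' @param dos_a,dos_b dosage vectors (0/1/2/`NA`) of the two individuals
#' @param allele_freqs per-locus alternate-allele frequencies, estimated
#'   from the full sample
#' @param min_loci refuse the estimate when fewer informative loci are
#'   typed in both individuals (default 100)
#' @param tol EM convergence tolerance on the mode weights (default 1e-6)
#' @param max_iter EM iteration cap (default 500)
#' @return A one-row tibble: `k0`, `k1`, `k2`, `phi`, `n_loci_used`,
#'   `loglik`, `converged`. Attribute `"loglik_trace"` holds the per-
#'   iteration log-likelihood (non-decreasing). When too few loci are
#'   usable the estimate is refused: all values `NA` and
#'   `n_loci_used` reported.
#' @export
ml_kinship_pair <- function(dos_a, dos_b, allele_freqs, min_loci = 100,
                            tol = 1e-6, max_iter = 500) {
  stopifnot(length(dos_a) == length(dos_b),
            length(allele_freqs) == length(dos_a))
  use <- !is.na(dos_a) & !is.na(dos_b) &
    allele_freqs > 0 & allele_freqs < 1
  n_used <- sum(use)
  if (n_used < min_loci) {
    return(tibble(k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                  phi = NA_real_, n_loci_used = n_used,
                  loglik = NA_real_, converged = NA))
  }
  tabs <- ibd_mode_tables(allele_freqs[use])
  idx <- cbind(dos_a[use] * 3 + dos_b[use] + 1, seq_len(n_used))
  fit <- em_ibd(tabs$L0[idx], tabs$L1[idx], tabs$L2[idx],
                tol = tol, max_iter = max_iter)
  out <- tibble(k0 = fit$k[1], k1 = fit$k[2], k2 = fit$k[3],
                phi = fit$k[3] / 2 + fit$k[2] / 4,
                n_loci_used = n_used, loglik = fit$loglik,
                converged = fit$iterations < max_iter)
  attr(out, "loglik_trace") <- fit$trace
  out
}

#' Maximum-likelihood kinship for all pairs
#'
#' Runs [ml_kinship_pair()] for every unordered pair of individuals.
#' Allele frequencies are estimated once from all typed individuals
#' (clonal replicates therefore pull the frequencies slightly toward their
#' genet — inherent to pooled estimation and not corrected). Run this on
#' the filtered neutral panel.
#'
#' @param x a [geno] object
#' @param allele_freqs optional frequency override (e.g. truth from a
#'   simulation)
#' @inheritParams ml_kinship_pair
#' @return A list of class `kinship_result`: `pairs` (long tibble with
#'   `id_a`, `id_b`, `k0`, `k1`, `k2`, `phi`, `n_loci_used`) and `matrix`
#'   (a `pairwise_matrix` of kind `"kinship"` with `NA` diagonal; refused
#'   pairs are `NA` and flagged in `pairs$refused`).
#' @export
kinship_matrix <- function(x, allele_freqs = NULL, min_loci = 100,
                           tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(x, "geno"))
  d <- x$dosage
  n <- nrow(d)
  if (n < 2) abort("need at least 2 individuals")
  p <- allele_freqs %||% (colMeans(d, na.rm = TRUE) / 2)
  informative <- !is.na(p) & p > 0 & p < 1
  d <- d[, informative, drop = FALSE]
  p <- p[informative]
  tabs <- ibd_mode_tables(p)
  ids <- x$samples$sample_id
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- vector("list", nrow(pair_idx))
  for (r in seq_len(nrow(pair_idx))) {
    i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
    use <- which(!is.na(d[i, ]) & !is.na(d[j, ]))
    if (length(use) < min_loci) {
      res[[r]] <- tibble(id_a = ids[i], id_b = ids[j], k0 = NA_real_,
                         k1 = NA_real_, k2 = NA_real_, phi = NA_real_,
                         n_loci_used = length(use), refused = TRUE)
      next
    }
    idx <- cbind(d[i, use] * 3 + d[j, use] + 1, use)
    fit <- em_ibd(tabs$L0[idx], tabs$L1[idx], tabs$L2[idx],
                  tol = tol, max_iter = max_iter)
    res[[r]] <- tibble(id_a = ids[i], id_b = ids[j], k0 = fit$k[1],
                       k1 = fit$k[2], k2 = fit$k[3],
                       phi = fit$k[3] / 2 + fit$k[2] / 4,
                       n_loci_used = length(use), refused = FALSE)
  }
  pairs <- bind_rows(res)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  m[cbind(match(pairs$id_a, ids), match(pairs$id_b, ids))] <- pairs$phi
  m[cbind(match(pairs$id_b, ids), match(pairs$id_a, ids))] <- pairs$phi
  structure(list(pairs = pairs, matrix = pairwise_matrix(m, "kinship")),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf("<kinship_result> %d pairs (%d refused); phi range %.3f..%.3f\n",
              nrow(x$pairs), sum(x$pairs$refused),
              min(x$pairs$phi, na.rm = TRUE), max(x$pairs$phi, na.rm = TRUE)))
  invisible(x)
}

#' @rdname kinship_matrix
#' @param ... unused
#' @export
tidy.kinship_result <- function(x, ...) x$pairs

#' Method-of-moments kinship (cross-check estimator)
#'
#' The simple product-moment relatedness estimator
#' `phi = mean_l[(g_a - 2p)(g_b - 2p) / (2 p (1 - p))] / 2`, used as an
#' independent check on the EM estimator for non-inbred pairs.
#'
#' @inheritParams ml_kinship_pair
#' @return A single numeric phi (can be negative).
#' @export
mom_kinship_pair <- function(dos_a, dos_b, allele_freqs) {
  use <- !is.na(dos_a) & !is.na(dos_b) &
    allele_freqs > 0 & allele_freqs < 1
  p <- allele_freqs[use]
  mean((dos_a[use] - 2 * p) * (dos_b[use] - 2 * p) / (2 * p * (1 - p))) / 2
}

#' Multi-scale asexuality rates from a kinship matrix
#'
#' The proportion of pairwise kinship values strictly above `threshold`
#' (0.45 by default: past that point a pair is taken as two ramets of a
#' clonal or apomictic genet) at three spatial scopes: the whole dataset,
#' within locations (burnt and unburnt sites pooled), and within sites.
#' Refused (undefined) pairs are excluded; scopes with no defined pair are
#' dropped.
#'
#' @param kin a `kinship_result` (or a `pairwise_matrix` of kind
#'   `"kinship"`)
#' @param samples sample tibble with `sample_id`, `location_id`, `site_id`
#'   (e.g. a [geno]'s `$samples`)
#' @param threshold clonality cutoff, strict `>` (default 0.45)
#' @return A tibble: `scope` (`dataset` / `location` / `site`),
#'   `scope_id`, `n_pairs`, `n_above`, `rate`.
#' @export
asexuality_rates <- function(kin, samples, threshold = 0.45) {
  if (inherits(samples, "geno")) samples <- samples$samples
  pairs <- if (inherits(kin, "kinship_result")) kin$pairs else
    rename(tidy(kin), phi = "value")
  pairs <- filter(pairs, !is.na(.data$phi))
  if (!nrow(pairs)) abort("no defined kinship pairs")
  key <- samples[, c("sample_id", "location_id", "site_id")]
  pairs <- pairs %>%
    left_join(rename(key, loc_a = "location_id", site_a = "site_id"),
              by = c(id_a = "sample_id")) %>%
    left_join(rename(key, loc_b = "location_id", site_b = "site_id"),
              by = c(id_b = "sample_id"))
  rate_tbl <- function(df, scope, scope_id) {
    tibble(scope = scope, scope_id = scope_id, n_pairs = nrow(df),
           n_above = sum(df$phi > threshold),
           rate = sum(df$phi > threshold) / nrow(df))
  }
  out <- list(rate_tbl(pairs, "dataset", "all"))
  by_loc <- filter(pairs, .data$loc_a == .data$loc_b)
  for (l in unique(by_loc$loc_a))
    out <- c(out, list(rate_tbl(filter(by_loc, .data$loc_a == l),
                                "location", l)))
  by_site <- filter(pairs, .data$site_a == .data$site_b)
  for (s in unique(by_site$site_a))
    out <- c(out, list(rate_tbl(filter(by_site, .data$site_a == s),
                                "site", s)))
  bind_rows(out)
}
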