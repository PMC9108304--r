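#' Per-locus, per-group diversity statistics
#'
#' For each group and locus with at least one typed individual: the
#' alternate-allele frequency `p`, observed heterozygosity `Ho`, unbiased
#' expected heterozygosity `He = (2n / (2n - 1)) * 2p(1 - p)` (Nei-style
#' small-sample correction on gene diversity) and the inbreeding
#' coefficient `Fis = 1 - Ho / He`, left `NA` where `He = 0`. Strongly
#' negative, high-variance, left-skewed F_IS distributions are the
#' signature of partial clonality.
#'
#' @param x a [geno] object
#' @param grouping see [sample_groups()]; default `"site_id"`
#' @return A tibble with columns `group`, `locus_id`, `n_typed`, `p`,
#'   `Ho`, `He`, `Fis`. Group-locus combinations with no typed individuals
#'   are dropped, not zero-filled.
#' @export
site_diversity <- function(x, grouping = "site_id") {
  g <- sample_groups(x, grouping)
  purrr::map_dfr(unique(g), function(grp) {
    d <- x$dosage[g == grp, , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    ho <- colMeans(d == 1L, na.rm = TRUE)
    he <- (2 * n) / (2 * n - 1) * 2 * p * (1 - p)
    fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
    keep <- n > 0
    tibble(group = grp, locus_id = colnames(d)[keep],
           n_typed = as.integer(unname(n[keep])), p = unname(p[keep]),
           Ho = unname(ho[keep]), He = unname(he[keep]),
           Fis = unname(fis[keep]))
  })
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' allele copies, computed hypergeometrically per locus and group:
#' `AR = sum_a [1 - choose(N - N_a, g) / choose(N, g)]` where `N` is the
#' number of typed allele copies in the group and `N_a` the copies of
#' allele `a`. For biallelic loci `1 <= AR <= 2`. Group values are means
#' over loci; loci untyped in any group are excluded from all groups so
#' that groups are compared on the same panel.
#'
#' @param x a [geno] object
#' @param grouping see [sample_groups()]
#' @param g rarefaction size in allele copies; defaults to twice the
#'   smallest per-locus typed count over groups (after excluding loci
#'   untyped somewhere), the largest size every group supports
#' @return A tibble with `group`, `allelic_richness` (mean over loci) and
#'   `n_loci`; the per-locus values are in attribute `"per_locus"`.
#' @export
allelic_richness <- function(x, grouping = "site_id", g = NULL) {
  grp <- sample_groups(x, grouping)
  groups <- unique(grp)
  counts <- lapply(groups, function(gg) {
    d <- x$dosage[grp == gg, , drop = FALSE]
    n <- colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    cbind(N = 2 * n, Na = alt)
  })
  names(counts) <- groups
  typed_everywhere <- Reduce(`&`, lapply(counts, function(m) m[, "N"] > 0))
  if (!any(typed_everywhere))
    abort("no locus is typed in every group")
  min_copies <- min(vapply(counts, function(m)
    min(m[typed_everywhere, "N"]), numeric(1)))
  if (is.null(g)) g <- min_copies
  if (g < 2) abort("rarefaction size g must be >= 2")
  if (g > min_copies)
    abort(sprintf("g = %d exceeds the smallest typed copy count (%d)",
                  g, min_copies))
  per_locus <- purrr::map_dfr(groups, function(gg) {
    m <- counts[[gg]][typed_everywhere, , drop = FALSE]
    N <- m[, "N"]; Na <- m[, "Na"]
    ar <- rarefied_allele_count(N, Na, g) +
      rarefied_allele_count(N, N - Na, g)
    tibble(group = gg, locus_id = colnames(x$dosage)[typed_everywhere],
           allelic_richness = ar)
  })
  out <- per_locus %>% group_by(.data$group) %>%
    summarise(allelic_richness = mean(.data$allelic_richness),
              n_loci = dplyr::n(), .groups = "drop")
  attr(out, "per_locus") <- per_locus
  attr(out, "g") <- g
  out
}

# P(allele with Na copies out of N appears in a subsample of size g),
# computed on log scale: 1 - C(N - Na, g)/C(N, g)
rarefied_allele_count <- function(N, Na, g) {
  miss <- rep(0, length(N))
  can_miss <- (N - Na) >= g
  miss[can_miss] <- exp(lchoose(N[can_miss] - Na[can_miss], g) -
                          lchoose(N[can_miss], g))
  1 - miss
}

#' Per-individual heterozygosity
#'
#' The proportion of an individual's typed loci called heterozygous.
#'
#' @param x a [geno] object
#' @return A tibble with `sample_id`, `n_typed`, `heterozygosity`
#'   (`NA` when no locus is typed).
#' @export
individual_heterozygosity <- function(x) {
  stopifnot(inherits(x, "geno"))
  n <- rowSums(!is.na(x$dosage))
  het <- rowSums(x$dosage == 1L, na.rm = TRUE)
  tibble(sample_id = x$samples$sample_id, n_typed = as.integer(unname(n)),
         heterozygosity = unname(ifelse(n > 0, het / n, NA_real_)))
}

#' F_IS distribution moments per group
#'
#' Summarises the per-locus F_IS distribution of each group (typically the
#' genetic clusters) by its mean, interlocus standard deviation and
#' skewness (third standardized moment). Loci with `He = 0` are excluded.
#' Run this on the stage-1-only panel so loci with extreme F_IS, which
#' later filters remove, still contribute.
#'
#' @param x a [geno] object
#' @param grouping see [sample_groups()]
#' @return A tibble with `group`, `n_loci`, `Fis_mean`, `Fis_sd`,
#'   `Fis_skew`.
#' @export
fis_moments <- function(x, grouping = "site_id") {
  site_diversity(x, grouping) %>%
    filter(!is.na(.data$Fis)) %>%
    group_by(group = .data$group) %>%
    summarise(n_loci = dplyr::n(),
              Fis_mean = mean(.data$Fis),
              Fis_sd = sd(.data$Fis),
              Fis_skew = skewness(.data$Fis),
              .groups = "drop")
}

skewness <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((v - m)^3) / s2^1.5
}

#' Group-level diversity summary
#'
#' Convenience wrapper combining mean He/Ho, F_IS moments and rarefied
#' allelic richness per group.
#'
#' @inheritParams allelic_richness
#' @return A tibble with one row per group.
#' @export
diversity_summary <- function(x, grouping = "site_id", g = NULL) {
  div <- site_diversity(x, grouping)
  base <- div %>% group_by(group = .data$group) %>%
    summarise(He_mean = mean(.data$He), Ho_mean = mean(.data$Ho),
              .groups = "drop")
  ar <- allelic_richness(x, grouping, g)
  fm <- fis_moments(x, grouping)
  base %>%
    left_join(select(ar, "group", "allelic_richness"), by = "group") %>%
    left_join(select(fm, "group", dplyr::starts_with("Fis")), by = "group")
}
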