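#' Simulation configuration for cultivar/clone genotype datasets
#'
#' Describes a synthetic sampling design emulating paired burnt/unburnt
#' roadside sites along a longitudinal gradient, invaded by a small number
#' of highly divergent cultivars that reproduce partly clonally (vegetative
#' spread or apomictic seed — indistinguishable in SNP data, and not
#' distinguished here).
#'
#' Cultivar allele frequencies follow a Balding-Nichols beta model around
#' ancestral frequencies: mean `p`, variance `d * p * (1 - p)` where `d` is
#' `divergence`, an F_ST-like parameter. `d >= 0.9` gives near-fixation
#' within cultivars, the regime of strongly differentiated crop accessions.
#'
#' @param n_cultivars number of divergent cultivars (default 3)
#' @param divergence Balding-Nichols divergence in \[0, 1) (default 0.9)
#' @param n_locations number of paired burnt/unburnt roadside locations
#'   (default 8)
#' @param samples_per_site individuals sampled per site (default 5)
#' @param clonal_fraction probability that an individual is a clone of a
#'   previously sampled member of its site; either a single number or a
#'   vector named by fire category, e.g.
#'   `c(burnt = 0.2, unburnt = 0.5, ranger = 0.1)` (default 0.3)
#' @param ancestral_maf_range range the ancestral minor-allele frequency is
#'   drawn uniformly from (default `c(0.05, 0.5)`)
#' @param n_loci number of biallelic loci (default 5000)
#' @param missing_rate per-call missing probability (default 0.02)
#' @param genotype_error_rate per-call probability that the dosage is
#'   resampled from the two wrong values (default 0.001)
#' @param selfing_or_inbreeding_f inbreeding coefficient applied to sexual
#'   individuals (default 0)
#' @param include_ranger add a ninth, ranger-managed location of 3 sites
#'   (default `TRUE`, mirroring a design with a descriptive-only location)
#' @param cultivar_of_location optional integer vector assigning a cultivar
#'   to each location (default: round-robin)
#' @param seed integer RNG seed
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cultivars = 3,
                       divergence = 0.9,
                       n_locations = 8,
                       samples_per_site = 5,
                       clonal_fraction = 0.3,
                       ancestral_maf_range = c(0.05, 0.5),
                       n_loci = 5000,
                       missing_rate = 0.02,
                       genotype_error_rate = 0.001,
                       selfing_or_inbreeding_f = 0,
                       include_ranger = TRUE,
                       cultivar_of_location = NULL,
                       seed = 1L) {
  chk01 <- function(x, nm, right_open = FALSE) {
    if (any(x < 0) || any(if (right_open) x >= 1 else x > 1))
      abort(sprintf("`%s` must lie in [0, 1%s", nm,
                    if (right_open) ")" else "]"))
  }
  if (n_loci < 1) abort("`n_loci` must be >= 1")
  if (n_cultivars < 1) abort("`n_cultivars` must be >= 1")
  if (samples_per_site < 1)
    abort("`samples_per_site` must be >= 1: each site needs a founder")
  chk01(divergence, "divergence", right_open = TRUE)
  chk01(clonal_fraction, "clonal_fraction")
  chk01(missing_rate, "missing_rate")
  chk01(genotype_error_rate, "genotype_error_rate")
  chk01(selfing_or_inbreeding_f, "selfing_or_inbreeding_f")
  if (length(ancestral_maf_range) != 2 || any(ancestral_maf_range <= 0) ||
      any(ancestral_maf_range > 0.5) || diff(ancestral_maf_range) < 0)
    abort("`ancestral_maf_range` must be an increasing interval in (0, 0.5]")
  n_total_loc <- n_locations + as.integer(include_ranger)
  if (is.null(cultivar_of_location)) {
    cultivar_of_location <- rep_len(seq_len(n_cultivars), n_total_loc)
  } else if (length(cultivar_of_location) != n_total_loc ||
             any(!cultivar_of_location %in% seq_len(n_cultivars))) {
    abort("`cultivar_of_location` needs one cultivar index per location")
  }
  structure(list(
    n_cultivars = n_cultivars, divergence = divergence,
    n_locations = n_locations, samples_per_site = samples_per_site,
    clonal_fraction = clonal_fraction,
    ancestral_maf_range = ancestral_maf_range, n_loci = n_loci,
    missing_rate = missing_rate, genotype_error_rate = genotype_error_rate,
    selfing_or_inbreeding_f = selfing_or_inbreeding_f,
    include_ranger = include_ranger,
    cultivar_of_location = cultivar_of_location, seed = as.integer(seed)
  ), class = "sim_config")
}

clonal_fraction_for <- function(cf, fire_category) {
  if (length(cf) == 1 && is.null(names(cf))) return(unname(cf))
  if (!fire_category %in% names(cf))
    abort(sprintf("clonal_fraction has no entry for fire category '%s'",
                  fire_category))
  unname(cf[[fire_category]])
}

#' Draw unrelated genotypes from allele frequencies
#'
#' Hardy-Weinberg draws with optional inbreeding: with probability `f` the
#' two alleles at a locus are identical by descent (dosage 0 or 2), else
#' they are independent draws.
#'
#' @param n number of individuals
#' @param p vector of alternate-allele frequencies, one per locus
#' @param f inbreeding coefficient in \[0, 1\]
#' @return Integer matrix `n` x `length(p)` of dosages.
#' @export
hwe_genotypes <- function(n, p, f = 0) {
  L <- length(p)
  out <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    ibd <- runif(L) < f
    a1 <- rbinom(L, 1L, p)
    a2 <- rbinom(L, 1L, p)
    d <- a1 + a2
    d[ibd] <- 2L * a1[ibd]
    out[i, ] <- d
  }
  out
}

#' Mendelian offspring of two genotyped parents
#'
#' Each parent transmits its alternate allele with probability dosage / 2,
#' independently across loci.
#'
#' @param parent_a,parent_b integer dosage vectors (0/1/2)
#' @return Integer dosage vector of the offspring.
#' @export
mendelian_offspring <- function(parent_a, parent_b) {
  stopifnot(length(parent_a) == length(parent_b))
  rbinom(length(parent_a), 1L, parent_a / 2) +
    rbinom(length(parent_b), 1L, parent_b / 2)
}

#' Simulate a cultivar/clone genotype dataset
#'
#' Generates genotypes under the design in [sim_config()]: Balding-Nichols
#' cultivar allele frequencies, one dominant cultivar per location, and
#' per-site sequential sampling in which each individual is, with
#' probability `clonal_fraction` (possibly fire-category-specific), an exact
#' pre-error copy of a previously sampled site member (a ramet of the same
#' genet), and otherwise a sexual recruit drawn from the site cultivar's
#' mating pool with inbreeding `f`. Genotyping error then resamples each
#' call to a wrong dosage with probability `genotype_error_rate`, and calls
#' go missing with probability `missing_rate`; per-locus call rate is the
#' realised non-missing fraction and reproducibility is drawn near 0.99.
#'
#' @param config a [sim_config()]
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{genotypes}{[geno] with full sample and locus metadata}
#'     \item{truth}{tibble: `sample_id`, `cultivar`, `genet_id`,
#'       `is_clone`, `parent_id` (`NA` for sexual recruits)}
#'     \item{true_allele_freqs}{cultivars x loci matrix of the
#'       Balding-Nichols frequencies}
#'     \item{pre_error}{integer matrix of genotypes before error/missingness
#'       (clone pairs are identical here)}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  p_anc <- runif(L, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  d <- config$divergence
  freqs <- matrix(0, config$n_cultivars, L)
  for (k in seq_len(config$n_cultivars)) {
    freqs[k, ] <- if (d == 0) p_anc else
      rbeta(L, p_anc * (1 - d) / d, (1 - p_anc) * (1 - d) / d)
  }
  rownames(freqs) <- paste0("cultivar", seq_len(config$n_cultivars))

  # sampling frame: paired b/u sites per roadside location, optional ranger
  locs <- tibble(
    location_id = sprintf("loc%02d", seq_along(config$cultivar_of_location)),
    cultivar = config$cultivar_of_location,
    longitude = 133.5 - 0.12 * (seq_along(config$cultivar_of_location) - 1),
    latitude = -23.70
  )
  site_rows <- purrr::map_dfr(seq_len(nrow(locs)), function(i) {
    ranger <- config$include_ranger && i == nrow(locs)
    if (ranger) {
      tibble(location_id = locs$location_id[i],
             site_id = paste0(locs$location_id[i], "_r", 1:3),
             fire_category = "ranger", cultivar = locs$cultivar[i],
             longitude = locs$longitude[i] + c(0, 5e-4, 1e-3),
             latitude = locs$latitude[i] + c(0, 5e-4, 1e-3))
    } else {
      tibble(location_id = locs$location_id[i],
             site_id = paste0(locs$location_id[i], c("_b", "_u")),
             fire_category = c("burnt", "unburnt"), cultivar = locs$cultivar[i],
             longitude = locs$longitude[i] + c(0, 2e-4),
             latitude = locs$latitude[i] + c(0, 2e-4))
    }
  })

  n_total <- nrow(site_rows) * config$samples_per_site
  pre <- matrix(0L, n_total, L)
  samples <- vector("list", nrow(site_rows))
  truth <- vector("list", nrow(site_rows))
  genet_counter <- 0L
  row0 <- 0L
  for (s in seq_len(nrow(site_rows))) {
    cf <- clonal_fraction_for(config$clonal_fraction, site_rows$fire_category[s])
    pk <- freqs[site_rows$cultivar[s], ]
    ids <- sprintf("%s_i%02d", site_rows$site_id[s], seq_len(config$samples_per_site))
    genet <- character(config$samples_per_site)
    parent <- rep(NA_character_, config$samples_per_site)
    is_clone <- logical(config$samples_per_site)
    for (i in seq_len(config$samples_per_site)) {
      if (i > 1 && runif(1) < cf) {
        j <- sample.int(i - 1L, 1L)
        pre[row0 + i, ] <- pre[row0 + j, ]
        genet[i] <- genet[j]
        parent[i] <- ids[j]
        is_clone[i] <- TRUE
      } else {
        pre[row0 + i, ] <- hwe_genotypes(1, pk, config$selfing_or_inbreeding_f)
        genet_counter <- genet_counter + 1L
        genet[i] <- sprintf("genet%04d", genet_counter)
      }
    }
    samples[[s]] <- tibble(
      sample_id = ids,
      location_id = site_rows$location_id[s], site_id = site_rows$site_id[s],
      fire_category = site_rows$fire_category[s],
      longitude = site_rows$longitude[s], latitude = site_rows$latitude[s])
    truth[[s]] <- tibble(sample_id = ids,
                         cultivar = rownames(freqs)[site_rows$cultivar[s]],
                         genet_id = genet, is_clone = is_clone,
                         parent_id = parent)
    row0 <- row0 + config$samples_per_site
  }
  samples <- bind_rows(samples)
  truth <- bind_rows(truth)
  rownames(pre) <- samples$sample_id
  locus_ids <- sprintf("L%06d", seq_len(L))
  colnames(pre) <- locus_ids

  obs <- pre
  if (config$genotype_error_rate > 0) {
    err <- which(matrix(runif(length(obs)) < config$genotype_error_rate,
                        nrow(obs)))
    if (length(err)) {
      truev <- obs[err]
      obs[err] <- vapply(truev, function(g)
        sample(setdiff(0:2, g), 1L), integer(1))
    }
  }
  if (config$missing_rate > 0)
    obs[matrix(runif(length(obs)) < config$missing_rate, nrow(obs))] <- NA_integer_

  loci <- tibble(
    locus_id = locus_ids,
    tag_id = sprintf("tag%06d", seq_len(L)),
    call_rate = unname(colMeans(!is.na(obs))),
    reproducibility = pmin(1, 0.99 + rnorm(L, 0, 0.004))
  )
  structure(list(
    genotypes = geno(obs, samples = samples, loci = loci),
    truth = truth, true_allele_freqs = freqs, pre_error = pre,
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d individuals, %d loci, %d cultivars, %d genets\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              nrow(x$true_allele_freqs), length(unique(x$truth$genet_id))))
  invisible(x)
}

#' True clone-pair proportions of a simulated dataset
#'
#' The realised proportion of pairs that are ramets of one genet, at
#' dataset, location and site scope — the ground truth that estimated
#' asexuality rates are compared against.
#'
#' @param dataset a `sim_dataset`
#' @return A tibble with `scope`, `scope_id`, `n_pairs`, `rate`.
#' @export
true_clone_pair_rates <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  tr <- left_join(dataset$truth,
                  dataset$genotypes$samples[, c("sample_id", "location_id", "site_id")],
                  by = "sample_id")
  rate_in <- function(df) {
    n <- nrow(df)
    if (n < 2) return(tibble(n_pairs = 0L, rate = NA_real_))
    tab <- table(df$genet_id)
    same <- sum(choose(tab, 2))
    tibble(n_pairs = choose(n, 2), rate = same / choose(n, 2))
  }
  bind_rows(
    mutate(rate_in(tr), scope = "dataset", scope_id = "all", .before = 1),
    tr %>% group_by(scope_id = .data$location_id) %>%
      dplyr::group_modify(~ rate_in(.x)) %>% ungroup() %>%
      mutate(scope = "location", .before = 1),
    tr %>% group_by(scope_id = .data$site_id) %>%
      dplyr::group_modify(~ rate_in(.x)) %>% ungroup() %>%
      mutate(scope = "site", .before = 1)
  )
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Emits the single-row SNP report and the sample metadata CSV read back by
#' [read_snp_report()] and [read_sample_metadata()]; the round trip is
#' lossless and, for a fixed seed, byte-identical.
#'
#' @param dataset a `sim_dataset`
#' @param out_dir writable directory (created if needed)
#' @return Invisibly, named paths `snp` and `meta`.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  g <- dataset$genotypes
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0)
    abort("refusing to write an empty dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snp <- file.path(out_dir, "snp_report.csv")
  meta <- file.path(out_dir, "sample_metadata.csv")
  write_snp_report(g, snp, meta)
  invisible(c(snp = snp, meta = meta))
}
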