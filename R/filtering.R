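#' Filter thresholds for the two-stage SNP quality cascade
#'
#' All boundaries are strict: a locus survives when it sits exactly on a
#' threshold (call rate 0.50 is kept, MAF 0.05 is kept, reproducibility
#' 0.95 is kept, observed heterozygosity 0.80 is kept, |r| = 0.75 is kept).
#'
#' @param min_call_rate loci with call rate strictly below are removed
#'   (default 0.50)
#' @param min_maf minor allele frequency lower bound, strict (default 0.05)
#' @param min_reproducibility reproducibility lower bound, strict
#'   (default 0.95)
#' @param max_hobs observed-heterozygosity ceiling flagging putative
#'   paralogs, strict (default 0.80)
#' @param ld_r_max absolute genotype-correlation ceiling for linkage
#'   pruning, strict (default 0.75)
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_call_rate = 0.50, min_maf = 0.05,
                              min_reproducibility = 0.95, max_hobs = 0.80,
                              ld_r_max = 0.75) {
  vals <- c(min_call_rate, min_maf, min_reproducibility, max_hobs, ld_r_max)
  if (any(vals < 0) || any(vals > 1))
    abort("all thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_reproducibility = min_reproducibility,
                 max_hobs = max_hobs, ld_r_max = ld_r_max),
            class = "filter_thresholds")
}

new_filter_report <- function() {
  structure(list(stages = tibble(stage = character(), n_before = integer(),
                                 n_removed = integer(), n_after = integer()),
                 removed = list()),
            class = "filter_report")
}

log_stage <- function(report, stage, before_ids, kept_ids) {
  removed <- setdiff(before_ids, kept_ids)
  report$stages <- bind_rows(report$stages, tibble(
    stage = stage, n_before = length(before_ids),
    n_removed = length(removed), n_after = length(kept_ids)))
  report$removed[[stage]] <- removed
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' @rdname filter_stage1
#' @export
tidy.filter_report <- function(x, ...) x$stages

#' Stage-1 SNP filtering: tag dedup, monomorphic, call rate
#'
#' Applies the first filter pass in a fixed, logged order: (1) among loci
#' sharing a sequence tag keep only the one with the highest call rate
#' (ties broken by lexicographically smallest locus id), reducing physical
#' linkage; (2) drop monomorphic loci (observed MAF = 0); (3) drop loci
#' with call rate strictly below `min_call_rate`. This pass precedes all
#' analyses; notably, per-cluster F_IS clonality signatures are computed on
#' this panel so that extreme-F_IS loci are retained.
#'
#' @param x a [geno] object
#' @param thresholds a [filter_thresholds()]
#' @return A list with `genotypes` (filtered [geno]) and `report`
#'   (a `filter_report` whose `tidy()` is the attrition ledger).
#' @export
filter_stage1 <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "geno"))
  if (ncol(x$dosage) == 0) abort("no loci to filter")
  rep <- new_filter_report()

  # same-tag dedup: keep highest call rate, tie -> smallest locus_id
  before <- x$loci$locus_id
  if ("tag_id" %in% names(x$loci)) {
    cr <- locus_call_rate(x)
    keep <- x$loci %>%
      mutate(.cr = cr) %>%
      arrange(.data$tag_id, dplyr::desc(.data$.cr), .data$locus_id) %>%
      distinct(.data$tag_id, .keep_all = TRUE) %>%
      pull(.data$locus_id)
    keep <- before[before %in% keep]
  } else {
    keep <- before
  }
  rep <- log_stage(rep, "tag_dedup", before, keep)
  x <- geno_subset(x, loci = keep)

  # monomorphic
  st <- locus_stats(x)
  keep <- st$locus_id[!is.na(st$maf) & st$maf > 0]
  rep <- log_stage(rep, "monomorphic", st$locus_id, keep)
  x <- geno_subset(x, loci = keep)

  # call rate
  cr <- locus_call_rate(x)
  keep <- x$loci$locus_id[cr >= thresholds$min_call_rate]
  rep <- log_stage(rep, "call_rate", x$loci$locus_id, keep)
  if (!length(keep)) abort("stage 1 removed every locus")
  x <- geno_subset(x, loci = keep)
  list(genotypes = x, report = rep)
}

# metadata call rate when present (the platform's), else observed
locus_call_rate <- function(x) {
  if ("call_rate" %in% names(x$loci) && !anyNA(x$loci$call_rate))
    x$loci$call_rate
  else colMeans(!is.na(x$dosage))
}

#' Stage-2 SNP filtering: MAF, reproducibility, paralogs, linkage
#'
#' Applies the second filter pass, again in a fixed, logged order:
#' (1) observed minor allele frequency strictly below `min_maf`;
#' (2) reproducibility strictly below `min_reproducibility`;
#' (3) putative paralogs — observed heterozygosity over the full pooled
#' sample strictly above `max_hobs`; (4) linkage pruning via [ld_prune()].
#'
#' @inheritParams filter_stage1
#' @return As [filter_stage1()].
#' @export
filter_stage2 <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "geno"))
  if (ncol(x$dosage) == 0) abort("no loci to filter")
  rep <- new_filter_report()

  st <- locus_stats(x)
  keep <- st$locus_id[!is.na(st$maf) & st$maf >= thresholds$min_maf]
  rep <- log_stage(rep, "maf", st$locus_id, keep)
  if (!length(keep)) abort("stage 2 removed every locus")
  x <- geno_subset(x, loci = keep)

  if ("reproducibility" %in% names(x$loci)) {
    keep <- x$loci$locus_id[x$loci$reproducibility >= thresholds$min_reproducibility]
  } else {
    keep <- x$loci$locus_id
  }
  rep <- log_stage(rep, "reproducibility", x$loci$locus_id, keep)
  if (!length(keep)) abort("stage 2 removed every locus")
  x <- geno_subset(x, loci = keep)

  hobs <- colMeans(x$dosage == 1L, na.rm = TRUE)
  keep <- x$loci$locus_id[hobs <= thresholds$max_hobs]
  rep <- log_stage(rep, "paralog_hobs", x$loci$locus_id, keep)
  if (!length(keep)) abort("stage 2 removed every locus")
  x <- geno_subset(x, loci = keep)

  before <- x$loci$locus_id
  if (ncol(x$dosage) >= 2) x <- ld_prune(x, r_max = thresholds$ld_r_max)$genotypes
  rep <- log_stage(rep, "ld_prune", before, x$loci$locus_id)
  list(genotypes = x, report = rep)
}

#' Greedy linkage-disequilibrium pruning
#'
#' Computes the Pearson correlation of dosage vectors over
#' pairwise-complete samples for every locus pair and removes one member of
#' each pair with `|r|` strictly above `r_max`. The scan is greedy and
#' deterministic in locus order: pairs are visited in column order, the
#' lower-call-rate member of a still-alive correlated pair is removed, and
#' on equal call rates the later-scanned locus is removed. Pairs sharing
#' fewer than 3 complete samples have undefined correlation; they are kept
#' and a warning reports the count.
#'
#' @param x a [geno] object with at least 2 loci
#' @param r_max strict absolute-correlation ceiling (default 0.75)
#' @return A list with `genotypes` (pruned [geno]) and `removed`
#'   (character vector of removed locus ids).
#' @export
ld_prune <- function(x, r_max = 0.75) {
  stopifnot(inherits(x, "geno"))
  L <- ncol(x$dosage)
  if (L < 2) abort("ld_prune needs at least 2 loci")
  d <- x$dosage
  suppressWarnings(r <- cor(d, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(d))
  hot <- !is.na(r) & abs(r) > r_max
  hot[shared < 3] <- FALSE
  n_undef <- sum(shared < 3 & upper.tri(shared))
  if (n_undef > 0)
    warn(sprintf("%d locus pairs had < 3 shared complete samples; correlation undefined, pair kept",
                 n_undef))
  cr <- locus_call_rate(x)
  alive <- rep(TRUE, L)
  for (i in seq_len(L - 1)) {
    if (!alive[i]) next
    js <- which(hot[i, ] & alive & seq_len(L) > i)
    for (j in js) {
      if (!alive[i]) break
      if (!alive[j]) next
      if (cr[j] < cr[i]) alive[j] <- FALSE
      else if (cr[i] < cr[j]) alive[i] <- FALSE
      else alive[j] <- FALSE
    }
  }
  removed <- x$loci$locus_id[!alive]
  list(genotypes = geno_subset(x, loci = which(alive)), removed = removed)
}

#' Run both filter stages and merge the ledgers
#'
#' @inheritParams filter_stage1
#' @return A list with `genotypes` and a combined `report`; ledger
#'   conservation holds across the whole cascade
#'   (`n_before - sum(n_removed) = n_after`).
#' @export
filter_cascade <- function(x, thresholds = filter_thresholds()) {
  s1 <- filter_stage1(x, thresholds)
  s2 <- filter_stage2(s1$genotypes, thresholds)
  rep <- new_filter_report()
  rep$stages <- bind_rows(s1$report$stages, s2$report$stages)
  rep$removed <- c(s1$report$removed, s2$report$removed)
  list(genotypes = s2$genotypes, report = rep,
       stage1 = s1$genotypes)
}
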