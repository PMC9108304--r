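#' Genotype dosage container
#'
#' A `geno` object is the central data structure of clonefire: an
#' individuals-by-loci matrix of biallelic dosages (counts of the alternate
#' allele: 0, 1, 2, or `NA` for a missing call) together with a tibble of
#' per-sample metadata and a tibble of per-locus metadata. Every analysis
#' stage consumes and/or returns one.
#'
#' @param dosage integer matrix, individuals in rows, loci in columns.
#'   Row names are sample ids, column names locus ids. Values must be
#'   0, 1, 2 or `NA`.
#' @param samples tibble of per-sample metadata with at least `sample_id`;
#'   when field metadata have been attached it also carries `location_id`,
#'   `site_id`, `fire_category` (one of `"burnt"`, `"unburnt"`, `"ranger"`),
#'   `longitude`, `latitude`.
#' @param loci tibble of per-locus metadata with at least `locus_id`;
#'   DArT-style reports add `tag_id` (the 69-bp sequence tag identifier,
#'   shared by loci on one tag), `call_rate` and `reproducibility`,
#'   both fractions in \[0, 1\].
#'
#' @return An object of class `geno`.
#' @export
#' @examples
#' m <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("L1", "L2")))
#' g <- geno(m)
#' dim(g)
geno <- function(dosage,
                 samples = tibble(sample_id = rownames(dosage)),
                 loci = tibble(locus_id = colnames(dosage))) {
  if (!is.matrix(dosage)) abort("`dosage` must be a matrix.")
  storage.mode(dosage) <- "integer"
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    abort(sprintf("dosage values must be 0, 1, 2 or NA; found %s",
                  paste(unique(dosage[bad]), collapse = ", ")))
  }
  if (is.null(rownames(dosage))) rownames(dosage) <- samples$sample_id
  if (is.null(colnames(dosage))) colnames(dosage) <- loci$locus_id
  samples <- as_tibble(samples)
  loci <- as_tibble(loci)
  if (nrow(samples) != nrow(dosage))
    abort("row count of `dosage` must equal nrow(samples)")
  if (nrow(loci) != ncol(dosage))
    abort("column count of `dosage` must equal nrow(loci)")
  if (anyDuplicated(samples$sample_id))
    abort(sprintf("duplicate sample ids: %s",
                  paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                        collapse = ", ")))
  if (anyDuplicated(loci$locus_id))
    abort(sprintf("duplicate locus ids: %s",
                  paste(unique(loci$locus_id[duplicated(loci$locus_id)]),
                        collapse = ", ")))
  if (!identical(rownames(dosage) %||% character(0),
                 as.character(samples$sample_id)) ||
      !identical(colnames(dosage) %||% character(0),
                 as.character(loci$locus_id)))
    abort("dimnames of `dosage` must match sample_id / locus_id")
  structure(list(dosage = dosage, samples = samples, loci = loci),
            class = "geno")
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  cat("sample columns:", paste(names(x$samples), collapse = ", "), "\n")
  cat("locus columns: ", paste(names(x$loci), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a geno object by samples and/or loci
#'
#' @param x a [geno] object
#' @param samples sample ids, logical mask or integer indices (rows)
#' @param loci locus ids, logical mask or integer indices (columns)
#' @return A `geno` restricted to the requested rows/columns.
#' @export
geno_subset <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "geno"))
  ri <- resolve_idx(samples, rownames(x$dosage), "sample")
  ci <- resolve_idx(loci, colnames(x$dosage), "locus")
  geno(x$dosage[ri, ci, drop = FALSE],
       x$samples[ri, , drop = FALSE],
       x$loci[ci, , drop = FALSE])
}

resolve_idx <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    miss <- setdiff(idx, ids)
    if (length(miss))
      abort(sprintf("unknown %s ids: %s", what,
                    paste(head(miss, 5), collapse = ", ")))
    return(match(idx, ids))
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  as.integer(idx)
}

#' Per-locus summary of a geno object
#'
#' Observed call rate, alternate-allele frequency, minor allele frequency
#' and observed heterozygosity, each computed over non-missing calls only.
#'
#' @param x a [geno] object
#' @return A tibble with one row per locus: `locus_id`, `n_typed`,
#'   `call_rate_obs`, `p_alt`, `maf`, `hobs`.
#' @export
locus_stats <- function(x) {
  stopifnot(inherits(x, "geno"))
  d <- x$dosage
  n_typed <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[n_typed == 0] <- NA_real_
  tibble(
    locus_id = x$loci$locus_id,
    n_typed = as.integer(n_typed),
    call_rate_obs = n_typed / nrow(d),
    p_alt = p,
    maf = pmin(p, 1 - p),
    hobs = colMeans(d == 1L, na.rm = TRUE)
  )
}

#' Grouping vector for samples
#'
#' Resolves a grouping specification to a factor over samples. `grouping`
#' may be the name of a column of `x$samples` (e.g. `"site_id"`) or a
#' vector of length `nrow(x)`.
#'
#' @param x a [geno] object
#' @param grouping column name in `x$samples` or a vector of group labels
#' @return A character vector of group labels, one per sample.
#' @export
sample_groups <- function(x, grouping = "site_id") {
  stopifnot(inherits(x, "geno"))
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(x$samples)) {
    g <- x$samples[[grouping]]
  } else {
    g <- grouping
  }
  if (length(g) != nrow(x$dosage))
    abort("grouping must name a sample column or give one label per sample")
  if (anyNA(g)) abort("grouping contains missing labels")
  as.character(g)
}
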