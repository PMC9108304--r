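#' Read a single-row DArT-style SNP report
#'
#' Reads the one-row-per-SNP dosage dialect: a CSV whose leading columns are
#' locus metadata (`locus_id`, `tag_id`, `call_rate`, `reproducibility` by
#' default) and whose remaining columns are one per sample, holding dosage
#' codes `0`, `1`, `2` or `-` (missing). Column names are configurable
#' because real DArT exports vary.
#'
#' @param path CSV file path
#' @param locus_cols named character vector mapping the internal names
#'   `locus_id`, `tag_id`, `call_rate`, `reproducibility` to the column
#'   names used in the file. Only `locus_id` is required to be present.
#' @param missing_code string used for missing calls on disk (default `"-"`)
#' @return A [geno] object without field sample metadata (samples carry only
#'   `sample_id`).
#' @export
read_snp_report <- function(path,
                            locus_cols = c(locus_id = "locus_id",
                                           tag_id = "tag_id",
                                           call_rate = "call_rate",
                                           reproducibility = "reproducibility"),
                            missing_code = "-") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!locus_cols[["locus_id"]] %in% names(raw))
    abort(sprintf("required column '%s' not found in %s",
                  locus_cols[["locus_id"]], path))
  present <- locus_cols[locus_cols %in% names(raw)]
  meta <- raw[, unname(present), drop = FALSE]
  names(meta) <- names(present)
  if (anyDuplicated(meta$locus_id))
    abort(sprintf("duplicate locus ids in %s: %s", path,
                  paste(unique(meta$locus_id[duplicated(meta$locus_id)]),
                        collapse = ", ")))
  for (nm in intersect(c("call_rate", "reproducibility"), names(meta)))
    meta[[nm]] <- as.numeric(meta[[nm]])
  sample_cols <- setdiff(names(raw), unname(present))
  if (!length(sample_cols)) abort(sprintf("no sample columns found in %s", path))
  codes <- as.matrix(raw[, sample_cols, drop = FALSE])
  codes[codes == missing_code] <- NA_character_
  bad <- !is.na(codes) & !(codes %in% c("0", "1", "2"))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "malformed dosage '%s' at locus '%s', sample '%s' in %s",
      codes[bad][1], meta$locus_id[ij[1]], sample_cols[ij[2]], path))
  }
  dosage <- t(matrix(as.integer(codes), nrow = nrow(codes),
                     dimnames = list(meta$locus_id, sample_cols)))
  geno(dosage, samples = tibble(sample_id = sample_cols),
       loci = as_tibble(meta))
}

#' Read sample (field) metadata
#'
#' @param path CSV with columns `sample_id`, `location_id`, `site_id`,
#'   `fire_category`, `longitude`, `latitude`
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    location_id = readr::col_character(),
    site_id = readr::col_character(),
    fire_category = readr::col_character(),
    longitude = readr::col_double(),
    latitude = readr::col_double()
  ), progress = FALSE)
  need <- c("sample_id", "location_id", "site_id", "fire_category",
            "longitude", "latitude")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort(sprintf("metadata file %s lacks columns: %s", path,
                  paste(miss, collapse = ", ")))
  okfc <- meta$fire_category %in% c("burnt", "unburnt", "ranger")
  if (!all(okfc))
    abort(sprintf("unknown fire_category values: %s",
                  paste(unique(meta$fire_category[!okfc]), collapse = ", ")))
  meta
}

#' Attach sample metadata to a genotype object
#'
#' Joins field metadata onto the genotyped samples. Every genotyped sample
#' must appear in the metadata; metadata rows for samples that were not
#' genotyped are dropped with a warning giving the count.
#'
#' @param x a [geno] object
#' @param meta tibble from [read_sample_metadata()]
#' @return A [geno] with populated sample metadata, sample order preserved.
#' @export
attach_sample_metadata <- function(x, meta) {
  stopifnot(inherits(x, "geno"))
  absent <- setdiff(x$samples$sample_id, meta$sample_id)
  if (length(absent))
    abort(sprintf("genotyped samples absent from metadata: %s",
                  paste(absent, collapse = ", ")))
  extra <- setdiff(meta$sample_id, x$samples$sample_id)
  if (length(extra))
    warn(sprintf("%d metadata rows had no genotypes and were dropped",
                 length(extra)))
  joined <- left_join(x$samples["sample_id"], meta, by = "sample_id")
  geno(x$dosage, samples = joined, loci = x$loci)
}

#' Write a geno object as SNP report + sample metadata CSVs
#'
#' Inverse of [read_snp_report()] / [read_sample_metadata()]; the pair of
#' files round-trips losslessly (including the missing mask).
#'
#' @param x a [geno] object with at least one sample and one locus
#' @param snp_path output path for the SNP report CSV
#' @param meta_path output path for the sample metadata CSV, or `NULL` to
#'   skip (e.g. when no field metadata are attached)
#' @param missing_code string written for missing calls (default `"-"`)
#' @return Invisibly, a character vector of the paths written.
#' @export
write_snp_report <- function(x, snp_path, meta_path = NULL, missing_code = "-") {
  stopifnot(inherits(x, "geno"))
  if (nrow(x$dosage) == 0 || ncol(x$dosage) == 0)
    abort("refusing to write an empty genotype set")
  codes <- t(x$dosage)
  mode(codes) <- "character"
  codes[is.na(codes)] <- missing_code
  out <- dplyr::bind_cols(x$loci, as_tibble(codes))
  readr::write_csv(out, snp_path, progress = FALSE)
  written <- snp_path
  if (!is.null(meta_path)) {
    readr::write_csv(x$samples, meta_path, progress = FALSE)
    written <- c(written, meta_path)
  }
  invisible(written)
}

#' Convert a two-row DArT presence/absence report to single-row dosages
#'
#' Some DArT exports score each SNP as two rows (one per allele) of
#' presence/absence calls. This converter collapses consecutive row pairs
#' sharing a locus id into alternate-allele dosages: reference-only -> 0,
#' both -> 1, alternate-only -> 2, neither or missing -> `NA`.
#'
#' @param two_row data frame with a locus id column, an `allele` column
#'   coded `ref`/`alt`, and one 0/1 presence column per sample
#' @param locus_col name of the locus id column (default `"locus_id"`)
#' @return A [geno] object.
#' @export
two_row_to_dosage <- function(two_row, locus_col = "locus_id") {
  two_row <- as_tibble(two_row)
  if (!all(c(locus_col, "allele") %in% names(two_row)))
    abort(sprintf("need columns '%s' and 'allele'", locus_col))
  sample_cols <- setdiff(names(two_row), c(locus_col, "allele"))
  ids <- unique(two_row[[locus_col]])
  ref <- two_row[two_row$allele == "ref", , drop = FALSE]
  alt <- two_row[two_row$allele == "alt", , drop = FALSE]
  if (!identical(sort(ref[[locus_col]]), sort(ids)) ||
      !identical(sort(alt[[locus_col]]), sort(ids)))
    abort("each locus needs exactly one 'ref' and one 'alt' row")
  ref <- ref[match(ids, ref[[locus_col]]), sample_cols, drop = FALSE]
  alt <- alt[match(ids, alt[[locus_col]]), sample_cols, drop = FALSE]
  rmat <- as.matrix(ref); amat <- as.matrix(alt)
  dos <- matrix(NA_integer_, nrow = length(sample_cols), ncol = length(ids),
                dimnames = list(sample_cols, ids))
  both_typed <- !is.na(t(rmat)) & !is.na(t(amat))
  tr <- t(rmat); ta <- t(amat)
  dos[both_typed & tr == 1 & ta == 0] <- 0L
  dos[both_typed & tr == 1 & ta == 1] <- 1L
  dos[both_typed & tr == 0 & ta == 1] <- 2L
  geno(dos)
}

#' Export genotypes as a minimal VCF (v4.2, GT only)
#'
#' Chromosome and position are synthesised from the tag id (one pseudo-contig
#' per tag, position = locus index within the file) purely for
#' interoperability with VCF consumers; they carry no genomic meaning.
#'
#' @param x a [geno] object
#' @param path output file
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno"))
  tag <- if ("tag_id" %in% names(x$loci)) x$loci$tag_id else x$loci$locus_id
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- t(x$dosage)
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  typed <- !is.na(d)
  gt[typed] <- gt_code[as.character(d[typed])]
  body <- cbind(tag, seq_len(nrow(d)), x$loci$locus_id, "A", "T", ".",
                "PASS", ".", "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=clonefire",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
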