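#' SNP table of biallelic loci by samples
#'
#' The raw input of the pipeline: one row per biallelic locus with two allele
#' read counts per sample, as produced by reference-free SNP callers.  Counts
#' are held as a loci x samples x 2 integer array (reference allele first).
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param alleles two-column character matrix (reference, alternate allele).
#' @param counts integer array of dimension `c(n_loci, n_samples, 2)`; the
#'   third dimension holds reference and alternate allele read counts.
#' @param sample_ids character vector of sample identifiers (one metagenome,
#'   i.e. one station x size-fraction combination).
#' @param station_of_sample named character vector mapping each sample id to
#'   its station id.
#'
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(locus_id, alleles, counts, sample_ids, station_of_sample) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) stop_input("locus ids must be unique")
  counts <- unclass(counts)
  if (length(dim(counts)) != 3L || dim(counts)[3] != 2L) {
    stop_input("counts must be a loci x samples x 2 array")
  }
  if (dim(counts)[1] != length(locus_id) || dim(counts)[2] != length(sample_ids)) {
    stop_input("counts dimensions do not match locus/sample ids")
  }
  if (any(counts < 0, na.rm = TRUE)) stop_input("allele counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (!all(sample_ids %in% names(station_of_sample))) {
    stop_input("every sample must map to a station")
  }
  alleles <- as.matrix(alleles)
  dimnames(counts) <- list(locus_id, sample_ids, c("ref", "alt"))
  structure(list(
    locus_id = locus_id,
    alleles = alleles,
    counts = counts,
    sample_ids = as.character(sample_ids),
    station_of_sample = station_of_sample[sample_ids]
  ), class = "snp_table")
}

#' Depth of coverage matrix of a SNP table
#'
#' @param x a [snp_table()].
#' @return loci x samples matrix of total read depth (sum of the two allele
#'   counts), the quantity all coverage-based filters and clustering act on.
#' @export
snp_depth <- function(x) {
  x$counts[, , 1L, drop = FALSE][, , 1L] + x$counts[, , 2L, drop = FALSE][, , 1L]
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("<snp_table> %d loci x %d samples (%d stations)\n",
              length(x$locus_id), length(x$sample_ids),
              length(unique(x$station_of_sample))))
  invisible(x)
}

#' Subset a SNP table by locus
#'
#' @param x a [snp_table()].
#' @param loci integer or character index of loci to keep.
#' @return a new `snp_table` restricted to the requested loci.
#' @export
subset_loci <- function(x, loci) {
  snp_table(x$locus_id[loci], x$alleles[loci, , drop = FALSE],
            x$counts[loci, , , drop = FALSE], x$sample_ids,
            x$station_of_sample)
}

#' Read / write the SNP table TSV dialect
#'
#' Columns: `locus_id`, `allele_ref`, `allele_alt`, then for every sample `s`
#' the pair `<s>_ref_count`, `<s>_alt_count`.
#'
#' @param path file path.
#' @param station_of_sample named character vector sample -> station; when
#'   `NULL`, stations are derived from sample ids of the form
#'   `<station>.<fraction>` (everything before the last dot).
#' @return [read_snp_table()] returns a [snp_table()];
#'   [write_snp_table()] returns `path` invisibly.
#' @export
read_snp_table <- function(path, station_of_sample = NULL) {
  df <- read_tsv(path)
  fixed <- c("locus_id", "allele_ref", "allele_alt")
  if (!all(fixed %in% names(df))) stop_input("not a SNP table TSV: ", path)
  cc <- setdiff(names(df), fixed)
  refs <- grep("_ref_count$", cc, value = TRUE)
  samples <- sub("_ref_count$", "", refs)
  alts <- paste0(samples, "_alt_count")
  if (!all(alts %in% cc)) stop_input("unpaired allele count columns in ", path)
  n <- nrow(df)
  counts <- array(0L, dim = c(n, length(samples), 2L))
  counts[, , 1L] <- as.matrix(df[refs])
  counts[, , 2L] <- as.matrix(df[alts])
  if (is.null(station_of_sample)) {
    station_of_sample <- stats::setNames(sub("\\.[^.]*$", "", samples), samples)
  }
  snp_table(df$locus_id, cbind(df$allele_ref, df$allele_alt), counts,
            samples, station_of_sample)
}

#' @rdname read_snp_table
#' @param x a [snp_table()] to serialize.
#' @export
write_snp_table <- function(x, path) {
  df <- data.frame(locus_id = x$locus_id,
                   allele_ref = x$alleles[, 1],
                   allele_alt = x$alleles[, 2],
                   stringsAsFactors = FALSE)
  for (i in seq_along(x$sample_ids)) {
    s <- x$sample_ids[i]
    df[[paste0(s, "_ref_count")]] <- x$counts[, i, 1L]
    df[[paste0(s, "_alt_count")]] <- x$counts[, i, 2L]
  }
  write_tsv(df, path)
  invisible(path)
}
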