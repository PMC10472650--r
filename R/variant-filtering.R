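#' Pre-clustering locus filter parameters
#'
#' Depth-based locus filters applied to the raw SNP set before clustering:
#' a minimum depth `a` (removes low-coverage calls), a maximum depth `b`
#' (removes repeat-like very high coverage), and a minimum number of samples
#' `c` with non-zero coverage (removes loci seen almost nowhere).
#'
#' @param min_depth minimum allowed depth (`a`, default 5) in samples where
#'   the locus is present; inclusive bound.
#' @param max_depth maximum allowed depth (`b`, default 5000); inclusive.
#' @param min_present minimum number of samples with depth > 0 (`c`,
#'   default 4).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(min_depth = 5, max_depth = 5000, min_present = 4) {
  if (min_depth > max_depth) stop_param("min_depth must be <= max_depth")
  if (min_present < 1) stop_param("min_present must be >= 1")
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_present = min_present), class = "filter_params")
}

#' Filter loci of a SNP table on depth of coverage
#'
#' A locus is retained iff (i) it has at least `min_present` samples with
#' non-zero depth and (ii) in every sample where it is present (depth > 0) the
#' depth lies within `[min_depth, max_depth]`.  The depth bounds deliberately
#' ignore zero-depth samples: a locus genuinely absent from a station must not
#' be discarded by the low-depth rule.
#'
#' @param table a [snp_table()].
#' @param params a [filter_params()].
#' @return list with elements `table` (the filtered [snp_table()]) and
#'   `report` (counts of loci removed per rule; a locus violating several
#'   rules is counted under each).
#' @export
filter_loci <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "snp_table"), inherits(params, "filter_params"))
  n <- length(table$locus_id)
  if (n == 0L) {
    return(list(table = table,
                report = list(n_input = 0L, n_retained = 0L,
                              removed_low_depth = 0L, removed_high_depth = 0L,
                              removed_few_samples = 0L)))
  }
  depth <- snp_depth(table)
  present <- depth > 0
  viol_low <- rowSums(present & depth < params$min_depth) > 0
  viol_high <- rowSums(depth > params$max_depth) > 0
  viol_few <- rowSums(present) < params$min_present
  keep <- !(viol_low | viol_high | viol_few)
  list(
    table = subset_loci(table, which(keep)),
    report = list(
      n_input = n,
      n_retained = sum(keep),
      removed_low_depth = sum(viol_low),
      removed_high_depth = sum(viol_high),
      removed_few_samples = sum(viol_few)
    )
  )
}
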