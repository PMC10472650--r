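#' Minor allele frequency matrix of a metavariant species
#'
#' For each locus, the species-wide minor allele is the allele with the lower
#' total read count over all retained samples (ties broken to the
#' alphabetically smaller allele string); the per-population frequency is its
#' read count over the cell depth.  Cells masked by the final depth filters
#' stay masked (`NA`).  Each retained sample is one population.
#'
#' @param species a `metavariant_species` (see [apply_final_filters()]).
#' @return populations x loci matrix of minor allele frequencies with `NA`
#'   for masked cells; attribute `minor_allele` records the allele chosen per
#'   locus.
#' @export
compute_maf <- function(species) {
  counts <- species$counts
  n_loci <- dim(counts)[1]
  ref <- counts[, , 1L, drop = FALSE][, , 1L, drop = TRUE]
  alt <- counts[, , 2L, drop = FALSE][, , 1L, drop = TRUE]
  ref <- matrix(ref, nrow = n_loci)
  alt <- matrix(alt, nrow = n_loci)
  depth <- ref + alt
  if (any(!is.na(depth) & depth == 0)) {
    stop("zero-depth unmasked cell: mask contract violated")
  }
  tot_ref <- rowSums(ref, na.rm = TRUE)
  tot_alt <- rowSums(alt, na.rm = TRUE)
  minor_is_alt <- tot_alt < tot_ref |
    (tot_alt == tot_ref & species$alleles[, 2] < species$alleles[, 1])
  minor <- ref
  minor[minor_is_alt, ] <- alt[minor_is_alt, , drop = FALSE]
  freq <- t(minor / depth)            # populations x loci
  rownames(freq) <- species$sample_ids
  colnames(freq) <- species$snp_ids
  attr(freq, "minor_allele") <- ifelse(minor_is_alt, species$alleles[, 2],
                                       species$alleles[, 1])
  attr(freq, "depth") <- t(depth)
  freq
}

#' Per-variant F_ST from population allele frequencies
#'
#' `F_ST = sigma^2 / (pbar (1 - pbar))` where `pbar` and `sigma^2` are the
#' mean and the population variance (divide by n) of the minor allele
#' frequency across populations.  Undefined (`NA`) when fewer than two
#' populations are typed or when `pbar` is 0 or 1 (monomorphic).  The
#' divide-by-n convention bounds every defined value in \[0, 1\] and makes
#' the two-population fixation case exactly 1.
#'
#' @param freqs numeric vector of per-population frequencies (`NA` = masked).
#' @return a single F_ST value in \[0, 1\], or `NA` if undefined.
#' @export
fst_per_variant <- function(freqs) {
  f <- freqs[!is.na(freqs)]
  if (length(f) < 2L) return(NA_real_)
  p <- mean(f)
  if (p <= 0 || p >= 1) return(NA_real_)
  s2 <- mean((f - p)^2)
  min(max(s2 / (p * (1 - p)), 0), 1)
}

# vectorized per-variant F_ST over the columns of a populations x loci matrix
fst_variants <- function(m) {
  n <- colSums(!is.na(m))
  p <- colMeans(m, na.rm = TRUE)
  s2 <- colMeans(m * m, na.rm = TRUE) - p^2
  fst <- pmin(pmax(s2 / (p * (1 - p)), 0), 1)
  fst[n < 2L | p <= 0 | p >= 1 | !is.finite(fst)] <- NA_real_
  fst
}

#' Global and pairwise-median F_ST of a species
#'
#' Computes the per-variant global F_ST over all populations jointly (the
#' global median summarizes it), and for every population pair the median of
#' the defined per-variant pairwise F_ST values — the species' measure of
#' genomic differentiation between the two populations.  Pairs with fewer
#' than `min_pair_variants` defined variants are flagged low-confidence.
#'
#' @param species a `metavariant_species`, or a populations x loci minor
#'   allele frequency matrix as returned by [compute_maf()].
#' @param min_pair_variants low-confidence threshold (default 50 variants).
#' @return object of class `fst_result`: `per_variant_global`,
#'   `global_median`, `pairwise_median` (symmetric, zero diagonal),
#'   `pairwise_n`, `low_confidence`, `populations`, `station_of_population`,
#'   `empty` flag.
#' @export
summarize_fst <- function(species, min_pair_variants = 50) {
  if (inherits(species, "metavariant_species")) {
    freq <- compute_maf(species)
    station_of_population <- species$station_of_sample
  } else {
    freq <- species
    station_of_population <- attr(freq, "station_of_population") %||%
      stats::setNames(rownames(freq), rownames(freq))
  }
  pops <- rownames(freq) %||% paste0("P", seq_len(nrow(freq)))
  n_pop <- length(pops)
  if (n_pop < 2L) stop_input("F_ST requires at least two populations")
  per_variant <- fst_variants(freq)
  global_median <- stats::median(per_variant, na.rm = TRUE)
  pw <- matrix(NA_real_, n_pop, n_pop, dimnames = list(pops, pops))
  pn <- matrix(0L, n_pop, n_pop, dimnames = list(pops, pops))
  diag(pw) <- 0
  for (i in seq_len(n_pop - 1L)) {
    for (j in (i + 1L):n_pop) {
      fi <- freq[i, ]
      fj <- freq[j, ]
      ok <- !is.na(fi) & !is.na(fj)
      p <- (fi[ok] + fj[ok]) / 2
      defined <- p > 0 & p < 1
      v <- ((fi[ok] - fj[ok])^2 / 4)[defined] / (p * (1 - p))[defined]
      v <- pmin(pmax(v, 0), 1)
      pn[i, j] <- pn[j, i] <- length(v)
      if (length(v)) pw[i, j] <- pw[j, i] <- stats::median(v)
    }
  }
  low_conf <- pn < min_pair_variants
  diag(low_conf) <- FALSE
  structure(list(
    per_variant_global = per_variant,
    global_median = global_median,
    pairwise_median = pw,
    pairwise_n = pn,
    low_confidence = low_conf,
    populations = pops,
    station_of_population = station_of_population,
    empty = all(is.na(per_variant))
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %d populations, %d variants, global median F_ST = %s\n",
              length(x$populations), length(x$per_variant_global),
              format(x$global_median, digits = 3)))
  invisible(x)
}

# reduce a species' population-level pairwise medians to station pairs
# (mean over population pairs spanning the two stations)
station_pair_fst <- function(fst_result) {
  st <- fst_result$station_of_population[fst_result$populations]
  stations <- sort(unique(st))
  if (length(stations) < 2L) return(NULL)
  pairs <- utils::combn(stations, 2L)
  vals <- apply(pairs, 2L, function(pr) {
    sub <- fst_result$pairwise_median[st == pr[1], st == pr[2], drop = FALSE]
    if (all(is.na(sub))) NA_real_ else mean(sub, na.rm = TRUE)
  })
  data.frame(station_a = pairs[1, ], station_b = pairs[2, ], fst = vals,
             stringsAsFactors = FALSE)
}

#' Aggregate pairwise-median F_ST by oceanic basin
#'
#' Entry (A, B) is the mean, over all species and over all station pairs with
#' one station in basin A and one in basin B (unordered; same-station pairs
#' excluded when A = B), of the species' median pairwise F_ST between the two
#' stations.
#'
#' @param fst_results list of [summarize_fst()] results (one per species).
#' @param basin_of_station named character vector station -> basin.
#' @return symmetric basins x basins matrix of mean F_ST (`NA` where no
#'   station pair is observed).
#' @export
aggregate_basins <- function(fst_results, basin_of_station) {
  basins <- sort(unique(basin_of_station))
  acc <- matrix(0, length(basins), length(basins),
                dimnames = list(basins, basins))
  cnt <- matrix(0L, length(basins), length(basins),
                dimnames = list(basins, basins))
  for (res in fst_results) {
    sp <- station_pair_fst(res)
    if (is.null(sp)) next
    for (r in seq_len(nrow(sp))) {
      if (is.na(sp$fst[r])) next
      ba <- basin_of_station[[sp$station_a[r]]]
      bb <- basin_of_station[[sp$station_b[r]]]
      acc[ba, bb] <- acc[ba, bb] + sp$fst[r]
      cnt[ba, bb] <- cnt[ba, bb] + 1L
      if (ba != bb) {
        acc[bb, ba] <- acc[bb, ba] + sp$fst[r]
        cnt[bb, ba] <- cnt[bb, ba] + 1L
      }
    }
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Compare per-species F_ST medians between groups
#'
#' Kruskal-Wallis test across groups; iff significant (p < 0.05), pairwise
#' two-sided Wilcoxon rank-sum tests between all group pairs (unadjusted
#' p-values reported per pair).
#'
#' @param values numeric vector (e.g. per-species median pairwise F_ST).
#' @param groups factor or character grouping (size fraction, taxonomic
#'   group, basin membership, ...).
#' @param alpha significance gate for the pairwise stage (default 0.05).
#' @return object of class `group_comparison`: either `untestable = TRUE`
#'   with a reason, or the Kruskal-Wallis statistic/p and (when run) the
#'   pairwise p-value matrix.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L || any(sizes < 2L)) {
    return(structure(list(untestable = TRUE,
                          reason = "need >= 2 groups with >= 2 values each"),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(values, groups)
  pairwise <- NULL
  if (kw$p.value < alpha) {
    pairwise <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups,
                                  p.adjust.method = "none")$p.value)
  }
  structure(list(untestable = FALSE,
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value,
                 pairwise_p = pairwise),
            class = "group_comparison")
}
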