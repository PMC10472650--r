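make_species <- function(ref, alt, sample_ids = NULL, stations = NULL) {
  # ref/alt: loci x samples matrices of allele counts
  n <- nrow(ref)
  s <- ncol(ref)
  sample_ids <- sample_ids %||% paste0("P", seq_len(s))
  stations <- stations %||% setNames(sample_ids, sample_ids)
  counts <- array(NA_integer_, c(n, s, 2))
  counts[, , 1] <- ref
  counts[, , 2] <- alt
  structure(list(species_id = "SP1", snp_ids = paste0("L", seq_len(n)),
                 coverage = ref + alt, counts = counts,
                 sample_ids = sample_ids,
                 station_of_sample = stations,
                 alleles = cbind(rep("A", n), rep("C", n)),
                 score = 1),
            class = "metavariant_species")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("minor allele frequencies are computed against the global minor allele", {
  # one locus: alt is globally minor (3 + 1 < 7 + 9)
  sp <- make_species(ref = rbind(c(7, 9)), alt = rbind(c(3, 1)))
  freq <- compute_maf(sp)
  expect_equal(unname(freq[, 1]), c(0.3, 0.1))
  # the two allele frequencies sum to one per cell
  expect_equal(unname(1 - freq[, 1]), c(0.7, 0.9))

  # tie in totals: alphabetically smaller allele ("A" = ref) chosen
  sp2 <- make_species(ref = rbind(c(5, 5)), alt = rbind(c(5, 5)))
  expect_identical(attr(compute_maf(sp2), "minor_allele"), "A")

  # masked cells stay masked; an unmasked zero-depth cell violates the contract
  spna <- make_species(ref = rbind(c(7, NA)), alt = rbind(c(3, NA)))
  expect_true(is.na(compute_maf(spna)[2, 1]))
  sp0 <- make_species(ref = rbind(c(7, 0)), alt = rbind(c(3, 0)))
  expect_error(compute_maf(sp0), "mask contract")
})

test_that("per-variant F_ST matches the direct formula and stays in [0, 1]", {
  expect_equal(fst_per_variant(c(0, 1)), 1)          # fixation between 2 pops
  expect_equal(fst_per_variant(c(0.3, 0.3, 0.3)), 0)
  # sigma2 = mean((f - 0.2)^2) = 0.02/3; pbar(1-pbar) = 0.16
  expect_equal(fst_per_variant(c(0.1, 0.2, 0.3)), (0.02 / 3) / 0.16,
               tolerance = 1e-12)
  expect_equal(fst_per_variant(c(0.1, 0.2, 0.3)), 0.041667, tolerance = 1e-4)
  # undefined cases
  expect_true(is.na(fst_per_variant(c(0.5))))
  expect_true(is.na(fst_per_variant(c(0, 0, 0))))
  expect_true(is.na(fst_per_variant(c(1, 1))))

  set.seed(123)
  for (rep in 1:100) {
    f <- runif(sample(2:10, 1))
    v <- fst_per_variant(f)
    if (!is.na(v)) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
  # vectorized fuzzing against the scalar implementation
  m <- matrix(runif(10000 * 6), 6, 10000)
  vv <- mvspop:::fst_variants(m)
  expect_true(all(vv >= 0 & vv <= 1, na.rm = TRUE))
  idx <- sample(10000, 50)
  expect_equal(vv[idx], apply(m[, idx], 2, fst_per_variant),
               tolerance = 1e-12)
})

test_that("summaries collapse correctly for two populations and degenerate data", {
  set.seed(2)
  ref <- matrix(rbinom(200, 30, 0.7), 100, 2)
  alt <- 30 - ref
  res <- summarize_fst(make_species(ref, alt))
  expect_equal(res$global_median, res$pairwise_median[1, 2])
  expect_true(isSymmetric(res$pairwise_median))
  expect_equal(diag(res$pairwise_median), setNames(c(0, 0), res$populations))

  # monomorphic everywhere -> all variants excluded -> flagged empty
  mono <- make_species(matrix(30L, 60, 3), matrix(0L, 60, 3))
  expect_true(summarize_fst(mono)$empty)

  expect_error(summarize_fst(make_species(rbind(c(10)), rbind(c(5)))),
               class = "mvspop_input_error")
})

test_that("population relabelling permutes the pairwise matrix consistently", {
  set.seed(3)
  ref <- matrix(rbinom(400, 40, runif(400, 0.3, 0.9)), 100, 4)
  alt <- 40 - ref
  sp <- make_species(ref, alt)
  res <- summarize_fst(sp)
  perm <- c(3, 1, 4, 2)
  sp2 <- make_species(ref[, perm], alt[, perm],
                      sample_ids = sp$sample_ids[perm])
  res2 <- summarize_fst(sp2)
  expect_equal(res2$global_median, res$global_median)
  expect_equal(res2$pairwise_median[sp$sample_ids, sp$sample_ids],
               res$pairwise_median)
})

test_that("median F_ST responds monotonically to the planted divergence", {
  # sampled-count estimate agrees with an independent direct-formula oracle
  set.seed(11)
  fr <- simulate_allele_frequencies(runif(2000, 0.2, 0.8), 5, 0.2, seed = 21)
  cnt <- matrix(rbinom(10000, 100, t(fr)), 2000, 5)
  freq <- t(cnt / 100)
  med_pkg <- median(mvspop:::fst_variants(freq), na.rm = TRUE)
  oracle <- apply(freq, 2, function(f) {
    p <- mean(f)
    if (p <= 0 || p >= 1) return(NA_real_)
    mean((f - p)^2) / (p * (1 - p))
  })
  expect_equal(med_pkg, median(oracle, na.rm = TRUE), tolerance = 1e-12)

  correct <- 0L
  for (rep in 1:20) {
    meds <- vapply(c(0.05, 0.1, 0.2, 0.4), function(F) {
      fr <- simulate_allele_frequencies(runif(500, 0.2, 0.8), 5, F,
                                        seed = 1000 + rep * 7 + round(F * 100))
      cnt <- matrix(rbinom(2500, 100, t(fr)), 500, 5)
      median(mvspop:::fst_variants(t(cnt / 100)), na.rm = TRUE)
    }, numeric(1))
    if (!is.unsorted(meds)) correct <- correct + 1L
  }
  expect_gte(correct, 18L)
})

test_that("basin aggregation averages station-pair medians", {
  # single species, two basins of one station each, pairwise median 0.4
  ref <- matrix(rbinom(200, 30, 0.7), 100, 2)
  sp <- make_species(ref, 30 - ref, sample_ids = c("A1", "B1"),
                     stations = c(A1 = "STA", B1 = "STB"))
  res <- summarize_fst(sp)
  res$pairwise_median[1, 2] <- res$pairwise_median[2, 1] <- 0.4
  agg <- aggregate_basins(list(res), c(STA = "MED", STB = "NAO"))
  expect_equal(agg["MED", "NAO"], 0.4)
  expect_true(is.na(agg["MED", "MED"]))

  # 3 stations, 2 species toy vs brute-force mean
  make_res <- function(vals, stations) {
    pw <- matrix(0, 3, 3, dimnames = list(names(stations), names(stations)))
    pw[upper.tri(pw)] <- vals
    pw <- pw + t(pw)
    structure(list(pairwise_median = pw, populations = names(stations),
                   station_of_population = stations),
              class = "fst_result")
  }
  st <- c(P1 = "S1", P2 = "S2", P3 = "S3")
  basin <- c(S1 = "MED", S2 = "MED", S3 = "NAO")
  r1 <- make_res(c(0.1, 0.2, 0.3), st)   # pairs (1,2)=0.1 (1,3)=0.2 (2,3)=0.3
  r2 <- make_res(c(0.5, 0.6, 0.7), st)
  agg <- aggregate_basins(list(r1, r2), basin)
  expect_equal(agg["MED", "MED"], mean(c(0.1, 0.5)))
  expect_equal(agg["MED", "NAO"], mean(c(0.2, 0.3, 0.6, 0.7)))
  expect_equal(agg["MED", "NAO"], agg["NAO", "MED"])
})

test_that("group comparisons gate the pairwise stage on the omnibus test", {
  set.seed(4)
  shifted <- c(rnorm(20, 0), rnorm(20, 10))   # 10 SD shift
  g <- rep(c("a", "b"), each = 20)
  res <- compare_groups(shifted, g)
  expect_false(res$untestable)
  expect_lt(res$p_value, 0.001)
  expect_false(is.null(res$pairwise_p))

  expect_true(compare_groups(rnorm(5), rep("a", 5))$untestable)
  expect_true(compare_groups(c(1, 2, 3), c("a", "a", "b"))$untestable)
})
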