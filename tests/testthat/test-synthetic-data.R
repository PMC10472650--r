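test_that("Balding-Nichols frequencies have the planted mean and variance", {
  # Beta(p(1-F)/F, (1-p)(1-F)/F) has variance p(1-p)F = 0.05 at p=0.5, F=0.2
  f <- simulate_allele_frequencies(rep(0.5, 20000), 20, 0.2, seed = 1)
  expect_equal(dim(f), c(20, 20000))
  per_locus_var <- apply(f, 2, var)
  expect_equal(mean(per_locus_var), 0.05, tolerance = 0.02)
  expect_equal(mean(f), 0.5, tolerance = 0.01)

  # F -> 0 limit: all population frequencies collapse onto the ancestral p
  f0 <- simulate_allele_frequencies(rep(0.3, 500), 10, 1e-4, seed = 2)
  expect_lt(max(abs(f0 - 0.3)), 0.05)

  expect_error(simulate_allele_frequencies(0.5, 5, 1.2),
               class = "mvspop_parameter_error")
  expect_error(simulate_allele_frequencies(c(0, 0.5), 5, 0.2),
               class = "mvspop_parameter_error")
})

test_that("generators are byte-identical under a fixed seed", {
  anc <- runif(50, .2, .8)
  expect_identical(simulate_allele_frequencies(anc, 4, .3, seed = 9),
                   simulate_allele_frequencies(anc, 4, .3, seed = 9))
  ab <- matrix(c(10, 0, 5, 20), 2)
  expect_identical(simulate_coverage(ab, 30, 5, seed = 9),
                   simulate_coverage(ab, 30, 5, seed = 9))
  oc <- toy_ocean()
  expect_identical(simulate_drifters(oc, 20, 30, 1, seed = 9),
                   simulate_drifters(oc, 20, 30, 1, seed = 9))
  st <- data.frame(station_id = c("a", "b"), lon = c(1, 2), lat = c(3, 4))
  expect_identical(simulate_environment(st, seed = 9),
                   simulate_environment(st, seed = 9))
  d1 <- simulate_dataset(simulation_config(n_taxa = 2, loci_per_taxon = 40,
                                           seed = 9), n_drifters = 10,
                         duration_days = 10)
  d2 <- simulate_dataset(simulation_config(n_taxa = 2, loci_per_taxon = 40,
                                           seed = 9), n_drifters = 10,
                         duration_days = 10)
  expect_identical(d1$snp_table$counts, d2$snp_table$counts)
  expect_identical(d1$trajectories, d2$trajectories)
})

test_that("negative-binomial coverage has the requested moments and covariation", {
  ab0 <- rbind(t1 = c(30, 30, 0, 0), t2 = c(0, 0, 30, 30))
  dep <- simulate_coverage(ab0, c(10000, 100), 50, seed = 3)
  t1 <- attr(dep, "taxon_of_locus") == 1L
  # absent sample -> all-zero depth for that taxon
  expect_true(all(dep[t1, 3:4] == 0))
  # NB mean within 5% at 1e4 loci with large dispersion
  expect_equal(mean(dep[t1, 1]), 30, tolerance = 0.05)
  expect_error(simulate_coverage(ab0, 10, -1), class = "mvspop_parameter_error")

  # orthogonal abundance profiles (zero profile correlation) -> near-zero
  # mean cross-taxon locus-depth correlation, while within-taxon loci covary
  ab <- rbind(t1 = 30 + 15 * rep(c(1, 1, -1, -1), 3),
              t2 = 30 + 15 * rep(c(1, -1, 1, -1), 3))
  dep <- simulate_coverage(ab, c(300, 300), 5, seed = 4)
  t1 <- attr(dep, "taxon_of_locus") == 1L
  set.seed(5)
  cross <- replicate(300, cor(dep[sample(which(t1), 1), ],
                              dep[sample(which(!t1), 1), ]))
  within <- replicate(300, {
    idx <- sample(which(t1), 2)
    cor(dep[idx[1], ], dep[idx[2], ])
  })
  expect_lt(abs(mean(cross)), 0.1)
  expect_gt(mean(within), 0.3)
})

test_that("read counts are binomial in the population frequency and conserve depth", {
  freqs <- matrix(c(0, 0.5), 2, 200, dimnames = list(c("P1", "P2"), NULL))
  depths <- matrix(1000L, 200, 2, dimnames = list(NULL, c("s1", "s2")))
  som <- c(s1 = "P1", s2 = "P2")
  tab <- simulate_read_counts(freqs, depths, som, seed = 4)
  minor <- tab$counts[, , 2]
  expect_true(all(minor[, 1] == 0))                       # freq 0 -> count 0
  expect_equal(mean(minor[, 2]) / 1000, 0.5, tolerance = 0.05)
  expect_true(all(tab$counts[, , 1] + tab$counts[, , 2] == 1000))

  d <- planted_dataset()
  dep <- snp_depth(d$snp_table)
  expect_true(all(d$snp_table$counts[, , 1] + d$snp_table$counts[, , 2] == dep))
})

test_that("planted truth is recoverable: naive F_ST on true frequencies matches the target", {
  f <- simulate_allele_frequencies(runif(10000, 0.2, 0.8), 20, 0.2, seed = 5)
  per_variant <- apply(f, 2, fst_per_variant)
  expect_equal(mean(per_variant, na.rm = TRUE), 0.2, tolerance = 0.1)
})

test_that("drifters follow the prescribed currents and stay in the domain", {
  still <- toy_ocean("uniform-zonal", u0 = 0, diffusion = 0)
  tr <- simulate_drifters(still, 10, 50, 1, seed = 6)
  expect_true(all(tapply(tr$lon, tr$id, function(x) diff(range(x))) == 0))
  expect_true(all(tapply(tr$lat, tr$id, function(x) diff(range(x))) == 0))

  east <- toy_ocean("uniform-zonal", lon_range = c(0, 100), u0 = 0.1,
                    diffusion = 0)
  tr <- simulate_drifters(east, 50, 100, 1, seed = 6)
  net <- tapply(tr$lon, tr$id, function(x) x[length(x)] - x[1])
  start <- tapply(tr$lon, tr$id, `[`, 1)
  away <- start < 85   # drifters that never touch the reflecting boundary
  expect_true(all(abs(net[away] - 10) < 1e-9))

  gyre <- toy_ocean("double-gyre", diffusion = 0.01)
  tr <- simulate_drifters(gyre, 50, 200, 1, seed = 6)
  expect_true(all(tr$lon >= gyre$lon_range[1] & tr$lon <= gyre$lon_range[2]))
  expect_true(all(tr$lat >= gyre$lat_range[1] & tr$lat <= gyre$lat_range[2]))
})

test_that("environmental gradients are smooth, monotone and seed-stable", {
  st <- data.frame(station_id = paste0("s", 1:8), lon = 1:8,
                   lat = seq(10, 45, length.out = 8))
  spec <- list(temperature = list(base = 30, lon_slope = 0, lat_slope = -0.5,
                                  noise_sd = 0))
  env <- simulate_environment(st, spec, seed = 1)
  expect_true(all(diff(env$temperature[order(abs(st$lat))]) < 0))
  # amplitude zero -> identical values everywhere
  flat <- simulate_environment(st, list(x = list(base = 2, lon_slope = 0,
                                                 lat_slope = 0, noise_sd = 0)))
  expect_true(all(flat$x == 2))
})

test_that("ground-truth labels live beside the inputs, not inside them", {
  dir <- withr::local_tempdir()
  d <- simulate_dataset(simulation_config(n_taxa = 2, loci_per_taxon = 30,
                                          seed = 11),
                        n_drifters = 5, duration_days = 10, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("snp.tsv", "stations.tsv",
                                               "environment.tsv",
                                               "trajectories.tsv",
                                               "truth.json")))))
  snp_cols <- names(read.delim(file.path(dir, "snp.tsv"), nrows = 1))
  expect_false(any(grepl("taxon", snp_cols)))
  rt <- read_snp_table(file.path(dir, "snp.tsv"))
  expect_identical(rt$counts, d$snp_table$counts)
  expect_identical(rt$station_of_sample, d$snp_table$station_of_sample)
})
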