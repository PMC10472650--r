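make_env <- function(stations, temperature = NULL) {
  n <- length(stations)
  data.frame(station_id = stations,
             temperature = temperature %||% seq(10, 20, length.out = n),
             salinity = seq(34, 36, length.out = n),
             nitrate = seq(1, 3, length.out = n),
             phosphate = seq(0.1, 0.3, length.out = n),
             silicate = seq(2, 5, length.out = n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_travel <- function(stations, seed = 1) {
  set.seed(seed)
  n <- length(stations)
  m <- matrix(0, n, n, dimnames = list(stations, stations))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 10, 400)
  m + t(m)
}

test_that("distance predictors are one-dimensional Euclidean and standardized", {
  st <- paste0("S", 1:5)
  env <- make_env(st, temperature = c(10, 14, 11, 12, 13))
  tt <- make_travel(st)
  pred <- build_predictors(env, tt, st)
  expect_equal(nrow(pred$Z), 10)
  # |10 - 14| = 4 before scaling for the (S1, S2) pair
  expect_equal(unname(pred$raw[1, "temperature"]), 4)
  # each standardized column has sample variance 1
  expect_equal(unname(apply(pred$Z, 2, var)), rep(1, ncol(pred$Z)))
  expect_equal(unname(colMeans(pred$Z)), rep(0, ncol(pred$Z)),
               tolerance = 1e-12)

  # constant salinity -> column dropped and recorded
  env2 <- make_env(st)
  env2$salinity <- 35
  pred2 <- build_predictors(env2, tt, st)
  expect_identical(pred2$dropped, "salinity")
  expect_false("salinity" %in% colnames(pred2$Z))

  # missing travel time -> pair dropped
  tt3 <- tt
  tt3["S1", "S2"] <- tt3["S2", "S1"] <- NA
  pred3 <- build_predictors(env, tt3, st)
  expect_equal(nrow(pred3$Z), 9)
  expect_equal(pred3$n_dropped_pairs, 1)
})

test_that("variance components handle degenerate and exact-signal cases", {
  set.seed(10)
  Z <- scale(matrix(rnorm(28 * 3), 28, 3))
  colnames(Z) <- c("lagrangian", "temperature", "salinity")

  # constant response: everything zero, residual zero, mu = constant
  fit <- fit_variance_components(rep(0.37, 28), Z)
  expect_true(all(fit$sigma2 == 0))
  expect_equal(fit$residual, 0)
  expect_equal(fit$mu, 0.37)
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-6)

  # y an exact multiple of one column: that predictor takes everything
  fit2 <- fit_variance_components(2.5 * Z[, 2], Z)
  expect_gt(fit2$proportions[["temperature"]], 0.99)
  expect_lt(fit2$proportions[["residual"]], 0.01)
  expect_equal(sum(fit2$proportions), 1, tolerance = 1e-6)

  # too few pairs for the predictor count -> untestable flag, not an error
  fit3 <- fit_variance_components(rnorm(4), Z[1:4, ])
  expect_true(fit3$untestable)
})

test_that("the REML objective is monotone and components stay non-negative", {
  set.seed(20)
  for (rep in 1:5) {
    Z <- scale(matrix(rnorm(20 * 4), 20, 4))
    y <- 0.2 + 0.1 * Z[, 1] + rnorm(20, 0, 0.05)
    fit <- fit_variance_components(y, Z)
    expect_true(all(fit$sigma2 >= 0))
    expect_gte(fit$residual, 0)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
    expect_equal(sum(fit$proportions), 1, tolerance = 1e-6)
  }
})

test_that("REML matches a dense grid-search oracle on two-predictor toys", {
  set.seed(30)
  for (rep in 1:3) {
    n <- 15
    Z <- scale(matrix(rnorm(n * 2), n, 2))
    y <- 0.3 + 0.2 * Z[, 1] + 0.1 * Z[, 2] + rnorm(n, 0, 0.1)
    fit <- fit_variance_components(y, Z)
    grid <- seq(0, 0.15, length.out = 16)
    best <- -Inf
    for (a in grid) for (b in grid) for (e in grid[-1]) {
      ll <- ref_restricted_loglik(y, Z, c(a, b), e)
      if (ll > best) best <- ll
    }
    # the fitted solution is at least as good as the best grid point
    ll_fit <- ref_restricted_loglik(y, Z, unname(fit$sigma2), fit$residual)
    expect_gte(ll_fit, best - 0.05)
  }
})

test_that("a planted driver is recovered as the dominant component", {
  set.seed(40)
  hits <- 0L
  for (rep in 1:20) {
    Z <- scale(matrix(rnorm(28 * 6), 28, 6))
    colnames(Z) <- mvspop:::predictor_names()
    y <- 0.3 + 0.09 * Z[, "salinity"] + rnorm(28, 0, 0.03)  # 9:1 variance
    fit <- fit_variance_components(y, Z)
    props <- fit$proportions[mvspop:::predictor_names()]
    if (names(which.max(props)) == "salinity") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("per-taxon partitioning is permutation invariant and row-normalized", {
  set.seed(50)
  st <- paste0("S", 1:6)
  env <- make_env(st)
  tt <- make_travel(st)
  pw <- matrix(0, 6, 6, dimnames = list(st, st))
  pw[upper.tri(pw)] <- runif(15, 0.05, 0.6)
  pw <- pw + t(pw)
  res <- structure(list(pairwise_median = pw, populations = st,
                        station_of_population = setNames(st, st)),
                   class = "fst_result")
  part <- partition_all_taxa(list(T1 = res), env, tt)
  expect_equal(unname(rowSums(part$proportions)), 1, tolerance = 1e-6)
  expect_true(all(part$proportions >= 0))

  # permute the station order consistently everywhere: identical proportions
  perm <- c(4, 2, 6, 1, 3, 5)
  res2 <- structure(list(pairwise_median = pw[perm, perm],
                         populations = st[perm],
                         station_of_population = setNames(st[perm], st[perm])),
                    class = "fst_result")
  part2 <- partition_all_taxa(list(T1 = res2), env, tt)
  expect_equal(part2$proportions, part$proportions, tolerance = 1e-6)

  # taxa below the station minimum are excluded with a reason
  small <- structure(list(pairwise_median = pw[1:3, 1:3],
                          populations = st[1:3],
                          station_of_population = setNames(st[1:3], st[1:3])),
                     class = "fst_result")
  part3 <- partition_all_taxa(list(T2 = small), env, tt)
  expect_identical(names(part3$excluded), "T2")
})
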