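# shared fixture: uniform eastward channel with 1000 drifters
channel_fixture <- function() {
  fixture("channel", function() {
    ocean <- toy_ocean("uniform-zonal", lon_range = c(0, 20),
                       lat_range = c(30, 40), u0 = 0.2, diffusion = 0.02)
    trajectories <- simulate_drifters(ocean, 1000, 180, 1, seed = 31)
    stations <- data.frame(station_id = paste0("S", 1:5),
                           lon = c(3, 6.5, 10, 13.5, 17), lat = 35)
    matrix <- travel_time_matrix(trajectories, stations, n_rotations = 24,
                                 lag_days = 5, cell_deg = 1)
    list(ocean = ocean, trajectories = trajectories, stations = stations,
         matrix = matrix)
  })
}

test_that("trajectory discretization counts the expected transitions", {
  grid <- lagrangian_grid(1, 0, c(0, 0))
  # one drifter advancing exactly one cell east per lag
  east <- data.frame(id = "d1", time_days = seq(0, 50, 5),
                     lon = seq(0.5, 10.5, 1), lat = 0.5, drogued = 1)
  mod <- discretize_trajectories(east, grid, lag_days = 5)
  moves <- mod$edges[mod$edges$from != mod$edges$to, ]
  expect_true(all(vapply(strsplit(moves$to, "_"), function(p)
    as.integer(p[1]), integer(1)) -
    vapply(strsplit(moves$from, "_"), function(p)
      as.integer(p[1]), integer(1)) == 1L))
  expect_equal(moves$mean_time, rep(5, nrow(moves)))

  # stationary drifter -> only self-transitions
  still <- data.frame(id = "d2", time_days = seq(0, 50, 5), lon = 0.5,
                      lat = 0.5, drogued = 0)
  mod2 <- discretize_trajectories(still, grid, lag_days = 5)
  expect_true(all(mod2$edges$from == mod2$edges$to))

  # outgoing probabilities (self included) sum to one per cell
  ch <- channel_fixture()
  mod3 <- discretize_trajectories(ch$trajectories, grid, lag_days = 5)
  sums <- tapply(mod3$edges$prob, mod3$edges$from, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  # under a weak-diffusion eastward current, eastward transitions dominate
  moves <- mod3$edges[mod3$edges$from != mod3$edges$to, ]
  dx <- vapply(strsplit(moves$to, "_"), function(p) as.integer(p[1]),
               integer(1)) -
    vapply(strsplit(moves$from, "_"), function(p) as.integer(p[1]),
           integer(1))
  east_count <- sum(moves$count[dx > 0])
  west_count <- sum(moves$count[dx < 0])
  expect_gt(east_count, 19 * west_count)
})

test_that("most likely path time is additive and probability-weighted", {
  grid <- lagrangian_grid(1, 0, c(0, 0))
  chain <- data.frame(id = "d1", time_days = seq(0, 100, 5),
                      lon = seq(0.5, 20.5, 1), lat = 0.5, drogued = 1)
  mod <- discretize_trajectories(chain, grid, lag_days = 5)
  expect_equal(most_likely_path_time(mod, "0_0", "2_0"), 10)
  expect_equal(most_likely_path_time(mod, "0_0", "0_0"), 0)
  expect_true(is.na(most_likely_path_time(mod, "2_0", "0_0")))

  # high-probability long route beats low-probability short route
  mk <- function(id, lons, t0 = 0) {
    data.frame(id = id, time_days = seq(t0, by = 5, length.out = length(lons)),
               lon = lons, lat = 0.5, drogued = 1)
  }
  long_route <- do.call(rbind, lapply(1:9, function(i)
    mk(paste0("L", i), c(0.5, 0.5 + 10, 0.5 + 20, 0.5 + 30))))   # 3 hops of 5 d
  short_route <- mk("S1", c(0.5, 15.5, 30.5))                    # 2 hops of 5 d
  mod2 <- discretize_trajectories(rbind(long_route, short_route), grid, 5)
  # origin cell 0_0 -> dest 30_0: most probable route is the 15-day one
  expect_equal(most_likely_path_time(mod2, "0_0", "30_0"), 15)
})

test_that("travel times are calibrated against the channel crossing time", {
  ch <- channel_fixture()
  m <- ch$matrix
  expect_true(all(diag(m) == 0))
  expect_true(all(m[!is.na(m)] >= 0))
  # downstream calibration: time within 25% of L / v for every aligned pair
  v <- ch$ocean$u0
  for (i in 1:4) {
    for (j in (i + 1):5) {
      L <- ch$stations$lon[j] - ch$stations$lon[i]
      expect_lt(abs(m[i, j] - L / v) / (L / v), 0.25)
    }
  }
})

test_that("a uniform current makes downstream travel faster than upstream", {
  ch <- channel_fixture()
  m <- ch$matrix
  # unreachable upstream directions are slower than any defined time (the
  # min-symmetrization convention: missing = +Inf)
  up <- m[lower.tri(m)]
  down <- t(m)[lower.tri(m)]
  up[is.na(up)] <- Inf
  wins <- sum(down < up)
  n <- length(up)
  expect_lt(binom.test(wins, n, alternative = "greater")$p.value, 0.01)
})

test_that("basin penalties and min-symmetrization follow the stated rules", {
  m <- matrix(c(0, 200, 150,
                200, 0, 120,
                90, 80, 0), 3, byrow = TRUE,
              dimnames = list(c("M1", "N1", "A1"), c("M1", "N1", "A1")))
  basins <- c(M1 = "MED", N1 = "NAO", A1 = "SAO")
  adj <- apply_basin_adjustments(m, basins)
  expect_equal(adj["M1", "N1"], 200 + 36500)   # out of the Mediterranean
  expect_equal(adj["N1", "M1"], 200 + 365)     # into the Mediterranean
  expect_equal(adj["N1", "A1"], 120)           # untouched elsewhere
  expect_equal(adj["A1", "N1"], 80)

  sym <- min_symmetrize(adj)
  expect_true(isSymmetric(sym))
  # MED pairs resolve to the inbound + 1 year value
  expect_equal(sym["M1", "N1"], 200 + 365)
  expect_equal(sym["M1", "A1"], 90 + 365)
  # idempotence and the simple min rule
  expect_equal(min_symmetrize(sym), sym)
  m2 <- matrix(c(0, 3, 7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(min_symmetrize(m2)["a", "b"], 3)
  expect_equal(min_symmetrize(m2)["b", "a"], 3)
  # missing handling: one-sided NA takes the defined direction, two-sided stays
  m3 <- matrix(c(0, NA, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(min_symmetrize(m3)["a", "b"], 5)
  m4 <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(min_symmetrize(m4)["a", "b"]))
})

test_that("per-rotation estimates stabilize with more drifters", {
  ocean <- toy_ocean("uniform-zonal", u0 = 0.2, diffusion = 0.02)
  per_rotation <- function(n_drifters) {
    tr <- simulate_drifters(ocean, n_drifters, 120, 1, seed = 77)
    center <- c(mean(range(tr$lon)), mean(range(tr$lat)))
    vapply(90 * (0:7) / 8, function(ang) {
      grid <- lagrangian_grid(1, ang, center)
      mod <- discretize_trajectories(tr, grid, lag_days = 5)
      cells <- mvspop:::grid_cell(grid, c(5, 15), c(35, 35))
      most_likely_path_time(mod, cells[1], cells[2])
    }, numeric(1))
  }
  small <- per_rotation(100)
  large <- per_rotation(1000)
  expect_gt(var(small, na.rm = TRUE), var(large, na.rm = TRUE))
})
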