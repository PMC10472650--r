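#' Square grid specification for drifter discretization
#'
#' Cells are squares of `cell_deg` degrees in coordinates rotated by `angle`
#' degrees about `center`.  Rotating the grid (rather than the data) lets the
#' travel-time estimator average out grid artefacts.
#'
#' @param cell_deg cell size in degrees (default 1).
#' @param angle rotation angle in degrees.
#' @param center length-2 numeric, rotation center (lon, lat).
#' @return object of class `lagrangian_grid`.
#' @export
lagrangian_grid <- function(cell_deg = 1, angle = 0, center = c(0, 0)) {
  if (cell_deg <= 0) stop_param("cell_deg must be positive")
  structure(list(cell_deg = cell_deg, angle = angle, center = center),
            class = "lagrangian_grid")
}

# cell key ("i_j") of positions under a grid
grid_cell <- function(grid, lon, lat) {
  th <- grid$angle * pi / 180
  dx <- lon - grid$center[1]
  dy <- lat - grid$center[2]
  x <- dx * cos(th) + dy * sin(th)
  y <- -dx * sin(th) + dy * cos(th)
  paste(floor(x / grid$cell_deg), floor(y / grid$cell_deg), sep = "_")
}

#' Discretize drifter trajectories into a cell transition model
#'
#' Every drifter's positions (drogued and undrogued alike) are resampled at a
#' fixed `lag_days` by linear interpolation and mapped to grid cells.  For
#' each pair of consecutive distinct cells a transition is counted, with an
#' elapsed time equal to the time from *entering* the source cell to arriving
#' in the destination cell (so dwell inside the source cell is part of the
#' edge's transit time).  Self-transitions are also counted so that outgoing
#' probabilities per cell sum to one, but path edges use the probabilities
#' conditional on leaving the cell.
#'
#' @param trajectories data.frame with `id`, `time_days`, `lon`, `lat` (and
#'   optionally `drogued` — both classes are used).
#' @param grid a [lagrangian_grid()].
#' @param lag_days resampling lag in days (default 5).
#' @return object of class `transition_model`: `edges` data.frame (`from`,
#'   `to`, `count`, `prob`, `prob_leave`, `mean_time`), the `grid`, the lag,
#'   and the prebuilt directed path graph.
#' @export
discretize_trajectories <- function(trajectories, grid, lag_days = 5) {
  if (lag_days <= 0) stop_param("lag_days must be positive")
  from_all <- character(0)
  to_all <- character(0)
  time_all <- numeric(0)
  n_skipped <- 0L
  for (tr in split(trajectories, trajectories$id)) {
    tr <- tr[order(tr$time_days), , drop = FALSE]
    if (nrow(tr) < 2L || any(diff(tr$time_days) <= 0)) {
      n_skipped <- n_skipped + 1L
      next
    }
    times <- seq(tr$time_days[1], tr$time_days[nrow(tr)], by = lag_days)
    if (length(times) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    lon <- stats::approx(tr$time_days, tr$lon, xout = times)$y
    lat <- stats::approx(tr$time_days, tr$lat, xout = times)$y
    cells <- grid_cell(grid, lon, lat)
    runs <- rle(cells)
    k <- length(runs$values)
    # self-transitions: each run of length L contributes L-1 of them
    self_n <- runs$lengths - 1L
    if (any(self_n > 0L)) {
      from_all <- c(from_all, rep(runs$values, self_n))
      to_all <- c(to_all, rep(runs$values, self_n))
      time_all <- c(time_all, rep(lag_days, sum(self_n)))
    }
    if (k >= 2L) {
      # run r -> run r+1, elapsed = dwell in source run (length * lag)
      from_all <- c(from_all, runs$values[-k])
      to_all <- c(to_all, runs$values[-1L])
      time_all <- c(time_all, runs$lengths[-k] * lag_days)
    }
  }
  if (!length(from_all)) {
    edges <- data.frame(from = character(), to = character(),
                        count = integer(), total_time = numeric(),
                        prob = numeric(), prob_leave = numeric(),
                        mean_time = numeric(), stringsAsFactors = FALSE)
  } else {
    key <- paste(from_all, to_all, sep = ">")
    agg_count <- table(key)
    agg_time <- tapply(time_all, key, sum)
    uk <- names(agg_count)
    parts <- strsplit(uk, ">", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1L),
      to = vapply(parts, `[`, "", 2L),
      count = as.integer(agg_count),
      total_time = as.numeric(agg_time[uk]),
      stringsAsFactors = FALSE
    )
    out_tot <- tapply(edges$count, edges$from, sum)
    edges$prob <- edges$count / out_tot[edges$from]
    nonself <- edges$from != edges$to
    out_ns <- tapply(edges$count[nonself], edges$from[nonself], sum)
    edges$prob_leave <- NA_real_
    edges$prob_leave[nonself] <- edges$count[nonself] /
      out_ns[edges$from[nonself]]
    edges$mean_time <- edges$total_time / edges$count
  }
  path_edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    path_edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = unique(c(edges$from, edges$to))))
  if (nrow(path_edges)) {
    igraph::E(g)$weight <- -log(path_edges$prob_leave)
    igraph::E(g)$mean_time <- path_edges$mean_time
  }
  structure(list(edges = edges, grid = grid, lag_days = lag_days,
                 graph = g, n_skipped = n_skipped),
            class = "transition_model")
}

#' Travel time of the most likely path between two cells
#'
#' The most likely path maximizes the product of leave-conditional transition
#' probabilities (shortest path under `-log p` edge weights, self-transitions
#' excluded); its travel time is the sum of the mean transit times of its
#' edges.
#'
#' @param model a [discretize_trajectories()] transition model.
#' @param origin_cell,dest_cell cell keys (see grid cells of the model).
#' @return time in days, 0 when origin equals destination, `NA` when no path
#'   exists or a cell was never visited.
#' @export
most_likely_path_time <- function(model, origin_cell, dest_cell) {
  if (identical(origin_cell, dest_cell)) return(0)
  vs <- igraph::V(model$graph)$name
  if (!(origin_cell %in% vs) || !(dest_cell %in% vs)) return(NA_real_)
  sp <- suppressWarnings(igraph::shortest_paths(
    model$graph, from = origin_cell, to = dest_cell,
    weights = igraph::E(model$graph)$weight, output = "epath"))
  ep <- sp$epath[[1]]
  if (length(ep) == 0L) return(NA_real_)
  sum(igraph::E(model$graph)$mean_time[as.integer(ep)])
}

# travel times from one origin cell to many destination cells
path_times_from <- function(model, origin_cell, dest_cells) {
  vs <- igraph::V(model$graph)$name
  out <- rep(NA_real_, length(dest_cells))
  out[dest_cells == origin_cell] <- 0
  if (!(origin_cell %in% vs)) return(out)
  ok <- dest_cells %in% vs & dest_cells != origin_cell
  if (!any(ok)) return(out)
  sp <- suppressWarnings(igraph::shortest_paths(
    model$graph, from = origin_cell, to = dest_cells[ok],
    weights = igraph::E(model$graph)$weight, output = "epath"))
  mt <- igraph::E(model$graph)$mean_time
  out[ok] <- vapply(sp$epath, function(ep) {
    if (length(ep) == 0L) NA_real_ else sum(mt[as.integer(ep)])
  }, numeric(1))
  out
}

#' Rotation-averaged Lagrangian travel time matrix between stations
#'
#' For `n_rotations` grid rotation angles evenly spaced in \[0, 90) degrees,
#' the transition model is rebuilt on the rotated grid and both directions of
#' every station pair are computed; the final (asymmetric) entry is the mean
#' over rotations with a defined path.  Entries defined in fewer than 10% of
#' rotations are reported missing.
#'
#' @param trajectories drifter trajectory data.frame (see
#'   [discretize_trajectories()]).
#' @param stations data.frame with `station_id`, `lon`, `lat`.
#' @param n_rotations number of grid rotations (the reference analysis uses
#'   450; scaled-down values are appropriate for toy data).
#' @param lag_days resampling lag in days.
#' @param cell_deg grid cell size in degrees.
#' @param min_defined_frac minimum fraction of rotations with a defined path
#'   (default 0.1).
#' @return asymmetric stations x stations matrix of travel times in days
#'   (zero diagonal, `NA` = unreachable), of class `travel_time_matrix`.
#' @export
travel_time_matrix <- function(trajectories, stations, n_rotations = 450,
                               lag_days = 5, cell_deg = 1,
                               min_defined_frac = 0.1) {
  n <- nrow(stations)
  center <- c(mean(range(trajectories$lon)), mean(range(trajectories$lat)))
  acc <- matrix(0, n, n, dimnames = list(stations$station_id,
                                         stations$station_id))
  cnt <- matrix(0L, n, n, dimnames = dimnames(acc))
  angles <- 90 * (seq_len(n_rotations) - 1L) / n_rotations
  for (ang in angles) {
    grid <- lagrangian_grid(cell_deg, ang, center)
    model <- discretize_trajectories(trajectories, grid, lag_days)
    cells <- grid_cell(grid, stations$lon, stations$lat)
    for (i in seq_len(n)) {
      tt <- path_times_from(model, cells[i], cells)
      ok <- !is.na(tt)
      acc[i, ok] <- acc[i, ok] + tt[ok]
      cnt[i, ok] <- cnt[i, ok] + 1L
    }
  }
  out <- acc / cnt
  out[cnt < max(1L, ceiling(min_defined_frac * n_rotations))] <- NA_real_
  diag(out) <- 0
  class(out) <- c("travel_time_matrix", class(out))
  out
}

#' Add Mediterranean exchange penalties to a travel time matrix
#'
#' Surface drifters are not observed to exit the Mediterranean through the
#' Strait of Gibraltar, so outbound Mediterranean pathways get a large fixed
#' penalty and inbound pathways a small one instead of being missing:
#' MED -> non-MED entries gain `out_penalty_years` years and non-MED -> MED
#' entries gain `in_penalty_years` years (1 year = 365 days).
#'
#' @param matrix asymmetric travel time matrix (days), stations as dimnames.
#' @param basin_of_station named character vector station -> basin.
#' @param med_label basin label of the Mediterranean (default `"MED"`).
#' @param out_penalty_years,in_penalty_years penalties in years (defaults
#'   100 and 1).
#' @return the adjusted matrix.
#' @export
apply_basin_adjustments <- function(matrix, basin_of_station,
                                    med_label = "MED",
                                    out_penalty_years = 100,
                                    in_penalty_years = 1) {
  st <- rownames(matrix)
  med <- st[basin_of_station[st] == med_label]
  other <- setdiff(st, med)
  if (length(med) && length(other)) {
    matrix[med, other] <- matrix[med, other] + out_penalty_years * 365
    matrix[other, med] <- matrix[other, med] + in_penalty_years * 365
  }
  matrix
}

#' Min-symmetrize an asymmetric travel time matrix
#'
#' Of the two directed travel times of each station pair only the minimum is
#' retained; a missing direction is treated as infinite unless both are
#' missing.
#'
#' @param matrix asymmetric travel time matrix.
#' @return symmetric matrix with `out[i, j] = out[j, i] = min(in[i, j],
#'   in[j, i])`.
#' @export
min_symmetrize <- function(matrix) {
  m <- unclass(matrix)
  out <- pmin(m, t(m), na.rm = TRUE)
  out[is.na(m) & is.na(t(m))] <- NA_real_
  diag(out) <- 0
  out
}
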