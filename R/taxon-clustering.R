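#' Build the (epsilon, MinPts) density-clustering parameter grid
#'
#' Full Cartesian product in deterministic order: epsilon-major, MinPts
#' ascending within each epsilon.  The defaults are the reference grid of
#' 11 epsilon values by 17 MinPts values (187 parameter couples).
#'
#' @param epsilon_set numeric vector of DBSCAN neighbourhood radii.
#' @param minpts_set integer vector of DBSCAN core-point thresholds.
#' @return data.frame with columns `epsilon`, `min_pts`.
#' @export
build_parameter_grid <- function(epsilon_set = c(4, 5, 6, 7, 8, 9, 10, 12, 15, 18, 20),
                                 minpts_set = c(1:10, 20, 50, 100, 200, 300, 400, 500)) {
  if (length(epsilon_set) == 0L || length(minpts_set) == 0L) {
    stop_param("epsilon and MinPts sets must be non-empty")
  }
  epsilon_set <- sort(epsilon_set)
  minpts_set <- sort(as.integer(minpts_set))
  data.frame(epsilon = rep(epsilon_set, each = length(minpts_set)),
             min_pts = rep(minpts_set, times = length(epsilon_set)))
}

# neighbourhood adjacency within eps from a precomputed distance matrix
neighbours_within <- function(dist_matrix, epsilon) {
  lapply(seq_len(nrow(dist_matrix)),
         function(i) which(dist_matrix[i, ] <= epsilon))
}

# DBSCAN labelling given adjacency lists; 0 = noise.  Core points are loci
# with >= min_pts neighbours (self included); clusters are connected
# components of core points, border points join the first cluster that
# reaches them (deterministic in locus order).
dbscan_labels <- function(adj, min_pts) {
  n <- length(adj)
  core <- lengths(adj) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      nb <- adj[[j]]
      new <- nb[labels[nb] == 0L]
      if (length(new)) {
        labels[new] <- cl
        queue <- c(queue, new[core[new]])
      }
    }
  }
  labels
}

#' Density-based clustering of loci by depth-of-coverage covariation
#'
#' DBSCAN on Euclidean distances between the loci's depth vectors.  A core
#' locus has at least `min_pts` loci (itself included) within distance
#' `epsilon`; clusters are the connected components of core loci plus the
#' border loci they reach; remaining loci are noise (label 0).
#'
#' @param coverage loci x samples depth matrix.
#' @param epsilon neighbourhood radius (read-count units).
#' @param min_pts core-point threshold.
#' @param dist_matrix optional precomputed loci x loci distance matrix
#'   (reused across an ensemble run).
#' @return integer vector of cluster labels, 0 for noise.
#' @export
run_density_clustering <- function(coverage, epsilon, min_pts,
                                   dist_matrix = NULL) {
  if (epsilon <= 0 || min_pts < 1) stop_param("invalid clustering parameters")
  if (is.null(dist_matrix)) {
    dist_matrix <- as.matrix(stats::dist(coverage))
  }
  dbscan_labels(neighbours_within(dist_matrix, epsilon), min_pts)
}

#' Score a cluster by negative-binomial fit of its depth distribution
#'
#' For every sample with non-zero median depth over the cluster's loci, a
#' negative binomial is fitted by method of moments (variance floored at
#' mean + 1e-6, dispersion floored at 1e-3) and the mean per-locus
#' log-likelihood is computed.  The score is
#'
#' `n_loci * (n_fitted / n_covered) * exp(mean over fitted samples of the
#' mean per-locus log-likelihood)`
#'
#' i.e. cluster size, weighted by the geometric-mean per-locus NB likelihood
#' and by the fraction of covered samples (any non-zero depth) in which the
#' cluster is coherently present (non-zero median).  The score grows with
#' cluster size at equal fit quality and is always finite and non-negative
#' (suitable as an independent-set weight).  Chimeric clusters mixing several
#' taxa are punished twice: samples where only part of the membership occurs
#' fit the NB poorly, and samples that are mostly zero fail the median rule
#' and shrink the presence fraction.
#'
#' @param cluster_coverage loci x samples depth matrix of one cluster.
#' @return a single non-negative score; single-locus clusters get the minimal
#'   sentinel score 0.
#' @export
score_cluster <- function(cluster_coverage) {
  cluster_coverage <- as.matrix(cluster_coverage)
  n_loci <- nrow(cluster_coverage)
  if (n_loci < 2L) return(0)
  covered <- which(colSums(cluster_coverage) > 0)
  med <- apply(cluster_coverage, 2L, stats::median)
  use <- which(med > 0)
  if (!length(use)) return(0)
  ll <- vapply(use, function(s) {
    x <- cluster_coverage[, s]
    fit <- fit_nb_moments(x)
    mean(stats::dnbinom(x, size = fit[["dispersion"]],
                        mu = max(fit[["mean"]], 1e-9), log = TRUE))
  }, numeric(1))
  n_loci * (length(use) / length(covered)) * exp(mean(ll))
}

#' Select a maximum-weight set of SNP-disjoint clusters
#'
#' Builds the conflict graph (an edge between clusters sharing at least one
#' SNP) and returns an independent set maximizing total score: exact
#' branch-and-bound on every conflict component of at most `exact_limit`
#' nodes, greedy (descending score, ties by smaller cluster index) on larger
#' components.  The branch-and-bound starts from the greedy solution as its
#' incumbent and is capped in search effort, so on every component the result
#' is an independent set with total score at least the greedy total.
#'
#' @param clusters list of clusters, each a list with elements `snp_ids`
#'   (vector of locus ids) and `score` (finite numeric weight).
#' @param exact_limit component size up to which the exact solver is used.
#' @return integer indices (into `clusters`) of the selected, pairwise
#'   SNP-disjoint clusters.
#' @export
select_mwis <- function(clusters, exact_limit = 60L) {
  k <- length(clusters)
  if (k == 0L) return(integer())
  scores <- vapply(clusters, function(cl) as.numeric(cl$score), numeric(1))
  stopifnot(all(is.finite(scores)))
  # conflict edges via SNP -> cluster incidence
  snp <- unlist(lapply(clusters, function(cl) as.character(cl$snp_ids)),
                use.names = FALSE)
  owner <- rep.int(seq_len(k), vapply(clusters, function(cl)
    length(cl$snp_ids), integer(1)))
  edges <- unique(do.call(rbind, unname(lapply(
    split(owner, snp), function(o) {
      o <- sort(unique(o))
      if (length(o) < 2L) return(NULL)
      t(utils::combn(o, 2L))
    }))))
  adj <- vector("list", k)
  for (i in seq_len(k)) adj[[i]] <- integer()
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges) || !nrow(edges)) {
      data.frame(from = integer(), to = integer())
    } else {
      data.frame(from = edges[, 1L], to = edges[, 2L])
    },
    directed = FALSE,
    vertices = data.frame(name = seq_len(k)))
  comp <- igraph::components(g)$membership[as.character(seq_len(k))]
  selected <- integer()
  for (cid in unique(comp)) {
    nodes <- which(comp == cid)
    if (length(nodes) == 1L) {
      if (scores[nodes] > 0) selected <- c(selected, nodes)
    } else if (length(nodes) <= exact_limit) {
      local_adj <- lapply(adj[nodes], function(nb) match(nb, nodes))
      greedy <- match(mwis_greedy(nodes, adj, scores), nodes)
      sel <- mwis_exact(local_adj, scores[nodes], incumbent = greedy)
      selected <- c(selected, nodes[sel])
    } else {
      selected <- c(selected, mwis_greedy(nodes, adj, scores))
    }
  }
  sort(unname(selected))
}

# maximum-weight independent set by branch and bound on one component;
# adj is a local adjacency list (indices 1..n), w the weights.  The search
# starts from an optional incumbent (e.g. the greedy set) and is capped at
# max_calls expansions, so the result is exact on small components and never
# worse than the incumbent on pathological ones.
mwis_exact <- function(adj, w, incumbent = integer(), max_calls = 2e6) {
  n <- length(w)
  best_w <- sum(w[incumbent])
  best_set <- incumbent
  calls <- 0L
  bb <- function(cand, cur_set, cur_w) {
    calls <<- calls + 1L
    if (calls > max_calls) return(invisible())
    if (cur_w + sum(pmax(w[cand], 0)) <= best_w) return(invisible())
    if (!length(cand)) {
      if (cur_w > best_w) {
        best_w <<- cur_w
        best_set <<- cur_set
      }
      return(invisible())
    }
    v <- cand[which.max(w[cand])]
    # include v
    bb(setdiff(cand, c(v, adj[[v]])), c(cur_set, v), cur_w + w[v])
    # exclude v
    bb(setdiff(cand, v), cur_set, cur_w)
    invisible()
  }
  bb(seq_len(n), integer(), 0)
  best_set
}

# greedy independent set: descending score, ties by smaller index
mwis_greedy <- function(nodes, adj, scores) {
  ord <- nodes[order(-scores[nodes], nodes)]
  taken <- integer()
  blocked <- logical(length(scores))
  for (v in ord) {
    if (blocked[v] || scores[v] <= 0) next
    taken <- c(taken, v)
    blocked[adj[[v]]] <- TRUE
  }
  taken
}

#' Apply the final depth and size filters to selected clusters
#'
#' For each selected cluster and each sample, a negative binomial is fitted
#' to the cluster's locus depths; cells with depth below `min_depth` or above
#' the fitted distribution's 99th percentile (the maximum expected depth) are
#' masked (set `NA`) so they never reach allele-frequency computation.
#' Samples whose median depth over the cluster's loci is not strictly greater
#' than `min_depth` are dropped from the species' population set.  A cluster
#' becomes a metavariant species iff it keeps at least `min_snps` SNPs and at
#' least `min_samples` retained samples.
#'
#' @param selected list of clusters (elements `snp_ids`, and optionally `score`).
#' @param snp_table the filtered [snp_table()] the clusters index into.
#' @param min_snps minimum SNPs per species (default 100).
#' @param min_samples minimum retained samples (default 3).
#' @param min_depth per-cell depth threshold and (strict) median threshold
#'   (default 8).
#' @return list of `metavariant_species` objects: `species_id`, `snp_ids`,
#'   `coverage` (masked depths), `counts` (masked allele counts), `sample_ids`
#'   (retained), `station_of_sample`, `alleles`, `score`.
#' @export
apply_final_filters <- function(selected, snp_table, min_snps = 100,
                                min_samples = 3, min_depth = 8) {
  depth_all <- snp_depth(snp_table)
  out <- list()
  for (ci in seq_along(selected)) {
    cl <- selected[[ci]]
    rows <- match(as.character(cl$snp_ids), snp_table$locus_id)
    if (anyNA(rows)) stop_input("cluster refers to unknown loci")
    if (length(rows) < min_snps) next
    depth <- depth_all[rows, , drop = FALSE]
    med <- apply(depth, 2L, stats::median)
    keep_samples <- which(med > min_depth)
    if (length(keep_samples) < min_samples) next
    depth <- depth[, keep_samples, drop = FALSE]
    counts <- snp_table$counts[rows, keep_samples, , drop = FALSE]
    for (s in seq_along(keep_samples)) {
      fit <- fit_nb_moments(depth[, s])
      max_expected <- stats::qnbinom(0.99, size = fit[["dispersion"]],
                                     mu = max(fit[["mean"]], 1e-9))
      mask <- depth[, s] < min_depth | depth[, s] > max_expected
      if (any(mask)) {
        depth[mask, s] <- NA_integer_
        counts[mask, s, ] <- NA_integer_
      }
    }
    out[[length(out) + 1L]] <- structure(list(
      species_id = sprintf("MVS%03d", length(out) + 1L),
      snp_ids = snp_table$locus_id[rows],
      coverage = depth,
      counts = counts,
      sample_ids = snp_table$sample_ids[keep_samples],
      station_of_sample = snp_table$station_of_sample[keep_samples],
      alleles = snp_table$alleles[rows, , drop = FALSE],
      score = cl$score %||% NA_real_
    ), class = "metavariant_species")
  }
  out
}

#' @export
print.metavariant_species <- function(x, ...) {
  cat(sprintf("<metavariant_species %s> %d SNPs x %d samples (%d stations)\n",
              x$species_id, length(x$snp_ids), length(x$sample_ids),
              length(unique(x$station_of_sample))))
  invisible(x)
}

#' Delineate metavariant species from a filtered SNP table
#'
#' Runs the full ensemble: density clustering of loci by depth covariation at
#' every (epsilon, MinPts) couple of the grid, negative-binomial scoring of
#' every distinct cluster found, selection of SNP-disjoint clusters by
#' maximum-weight independent set, and the final depth/size filters.
#'
#' @param table a (filtered) [snp_table()].
#' @param epsilon_set,minpts_set clustering grid (see
#'   [build_parameter_grid()]).
#' @param min_snps,min_samples,min_depth final filters (see
#'   [apply_final_filters()]).
#' @param verbose print per-stage counts.
#' @return list with `species` (list of `metavariant_species`) and `log`
#'   (grid size and per-stage counts).
#' @export
delineate_species <- function(table,
                              epsilon_set = c(4, 5, 6, 7, 8, 9, 10, 12, 15, 18, 20),
                              minpts_set = c(1:10, 20, 50, 100, 200, 300, 400, 500),
                              min_snps = 100, min_samples = 3, min_depth = 8,
                              verbose = FALSE) {
  grid <- build_parameter_grid(epsilon_set, minpts_set)
  depth <- snp_depth(table)
  dist_matrix <- as.matrix(stats::dist(depth))
  seen <- new.env(parent = emptyenv())
  n_clusters_total <- 0L
  for (eps in unique(grid$epsilon)) {
    adj <- neighbours_within(dist_matrix, eps)
    for (mp in grid$min_pts[grid$epsilon == eps]) {
      labels <- dbscan_labels(adj, mp)
      for (cl in setdiff(unique(labels), 0L)) {
        rows <- which(labels == cl)
        if (length(rows) < 2L) next
        n_clusters_total <- n_clusters_total + 1L
        key <- paste(rows, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, rows, envir = seen)
        }
      }
    }
  }
  keys <- ls(seen)
  clusters <- lapply(keys, function(k) {
    rows <- get(k, envir = seen)
    list(snp_ids = table$locus_id[rows],
         score = score_cluster(depth[rows, , drop = FALSE]))
  })
  sel_idx <- select_mwis(clusters)
  species <- apply_final_filters(clusters[sel_idx], table,
                                 min_snps = min_snps,
                                 min_samples = min_samples,
                                 min_depth = min_depth)
  log <- list(grid_size = nrow(grid),
              n_clusters_total = n_clusters_total,
              n_clusters_unique = length(clusters),
              n_selected = length(sel_idx),
              n_species = length(species))
  if (verbose) {
    message(sprintf(
      "grid %d couples; %d clusters (%d distinct); %d selected; %d species",
      log$grid_size, log$n_clusters_total, log$n_clusters_unique,
      log$n_selected, log$n_species))
  }
  list(species = species, log = log)
}
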