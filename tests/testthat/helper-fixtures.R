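# shared fixtures (computed once per test run) and independent oracles

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the reference planted dataset: 5 taxa x 300 loci, NB(30, 5) coverage,
# 10% noise SNPs, fixed seed
planted_dataset <- function() {
  fixture("planted_dataset", function() {
    simulate_dataset(simulation_config(seed = 7))
  })
}

# delineation of the planted dataset with a read-count-scale epsilon grid
planted_delineation <- function() {
  fixture("planted_delineation", function() {
    d <- planted_dataset()
    filtered <- filter_loci(d$snp_table, filter_params())$table
    delineate_species(filtered,
                      epsilon_set = c(40, 55, 70, 85, 100),
                      minpts_set = c(3, 5, 10, 20))
  })
}

# purity/recall of recovered species against the planted taxon labels
recovery_stats <- function(species, taxon_of_locus) {
  do.call(rbind, lapply(species, function(sp) {
    truth <- taxon_of_locus[sp$snp_ids]
    tab <- table(truth)
    top <- names(which.max(tab))
    data.frame(species_id = sp$species_id, taxon = top,
               purity = max(tab) / length(truth),
               recall = max(tab) / sum(taxon_of_locus == top),
               stringsAsFactors = FALSE)
  }))
}

# --- independent oracles -----------------------------------------------------

# exhaustive maximum-weight independent set by recursive enumeration of all
# independent sets (no pruning beyond feasibility)
mwis_enumerate <- function(adj, w) {
  n <- length(w)
  best <- 0
  recurse <- function(v, cur, cur_w) {
    if (v > n) {
      if (cur_w > best) best <<- cur_w
      return(invisible())
    }
    recurse(v + 1L, cur, cur_w)                       # exclude v
    if (!any(adj[[v]] %in% cur)) {                    # include v if feasible
      recurse(v + 1L, c(cur, v), cur_w + w[v])
    }
    invisible()
  }
  recurse(1L, integer(), 0)
  best
}

# random conflict graph encoded as clusters sharing synthetic SNP ids
random_conflict_clusters <- function(n, p_edge, score_range = c(0.1, 10)) {
  adj <- replicate(n, integer(), simplify = FALSE)
  snp_ids <- lapply(seq_len(n), function(i) paste0("own", i))
  eid <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p_edge) {
        eid <- eid + 1L
        shared <- paste0("e", eid)
        snp_ids[[i]] <- c(snp_ids[[i]], shared)
        snp_ids[[j]] <- c(snp_ids[[j]], shared)
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  w <- stats::runif(n, score_range[1], score_range[2])
  list(clusters = Map(function(s, sc) list(snp_ids = s, score = sc),
                      snp_ids, w),
       adj = adj, w = w)
}

# restricted log-likelihood written independently of the package's fitter
# (direct dense formula), for the grid-search REML oracle
ref_restricted_loglik <- function(y, Z, s2, s2e) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- diag(s2e, n)
  for (k in seq_along(s2)) V <- V + s2[k] * tcrossprod(Z[, k])
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  ldV <- determinant(V)$modulus
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (ldV + determinant(A)$modulus + t(r) %*% Vi %*% r))
}

# strict LCA of a set of taxa by explicit ancestor-path intersection
strict_lca_oracle <- function(taxa, tree) {
  paths <- lapply(taxa, function(t) {
    p <- t
    while (t != tree$root) {
      t <- tree$parent[[t]]
      p <- c(p, t)
    }
    p
  })
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[common])]
}

# random taxonomy tree: n nodes, each attached to a uniformly chosen earlier
# node
random_tree <- function(n) {
  parent <- c(NA, paste0("n", vapply(2:n, function(i) sample(i - 1L, 1L),
                                     integer(1))))
  taxonomy_tree(data.frame(id = paste0("n", 1:n), parent = parent))
}

# small planted profile cohort for the classification stage: three groups of
# taxa, each dominated by one predictor
planted_profiles <- function(n_per_group = 15, drivers = c("lagrangian",
                                                           "temperature",
                                                           "salinity"),
                             seed = 42) {
  set.seed(seed)
  n <- n_per_group * length(drivers)
  preds <- c("lagrangian", "temperature", "salinity", "nitrate",
             "phosphate", "silicate")
  truth <- rep(drivers, each = n_per_group)
  m <- matrix(0.05, n, length(preds), dimnames = list(paste0("t", 1:n), preds))
  for (i in seq_len(n)) {
    m[i, truth[i]] <- 0.6 + stats::runif(1, -0.05, 0.05)
    m[i, ] <- abs(m[i, ] + stats::rnorm(length(preds), 0, 0.02))
  }
  list(profiles = m, truth = truth)
}

# adjusted Rand index (contingency-table formula), independent of mclust
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(sum(tab))
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
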