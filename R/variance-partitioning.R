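predictor_names <- function() {
  c("lagrangian", "temperature", "salinity", "nitrate", "phosphate",
    "silicate")
}

#' Build standardized distance predictors for one taxon
#'
#' For every unordered pair of the taxon's stations: the min-symmetrized
#' Lagrangian travel time, and the absolute difference of each of the five
#' environmental parameters (a Euclidean distance in one dimension).  Each
#' column is then standardized to mean 0 and sample variance 1 over the
#' taxon's pairs; constant columns are dropped and recorded.  Pairs with a
#' missing travel time are dropped and recorded.
#'
#' @param env_table data.frame with `station_id` and the columns
#'   `temperature`, `salinity`, `nitrate`, `phosphate`, `silicate`.
#' @param travel_times symmetric station x station matrix (days).
#' @param stations character vector of the taxon's stations.
#' @return object of class `distance_predictors`: `Z` (pairs x kept
#'   predictors, standardized), `raw`, `pairs` (two-column data.frame),
#'   `dropped` (constant predictor names), `n_dropped_pairs`.
#' @export
build_predictors <- function(env_table, travel_times, stations) {
  stations <- as.character(stations)
  if (!all(stations %in% env_table$station_id)) {
    stop_input("stations missing from the environmental table")
  }
  if (!all(stations %in% rownames(travel_times))) {
    stop_input("stations missing from the travel time matrix")
  }
  pr <- utils::combn(stations, 2L)
  pairs <- data.frame(station_a = pr[1, ], station_b = pr[2, ],
                      stringsAsFactors = FALSE)
  env <- env_table[match(stations, env_table$station_id), , drop = FALSE]
  rownames(env) <- stations
  raw <- matrix(NA_real_, nrow(pairs), 6L,
                dimnames = list(NULL, predictor_names()))
  raw[, "lagrangian"] <- travel_times[cbind(pairs$station_a, pairs$station_b)]
  for (p in setdiff(predictor_names(), "lagrangian")) {
    raw[, p] <- abs(env[pairs$station_a, p] - env[pairs$station_b, p])
  }
  ok <- !is.na(raw[, "lagrangian"])
  n_dropped_pairs <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  pairs <- pairs[ok, , drop = FALSE]
  sds <- apply(raw, 2L, stats::sd)
  dropped <- colnames(raw)[is.na(sds) | sds < 1e-12]
  kept <- setdiff(colnames(raw), dropped)
  Z <- scale(raw[, kept, drop = FALSE])
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  structure(list(Z = Z, raw = raw, pairs = pairs, dropped = dropped,
                 n_dropped_pairs = n_dropped_pairs),
            class = "distance_predictors")
}

# restricted log-likelihood of y under V with fixed-effect design X
restricted_loglik <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  A <- XtVi %*% X
  beta <- solve(A, XtVi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) + determinant(A)$modulus +
                       crossprod(r, Vi %*% r)))
}

#' REML variance components of pairwise F_ST over distance predictors
#'
#' Fits `y = X beta + sum_k u_k z_k + e` with one scalar random regression
#' coefficient per predictor column (`u_k ~ N(0, sigma2_k)`) and white-noise
#' residual, i.e. covariance `V = sum_k sigma2_k z_k z_k' + sigma2_e I`.
#' Components are estimated by the REML EM (minorization-maximization)
#' update, which keeps every component non-negative and increases the
#' restricted likelihood at every iteration; the fixed effects (an intercept
#' by default) are estimated by GLS at convergence.  The per-predictor
#' variance proportions are each component over the total
#' (fixed-part variance + all components + residual).
#'
#' @param y numeric vector of pairwise F_ST observations.
#' @param Z a [build_predictors()] object or a numeric matrix of standardized
#'   predictor columns.
#' @param X optional fixed-effect design (default intercept only, matching
#'   the model's printed form; extra covariates make the fixed proportion
#'   non-zero).
#' @param tol convergence tolerance on components (default 1e-8).
#' @param max_iter maximum EM iterations (default 5000).
#' @return object of class `variance_partition`: `sigma2` (named, dropped
#'   predictors as 0), `residual`, `mu`, `beta`, `proportions` (predictors +
#'   `fixed` + `residual`, summing to 1), `converged`, `n_iter`, `loglik`,
#'   `loglik_trace`, `untestable` flag.
#' @export
fit_variance_components <- function(y, Z, X = NULL, tol = 1e-8,
                                    max_iter = 5000) {
  dropped <- character()
  if (inherits(Z, "distance_predictors")) {
    dropped <- Z$dropped
    Z <- Z$Z
  }
  Z <- as.matrix(Z)
  n <- length(y)
  K <- ncol(Z)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (n < K + 2L || n < 6L) {
    return(structure(list(untestable = TRUE,
                          reason = sprintf("%d pairs for %d predictors", n, K)),
                     class = "variance_partition"))
  }
  cn <- colnames(Z) %||% paste0("z", seq_len(K))

  s2y <- stats::var(y)
  if (s2y < 1e-14) {
    sigma2 <- stats::setNames(rep(0, K), cn)
    props <- stats::setNames(c(rep(0, K), 0, 1), c(cn, "fixed", "residual"))
    return(structure(list(untestable = FALSE, sigma2 = sigma2, residual = 0,
                          mu = mean(y), beta = c(mean(y), rep(0, ncol(X) - 1L)),
                          proportions = props, converged = TRUE, n_iter = 0L,
                          loglik = NA_real_, loglik_trace = numeric(),
                          dropped = dropped),
                     class = "variance_partition"))
  }

  sig <- rep(s2y / (K + 1), K)
  sig_e <- s2y / (K + 1)
  trace <- numeric()
  converged <- FALSE
  p <- ncol(X)
  for (it in seq_len(max_iter)) {
    V <- diag(sig_e, n)
    for (k in seq_len(K)) V <- V + sig[k] * tcrossprod(Z[, k])
    Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
    if (is.null(Vi)) break
    XtVi <- crossprod(X, Vi)
    P <- Vi - t(XtVi) %*% solve(XtVi %*% X, XtVi)
    Py <- P %*% y
    new_sig <- sig
    for (k in seq_len(K)) {
      zk <- Z[, k]
      zPy <- sum(zk * Py)
      zPz <- as.numeric(crossprod(zk, P %*% zk))
      new_sig[k] <- max(sig[k] + sig[k]^2 * (zPy^2 - zPz), 0)
    }
    new_sig_e <- max(sig_e + sig_e^2 * (sum(Py^2) - sum(diag(P))) / (n - p), 0)
    trace <- c(trace, restricted_loglik(y, X, V))
    delta <- max(abs(c(new_sig - sig, new_sig_e - sig_e)))
    sig <- new_sig
    sig_e <- new_sig_e
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  V <- diag(sig_e, n)
  for (k in seq_len(K)) V <- V + sig[k] * tcrossprod(Z[, k])
  Vi <- chol2inv(chol(V + diag(1e-12, n)))
  XtVi <- crossprod(X, Vi)
  beta <- as.vector(solve(XtVi %*% X, XtVi %*% y))
  fixed_part <- as.vector(X %*% beta)
  var_fixed <- if (ncol(X) > 1L) stats::var(fixed_part) else 0
  sigma2 <- stats::setNames(rep(0, K + length(dropped)), c(cn, dropped))
  sigma2[cn] <- sig
  sigma2 <- sigma2[intersect(c(predictor_names(), names(sigma2)),
                             names(sigma2))]
  total <- sum(sigma2) + sig_e + var_fixed
  if (total < 1e-14) {
    props <- stats::setNames(c(rep(0, length(sigma2)), 0, 1),
                             c(names(sigma2), "fixed", "residual"))
  } else {
    props <- c(sigma2 / total, fixed = var_fixed / total,
               residual = sig_e / total)
  }
  structure(list(untestable = FALSE, sigma2 = sigma2, residual = sig_e,
                 mu = beta[1], beta = beta, proportions = props,
                 converged = converged, n_iter = length(trace),
                 loglik = restricted_loglik(y, X, V),
                 loglik_trace = trace, dropped = dropped),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("<variance_partition> untestable:", x$reason, "\n")
  } else {
    cat("<variance_partition>",
        if (x$converged) "converged" else "NOT converged",
        sprintf("after %d iterations\n", x$n_iter))
    print(round(x$proportions, 4))
  }
  invisible(x)
}

#' Partition F_ST variance for every taxon
#'
#' For every species, builds the station-pair response (the species' median
#' pairwise F_ST reduced to station pairs), the standardized distance
#' predictors, and the REML variance partition; returns one proportions row
#' per taxon (six predictors + fixed + residual, summing to 1, dropped
#' predictors reported as 0).
#'
#' @param fst_results named list of [summarize_fst()] results.
#' @param env_table environmental table (see [build_predictors()]).
#' @param travel_times min-symmetrized travel time matrix.
#' @param min_stations minimum stations per taxon (default 4).
#' @return list with `proportions` (taxa x 8 matrix), `fits` (per-taxon
#'   `variance_partition` objects), `excluded` (named reasons).
#' @export
partition_all_taxa <- function(fst_results, env_table, travel_times,
                               min_stations = 4) {
  prop_cols <- c(predictor_names(), "fixed", "residual")
  rows <- list()
  fits <- list()
  excluded <- character()
  for (nm in names(fst_results)) {
    res <- fst_results[[nm]]
    sp <- station_pair_fst(res)
    stations <- sort(unique(res$station_of_population[res$populations]))
    if (is.null(sp) || length(stations) < min_stations) {
      excluded[nm] <- "fewer stations than required"
      next
    }
    pred <- build_predictors(env_table, travel_times, stations)
    key <- paste(pred$pairs$station_a, pred$pairs$station_b)
    y <- sp$fst[match(key, paste(sp$station_a, sp$station_b))]
    ok <- !is.na(y)
    fit <- fit_variance_components(y[ok], pred$Z[ok, , drop = FALSE])
    if (isTRUE(fit$untestable)) {
      excluded[nm] <- fit$reason
      next
    }
    row <- stats::setNames(rep(0, length(prop_cols)), prop_cols)
    row[names(fit$proportions)] <- fit$proportions
    rows[[nm]] <- row
    fits[[nm]] <- fit
  }
  proportions <- do.call(rbind, rows)
  list(proportions = proportions, fits = fits, excluded = excluded)
}
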