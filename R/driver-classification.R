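#' PCA diagnostics of variance-explained profiles
#'
#' Centered and scaled PCA of the taxa x predictors proportion matrix, with
#' the diagnostics used to read driver structure: Pearson correlation of each
#' variable with the component scores (and its test p-value), the variable
#' cos^2, and the contribution of each variable to each component — the ratio
#' of its cos^2 to the component's total cos^2, so contributions sum to one
#' per component.  Two variants mirror the two analyses: with and without
#' the unexplained (residual) part of the variance.
#'
#' @param matrix taxa x predictors numeric matrix of variance proportions.
#' @param include_residual keep the `residual` column if present (default
#'   `FALSE` drops it).
#' @return list: `loadings`, `sdev`, `var_explained`, `correlations`,
#'   `p_values`, `contributions`, `dropped` (constant columns).
#' @export
pca_diagnostics <- function(matrix, include_residual = FALSE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 3L) stop_param("PCA diagnostics require at least 3 taxa")
  if (!include_residual && "residual" %in% colnames(m)) {
    m <- m[, colnames(m) != "residual", drop = FALSE]
  }
  if ("fixed" %in% colnames(m)) m <- m[, colnames(m) != "fixed", drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  dropped <- colnames(m)[sds < 1e-12]
  m <- m[, sds >= 1e-12, drop = FALSE]
  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pca$x
  correlations <- stats::cor(m, scores)
  p_values <- correlations
  for (v in seq_len(nrow(p_values))) {
    for (cp in seq_len(ncol(p_values))) {
      p_values[v, cp] <- stats::cor.test(m[, v], scores[, cp])$p.value
    }
  }
  cos2 <- correlations^2
  contributions <- sweep(cos2, 2L, colSums(cos2), "/")
  list(loadings = pca$rotation, sdev = pca$sdev,
       var_explained = pca$sdev^2 / sum(pca$sdev^2),
       correlations = correlations, p_values = p_values,
       contributions = contributions, dropped = dropped)
}

# squared Euclidean distance matrix
sq_dist <- function(x) {
  s <- rowSums(x * x)
  d <- outer(s, s, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# conditional Gaussian affinities at a fixed perplexity (binary search on
# precision per point)
tsne_affinities <- function(d2, perplexity, tol = 1e-5) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf
    hi <- Inf
    beta <- 1
    for (iter in seq_len(60)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) {        # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of variance-explained profiles
#'
#' Standard t-distributed stochastic neighbour embedding to two dimensions:
#' Gaussian input affinities calibrated per point to the requested
#' perplexity, Student-t output kernel, gradient descent with momentum,
#' adaptive gains and early exaggeration.  Deterministic under a fixed seed.
#'
#' @param matrix taxa x predictors numeric matrix.
#' @param perplexity neighbourhood size parameter (default 5); must satisfy
#'   `n_taxa > 3 * perplexity`.
#' @param max_iter gradient-descent iterations (default 5000).
#' @param seed optional integer seed for the random initialization.
#' @return taxa x 2 matrix of embedding coordinates.
#' @export
embed_tsne <- function(matrix, perplexity = 5, max_iter = 5000, seed = NULL) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    stop_param("perplexity too large: need n_taxa > 3 * perplexity")
  }
  P <- tsne_affinities(sq_dist(x), perplexity)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
    inc <- matrix(0, n, 2L)
    gains <- matrix(1, n, 2L)
    eta <- 200
    exaggeration <- 12
    stop_exag <- min(250L, max_iter %/% 4L)
    for (it in seq_len(max_iter)) {
      Pe <- if (it <= stop_exag) P * exaggeration else P
      num <- 1 / (1 + sq_dist(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      momentum <- if (it < 250L) 0.5 else 0.8
      inc <- momentum * inc - eta * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- c("tsne1", "tsne2")
    Y
  })
}

#' K-means clustering of embedding coordinates
#'
#' Best of `n_restarts` random starts by within-cluster sum of squares,
#' deterministic under a fixed seed.  Labels are canonicalized by descending
#' cluster size (ties by smallest member index) so reruns are comparable.
#'
#' @param coords taxa x d numeric matrix (typically the t-SNE coordinates).
#' @param k number of clusters (default 8, chosen in the reference analysis
#'   from the embedding's point density).
#' @param seed optional integer seed.
#' @param n_restarts random restarts (default 50).
#' @return integer vector of cluster labels (1 = largest cluster) with
#'   attribute `wcss`.
#' @export
cluster_kmeans <- function(coords, k = 8, seed = NULL, n_restarts = 50) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop_param("k cannot exceed the number of taxa")
  if (k == nrow(coords)) {
    # one cluster per point: zero within-cluster sum of squares
    labels <- seq_len(k)
    attr(labels, "wcss") <- 0
    return(labels)
  }
  km <- with_seed(seed, stats::kmeans(coords, centers = k,
                                      nstart = n_restarts, iter.max = 100L))
  sizes <- tabulate(km$cluster, nbins = k)
  first <- vapply(seq_len(k), function(cl) min(which(km$cluster == cl)),
                  integer(1))
  ord <- order(-sizes, first)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  attr(labels, "wcss") <- km$tot.withinss
  labels
}

#' Dominant connectivity drivers of each cluster
#'
#' Within each cluster of taxa, the distributions of the variance explained
#' by each predictor are compared with a Kruskal-Wallis test across the
#' predictor columns; iff significant (p < 0.05), one-sided paired Wilcoxon
#' tests between predictor columns identify, for every predictor, whether any
#' other predictor significantly exceeds it.  The cluster's dominant set is
#' the predictors not significantly exceeded by any other — a single driver
#' in clear cases, two when the top predictors are tied, empty (`"none"`)
#' under exchangeable columns.
#'
#' @param labels integer cluster labels per taxon.
#' @param profiles taxa x predictors matrix of variance proportions.
#' @param alpha significance level (default 0.05).
#' @return named list per cluster: `kruskal_p`, `dominant` (character vector
#'   or `"none"`), `n_taxa`.
#' @export
identify_cluster_drivers <- function(labels, profiles, alpha = 0.05) {
  profiles <- as.matrix(profiles)
  preds <- intersect(predictor_names(), colnames(profiles))
  profiles <- profiles[, preds, drop = FALSE]
  out <- list()
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    nm <- as.character(cl)
    if (length(rows) < 3L) {
      out[[nm]] <- list(kruskal_p = NA_real_, dominant = "none",
                        n_taxa = length(rows))
      next
    }
    sub <- profiles[rows, , drop = FALSE]
    kw <- stats::kruskal.test(as.vector(sub),
                              factor(rep(preds, each = length(rows))))
    if (kw$p.value >= alpha) {
      out[[nm]] <- list(kruskal_p = kw$p.value, dominant = "none",
                        n_taxa = length(rows))
      next
    }
    exceeded <- stats::setNames(rep(FALSE, length(preds)), preds)
    for (a in preds) {
      for (b in setdiff(preds, a)) {
        p <- suppressWarnings(stats::wilcox.test(
          sub[, a], sub[, b], paired = TRUE, alternative = "greater",
          exact = FALSE)$p.value)
        if (!is.na(p) && p < alpha) exceeded[b] <- TRUE
      }
    }
    dominant <- preds[!exceeded]
    if (!length(dominant)) dominant <- "none"
    out[[nm]] <- list(kruskal_p = kw$p.value, dominant = dominant,
                      n_taxa = length(rows))
  }
  out
}

#' Fisher exact enrichment of taxonomic groups in driver clusters
#'
#' For every (cluster, taxonomic group) combination, a two-sided Fisher exact
#' test on the 2x2 membership table (in/out of the cluster by in/out of the
#' group).
#'
#' @param labels cluster labels per taxon.
#' @param taxon_groups group label per taxon (same length).
#' @return clusters x groups matrix of two-sided p-values (`NA` when a
#'   margin is empty).
#' @export
enrichment_test <- function(labels, taxon_groups) {
  taxon_groups <- as.character(taxon_groups)
  if (length(unique(taxon_groups)) < 2L) {
    stop_param("enrichment requires at least two taxonomic groups")
  }
  cls <- sort(unique(labels))
  grs <- sort(unique(taxon_groups))
  out <- matrix(NA_real_, length(cls), length(grs),
                dimnames = list(as.character(cls), grs))
  for (ci in seq_along(cls)) {
    for (gi in seq_along(grs)) {
      a <- sum(labels == cls[ci] & taxon_groups == grs[gi])
      b <- sum(labels == cls[ci] & taxon_groups != grs[gi])
      cc <- sum(labels != cls[ci] & taxon_groups == grs[gi])
      d <- sum(labels != cls[ci] & taxon_groups != grs[gi])
      tab <- matrix(c(a, b, cc, d), 2L)
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) next
      out[ci, gi] <- stats::fisher.test(tab)$p.value
    }
  }
  out
}

#' Classify taxa into driver groups
#'
#' The full classification stage: t-SNE embedding of the variance-explained
#' profiles, k-means on the embedding coordinates, and per-cluster dominant
#' driver identification.  Reproducible bit-for-bit under a fixed seed.
#'
#' @param profiles taxa x predictors matrix of variance proportions (the
#'   six predictor columns are used; `fixed`/`residual` are ignored for the
#'   driver tests).
#' @param k number of k-means clusters (default 8).
#' @param perplexity,max_iter t-SNE parameters (defaults 5 and 5000).
#' @param seed integer master seed.
#' @param on_profiles cluster on the raw profiles instead of the t-SNE
#'   coordinates (escape hatch; embedding-space clustering is seed
#'   sensitive).
#' @return object of class `driver_cluster_report`: `labels`, `embedding`,
#'   `drivers`, `pca`, `pca_no_residual`.
#' @export
classify_drivers <- function(profiles, k = 8, perplexity = 5, max_iter = 5000,
                             seed = 1L, on_profiles = FALSE) {
  profiles <- as.matrix(profiles)
  embedding <- embed_tsne(profiles[, intersect(colnames(profiles),
                                               c(predictor_names(), "residual")),
                                   drop = FALSE],
                          perplexity = perplexity, max_iter = max_iter,
                          seed = seed)
  space <- if (on_profiles) profiles else embedding
  labels <- cluster_kmeans(space, k = k, seed = seed + 1L)
  drivers <- identify_cluster_drivers(labels, profiles)
  structure(list(
    labels = stats::setNames(as.integer(labels), rownames(profiles)),
    embedding = embedding,
    drivers = drivers,
    pca = if (nrow(profiles) >= 3L) {
      pca_diagnostics(profiles, include_residual = TRUE)
    },
    pca_no_residual = if (nrow(profiles) >= 3L) {
      pca_diagnostics(profiles, include_residual = FALSE)
    }
  ), class = "driver_cluster_report")
}
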