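#' Taxonomy tree from a parent-child table
#'
#' @param nodes data.frame with columns `id` and `parent` (the root points to
#'   itself or has `NA` parent) and optionally `name` and `rank`.
#' @return object of class `taxonomy_tree`: `parent` (named vector), `depth`
#'   (root = 0), `name`, `rank`, `root`.
#' @export
taxonomy_tree <- function(nodes) {
  id <- as.character(nodes$id)
  parent <- as.character(nodes$parent)
  if (anyDuplicated(id)) stop_input("duplicate taxonomy node ids")
  root <- id[is.na(parent) | parent == id]
  if (length(root) != 1L) stop_input("taxonomy must have a single root")
  parent[is.na(parent)] <- root
  names(parent) <- id
  if (!all(parent %in% id)) stop_input("parent ids missing from the tree")
  depth <- stats::setNames(rep(NA_integer_, length(id)), id)
  depth[root] <- 0L
  for (nd in id) {
    if (!is.na(depth[nd])) next
    chain <- nd
    cur <- nd
    while (is.na(depth[cur])) {
      cur <- parent[[cur]]
      if (cur %in% chain) stop_input("taxonomy contains a cycle")
      chain <- c(chain, cur)
    }
    d <- depth[[cur]]
    for (x in rev(chain[-length(chain)])) {
      d <- d + 1L
      depth[x] <- d
    }
  }
  nm <- if (is.null(nodes$name)) id else as.character(nodes$name)
  rk <- if (is.null(nodes$rank)) rep(NA_character_, length(id)) else
    as.character(nodes$rank)
  structure(list(parent = parent, depth = depth, root = root,
                 name = stats::setNames(nm, id),
                 rank = stats::setNames(rk, id)),
            class = "taxonomy_tree")
}

# node and all its ancestors up to the root
ancestry <- function(tree, node) {
  path <- node
  while (node != tree$root) {
    node <- tree$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Filter a hit table by E-value and per-query cap
#'
#' Keeps hits with `evalue` strictly below the threshold, then at most
#' `per_query_cap` hits per query by descending bitscore (ties broken by
#' taxon id).
#'
#' @param hits data.frame with columns `query_id`, `taxon_id`, `bitscore`,
#'   `evalue`.
#' @param evalue_max strict E-value threshold (default 1e-5).
#' @param per_query_cap maximum hits per query (default 10).
#' @return the filtered hit table.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, per_query_cap = 10) {
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                        function(idx) {
    ord <- idx[order(-hits$bitscore[idx], hits$taxon_id[idx])]
    utils::head(ord, per_query_cap)
  }), use.names = FALSE)
  hits[sort(keep), , drop = FALSE]
}

#' Bitscore-weighted fuzzy lowest common ancestor of one query's hits
#'
#' Each hit's bitscore is propagated from its taxon up to the root; the
#' assignment is the deepest node whose accumulated bitscore covers at least
#' a fraction `r` of the total.  With `r = 1` this reduces to the strict LCA
#' of all hit taxa; smaller `r` tolerates a minority of discordant hits.  For
#' `r > 0.5` the qualifying node at maximal depth is unique on a tree.
#'
#' @param hits data.frame with columns `taxon_id` and `bitscore` (the hits of
#'   a single query, already filtered).
#' @param tree a [taxonomy_tree()].
#' @param r bitscore coverage ratio in (0, 1\] (default 0.67).
#' @return the assigned taxon id, or `NA` if no hit taxon is in the tree.
#' @export
fuzzy_lca <- function(hits, tree, r = 0.67) {
  if (r <= 0 || r > 1) stop_param("r must lie in (0, 1]")
  known <- hits$taxon_id %in% names(tree$parent)
  if (any(!known)) {
    warning(sprintf("%d hit(s) with taxa absent from the tree skipped",
                    sum(!known)))
    hits <- hits[known, , drop = FALSE]
  }
  if (!nrow(hits)) return(NA_character_)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    for (nd in ancestry(tree, as.character(hits$taxon_id[i]))) {
      assign(nd, (get0(nd, envir = acc) %||% 0) + hits$bitscore[i],
             envir = acc)
    }
  }
  total <- sum(hits$bitscore)
  nodes <- ls(acc)
  scores <- vapply(nodes, get, numeric(1), envir = acc)
  qualifying <- nodes[scores >= r * total - 1e-9]
  depths <- tree$depth[qualifying]
  deepest <- qualifying[depths == max(depths)]
  if (r > 0.5 && length(deepest) > 1L) {
    stop("multiple equally deep qualifying nodes with r > 0.5 (tree invariant violated)")
  }
  sort(deepest)[1]
}

#' Aggregate per-query assignments into a species-level assignment
#'
#' For every source hit table, the species is assigned the plurality taxon of
#' its queries' assignments; the per-source assignments are then reported at
#' three widening levels, ordered by decreasing depth and padded with
#' ancestors of the most precise assignment when fewer than three sources
#' agree on distinct nodes.  Queries without any assignment are counted.
#'
#' @param assignments named list (one element per source) of character
#'   vectors of per-query taxon ids (`NA` = unassigned).
#' @param tree a [taxonomy_tree()].
#' @return list: `levels` (character, length 3, most precise first —
#'   `"unclassified"` when nothing is assigned), `per_source` (plurality
#'   taxon and dissent fraction per source), `n_unassigned`.
#' @export
assign_species <- function(assignments, tree) {
  per_source <- list()
  nodes <- character()
  n_unassigned <- 0L
  for (src in names(assignments)) {
    a <- assignments[[src]]
    n_unassigned <- n_unassigned + sum(is.na(a))
    a <- a[!is.na(a)]
    if (!length(a)) {
      per_source[[src]] <- list(taxon = NA_character_, dissent = NA_real_)
      next
    }
    tab <- sort(table(a), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    taxon <- sort(top)[1]
    per_source[[src]] <- list(taxon = taxon,
                              dissent = 1 - tab[[1]] / length(a))
    nodes <- c(nodes, taxon)
  }
  nodes <- unique(nodes)
  if (!length(nodes)) {
    return(list(levels = rep("unclassified", 3L), per_source = per_source,
                n_unassigned = n_unassigned))
  }
  nodes <- nodes[order(-tree$depth[nodes])]
  levels <- nodes
  while (length(levels) < 3L) {
    last <- levels[length(levels)]
    nxt <- if (last == tree$root) tree$root else tree$parent[[last]]
    levels <- c(levels, nxt)
  }
  list(levels = utils::head(levels, 3L), per_source = per_source,
       n_unassigned = n_unassigned)
}
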