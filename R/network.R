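#' Thresholded item correlation network
#'
#' Items whose pairwise correlation exceeds `threshold` (strictly) are
#' connected by an edge weighted by that correlation; items with no
#' supra-threshold correlation are kept aside as isolated selection
#' candidates rather than dropped.
#'
#' @param corr symmetric item x item correlation matrix with unit diagonal
#'   and item ids as dimnames, e.g. from [item_correlations()].
#' @param threshold edge threshold in (0, 1); default 0.70.
#' @return An object of class `item_network`: list with `nodes`,
#'   `edges` (data frame `item_a`, `item_b`, `weight`), `threshold`,
#'   `isolated_items`, `item_ids`, and `graph` (the igraph object over the
#'   networked nodes).
#' @export
build_network <- function(corr, threshold = 0.70) {
  corr <- as.matrix(corr)
  if (is.null(rownames(corr)))
    rownames(corr) <- colnames(corr) <- paste0("IP", seq_len(nrow(corr)))
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- rownames(corr)
  ut <- which(upper.tri(corr) & corr > threshold, arr.ind = TRUE)
  edges <- data.frame(item_a = ids[ut[, 1]], item_b = ids[ut[, 2]],
                      weight = corr[ut], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$item_a, edges$item_b)))
  nodes <- ids[ids %in% nodes]   # preserve input item order
  isolated <- setdiff(ids, nodes)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         isolated_items = isolated, item_ids = ids, graph = g),
    class = "item_network")
}

#' @export
print.item_network <- function(x, ...) {
  cat(sprintf(
    "Item network: %d of %d items above r > %.2f (%d edges, %d isolated)\n",
    length(x$nodes), length(x$item_ids), x$threshold,
    nrow(x$edges), length(x$isolated_items)))
  invisible(x)
}

#' Pooled item correlations
#'
#' Pearson (default), Spearman, or polychoric correlations of the item
#' columns, pooled across both groups, with reverse-keyed items recoded
#' first so that all correlations are on the keyed scale.
#'
#' @param matrix a [response_matrix()].
#' @param method `"pearson"`, `"spearman"` or `"polychoric"`.
#' @param reverse reverse-keyed item ids to recode before correlating.
#' @return Item x item correlation matrix.
#' @export
item_correlations <- function(matrix, method = c("pearson", "spearman", "polychoric"),
                              reverse = character()) {
  stopifnot(inherits(matrix, "response_matrix"))
  method <- match.arg(method)
  m <- recode_reversed(matrix, intersect(reverse, matrix$item_ids))
  if (method == "polychoric") {
    polychoric_matrix(m$values, n_categories = m$n_categories)$rho
  } else {
    stats::cor(m$values, method = method)
  }
}

#' Walktrap community detection on an item network
#'
#' Agglomerative community detection from short random-walk distances
#' (edge weights act as walk transition weights), returning the partition
#' on the merge path with maximum modularity.
#'
#' @param net an [build_network()] result.
#' @param steps random-walk length (default 4).
#' @return An object of class `community_partition`: list with `assignment`
#'   (named community index per networked node), `sizes`, `n_communities`,
#'   and `modularity`.
#' @export
walktrap_communities <- function(net, steps = 4L) {
  stopifnot(inherits(net, "item_network"))
  if (steps < 1) stop("steps must be >= 1")
  if (length(net$nodes) == 0) stop("network has no nodes")
  wt <- igraph::cluster_walktrap(net$graph, weights = igraph::E(net$graph)$weight,
                                 steps = steps)
  assignment <- igraph::membership(wt)
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  adj <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight",
                                               sparse = FALSE))
  assignment <- refine_partition(adj, assignment)
  assignment <- stats::setNames(match(assignment, unique(assignment)),
                                names(assignment))
  sizes <- table(assignment)
  structure(
    list(assignment = assignment,
         sizes = stats::setNames(as.integer(sizes), names(sizes)),
         n_communities = length(sizes),
         modularity = igraph::modularity(net$graph, assignment,
                                         weights = igraph::E(net$graph)$weight)),
    class = "community_partition")
}

# Greedy single-node-move refinement of a partition under weighted
# modularity: repeatedly move the node whose reassignment (to any other
# community or a new singleton) most increases modularity, until no move
# improves. Deterministic; polishes the merge-path cut on small graphs.
refine_partition <- function(adj, membership) {
  two_m <- sum(adj)
  if (two_m == 0) return(membership)
  k <- rowSums(adj)
  q_of <- function(memb) {
    same <- outer(memb, memb, "==")
    sum((adj - outer(k, k) / two_m) * same) / two_m
  }
  local_search <- function(memb) {
    q_best <- q_of(memb)
    repeat {
      improved <- FALSE
      # single-node moves (to any other community or a fresh singleton)
      for (i in seq_along(memb)) {
        for (cc in setdiff(unique(c(memb[-i], max(memb) + 1L)), memb[i])) {
          trial <- memb
          trial[i] <- cc
          q <- q_of(trial)
          if (q > q_best + 1e-12) {
            memb <- trial; q_best <- q; improved <- TRUE
          }
        }
      }
      # whole-community merges
      comms <- unique(memb)
      if (length(comms) > 1) {
        for (a in seq_along(comms)[-length(comms)])
          for (b in seq((a + 1), length(comms))) {
            trial <- memb
            trial[trial == comms[b]] <- comms[a]
            q <- q_of(trial)
            if (q > q_best + 1e-12) {
              memb <- trial; q_best <- q; improved <- TRUE
            }
          }
      }
      if (!improved) break
    }
    list(memb = memb, q = q_best)
  }
  cand1 <- local_search(membership)
  cand2 <- local_search(stats::setNames(seq_along(membership),
                                        names(membership)))
  if (cand2$q > cand1$q + 1e-12) cand2$memb else cand1$memb
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Walktrap partition: %d communities (sizes %s), modularity %.3f\n",
              x$n_communities,
              paste(sort(x$sizes, decreasing = TRUE), collapse = "/"),
              x$modularity))
  invisible(x)
}

#' Degree and eigenvector centrality of a weighted item network
#'
#' Degree is the count of incident edges. Eigenvector centrality is the
#' leading eigenvector of the weighted adjacency matrix, computed per
#' connected component and max-normalised to 1 within each component.
#'
#' @param net an [build_network()] result.
#' @return An object of class `centrality_table`: list of named vectors
#'   `degree` and `eigenvector` over the networked nodes.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "item_network"))
  if (length(net$nodes) == 0) stop("network has no nodes")
  g <- net$graph
  deg <- igraph::degree(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  comp <- igraph::components(g)$membership
  eig <- stats::setNames(numeric(length(deg)), names(deg))
  for (cc in unique(comp)) {
    idx <- names(comp)[comp == cc]
    if (length(idx) == 1) { eig[idx] <- 1; next }
    sub <- adj[idx, idx, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v <- es$vectors[, 1]
    v <- abs(v)           # Perron vector is sign-indeterminate; take >= 0
    eig[idx] <- v / max(v)
  }
  structure(list(degree = stats::setNames(as.integer(deg), names(deg)),
                 eigenvector = eig),
            class = "centrality_table")
}

#' Multi-strategy item selection
#'
#' Combines four complementary strategies into one deduplicated item set:
#' \enumerate{
#'   \item community representatives: for each community of size at least
#'     `min_community_size`, the member with highest discrimination d;
#'   \item isolated discriminators: the `k_isolated` isolated (off-network)
#'     items with highest d;
#'   \item central hubs: the `k_hubs` networked items with highest
#'     eigenvector centrality;
#'   \item top discriminators: the `k_top` items with highest d overall.
#' }
#' Ties are broken by higher d first, then lexicographic item id.
#'
#' @param d_values named per-item discrimination values covering all items.
#' @param net an [build_network()] result.
#' @param part a [walktrap_communities()] partition.
#' @param cent a [centralities()] table.
#' @param min_community_size smallest community granted a representative.
#' @param k_isolated,k_hubs,k_top strategy cardinalities.
#' @return An object of class `selection_result`: list with `selected`,
#'   `provenance` (list of strategy tags per selected item),
#'   `communities_covered`, and per-strategy sets.
#' @export
select_items <- function(d_values, net, part, cent,
                         min_community_size = 2L, k_isolated = 5L,
                         k_hubs = 8L, k_top = 12L) {
  stopifnot(inherits(net, "item_network"),
            inherits(part, "community_partition"),
            inherits(cent, "centrality_table"))
  if (length(net$item_ids) == 0) stop("empty item set")
  missing_d <- setdiff(net$item_ids, names(d_values))
  if (length(missing_d))
    stop("d_values missing for item(s): ", paste(missing_d, collapse = ", "))

  # deterministic ordering: higher d first, then item id; keys rounded so
  # numerically equal values (e.g. symmetric centralities) tie exactly
  rank_items <- function(ids, primary = d_values[ids]) {
    ids[order(-round(primary, 9), -round(d_values[ids], 9), ids)]
  }

  s_comm <- character()
  for (cc in names(part$sizes)) {
    members <- names(part$assignment)[part$assignment == as.integer(cc)]
    if (length(members) >= min_community_size)
      s_comm <- c(s_comm, rank_items(members)[1])
  }
  s_iso <- utils::head(rank_items(net$isolated_items), k_isolated)
  s_hub <- utils::head(rank_items(names(cent$eigenvector),
                                  primary = cent$eigenvector), k_hubs)
  s_top <- utils::head(rank_items(net$item_ids), k_top)

  strategies <- list(community_representative = s_comm,
                     isolated_discriminator = s_iso,
                     central_hub = s_hub,
                     top_discriminator = s_top)
  selected <- sort(unique(unlist(strategies)))
  selected <- rank_items(selected)
  provenance <- lapply(stats::setNames(selected, selected), function(id)
    names(strategies)[vapply(strategies, function(s) id %in% s, logical(1))])
  covered <- unique(part$assignment[intersect(selected, names(part$assignment))])
  structure(
    list(selected = selected, provenance = provenance,
         communities_covered = length(covered),
         strategies = strategies),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selected %d items covering %d communities\n",
              length(x$selected), x$communities_covered))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Export an item network
#'
#' @param net an [build_network()] result.
#' @param path output file path.
#' @param format `"csv"` (edge list `item_a,item_b,weight`) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "graphml")) {
  stopifnot(inherits(net, "item_network"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}
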