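# Density-thresholded binary covariance graphs and regional topology.

#' Binarize an association matrix at a network density
#'
#' Keeps the top `floor(density * p(p-1)/2 + 0.5)` region pairs ranked by
#' signed correlation, descending (ties broken lexicographically by region
#' pair for determinism), and returns the corresponding undirected binary
#' graph without self-loops. Because selection is by rank, edge sets are
#' nested across densities.
#'
#' @param assoc An `association_matrix`.
#' @param density Target density in (0, 0.5].
#' @param rank_by `"signed"` (default) or `"absolute"` correlation.
#' @return A `binary_graph`: list with `region_ids`, binary `adjacency`
#'   and `density`.
#' @export
binarize_at_density <- function(assoc, density,
                                rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(assoc, "association_matrix"))
  if (density <= 0 || density > 0.5)
    stop("density must lie in (0, 0.5]")
  p <- length(assoc$region_ids)
  pairs <- which(upper.tri(assoc$r), arr.ind = TRUE)
  val <- assoc$r[pairs]
  if (rank_by == "absolute") val <- abs(val)
  m_edges <- floor(density * p * (p - 1) / 2 + 0.5)
  if (m_edges < 1) stop("density ", density, " yields zero edges")
  ord <- order(-val, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(m_edges)], , drop = FALSE]
  adj <- matrix(0L, p, p, dimnames = list(assoc$region_ids,
                                          assoc$region_ids))
  adj[keep] <- 1L
  adj[keep[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(region_ids = assoc$region_ids, adjacency = adj,
                 density = density),
            class = "binary_graph")
}

# breadth-first search connectivity on an adjacency matrix
.bfs_connected <- function(adj) {
  p <- nrow(adj)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Minimum density at which both groups' graphs are connected
#'
#' Scans the density grid `{step, 2*step, ..., d_max}` and returns the
#' smallest density whose binarized graphs form a single connected
#' component (breadth-first search) in both groups.
#'
#' @param assoc_a,assoc_b `association_matrix` objects on the same nodes.
#' @param step Grid step, in (0, 0.1] (default 0.02).
#' @param d_max Maximum density tried (default 0.5).
#' @return The minimum connecting density (a grid member).
#' @export
find_dmin <- function(assoc_a, assoc_b, step = 0.02, d_max = 0.5) {
  if (step <= 0 || step > 0.1) stop("step must lie in (0, 0.1]")
  if (length(assoc_a$region_ids) != length(assoc_b$region_ids))
    stop("association matrices differ in node count")
  p <- length(assoc_a$region_ids)
  grid <- seq(step, d_max + 1e-12, by = step)
  for (d in grid) {
    # a grid point keeping fewer edges than a spanning tree cannot connect
    if (floor(d * p * (p - 1) / 2 + 0.5) < p - 1) next
    ga <- binarize_at_density(assoc_a, d)
    gb <- binarize_at_density(assoc_b, d)
    if (.bfs_connected(ga$adjacency) && .bfs_connected(gb$adjacency))
      return(d)
  }
  stop("graphs not connected at any density up to ", max(grid))
}

#' Regional topology of a binary graph
#'
#' Degree (row sums), betweenness centrality (raw shortest-path counts on
#' the unweighted undirected graph, each unordered endpoint pair counted
#' once) and local clustering (`2 * triangles / (k * (k - 1))`, 0 when the
#' degree is below 2).
#'
#' @param graph A `binary_graph`.
#' @return A `nodal_metrics` data frame: `region_id`, `density`, `degree`,
#'   `betweenness`, `clustering`.
#' @export
nodal_metrics <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected")
  deg <- as.integer(rowSums(graph$adjacency))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  clu <- igraph::transitivity(g, type = "local", isolates = "zero")
  clu[deg < 2] <- 0
  out <- data.frame(region_id = graph$region_ids, density = graph$density,
                    degree = deg, betweenness = unname(btw),
                    clustering = clu, stringsAsFactors = FALSE)
  class(out) <- c("nodal_metrics", "data.frame")
  out
}

# population SD (divisor n), used for the hub rule
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Hub detection by the mean + 2 SD rule
#'
#' Flags nodes whose density-integrated degree or betweenness strictly
#' exceeds the group mean by more than two (population) standard
#' deviations of the node scores.
#'
#' @param scores Data frame with columns `region_id`, `metric`
#'   (`degree`/`betweenness`) and `score` (density-integrated value), as
#'   produced by [integrate_metric_curves()].
#' @param group Group label recorded in the output.
#' @return A `hub_table` data frame of flagged nodes with the group mean
#'   and SD used; zero rows (with a warning) when an SD is zero.
#' @export
detect_hubs <- function(scores, group) {
  stopifnot(all(c("region_id", "metric", "score") %in% names(scores)))
  out <- list()
  # the hub rule applies to degree and betweenness only
  for (m in intersect(unique(scores$metric),
                      c("degree", "betweenness"))) {
    sub <- scores[scores$metric == m, ]
    if (nrow(sub) < 3) stop("need >= 3 nodes for hub detection")
    mu <- mean(sub$score); sdev <- .pop_sd(sub$score)
    if (sdev == 0) {
      warning("zero SD for metric '", m, "': no hubs detectable")
      next
    }
    hit <- sub$score > mu + 2 * sdev
    if (any(hit))
      out[[m]] <- data.frame(group = group, region_id = sub$region_id[hit],
                             metric = m, score = sub$score[hit],
                             group_mean = mu, group_sd = sdev,
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(), region_id = character(),
               metric = character(), score = numeric(),
               group_mean = numeric(), group_sd = numeric())
  rownames(res) <- NULL
  class(res) <- c("hub_table", "data.frame")
  res
}

#' Nodal metrics across a density sweep
#'
#' Binarizes one association matrix at every grid density and stacks the
#' per-density [nodal_metrics()].
#'
#' @param assoc An `association_matrix`.
#' @param densities Increasing density grid.
#' @return A `nodal_metrics` data frame over all densities.
#' @export
sweep_metrics <- function(assoc, densities) {
  do.call(rbind, lapply(densities, function(d)
    nodal_metrics(binarize_at_density(assoc, d))))
}

#' Integrate metric curves over the density sweep
#'
#' Collapses per-density nodal metrics to one score per node and metric by
#' the trapezoidal area under the metric-versus-density curve
#' (see [fda_auc()]).
#'
#' @param metrics Output of [sweep_metrics()].
#' @return Long data frame: `region_id`, `metric`, `score`.
#' @export
integrate_metric_curves <- function(metrics) {
  dens <- sort(unique(metrics$density))
  regions <- unique(metrics$region_id)
  metrics <- metrics[order(metrics$density), ]
  out <- list()
  for (m in c("degree", "betweenness", "clustering")) {
    curves <- matrix(metrics[[m]],
                     nrow = length(regions), ncol = length(dens),
                     dimnames = list(metrics$region_id[
                       metrics$density == dens[1]], NULL))
    auc <- apply(curves, 1, fda_auc, densities = dens)
    out[[m]] <- data.frame(region_id = names(auc), metric = m,
                           score = unname(auc), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a binary graph
#'
#' Writes the adjacency matrix and an edge list as TSV.
#'
#' @param graph A `binary_graph`.
#' @param prefix Path prefix; writes `<prefix>_adjacency.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return Written paths, invisibly.
#' @export
write_graph_tsv <- function(graph, prefix) {
  ap <- paste0(prefix, "_adjacency.tsv")
  df <- data.frame(region_id = graph$region_ids, graph$adjacency,
                   check.names = FALSE)
  utils::write.table(df, ap, sep = "\t", row.names = FALSE, quote = FALSE)
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0,
               arr.ind = TRUE)
  ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(
    data.frame(region_i = graph$region_ids[idx[, 1]],
               region_j = graph$region_ids[idx[, 2]]),
    ep, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(adjacency = ap, edges = ep))
}
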