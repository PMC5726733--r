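#' Path existence search in residue contact graphs
#'
#' The null model only needs to know whether any contiguous path joins the
#' two site residues inside an induced subgraph. Three routes are provided:
#' an A* best-first search ordered by f = g + h (g = accumulated Euclidean
#' step length between representative coordinates, h = straight-line
#' distance to the end residue; h is admissible for that g, and A* is
#' complete on finite graphs regardless of heuristic quality), a
#' goal-directed depth-first search that explores children closest to the
#' end residue first, and a plain breadth-first connectivity oracle with no
#' heuristic, kept as an independent reference. All tie-breaks are by node
#' index so fixed seeds give bit-identical runs.
#'
#' @name pathnull-search
#' @keywords internal
NULL

path_result <- function(found, path, nodes_expanded) {
  structure(list(found = found, path = as.integer(path),
                 nodes_expanded = as.integer(nodes_expanded)),
            class = "pn_path_result")
}

#' @export
print.pn_path_result <- function(x, ...) {
  if (x$found)
    cat(sprintf("<pn_path_result> found, %d nodes, %d expanded\n",
                length(x$path), x$nodes_expanded))
  else
    cat(sprintf("<pn_path_result> not found (%d expanded)\n", x$nodes_expanded))
  invisible(x)
}

check_search_args <- function(graph, start, end) {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
      length(end) != 1L)
    pn_stop("pathnull_input_error", "start/end must be single node indices")
  if (start == end)
    pn_stop("pathnull_input_error", "start and end must differ")
  if (!(start %in% graph$nodes) || !(end %in% graph$nodes))
    pn_stop("pathnull_input_error", "start or end is not a node of the graph")
}

reconstruct <- function(parent, end) {
  path <- end
  v <- end
  while (parent[v] != 0L) {
    v <- parent[v]
    path <- c(v, path)
  }
  path
}

# shared A* core over an adjacency list; `mask` (logical or NULL) restricts
# traversal without building an induced-subgraph object
astar_core <- function(adj, coords, start, end, mask = NULL) {
  n <- length(adj)
  g <- rep(Inf, n)
  f <- rep(Inf, n)
  parent <- integer(n)
  open <- logical(n)
  closed <- logical(n)
  ex <- coords[end, 1]; ey <- coords[end, 2]; ez <- coords[end, 3]
  h0 <- sqrt((coords[start, 1] - ex)^2 + (coords[start, 2] - ey)^2 +
               (coords[start, 3] - ez)^2)
  g[start] <- 0; f[start] <- h0; open[start] <- TRUE
  expanded <- 0L
  repeat {
    oi <- which(open)
    if (!length(oi)) return(path_result(FALSE, integer(0), expanded))
    cur <- oi[which.min(f[oi])]     # which.min takes the first (lowest index) tie
    open[cur] <- FALSE
    closed[cur] <- TRUE
    expanded <- expanded + 1L
    if (cur == end) return(path_result(TRUE, reconstruct(parent, end), expanded))
    nb <- adj[[cur]]
    if (!is.null(mask)) nb <- nb[mask[nb]]
    for (v in nb) {
      if (closed[v]) next
      gv <- g[cur] + sqrt(sum((coords[cur, ] - coords[v, ])^2))
      if (gv < g[v]) {
        g[v] <- gv
        f[v] <- gv + sqrt((coords[v, 1] - ex)^2 + (coords[v, 2] - ey)^2 +
                            (coords[v, 3] - ez)^2)
        parent[v] <- cur
        open[v] <- TRUE
      }
    }
  }
}

dfs_core <- function(adj, coords, start, end, mask = NULL) {
  n <- length(adj)
  visited <- logical(n)
  parent <- integer(n)
  ex <- coords[end, 1]; ey <- coords[end, 2]; ez <- coords[end, 3]
  stack <- integer(n)
  top <- 1L
  stack[1L] <- start
  visited[start] <- TRUE
  expanded <- 0L
  while (top > 0L) {
    cur <- stack[top]
    top <- top - 1L
    expanded <- expanded + 1L
    if (cur == end) return(path_result(TRUE, reconstruct(parent, end), expanded))
    nb <- adj[[cur]]
    if (!is.null(mask)) nb <- nb[mask[nb]]
    nb <- nb[!visited[nb]]
    if (length(nb)) {
      hd <- sqrt((coords[nb, 1] - ex)^2 + (coords[nb, 2] - ey)^2 +
                   (coords[nb, 3] - ez)^2)
      # closest-to-end explored first: push in reverse (farthest first);
      # ties by node index (adjacency is sorted, order() is stable)
      ord <- rev(order(hd))
      for (v in nb[ord]) {
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, integer(n))
        stack[top] <- v
        visited[v] <- TRUE
        parent[v] <- cur
      }
    }
  }
  path_result(FALSE, integer(0), expanded)
}

bfs_core <- function(adj, start, end, mask = NULL) {
  n <- length(adj)
  visited <- logical(n)
  parent <- integer(n)
  queue <- integer(n)
  qh <- 1L; qt <- 1L
  queue[1L] <- start
  visited[start] <- TRUE
  while (qh <= qt) {
    cur <- queue[qh]
    qh <- qh + 1L
    if (cur == end) return(list(found = TRUE, parent = parent))
    nb <- adj[[cur]]
    if (!is.null(mask)) nb <- nb[mask[nb]]
    for (v in nb) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- cur
        qt <- qt + 1L
        queue[qt] <- v
      }
    }
  }
  list(found = FALSE, parent = parent)
}

#' A* path existence between two residues
#'
#' Best-first search with f = g + h: g accumulates Euclidean step lengths
#' between representative coordinates, h is the straight-line distance to
#' the end residue. Complete on finite graphs: `found` is TRUE iff the end
#' is reachable. Deterministic (ties by node index).
#'
#' @param graph a `pn_graph` (typically an induced subgraph).
#' @param coords n x 3 matrix of per-node representative coordinates;
#'   defaults to the coordinates carried by the graph.
#' @param start,end distinct node indices present in the graph.
#' @return a `pn_path_result`: found flag, path (original node indices,
#'   empty when not found), and the number of nodes expanded.
#' @export
find_path_astar <- function(graph, coords = graph$rep_xyz, start, end) {
  check_search_args(graph, start, end)
  astar_core(graph$adj, coords, as.integer(start), as.integer(end))
}

#' Goal-directed depth-first path existence
#'
#' Iterative (explicit stack, no recursion, so MutS-scale subgraphs with
#' deep paths are safe) depth-first search that explores the child closest
#' to the end residue first; a visited set prevents revisits.
#'
#' @inheritParams find_path_astar
#' @return a `pn_path_result`.
#' @export
find_path_dfs <- function(graph, coords = graph$rep_xyz, start, end) {
  check_search_args(graph, start, end)
  dfs_core(graph$adj, coords, as.integer(start), as.integer(end))
}

#' Heuristic-free connectivity oracle
#'
#' Plain breadth-first search: TRUE iff start and end lie in the same
#' connected component. Kept deliberately independent of the heuristic
#' searches as a reference implementation.
#'
#' @inheritParams find_path_astar
#' @return logical flag.
#' @export
connected_oracle <- function(graph, start, end) {
  check_search_args(graph, start, end)
  bfs_core(graph$adj, as.integer(start), as.integer(end))$found
}

#' Fewest-hop shortest path (breadth-first)
#'
#' Returns a path with the minimum possible number of nodes; within a BFS
#' layer, neighbours are discovered in increasing node-index order, so the
#' result is deterministic.
#'
#' @inheritParams find_path_astar
#' @return a `pn_path_result` whose `path` has minimal node count.
#' @export
shortest_path <- function(graph, start, end) {
  check_search_args(graph, start, end)
  r <- bfs_core(graph$adj, as.integer(start), as.integer(end))
  if (!r$found) return(path_result(FALSE, integer(0), NA_integer_))
  path_result(TRUE, reconstruct(r$parent, as.integer(end)), NA_integer_)
}

#' Format a path in author residue numbering
#'
#' Renders a node-index path as e.g. `"376 -> 367 -> 388 -> 313"` using the
#' structure's author numbering (chain-qualified when the structure has
#' more than one chain).
#'
#' @param structure a `pn_structure`.
#' @param path integer vector of node indices.
#' @export
format_path <- function(structure, path) {
  res <- structure$residues[path, , drop = FALSE]
  lab <- if (length(unique(structure$residues$chain)) > 1L)
    paste0(res$chain, ":", res$resno, res$insert)
  else paste0(res$resno, res$insert)
  paste(lab, collapse = " -> ")
}
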