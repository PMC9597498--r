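#' Density-thresholded binary graph from a connectivity matrix
#'
#' Keeps the `k = floor(density * n(n-1)/2)` strongest off-diagonal
#' upper-triangle weights and symmetrizes.  Ties are broken by descending
#' weight, then ascending (row, column) index, so the graph is
#' deterministic even for constant matrices.
#'
#' @param conn Symmetric numeric matrix (e.g. a `connectivity_matrix`).
#' @param density Fraction of possible edges to keep, in `(0, 1]`;
#'   0.25 on 68 nodes gives exactly 569 edges.
#' @return A `binary_graph`: 0/1 adjacency matrix with attributes
#'   `density` and `n_edges`.
#' @export
binarize_by_density <- function(conn, density = 0.25) {
  if (density <= 0 || density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(conn)
  pairs <- which(upper.tri(conn), arr.ind = TRUE)
  w <- conn[pairs]
  k <- floor(density * n * (n - 1) / 2)
  ord <- order(-w, pairs[, 1], pairs[, 2])
  sel <- ord[seq_len(k)]
  A <- matrix(0L, n, n, dimnames = dimnames(conn))
  A[pairs[sel, , drop = FALSE]] <- 1L
  A <- A + t(A)
  attr(A, "density") <- density
  attr(A, "n_edges") <- k
  class(A) <- c("binary_graph", "matrix")
  A
}

#' All-pairs shortest path lengths of a binary graph
#'
#' Unit-weight breadth-first distances; unreachable pairs are `Inf`.
#'
#' @param graph 0/1 adjacency matrix.
#' @return Integer-valued distance matrix (`Inf` for unreachable pairs,
#'   0 on the diagonal).
#' @export
shortest_paths_bfs <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(unclass_graph(graph),
                                           mode = "undirected")
  igraph::distances(g, algorithm = "unweighted")
}

unclass_graph <- function(graph) {
  a <- unclass(graph)
  attr(a, "density") <- NULL
  attr(a, "n_edges") <- NULL
  storage.mode(a) <- "double"
  a
}

local_clustering <- function(A) {
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2))
}

#' Nodal and global graph metrics with small-worldness
#'
#' Degree, local clustering coefficient (0 when degree < 2), nodal
#' characteristic path length (mean finite BFS distance from the node;
#' unreachable pairs are excluded and their fraction reported), global
#' characteristic path length over ordered reachable pairs, mean
#' clustering, and small-worldness
#' `sigma = (C / C_rand) / (L / L_rand)` where the reference values are
#' averaged over degree-preserving double-edge-swap surrogates.
#'
#' @param graph 0/1 adjacency matrix (a [binarize_by_density()] result).
#' @param n_surrogates Number of rewired surrogates for sigma (0 skips
#'   sigma).
#' @param rewires_per_edge Double-edge swaps per edge in each surrogate.
#' @param seed Integer seed for the surrogate rewiring.
#' @return A `graph_metrics` list: `nodal` data frame (`node`, `degree`,
#'   `clustering`, `path_length`), `global` list (`L`, `C`, `sigma`,
#'   `C_rand`, `L_rand`, `unreachable_frac`), and surrogate metadata.
#' @export
graph_metrics <- function(graph, n_surrogates = 20, rewires_per_edge = 10,
                          seed = 1) {
  A <- unclass_graph(graph)
  n <- nrow(A)
  n_edges <- sum(A) / 2
  if (n_edges == 0)
    return(structure(list(nodal = data.frame(
      node = rownames(A) %||% seq_len(n), degree = 0,
      clustering = NA_real_, path_length = NA_real_),
      global = list(L = NA_real_, C = NA_real_, sigma = NA_real_,
                    C_rand = NA_real_, L_rand = NA_real_,
                    unreachable_frac = 1),
      surrogates = list(n = n_surrogates, rewires_per_edge = rewires_per_edge,
                        seed = seed)),
      class = "graph_metrics"))
  deg <- rowSums(A)
  clus <- local_clustering(A)
  D <- shortest_paths_bfs(A)
  off <- D; diag(off) <- NA
  nodal_L <- apply(off, 1, function(d) {
    d <- d[!is.na(d)]
    fin <- is.finite(d)
    if (!any(fin)) NA_real_ else mean(d[fin])
  })
  finite_off <- is.finite(off) & !is.na(off)
  unreach <- 1 - sum(finite_off, na.rm = TRUE) / (n * (n - 1))
  global_L <- mean(off[finite_off])
  C <- mean(clus)

  sigma <- C_rand <- L_rand <- NA_real_
  if (n_surrogates > 0) {
    set.seed(seed)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cs <- ls <- numeric(n_surrogates)
    for (s in seq_len(n_surrogates)) {
      gs <- igraph::rewire(g, igraph::keeping_degseq(
        niter = rewires_per_edge * n_edges))
      As <- as.matrix(igraph::as_adjacency_matrix(gs))
      cs[s] <- mean(local_clustering(As))
      Ds <- igraph::distances(gs, algorithm = "unweighted")
      diag(Ds) <- NA
      ls[s] <- mean(Ds[is.finite(Ds) & !is.na(Ds)])
    }
    C_rand <- mean(cs)
    L_rand <- mean(ls)
    if (C_rand > 0 && is.finite(global_L) && L_rand > 0)
      sigma <- (C / C_rand) / (global_L / L_rand)
  }
  structure(list(
    nodal = data.frame(node = rownames(A) %||% as.character(seq_len(n)),
                       degree = deg, clustering = clus,
                       path_length = nodal_L, row.names = NULL),
    global = list(L = global_L, C = C, sigma = sigma,
                  C_rand = C_rand, L_rand = L_rand,
                  unreachable_frac = unreach),
    surrogates = list(n = n_surrogates, rewires_per_edge = rewires_per_edge,
                      seed = seed)),
    class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  g <- x$global
  cat(sprintf("<graph_metrics> L = %.3f, C = %.3f, sigma = %s, unreachable = %.1f%%\n",
              g$L, g$C,
              if (is.na(g$sigma)) "NA" else sprintf("%.3f", g$sigma),
              100 * g$unreachable_frac))
  invisible(x)
}
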