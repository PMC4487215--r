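#' Partition a network by a complex catalogue
#'
#' Turns each catalogue complex into a candidate subnetwork of `net` by
#' intersecting its membership with the network's node set, preserving
#' catalogue order. Complexes with no member present are dropped with a
#' warning.
#'
#' @param catalogue Complex catalogue tibble (see [read_complexes()]).
#' @param net The [ppi_network] being partitioned.
#' @return A tibble of subnetworks: `subnetwork_id`, `members` (list of
#'   character vectors), `origin` (`"known_complex"`), `source_network`.
#' @export
partition_from_catalogue <- function(catalogue, net) {
  nodes <- network_nodes(net)
  members <- lapply(catalogue$members, function(m) intersect(m, nodes))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sprintf("partition_from_catalogue: dropped %d complex(es) with no member in network '%s'",
                    sum(empty), net$species))
  }
  tibble::tibble(
    subnetwork_id = catalogue$complex_id[!empty],
    members = members[!empty],
    origin = "known_complex",
    source_network = net$species
  )
}

#' Markov clustering (MCL) partition of a PPI network
#'
#' A compact implementation of standard MCL used as the built-in
#' partitioner: the column-stochastic adjacency matrix (with self-loops)
#' is alternately expanded (matrix squaring) and inflated (entrywise power
#' followed by column renormalisation) until the matrix changes by less than
#' `tol` or `max_iter` rounds elapse; clusters are then read off the
#' attractor rows. The result is a set of non-overlapping subnetworks
#' covering all non-isolated nodes (isolated nodes form singletons).
#' Self-loops are weighted by each node's maximum incident weight (1 for an
#' unweighted network).
#'
#' @param net A [ppi_network].
#' @param inflation Inflation exponent (> 1); default 2.
#' @param max_iter Maximum expansion/inflation rounds; default 100.
#' @param tol Convergence threshold on the max absolute entry change;
#'   default 1e-6.
#' @param prune Entries below this value are zeroed after inflation to keep
#'   the matrix sparse; default 1e-8.
#' @return A subnetwork tibble as in [partition_from_catalogue()], with
#'   `origin = "cluster"`, ordered by cluster size (largest first) then by
#'   smallest member ID.
#' @export
mcl_partition <- function(net, inflation = 2.0, max_iter = 100L, tol = 1e-6,
                          prune = 1e-8) {
  stopifnot(inflation > 1)
  nodes <- network_nodes(net)
  n <- length(nodes)
  if (n == 0L) {
    return(tibble::tibble(subnetwork_id = character(), members = list(),
                          origin = character(), source_network = character()))
  }
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  adj <- methods::as(methods::as(adj, "dMatrix"), "generalMatrix")
  M <- adj + Matrix::Diagonal(n, x = 1)  # self-loops at max incident weight
  colnorm <- function(m) {
    cs <- Matrix::colSums(m)
    cs[cs == 0] <- 1
    m %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- colnorm(M)
  for (iter in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                      # expansion
    M@x <- M@x^inflation              # inflation
    M <- Matrix::drop0(M, tol = prune)
    M <- colnorm(M)
    if (max(abs(M - prev)) < tol) break
  }
  # attractors: rows with a positive diagonal; each column joins the cluster
  # of the attractors it flows to, merged when attractors share columns
  M <- Matrix::drop0(M, tol = prune)
  S <- methods::as(M, "TsparseMatrix")
  memb_graph <- igraph::graph_from_data_frame(
    data.frame(from = nodes[S@i + 1L], to = nodes[S@j + 1L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(memb_graph)
  members <- split(nodes, comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), ""))
  members <- unname(members[ord])
  tibble::tibble(
    subnetwork_id = sprintf("MCL%03d", seq_along(members)),
    members = members,
    origin = "cluster",
    source_network = net$species
  )
}
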