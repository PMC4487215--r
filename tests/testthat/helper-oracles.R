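# Independent brute-force oracles used to validate the implementation.
# These deliberately use plain dense base-R arithmetic and explicit loops,
# not the package's sparse code paths.

# dense reference for the unbalanced bi-random walk recurrence
walk_oracle <- function(P, H, A, l, r, alpha = 0.5) {
  P <- as.matrix(P); H <- as.matrix(H); A <- as.matrix(A)
  R <- A
  tmax <- max(l, r)
  if (tmax > 0) {
    for (t in seq_len(tmax)) {
      lp <- as.numeric(t <= l)
      lh <- as.numeric(t <= r)
      R <- alpha * (lp * (P %*% R) + lh * (R %*% H)) / (lp + lh) +
        (1 - alpha) * A
    }
  }
  R
}

# all-pairs shortest paths by Floyd-Warshall on an edge list
apsp_oracle <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges[k, 1], nodes); j <- match(edges[k, 2], nodes)
      d[i, j] <- 1; d[j, i] <- 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Erdos-Renyi test network with string node names
random_net <- function(n, p, prefix = "n", species = "rand") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(as.data.frame(pairs[keep, , drop = FALSE]),
              species, nodes = nodes)
}

# random binary seed matrix between two node sets
random_seed_matrix <- function(net1, net2, p = 0.2) {
  n1 <- network_nodes(net1); n2 <- network_nodes(net2)
  m <- matrix(as.numeric(stats::runif(length(n1) * length(n2)) < p),
              length(n1), length(n2), dimnames = list(n1, n2))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
}

# random solution sets for the overlap-filter stress test
random_solution_set <- function(n_sol, pool_size = 15) {
  pool1 <- sprintf("a%02d", seq_len(pool_size))
  pool2 <- sprintf("b%02d", seq_len(pool_size))
  tibble::tibble(
    solution_id = sprintf("S%03d", seq_len(n_sol)),
    members_one = lapply(seq_len(n_sol), function(i)
      sort(sample(pool1, sample(1:8, 1)))),
    members_two = lapply(seq_len(n_sol), function(i)
      sort(sample(pool2, sample(1:8, 1))))
  )
}

# tiny hand-built GO fixture: one BP namespace, five terms under a root
# root <- t1, t2; t3 is_a t1; t4 is_a t1 and part_of t2
toy_ontology <- function() {
  tibble::tibble(
    id = c("GO:0", "GO:1", "GO:2", "GO:3", "GO:4"),
    name = c("root", "t1", "t2", "t3", "t4"),
    namespace = "biological_process",
    parents = list(character(), "GO:0", "GO:0", "GO:1", c("GO:1", "GO:2"))
  )
}

toy_annotations <- function() {
  tibble::tibble(
    protein = c("p1", "p2", "p3", "p4"),
    term = c("GO:3", "GO:4", "GO:2", "GO:1")
  )
}

# brute-force Resnik on the toy fixture: enumerate ancestors explicitly.
# `p` is the term-probability vector of the annotation corpus in use; the
# default corresponds to toy_annotations() (closures: p1 {3,1,0},
# p2 {4,1,2,0}, p3 {2,0}, p4 {1,0}).
toy_resnik_oracle <- function(t1, t2,
                              p = c("GO:0" = 4 / 4, "GO:1" = 3 / 4,
                                    "GO:2" = 2 / 4, "GO:3" = 1 / 4,
                                    "GO:4" = 1 / 4)) {
  anc <- list("GO:0" = "GO:0",
              "GO:1" = c("GO:1", "GO:0"),
              "GO:2" = c("GO:2", "GO:0"),
              "GO:3" = c("GO:3", "GO:1", "GO:0"),
              "GO:4" = c("GO:4", "GO:1", "GO:2", "GO:0"))
  common <- intersect(anc[[t1]], anc[[t2]])
  max(-log(p[common]))
}

# standard pipeline wiring used by several tests
build_pipeline <- function(bench, l = 2, r = 2, alpha = 0.5) {
  A <- build_seed_matrix(bench$homology, bench$net1, bench$net2)
  R <- bi_random_walk(transition_matrix(bench$net1, "row"),
                      transition_matrix(bench$net2, "column"),
                      A, l = l, r = r, alpha = alpha)
  subs <- partition_from_catalogue(bench$catalogue, bench$net1)
  align_networks(bench$net1, bench$net2, subs, NULL, R, A, l = l, r = r)
}
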