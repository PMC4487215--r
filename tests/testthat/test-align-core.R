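# small fixtures used by the step-by-step traces
mirror_pair <- function() {
  n1 <- ppi_network(data.frame(a = "u1", b = "u2"), "one")
  n2 <- ppi_network(data.frame(a = "v1", b = "v2"), "two")
  hom <- tibble::tibble(protein_a = c("u1", "u2"),
                        protein_b = c("v1", "v2"),
                        e_ab = 1e-50, e_ba = 1e-50)
  A <- build_seed_matrix(hom, n1, n2)
  R <- bi_random_walk(transition_matrix(n1, "row"),
                      transition_matrix(n2, "column"), A, 2, 2)
  list(n1 = n1, n2 = n2, A = A, R = R)
}

named_matrix <- function(rows, cols, entries) {
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (e in entries) m[e[[1]], e[[2]]] <- as.numeric(e[[3]])
  methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
}

test_that("bounded connectivity respects the path-length threshold", {
  net <- ppi_network(data.frame(a = c("a", "b", "c", "d"),
                                b = c("b", "c", "d", "e")), "path")
  expect_true(bounded_connected(net, "a", "b", 2))
  expect_true(bounded_connected(net, c("a", "b"), "d", 2))
  expect_false(bounded_connected(net, "a", "d", 2))   # shortest path 3
  expect_false(bounded_connected(net, "a", "zz", 2))  # absent candidate
  expect_false(bounded_connected(net, character(), "a", 2))
})

test_that("a mirrored edge pair grows into the full conserved pair", {
  fx <- mirror_pair()
  sol <- grow_modules(c("u1", "u2"), fx$n1, fx$n2, fx$R, fx$A, l = 2)
  expect_equal(sol$members_one, c("u1", "u2"))
  expect_equal(sol$members_two, c("v1", "v2"))
  sol <- refine_module_two(sol, fx$n2, fx$R, fx$A, r = 2)
  sol <- attach_isolated(sol, c("u1", "u2"), fx$n2, fx$A, r = 2)
  expect_equal(sol$members_one, c("u1", "u2"))
  expect_equal(sol$members_two, c("v1", "v2"))
  # and align() emits exactly one solution for it
  subs <- tibble::tibble(subnetwork_id = "K1",
                         members = list(c("u1", "u2")),
                         origin = "known_complex", source_network = "one")
  res <- align_networks(fx$n1, fx$n2, subs, NULL, fx$R, fx$A, 2, 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$members_one[[1]], c("u1", "u2"))
  expect_equal(nrow(res$links[[1]]), 2L)
})

test_that("a subnetwork member without walk support stays out of ModuleOne", {
  # u3 is adjacent to u2 but its walk-matrix row is empty, so it shares no
  # homolog with any neighbour and is never admitted
  n1 <- ppi_network(data.frame(a = c("u1", "u2"), b = c("u2", "u3")), "one")
  n2 <- ppi_network(data.frame(a = "v1", b = "v2"), "two")
  A <- named_matrix(c("u1", "u2", "u3"), c("v1", "v2"),
                    list(list("u1", "v1", 1), list("u2", "v2", 1)))
  R <- named_matrix(c("u1", "u2", "u3"), c("v1", "v2"),
                    list(list("u1", "v1", 0.6), list("u1", "v2", 0.2),
                         list("u2", "v1", 0.2), list("u2", "v2", 0.6)))
  sol <- grow_modules(c("u1", "u2", "u3"), n1, n2, R, A, l = 1)
  expect_setequal(sol$members_one, c("u1", "u2"))
  expect_false("u3" %in% sol$members_one)
})

test_that("a single seed-linked member yields a (1,1) degenerate solution", {
  n1 <- ppi_network(NULL, "one", nodes = "u1")
  n2 <- ppi_network(NULL, "two", nodes = "v1")
  A <- named_matrix("u1", "v1", list(list("u1", "v1", 1)))
  R <- A * 0.5
  sol <- grow_modules("u1", n1, n2, R, A, l = 2)
  expect_equal(sol$members_one, "u1")
  expect_equal(sol$members_two, "v1")
})

test_that("isolated subnetwork members attach through their homolog (Step 3)", {
  n1 <- ppi_network(data.frame(a = "u1", b = "u2"), "one",
                    nodes = c("u1", "u2", "u3"))
  n2 <- ppi_network(data.frame(a = c("v1", "v2"), b = c("v2", "v3")), "two")
  hom <- tibble::tibble(protein_a = c("u1", "u2", "u3"),
                        protein_b = c("v1", "v2", "v3"),
                        e_ab = 1e-50, e_ba = 1e-50)
  A <- build_seed_matrix(hom, n1, n2)
  R <- bi_random_walk(transition_matrix(n1, "row"),
                      transition_matrix(n2, "column"), A, 2, 2)
  sub <- c("u1", "u2", "u3")
  sol <- grow_modules(sub, n1, n2, R, A, l = 2)
  expect_setequal(sol$members_one, c("u1", "u2"))  # u3 is isolated in net one
  sol <- refine_module_two(sol, n2, R, A, r = 2)
  sol <- attach_isolated(sol, sub, n2, A, r = 2)
  expect_setequal(sol$members_one, c("u1", "u2", "u3"))
  expect_setequal(sol$members_two, c("v1", "v2", "v3"))

  # homolog beyond depth r is not attached; enlarging r attaches it
  n2b <- ppi_network(data.frame(a = c("v1", "v2", "x"),
                                b = c("v2", "x", "v3")), "two")
  sol0 <- list(members_one = c("u1", "u2"), members_two = c("v1", "v2"),
               origin = NA_character_)
  r1 <- attach_isolated(sol0, sub, n2b, A, r = 1)
  expect_false("u3" %in% r1$members_one)
  r2 <- attach_isolated(sol0, sub, n2b, A, r = 2)
  expect_true("u3" %in% r2$members_one)
  expect_true("v3" %in% r2$members_two)
  for (rr in 1:4) {
    expect_gte(length(attach_isolated(sol0, sub, n2b, A, r = rr)$members_one),
               length(attach_isolated(sol0, sub, n2b, A,
                                      r = max(rr - 1, 1))$members_one))
  }
  # members with no seed link are never attached
  hom2 <- hom[1:2, ]
  A2 <- build_seed_matrix(hom2, n1, n2)
  r3 <- attach_isolated(sol0, sub, n2, A2, r = 3)
  expect_false("u3" %in% r3$members_one)
})

test_that("Step-2 exclusion removes covered singletons and keeps the heaviest rival", {
  n2 <- ppi_network(data.frame(a = "v1", b = "v2"), "two",
                    nodes = c("v1", "v2", "w1", "w2"))
  A <- named_matrix(c("u1", "u2"), c("v1", "v2", "w1", "w2"),
                    list(list("u1", "v1", 1), list("u2", "v2", 1),
                         list("u1", "w1", 1), list("u1", "w2", 1)))
  R <- named_matrix(c("u1", "u2"), c("v1", "v2", "w1", "w2"),
                    list(list("u1", "v1", 0.5), list("u2", "v2", 0.5),
                         list("u1", "w1", 0.2), list("u1", "w2", 0.1)))
  sol <- list(members_one = c("u1", "u2"),
              members_two = c("v1", "v2", "w1", "w2"),
              origin = NA_character_)
  out <- refine_module_two(sol, n2, R, A, r = 2)
  expect_setequal(out$members_two, c("v1", "v2"))

  # two uncovered singletons competing for the same counterpart: higher
  # weight wins; on a tie the lexicographically smallest survives
  n2b <- ppi_network(NULL, "two", nodes = c("w1", "w2"))
  Ab <- named_matrix("u1", c("w1", "w2"),
                     list(list("u1", "w1", 1), list("u1", "w2", 1)))
  Rb <- named_matrix("u1", c("w1", "w2"),
                     list(list("u1", "w1", 0.7), list("u1", "w2", 0.3)))
  solb <- list(members_one = "u1", members_two = c("w1", "w2"),
               origin = NA_character_)
  expect_equal(refine_module_two(solb, n2b, Rb, Ab, r = 2)$members_two, "w1")
  Rtie <- named_matrix("u1", c("w1", "w2"),
                       list(list("u1", "w1", 0.5), list("u1", "w2", 0.5)))
  expect_equal(refine_module_two(solb, n2b, Rtie, Ab, r = 2)$members_two, "w1")
  # a connected pair is left untouched
  fx <- mirror_pair()
  sol1 <- list(members_one = c("u1", "u2"), members_two = c("v1", "v2"),
               origin = NA_character_)
  expect_equal(refine_module_two(sol1, fx$n2, fx$R, fx$A, r = 2)$members_two,
               c("v1", "v2"))
})

test_that("overlap filtering removes only strictly-larger dominated solutions", {
  mk <- function(...) {
    sets <- list(...)
    tibble::tibble(
      solution_id = sprintf("S%d", seq_along(sets)),
      members_one = sets,
      members_two = lapply(seq_along(sets), function(i) c("z1", "z2"))
    )
  }
  # identical sets: no strictly larger complex, both kept
  expect_equal(nrow(filter_overlaps(mk(c("a", "b", "c"), c("a", "b", "c")))), 2L)
  # OS = 9/12 = 0.75 <= 0.8: both kept
  expect_equal(nrow(filter_overlaps(mk(c("a", "b", "c", "d"),
                                       c("a", "b", "c")))), 2L)
  # boundary OS = 16/20 = 0.8 exactly: strict inequality keeps both
  expect_equal(nrow(filter_overlaps(mk(c("a", "b", "c", "d", "e"),
                                       c("a", "b", "c", "d")))), 2L)
  # OS = 25/30 > 0.8 against a larger complex: the smaller one is removed
  filtered <- filter_overlaps(mk(c("a", "b", "c", "d", "e", "f"),
                                 c("a", "b", "c", "d", "e")))
  expect_equal(nrow(filtered), 1L)
  expect_length(filtered$members_one[[1]], 6L)
  expect_error(filter_overlaps(mk(c("a")), t = 0), "t must")
})

test_that("retained solutions never violate the removal rule (re-scan)", {
  set.seed(404)
  for (case in 1:50) {
    sols <- random_solution_set(sample(5:15, 1))
    kept <- filter_overlaps(sols, t = 0.8)
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept))) {
      for (j in seq_len(nrow(kept))) {
        if (i == j) next
        bigger <- kept$members_one[[j]]
        smaller <- kept$members_one[[i]]
        if (length(bigger) > length(smaller)) {
          expect_lte(overlap_score(bigger, smaller), 0.8)
        }
      }
    }
  }
})

test_that("distinct complexes drop duplicates and singletons", {
  sols <- tibble::tibble(
    solution_id = sprintf("S%d", 1:5),
    members_one = list(c("a", "b"), c("b", "a"), c("c"),
                       c("d", "e", "f"), c("a", "b")),
    members_two = list(c("x", "y"), c("x", "y"), c("q", "r"),
                       c("x", "z"), c("y", "x"))
  )
  d1 <- distinct_complexes(sols, "one")
  expect_equal(d1, list(c("a", "b"), c("d", "e", "f")))
  expect_length(distinct_complexes(sols, "two"), 3L)
  expect_length(distinct_complexes(sols[0, ], "one"), 0L)
})

test_that("emitted modules are internally connected under the leniency bounds", {
  bench <- generate_synthetic(synth_params(seed = 7))
  A <- build_seed_matrix(bench$homology, bench$net1, bench$net2)
  R <- bi_random_walk(transition_matrix(bench$net1, "row"),
                      transition_matrix(bench$net2, "column"), A, 2, 2)
  subs <- partition_from_catalogue(bench$catalogue, bench$net1)
  res <- align_networks(bench$net1, bench$net2, subs, NULL, R, A, 2, 2)
  expect_gt(nrow(res), 0L)
  connected_under <- function(members, net, depth) {
    if (length(members) <= 1) return(TRUE)
    d <- igraph::distances(net$graph, v = members, to = members)
    g <- igraph::graph_from_adjacency_matrix(is.finite(d) & d <= depth,
                                             mode = "undirected", diag = FALSE)
    igraph::components(g)$no == 1L
  }
  for (i in seq_len(nrow(res))) {
    expect_true(connected_under(res$members_one[[i]], bench$net1, 2))
    expect_true(connected_under(res$members_two[[i]], bench$net2, 2))
  }
  # every member of either module carries at least one seed link
  for (i in seq_len(nrow(res))) {
    lk <- res$links[[i]]
    expect_setequal(unique(lk[, 1]), res$members_one[[i]])
    expect_setequal(unique(lk[, 2]), res$members_two[[i]])
  }
})

test_that("with l = r the alignment is symmetric under side swap", {
  bench <- generate_synthetic(synth_params(
    homolog_dropout = 0, edge_rewire_rate = 0, duplicate_rate = 0,
    background_nodes = 0, background_edge_prob = 0, seed = 12))
  A <- build_seed_matrix(bench$homology, bench$net1, bench$net2)
  R <- bi_random_walk(transition_matrix(bench$net1, "row"),
                      transition_matrix(bench$net2, "column"), A, 2, 2)
  fwd <- align_networks(bench$net1, bench$net2,
                        partition_from_catalogue(bench$catalogue, bench$net1),
                        NULL, R, A, 2, 2)
  cat2 <- tibble::tibble(complex_id = bench$truth$solution_id,
                         members = bench$truth$members_two)
  Rt <- bi_random_walk(transition_matrix(bench$net2, "row"),
                       transition_matrix(bench$net1, "column"),
                       Matrix::t(A), 2, 2)
  rev <- align_networks(bench$net2, bench$net1,
                        partition_from_catalogue(cat2, bench$net2),
                        NULL, Rt, Matrix::t(A), 2, 2)
  key <- function(m1, m2) paste(paste(sort(m1), collapse = ","),
                                paste(sort(m2), collapse = ","))
  expect_setequal(
    mapply(key, fwd$members_one, fwd$members_two),
    mapply(key, rev$members_two, rev$members_one))
})

test_that("empty subnetwork lists produce an empty alignment", {
  fx <- mirror_pair()
  subs0 <- tibble::tibble(subnetwork_id = character(), members = list(),
                          origin = character(), source_network = character())
  res <- align_networks(fx$n1, fx$n2, subs0, NULL, fx$R, fx$A, 2, 2)
  expect_equal(nrow(res), 0L)
  expect_error(align_networks(fx$n1, fx$n2, subs0, NULL, fx$R,
                              fx$A[1, , drop = FALSE], 2, 2),
               "dimensions")
})
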