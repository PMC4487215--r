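#' Parameters for the paired-network generator
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' validation: 10 planted complexes of 4-8 proteins, dense (0.9) within-
#' complex wiring on top of a guaranteed spanning path, 10% homolog dropout,
#' 10% edge rewiring in the mirrored network, 10% protein duplication on the
#' mirrored side (creating many-to-many mappings), and a sparse
#' Erdos-Renyi background of 100 extra proteins per network.
#'
#' @param n_complexes Number of planted conserved complexes.
#' @param complex_size_range Integer pair: min/max complex size (>= 2).
#' @param intra_edge_prob Probability of each non-path within-complex edge.
#' @param background_nodes Extra background proteins per network.
#' @param background_edge_prob Erdos-Renyi edge probability among all node
#'   pairs not inside a planted complex.
#' @param homolog_dropout Fraction of planted cross-links deleted from the
#'   emitted homology table.
#' @param duplicate_rate Fraction of network-two complex proteins duplicated
#'   with identical interactions and homology links.
#' @param edge_rewire_rate Fraction of mirrored within-complex edges
#'   replaced by random within-complex pairs in network two.
#' @param evalue_hit E-value recorded (both directions) for true homolog
#'   pairs; must pass the default seed cutoff.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_complexes = 10L,
                         complex_size_range = c(4L, 8L),
                         intra_edge_prob = 0.9,
                         background_nodes = 100L,
                         background_edge_prob = 0.01,
                         homolog_dropout = 0.1,
                         duplicate_rate = 0.1,
                         edge_rewire_rate = 0.1,
                         evalue_hit = 1e-50,
                         seed = 1L) {
  p <- list(n_complexes = as.integer(n_complexes),
            complex_size_range = as.integer(complex_size_range),
            intra_edge_prob = intra_edge_prob,
            background_nodes = as.integer(background_nodes),
            background_edge_prob = background_edge_prob,
            homolog_dropout = homolog_dropout,
            duplicate_rate = duplicate_rate,
            edge_rewire_rate = edge_rewire_rate,
            evalue_hit = evalue_hit,
            seed = as.integer(seed))
  stopifnot(p$n_complexes >= 1L,
            length(p$complex_size_range) == 2L,
            p$complex_size_range[1L] >= 2L,
            p$complex_size_range[2L] >= p$complex_size_range[1L],
            p$intra_edge_prob >= 0, p$intra_edge_prob <= 1,
            p$background_edge_prob >= 0, p$background_edge_prob <= 1,
            p$homolog_dropout >= 0, p$homolog_dropout <= 1,
            p$duplicate_rate >= 0, p$duplicate_rate <= 1,
            p$edge_rewire_rate >= 0, p$edge_rewire_rate <= 1,
            p$evalue_hit < 1e-9)
  class(p) <- "synth_params"
  p
}

# all unordered pairs of a character vector, as a 2-column matrix
.all_pairs <- function(v) {
  if (length(v) < 2L) return(matrix(character(), 0L, 2L))
  t(utils::combn(v, 2L))
}

#' Generate a paired-network benchmark with planted conserved complexes
#'
#' Plants `n_complexes` connected dense modules in network one and mirrors
#' each into network two: nodes are copied, each within-module edge is kept
#' with probability `1 - edge_rewire_rate` and every dropped edge is
#' replaced by a random within-module pair, so the mirror stays equally
#' dense but topologically perturbed. Mirrored protein pairs receive
#' bidirectional E-values of `evalue_hit` in the homology table, from which
#' a `homolog_dropout` fraction is deleted. A `duplicate_rate` fraction of
#' network-two module proteins is duplicated with identical interactions
#' and homology links, creating many-to-many mappings. Finally both
#' networks receive `background_nodes` extra proteins and sparse
#' Erdos-Renyi background edges over all node pairs not internal to a
#' planted module. With all noise rates at zero every planted pair is an
#' exactly mirrored module.
#'
#' @param params A [synth_params()] object.
#' @return List with elements `net1`, `net2` ([ppi_network]s), `homology`
#'   (tibble), `truth` (solutions tibble: the planted module pairs),
#'   `catalogue` (the planted network-one modules as a complex catalogue),
#'   and `params`.
#' @export
generate_synthetic <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  sizes <- sample(seq(params$complex_size_range[1L],
                      params$complex_size_range[2L]),
                  params$n_complexes, replace = TRUE)
  edges1 <- list(); edges2 <- list()
  hom_a <- character(); hom_b <- character()
  truth1 <- list(); truth2 <- list()
  cat_ids <- sprintf("PLANT%02d", seq_len(params$n_complexes))

  for (k in seq_len(params$n_complexes)) {
    m1 <- sprintf("P%02d_%02d", k, seq_len(sizes[k]))
    m2 <- sprintf("H%02d_%02d", k, seq_len(sizes[k]))
    # connected module: spanning path over a shuffled order + dense extras
    ord <- sample(m1)
    path <- cbind(ord[-length(ord)], ord[-1L])
    extra <- .all_pairs(m1)
    pkey <- paste(pmin(path[, 1L], path[, 2L]), pmax(path[, 1L], path[, 2L]))
    ekey <- paste(pmin(extra[, 1L], extra[, 2L]), pmax(extra[, 1L], extra[, 2L]))
    extra <- extra[!(ekey %in% pkey) &
                     stats::runif(nrow(extra)) < params$intra_edge_prob, ,
                   drop = FALSE]
    e1 <- rbind(path, extra)
    edges1[[k]] <- e1
    # mirror with rewiring: keep each edge w.p. 1 - rate, replace drops
    idx <- match(e1, m1)
    e2 <- matrix(m2[idx], ncol = 2L)
    dropped <- stats::runif(nrow(e2)) < params$edge_rewire_rate
    kept <- e2[!dropped, , drop = FALSE]
    n_re <- sum(dropped)
    if (n_re > 0L && length(m2) >= 2L) {
      pool <- .all_pairs(m2)
      kk <- paste(kept[, 1L], kept[, 2L])
      pool <- pool[!(paste(pool[, 1L], pool[, 2L]) %in% kk), , drop = FALSE]
      if (nrow(pool)) {
        take <- sample(seq_len(nrow(pool)), min(n_re, nrow(pool)))
        kept <- rbind(kept, pool[take, , drop = FALSE])
      }
    }
    edges2[[k]] <- kept
    hom_a <- c(hom_a, m1); hom_b <- c(hom_b, m2)
    truth1[[k]] <- m1; truth2[[k]] <- m2
  }

  # many-to-many: duplicate a fraction of network-two module proteins
  all_m2 <- unlist(truth2)
  n_dup <- round(params$duplicate_rate * length(all_m2))
  dup_src <- if (n_dup > 0L) sample(all_m2, n_dup) else character()
  dup_edges <- list(); dup_hom_a <- character(); dup_hom_b <- character()
  e2all <- do.call(rbind, edges2)
  for (w in dup_src) {
    w2 <- paste0(w, "dup")
    nb <- unique(c(e2all[e2all[, 1L] == w, 2L], e2all[e2all[, 2L] == w, 1L]))
    if (length(nb)) dup_edges[[length(dup_edges) + 1L]] <- cbind(w2, nb)
    partners <- hom_a[hom_b == w]
    dup_hom_a <- c(dup_hom_a, partners)
    dup_hom_b <- c(dup_hom_b, rep(w2, length(partners)))
  }

  # homolog dropout applies to the planted (non-duplicate) links
  n_drop <- round(params$homolog_dropout * length(hom_a))
  if (n_drop > 0L) {
    gone <- sample(seq_along(hom_a), n_drop)
    hom_a <- hom_a[-gone]; hom_b <- hom_b[-gone]
  }
  hom_a <- c(hom_a, dup_hom_a); hom_b <- c(hom_b, dup_hom_b)

  # background
  bg1 <- if (params$background_nodes > 0L)
    sprintf("B1_%03d", seq_len(params$background_nodes)) else character()
  bg2 <- if (params$background_nodes > 0L)
    sprintf("B2_%03d", seq_len(params$background_nodes)) else character()
  nodes1 <- c(unlist(truth1), bg1)
  nodes2 <- unique(c(unlist(truth2), dup_hom_b, bg2))
  er_edges <- function(nodes, module_sets, prob) {
    if (length(nodes) < 2L || prob <= 0) return(matrix(character(), 0L, 2L))
    pairs <- .all_pairs(sort(nodes))
    mod_of <- stats::setNames(rep(seq_along(module_sets),
                                  lengths(module_sets)),
                              unlist(module_sets))
    same_mod <- !is.na(mod_of[pairs[, 1L]]) & !is.na(mod_of[pairs[, 2L]]) &
      mod_of[pairs[, 1L]] == mod_of[pairs[, 2L]]
    pairs <- pairs[!same_mod, , drop = FALSE]
    pairs[stats::runif(nrow(pairs)) < prob, , drop = FALSE]
  }
  bg_e1 <- er_edges(nodes1, truth1, params$background_edge_prob)
  bg_e2 <- er_edges(nodes2, truth2, params$background_edge_prob)

  e1 <- do.call(rbind, c(edges1, list(bg_e1)))
  e2 <- do.call(rbind, c(c(edges2, dup_edges), list(bg_e2)))
  net1 <- ppi_network(as.data.frame(e1, stringsAsFactors = FALSE),
                      "synthetic_one", nodes = nodes1)
  net2 <- ppi_network(as.data.frame(e2, stringsAsFactors = FALSE),
                      "synthetic_two", nodes = nodes2)
  homology <- tibble::tibble(
    protein_a = hom_a, protein_b = hom_b,
    e_ab = params$evalue_hit, e_ba = params$evalue_hit
  )
  truth <- tibble::tibble(
    solution_id = cat_ids,
    members_one = truth1,
    members_two = truth2
  )
  catalogue <- tibble::tibble(complex_id = cat_ids, members = truth1)
  list(net1 = net1, net2 = net2, homology = homology,
       truth = truth, catalogue = catalogue, params = params)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fraction of planted solutions recovered by an alignment
#'
#' A planted module pair counts as recovered when some predicted solution
#' overlaps it with score at least `os_threshold` on both sides.
#'
#' @param alignment Solutions tibble from [align_networks()].
#' @param truth Truth tibble from [generate_synthetic()].
#' @param os_threshold Overlap-score threshold (default 0.2).
#' @return Numeric scalar in `[0, 1]`.
#' @export
recovery_rate <- function(alignment, truth, os_threshold = 0.2) {
  if (nrow(truth) == 0L) stop("truth is empty")
  if (nrow(alignment) == 0L) return(0)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    t1 <- truth$members_one[[i]]; t2 <- truth$members_two[[i]]
    any(vapply(seq_len(nrow(alignment)), function(j) {
      overlap_score(alignment$members_one[[j]], t1) >= os_threshold &&
        overlap_score(alignment$members_two[[j]], t2) >= os_threshold
    }, TRUE))
  }, TRUE)
  mean(hit)
}
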