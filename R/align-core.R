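# Module growth under unequally lenient path-length criteria.
#
# A candidate conserved complex is grown from one subnetwork of the divided
# network: members that share walk-supported homologs are admitted into
# ModuleOne, their seed-supported ("real") homologs into ModuleTwo, with the
# connecting paths allowed to span up to l edges in network one and up to r
# edges in network two.

#' Depth-bounded connectivity test
#'
#' Is `candidate` joined to any member of `anchor_set` by a path of at most
#' `depth` edges in `net`? Paths may traverse any node of the network, not
#' only anchors. A candidate absent from the network is reported as not
#' connected.
#'
#' @param net A [ppi_network].
#' @param anchor_set Character vector of anchor protein IDs.
#' @param candidate Single protein ID.
#' @param depth Maximum path length in edges (>= 1).
#' @return Logical scalar.
#' @export
bounded_connected <- function(net, anchor_set, candidate, depth) {
  stopifnot(depth >= 1)
  nodes <- network_nodes(net)
  anchor_set <- intersect(anchor_set, nodes)
  if (!(candidate %in% nodes) || length(anchor_set) == 0L) return(FALSE)
  d <- igraph::distances(net$graph, v = candidate, to = anchor_set)
  any(is.finite(d) & d <= depth)
}

# ball of radius `depth` around each of `vs` (names), excluding nothing
.balls <- function(graph, vs, depth) {
  out <- igraph::ego(graph, order = depth, nodes = vs)
  stats::setNames(lapply(out, function(v) v$name), vs)
}

.row_support <- function(M, i) colnames(M)[which(M[i, ] != 0)]
.col_support <- function(M, j) rownames(M)[which(M[, j] != 0)]

new_solution <- function(members_one = character(), members_two = character(),
                         origin = NA_character_) {
  list(members_one = sort(unique(members_one)),
       members_two = sort(unique(members_two)),
       origin = origin)
}

solution_links <- function(sol, A) {
  m1 <- intersect(sol$members_one, rownames(A))
  m2 <- intersect(sol$members_two, colnames(A))
  if (!length(m1) || !length(m2)) return(matrix(character(), 0L, 2L))
  sub <- A[m1, m2, drop = FALSE]
  S <- methods::as(methods::as(sub, "generalMatrix"), "TsparseMatrix")
  cbind(m1[S@i + 1L], m2[S@j + 1L])[order(S@i, S@j), , drop = FALSE]
}

#' Grow a candidate conserved module pair from one subnetwork (Step 1)
#'
#' Starting from the lexicographically smallest subnetwork member, performs
#' a breadth-first admission over the subnetwork: for the current member `u`
#' and each other subnetwork member `v` within path length `l` of `u` in
#' `netP`, the pair is admitted into ModuleOne when the walk matrix `R`
#' gives them a shared homolog in `netH` and either
#' (a) at least one shared homolog is a real (seed-matrix) homolog of `u` or
#' `v`, or
#' (b) two different shared homologs are really matched to two distinct
#' subnetwork members outside `u` and its neighbour set.
#' Only seed-supported homologs enter ModuleTwo. A subnetwork yielding no
#' admissible pair falls back to its smallest seed-linked member as a
#' singleton seed, which later refinement may keep or discard.
#'
#' @param sub Character vector: the subnetwork's members (from `netP`).
#' @param netP,netH The divided network and the counterpart network.
#' @param R Mapping matrix from [bi_random_walk()] (rows: `netP`, columns:
#'   `netH`).
#' @param A Seed matrix (same indexing).
#' @param l Path-length leniency inside `netP`.
#' @param origin Optional subnetwork identifier stored on the result.
#' @return A solution: list with sorted character vectors `members_one`,
#'   `members_two` and the `origin` id.
#' @export
grow_modules <- function(sub, netP, netH, R, A, l, origin = NA_character_) {
  stopifnot(l >= 1)
  sub <- sort(intersect(unique(sub), network_nodes(netP)))
  if (!length(sub)) return(new_solution(origin = origin))
  balls <- .balls(netP$graph, sub, l)
  cands <- lapply(sub, function(u) sort(setdiff(intersect(balls[[u]], sub), u)))
  names(cands) <- sub
  rsupp <- stats::setNames(lapply(sub, function(u) .row_support(R, u)), sub)
  realh <- stats::setNames(lapply(sub, function(u) .row_support(A, u)), sub)
  # seed partners inside the subnetwork, per network-two protein
  sub_partners <- function(w) intersect(.col_support(A, w), sub)

  m1 <- character(); m2 <- character()
  start <- sub[1L]
  queue <- start
  seen <- stats::setNames(rep(FALSE, length(sub)), sub)
  seen[start] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    excl <- c(u, cands[[u]])
    for (v in cands[[u]]) {
      shared <- intersect(rsupp[[u]], rsupp[[v]])
      if (!length(shared)) next
      real_uv <- intersect(shared, union(realh[[u]], realh[[v]]))
      cond_a <- length(real_uv) > 0L
      cond_b <- FALSE
      anchored <- character()
      if (!cond_a) {
        outside <- lapply(shared, function(w) setdiff(sub_partners(w), excl))
        has <- lengths(outside) > 0L
        if (sum(has) >= 2L && length(unique(unlist(outside[has]))) >= 2L) {
          cond_b <- TRUE
          anchored <- shared[has]
        }
      }
      if (cond_a || cond_b) {
        m1 <- union(m1, c(u, v))
        m2 <- union(m2, if (cond_a) real_uv else anchored)
        if (!seen[v]) {
          seen[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  if (!length(m1)) {
    # degenerate seed: smallest member with at least one real homolog
    for (u in sub) {
      if (length(realh[[u]])) {
        m1 <- u; m2 <- realh[[u]]
        break
      }
    }
  }
  new_solution(m1, m2, origin)
}

#' Refine ModuleTwo by resolving many-to-many mappings (Step 2)
#'
#' Each ModuleTwo protein is weighted by the sum of its walk-matrix values
#' to its ModuleOne counterparts. Connected components of ModuleTwo are
#' formed under depth-`r` bounded connectivity in `netH` (paths may traverse
#' proteins outside ModuleTwo). Components of two or more proteins mark
#' their seed-linked ModuleOne counterparts as covered; a singleton
#' component is removed when all its counterparts are already covered, and
#' otherwise survives only if it carries the highest weight among the
#' singletons competing for some uncovered counterpart (ties break to the
#' lexicographically smallest protein ID).
#'
#' @param sol Solution from [grow_modules()].
#' @param netH The counterpart network (where ModuleTwo lives).
#' @param R,A Mapping and seed matrices (rows: network one).
#' @param r Path-length leniency inside `netH`.
#' @return The refined solution.
#' @export
refine_module_two <- function(sol, netH, R, A, r) {
  stopifnot(r >= 1)
  m2 <- intersect(sol$members_two, network_nodes(netH))
  m2 <- sort(unique(c(m2, setdiff(sol$members_two, network_nodes(netH)))))
  present <- intersect(m2, network_nodes(netH))
  if (length(m2) <= 1L) return(sol)
  m1 <- sol$members_one
  weight <- vapply(m2, function(w) {
    if (!length(m1)) return(0)
    sum(R[m1, w])
  }, 0)
  counterparts <- stats::setNames(
    lapply(m2, function(w) intersect(.col_support(A, w), m1)), m2)

  # bounded-connectivity components (through the full network)
  comp_id <- stats::setNames(seq_along(m2), m2)
  if (length(present) >= 2L) {
    d <- igraph::distances(netH$graph, v = present, to = present)
    close <- is.finite(d) & d <= r
    g <- igraph::graph_from_adjacency_matrix(close, mode = "undirected",
                                             diag = FALSE)
    cc <- igraph::components(g)$membership
    comp_id[present] <- cc + length(m2)  # distinct namespace
  }
  tab <- table(comp_id)
  big <- names(tab)[tab >= 2L]
  covered <- unique(unlist(counterparts[m2[comp_id %in% as.integer(big)]]))

  singles <- m2[!(comp_id %in% as.integer(big))]
  drop <- character()
  uncovered_of <- stats::setNames(
    lapply(singles, function(w) setdiff(counterparts[[w]], covered)), singles)
  for (w in singles) {
    if (length(counterparts[[w]]) && !length(uncovered_of[[w]])) {
      drop <- c(drop, w)  # counterparts all covered elsewhere
    }
  }
  contenders <- setdiff(singles, drop)
  keep <- character()
  uncovered_targets <- unique(unlist(uncovered_of[contenders]))
  for (m in uncovered_targets) {
    rivals <- contenders[vapply(contenders,
                                function(w) m %in% uncovered_of[[w]], TRUE)]
    if (!length(rivals)) next
    best <- rivals[order(-weight[rivals], rivals)][1L]
    keep <- c(keep, best)
  }
  # contenders competing only for covered/no targets, or beaten everywhere
  losers <- setdiff(contenders[lengths(uncovered_of[contenders]) > 0L], keep)
  drop <- union(drop, losers)
  new_solution(sol$members_one, setdiff(m2, drop), sol$origin)
}

#' Attach isolated subnetwork members (Step 3)
#'
#' Subnetwork members that Step 1 left outside ModuleOne are appended when
#' their real (seed-matrix) homolog already sits in ModuleTwo, or connects
#' to ModuleTwo by a path of at most `r` edges in `netH` (in which case the
#' homolog joins ModuleTwo as well). Finally, members of either module
#' without any seed link into the other module are discarded.
#'
#' @param sol Refined solution.
#' @param sub The originating subnetwork's members.
#' @param netH Counterpart network.
#' @param A Seed matrix (rows: network one).
#' @param r Path-length leniency inside `netH`.
#' @return The completed solution (possibly empty after the final discard).
#' @export
attach_isolated <- function(sol, sub, netH, A, r) {
  stopifnot(r >= 1)
  m1 <- sol$members_one
  m2 <- sol$members_two
  rest <- sort(setdiff(intersect(unique(sub), rownames(A)), m1))
  for (u in rest) {
    hom <- .row_support(A, u)
    if (!length(hom)) next
    if (length(intersect(hom, m2))) {
      m1 <- union(m1, u)
      next
    }
    if (!length(m2)) next
    reach <- hom[vapply(hom, function(w)
      bounded_connected(netH, m2, w, r), TRUE)]
    if (length(reach)) {
      m1 <- union(m1, u)
      m2 <- union(m2, reach)
    }
  }
  # conserved complexes consist of homologous proteins: discard unlinked
  repeat {
    m1_ok <- m1[vapply(m1, function(u)
      length(intersect(.row_support(A, u), m2)) > 0L, TRUE)]
    m2_ok <- m2[vapply(m2, function(w)
      length(intersect(.col_support(A, w), m1_ok)) > 0L, TRUE)]
    if (setequal(m1_ok, m1) && setequal(m2_ok, m2)) break
    m1 <- m1_ok; m2 <- m2_ok
  }
  new_solution(m1, m2, sol$origin)
}

#' Overlap-based filtering of near-duplicate solutions (Step 4)
#'
#' A solution is filtered out when another retained solution carries a
#' strictly larger network-one complex whose overlap score with it exceeds
#' `t`. Solutions are processed in order of decreasing network-one size,
#' ties broken by decreasing network-two size and then by the
#' lexicographically smallest membership; equal-sized complexes never
#' eliminate each other, and an overlap score exactly equal to `t` does not
#' trigger removal.
#'
#' @param solutions Solutions tibble with list columns `members_one`,
#'   `members_two`.
#' @param t Overlap-score threshold in (0, 1]; default 0.8.
#' @return The retained subset of `solutions` (original row order restored).
#' @export
filter_overlaps <- function(solutions, t = 0.8) {
  if (!(t > 0 && t <= 1)) stop("t must lie in (0, 1]")
  n <- nrow(solutions)
  if (n <= 1L) return(solutions)
  key1 <- vapply(solutions$members_one,
                 function(m) paste(sort(m), collapse = "\r"), "")
  key2 <- vapply(solutions$members_two,
                 function(m) paste(sort(m), collapse = "\r"), "")
  ord <- order(-lengths(solutions$members_one),
               -lengths(solutions$members_two), key1, key2)
  kept_idx <- integer()
  for (i in ord) {
    mi <- solutions$members_one[[i]]
    removed <- FALSE
    for (k in kept_idx) {
      mk <- solutions$members_one[[k]]
      if (length(mk) > length(mi) && overlap_score(mk, mi) > t) {
        removed <- TRUE
        break
      }
    }
    if (!removed) kept_idx <- c(kept_idx, i)
  }
  solutions[sort(kept_idx), , drop = FALSE]
}

#' Distinct complexes on one side of a solution set
#'
#' Collapses each solution's complex on the requested side to its distinct
#' protein set, drops exact duplicate complexes and complexes of fewer than
#' two proteins — the accounting used when counting distinct conserved
#' complexes per network.
#'
#' @param solutions Solutions tibble.
#' @param side `"one"` or `"two"`.
#' @return List of distinct character vectors (sorted members), in first
#'   appearance order.
#' @export
distinct_complexes <- function(solutions, side = c("one", "two")) {
  side <- match.arg(side)
  col <- if (side == "one") solutions$members_one else solutions$members_two
  sets <- lapply(col, function(m) sort(unique(m)))
  sets <- sets[lengths(sets) >= 2L]
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets[!duplicated(keys)]
}

run_one_side <- function(subs, netP, netH, R, A, l, r) {
  out <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    sol <- grow_modules(subs$members[[i]], netP, netH, R, A, l,
                        origin = subs$subnetwork_id[i])
    sol <- refine_module_two(sol, netH, R, A, r)
    sol <- attach_isolated(sol, subs$members[[i]], netH, A, r)
    out[[i]] <- sol
  }
  out[vapply(out, function(s)
    length(s$members_one) >= 1L && length(s$members_two) >= 1L, TRUE)]
}

#' Detect conserved protein complexes between two PPI networks
#'
#' The full dividing-and-matching procedure: every subnetwork of `netP` is
#' grown into a candidate module pair (Step 1), its counterpart module is
#' refined (Step 2) and isolated members are attached (Step 3); the roles of
#' the two networks are then reversed for the subnetworks of `netH` (with
#' `l`/`r` swapped and the matrices transposed); finally highly overlapping
#' solutions are filtered (Step 4, threshold `overlap_t`).
#'
#' @param netP,netH The two [ppi_network]s (network one and network two).
#' @param subsP Subnetwork tibble for `netP` (see
#'   [partition_from_catalogue()] / [mcl_partition()]).
#' @param subsH Subnetwork tibble for `netH`; may have zero rows to skip the
#'   reversed pass.
#' @param R,A Mapping and seed matrices (rows: `netP` nodes, columns:
#'   `netH` nodes).
#' @param l,r Path-length leniencies for `netP` and `netH` (defaults 2).
#' @param overlap_t Step-4 overlap threshold; default 0.8.
#' @return A `conserved_alignment` object: a tibble with columns
#'   `solution_id`, `members_one`, `members_two` (list columns of sorted
#'   protein IDs), `links` (two-column character matrix of seed pairs),
#'   `origin_subnetwork`, `direction` (`"forward"`/`"reversed"`), plus the
#'   run parameters as attributes.
#' @export
align_networks <- function(netP, netH, subsP, subsH = NULL, R, A,
                           l = 2L, r = 2L, overlap_t = 0.8) {
  n1 <- network_nodes(netP); n2 <- network_nodes(netH)
  if (nrow(A) != length(n1) || ncol(A) != length(n2) ||
      nrow(R) != length(n1) || ncol(R) != length(n2)) {
    stop("R/A dimensions do not match the networks")
  }
  sols <- list(); dir <- character()
  if (!is.null(subsP) && nrow(subsP)) {
    fw <- run_one_side(subsP, netP, netH, R, A, l, r)
    sols <- c(sols, fw)
    dir <- c(dir, rep("forward", length(fw)))
  }
  if (!is.null(subsH) && nrow(subsH)) {
    rv <- run_one_side(subsH, netH, netP, Matrix::t(R), Matrix::t(A), r, l)
    rv <- lapply(rv, function(s)
      new_solution(s$members_two, s$members_one, s$origin))  # restore sides
    sols <- c(sols, rv)
    dir <- c(dir, rep("reversed", length(rv)))
  }
  if (!length(sols)) {
    res <- tibble::tibble(solution_id = character(),
                          members_one = list(), members_two = list(),
                          links = list(), origin_subnetwork = character(),
                          direction = character())
  } else {
    res <- tibble::tibble(
      solution_id = sprintf("S%04d", seq_along(sols)),
      members_one = lapply(sols, `[[`, "members_one"),
      members_two = lapply(sols, `[[`, "members_two"),
      links = lapply(sols, solution_links, A = A),
      origin_subnetwork = vapply(sols, `[[`, "", "origin"),
      direction = dir
    )
    res <- filter_overlaps(res, t = overlap_t)
  }
  structure(res,
            class = c("conserved_alignment", class(res)),
            params = list(l = l, r = r, overlap_t = overlap_t,
                          species = c(netP$species, netH$species)))
}
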