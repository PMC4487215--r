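# Resnik semantic similarity over the Gene Ontology, with annotation-based
# information content. Only `is_a` and `part_of` edges are used and terms
# are restricted to one namespace (biological process by default).

#' Read a Gene Ontology file (OBO 1.2 flat format)
#'
#' Minimal OBO reader covering what semantic similarity needs: term IDs,
#' names, namespaces, `is_a` parents and `part_of` relationships. Obsolete
#' terms are skipped.
#'
#' @param path Path to the `.obo` file.
#' @return Tibble with columns `id`, `name`, `namespace`, `parents`
#'   (list of character vectors).
#' @export
read_obo <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  out <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      out[[length(out) + 1L]] <<- cur
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) cur$namespace <- sub("^namespace: ", "", ln)
      else if (startsWith(ln, "is_a: ")) {
        cur$parents <- c(cur$parents,
                         sub("^is_a: +(\\S+).*$", "\\1", ln))
      } else if (startsWith(ln, "relationship: part_of ")) {
        cur$parents <- c(cur$parents,
                         sub("^relationship: part_of +(\\S+).*$", "\\1", ln))
      } else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
    }
  }
  flush(cur)
  tibble::tibble(
    id = vapply(out, `[[`, "", "id"),
    name = vapply(out, function(t) t$name %||% "", ""),
    namespace = vapply(out, function(t) t$namespace %||% "", ""),
    parents = lapply(out, `[[`, "parents")
  )
}

#' Read protein GO annotations (GAF 2.x)
#'
#' Keeps the DB object symbol (column 3), GO ID (column 5) and aspect
#' (column 9), filtered to one aspect. `NOT`-qualified annotations are
#' skipped.
#'
#' @param path Path to the GAF file.
#' @param aspect Single-letter aspect filter: `"P"` (biological process,
#'   default), `"F"` or `"C"`.
#' @return Tibble with columns `protein`, `term`.
#' @export
read_gaf <- function(path, aspect = "P") {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) return(tibble::tibble(protein = character(),
                                            term = character()))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(toks, length, 1L) >= 9L
  toks <- toks[ok]
  qual <- vapply(toks, `[[`, "", 4L)
  asp <- vapply(toks, `[[`, "", 9L)
  keep <- asp == aspect & !grepl("\\bNOT\\b", qual)
  tb <- tibble::tibble(
    protein = vapply(toks, `[[`, "", 3L)[keep],
    term = vapply(toks, `[[`, "", 5L)[keep]
  )
  dplyr::distinct(tb)
}

#' Build a GO annotation set with information content
#'
#' Combines an ontology with a protein annotation corpus, restricted to one
#' namespace. Each protein's annotation is closed upward over `is_a`/
#' `part_of`; the probability of a term is the fraction of annotated
#' proteins whose closure contains it (descendant-closed counts), so the
#' namespace root has probability 1 and information content
#' `IC = -ln p` of 0.
#'
#' @param ontology Tibble from [read_obo()].
#' @param annotations Tibble from [read_gaf()] (or any `protein`/`term`
#'   table). Terms absent from the ontology are dropped with a warning.
#' @param namespace Namespace filter; default `"biological_process"`.
#' @return A `go_annotation_set`: list with `ancestors` (term -> ancestor
#'   IDs, self included), `ic` (named numeric), `annotations` (protein ->
#'   closed term sets), `namespace`.
#' @export
go_annotation_set <- function(ontology, annotations,
                              namespace = "biological_process") {
  onto <- ontology[ontology$namespace == namespace, ]
  ids <- onto$id
  parent_of <- stats::setNames(
    lapply(onto$parents, function(p) intersect(p, ids)), ids)
  # ancestor closure (self included), memoised over the DAG
  anc <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    anc[[t]] <- t  # guard against accidental cycles
    res <- t
    for (p in parent_of[[t]]) res <- union(res, get_anc(p))
    anc[[t]] <- res
    res
  }
  ancestors <- stats::setNames(lapply(ids, get_anc), ids)

  known <- annotations$term %in% ids
  if (any(!known)) {
    warning(sprintf("go_annotation_set: dropped %d annotation(s) to terms outside the '%s' ontology",
                    sum(!known), namespace))
  }
  annotations <- annotations[known, ]
  prot_terms <- split(annotations$term, annotations$protein)
  closed <- lapply(prot_terms, function(ts)
    unique(unlist(ancestors[unique(ts)], use.names = FALSE)))
  n_prot <- length(closed)
  counts <- table(unlist(closed, use.names = FALSE))
  p <- stats::setNames(rep(0, length(ids)), ids)
  if (n_prot > 0L) p[names(counts)] <- as.numeric(counts) / n_prot
  ic <- ifelse(p > 0, -log(p), NA_real_)
  structure(list(ancestors = ancestors, ic = ic, annotations = closed,
                 namespace = namespace),
            class = "go_annotation_set")
}

#' Resnik similarity of two GO terms
#'
#' The information content of the most informative common ancestor of the
#' two terms (a term is an ancestor of itself). Terms sharing only the root
#' score 0.
#'
#' @param t1,t2 GO term IDs present in the annotation set's ontology.
#' @param ann A [go_annotation_set()].
#' @return Numeric scalar (>= 0).
#' @export
resnik_term_sim <- function(t1, t2, ann) {
  if (is.null(ann$ancestors[[t1]]) || is.null(ann$ancestors[[t2]])) {
    stop(sprintf("term '%s' or '%s' is not in the ontology", t1, t2))
  }
  common <- intersect(ann$ancestors[[t1]], ann$ancestors[[t2]])
  ics <- ann$ic[common]
  ics <- ics[!is.na(ics)]
  if (!length(ics)) return(0)
  max(ics)
}

#' Functional similarity of two proteins
#'
#' The maximum Resnik similarity over all pairs of the two proteins' GO
#' annotations. Proteins without annotation in the set score 0 (flagged via
#' the `"missing"` attribute).
#'
#' @param p1,p2 Protein IDs.
#' @param ann A [go_annotation_set()].
#' @return Numeric scalar with attribute `missing` (logical).
#' @export
protein_fun_sim <- function(p1, p2, ann) {
  a1 <- ann$annotations[[p1]]
  a2 <- ann$annotations[[p2]]
  if (is.null(a1) || is.null(a2)) {
    return(structure(0, missing = TRUE))
  }
  # closures already include ancestors; the max-IC common term over the
  # closures equals the max Resnik value over direct term pairs
  common <- intersect(a1, a2)
  ics <- ann$ic[common]
  ics <- ics[!is.na(ics)]
  structure(if (length(ics)) max(ics) else 0, missing = FALSE)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Functional-relevance averages for conserved solutions
#'
#' For each solution, averages the pairwise protein functional similarity
#' within its network-one module (`avg_one`), within its network-two module
#' (`avg_two`), across the two modules only (`avg_inter`), and over all
#' pairs both within and across (`avg_mixed`); self-pairs are excluded and
#' pairs are unordered. The returned values are the unweighted means over
#' solutions; a single-protein module contributes no within-module average
#' and is excluded from that mean.
#'
#' @param solutions Solutions tibble (`members_one`/`members_two` list
#'   columns).
#' @param ann1 Annotation set for network-one proteins.
#' @param ann2 Annotation set for network-two proteins (may be the same
#'   object).
#' @return One-row tibble: `avg_mixed`, `avg_one`, `avg_two`, `avg_inter`,
#'   `n_solutions`.
#' @export
relevance_averages <- function(solutions, ann1, ann2 = ann1) {
  if (is.null(solutions) || nrow(solutions) == 0L) {
    stop("relevance_averages: no solutions given")
  }
  pair_mean <- function(members, ann) {
    if (length(members) < 2L) return(NA_real_)
    prs <- utils::combn(sort(members), 2L)
    mean(vapply(seq_len(ncol(prs)), function(k)
      as.numeric(protein_fun_sim(prs[1L, k], prs[2L, k], ann)), 0))
  }
  per <- lapply(seq_len(nrow(solutions)), function(i) {
    m1 <- unique(solutions$members_one[[i]])
    m2 <- unique(solutions$members_two[[i]])
    w1 <- pair_mean(m1, ann1)
    w2 <- pair_mean(m2, ann2)
    inter <- as.vector(outer(m1, m2, Vectorize(function(a, b) {
      s1 <- ann1$annotations[[a]]; s2 <- ann2$annotations[[b]]
      if (is.null(s1) || is.null(s2)) return(0)
      common <- intersect(s1, s2)
      ics <- ann1$ic[common]
      ics <- ics[!is.na(ics)]
      if (length(ics)) max(ics) else 0
    })))
    intra_vals <- c(
      if (length(m1) >= 2L) utils::combn(sort(m1), 2L, function(p)
        as.numeric(protein_fun_sim(p[1L], p[2L], ann1))) else numeric(),
      if (length(m2) >= 2L) utils::combn(sort(m2), 2L, function(p)
        as.numeric(protein_fun_sim(p[1L], p[2L], ann2))) else numeric()
    )
    c(one = w1, two = w2,
      inter = mean_or_na(inter),
      mixed = mean_or_na(c(intra_vals, inter)))
  })
  mat <- do.call(rbind, per)
  tibble::tibble(
    avg_mixed = mean(mat[, "mixed"], na.rm = TRUE),
    avg_one = mean(mat[, "one"], na.rm = TRUE),
    avg_two = mean(mat[, "two"], na.rm = TRUE),
    avg_inter = mean(mat[, "inter"], na.rm = TRUE),
    n_solutions = nrow(solutions)
  )
}
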