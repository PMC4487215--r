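#' Sequence similarity from bidirectional BLAST E-values
#'
#' Scores a cross-network protein pair as the arithmetic mean of the two
#' directional minimum BLAST E-values, `(E_ab + E_ba) / 2`. The alignment
#' itself uses only the binary pass/fail of the E-value cutoff; this score is
#' kept alongside for diagnostics.
#'
#' @param e_ab,e_ba Nonnegative E-values for the two BLAST directions
#'   (vectorised).
#' @return Numeric vector of similarity scores.
#' @examples
#' sequence_similarity(1e-10, 3e-10)
#' @export
sequence_similarity <- function(e_ab, e_ba) {
  if (any(e_ab < 0, na.rm = TRUE) || any(e_ba < 0, na.rm = TRUE)) {
    stop("E-values must be nonnegative")
  }
  (e_ab + e_ba) / 2
}

#' Read a homology table
#'
#' Tab-delimited table of cross-network homolog candidates with columns
#' `protein_a`, `protein_b`, `e_ab`, `e_ba` (the minimum BLAST E-value in
#' each direction). Alternatively, with `format = "blast"`, a BLAST
#' tabular-style file where each direction occupies its own row
#' (`query`, `subject`, `evalue`; extra columns ignored): rows `(a, b, .)`
#' and `(b, a, .)` collapse into one pair record oriented as first seen,
#' keeping the minimum E-value per direction. A missing reverse E-value is
#' recorded as `NA` and always fails the seed cutoff downstream.
#'
#' @param path File path.
#' @param format Either `"pair"` (one row per pair, both E-values) or
#'   `"blast"` (one row per direction, merged).
#' @return A tibble with columns `protein_a`, `protein_b`, `e_ab`, `e_ba`.
#' @export
read_homology <- function(path, format = c("pair", "blast")) {
  format <- match.arg(format)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  if (format == "pair") {
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) stop(sprintf("homology line %d has fewer than 4 fields", bad[1L]))
    tb <- tibble::tibble(
      protein_a = vapply(toks, `[[`, "", 1L),
      protein_b = vapply(toks, `[[`, "", 2L),
      e_ab = as.numeric(vapply(toks, `[[`, "", 3L)),
      e_ba = as.numeric(vapply(toks, `[[`, "", 4L))
    )
  } else {
    bad <- which(vapply(toks, length, 1L) < 3L)
    if (length(bad)) stop(sprintf("homology line %d has fewer than 3 fields", bad[1L]))
    q <- vapply(toks, `[[`, "", 1L)
    s <- vapply(toks, `[[`, "", 2L)
    e <- as.numeric(vapply(toks, `[[`, "", 3L))
    key <- ifelse(q < s, paste(q, s, sep = "\r"), paste(s, q, sep = "\r"))
    first <- match(unique(key), key)
    pa <- q[first]; pb <- s[first]
    e_ab <- rep(NA_real_, length(first))
    e_ba <- rep(NA_real_, length(first))
    idx <- match(key, unique(key))
    for (r in seq_along(key)) {
      k <- idx[r]
      if (q[r] == pa[k]) {
        e_ab[k] <- min(e_ab[k], e[r], na.rm = TRUE)
      } else {
        e_ba[k] <- min(e_ba[k], e[r], na.rm = TRUE)
      }
    }
    tb <- tibble::tibble(protein_a = pa, protein_b = pb,
                         e_ab = e_ab, e_ba = e_ba)
  }
  dup <- duplicated(paste(tb$protein_a, tb$protein_b, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("read_homology: collapsed %d duplicate pair record(s)", sum(dup)))
    tb <- tb[!dup, ]
  }
  tb
}

#' Build the binary seed mapping matrix
#'
#' The seed matrix `A` (rows: network-one proteins, columns: network-two
#' proteins) records the "real" homologous mappings: `A[i, j] = 1` iff the
#' homology table holds a record for `(i, j)` whose E-values are strictly
#' below `cutoff` in *both* BLAST directions and both proteins occur in
#' their respective networks. Records naming proteins absent from a network
#' are dropped with a warning. A missing (NA) E-value fails the cutoff.
#'
#' @param table Homology tibble as from [read_homology()].
#' @param net1,net2 The two [ppi_network]s; `net1` indexes rows, `net2`
#'   columns.
#' @param cutoff Strict E-value cutoff applied to both directions
#'   (default `1e-9`).
#' @return A sparse binary [Matrix][Matrix::sparseMatrix] with dimnames
#'   `(nodes of net1, nodes of net2)`.
#' @export
build_seed_matrix <- function(table, net1, net2, cutoff = 1e-9) {
  stopifnot(cutoff > 0)
  n1 <- network_nodes(net1)
  n2 <- network_nodes(net2)
  A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(length(n1), length(n2)),
                            dimnames = list(n1, n2))
  if (is.null(table) || nrow(table) == 0L) return(A)
  i <- match(table$protein_a, n1)
  j <- match(table$protein_b, n2)
  absent <- is.na(i) | is.na(j)
  if (any(absent)) {
    warning(sprintf("build_seed_matrix: dropped %d record(s) naming proteins absent from their network",
                    sum(absent)))
  }
  pass <- !absent &
    !is.na(table$e_ab) & !is.na(table$e_ba) &
    table$e_ab < cutoff & table$e_ba < cutoff
  if (any(pass)) {
    A <- Matrix::sparseMatrix(i = i[pass], j = j[pass], x = 1,
                              dims = c(length(n1), length(n2)),
                              dimnames = list(n1, n2))
    A@x[] <- 1  # collapse any accidental duplicates to binary
    A <- methods::as(A, "generalMatrix")
  }
  A
}

#' Degree-normalised transition matrix of a PPI network
#'
#' Row orientation divides each adjacency row by the node's degree (used for
#' the left-multiplying walk on network one); column orientation divides each
#' column by the column node's degree (right-multiplying walk on network
#' two). Isolated nodes yield all-zero rows/columns.
#'
#' @param net A [ppi_network].
#' @param orientation `"row"` or `"column"`.
#' @return A sparse square matrix with the network's node names as dimnames;
#'   rows (or columns) sum to 1 or 0.
#' @export
transition_matrix <- function(net, orientation = c("row", "column")) {
  orientation <- match.arg(orientation)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  if (n == 0L) return(Matrix::Matrix(0, 0, 0, sparse = TRUE))
  adj <- methods::as(methods::as(adj, "dMatrix"), "generalMatrix")
  deg <- Matrix::rowSums(adj)  # symmetric, so row == column degree
  inv <- ifelse(deg > 0, 1 / deg, 0)
  out <- if (orientation == "row") {
    Matrix::Diagonal(n, inv) %*% adj
  } else {
    adj %*% Matrix::Diagonal(n, inv)
  }
  dimnames(out) <- list(nodes, nodes)
  out
}
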