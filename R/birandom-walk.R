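#' Unbalanced bi-random walk over a pair of PPI networks
#'
#' Propagates the seed homology matrix `A` by taking unequal numbers of
#' random-walk steps on the two networks, producing the mapping matrix `R`
#' whose entry `R[i, j]` scores how likely protein `i` of network one maps to
#' protein `j` of network two. Walking on network one is a left
#' multiplication by its row-normalised transition matrix `P`; walking on
#' network two is a right multiplication by its column-normalised transition
#' matrix `H`. The recurrence is
#'
#' \deqn{R_0 = A;\qquad
#'   R_t = \alpha\,\frac{\lambda_p(t)\,P R_{t-1} + \lambda_h(t)\,R_{t-1} H}
#'                    {\lambda_p(t) + \lambda_h(t)} + (1-\alpha)\,A,}
#'
#' for \eqn{t = 1, \ldots, \max(l, r)}, where the indicator
#' \eqn{\lambda_p(t) = 1} iff \eqn{t \le l} and \eqn{\lambda_h(t) = 1} iff
#' \eqn{t \le r}. The walk therefore takes at most `l` steps on network one
#' and at most `r` steps on network two; the seed matrix regularises every
#' iteration with weight `1 - alpha`. No convergence test is applied — the
#' iteration count is exactly `max(l, r)`, and `R` is not re-normalised
#' between iterations. With a binary `A` every entry of `R` lies in
#' \eqn{[0, 1]}.
#'
#' Entries `R[i, j] > threshold` without a seed entry (`A[i, j] = 0`) are the
#' *artificial* homologous mappings; see [artificial_mappings()].
#'
#' @param P Row-normalised transition matrix of network one
#'   (see [transition_matrix()]).
#' @param H Column-normalised transition matrix of network two.
#' @param A Seed matrix from [build_seed_matrix()] (N x M).
#' @param l,r Maximum walk steps on network one / network two
#'   (nonnegative integers; defaults 2).
#' @param alpha Seed-regularisation weight in (0, 1); default 0.5.
#' @return Sparse nonnegative matrix `R` with the dimnames of `A`, carrying
#'   attributes `l`, `r`, `alpha`.
#' @examples
#' n1 <- ppi_network(data.frame(a = "u1", b = "u2"), "one")
#' n2 <- ppi_network(data.frame(a = "v1", b = "v2"), "two")
#' A <- build_seed_matrix(
#'   tibble::tibble(protein_a = "u1", protein_b = "v1",
#'                  e_ab = 1e-50, e_ba = 1e-50),
#'   n1, n2)
#' bi_random_walk(transition_matrix(n1, "row"),
#'                transition_matrix(n2, "column"), A, l = 1, r = 1)
#' @export
bi_random_walk <- function(P, H, A, l = 2L, r = 2L, alpha = 0.5) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  if (l < 0 || r < 0) stop("l and r must be nonnegative")
  l <- as.integer(l); r <- as.integer(r)
  if (nrow(P) != ncol(P) || nrow(H) != ncol(H)) stop("P and H must be square")
  if (nrow(A) != nrow(P) || ncol(A) != nrow(H)) {
    stop(sprintf("dimension mismatch: A is %dx%d but P is %dx%d and H is %dx%d",
                 nrow(A), ncol(A), nrow(P), nrow(P), nrow(H), nrow(H)))
  }
  A <- methods::as(methods::as(A, "dMatrix"), "generalMatrix")
  R <- A
  tmax <- max(l, r)
  if (tmax > 0L) {
    for (t in seq_len(tmax)) {
      lp <- as.numeric(t <= l)
      lh <- as.numeric(t <= r)
      step <- (lp * (P %*% R) + lh * (R %*% H)) / (lp + lh)
      R <- alpha * step + (1 - alpha) * A
    }
  }
  R <- Matrix::drop0(R)
  dimnames(R) <- dimnames(A)
  attr(R, "l") <- l; attr(R, "r") <- r; attr(R, "alpha") <- alpha
  R
}

#' Artificial homologous mappings discovered by the walk
#'
#' Cross-network pairs that carry positive mass in the mapping matrix `R`
#' but are not seed ("real") mappings in `A`. These correspond to the
#' indirect mappings the walk infers from network neighbourhoods.
#'
#' @param R Mapping matrix from [bi_random_walk()].
#' @param A Seed matrix the walk was run with.
#' @param threshold Minimum `R` value to report (default 0: any positive
#'   mass).
#' @return Tibble with columns `protein_a`, `protein_b`, `score`, sorted by
#'   decreasing score.
#' @export
artificial_mappings <- function(R, A, threshold = 0) {
  S <- methods::as(Matrix::drop0(R), "TsparseMatrix")
  if (length(S@x) == 0L) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric()))
  }
  keep <- S@x > threshold
  i <- S@i[keep] + 1L; j <- S@j[keep] + 1L; x <- S@x[keep]
  seeded <- as.vector(A[cbind(i, j)]) != 0
  tb <- tibble::tibble(
    protein_a = rownames(R)[i][!seeded],
    protein_b = colnames(R)[j][!seeded],
    score = x[!seeded]
  )
  dplyr::arrange(tb, dplyr::desc(.data$score), .data$protein_a, .data$protein_b)
}
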