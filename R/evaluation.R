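#' Overlap score between two protein sets
#'
#' `OS(B, C) = |B intersect C|^2 / (|B| * |C|)`, the neighbourhood-affinity
#' style score used both to filter near-duplicate solutions and to match
#' predictions against known complexes. Lies in `[0, 1]`, equals 1 iff the
#' sets are identical.
#'
#' @param b,c Nonempty character vectors (duplicates ignored).
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' overlap_score(letters[1:4], letters[3:7])
#' @export
overlap_score <- function(b, c) {
  b <- unique(b); c <- unique(c)
  if (!length(b) || !length(c)) stop("overlap_score: sets must be nonempty")
  length(intersect(b, c))^2 / (length(b) * length(c))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Rates in `[0, 1]` (vectorised). Returns 0 where
#'   both are 0.
#' @return F-measure vector.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Match predicted complexes against a known catalogue
#'
#' A prediction matches a known complex when their overlap score is at least
#' `os_threshold`. Counts the matched predictions (MPC, the true positives),
#' the known complexes matched at least once (MKC), and predictions whose
#' protein set is identical to some known complex (PM). Precision is
#' `MPC / PC`, recall is `MKC / known_total`, and the F-measure their
#' harmonic mean. With no predictions, precision and F are defined as 0.
#'
#' @param predicted List of character vectors (predicted complexes), or a
#'   `conserved_alignment` side via [distinct_complexes()].
#' @param known Complex catalogue tibble ([read_complexes()]).
#' @param os_threshold Match threshold on the overlap score; default 0.2.
#' @param known_total Denominator for recall; defaults to the number of
#'   catalogue complexes.
#' @return A `match_report` object (one-row tibble) with columns `pc`,
#'   `mpc`, `mkc`, `pm`, `precision`, `recall`, `f_measure`,
#'   `coverage_rate`, `known_total`.
#' @export
match_stats <- function(predicted, known, os_threshold = 0.2,
                        known_total = nrow(known)) {
  if (!(os_threshold > 0 && os_threshold <= 1)) {
    stop("os_threshold must lie in (0, 1]")
  }
  preds <- lapply(predicted, unique)
  kn <- lapply(known$members, unique)
  pc <- length(preds)
  os <- matrix(0, nrow = pc, ncol = length(kn))
  if (pc && length(kn)) {
    for (i in seq_len(pc)) {
      for (j in seq_along(kn)) {
        os[i, j] <- overlap_score(preds[[i]], kn[[j]])
      }
    }
  }
  hit <- os >= os_threshold
  mpc <- if (pc) sum(apply(hit, 1L, any)) else 0L
  mkc <- if (pc && length(kn)) sum(apply(hit, 2L, any)) else 0L
  pm <- if (pc) sum(vapply(preds, function(p)
    any(vapply(kn, setequal, TRUE, y = p)), TRUE)) else 0L
  precision <- if (pc > 0) mpc / pc else 0
  recall <- if (known_total > 0) mkc / known_total else 0
  cr <- if (length(kn)) coverage_rate(preds, known) else 0
  out <- tibble::tibble(
    pc = pc, mpc = as.integer(mpc), mkc = as.integer(mkc),
    pm = as.integer(pm),
    precision = precision, recall = recall,
    f_measure = f_measure(precision, recall),
    coverage_rate = cr,
    known_total = as.integer(known_total)
  )
  class(out) <- c("match_report", class(out))
  out
}

#' Coverage rate of a known catalogue by predictions
#'
#' For each known complex, the size of its largest intersection with any
#' single prediction, summed over the catalogue and divided by the total
#' protein count of the catalogue. The maximum over an empty prediction
#' list is 0.
#'
#' @param predicted List of character vectors.
#' @param known Complex catalogue tibble (nonempty).
#' @return Numeric scalar in `[0, 1]`.
#' @export
coverage_rate <- function(predicted, known) {
  kn <- lapply(known$members, unique)
  if (!length(kn)) stop("coverage_rate: known catalogue is empty")
  preds <- lapply(predicted, unique)
  best <- vapply(kn, function(k) {
    if (!length(preds)) return(0L)
    max(vapply(preds, function(p) length(intersect(k, p)), 0L))
  }, 0L)
  sum(best) / sum(lengths(kn))
}

#' @exportS3Method generics::glance
glance.match_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::tidy
tidy.match_report <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x))
  tidyr::pivot_longer(tb, dplyr::everything(),
                      names_to = "statistic", values_to = "value",
                      values_transform = as.numeric)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> PC=%d MPC=%d MKC=%d PM=%d | precision=%.4f recall=%.4f F=%.4f CR=%.4f (known_total=%d)\n",
    x$pc, x$mpc, x$mkc, x$pm, x$precision, x$recall, x$f_measure,
    x$coverage_rate, x$known_total))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conserved_alignment <- function(x, ...) {
  tibble::tibble(
    solution_id = x$solution_id,
    size_one = lengths(x$members_one),
    size_two = lengths(x$members_two),
    n_links = vapply(x$links, nrow, 0L),
    origin_subnetwork = x$origin_subnetwork,
    direction = x$direction
  )
}

#' @exportS3Method generics::glance
glance.conserved_alignment <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_solutions = nrow(x),
    n_distinct_one = length(distinct_complexes(x, "one")),
    n_distinct_two = length(distinct_complexes(x, "two")),
    avg_size_one = mean(lengths(x$members_one)),
    avg_size_two = mean(lengths(x$members_two)),
    l = p$l, r = p$r, overlap_t = p$overlap_t
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
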