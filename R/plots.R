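#' Plot the size structure of an alignment's solutions
#'
#' Scatter of network-one versus network-two module sizes, with point size
#' showing multiplicity, faceted by detection direction.
#'
#' @param object A `conserved_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conserved_alignment <- function(object, ...) {
  tb <- tidy(object)
  counts <- dplyr::count(tb, .data$size_one, .data$size_two, .data$direction)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$size_one, y = .data$size_two,
                               size = .data$n)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "module size, network one",
                  y = "module size, network two",
                  size = "solutions",
                  title = "Conserved solution sizes") +
    ggplot2::theme_bw()
}

#' Plot a match report as a metric bar chart
#'
#' @param object A `match_report` from [match_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.match_report <- function(object, ...) {
  tb <- tibble::tibble(
    metric = factor(c("precision", "recall", "F-measure", "coverage rate"),
                    levels = c("precision", "recall", "F-measure",
                               "coverage rate")),
    value = c(object$precision, object$recall, object$f_measure,
              object$coverage_rate)
  )
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Match against known catalogue") +
    ggplot2::theme_bw()
}

#' Plot the mapping-matrix mass around the seed mappings
#'
#' Histogram of the positive walk scores, split into seed ("real") and
#' artificial mappings.
#'
#' @param R Mapping matrix from [bi_random_walk()].
#' @param A Seed matrix.
#' @return A ggplot object.
#' @export
plot_mapping_scores <- function(R, A) {
  S <- methods::as(Matrix::drop0(R), "TsparseMatrix")
  seeded <- as.vector(A[cbind(S@i + 1L, S@j + 1L)]) != 0
  tb <- tibble::tibble(
    score = S@x,
    kind = ifelse(seeded, "real (seed)", "artificial")
  )
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$score, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "walk score", y = "mappings", fill = NULL,
                  title = "Bi-random walk mapping scores") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
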