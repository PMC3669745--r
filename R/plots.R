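#' Plot a reproduced count table
#'
#' Observed versus published configuration counts, one bar pair per table row,
#' on a square-root scale (counts span five orders of magnitude).
#'
#' @param object A [reproduce_table()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.table_reproduction <- function(object, ...) {
  long <- tidyr_pivot_counts(object)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$row), y = .data$count,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "table row", y = "configurations",
                  title = paste0("Model ", object$model[1],
                                 ": observed vs published counts"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

## minimal long-format helper (avoids importing tidyr for one call)
tidyr_pivot_counts <- function(tab) {
  dplyr::bind_rows(
    tibble::tibble(row = tab$row, count = tab$expected, which = "published"),
    tibble::tibble(row = tab$row, count = tab$observed, which = "observed")
  )
}

#' Plot a terminal set
#'
#' Distribution of final signed weights across the terminal configurations,
#' one panel per modifiable connection.
#'
#' @param object A `terminal_set`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.terminal_set <- function(object, ...) {
  exp <- attr(object, "experiment")
  cn <- exp$circuit$connections
  cols <- cn$name[cn$modifiable]
  long <- purrr::map_dfr(cols, function(w) {
    tibble::tibble(connection = w, weight = object[[w]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$weight))) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~connection) +
    ggplot2::labs(x = "final signed weight", y = "configurations",
                  title = paste0("Terminal configurations, model ",
                                 exp$model, " row ", exp$row)) +
    ggplot2::theme_minimal()
}

#' Plot a directed-search batch
#'
#' Final error distribution, split by whether the key interneuron weight
#' underwent extinction LTD.
#'
#' @param object A [batch_search()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.batch_search <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = factor(.data$error), fill = .data$ltd)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "final error", y = "searches",
                  fill = paste0("LTD of ", object$ltd_connection),
                  title = paste0("Model ", object$model, ": ", object$n,
                                 " random-start directed searches")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
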