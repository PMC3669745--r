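#' Did a weight undergo LTD during extinction?
#'
#' A record-tracked weight underwent extinction LTD iff its final magnitude is
#' strictly below the magnitude recorded when conditioning completed.  (Both
#' are stored signed in a terminal set; the comparison is on absolute values.)
#'
#' @param terminals A `terminal_set` from [enumerate_terminals()].
#' @param connection Name of a record-tracked connection, e.g. `"wLAi1toLA1"`.
#' @return A logical vector, one element per terminal configuration.
#' @export
ltd_occurred <- function(terminals, connection) {
  stopifnot(inherits(terminals, "terminal_set"))
  rec_col <- paste0("record.", connection)
  if (!rec_col %in% names(terminals)) {
    stop("'", connection, "' is not record-tracked in this experiment")
  }
  abs(terminals[[connection]]) < abs(terminals[[rec_col]])
}

## filter name -> logical vector over a terminal set
eval_filter <- function(terminals, f) {
  ts <- terminals
  switch(
    f$name,
    ltd_of = ltd_occurred(ts, f$args[1]),
    no_ltd_of = !ltd_occurred(ts, f$args[1]),
    finals_equal = ts[[f$args[1]]] == ts[[f$args[2]]],
    records_equal = ts[[paste0("record.", f$args[1])]] ==
      ts[[paste0("record.", f$args[2])]],
    excited_by_cs = terminal_cs_responses(ts, f$args[1])[, 1] > 0,
    not_inhibited_by_cs = !(terminal_cs_responses(ts, f$args[1])[, 1] < 0),
    any_excited = {
      r <- terminal_cs_responses(ts, f$args)
      apply(r > 0, 1, any)
    },
    stop("unknown filter: ", f$name)
  )
}

## CS responses of elements at each terminal configuration, evaluated at the
## final weights in the extinction context (US = 0, IL = 1; under linear
## semantics the IL value is irrelevant by cancellation).
terminal_cs_responses <- function(terminals, elements) {
  exp <- attr(terminals, "experiment")
  circ <- exp$circuit
  bad <- setdiff(elements, circ$elements$name)
  if (length(bad)) stop("filter references absent element(s): ",
                        paste(bad, collapse = ", "))
  cn <- circ$connections
  M <- abs(as.matrix(terminals[, cn$name, drop = FALSE]))
  if (nrow(M) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = length(elements),
                  dimnames = list(NULL, elements)))
  }
  cs_response_matrix(circ, M, elements, us = 0, il = 1,
                     rectify = attr(terminals, "rectify"))
}

#' Filter a terminal set by constraint predicates
#'
#' Applies a conjunction of terminal-state predicates and returns the
#' satisfying subset, with one annotation column per predicate.  Available
#' predicates: `ltd_of(w)` / `no_ltd_of(w)` (extinction LTD of a
#' record-tracked weight), `finals_equal(w1, w2)`, `records_equal(w1, w2)`,
#' `excited_by_cs(el)` (strictly positive CS response at the final weights),
#' `not_inhibited_by_cs(el)` (CS response not strictly negative), and
#' `any_excited(el, ...)`.  A response of exactly zero counts as neither
#' excited nor inhibited.
#'
#' @param terminals A `terminal_set`.
#' @param filters A list of filters, each `list(name = , args = )`; usually
#'   taken from an [experiment()]'s `$filters`.  An empty list returns the
#'   set unchanged.
#' @return The filtered `terminal_set` (attributes preserved), with logical
#'   annotation columns named `filter.<i>.<name>`.
#' @seealso [count_configurations()]
#' @export
apply_filters <- function(terminals, filters) {
  stopifnot(inherits(terminals, "terminal_set"))
  if (!length(filters)) return(terminals)
  keep <- rep(TRUE, nrow(terminals))
  at <- attributes(terminals)
  for (i in seq_along(filters)) {
    v <- eval_filter(terminals, filters[[i]])
    terminals[[paste(c("filter", i, filters[[i]]$name), collapse = ".")]] <- v
    keep <- keep & v
  }
  out <- terminals[keep, ]
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- at$class
  out
}

#' Count configurations satisfying an experiment's filters
#'
#' @inheritParams apply_filters
#' @return The number of terminal configurations satisfying the conjunction.
#' @export
count_configurations <- function(terminals, filters = list()) {
  nrow(apply_filters(terminals, filters))
}

#' Run one registry experiment end to end
#'
#' Enumerates the experiment's terminal set and applies its filters.
#'
#' @inheritParams enumerate_terminals
#' @return The filtered `terminal_set`.
#' @export
run_experiment <- function(exp, rectify = TRUE) {
  apply_filters(enumerate_terminals(exp, rectify = rectify), exp$filters)
}

#' Reproduce a published count table
#'
#' Runs all 13 registry experiments for a model and compares the observed
#' configuration counts with the published ones.
#'
#' @param model_id 1 or 2.
#' @param rectify Activity semantics flag (see [activities()]).  Under the
#'   rectified default, all of table 1 except row 11 and table 2 rows 1, 2
#'   and 6 reproduce exactly; the remaining rows, whose conditions involve
#'   the CS-response predicates, do not (see the methods vignette for the
#'   analysis of why no per-element response predicate can).
#' @return A tibble of class `table_reproduction` with columns `model`, `row`,
#'   `label`, `space_size`, `expected`, `observed`, `max_depth` and `pass`.
#' @examples
#' \donttest{
#' reproduce_table(1)
#' }
#' @export
reproduce_table <- function(model_id, rectify = TRUE) {
  out <- purrr::map_dfr(1:13, function(r) {
    exp <- experiment(model_id, r)
    ts <- run_experiment(exp, rectify = rectify)
    tibble::tibble(
      model = exp$model, row = r, label = exp$label,
      space_size = config_space_size(exp),
      expected = exp$expected, observed = nrow(ts),
      max_depth = attr(ts, "max_depth"),
      pass = nrow(ts) == exp$expected
    )
  })
  class(out) <- c("table_reproduction", class(out))
  out
}
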