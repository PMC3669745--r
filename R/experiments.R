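## Schedule/structure editing helpers -----------------------------------------

set_schedule <- function(circ, conns, cond = NULL, ext = NULL) {
  i <- match(conns, circ$connections$name)
  if (anyNA(i)) stop("unknown connection(s): ",
                     paste(conns[is.na(i)], collapse = ", "))
  if (!is.null(cond)) circ$connections$cond[i] <- cond
  if (!is.null(ext)) circ$connections$ext[i] <- ext
  validate_circuit(circ)
}

freeze_connections <- function(circ, conns) {
  set_schedule(circ, conns, cond = "", ext = "")
}

set_ties <- function(circ, groups) {
  for (g in names(groups)) {
    i <- match(groups[[g]], circ$connections$name)
    if (anyNA(i)) stop("unknown connection(s) in tie group '", g, "'")
    circ$connections$tie[i] <- g
  }
  validate_circuit(circ)
}

flt <- function(name, ...) list(name = name, args = c(...))

## The 26 registry rows: schedule variants, structural edits and terminal-state
## filters for the two count tables.  Conditions are described in the
## package's own words; `expected` carries the published count for regression.
registry_entries <- function() {
  ltd12 <- list(flt("ltd_of", "wLAi1toLA1"), flt("ltd_of", "wLAi2toLA2"))
  eqf <- flt("finals_equal", "wLAi1toLA1", "wLAi2toLA2")
  eqr <- flt("records_equal", "wLAi1toLA1", "wLAi2toLA2")
  m1 <- list(
    list(label = "baseline: 9 modifiable weights, LTP in conditioning, LTD in extinction",
         filters = list(), expected = 19273L),
    list(label = "baseline + LTD of wLAi1toLA1 (CB1-mediated LTD, No Fear pathway)",
         filters = list(flt("ltd_of", "wLAi1toLA1")), expected = 11310L),
    list(label = "baseline + LTD of wLAi2toLA2 (CB1-mediated LTD, Fear pathway)",
         filters = list(flt("ltd_of", "wLAi2toLA2")), expected = 11761L),
    list(label = "baseline + LTD of both interneuron weights",
         filters = ltd12, expected = 6914L),
    list(label = "row 4 + wLAi1toLA1 = wLAi2toLA2 after extinction",
         filters = c(ltd12, list(eqf)), expected = 3833L),
    list(label = "row 5 + wLAi1toLA1 = wLAi2toLA2 after conditioning as well",
         filters = c(ltd12, list(eqf, eqr)), expected = 2315L),
    list(label = "row 6 with wITCmtoCEm frozen",
         freeze = "wITCmtoCEm",
         filters = c(ltd12, list(eqf, eqr)), expected = 777L),
    list(label = "row 7; wCStoLA1 not conditionable, LTP-only in extinction; wCStoLA2 keeps extinction LTD",
         freeze = "wITCmtoCEm",
         sched = list(list("wCStoLA1", cond = "", ext = "+")),
         filters = c(ltd12, list(eqf, eqr)), expected = 773L),
    list(label = "row 8 with LTP-only extinction for wCStoLA2 as well",
         freeze = "wITCmtoCEm",
         sched = list(list("wCStoLA1", cond = "", ext = "+"),
                      list("wCStoLA2", ext = "+")),
         filters = c(ltd12, list(eqf, eqr)), expected = 619L),
    list(label = "row 9 with the four downstream pathway weights frozen",
         freeze = c("wITCmtoCEm", "wLA1toBA1", "wBA1toITCm", "wLA2toBA2", "wBA2toCEm"),
         sched = list(list("wCStoLA1", cond = "", ext = "+"),
                      list("wCStoLA2", ext = "+")),
         filters = c(ltd12, list(eqf, eqr)), expected = 6L),
    list(label = "row 10 with extinction LTD of the interneuron weights disallowed; equality filters only",
         freeze = c("wITCmtoCEm", "wLA1toBA1", "wBA1toITCm", "wLA2toBA2", "wBA2toCEm"),
         sched = list(list("wCStoLA1", cond = "", ext = "+"),
                      list("wCStoLA2", ext = "+"),
                      list("wLAi1toLA1", ext = ""),
                      list("wLAi2toLA2", ext = "")),
         filters = list(eqf, eqr), expected = 3L),
    list(label = "row 10 with wCStoLA1 fully frozen",
         freeze = c("wITCmtoCEm", "wLA1toBA1", "wBA1toITCm", "wLA2toBA2",
                    "wBA2toCEm", "wCStoLA1"),
         sched = list(list("wCStoLA2", ext = "+")),
         filters = c(ltd12, list(eqf, eqr)), expected = 0L),
    list(label = "baseline with BA1 and BA2 removed",
         remove = c("BA1", "BA2"),
         filters = list(), expected = 0L)
  )

  cs3 <- c("wCStoLAi", "wCStoLA1", "wCStoLA2")
  la2 <- c("wLA1toITCl", "wLA2toITCl")
  il3 <- c("wILtoLAi", "wILtoITCl", "wILtoITCm")
  ltd1 <- flt("ltd_of", "wLAitoLA1")
  exc <- flt("any_excited", "LA1", "LA2")
  ni1 <- flt("not_inhibited_by_cs", "LA1")
  ni2 <- flt("not_inhibited_by_cs", "LA2")
  m2 <- list(
    list(label = "baseline: 6 weights LTP/LTD in conditioning/extinction, 3 IL weights LTP-only in extinction",
         filters = list(), expected = 8394L),
    list(label = "baseline + LTD of wLAitoLA1 (CB1-mediated LTD required)",
         filters = list(ltd1), expected = 4659L),
    list(label = "row 2 + LA1 or LA2 excited by CS after extinction",
         filters = list(ltd1, exc), expected = 2335L),
    list(label = "row 3 + neither LA1 nor LA2 inhibited by CS after extinction",
         filters = list(ltd1, exc, ni1, ni2), expected = 957L),
    list(label = "row 4 with extinction LTD of wLA1toITCl and wLA2toITCl disallowed",
         sched = list(list("wLA1toITCl", ext = ""), list("wLA2toITCl", ext = "")),
         filters = list(ltd1, exc, ni1, ni2), expected = 129L),
    list(label = "row 5 with the three IL weights frozen as well",
         sched = list(list("wLA1toITCl", ext = ""), list("wLA2toITCl", ext = "")),
         freeze = il3,
         filters = list(ltd1, exc, ni1, ni2), expected = 0L),
    list(label = "row 6 but with extinction LTD of wLA1toITCl and wLA2toITCl re-allowed",
         freeze = il3,
         filters = list(ltd1, exc, ni1, ni2), expected = 49L),
    list(label = "row 4 with tied updates: CS triplet, LA pair and IL triplet each change jointly",
         ties = list(CS = cs3, LA = la2, IL = il3),
         filters = list(ltd1, exc, ni1, ni2), expected = 0L),
    list(label = "row 8 without requiring LTD of wLAitoLA1",
         ties = list(CS = cs3, LA = la2, IL = il3),
         filters = list(exc, ni1, ni2), expected = 0L),
    list(label = "row 4 with LA pair and IL triplet tied (CS weights free)",
         ties = list(LA = la2, IL = il3),
         filters = list(ltd1, exc, ni1, ni2), expected = 0L),
    list(label = "row 4 with CS triplet and IL triplet tied (LA weights free)",
         ties = list(CS = cs3, IL = il3),
         filters = list(ltd1, exc, ni1, ni2), expected = 21L),
    list(label = "row 4 with CS triplet and LA pair tied (IL weights free)",
         ties = list(CS = cs3, LA = la2),
         filters = list(ltd1, exc, ni1, ni2), expected = 42L),
    list(label = "row 4 filters without the LTD requirement; extinction LTD of wLAitoLA1 disallowed",
         sched = list(list("wLAitoLA1", ext = "")),
         filters = list(exc, ni1, ni2), expected = 303L)
  )
  list(`1` = m1, `2` = m2)
}

#' Look up a registry experiment
#'
#' The registry holds the 26 search conditions analysed for the two models:
#' rows 1-13 of each count table.  Each entry is a schedule variant (which
#' unit weight moves are allowed in each phase), optional structural edits
#' (element removal), optional tied-update groups (weights constrained to
#' change jointly by the same amount), and a conjunction of terminal-state
#' filters.
#'
#' @param model_id 1 or 2.
#' @param row_id Row number, 1 to 13.
#' @return An object of class `experiment`: the edited circuit, the filter
#'   list, the published count (`expected`) for regression, and bookkeeping
#'   fields.
#' @seealso [experiments()] for the full registry as a tibble,
#'   [enumerate_terminals()] to run one, [reproduce_table()] to run all.
#' @export
experiment <- function(model_id, row_id) {
  model_id <- as.integer(model_id)
  row_id <- as.integer(row_id)
  if (!model_id %in% c(1L, 2L)) stop("model_id must be 1 or 2")
  if (!row_id %in% 1:13) stop("row_id must be in 1..13")
  entry <- registry_entries()[[as.character(model_id)]][[row_id]]
  circ <- if (model_id == 1L) model1() else model2()
  if (!is.null(entry$remove)) circ <- suppressMessages(remove_elements(circ, entry$remove))
  if (!is.null(entry$freeze)) circ <- freeze_connections(circ, entry$freeze)
  for (s in entry$sched %||% list()) {
    circ <- set_schedule(circ, s[[1]], cond = s$cond, ext = s$ext)
  }
  if (!is.null(entry$ties)) circ <- set_ties(circ, entry$ties)
  structure(
    list(model = model_id, row = row_id, label = entry$label,
         circuit = circ, filters = entry$filters,
         expected = entry$expected, dims = exp_dims(circ)),
    class = "experiment"
  )
}

#' @export
print.experiment <- function(x, ...) {
  cat("<experiment> model ", x$model, ", row ", x$row, ": ", x$label, "\n",
      "  configuration space: ", config_space_size(x),
      if (!is.na(x$expected)) paste0("; published count: ", x$expected), "\n",
      sep = "")
  invisible(x)
}

#' Build an experiment from a custom circuit
#'
#' Wraps any [circuit_spec()] circuit (with its schedule encoded in the
#' `cond`/`ext` columns) as an experiment so it can be run through
#' [enumerate_terminals()] and [apply_filters()].
#'
#' @param circuit A [circuit_spec()] object.
#' @param filters List of terminal filters (see [apply_filters()]).
#' @param label Description of the search condition.
#' @param expected Optional reference count for regression.
#' @return An `experiment` object with `model = NA`.
#' @export
custom_experiment <- function(circuit, filters = list(), label = "custom",
                              expected = NA_integer_) {
  stopifnot(inherits(circuit, "circuit"))
  structure(
    list(model = NA_integer_, row = NA_integer_, label = label,
         circuit = circuit, filters = filters,
         expected = as.integer(expected), dims = exp_dims(circuit)),
    class = "experiment"
  )
}

#' The experiment registry as a tibble
#'
#' @return One row per registry entry: model, row, condition description,
#'   configuration-space size and the published count.
#' @export
experiments <- function() {
  purrr::map_dfr(1:2, function(m) {
    purrr::map_dfr(1:13, function(r) {
      e <- experiment(m, r)
      tibble::tibble(model = m, row = r, label = e$label,
                     space_size = config_space_size(e), expected = e$expected)
    })
  })
}

## Independent search dimensions of an experiment: one per untied modifiable
## connection with a non-empty move set, one per tie group.  Each dim carries
## the connection indices it writes, its common initial magnitude and the
## allowed step directions per phase.
exp_dims <- function(circ) {
  cn <- circ$connections
  live <- cn$modifiable & (cn$cond != "" | cn$ext != "")
  dirset <- function(s) switch(s, "+" = 1L, "-" = -1L, "+-" = c(1L, -1L), integer(0))
  dims <- list()
  seen_tie <- character(0)
  for (i in which(live)) {
    g <- cn$tie[i]
    if (!is.na(g)) {
      if (g %in% seen_tie) next
      seen_tie <- c(seen_tie, g)
      idx <- which(!is.na(cn$tie) & cn$tie == g)
    } else {
      idx <- i
    }
    dims[[length(dims) + 1L]] <- list(
      name = if (!is.na(g)) paste(cn$name[idx], collapse = "="),
      conns = idx,
      init = cn$initial[idx[1]],
      cond = dirset(cn$cond[idx[1]]),
      ext = dirset(cn$ext[idx[1]])
    )
  }
  for (d in seq_along(dims)) {
    if (is.null(dims[[d]]$name)) dims[[d]]$name <- cn$name[dims[[d]]$conns]
  }
  dims
}

#' Size of an experiment's configuration space
#'
#' Registry arithmetic: each independent search dimension (an untied
#' modifiable weight, or one tie group changing jointly) contributes 3
#' magnitude levels; each record-tracked weight whose dimension can be
#' potentiated during conditioning contributes a factor 2 for its
#' post-conditioning record (stay at 1 or rise to 2).
#'
#' @param x An [experiment()] object.
#' @return An integer.
#' @export
config_space_size <- function(x) {
  stopifnot(inherits(x, "experiment"))
  dims <- exp_dims(x$circuit)
  cn <- x$circuit$connections
  nrec <- sum(vapply(dims, function(d) {
    any(cn$record[d$conns]) && length(d$cond) > 0
  }, logical(1)))
  3L^length(dims) * 2L^nrec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
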