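#' Build a circuit specification
#'
#' A circuit is a small feedforward rate-coded network: a set of named
#' elements, each with an additive bias, connected by signed weighted
#' connections.  The activity of every non-input element is the linear sum of
#' its weighted inputs plus its bias; a single gate element (conventionally
#' `PAG`) fires if and only if its summed input is strictly positive.
#' Connection weights are parameterised by a *magnitude* in `[0, 2]`; the
#' signed weight is `sign * magnitude`, so excitatory weights range over
#' `{0, +1, +2}` and inhibitory weights over `{0, -1, -2}` in integer mode.
#'
#' @param elements A data frame with columns `name` (unique identifiers),
#'   `bias` (numeric activity offsets, dimensionless firing-rate units) and
#'   `kind` (one of `"input"`, `"internal"`, `"gate"`).
#' @param connections A data frame with columns `source`, `target`, `sign`
#'   (`+1` or `-1`), `initial` (initial magnitude, in `[0, 2]`), `modifiable`
#'   (logical), `record` (logical: snapshot this weight at the end of
#'   conditioning), `tie` (character tie-group label, `NA` for untied), and
#'   the plasticity schedule columns `cond` and `ext`, each one of `""`
#'   (no change allowed), `"+"` (unit magnitude increase, LTP), `"-"` (unit
#'   magnitude decrease, LTD) or `"+-"`.
#'
#' @return A validated object of class `circuit`: the two tibbles plus a
#'   fixed topological evaluation order.  Connections are named
#'   `w<source>to<target>`.
#'
#' @details Validation enforces: unique element names; connections refer only
#'   to declared elements; the connection graph is acyclic (circuits are
#'   evaluated as one feedforward pass, no iterative settling); input elements
#'   have no incoming connections and bias 0; record-tracked connections are
#'   modifiable; members of a tie group have equal initial magnitudes and
#'   identical schedules.
#'
#' @examples
#' toy <- circuit_spec(
#'   elements = data.frame(
#'     name = c("CS", "CEm", "PAG"),
#'     bias = c(0, 0, 0),
#'     kind = c("input", "internal", "gate")
#'   ),
#'   connections = data.frame(
#'     source = c("CS", "CEm"), target = c("CEm", "PAG"),
#'     sign = c(1, 1), initial = c(0, 1),
#'     modifiable = c(TRUE, FALSE), record = c(TRUE, FALSE),
#'     tie = NA_character_, cond = c("+", ""), ext = c("-", "")
#'   )
#' )
#' activities(toy, cs = 1)
#' @export
circuit_spec <- function(elements, connections) {
  el <- tibble::as_tibble(elements)
  cn <- tibble::as_tibble(connections)
  stopifnot(
    all(c("name", "bias", "kind") %in% names(el)),
    all(c("source", "target", "sign", "initial", "modifiable",
          "record", "tie", "cond", "ext") %in% names(cn))
  )
  if (nrow(el) == 0L) stop("circuit has no elements")
  if (anyDuplicated(el$name)) stop("duplicate element names")
  if (!all(el$kind %in% c("input", "internal", "gate"))) {
    stop("element kind must be 'input', 'internal' or 'gate'")
  }

  unknown <- setdiff(c(cn$source, cn$target), el$name)
  if (length(unknown)) {
    stop("connection refers to undeclared element(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!all(cn$sign %in% c(-1, 1))) stop("connection sign must be +1 or -1")
  if (any(cn$initial < 0 | cn$initial > 2)) {
    stop("initial magnitudes must lie in [0, 2]")
  }
  if (any(cn$record & !cn$modifiable)) {
    stop("record-tracked connections must be modifiable")
  }
  bad_sched <- !(cn$cond %in% c("", "+", "-", "+-")) |
    !(cn$ext %in% c("", "+", "-", "+-"))
  if (any(bad_sched)) stop("schedule entries must be '', '+', '-' or '+-'")
  if (any(!cn$modifiable & (cn$cond != "" | cn$ext != ""))) {
    stop("non-modifiable connections must have empty move sets")
  }

  cn$name <- paste0("w", cn$source, "to", cn$target)
  if (anyDuplicated(cn$name)) stop("duplicate connections")

  inputs <- el$name[el$kind == "input"]
  if (any(cn$target %in% inputs)) stop("input elements cannot receive connections")
  if (any(el$bias[el$kind == "input"] != 0)) stop("input elements must have bias 0")

  for (g in unique(stats::na.omit(cn$tie))) {
    grp <- cn[!is.na(cn$tie) & cn$tie == g, ]
    if (length(unique(grp$initial)) != 1L) {
      stop("tie group '", g, "' has unequal initial magnitudes")
    }
    if (length(unique(grp$cond)) != 1L || length(unique(grp$ext)) != 1L) {
      stop("tie group '", g, "' has non-identical schedules")
    }
    if (any(!grp$modifiable)) stop("tie group '", g, "' contains a fixed connection")
  }

  g <- igraph::graph_from_data_frame(
    cn[, c("source", "target")], directed = TRUE,
    vertices = el[, "name", drop = FALSE]
  )
  if (!igraph::is_dag(g)) stop("cycle detected: circuit must be feedforward")
  topo <- igraph::topo_sort(g, mode = "out")$name
  topo <- topo[!(topo %in% inputs)]

  incoming <- lapply(topo, function(e) which(cn$target == e))
  names(incoming) <- topo

  structure(
    list(elements = el, connections = cn, topo = topo, incoming = incoming),
    class = "circuit"
  )
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", nrow(x$elements), " elements, ",
      nrow(x$connections), " connections (",
      sum(x$connections$modifiable), " modifiable)\n", sep = "")
  invisible(x)
}

#' @export
validate_circuit <- function(circuit) {
  circuit_spec(circuit$elements, circuit$connections)
}

## Internal vectorised evaluator.  `M` is an n-by-n_connection matrix of
## magnitudes (rows are weight assignments); context values are scalars.
## Returns a list of activity vectors, one per non-input element, plus the
## input values.  Gate elements fire 0/1 on strictly positive summed input.
eval_activities <- function(circ, M, us = 0, cs = 0, il = 0, rectify = TRUE) {
  cn <- circ$connections
  ctx <- c(US = us, CS = cs, IL = il)
  act <- list()
  for (e in circ$elements$name[circ$elements$kind == "input"]) {
    act[[e]] <- if (e %in% names(ctx)) ctx[[e]] else 0
  }
  bias <- stats::setNames(circ$elements$bias, circ$elements$name)
  kind <- stats::setNames(circ$elements$kind, circ$elements$name)
  for (e in circ$topo) {
    a <- bias[[e]]
    for (i in circ$incoming[[e]]) {
      a <- a + cn$sign[i] * M[, i] * act[[cn$source[i]]]
    }
    if (kind[[e]] == "gate") {
      a <- as.numeric(a > 0)
    } else if (rectify) {
      a <- pmax(a, 0)
    }
    act[[e]] <- unname(a)
  }
  act
}

## Resolve a user-supplied magnitude vector (named, per connection) against
## the circuit's initial magnitudes; returns a 1-row matrix.
resolve_magnitudes <- function(circ, magnitudes = NULL) {
  m <- circ$connections$initial
  names(m) <- circ$connections$name
  if (!is.null(magnitudes)) {
    unknown <- setdiff(names(magnitudes), names(m))
    if (length(unknown)) stop("unknown connection(s): ", paste(unknown, collapse = ", "))
    m[names(magnitudes)] <- magnitudes
  }
  if (any(m < 0 | m > 2)) stop("magnitudes must lie in [0, 2]")
  matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
}

#' Evaluate element activities for a weight assignment
#'
#' Computes the activity of every element in a single feedforward pass:
#' inputs take their context values, every other element is its bias plus the
#' sum of signed weight times source activity, and the gate element (`PAG`)
#' fires iff its summed input is strictly positive.
#'
#' @param circuit A [circuit_spec()] object.
#' @param magnitudes Optional named numeric vector of connection magnitudes
#'   (absolute weight values, in `[0, 2]`); unnamed connections keep their
#'   initial magnitudes.
#' @param us,cs,il Binary context inputs: unconditioned stimulus, conditioned
#'   stimulus, and infralimbic cortex drive (ignored by circuits without an
#'   `IL` element).
#' @param rectify If `TRUE` (the default, calibrated against the published
#'   configuration counts), every non-input, non-gate activity is floored at
#'   zero, as firing rates cannot be negative; `FALSE` selects the fully
#'   linear alternative in which activities may go negative.
#' @return A one-row tibble with one column per element plus `pag_active`.
#' @export
activities <- function(circuit, magnitudes = NULL, us = 0, cs = 0, il = 0,
                       rectify = TRUE) {
  stopifnot(inherits(circuit, "circuit"))
  M <- resolve_magnitudes(circuit, magnitudes)
  act <- eval_activities(circuit, M, us = us, cs = cs, il = il, rectify = rectify)
  out <- tibble::as_tibble(lapply(act[circuit$elements$name], function(v) v[1]))
  out$pag_active <- pag_from_activities(circuit, act)
  out
}

pag_from_activities <- function(circ, act) {
  gate <- circ$elements$name[circ$elements$kind == "gate"]
  if (length(gate) != 1L) stop("circuit must have exactly one gate element")
  act[[gate]][1] > 0
}

## Vectorised gate flag over rows of a magnitude matrix.
pag_flags <- function(circ, M, us = 0, cs = 0, il = 0, rectify = TRUE) {
  act <- eval_activities(circ, M, us = us, cs = cs, il = il, rectify = rectify)
  gate <- circ$elements$name[circ$elements$kind == "gate"]
  v <- act[[gate]]
  if (length(v) == 1L) v <- rep(v, nrow(M))
  v > 0
}

#' Is the fear output gate active?
#'
#' The periaqueductal gray (PAG) gate is active iff the activity feeding it
#' (CEm) is strictly positive; an input of exactly zero leaves it off.
#'
#' @inheritParams activities
#' @return A logical scalar.
#' @export
pag_active <- function(circuit, magnitudes = NULL, us = 0, cs = 0, il = 0,
                       rectify = TRUE) {
  M <- resolve_magnitudes(circuit, magnitudes)
  pag_flags(circuit, M, us = us, cs = cs, il = il, rectify = rectify)[1]
}

#' Response of an element to the conditioned stimulus
#'
#' The CS response of an element is its activity with `CS = 1` minus its
#' activity with `CS = 0`, all other context inputs held fixed.  An element is
#' *excited* by CS if the response is strictly positive and *inhibited* if it
#' is strictly negative.  Under the default linear semantics the response is
#' independent of the `IL` context value (the IL contribution cancels in the
#' difference); under rectified semantics it need not be.
#'
#' @inheritParams activities
#' @param element Name(s) of non-input element(s).
#' @return A named numeric vector of responses.
#' @export
cs_response <- function(circuit, element, magnitudes = NULL, us = 0, il = 0,
                        rectify = TRUE) {
  stopifnot(inherits(circuit, "circuit"))
  bad <- element[!(element %in% circuit$elements$name)]
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(element %in% circuit$elements$name[circuit$elements$kind == "input"])) {
    stop("cs_response is defined for non-input elements only")
  }
  M <- resolve_magnitudes(circuit, magnitudes)
  a1 <- eval_activities(circuit, M, us = us, cs = 1, il = il, rectify = rectify)
  a0 <- eval_activities(circuit, M, us = us, cs = 0, il = il, rectify = rectify)
  vapply(element, function(e) a1[[e]][1] - a0[[e]][1], numeric(1))
}

## Vectorised CS responses over rows of a magnitude matrix; returns a matrix
## with one column per requested element.
cs_response_matrix <- function(circ, M, elements, us = 0, il = 0, rectify = TRUE) {
  a1 <- eval_activities(circ, M, us = us, cs = 1, il = il, rectify = rectify)
  a0 <- eval_activities(circ, M, us = us, cs = 0, il = il, rectify = rectify)
  out <- vapply(elements, function(e) {
    v <- a1[[e]] - a0[[e]]
    if (length(v) == 1L) v <- rep(v, nrow(M))
    v
  }, numeric(nrow(M)))
  if (nrow(M) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, elements))
  out
}
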