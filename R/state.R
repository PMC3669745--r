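## Phase test contexts.  Conditioning success is probed with the cue alone
## (CS = 1, US = 0, IL = 0); extinction success and all post-extinction
## predicates with the cue during extinction training (CS = 1, US = 0, and
## IL = 1 where an IL element exists).  At the phase boundary the two
## coincide, because IL weights are still 0 when conditioning completes.
ctx_conditioning <- list(us = 0, cs = 1, il = 0)
ctx_extinction <- list(us = 0, cs = 1, il = 1)

state_pag <- function(circ, mags, ctx, rectify = TRUE) {
  M <- matrix(mags, nrow = 1)
  pag_flags(circ, M, us = ctx$us, cs = ctx$cs, il = ctx$il, rectify = rectify)[1]
}

#' Initial search state of an experiment
#'
#' A search state is the unit of state-space identity: the learning phase
#' (`"conditioning"`, `"extinguishing"` or `"done"`), the current magnitude of
#' every connection, and - once conditioning has completed - the recorded
#' magnitudes of the record-tracked connections.
#'
#' @param exp An [experiment()] object.
#' @return An object of class `search_state`.
#' @export
initial_state <- function(exp) {
  stopifnot(inherits(exp, "experiment"))
  circ <- exp$circuit
  structure(
    list(phase = "conditioning",
         mags = stats::setNames(circ$connections$initial, circ$connections$name),
         records = NULL, depth = 0L),
    class = "search_state"
  )
}

#' @export
print.search_state <- function(x, ...) {
  cat("<search_state> phase ", x$phase, ", depth ", x$depth, "\n", sep = "")
  print(x$mags)
  if (!is.null(x$records)) { cat("records:\n"); print(x$records) }
  invisible(x)
}

#' Moves applicable in a search state
#'
#' Weights change one at a time (a tie group counts as one joint move): during
#' conditioning, the allowed conditioning step of any dimension whose unit
#' step stays within magnitude bounds `[0, 2]`; during extinction, the allowed
#' extinction step.  A completed (`"done"`) state offers no moves.  Moves are
#' listed in connection declaration order, so traversal is reproducible.
#'
#' @param state A [initial_state()] search state.
#' @param exp The experiment it belongs to.
#' @param rectify Activity semantics flag, see [activities()].
#' @return A tibble with columns `dim` (dimension index), `name` and
#'   `direction` (+1 LTP, -1 LTD).
#' @export
applicable_moves <- function(state, exp, rectify = TRUE) {
  dims <- exp_dims(exp$circuit)
  empty <- tibble::tibble(dim = integer(), name = character(), direction = integer())
  if (state$phase == "done") return(empty)
  out <- empty
  for (d in seq_along(dims)) {
    dirs <- if (state$phase == "conditioning") dims[[d]]$cond else dims[[d]]$ext
    m <- state$mags[dims[[d]]$conns[1]]
    for (dir in dirs) {
      if ((dir > 0 && m < 2) || (dir < 0 && m > 0)) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          dim = d, name = dims[[d]]$name, direction = dir))
      }
    }
  }
  out
}

#' Apply one move and run the phase-transition logic
#'
#' The named dimension's magnitude changes by one unit (all members of a tie
#' group together).  If the circuit's PAG gate then fires under the
#' conditioning test context while conditioning, conditioning is complete: the
#' record-tracked magnitudes are snapshotted and the phase becomes
#' `"extinguishing"`.  If the gate stops firing under the extinction test
#' context while extinguishing, the state becomes `"done"` - a terminal
#' (extinguished) configuration.
#'
#' @inheritParams applicable_moves
#' @param dim Dimension index (as in [applicable_moves()]).
#' @param direction +1 or -1.
#' @return The successor `search_state`.
#' @export
apply_move <- function(state, exp, dim, direction, rectify = TRUE) {
  dims <- exp_dims(exp$circuit)
  circ <- exp$circuit
  ok <- applicable_moves(state, exp, rectify = rectify)
  if (!any(ok$dim == dim & ok$direction == direction)) {
    stop("move not applicable in this state")
  }
  d <- dims[[dim]]
  state$mags[d$conns] <- state$mags[d$conns] + direction
  state$depth <- state$depth + 1L
  if (state$phase == "conditioning") {
    if (state_pag(circ, state$mags, ctx_conditioning, rectify)) {
      tracked <- circ$connections$name[circ$connections$record]
      state$records <- state$mags[tracked]
      state$phase <- "extinguishing"
    }
  } else if (state$phase == "extinguishing") {
    if (!state_pag(circ, state$mags, ctx_extinction, rectify)) {
      state$phase <- "done"
    }
  }
  state
}
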