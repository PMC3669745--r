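## Exhaustive terminal-state enumeration.
##
## The engine exploits three structural facts about the registry experiments:
## (1) magnitudes live on {0,1,2}^K, so every weight assignment has an integer
##     code in [0, 3^K);
## (2) within a phase each dimension moves in a single direction, so the
##     signed digit sum phi is a potential that increases by exactly 1 per
##     move - every path between two states has the same length, and a sweep
##     over phi levels is simultaneously a breadth-first traversal and a
##     topological order for search-depth bookkeeping;
## (3) gate activity for the whole cube can be evaluated once, vectorised.
##
## States are keyed as code + 3^K * record-index, so the same final weights
## reached with different post-conditioning records count as distinct
## configurations.

## digit of `codes` at dimension d (0-based powers p3)
digit_at <- function(codes, p3d) (codes %/% p3d) %% 3L

## aggregate (keys, vals) -> unique keys with min val
agg_min <- function(keys, vals) {
  o <- order(keys, vals)
  keep <- !duplicated(keys[o])
  list(keys = keys[o][keep], vals = vals[o][keep])
}

#' Enumerate all terminal (extinguished) configurations of an experiment
#'
#' Explores the two-phase rewriting semantics exhaustively: from the initial
#' weights, every allowed unit conditioning step is applied in all possible
#' orders (with memoization on state identity) until the cue alone activates
#' PAG; the record-tracked magnitudes are snapshotted at that point; then
#' every allowed unit extinction step is applied until the cue no longer
#' activates PAG.  Each distinct completed (final magnitudes, records) pair is
#' one terminal configuration.
#'
#' @param exp An [experiment()] object.
#' @param rectify If `TRUE`, activities are floored at zero during evaluation
#'   (see [activities()]).  The rectified default is the setting calibrated
#'   against the published counts; model 1 is insensitive to it.
#' @return A `terminal_set`: a tibble with one row per terminal configuration,
#'   one signed-weight column per connection, one `record.*` column per
#'   record-tracked connection, and `depth`, the state's search depth (the
#'   length of the shortest rule-execution sequence reaching it, which is the
#'   tree depth at which a memoized breadth-first traversal discovers it).
#'   Attributes carry the experiment, `max_depth` (the depth at which the
#'   whole traversal, dead-ends included, is exhausted) and dead-end counts:
#'   conditioning states with no moves left that never activated PAG, and
#'   extinction states with no moves left where PAG never shut off.  Neither
#'   kind of dead-end is a terminal configuration.
#' @examples
#' ts <- enumerate_terminals(experiment(1, 10))
#' nrow(ts)               # published count: 6
#' attr(ts, "max_depth")  # < 20
#' @export
enumerate_terminals <- function(exp, rectify = TRUE) {
  stopifnot(inherits(exp, "experiment"))
  circ <- exp$circuit
  cn <- circ$connections
  dims <- exp_dims(circ)
  K <- length(dims)
  if (any(vapply(dims, function(d) length(d$cond) > 1 || length(d$ext) > 1, logical(1)))) {
    stop("the memoized engine requires at most one step direction per phase; ",
         "use enumerate_terminals_naive()")
  }
  ncode <- 3L^K
  p3 <- 3L^(seq_len(K) - 1L)
  codes <- seq_len(ncode) - 1L

  ## magnitudes for the whole cube
  M <- matrix(rep(cn$initial, each = ncode), nrow = ncode)
  for (d in seq_len(K)) {
    M[, dims[[d]]$conns] <- digit_at(codes, p3[d])
  }
  pag_cond <- pag_flags(circ, M, us = ctx_conditioning$us, cs = ctx_conditioning$cs,
                        il = ctx_conditioning$il, rectify = rectify)
  pag_ext <- pag_flags(circ, M, us = ctx_extinction$us, cs = ctx_extinction$cs,
                       il = ctx_extinction$il, rectify = rectify)

  ## record-tracked dimensions (each is a singleton connection by validation)
  rdims <- which(vapply(dims, function(d) any(cn$record[d$conns]), logical(1)))
  R <- length(rdims)
  pr3 <- 3L^(seq_len(R) - 1L)
  nrec <- 3L^R
  rec_index <- function(code) {
    if (R == 0L) return(rep(0L, length(code)))
    idx <- 0L
    for (j in seq_len(R)) idx <- idx + digit_at(code, p3[rdims[j]]) * pr3[j]
    idx
  }

  init_code <- sum(vapply(dims, function(d) d$init, numeric(1)) * p3)
  if (pag_cond[init_code + 1L]) {
    stop("PAG already active under the cue at the initial weights")
  }

  cond_moves <- purrr::keep(purrr::imap(dims, function(d, i) {
    if (length(d$cond)) list(d = i, dir = d$cond) else NULL
  }), Negate(is.null))
  ext_moves <- purrr::keep(purrr::imap(dims, function(d, i) {
    if (length(d$ext)) list(d = i, dir = d$ext) else NULL
  }), Negate(is.null))

  ## extinction potential: signed digit sum over extinction-mobile dims
  ext_dir <- integer(K)
  for (m in ext_moves) ext_dir[m$d] <- m$dir
  phi_ext <- function(code) {
    v <- integer(length(code))
    for (d in which(ext_dir != 0L)) v <- v + ext_dir[d] * digit_at(code, p3[d])
    v
  }

  ## ---- conditioning sweep (levels of the increase potential) ----
  frontier <- init_code
  lvl <- 0L
  max_depth <- 0L
  n_cond_deadend <- 0L
  entry_keys <- integer(0)
  entry_psi <- integer(0)
  while (length(frontier)) {
    max_depth <- max(max_depth, lvl)
    succ <- integer(0)
    has_move <- rep(FALSE, length(frontier))
    for (m in cond_moves) {
      dg <- digit_at(frontier, p3[m$d])
      ok <- if (m$dir > 0L) dg < 2L else dg > 0L
      has_move <- has_move | ok
      succ <- c(succ, frontier[ok] + m$dir * p3[m$d])
    }
    n_cond_deadend <- n_cond_deadend + sum(!has_move)
    if (!length(succ)) break
    succ <- unique(succ)
    lvl <- lvl + 1L
    act <- pag_cond[succ + 1L]
    ent <- succ[act]
    if (length(ent)) {
      entry_keys <- c(entry_keys, ent + ncode * rec_index(ent))
      entry_psi <- c(entry_psi, lvl - phi_ext(ent))
      max_depth <- max(max_depth, lvl)
    }
    frontier <- succ[!act]
  }

  ## ---- extinction sweep (levels of phi_ext; psi carries the conditioning
  ## path length so that psi + phi is the search depth of a state: the length
  ## of the shortest rewrite sequence reaching it, which is what a memoized
  ## breadth-first traversal of the state graph explores) ----
  term_keys <- integer(0)
  term_depth <- integer(0)
  n_ext_deadend <- 0L
  n_entries <- length(entry_keys)
  if (n_entries) {
    e_phi <- phi_ext(entry_keys %% ncode)
    pending <- split(seq_along(entry_keys), e_phi)
    vmin <- min(e_phi)
    vmax <- sum(2L * pmax(ext_dir, 0L))
    cur_keys <- integer(0)
    cur_psi <- integer(0)
    for (v in vmin:vmax) {
      pv <- pending[[as.character(v)]]
      if (!is.null(pv)) {
        a <- agg_min(c(cur_keys, entry_keys[pv]), c(cur_psi, entry_psi[pv]))
        cur_keys <- a$keys; cur_psi <- a$vals
      }
      if (!length(cur_keys)) {
        if (all(as.integer(names(pending)) <= v)) break else next
      }
      max_depth <- max(max_depth, max(cur_psi) + v)
      succ_keys <- integer(0)
      succ_psi <- integer(0)
      has_move <- rep(FALSE, length(cur_keys))
      code <- cur_keys %% ncode
      for (m in ext_moves) {
        dg <- digit_at(code, p3[m$d])
        ok <- if (m$dir > 0L) dg < 2L else dg > 0L
        has_move <- has_move | ok
        succ_keys <- c(succ_keys, cur_keys[ok] + m$dir * p3[m$d])
        succ_psi <- c(succ_psi, cur_psi[ok])
      }
      n_ext_deadend <- n_ext_deadend + sum(!has_move)
      if (!length(succ_keys)) { cur_keys <- integer(0); cur_psi <- integer(0); next }
      a <- agg_min(succ_keys, succ_psi)
      done <- !pag_ext[(a$keys %% ncode) + 1L]
      term_keys <- c(term_keys, a$keys[done])
      term_depth <- c(term_depth, a$vals[done] + v + 1L)
      cur_keys <- a$keys[!done]
      cur_psi <- a$vals[!done]
    }
    max_depth <- max(max_depth, if (length(term_depth)) max(term_depth) else 0L)
  }

  ## ---- decode terminal keys into a tidy atlas ----
  o <- order(term_keys)
  term_keys <- term_keys[o]
  term_depth <- term_depth[o]
  n <- length(term_keys)
  code <- term_keys %% ncode
  rec <- term_keys %/% ncode
  out <- tibble::tibble(.rows = n)
  final_M <- matrix(rep(cn$initial, each = max(n, 1L)), nrow = max(n, 1L))
  if (n) {
    for (d in seq_len(K)) {
      final_M[, dims[[d]]$conns] <- digit_at(code, p3[d])
    }
  }
  for (i in seq_len(nrow(cn))) {
    out[[cn$name[i]]] <- if (n) cn$sign[i] * final_M[, i] else numeric(0)
  }
  for (j in seq_len(R)) {
    i <- dims[[rdims[j]]]$conns[1]
    out[[paste0("record.", cn$name[i])]] <-
      if (n) cn$sign[i] * digit_at(rec, pr3[j]) else numeric(0)
  }
  out$depth <- term_depth
  structure(out,
            class = c("terminal_set", class(out)),
            experiment = exp, rectify = rectify, engine = "memoized",
            max_depth = max_depth, n_entries = n_entries,
            n_conditioning_deadends = n_cond_deadend,
            n_extinction_deadends = n_ext_deadend)
}

#' Brute-force oracle: enumerate every rule-execution sequence
#'
#' Walks the unmemoized state-transition tree depth-first via
#' [applicable_moves()] and [apply_move()], collecting every distinct
#' completed configuration and, for each, the shortest sequence reaching it.
#' Exponentially slower than [enumerate_terminals()]; intended as an
#' independent correctness oracle on small experiments.
#'
#' @inheritParams enumerate_terminals
#' @param depth_limit Paths longer than this abort the walk (safety net).
#' @param max_paths Budget on the number of root-to-leaf paths.
#' @return A `terminal_set` tibble with the same columns as
#'   [enumerate_terminals()].
#' @export
enumerate_terminals_naive <- function(exp, rectify = TRUE, depth_limit = 40L,
                                      max_paths = 1e6) {
  stopifnot(inherits(exp, "experiment"))
  circ <- exp$circuit
  cn <- circ$connections
  found <- new.env(parent = emptyenv())
  paths <- 0L
  recurse <- function(state) {
    if (state$depth > depth_limit) stop("depth_limit exceeded")
    moves <- applicable_moves(state, exp, rectify = rectify)
    if (state$phase == "done" || nrow(moves) == 0L) {
      paths <<- paths + 1L
      if (paths > max_paths) stop("path budget exceeded")
      if (state$phase == "done") {
        ## keep the shortest sequence reaching each configuration: that is
        ## the depth at which a memoized breadth-first search discovers it
        key <- paste(c(state$mags, state$records), collapse = ",")
        prev <- found[[key]]
        if (is.null(prev) || prev$depth > state$depth) found[[key]] <- state
      }
      return(invisible())
    }
    for (i in seq_len(nrow(moves))) {
      recurse(apply_move(state, exp, moves$dim[i], moves$direction[i],
                         rectify = rectify))
    }
  }
  if (depth_limit > 0L) recurse(initial_state(exp))
  states <- mget(ls(found), envir = found)
  n <- length(states)
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(cn))) {
    out[[cn$name[i]]] <- vapply(states, function(s) cn$sign[i] * s$mags[[cn$name[i]]],
                                numeric(1), USE.NAMES = FALSE)
  }
  for (nm in cn$name[cn$record]) {
    sg <- cn$sign[cn$name == nm]
    out[[paste0("record.", nm)]] <- vapply(states, function(s) sg * s$records[[nm]],
                                           numeric(1), USE.NAMES = FALSE)
  }
  out$depth <- vapply(states, function(s) s$depth, integer(1), USE.NAMES = FALSE)
  out <- dplyr::arrange(out, dplyr::across(dplyr::everything()))
  structure(out,
            class = c("terminal_set", class(out)),
            experiment = exp, rectify = rectify, engine = "naive",
            max_depth = if (n) max(out$depth) else 0L, n_entries = NA_integer_,
            n_conditioning_deadends = NA_integer_,
            n_extinction_deadends = NA_integer_)
}

#' @export
print.terminal_set <- function(x, ...) {
  exp <- attr(x, "experiment")
  cat("<terminal_set> ", nrow(x), " terminal configurations (model ",
      exp$model, ", row ", exp$row, "; ", attr(x, "engine"), " engine, ",
      if (attr(x, "rectify")) "rectified" else "linear",
      " semantics; search depth ", attr(x, "max_depth"), ")\n", sep = "")
  NextMethod()
}
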