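## Real-valued directed-search cross-check.
##
## The integer enumeration restricts weights to three levels; the directed
## search samples the corresponding *real-valued* space of weight changes.  A
## change set assigns every search dimension a conditioning change delta_cond
## and an extinction change delta_ext, in magnitude space, constrained so that
## the weights stay within [0, 2] after conditioning and after extinction.
## With `constrain_signs = TRUE` the changes additionally obey the phase
## schedule (conditioning changes >= 0 where only LTP is allowed, extinction
## changes <= 0 where only LTD is allowed); the default leaves the signs free
## within the bounds, which is how the published random-start searches are
## described (only the 0-to-2 bound constraint is stated), and is what
## reproduces their qualitative outcome.

ds_params <- function(exp, constrain_signs = FALSE) {
  dims <- exp_dims(exp$circuit)
  tibble::tibble(
    name = vapply(dims, function(d) d$name[1], character(1)),
    init = vapply(dims, function(d) d$init, numeric(1)),
    cond_free = vapply(dims, function(d) length(d$cond) > 0, logical(1)),
    ext_free = vapply(dims, function(d) length(d$ext) > 0, logical(1)),
    cond_dir = vapply(dims, function(d) if (length(d$cond)) d$cond[1] else 0L, integer(1)),
    ext_dir = vapply(dims, function(d) if (length(d$ext)) d$ext[1] else 0L, integer(1))
  )
}

## feasible interval of delta_cond given delta_ext (and vice versa)
dc_interval <- function(p, de, constrain_signs) {
  lo <- pmax(-p$init, -p$init - de)
  hi <- pmin(2 - p$init, 2 - p$init - de)
  if (constrain_signs) {
    lo <- ifelse(p$cond_dir > 0, pmax(lo, 0), lo)
    hi <- ifelse(p$cond_dir < 0, pmin(hi, 0), hi)
  }
  lo <- ifelse(p$cond_free, lo, 0)
  hi <- ifelse(p$cond_free, hi, 0)
  cbind(lo, hi)
}

de_interval <- function(p, dc, constrain_signs) {
  lo <- -(p$init + dc)
  hi <- 2 - (p$init + dc)
  if (constrain_signs) {
    lo <- ifelse(p$ext_dir > 0, pmax(lo, 0), lo)
    hi <- ifelse(p$ext_dir < 0, pmin(hi, 0), hi)
  }
  lo <- ifelse(p$ext_free, lo, 0)
  hi <- ifelse(p$ext_free, hi, 0)
  cbind(lo, hi)
}

#' Draw a random change set
#'
#' Samples uniformly over the constrained space of weight changes: each
#' conditioning change on its feasible interval, then each extinction change
#' on its interval conditional on the conditioning change.  Uses the current
#' RNG state.
#'
#' @param exp An [experiment()] object (typically a model baseline,
#'   `experiment(1, 1)` or `experiment(2, 1)`).
#' @param constrain_signs If `TRUE`, changes obey the phase schedule signs;
#'   the default constrains only the 0-to-2 weight bounds.
#' @return A `changeset`: list with numeric vectors `delta_cond` and
#'   `delta_ext` named by search dimension.
#' @export
sample_changeset <- function(exp, constrain_signs = FALSE) {
  p <- ds_params(exp, constrain_signs)
  ic <- dc_interval(p, rep(0, nrow(p)), constrain_signs)
  dc <- stats::runif(nrow(p), ic[, 1], ic[, 2])
  dc[!p$cond_free] <- 0
  ie <- de_interval(p, dc, constrain_signs)
  de <- stats::runif(nrow(p), ie[, 1], ie[, 2])
  de[!p$ext_free] <- 0
  structure(list(delta_cond = stats::setNames(dc, p$name),
                 delta_ext = stats::setNames(de, p$name)),
            class = "changeset")
}

## magnitude matrices for a batch of change sets (rows of DC / DE)
ds_magnitudes <- function(exp, DC, DE = NULL) {
  dims <- exp_dims(exp$circuit)
  cn <- exp$circuit$connections
  n <- nrow(DC)
  M <- matrix(rep(cn$initial, each = n), nrow = n)
  for (d in seq_along(dims)) {
    delta <- DC[, d] + if (is.null(DE)) 0 else DE[, d]
    M[, dims[[d]]$conns] <- dims[[d]]$init + delta
  }
  M
}

ds_errors <- function(exp, DC, DE, rectify = TRUE) {
  circ <- exp$circuit
  pag0 <- pag_flags(circ, ds_magnitudes(exp, 0 * DC),
                    us = 0, cs = 1, il = 0, rectify = rectify)
  pag1 <- pag_flags(circ, ds_magnitudes(exp, DC),
                    us = ctx_conditioning$us, cs = ctx_conditioning$cs,
                    il = ctx_conditioning$il, rectify = rectify)
  pag2 <- pag_flags(circ, ds_magnitudes(exp, DC, DE),
                    us = ctx_extinction$us, cs = ctx_extinction$cs,
                    il = ctx_extinction$il, rectify = rectify)
  as.numeric(pag0) + (1 - as.numeric(pag1)) + as.numeric(pag2)
}

#' Error of a change set
#'
#' The sum of absolute differences between desired and actual PAG responses in
#' three cases: *unconditioned* (initial weights, cue alone; desired off),
#' *conditioned* (weights after the conditioning changes, cue alone; desired
#' on) and *extinguished* (weights after conditioning plus extinction changes,
#' cue during extinction training; desired off).  PAG response is the binary
#' activation indicator, so the error is an integer in 0..3 (and the
#' unconditioned term is 0 by construction, since the changes do not affect
#' the initial weights).
#'
#' @inheritParams sample_changeset
#' @param changeset A [sample_changeset()] object.
#' @param rectify Activity semantics flag (see [activities()]).
#' @return Integer error in `0..3`.
#' @export
changeset_error <- function(changeset, exp, rectify = TRUE) {
  stopifnot(inherits(changeset, "changeset"))
  p <- ds_params(exp)
  dc <- changeset$delta_cond[p$name]
  de <- changeset$delta_ext[p$name]
  fin <- p$init + dc
  if (any(fin < -1e-9 | fin > 2 + 1e-9) ||
      any(fin + de < -1e-9 | fin + de > 2 + 1e-9)) {
    stop("change set violates the [0, 2] weight bounds")
  }
  ds_errors(exp, matrix(dc, nrow = 1), matrix(de, nrow = 1), rectify = rectify)
}

#' Derivative-free pattern search over weight changes
#'
#' Starting from a feasible change set, each change is perturbed in turn by
#' +Delta and -Delta (all others unperturbed, perturbations clipped to the
#' feasible region) and the errors of all perturbed sets are evaluated.  If
#' the best perturbed set improves on the current one it becomes current and
#' Delta doubles; otherwise the current set is kept and Delta halves.  The
#' procedure stops when Delta falls below `tol`.  Ties among equally-best
#' probes go to the earliest parameter (conditioning changes first), +Delta
#' before -Delta.
#'
#' @inheritParams changeset_error
#' @param start A feasible starting `changeset`.
#' @param delta0 Initial step size Delta (the published procedure leaves it
#'   unstated; 0.5 - a quarter of the weight range - is the package default).
#' @param tol Termination threshold for Delta, default `1e-6`.
#' @param keep_trace If `TRUE`, attach a per-iteration tibble.
#' @return A list: final `changeset`, `error`, `iterations`, and optionally
#'   `trace` (iteration, delta, error, accepted).
#' @export
pattern_search <- function(start, exp, delta0 = 0.5, tol = 1e-6,
                           constrain_signs = FALSE, rectify = TRUE,
                           keep_trace = FALSE) {
  stopifnot(inherits(start, "changeset"), delta0 > tol, tol > 0)
  p <- ds_params(exp, constrain_signs)
  engine <- ds_engine(exp, rectify)
  res <- pattern_search_impl(start$delta_cond[p$name], start$delta_ext[p$name],
                             p, engine, delta0, tol, constrain_signs, keep_trace)
  out <- list(
    changeset = structure(list(delta_cond = stats::setNames(res$dc, p$name),
                               delta_ext = stats::setNames(res$de, p$name)),
                          class = "changeset"),
    error = res$error, iterations = res$iterations
  )
  if (keep_trace) out$trace <- res$trace
  out
}

## precomputed error evaluator over batches of (DC, DE) rows
ds_engine <- function(exp, rectify = TRUE) {
  circ <- exp$circuit
  dims <- exp$dims %||% exp_dims(circ)
  K <- length(dims)
  init_vec <- circ$connections$initial
  dim_cols <- lapply(dims, function(d) d$conns)
  dim_init <- vapply(dims, function(d) d$init, numeric(1))
  magn <- function(DC, DE) {
    n <- nrow(DC)
    M <- matrix(rep(init_vec, each = n), nrow = n)
    for (d in seq_len(K)) {
      M[, dim_cols[[d]]] <- dim_init[d] + DC[, d] +
        (if (is.null(DE)) 0 else DE[, d])
    }
    M
  }
  pag0 <- pag_flags(circ, matrix(init_vec, nrow = 1),
                    us = 0, cs = 1, il = 0, rectify = rectify)
  function(DC, DE) {
    p1 <- pag_flags(circ, magn(DC, NULL),
                    us = ctx_conditioning$us, cs = ctx_conditioning$cs,
                    il = ctx_conditioning$il, rectify = rectify)
    p2 <- pag_flags(circ, magn(DC, DE),
                    us = ctx_extinction$us, cs = ctx_extinction$cs,
                    il = ctx_extinction$il, rectify = rectify)
    as.numeric(pag0) + (1 - as.numeric(p1)) + as.numeric(p2)
  }
}

## accept/double, reject/halve loop on plain vectors; probes clipped to the
## conditional feasible interval of the perturbed coordinate
pattern_search_impl <- function(dc, de, p, engine, delta0, tol,
                                constrain_signs, keep_trace = FALSE) {
  K <- nrow(p)
  init <- p$init
  csg <- constrain_signs
  free <- c(which(p$cond_free), K + which(p$ext_free))
  nb <- 2L * length(free)
  cur_err <- engine(matrix(dc, 1), matrix(de, 1))
  delta <- delta0
  it <- 0L
  trace <- if (keep_trace) list() else NULL
  while (delta >= tol) {
    it <- it + 1L
    DC <- matrix(dc, nb, K, byrow = TRUE)
    DE <- matrix(de, nb, K, byrow = TRUE)
    row <- 1L
    for (j in free) {
      for (step in c(delta, -delta)) {
        if (j <= K) {
          lo <- max(-init[j], -init[j] - de[j])
          hi <- min(2 - init[j], 2 - init[j] - de[j])
          if (csg && p$cond_dir[j] > 0) lo <- max(lo, 0)
          if (csg && p$cond_dir[j] < 0) hi <- min(hi, 0)
          DC[row, j] <- min(max(dc[j] + step, lo), hi)
        } else {
          d <- j - K
          lo <- -(init[d] + dc[d])
          hi <- 2 - init[d] - dc[d]
          if (csg && p$ext_dir[d] > 0) lo <- max(lo, 0)
          if (csg && p$ext_dir[d] < 0) hi <- min(hi, 0)
          DE[row, d] <- min(max(de[d] + step, lo), hi)
        }
        row <- row + 1L
      }
    }
    errs <- engine(DC, DE)
    best <- which.min(errs)
    accepted <- errs[best] < cur_err
    if (accepted) {
      dc <- DC[best, ]
      de <- DE[best, ]
      cur_err <- errs[best]
      delta <- delta * 2
    } else {
      delta <- delta / 2
    }
    if (keep_trace) {
      trace[[it]] <- tibble::tibble(iteration = it, delta = delta,
                                    error = cur_err, accepted = accepted)
    }
  }
  list(dc = dc, de = de, error = cur_err, iterations = it,
       trace = if (keep_trace) dplyr::bind_rows(trace))
}

#' Batch of random-start directed searches
#'
#' Runs `n` independent pattern searches from uniform random feasible starts
#' and summarises how many reach zero error, and how many of those do so in
#' conjunction with extinction LTD of the key interneuron-to-projection
#' weight (`wLAi1toLA1` for model 1, `wLAitoLA1` for model 2), classified as
#' a final extinction change below `-1e-9` in magnitude space.
#'
#' @param model_id 1 or 2 (the model baseline schedule is used).
#' @param n Number of searches (the published batches used 1000).
#' @param seed RNG seed for reproducibility.
#' @inheritParams pattern_search
#' @return An object of class `batch_search`: per-run results plus summary
#'   counts `n_zero_error`, `n_zero_error_with_ltd` and `ltd_percentage`
#'   (percentage of zero-error searches exhibiting the LTD, `NA` if no search
#'   reached zero error or `n = 0`).  [tidy()] returns the per-run tibble,
#'   [glance()] the one-row summary.
#' @examples
#' \donttest{
#' b <- batch_search(1, n = 50, seed = 1)
#' glance(b)
#' }
#' @export
batch_search <- function(model_id, n = 1000, seed = 1, delta0 = 0.5, tol = 1e-6,
                         constrain_signs = FALSE, rectify = TRUE) {
  stopifnot(n >= 0)
  exp <- experiment(model_id, 1)
  ltd_conn <- if (model_id == 1) "wLAi1toLA1" else "wLAitoLA1"
  p <- ds_params(exp, constrain_signs)
  engine <- ds_engine(exp, rectify)
  K <- nrow(p)
  jltd <- which(p$name == ltd_conn)
  set.seed(seed)
  empty <- tibble::tibble(run = integer(), error = numeric(),
                          iterations = integer(), delta_ext_ltd = numeric(),
                          ltd = logical())
  runs <- purrr::map_dfr(seq_len(n), function(i) {
    ic <- dc_interval(p, rep(0, K), constrain_signs)
    dc <- stats::runif(K, ic[, 1], ic[, 2])
    dc[!p$cond_free] <- 0
    ie <- de_interval(p, dc, constrain_signs)
    de <- stats::runif(K, ie[, 1], ie[, 2])
    de[!p$ext_free] <- 0
    res <- pattern_search_impl(dc, de, p, engine, delta0, tol, constrain_signs)
    tibble::tibble(
      run = i, error = res$error, iterations = res$iterations,
      delta_ext_ltd = res$de[jltd],
      ltd = res$de[jltd] < -1e-9
    )
  })
  if (n == 0L) runs <- empty
  n_zero <- sum(runs$error == 0)
  n_zero_ltd <- sum(runs$error == 0 & runs$ltd)
  structure(
    list(runs = runs, model = model_id, n = n,
         n_zero_error = n_zero, n_zero_error_with_ltd = n_zero_ltd,
         ltd_percentage = if (n_zero > 0) 100 * n_zero_ltd / n_zero else NA_real_,
         ltd_connection = ltd_conn,
         config = list(seed = seed, delta0 = delta0, tol = tol,
                       constrain_signs = constrain_signs, rectify = rectify)),
    class = "batch_search"
  )
}

#' @export
print.batch_search <- function(x, ...) {
  cat("<batch_search> model ", x$model, ": ", x$n, " searches, ",
      x$n_zero_error, " reached zero error, ",
      x$n_zero_error_with_ltd, " of those with LTD of ", x$ltd_connection,
      " (", if (is.na(x$ltd_percentage)) "NA" else round(x$ltd_percentage, 1),
      "%)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.batch_search <- function(x, ...) x$runs

#' @export
glance.batch_search <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, n_zero_error = x$n_zero_error,
    n_zero_error_with_ltd = x$n_zero_error_with_ltd,
    ltd_percentage = x$ltd_percentage,
    mean_iterations = mean(x$runs$iterations),
    seed = x$config$seed, delta0 = x$config$delta0,
    constrain_signs = x$config$constrain_signs
  )
}
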