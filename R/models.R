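#' The two amygdala circuit models
#'
#' `model1()` is the two-pathway (Fear / No Fear) circuit derived from the
#' Lafenetre-Chaouloff-Marsicano scheme: US and CS feed lateral amygdala
#' projection neurons LA1 (No Fear head) and LA2 (Fear head), each under
#' constant inhibition from its own interneuron (LAi1, LAi2); LA1 excites BA1
#' which excites the medial intercalated mass ITCm, which inhibits the output
#' stage CEm; LA2 excites BA2 which excites CEm directly; CEm drives the PAG
#' gate.  `model2()` is the single-pathway circuit derived from the
#' Pare-Quirk-LeDoux view: US and CS feed LAi, LA1 and LA2; LAi inhibits LA1
#' only; LA1 and LA2 excite the lateral intercalated mass ITCl, which inhibits
#' ITCm, which inhibits CEm; infralimbic cortex (IL, active only during
#' extinction) excites LAi, ITCl and ITCm.
#'
#' Biases are chosen so that every element with non-zero spontaneous activity
#' sits at rate 1 when all inputs are 0 and weights are at their initial
#' magnitudes (all 1 except the CS weights, and in model 2 the IL weights,
#' which start at 0).
#'
#' The baseline plasticity schedule allows each modifiable weight one unit
#' magnitude increase (LTP) at a time during conditioning and one unit
#' decrease (LTD) at a time during extinction, except the three IL weights of
#' model 2, which may only undergo LTP during extinction.  Fixed connections:
#' `wUStoLA2` and `wCEmtoPAG` in model 1; `wUStoLAi`, `wUStoLA1`, `wUStoLA2`,
#' `wITCltoITCm`, `wITCmtoCEm` and `wCEmtoPAG` in model 2.  The interneuron
#' weights central to the CB1-mediated GABAergic LTD question (`wLAi1toLA1`
#' and `wLAi2toLA2` in model 1, `wLAitoLA1` in model 2) are record-tracked:
#' their magnitudes are snapshotted when conditioning completes so that
#' extinction-phase LTD can be detected.
#'
#' @return A [circuit_spec()] object with the baseline schedule encoded in the
#'   `cond`/`ext` columns of its connection table.
#' @examples
#' m1 <- model1()
#' activities(m1)            # spontaneous rates, CEm = 0
#' activities(m1, us = 1)    # US activates the Fear pathway
#' @export
model1 <- function() {
  elements <- tibble::tribble(
    ~name,   ~bias, ~kind,
    "US",    0,     "input",
    "CS",    0,     "input",
    "LAi1",  1,     "internal",
    "LAi2",  1,     "internal",
    "LA1",   2,     "internal",
    "LA2",   2,     "internal",
    "BA1",   0,     "internal",
    "BA2",   0,     "internal",
    "ITCm",  0,     "internal",
    "CEm",   0,     "internal",
    "PAG",   0,     "gate"
  )
  connections <- tibble::tribble(
    ~source, ~target, ~sign, ~initial, ~modifiable, ~record,
    "CS",    "LA1",    1,    0,        TRUE,        FALSE,
    "CS",    "LA2",    1,    0,        TRUE,        FALSE,
    "LAi1",  "LA1",   -1,    1,        TRUE,        TRUE,
    "LAi2",  "LA2",   -1,    1,        TRUE,        TRUE,
    "US",    "LA2",    1,    1,        FALSE,       FALSE,
    "LA1",   "BA1",    1,    1,        TRUE,        FALSE,
    "LA2",   "BA2",    1,    1,        TRUE,        FALSE,
    "BA1",   "ITCm",   1,    1,        TRUE,        FALSE,
    "BA2",   "CEm",    1,    1,        TRUE,        FALSE,
    "ITCm",  "CEm",   -1,    1,        TRUE,        FALSE,
    "CEm",   "PAG",    1,    1,        FALSE,       FALSE
  )
  connections$tie <- NA_character_
  connections$cond <- ifelse(connections$modifiable, "+", "")
  connections$ext <- ifelse(connections$modifiable, "-", "")
  circuit_spec(elements, connections)
}

#' @rdname model1
#' @examples
#' m2 <- model2()
#' activities(m2)            # spontaneous rates, CEm = 0
#' cs_response(m2, "LA2")    # 0 at initial weights
#' @export
model2 <- function() {
  elements <- tibble::tribble(
    ~name,   ~bias, ~kind,
    "US",    0,     "input",
    "CS",    0,     "input",
    "IL",    0,     "input",
    "LAi",   1,     "internal",
    "LA1",   2,     "internal",
    "LA2",   1,     "internal",
    "ITCl", -1,     "internal",
    "ITCm",  2,     "internal",
    "CEm",   1,     "internal",
    "PAG",   0,     "gate"
  )
  connections <- tibble::tribble(
    ~source, ~target, ~sign, ~initial, ~modifiable, ~record, ~cond, ~ext,
    "CS",    "LAi",    1,    0,        TRUE,        FALSE,   "+",   "-",
    "CS",    "LA1",    1,    0,        TRUE,        FALSE,   "+",   "-",
    "CS",    "LA2",    1,    0,        TRUE,        FALSE,   "+",   "-",
    "LAi",   "LA1",   -1,    1,        TRUE,        TRUE,    "+",   "-",
    "LA1",   "ITCl",   1,    1,        TRUE,        FALSE,   "+",   "-",
    "LA2",   "ITCl",   1,    1,        TRUE,        FALSE,   "+",   "-",
    "IL",    "LAi",    1,    0,        TRUE,        FALSE,   "",    "+",
    "IL",    "ITCl",   1,    0,        TRUE,        FALSE,   "",    "+",
    "IL",    "ITCm",   1,    0,        TRUE,        FALSE,   "",    "+",
    "US",    "LAi",    1,    1,        FALSE,       FALSE,   "",    "",
    "US",    "LA1",    1,    1,        FALSE,       FALSE,   "",    "",
    "US",    "LA2",    1,    1,        FALSE,       FALSE,   "",    "",
    "ITCl",  "ITCm",  -1,    1,        FALSE,       FALSE,   "",    "",
    "ITCm",  "CEm",   -1,    1,        FALSE,       FALSE,   "",    "",
    "CEm",   "PAG",    1,    1,        FALSE,       FALSE,   "",    ""
  )
  connections$tie <- NA_character_
  circuit_spec(elements, connections)
}

#' Remove elements from a circuit
#'
#' Deletes the named elements together with every connection incident on them,
#' and revalidates the result.  Used for the structural variant in which both
#' basal-nucleus elements (BA1, BA2) are removed from model 1, leaving ITCm
#' with no inputs and CEm permanently at zero.  Removing elements that orphan
#' the output pathway is allowed (that degeneracy is itself a result of
#' interest), but a message is emitted.
#'
#' @param circuit A [circuit_spec()] object.
#' @param names Elements to remove; inputs and the gate cannot be removed.
#' @return The edited circuit.
#' @export
remove_elements <- function(circuit, names) {
  stopifnot(inherits(circuit, "circuit"))
  if (length(names) == 0L) return(circuit)
  unknown <- setdiff(names, circuit$elements$name)
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  kind <- circuit$elements$kind[match(names, circuit$elements$name)]
  if (any(kind %in% c("input", "gate"))) {
    stop("cannot remove input or gate elements")
  }
  el <- circuit$elements[!(circuit$elements$name %in% names), ]
  cn <- circuit$connections[!(circuit$connections$source %in% names) &
                              !(circuit$connections$target %in% names), ]
  out <- circuit_spec(el, cn[, setdiff(names(cn), "name")])
  orphaned <- setdiff(out$topo, unique(out$connections$target))
  if (length(orphaned)) {
    message("removal leaves element(s) with no inputs: ",
            paste(orphaned, collapse = ", "))
  }
  out
}
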