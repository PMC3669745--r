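## Minimal hand-checkable circuits used across tests.

## one excitatory weight from the cue straight onto CEm
toy_circuit <- function(cem_bias = 0) {
  circuit_spec(
    elements = data.frame(
      name = c("CS", "CEm", "PAG"),
      bias = c(0, cem_bias, 0),
      kind = c("input", "internal", "gate")
    ),
    connections = data.frame(
      source = c("CS", "CEm"), target = c("CEm", "PAG"),
      sign = c(1, 1), initial = c(0, 1),
      modifiable = c(TRUE, FALSE), record = c(TRUE, FALSE),
      tie = NA_character_, cond = c("+", ""), ext = c("-", "")
    )
  )
}

toy_experiment <- function(cem_bias = 0, filters = list()) {
  custom_experiment(toy_circuit(cem_bias), filters = filters,
                    label = "single-weight toy")
}

## reorder the connection declarations of an experiment's circuit
permute_experiment <- function(exp, perm) {
  cn <- exp$circuit$connections[perm, ]
  circ <- circuit_spec(exp$circuit$elements,
                       cn[, setdiff(names(cn), "name")])
  custom_experiment(circ, filters = exp$filters, label = exp$label)
}

## comparable key per configuration (weights + records), order-insensitive
config_keys <- function(ts) {
  cols <- sort(setdiff(names(ts), c("depth", grep("^filter\\.", names(ts), value = TRUE))))
  ts <- as.data.frame(ts)[, cols, drop = FALSE]
  sort(do.call(paste, c(ts, sep = ",")))
}
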