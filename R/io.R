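#' Read and write circuit specifications as JSON
#'
#' A circuit serialises to a JSON document with two arrays, `elements`
#' (name, bias, kind) and `connections` (source, target, sign, initial,
#' modifiable, record, tie, cond, ext).  Reading revalidates.
#'
#' @param circuit A [circuit_spec()] object.
#' @param path File path.
#' @return `read_circuit_json()` returns a validated circuit;
#'   `write_circuit_json()` returns `path` invisibly.
#' @export
write_circuit_json <- function(circuit, path) {
  stopifnot(inherits(circuit, "circuit"))
  jsonlite::write_json(
    list(elements = circuit$elements,
         connections = circuit$connections[, c("source", "target", "sign",
                                               "initial", "modifiable",
                                               "record", "tie", "cond", "ext")]),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- tibble::as_tibble(doc$connections)
  if (!"tie" %in% names(cn)) cn$tie <- NA_character_
  cn$tie <- as.character(cn$tie)
  circuit_spec(doc$elements, cn)
}

#' Write a terminal-configuration atlas as TSV
#'
#' One row per terminal configuration (signed weights, records, any filter
#' annotation columns, path depth), preceded by `#`-prefixed header lines
#' identifying the experiment and the semantics flags, so the data section is
#' byte-stable across runs.
#'
#' @param terminals A `terminal_set`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(terminals, path) {
  stopifnot(inherits(terminals, "terminal_set"))
  exp <- attr(terminals, "experiment")
  hdr <- c(
    paste0("# model: ", exp$model, "  row: ", exp$row),
    paste0("# condition: ", exp$label),
    paste0("# engine: ", attr(terminals, "engine"),
           "  semantics: ", if (attr(terminals, "rectify")) "rectified" else "linear"),
    paste0("# configurations: ", nrow(terminals),
           "  max_path_depth: ", attr(terminals, "max_depth"))
  )
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(tibble::as_tibble(terminals), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' Write a reproduced count table
#'
#' @param tab A [reproduce_table()] result.
#' @param path File path; `.json` extension selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_table_report <- function(tab, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(tibble::as_tibble(tab), path)
  }
  invisible(path)
}
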