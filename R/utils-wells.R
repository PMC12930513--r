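#' Well label utilities for SBS-format labware
#'
#' Plate formats are identified by short tags: `"96-well"` (8 rows A-H x 12
#' columns), `"24-well"` (4 rows A-D x 6 columns, used for reagent tube
#' racks), and `"6-well"` (2 rows A-B x 3 columns, used for agar plates).
#' Well labels are row letter + 1-based column number ("A1".."H12");
#' enumeration and auto-assignment are row-major.
#'
#' @param plate_format one of `"96-well"`, `"24-well"`, `"6-well"`.
#' @return `wellLabels()` returns the full row-major label vector for the
#'   format; `plateDims()` returns `c(rows, cols)`.
#' @examples
#' head(wellLabels("96-well"))
#' wellLabels("6-well")
#' @export
wellLabels <- function(plate_format) {
  d <- plateDims(plate_format)
  as.vector(t(outer(LETTERS[seq_len(d[1L])], seq_len(d[2L]), paste0)))
}

#' @rdname wellLabels
#' @export
plateDims <- function(plate_format) {
  switch(plate_format,
    "96-well" = c(8L, 12L),
    "24-well" = c(4L, 6L),
    "6-well"  = c(2L, 3L),
    stop("unknown plate format: ", plate_format)
  )
}

#' @rdname wellLabels
#' @param well character vector of well labels.
#' @export
isValidWell <- function(well, plate_format) {
  well %in% wellLabels(plate_format)
}

## Order wells row-major (A1 < A2 < ... < A12 < B1), i.e. by row letter then
## numeric column -- not lexicographic on the raw string.
wellOrder <- function(well) {
  row <- substr(well, 1L, 1L)
  col <- suppressWarnings(as.integer(substring(well, 2L)))
  order(row, col)
}

## ---- condition constructors ------------------------------------------------
## Error classes map onto the CLI exit codes: parse (2), grammar (3),
## capacity (4), simulation (5).

mcpError <- function(class, message, ...) {
  structure(
    class = c(class, "mcp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

parseError <- function(message, row = NULL) {
  if (!is.null(row)) message <- sprintf("row %d: %s", row, message)
  stop(mcpError("mcp_parse_error", message, row = row))
}

grammarError <- function(message) stop(mcpError("mcp_grammar_error", message))

capacityError <- function(message) stop(mcpError("mcp_capacity_error", message))

simulationError <- function(message) stop(mcpError("mcp_simulation_error", message))

## layout infeasibility is a capacity-class failure for exit-code purposes
layoutError <- function(message)
  stop(mcpError(c("mcp_layout_error", "mcp_capacity_error"), message))

## round half up at a given resolution (0.1 uL for master-mix totals);
## base round() is round-half-even, which is wrong for lab totals
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
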