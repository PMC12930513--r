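#' @include AllClasses.R
NULL

#' Built-in toolkit schemas
#'
#' `ytkLevel1Schema()` is the Level-1 grammar of the MoClo Yeast Toolkit:
#' a transcription unit is promoter (type 2), CDS (type 3), terminator
#' (type 4) in order, where type 3 may be replaced by the contiguous
#' sub-slot pair 3a+3b (e.g. signal peptide + CDS) and type 4 by 4a+4b
#' (C-terminal tag + terminator); backbones carry a GFP dropout.
#' `stkLevel1Schema()` is the Level-1 grammar of the SubtiToolKit:
#' promoter, RBS, CDS in 0C format, terminator; backbones carry a lacZ
#' dropout.
#'
#' @return a [ToolkitSchema-class].
#' @seealso [readToolkitSchema()] to load user-defined schemas.
#' @examples
#' ytkLevel1Schema()
#' @export
ytkLevel1Schema <- function() {
  ToolkitSchema(
    toolkit_name = "YTK Level 1",
    slot_order = c("2", "3", "4"),
    backbone_types = "backbone",
    dropout_marker = "GFP-dropout",
    equivalence_groups = list("3" = c("3a", "3b"), "4" = c("4a", "4b"))
  )
}

#' @rdname ytkLevel1Schema
#' @export
stkLevel1Schema <- function() {
  ToolkitSchema(
    toolkit_name = "STK Level 1",
    slot_order = c("promoter", "rbs", "0C", "terminator"),
    backbone_types = "backbone",
    dropout_marker = "lacZ-dropout",
    equivalence_groups = list()
  )
}

#' Read a toolkit schema from YAML or JSON
#'
#' Accepts a file with keys `toolkit_name`, `slot_order`, `backbone_types`,
#' `dropout_marker` and optionally `equivalence_groups` (mapping parent
#' slot -> list of sub-slots).
#'
#' @param path schema file (`.yaml`/`.yml` or `.json`).
#' @return a [ToolkitSchema-class].
#' @export
readToolkitSchema <- function(path) {
  if (!file.exists(path)) parseError(sprintf("schema file not found: %s", path))
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  eg <- lapply(x$equivalence_groups %||% list(), unlist, use.names = FALSE)
  tryCatch(
    ToolkitSchema(x$toolkit_name %||% "custom",
                  unlist(x$slot_order), unlist(x$backbone_types),
                  x$dropout_marker %||% "none", eg),
    error = function(e) parseError(sprintf("invalid schema %s: %s", path,
                                           conditionMessage(e))))
}

#' Write a toolkit schema to YAML
#'
#' @param schema a [ToolkitSchema-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeToolkitSchema <- function(schema, path) {
  yaml::write_yaml(list(
    toolkit_name = schema@toolkit_name,
    slot_order = as.list(schema@slot_order),
    backbone_types = as.list(schema@backbone_types),
    dropout_marker = schema@dropout_marker,
    equivalence_groups = lapply(schema@equivalence_groups, as.list)
  ), path)
  invisible(path)
}

## resolve one part name against the union of loaded plate maps.
## Returns list(labware, well, record) or a character error message.
## A part found in both maps is ambiguous unless both records agree.
resolvePart <- function(name, sources) {
  hits <- list()
  for (pm in sources) {
    w <- wells(pm)
    idx <- which(w$part_name == name)
    for (i in idx)
      hits[[length(hits) + 1L]] <- list(labware = labwareId(pm),
                                        well = w$well[i], record = w[i, ])
  }
  if (!length(hits))
    return(sprintf("part '%s' not found in any source plate", name))
  if (length(hits) > 1L) {
    recs <- lapply(hits, function(h)
      h$record[c("part_type", "concentration_ng_per_ul", "length_bp")])
    same <- all(vapply(recs[-1L], function(r)
      isTRUE(all.equal(r, recs[[1L]], check.attributes = FALSE)),
      logical(1)))
    if (!same)
      return(sprintf(
        "part '%s' is ambiguous: found in %s with differing records",
        name, paste(vapply(hits, function(h)
          sprintf("%s/%s", h$labware, h$well), character(1)),
          collapse = " and ")))
  }
  hits[[1L]]
}

## expand slot_order into the list of acceptable type sequences per slot:
## each slot accepts the slot label itself or its equivalence run
slotAlternatives <- function(schema) {
  lapply(schema@slot_order, function(s) {
    alts <- list(s)
    if (s %in% names(schema@equivalence_groups))
      alts <- c(alts, list(schema@equivalence_groups[[s]]))
    alts
  })
}

#' Validate an assembly design against a toolkit schema
#'
#' A design passes iff (a) the backbone and every part resolve to exactly
#' one source well across the loaded plate maps (a part present in both
#' maps is accepted only when the two records agree), (b) the backbone's
#' part type is an allowed backbone type, and (c) the ordered part types,
#' after rewriting equivalence-group runs (e.g. 3a+3b for 3), spell the
#' schema's slot order exactly once, in order. A resolvable part with a
#' recorded concentration of 0 ng/µL yields a warning finding (it cannot
#' be dosed by molarity) but does not fail the design.
#'
#' @param design an [AssemblyDesign-class].
#' @param schema a [ToolkitSchema-class].
#' @param sources list of [PlateMap-class] objects (toolkit + custom).
#' @return a [ValidationReport-class].
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' d <- AssemblyDesign("tu", "backbone_1",
#'                     c("2_1", "3_1", "4_1"), "A1")
#' validateDesign(d, ytkLevel1Schema(), list(tk))
#' @export
validateDesign <- function(design, schema, sources) {
  stopifnot(is(design, "AssemblyDesign"), is(schema, "ToolkitSchema"))
  sev <- character(); msg <- character()
  note <- function(severity, message) {
    sev <<- c(sev, severity); msg <<- c(msg, message)
  }

  bb <- resolvePart(design@backbone, sources)
  if (is.character(bb)) note("error", bb)
  else if (!bb$record$part_type %in% schema@backbone_types)
    note("error", sprintf(
      "backbone '%s' has type '%s', not an allowed backbone type (%s)",
      design@backbone, bb$record$part_type,
      paste(schema@backbone_types, collapse = ", ")))

  types <- character(length(design@parts))
  for (i in seq_along(design@parts)) {
    h <- resolvePart(design@parts[i], sources)
    if (is.character(h)) { note("error", h); types[i] <- NA_character_ }
    else {
      types[i] <- h$record$part_type
      conc <- h$record$concentration_ng_per_ul
      if (!is.na(conc) && conc == 0)
        note("warning", sprintf(
          "part '%s' has 0 ng/uL stock and cannot be dosed by molarity",
          design@parts[i]))
    }
  }

  if (!anyNA(types)) {
    # greedy left-to-right match of the type sequence against slot_order,
    # allowing each slot to be spelled by its equivalence run
    pos <- 1L
    ok <- TRUE
    for (alts in slotAlternatives(schema)) {
      matched <- FALSE
      for (a in alts) {
        k <- length(a)
        if (pos + k - 1L <= length(types) &&
            identical(types[pos:(pos + k - 1L)], a)) {
          pos <- pos + k; matched <- TRUE; break
        }
      }
      if (!matched) { ok <- FALSE; break }
    }
    if (!ok || pos != length(types) + 1L)
      note("error", sprintf(
        "part types [%s] do not spell slot order [%s] (with equivalences) exactly once, in order",
        paste(types, collapse = ", "),
        paste(schema@slot_order, collapse = ", ")))
  }

  f <- data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
  new("ValidationReport", design_name = design@construct_name,
      status = !any(f$severity == "error"), findings = f)
}

#' Expand a combinatorial design space into assembly designs
#'
#' Builds the full cross product over per-slot part choices, in
#' lexicographic slot order (the first listed slot varies slowest).
#' Construct names are instantiated from `naming_pattern`, where
#' `{slotlabel}` placeholders are replaced by the chosen part name and
#' `{i}` by the 1-based design index. Destination wells are assigned
#' row-major. A product larger than 96 is a capacity error reporting the
#' computed size.
#'
#' @param slot_choices named list: slot label -> character vector of part
#'   names (every slot needs at least one choice).
#' @param backbone backbone part name shared by all designs.
#' @param naming_pattern construct-name template; default
#'   `"assembly_{i}"`.
#' @return list of [AssemblyDesign-class], length = product of choice
#'   counts.
#' @examples
#' expandCombinatorial(list("2" = c("pA", "pB"), "3" = "gfp", "4" = "tT"),
#'                     backbone = "pWS064")
#' @export
expandCombinatorial <- function(slot_choices, backbone,
                                naming_pattern = "assembly_{i}") {
  stopifnot(length(slot_choices) >= 1L)
  if (any(!vapply(slot_choices, length, integer(1))))
    stop("every slot needs at least one choice")
  n <- prod(vapply(slot_choices, length, integer(1)))
  if (n > 96)
    capacityError(sprintf(
      "combinatorial expansion yields %d designs, exceeding the 96-assembly capacity",
      n))
  grid <- expand.grid(rev(slot_choices), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(slot_choices)), drop = FALSE]
  colnames(grid) <- names(slot_choices)
  auto <- wellLabels("96-well")
  designs <- vector("list", n)
  names_seen <- character()
  for (i in seq_len(n)) {
    nm <- naming_pattern
    nm <- gsub("{i}", as.character(i), nm, fixed = TRUE)
    nm <- gsub("{backbone}", backbone, nm, fixed = TRUE)
    for (s in colnames(grid))
      nm <- gsub(paste0("{", s, "}"), grid[i, s], nm, fixed = TRUE)
    if (nm %in% names_seen)
      stop("naming pattern '", naming_pattern,
           "' does not generate unique names (duplicate: ", nm, ")")
    names_seen <- c(names_seen, nm)
    designs[[i]] <- AssemblyDesign(nm, backbone,
                                   unlist(grid[i, ], use.names = FALSE),
                                   auto[i])
  }
  designs
}
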