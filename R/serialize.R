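#' @include AllClasses.R
NULL

planToList <- function(plan) {
  ins <- instructions(plan)
  ins_list <- lapply(seq_len(nrow(ins)), function(i) {
    r <- ins[i, ]
    list(kind = r$kind, pipette = r$pipette, labware = r$labware,
         well = r$well, volume_ul = r$volume_ul,
         offset_mm = c(r$x_mm, r$y_mm, r$z_mm), comment = r$comment)
  })
  dk <- deck(plan)
  rx <- reactionPlans(plan)
  list(
    deck = list(
      platform = dk@platform,
      slots = dk@slots,
      modules = dk@modules,
      tip_racks = dk@tip_racks
    ),
    stages = stages(plan),
    instructions = ins_list,
    initial_contents = initialContents(plan),
    reactions = lapply(rx, function(r) list(
      destination_well = r@destination_well,
      components = r@components,
      water_topup = r@water_topup,
      total_volume = r@total_volume))
  )
}

#' Serialize an instruction plan to JSON
#'
#' Writes the full plan — deck, stage ranges, instruction stream (with
#' `offset_mm` triples), initial labware contents and expected reaction
#' plans — as deterministic JSON: identical plans produce byte-identical
#' files. [readPlanJson()] is the exact inverse.
#'
#' @param plan an [InstructionPlan-class].
#' @param path output path (or connection).
#' @return invisibly, the path.
#' @export
writePlanJson <- function(plan, path) {
  jsonlite::write_json(planToList(plan), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writePlanJson
#' @export
planJsonString <- function(plan) {
  as.character(jsonlite::toJSON(planToList(plan), auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE,
                                dataframe = "rows"))
}

asDf <- function(x, template) {
  if (is.null(x) || !length(x)) return(template)
  df <- as.data.frame(do.call(rbind, lapply(x, function(r)
    lapply(r, function(v) if (is.null(v)) NA else v))),
    stringsAsFactors = FALSE)
  for (cn in colnames(df)) df[[cn]] <- unlist(df[[cn]], use.names = FALSE)
  for (cn in colnames(template)) df[[cn]] <- as(df[[cn]], class(template[[cn]]))
  df[, colnames(template), drop = FALSE]
}

#' Read an instruction plan from JSON
#'
#' @param path a plan file written by [writePlanJson()].
#' @return an [InstructionPlan-class].
#' @export
readPlanJson <- function(path) {
  if (!file.exists(path)) parseError(sprintf("plan file not found: %s", path))
  x <- jsonlite::read_json(path)
  dk <- x$deck
  slots <- lapply(dk$slots, function(s)
    if (is.character(s) && identical(s, "empty")) "empty"
    else list(type = s$type, labware_id = s$labware_id))
  tip_template <- data.frame(slot = character(), labware_id = character(),
                             capacity = integer(), stringsAsFactors = FALSE)
  deck <- new("DeckLayout", platform = dk$platform, slots = slots,
              modules = unlist(dk$modules),
              tip_racks = asDf(dk$tip_racks, tip_template))
  ins <- lapply(x$instructions, function(r) {
    off <- r$offset_mm
    off <- vapply(seq_len(3L), function(j) {
      v <- if (length(off) >= j) off[[j]] else NULL
      if (is.numeric(v) && length(v) == 1L) as.numeric(v) else NA_real_
    }, numeric(1))
    data.frame(
      kind = r$kind, pipette = r$pipette %||% NA_character_,
      labware = r$labware %||% NA_character_,
      well = r$well %||% NA_character_,
      volume_ul = if (is.null(r$volume_ul)) NA_real_ else r$volume_ul,
      x_mm = off[1L], y_mm = off[2L], z_mm = off[3L],
      comment = r$comment %||% "", stringsAsFactors = FALSE)
  })
  ins <- if (length(ins)) do.call(rbind, ins) else emptyInstructionsDf()
  stage_template <- data.frame(stage = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)
  init_template <- data.frame(labware = character(), well = character(),
                              component = character(), volume_ul = numeric(),
                              stringsAsFactors = FALSE)
  comp_template <- data.frame(source_labware = character(),
                              source_well = character(),
                              component = character(), volume_ul = numeric(),
                              stringsAsFactors = FALSE)
  reactions <- lapply(x$reactions, function(r)
    new("ReactionPlan", destination_well = r$destination_well,
        components = asDf(r$components, comp_template),
        water_topup = r$water_topup, total_volume = r$total_volume))
  new("InstructionPlan", deck = deck, instructions = ins,
      stages = asDf(x$stages, stage_template),
      initial_contents = asDf(x$initial_contents, init_template),
      reactions = reactions)
}

#' Serialize a simulation report
#'
#' Writes the violation list, final well ledger and tip count as JSON;
#' `simReportText()` renders the violations as human-readable lines.
#'
#' @param report a [SimReport-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSimReport <- function(report, path) {
  jsonlite::write_json(list(
    n_violations = nrow(violations(report)),
    violations = violations(report),
    tips_consumed = tipsConsumed(report),
    final_wells = finalWells(report)
  ), path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE,
    dataframe = "rows")
  invisible(path)
}

#' @rdname writeSimReport
#' @export
simReportText <- function(report) {
  v <- violations(report)
  if (!nrow(v)) return("simulation clean: 0 violations")
  c(sprintf("%d violation(s):", nrow(v)),
    sprintf("  [%s] at instruction %d: %s", v$rule, v$instruction_index,
            v$message))
}

#' Render an Opentrons API v2 protocol script
#'
#' Emits a Python protocol for the Opentrons app: a fixed interpreter
#' template with the serialized plan inlined as data (no generated
#' control flow), so the executable script and the plan JSON are
#' guaranteed to encode the same instruction sequence.
#'
#' @param plan an [InstructionPlan-class].
#' @param path output `.py` path.
#' @param protocol_name name placed in the script metadata.
#' @return invisibly, the path.
#' @export
renderProtocolScript <- function(plan, path,
                                 protocol_name = "goldengate_assembly") {
  tmpl_path <- system.file("templates", "opentrons_v2.py.tmpl",
                           package = "mocloplan")
  if (!nzchar(tmpl_path)) stop("protocol template not installed")
  tmpl <- paste(readLines(tmpl_path, warn = FALSE), collapse = "\n")
  api <- if (deck(plan)@platform == "Flex") "2.21" else "2.15"
  robot <- if (deck(plan)@platform == "Flex") "Flex" else "OT-2"
  # literal placeholder substitution (sub() would mangle \ and & in the
  # replacement text)
  fill <- function(text, token, value) {
    parts <- strsplit(text, token, fixed = TRUE)[[1L]]
    paste(parts, collapse = value)
  }
  out <- tmpl
  out <- fill(out, "{{PROTOCOL_NAME}}", protocol_name)
  out <- fill(out, "{{API_LEVEL}}", api)
  out <- fill(out, "{{ROBOT_TYPE}}", robot)
  out <- fill(out, "{{PLAN_JSON}}", planJsonString(plan))
  writeLines(out, path)
  invisible(path)
}

#' Extract the plan JSON embedded in a rendered protocol script
#'
#' Parser-free companion check for [renderProtocolScript()]: returns the
#' verbatim JSON text between the script's `PLAN-BEGIN` / `PLAN-END`
#' markers, which must equal the output of [planJsonString()].
#'
#' @param path a rendered `.py` protocol.
#' @return single string of JSON.
#' @export
extractEmbeddedPlan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i0 <- grep("# -- PLAN-BEGIN --", lines, fixed = TRUE)
  i1 <- grep("# -- PLAN-END --", lines, fixed = TRUE)
  if (length(i0) != 1L || length(i1) != 1L || i1 <= i0)
    parseError("no embedded plan markers found in script")
  paste(lines[(i0 + 1L):(i1 - 1L)], collapse = "\n")
}
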