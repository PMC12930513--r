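#' @import methods
NULL

## ---- PlateMap --------------------------------------------------------------

## wells data.frame schema shared by PlateMap and the part-map CSV dialect
emptyWellsDf <- function() {
  data.frame(
    well = character(), part_name = character(), part_type = character(),
    concentration_ng_per_ul = numeric(), length_bp = integer(),
    stringsAsFactors = FALSE
  )
}

#' PlateMap: named labware holding DNA part records
#'
#' A `PlateMap` represents one piece of labware (typically a 96-well plate
#' or a 24-tube reagent rack) whose occupied wells each carry one part
#' record: part name, MoClo part-type label, stock concentration (ng/µL)
#' and length (bp). Concentration and length may be `NA` for reagent-style
#' entries or when fixed-volume dosing is used; when present they must be
#' nonnegative / at least 1 bp.
#'
#' @slot labware_id single string naming the labware.
#' @slot plate_format one of `"96-well"`, `"24-well"`, `"6-well"`.
#' @slot wells data.frame with columns `well`, `part_name`, `part_type`,
#'   `concentration_ng_per_ul`, `length_bp`; one row per occupied well.
#' @seealso [readPlateMap()], [writePlateMap()], [makeToolkitPlate()]
#' @export
setClass("PlateMap",
  representation(
    labware_id = "character",
    plate_format = "character",
    wells = "data.frame"
  ),
  prototype(labware_id = "plate", plate_format = "96-well",
            wells = emptyWellsDf())
)

setValidity("PlateMap", function(object) {
  msg <- character()
  w <- object@wells
  if (length(object@labware_id) != 1L || !nzchar(object@labware_id))
    msg <- c(msg, "labware_id must be a single nonempty string")
  if (!object@plate_format %in% c("96-well", "24-well", "6-well"))
    msg <- c(msg, "unknown plate_format")
  need <- colnames(emptyWellsDf())
  if (!all(need %in% colnames(w)))
    return("wells is missing required columns")
  if (anyDuplicated(w$well))
    msg <- c(msg, sprintf("duplicate well label: %s",
                          w$well[duplicated(w$well)][1L]))
  bad <- !isValidWell(w$well, object@plate_format)
  if (any(bad))
    msg <- c(msg, sprintf("invalid well label for %s format: %s",
                          object@plate_format, w$well[bad][1L]))
  if (any(!nzchar(w$part_name)))
    msg <- c(msg, "empty part_name")
  conc <- w$concentration_ng_per_ul
  if (any(!is.na(conc) & conc < 0))
    msg <- c(msg, "negative concentration")
  len <- w$length_bp
  if (any(!is.na(len) & len < 1))
    msg <- c(msg, "length_bp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PlateMap
#'
#' @param labware_id labware name.
#' @param plate_format plate format tag (see [wellLabels()]).
#' @param wells data.frame of occupied wells (may be empty); rows are
#'   stored sorted row-major by well label, so row order never matters.
#' @return a validated [PlateMap-class] object.
#' @examples
#' PlateMap("tk", wells = data.frame(
#'   well = "A1", part_name = "pTDH3", part_type = "2",
#'   concentration_ng_per_ul = 60, length_bp = 2400L))
#' @export
PlateMap <- function(labware_id, plate_format = "96-well",
                     wells = emptyWellsDf()) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (nrow(wells)) {
    wells$length_bp <- as.integer(wells$length_bp)
    wells$concentration_ng_per_ul <- as.numeric(wells$concentration_ng_per_ul)
    wells <- wells[wellOrder(wells$well), colnames(emptyWellsDf()), drop = FALSE]
    rownames(wells) <- NULL
  } else {
    wells <- emptyWellsDf()
  }
  new("PlateMap", labware_id = labware_id, plate_format = plate_format,
      wells = wells)
}

## ---- AssemblyDesign --------------------------------------------------------

#' AssemblyDesign: one Golden Gate construct
#'
#' Names a backbone plus an ordered list of parts (by part name) and the
#' destination well in the reaction plate.
#'
#' @slot construct_name unique construct identifier.
#' @slot backbone part name of the recipient backbone plasmid.
#' @slot parts ordered character vector of part names (nonempty).
#' @slot destination_well reaction-plate well label.
#' @seealso [readCombinations()], [validateDesign()]
#' @export
setClass("AssemblyDesign",
  representation(
    construct_name = "character",
    backbone = "character",
    parts = "character",
    destination_well = "character"
  )
)

setValidity("AssemblyDesign", function(object) {
  msg <- character()
  if (length(object@construct_name) != 1L || !nzchar(object@construct_name))
    msg <- c(msg, "construct_name must be a single nonempty string")
  if (length(object@backbone) != 1L || !nzchar(object@backbone))
    msg <- c(msg, "backbone must be a single nonempty string")
  if (length(object@parts) < 1L || any(!nzchar(object@parts)))
    msg <- c(msg, "parts must be a nonempty vector of nonempty names")
  if (length(object@destination_well) != 1L ||
      !isValidWell(object@destination_well, "96-well"))
    msg <- c(msg, "destination_well must be a valid 96-well label")
  if (length(msg)) msg else TRUE
})

#' @rdname AssemblyDesign-class
#' @param construct_name,backbone,parts,destination_well see slots.
#' @export
AssemblyDesign <- function(construct_name, backbone, parts, destination_well) {
  new("AssemblyDesign", construct_name = construct_name, backbone = backbone,
      parts = as.character(parts), destination_well = destination_well)
}

## ---- ColonyPickSheet -------------------------------------------------------

#' ColonyPickSheet: picked colonies routed to PCR wells
#'
#' One row per picked colony: the construct it came from, the well of the
#' colony template plate, the primer-pair id used to screen it, and the
#' destination well in a 96-well PCR plate. Sheets larger than 96 rows are
#' partitioned into consecutive 96-row destination plates (row-major file
#' order); destination wells must be unique within each plate.
#'
#' @slot entries data.frame with columns `construct_name`, `template_well`,
#'   `primer_pair`, `destination_well`.
#' @seealso [readColonyPicks()], [compileColonyPcr()]
#' @export
setClass("ColonyPickSheet", representation(entries = "data.frame"))

setValidity("ColonyPickSheet", function(object) {
  e <- object@entries
  need <- c("construct_name", "template_well", "primer_pair", "destination_well")
  if (!all(need %in% colnames(e)))
    return("entries is missing required columns")
  msg <- character()
  if (nrow(e)) {
    bad <- !isValidWell(e$template_well, "96-well")
    if (any(bad))
      msg <- c(msg, sprintf("invalid template well label: %s",
                            e$template_well[bad][1L]))
    bad <- !isValidWell(e$destination_well, "96-well")
    if (any(bad))
      msg <- c(msg, sprintf("invalid destination well label: %s",
                            e$destination_well[bad][1L]))
    plate <- (seq_len(nrow(e)) - 1L) %/% 96L
    dup <- duplicated(paste(plate, e$destination_well))
    if (any(dup))
      msg <- c(msg, sprintf("duplicate destination PCR well: %s",
                            e$destination_well[dup][1L]))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ColonyPickSheet-class
#' @param entries data.frame of pick entries.
#' @export
ColonyPickSheet <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!nrow(entries))
    entries <- data.frame(construct_name = character(),
                          template_well = character(),
                          primer_pair = character(),
                          destination_well = character(),
                          stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("ColonyPickSheet", entries = entries)
}

## ---- ToolkitSchema ---------------------------------------------------------

#' ToolkitSchema: positional grammar of a Golden Gate toolkit
#'
#' Defines the ordered part-type slots of a complete Level-1 transcription
#' unit, the allowed backbone types, the dropout marker carried by the
#' backbone, and equivalence groups mapping contiguous runs of sub-slots
#' onto a parent slot (e.g. YTK "3a"+"3b" stands for "3").
#'
#' @slot toolkit_name schema name (e.g. "YTK Level 1").
#' @slot slot_order ordered character vector of part-type labels.
#' @slot backbone_types part-type labels accepted for the backbone.
#' @slot dropout_marker `"GFP-dropout"`, `"lacZ-dropout"` or `"none"`.
#' @slot equivalence_groups named list: parent slot label -> ordered
#'   character vector of sub-slot labels replacing it.
#' @seealso [ytkLevel1Schema()], [stkLevel1Schema()], [readToolkitSchema()]
#' @export
setClass("ToolkitSchema",
  representation(
    toolkit_name = "character",
    slot_order = "character",
    backbone_types = "character",
    dropout_marker = "character",
    equivalence_groups = "list"
  ),
  prototype(dropout_marker = "none", equivalence_groups = list())
)

setValidity("ToolkitSchema", function(object) {
  msg <- character()
  if (!length(object@slot_order))
    msg <- c(msg, "slot_order must be nonempty")
  if (anyDuplicated(object@slot_order))
    msg <- c(msg, "slot_order has duplicate labels")
  if (!object@dropout_marker %in% c("GFP-dropout", "lacZ-dropout", "none"))
    msg <- c(msg, "unknown dropout_marker")
  eg <- object@equivalence_groups
  if (length(eg)) {
    if (is.null(names(eg)) || any(!nzchar(names(eg))))
      msg <- c(msg, "equivalence_groups must be a named list")
    else if (!all(names(eg) %in% object@slot_order))
      msg <- c(msg, "equivalence group parents must appear in slot_order")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ToolkitSchema-class
#' @param toolkit_name,slot_order,backbone_types,dropout_marker,equivalence_groups
#'   see slots.
#' @export
ToolkitSchema <- function(toolkit_name, slot_order, backbone_types,
                          dropout_marker = "none",
                          equivalence_groups = list()) {
  new("ToolkitSchema", toolkit_name = toolkit_name,
      slot_order = as.character(slot_order),
      backbone_types = as.character(backbone_types),
      dropout_marker = dropout_marker,
      equivalence_groups = equivalence_groups)
}

## ---- ValidationReport ------------------------------------------------------

#' ValidationReport: outcome of grammar-checking one design
#'
#' @slot design_name the construct checked.
#' @slot status `TRUE` iff no error-severity finding.
#' @slot findings data.frame with columns `severity` ("error"/"warning")
#'   and `message`.
#' @export
setClass("ValidationReport",
  representation(design_name = "character", status = "logical",
                 findings = "data.frame")
)

setValidity("ValidationReport", function(object) {
  f <- object@findings
  if (!all(c("severity", "message") %in% colnames(f)))
    return("findings needs severity and message columns")
  has_err <- any(f$severity == "error")
  if (object@status == has_err)
    return("status must be FALSE iff an error finding is present")
  TRUE
})

## ---- Recipes ---------------------------------------------------------------

#' GoldenGateRecipe: platform constants for one Golden Gate reaction
#'
#' Defaults encode the platform presets: OT-2 reactions are 10 µL with
#' 50 fmol of every plasmid (entry parts and backbone alike), 0.5 µL BsaI
#' plus 0.5 µL T4 ligase, master mix distributed first; Flex reactions are
#' 12 µL with 25 fmol and 1.2 µL Golden Gate enzyme mix, buffer and water
#' dispensed first, then plasmids, then enzymes.
#'
#' @slot platform `"OT-2"` or `"Flex"`.
#' @slot total_volume reaction volume, µL.
#' @slot dna_amount_fmol molar DNA dose per part, fmol.
#' @slot enzyme_components data.frame (`name`, `volume_ul`).
#' @slot buffer_stock_fold fold concentration of the ligase buffer stock
#'   (default 10x, so buffer volume = total / 10).
#' @slot dispense_order `"master_mix_first"` or `"buffer_water_first"`.
#' @slot mass_per_bp average double-stranded base-pair mass,
#'   g·mol⁻¹·bp⁻¹ (default 650).
#' @slot fixed_dna_volume `NA` for molar dosing, else a fixed µL dose per
#'   part used when stock concentrations are not recorded.
#' @seealso [goldenGateRecipe()], [buildGgReaction()]
#' @export
setClass("GoldenGateRecipe",
  representation(
    platform = "character",
    total_volume = "numeric",
    dna_amount_fmol = "numeric",
    enzyme_components = "data.frame",
    buffer_stock_fold = "numeric",
    dispense_order = "character",
    mass_per_bp = "numeric",
    fixed_dna_volume = "numeric"
  )
)

setValidity("GoldenGateRecipe", function(object) {
  msg <- character()
  if (!object@platform %in% c("OT-2", "Flex"))
    msg <- c(msg, "platform must be OT-2 or Flex")
  if (object@total_volume <= 0)
    msg <- c(msg, "total_volume must be positive")
  fixed <- object@total_volume / object@buffer_stock_fold +
    sum(object@enzyme_components$volume_ul)
  if (fixed > object@total_volume)
    msg <- c(msg, "fixed components exceed total_volume")
  if (!object@dispense_order %in% c("master_mix_first", "buffer_water_first"))
    msg <- c(msg, "unknown dispense_order")
  if (object@mass_per_bp <= 0)
    msg <- c(msg, "mass_per_bp must be positive")
  if (length(msg)) msg else TRUE
})

#' PcrRecipe: platform constants for one colony PCR reaction
#'
#' OT-2 preset: 9 µL master mix + 1 µL colony template (10 µL total);
#' Flex preset: 13 µL master mix + 2 µL template (15 µL total). The master
#' mix contains water, the primer pair and 2x PCR master mix; the 2x mix
#' volume is half the total reaction volume.
#'
#' @slot platform `"OT-2"` or `"Flex"`.
#' @slot master_mix_volume µL of master mix dispensed per reaction.
#' @slot template_volume µL of colony template added per reaction.
#' @slot composition data.frame (`component`, `volume_ul`) per reaction:
#'   `twofold_mix`, `primers`, `water` summing to `master_mix_volume`.
#' @seealso [pcrRecipe()], [buildPcrReaction()]
#' @export
setClass("PcrRecipe",
  representation(
    platform = "character",
    master_mix_volume = "numeric",
    template_volume = "numeric",
    composition = "data.frame"
  )
)

setValidity("PcrRecipe", function(object) {
  msg <- character()
  if (!object@platform %in% c("OT-2", "Flex"))
    msg <- c(msg, "platform must be OT-2 or Flex")
  total <- object@master_mix_volume + object@template_volume
  comp <- object@composition
  if (abs(sum(comp$volume_ul) - object@master_mix_volume) > 1e-9)
    msg <- c(msg, "master mix composition must sum to master_mix_volume")
  two <- comp$volume_ul[comp$component == "twofold_mix"]
  if (length(two) != 1L || abs(two - total / 2) > 1e-9)
    msg <- c(msg, "2x PCR mix volume must be half the total reaction volume")
  if (any(comp$volume_ul < 0))
    msg <- c(msg, "negative component volume")
  if (length(msg)) msg else TRUE
})

## ---- ReactionPlan ----------------------------------------------------------

#' ReactionPlan: realized per-well component breakdown
#'
#' @slot destination_well reaction-plate well.
#' @slot components data.frame with columns `source_labware`, `source_well`,
#'   `component`, `volume_ul`, in dispense-relevant canonical order
#'   (buffer, enzymes, DNA).
#' @slot water_topup µL of water absorbing the remainder so that
#'   components + water sum exactly to `total_volume`.
#' @slot total_volume the recipe total, µL.
#' @export
setClass("ReactionPlan",
  representation(
    destination_well = "character",
    components = "data.frame",
    water_topup = "numeric",
    total_volume = "numeric"
  )
)

setValidity("ReactionPlan", function(object) {
  msg <- character()
  if (any(object@components$volume_ul < 0) || object@water_topup < 0)
    msg <- c(msg, "volumes must be nonnegative")
  s <- sum(object@components$volume_ul) + object@water_topup
  if (abs(s - object@total_volume) > 1e-9)
    msg <- c(msg, sprintf(
      "components + water (%.9f) do not close to total volume (%.9f)",
      s, object@total_volume))
  if (length(msg)) msg else TRUE
})

## ---- ThermalProfile --------------------------------------------------------

#' ThermalProfile: ordered temperature program
#'
#' Steps are grouped into blocks; all rows of a block share a repeat count
#' and the block's step sequence is cycled that many times (the default
#' Golden Gate profile cycles 37 °C/2 min + 16 °C/5 min as one block
#' repeated 25 times, then holds 60 °C/5 min once).
#'
#' @slot steps data.frame with columns `block`, `temperature_c`, `hold_s`,
#'   `repeat_n`.
#' @slot lid_temperature_c thermocycler lid temperature, °C.
#' @seealso [ggThermalProfile()], [totalDuration()]
#' @export
setClass("ThermalProfile",
  representation(steps = "data.frame", lid_temperature_c = "numeric"),
  prototype(lid_temperature_c = 105)
)

setValidity("ThermalProfile", function(object) {
  s <- object@steps
  if (!all(c("block", "temperature_c", "hold_s", "repeat_n") %in% colnames(s)))
    return("steps needs block, temperature_c, hold_s, repeat_n columns")
  msg <- character()
  if (any(s$repeat_n < 1)) msg <- c(msg, "repeat counts must be >= 1")
  if (any(s$hold_s <= 0)) msg <- c(msg, "holds must be positive")
  rep_per_block <- tapply(s$repeat_n, s$block, function(x) length(unique(x)))
  if (any(rep_per_block > 1))
    msg <- c(msg, "all steps of a block must share one repeat count")
  if (length(msg)) msg else TRUE
})

## ---- MasterMixSpec ---------------------------------------------------------

#' MasterMixSpec: scaled shared-component pool
#'
#' @slot n_reactions number of reactions served.
#' @slot overage_factor dimensionless overage (>= 1; default 1.1).
#' @slot per_reaction data.frame (`component`, `volume_ul`) per reaction.
#' @slot component_totals data.frame (`component`, `volume_ul`), each total
#'   = per-reaction x n x overage, reported at 0.1 µL (round half up).
#' @slot container chosen container class for the pooled volume.
#' @slot container_warning message when the pool escalates past a 1.5 mL
#'   tube's safe fill, else empty.
#' @seealso [buildMasterMix()]
#' @export
setClass("MasterMixSpec",
  representation(
    n_reactions = "integer",
    overage_factor = "numeric",
    per_reaction = "data.frame",
    component_totals = "data.frame",
    container = "character",
    container_warning = "character"
  )
)

setValidity("MasterMixSpec", function(object) {
  msg <- character()
  if (object@n_reactions < 1L) msg <- c(msg, "n_reactions must be >= 1")
  if (object@overage_factor < 1) msg <- c(msg, "overage_factor must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- DeckLayout ------------------------------------------------------------

#' DeckLayout: slot allocation on the robot deck
#'
#' The OT-2 deck exposes 11 addressable slots (1..11; slot 12 is the fixed
#' trash); an on-deck thermocycler occupies four of them (7, 8, 10, 11).
#' The Flex deck is modeled as 12 addressable letter-number slots (A1..D3,
#' D3 holding the trash chute is excluded, C4 staging unused); the on-deck
#' thermocycler is not supported on Flex here — Flex thermocycling runs on
#' benchtop machines.
#'
#' @slot platform `"OT-2"` or `"Flex"`.
#' @slot slots named list: slot id -> list(`type`, `labware_id`) or the
#'   string `"empty"`.
#' @slot modules character vector of installed modules.
#' @slot tip_racks data.frame (`slot`, `labware_id`, `capacity`).
#' @seealso [planDeck()]
#' @export
setClass("DeckLayout",
  representation(
    platform = "character",
    slots = "list",
    modules = "character",
    tip_racks = "data.frame"
  )
)

setValidity("DeckLayout", function(object) {
  msg <- character()
  ids <- deckSlotIds(object@platform)
  if (!all(names(object@slots) %in% ids))
    msg <- c(msg, "slot ids do not match the platform deck")
  if (anyDuplicated(names(object@slots)))
    msg <- c(msg, "a slot has more than one occupant")
  if (length(msg)) msg else TRUE
})

## slot id universe per platform
deckSlotIds <- function(platform) {
  if (platform == "OT-2") as.character(1:11)
  else as.vector(t(outer(c("A", "B", "C", "D"), 1:3, paste0)))
}

## ---- PlatingLayout ---------------------------------------------------------

#' PlatingLayout: droplet positions for agar plating
#'
#' Deterministic center + concentric-ring spot pattern inside one agar
#' well of a 6-well plate. Defaults follow the validated protocol: 13
#' spots, 4.5 µL droplets (2.5 µL on Flex), dispense height z = 5 mm above
#' the agar surface.
#'
#' @slot positions data.frame (`x_mm`, `y_mm`) offsets from well center.
#' @slot droplet_volume_ul droplet volume, µL.
#' @slot z_mm dispense height above the agar, mm.
#' @slot well_radius_mm,edge_margin_mm,min_spacing_mm geometry, mm.
#' @seealso [platingLayout()]
#' @export
setClass("PlatingLayout",
  representation(
    positions = "data.frame",
    droplet_volume_ul = "numeric",
    z_mm = "numeric",
    well_radius_mm = "numeric",
    edge_margin_mm = "numeric",
    min_spacing_mm = "numeric"
  )
)

setValidity("PlatingLayout", function(object) {
  p <- object@positions
  msg <- character()
  rmax <- object@well_radius_mm - object@edge_margin_mm
  r <- sqrt(p$x_mm^2 + p$y_mm^2)
  if (any(r > rmax + 1e-9))
    msg <- c(msg, "a spot lies outside well radius minus edge margin")
  if (nrow(p) > 1L) {
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    if (min(d) < object@min_spacing_mm - 1e-9)
      msg <- c(msg, "spots closer than min spacing")
  }
  if (object@droplet_volume_ul <= 0) msg <- c(msg, "droplet volume must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- InstructionPlan -------------------------------------------------------

instructionKinds <- c("pick_tip", "drop_tip", "aspirate", "dispense", "mix",
                      "move", "thermal_step", "pause_for_operator",
                      "set_temperature")

emptyInstructionsDf <- function() {
  data.frame(
    kind = character(), pipette = character(), labware = character(),
    well = character(), volume_ul = numeric(),
    x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
    comment = character(), stringsAsFactors = FALSE
  )
}

#' InstructionPlan: ordered atomic robot commands plus deck layout
#'
#' The compiled artifact: a deck layout, an ordered instruction table, the
#' named stage ranges partitioning it, the initial labware contents the
#' operator must load (used to seed the virtual robot), and the expected
#' per-well [ReactionPlan-class] objects for the composition audit.
#'
#' @slot deck a [DeckLayout-class].
#' @slot instructions data.frame: `kind`, `pipette`, `labware`, `well`,
#'   `volume_ul`, `x_mm`, `y_mm`, `z_mm`, `comment`.
#' @slot stages data.frame (`stage`, `start`, `end`), 1-based inclusive
#'   ranges partitioning the instruction list.
#' @slot initial_contents data.frame (`labware`, `well`, `component`,
#'   `volume_ul`).
#' @slot reactions list of expected [ReactionPlan-class] objects.
#' @seealso [compileGoldenGate()], [compileColonyPcr()], [simulatePlan()]
#' @export
setClass("InstructionPlan",
  representation(
    deck = "DeckLayout",
    instructions = "data.frame",
    stages = "data.frame",
    initial_contents = "data.frame",
    reactions = "list"
  )
)

setValidity("InstructionPlan", function(object) {
  ins <- object@instructions
  msg <- character()
  if (!all(ins$kind %in% instructionKinds))
    msg <- c(msg, "unknown instruction kind")
  liq <- ins$kind %in% c("aspirate", "dispense")
  if (any(liq & (is.na(ins$volume_ul) | ins$volume_ul <= 0)))
    msg <- c(msg, "aspirate/dispense volumes must be positive")
  st <- object@stages
  if (nrow(st)) {
    span <- unlist(Map(seq, st$start, st$end))
    if (!identical(sort(span), seq_len(nrow(ins))))
      msg <- c(msg, "stage ranges must partition the instruction list")
  } else if (nrow(ins)) {
    msg <- c(msg, "nonempty plan needs stage ranges")
  }
  if (length(msg)) msg else TRUE
})

## ---- SimReport -------------------------------------------------------------

#' SimReport: outcome of a virtual-robot run
#'
#' @slot final_wells data.frame (`labware`, `well`, `component`,
#'   `volume_ul`): the per-well composition ledger after the last
#'   instruction.
#' @slot violations data.frame (`instruction_index`, `rule`, `message`).
#'   Zero rows iff the plan is executable.
#' @slot tips_consumed total tips picked.
#' @seealso [simulatePlan()], [auditCompositions()]
#' @export
setClass("SimReport",
  representation(
    final_wells = "data.frame",
    violations = "data.frame",
    tips_consumed = "integer"
  )
)
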