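#' @include planner-deck.R recipes.R
NULL

## pipette models per platform: name and max working volume (uL)
platformPipettes <- function(platform) {
  if (platform == "OT-2")
    list(small = list(name = "p20_single_gen2", max = 20),
         large = list(name = "p300_single_gen2", max = 300))
  else
    list(small = list(name = "flex_1channel_50", max = 50),
         large = list(name = "flex_1channel_1000", max = 1000))
}

## Instruction emitter: accumulates the ordered command stream with tip
## accounting (move before every positioned action; fresh-tip bookkeeping;
## operator pauses to refill exhausted tip racks), and stage ranges.
newEmitter <- function(deck) {
  pip <- platformPipettes(deck@platform)
  tip_capacity <- sum(deck@tip_racks$capacity)
  labels96 <- wellLabels("96-well")

  n <- 0L
  cap <- 4096L
  kind <- character(cap); pipette <- character(cap)
  labware <- character(cap); well <- character(cap)
  volume <- numeric(cap); xm <- numeric(cap); ym <- numeric(cap)
  zm <- numeric(cap); comment <- character(cap)
  stage_name <- character(); stage_start <- integer(); stage_end <- integer()
  cur_stage_start <- NA_integer_; cur_stage <- NA_character_
  tips_since_refill <- 0L
  has_tip <- c(small = FALSE, large = FALSE)
  at <- c(small = NA_character_, large = NA_character_)  # last location key

  grow <- function() {
    cap <<- cap * 2L
    length(kind) <<- cap; length(pipette) <<- cap; length(labware) <<- cap
    length(well) <<- cap; length(volume) <<- cap; length(xm) <<- cap
    length(ym) <<- cap; length(zm) <<- cap; length(comment) <<- cap
  }
  emit <- function(k, p = NA_character_, l = NA_character_,
                   w = NA_character_, v = NA_real_, x = NA_real_,
                   y = NA_real_, z = NA_real_, cm = "") {
    if (n + 1L > cap) grow()
    n <<- n + 1L
    kind[n] <<- k; pipette[n] <<- p; labware[n] <<- l; well[n] <<- w
    volume[n] <<- v; xm[n] <<- x; ym[n] <<- y; zm[n] <<- z; comment[n] <<- cm
  }

  whichPip <- function(v) if (v <= pip$small$max) "small" else "large"

  moveTo <- function(p, l, w, x = NA_real_, y = NA_real_, z = NA_real_,
                     cm = "") {
    key <- paste(l, w, x, y, z)
    if (identical(at[[p]], key)) return(invisible())
    emit("move", pip[[p]]$name, l, w, NA_real_, x, y, z, cm)
    at[p] <<- key
  }

  pickTip <- function(p) {
    stopifnot(!has_tip[[p]])
    if (tips_since_refill >= tip_capacity) {
      emit("pause_for_operator",
           cm = "tip racks exhausted: replace all tip racks with full ones, then resume")
      tips_since_refill <<- 0L
    }
    idx <- tips_since_refill
    rack <- deck@tip_racks[idx %/% 96L + 1L, ]
    moveTo(p, rack$labware_id, labels96[idx %% 96L + 1L])
    emit("pick_tip", pip[[p]]$name, rack$labware_id,
         labels96[idx %% 96L + 1L])
    tips_since_refill <<- tips_since_refill + 1L
    has_tip[p] <<- TRUE
  }
  dropTip <- function(p) {
    stopifnot(has_tip[[p]])
    moveTo(p, "trash", NA_character_)
    emit("drop_tip", pip[[p]]$name, "trash")
    has_tip[p] <<- FALSE
  }

  ## one aspirate/dispense pair, chunked to the pipette's max volume;
  ## assumes the tip is already on
  pour <- function(p, src_l, src_w, dst_l, dst_w, vol, dst_off = NULL,
                   cm = "") {
    remaining <- vol
    mx <- pip[[p]]$max
    while (remaining > 1e-12) {
      v <- min(remaining, mx)
      moveTo(p, src_l, src_w)
      emit("aspirate", pip[[p]]$name, src_l, src_w, v, cm = cm)
      if (is.null(dst_off)) moveTo(p, dst_l, dst_w)
      else moveTo(p, dst_l, dst_w, dst_off[1L], dst_off[2L], dst_off[3L])
      emit("dispense", pip[[p]]$name, dst_l, dst_w, v,
           if (is.null(dst_off)) NA_real_ else dst_off[1L],
           if (is.null(dst_off)) NA_real_ else dst_off[2L],
           if (is.null(dst_off)) NA_real_ else dst_off[3L], cm = cm)
      remaining <- remaining - v
    }
  }

  ## fresh-tip single transfer (one DNA part, one template, ...)
  transfer <- function(src_l, src_w, dst_l, dst_w, vol, mix_after = NA,
                       dst_off = NULL, cm = "") {
    p <- whichPip(vol)
    pickTip(p)
    pour(p, src_l, src_w, dst_l, dst_w, vol, dst_off, cm)
    if (!is.na(mix_after)) {
      moveTo(p, dst_l, dst_w)
      emit("mix", pip[[p]]$name, dst_l, dst_w, mix_after, cm = "mix after dispense")
    }
    dropTip(p)
  }

  ## shared-tip distribution of one source to many destinations
  distribute <- function(src_l, src_w, dst_l, dst_w, vols, cm = "") {
    keep <- vols > 1e-12
    dst_l <- rep_len(dst_l, length(vols))[keep]
    dst_w <- dst_w[keep]; vols <- vols[keep]
    if (!length(vols)) return(invisible())
    p <- whichPip(max(vols))
    pickTip(p)
    for (i in seq_along(vols))
      pour(p, src_l, src_w, dst_l[i], dst_w[i], vols[i], cm = cm)
    dropTip(p)
  }

  mixAt <- function(l, w, vol, cm = "") {
    p <- whichPip(vol)
    pickTip(p)
    moveTo(p, l, w)
    emit("mix", pip[[p]]$name, l, w, vol, cm = cm)
    dropTip(p)
  }

  pause <- function(cm) emit("pause_for_operator", cm = cm)
  setTemp <- function(l, temp, cm = "")
    emit("set_temperature", l = l, v = temp, cm = cm)
  thermal <- function(profile, l) {
    s <- profile@steps
    setTemp(l, profile@lid_temperature_c, "set lid temperature")
    for (i in seq_len(nrow(s)))
      emit("thermal_step", l = l, v = s$temperature_c[i],
           cm = sprintf("%g C for %g s (x%d)", s$temperature_c[i],
                        s$hold_s[i], s$repeat_n[i]))
  }

  stageStart <- function(name) {
    cur_stage <<- name; cur_stage_start <<- n + 1L
  }
  stageEnd <- function() {
    stopifnot(n >= cur_stage_start)  # a stage never compiles empty
    stage_name <<- c(stage_name, cur_stage)
    stage_start <<- c(stage_start, cur_stage_start)
    stage_end <<- c(stage_end, n)
  }

  result <- function() {
    idx <- seq_len(n)
    list(
      instructions = data.frame(
        kind = kind[idx], pipette = pipette[idx], labware = labware[idx],
        well = well[idx], volume_ul = volume[idx], x_mm = xm[idx],
        y_mm = ym[idx], z_mm = zm[idx], comment = comment[idx],
        stringsAsFactors = FALSE),
      stages = data.frame(stage = stage_name, start = stage_start,
                          end = stage_end, stringsAsFactors = FALSE))
  }

  environment()
}

## Replay the instruction stream to find how much liquid each aspirated
## well must hold at load time; initial volume = peak net draw + dead
## volume. Component names come from the compiler's well registry.
computeInitialContents <- function(ins, registry, dead_volume = 5) {
  net <- new.env(parent = emptyenv())
  minnet <- new.env(parent = emptyenv())
  touch <- function(key) {
    if (is.null(net[[key]])) { net[[key]] <- 0; minnet[[key]] <- 0 }
  }
  liq <- which(ins$kind %in% c("aspirate", "dispense"))
  for (i in liq) {
    key <- paste0(ins$labware[i], "|", ins$well[i])
    touch(key)
    d <- if (ins$kind[i] == "aspirate") -ins$volume_ul[i] else ins$volume_ul[i]
    net[[key]] <- net[[key]] + d
    if (net[[key]] < minnet[[key]]) minnet[[key]] <- net[[key]]
  }
  keys <- ls(minnet)
  need <- vapply(keys, function(k) -minnet[[k]], numeric(1))
  keys <- keys[need > 1e-12]; need <- need[need > 1e-12]
  if (!length(keys))
    return(data.frame(labware = character(), well = character(),
                      component = character(), volume_ul = numeric(),
                      stringsAsFactors = FALSE))
  comp <- vapply(keys, function(k) {
    cm <- registry[[k]]
    if (is.null(cm))
      stop("internal: no component registered for source well ", k)
    cm
  }, character(1))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    labware = vapply(parts, `[`, character(1), 1L),
    well = vapply(parts, `[`, character(1), 2L),
    component = comp,
    volume_ul = need + dead_volume,
    stringsAsFactors = FALSE)
  out <- out[order(out$labware, out$well), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## reagent rack well assignments for the Golden Gate workflow
ggReagentWells <- function(recipe) {
  w <- c(water = "A1", ligase_buffer = "A2")
  enz <- recipe@enzyme_components$name
  w[enz] <- wellLabels("24-well")[2L + seq_along(enz)]
  w["master_mix"] <- "B1"
  w["competent_cells"] <- "B2"
  w
}

#' Compile the full Golden Gate cloning instruction plan
#'
#' Emits the ordered command stream for assembly setup, thermocycling,
#' E. coli transformation and agar plating. Stage structure: (1) reagent
#' distribution — on the OT-2 a master mix (buffer + enzymes, plus water
#' when its top-up is uniform) is pooled and distributed first, then
#' per-well water; on the Flex buffer and water are dispensed first;
#' (2) every plasmid (backbone, then parts in order) is transferred with
#' a fresh tip per source; on the Flex the enzyme mix follows the
#' plasmids; each destination is mixed; (3) the thermal profile runs on
#' the on-deck thermocycler, or compiles to an operator pause for
#' benchtop cycling; (4) competent cells are added and heat-shocked;
#' (5) each construct is plated as droplets at the plating layout's x-y
#' offsets and drop height, one agar well per construct, with operator
#' pauses to swap agar plates and refill tip racks as needed.
#'
#' @param designs list of [AssemblyDesign-class] (validated; pass
#'   `schema` to validate here).
#' @param sources list of [PlateMap-class] source plates; their labware
#'   ids must match the deck's source slots.
#' @param recipe a [GoldenGateRecipe-class].
#' @param deck a [DeckLayout-class]; default [planDeck()] for the recipe's
#'   platform.
#' @param plating a [PlatingLayout-class]; default [platingLayout()] with
#'   the platform droplet volume.
#' @param schema optional [ToolkitSchema-class]; when given, every design
#'   is checked with [validateDesign()] and any error finding aborts
#'   compilation.
#' @param overage master-mix overage factor; default 1.1.
#' @param cell_volume_ul competent cells added per reaction; default 20.
#' @param droplets_per_construct droplets plated per construct; default 1.
#' @param profile Golden Gate [ThermalProfile-class]; default
#'   [ggThermalProfile()].
#' @param heat_shock heat-shock [ThermalProfile-class]; default
#'   [heatShockProfile()].
#' @return an [InstructionPlan-class] that simulates with zero violations.
#' @seealso [simulatePlan()] to verify, [writePlanJson()] /
#'   [renderProtocolScript()] to emit artifacts.
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 3, seed = 1)
#' plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
#' countInstructions(plan)[["total"]]
#' @export
compileGoldenGate <- function(designs, sources, recipe, deck = NULL,
                              plating = NULL, schema = NULL, overage = 1.1,
                              cell_volume_ul = 20,
                              droplets_per_construct = 1L,
                              profile = ggThermalProfile(recipe),
                              heat_shock = heatShockProfile()) {
  stopifnot(length(designs) >= 1L, is(recipe, "GoldenGateRecipe"))
  n <- length(designs)
  if (n > 96L)
    capacityError(sprintf(
      "%d assemblies exceed the 96-assembly capacity of one run", n))
  dests <- vapply(designs, function(d) d@destination_well, character(1))
  if (anyDuplicated(dests))
    grammarError(sprintf("duplicate destination well '%s' across designs",
                         dests[duplicated(dests)][1L]))

  if (!is.null(schema)) {
    for (d in designs) {
      vr <- validateDesign(d, schema, sources)
      if (!passed(vr))
        grammarError(sprintf(
          "design '%s' fails validation: %s", d@construct_name,
          paste(findings(vr)$message[findings(vr)$severity == "error"],
                collapse = "; ")))
    }
  }

  if (is.null(deck))
    deck <- planDeck(recipe@platform, n,
                     use_onboard_thermocycler = recipe@platform == "OT-2",
                     n_agar_plates = min(2L, max(1L, ceiling(n / 6))))
  if (is.null(plating))
    plating <- platingLayout(
      droplet_volume_ul = if (recipe@platform == "Flex") 2.5 else 4.5)
  if (droplets_per_construct > nrow(plating@positions))
    layoutError(sprintf(
      "%d droplets per construct exceed the %d plating positions per agar well",
      droplets_per_construct, nrow(plating@positions)))

  types <- deckLabwareTypes(deck)
  src_ids <- vapply(sources, labwareId, character(1))
  missing_src <- setdiff(src_ids, names(types))
  if (length(missing_src))
    layoutError(sprintf("source plate(s) not on deck: %s",
                        paste(missing_src, collapse = ", ")))
  onboard <- "thermocycler" %in% deck@modules
  if (!"reaction_plate" %in% names(types))
    layoutError("deck has no reaction plate")

  plans <- lapply(designs, function(d) buildGgReaction(d, recipe, sources))
  names(plans) <- paste0("reaction_plate|", dests)

  rw <- ggReagentWells(recipe)
  topups <- vapply(plans, waterTopup, numeric(1))
  buffer_vol <- recipe@total_volume / recipe@buffer_stock_fold

  ## well registry: source of every aspirated well, for initial contents
  registry <- new.env(parent = emptyenv())
  reg <- function(lab, well, component)
    registry[[paste0(lab, "|", well)]] <- component
  reg("reagent_rack", rw[["water"]], "water")
  reg("reagent_rack", rw[["ligase_buffer"]], "ligase_buffer")
  for (e in recipe@enzyme_components$name) reg("reagent_rack", rw[[e]], e)
  reg("reagent_rack", rw[["competent_cells"]], "competent_cells")
  for (s in sources) {
    w <- wells(s)
    for (i in seq_len(nrow(w))) reg(labwareId(s), w$well[i], w$part_name[i])
  }

  em <- newEmitter(deck)

  ## ---- stage 1+2: reaction setup ----
  em$stageStart("gg_setup")
  em$setTemp("temperature_module", 4, "chill reagent rack")
  if (recipe@dispense_order == "master_mix_first") {
    # pool buffer + enzymes (+ water when uniform across wells) and
    # distribute, then top up water per well
    mm <- data.frame(component = c("ligase_buffer",
                                   recipe@enzyme_components$name),
                     volume_ul = c(buffer_vol,
                                   recipe@enzyme_components$volume_ul),
                     stringsAsFactors = FALSE)
    uniform_water <- n > 0 && diff(range(topups)) < 1e-12 && topups[1L] > 0
    if (uniform_water)
      mm <- rbind(mm, data.frame(component = "water",
                                 volume_ul = topups[1L]))
    mmspec <- buildMasterMix(mm, n, overage)
    # prep uses exact (unrounded) totals so the pooled ratio matches the
    # per-reaction recipe; the MasterMixSpec reports 0.1 uL totals
    for (i in seq_len(nrow(mm)))
      em$transfer("reagent_rack", rw[[mm$component[i]]],
                  "reagent_rack", rw[["master_mix"]],
                  mm$volume_ul[i] * n * overage,
                  cm = sprintf("master mix: %s", mm$component[i]))
    em$mixAt("reagent_rack", rw[["master_mix"]],
             min(platformPipettes(deck@platform)$large$max,
                 sum(mm$volume_ul) * n * overage / 2),
             cm = "homogenize master mix")
    em$distribute("reagent_rack", rw[["master_mix"]], "reaction_plate",
                  dests, rep(sum(mm$volume_ul), n),
                  cm = "distribute master mix")
    if (!uniform_water)
      em$distribute("reagent_rack", rw[["water"]], "reaction_plate",
                    dests, topups, cm = "per-well water top-up")
  } else {
    # Flex order: buffer and water first, then plasmids, then enzymes
    em$distribute("reagent_rack", rw[["ligase_buffer"]], "reaction_plate",
                  dests, rep(buffer_vol, n), cm = "dispense ligase buffer")
    em$distribute("reagent_rack", rw[["water"]], "reaction_plate",
                  dests, topups, cm = "dispense water")
  }

  for (k in seq_len(n)) {
    comp <- componentTable(plans[[k]])
    dna <- comp[comp$source_labware != "reagent_rack", , drop = FALSE]
    for (i in seq_len(nrow(dna)))
      em$transfer(dna$source_labware[i], dna$source_well[i],
                  "reaction_plate", dests[k], dna$volume_ul[i],
                  cm = sprintf("%s -> %s", dna$component[i],
                               designs[[k]]@construct_name))
  }

  if (recipe@dispense_order != "master_mix_first") {
    for (i in seq_len(nrow(recipe@enzyme_components)))
      em$distribute("reagent_rack",
                    rw[[recipe@enzyme_components$name[i]]],
                    "reaction_plate", dests,
                    rep(recipe@enzyme_components$volume_ul[i], n),
                    cm = sprintf("dispense %s",
                                 recipe@enzyme_components$name[i]))
  }
  for (k in seq_len(n))
    em$mixAt("reaction_plate", dests[k],
             min(platformPipettes(deck@platform)$small$max,
                 recipe@total_volume / 2),
             cm = "mix assembled reaction")
  em$stageEnd()

  ## ---- stage 3: thermocycling ----
  em$stageStart("thermocycle")
  if (onboard) {
    em$thermal(profile, "thermocycler")
  } else {
    em$pause(paste(
      "seal the reaction plate and run the Golden Gate profile",
      "on a benchtop thermocycler",
      sprintf("(%s); return the plate and resume",
              paste(sprintf("%g C/%g s x%d", profile@steps$temperature_c,
                            profile@steps$hold_s, profile@steps$repeat_n),
                    collapse = ", "))))
  }
  em$stageEnd()

  ## ---- stage 4: transformation ----
  em$stageStart("transformation")
  for (k in seq_len(n))
    em$transfer("reagent_rack", rw[["competent_cells"]], "reaction_plate",
                dests[k], cell_volume_ul,
                mix_after = min(platformPipettes(deck@platform)$large$max,
                                (recipe@total_volume + cell_volume_ul) / 2),
                cm = "add competent cells")
  if (onboard) {
    em$thermal(heat_shock, "thermocycler")
  } else {
    em$pause("heat-shock the sealed plate (42 C / 30 s with cold holds) off deck and resume")
  }
  em$stageEnd()

  ## ---- stage 5: plating ----
  em$stageStart("plating")
  agar_ids <- grep("^agar_plate_", names(types), value = TRUE)
  m <- length(agar_ids)
  if (!m) layoutError("deck has no agar plate")
  agar_wells <- wellLabels("6-well")
  batch <- 1L
  for (k in seq_len(n)) {
    phys_plate <- (k - 1L) %/% 6L + 1L          # physical 6-well plate
    this_batch <- (phys_plate - 1L) %/% m + 1L  # on-deck load
    if (this_batch > batch) {
      em$pause(sprintf(
        "plating batch %d done: replace the %d agar plate(s) on deck with fresh ones and resume",
        batch, m))
      batch <- this_batch
    }
    lab <- agar_ids[(phys_plate - 1L) %% m + 1L]
    wl <- agar_wells[(k - 1L) %% 6L + 1L]
    for (j in seq_len(droplets_per_construct))
      em$transfer("reaction_plate", dests[k], lab, wl,
                  plating@droplet_volume_ul,
                  dst_off = c(plating@positions$x_mm[j],
                              plating@positions$y_mm[j], plating@z_mm),
                  cm = sprintf("plate %s droplet %d (batch %d)",
                               designs[[k]]@construct_name, j, batch))
  }
  em$stageEnd()

  res <- em$result()
  init <- computeInitialContents(res$instructions, registry)
  new("InstructionPlan", deck = deck, instructions = res$instructions,
      stages = res$stages, initial_contents = init, reactions = plans)
}

#' Default colony PCR thermal profile
#'
#' Generic three-block program: initial denaturation, 30 cycles of
#' denature/anneal/extend, final extension. Polymerase-specific settings
#' (annealing temperature, extension time) are overridable.
#'
#' @param cycles cycle count; default 30.
#' @param denature_c,anneal_c,extend_c temperatures, °C.
#' @param init_s,denature_s,anneal_s,extend_s,final_s holds, s.
#' @return a [ThermalProfile-class].
#' @export
pcrThermalProfile <- function(cycles = 30, denature_c = 95, anneal_c = 55,
                              extend_c = 72, init_s = 180, denature_s = 15,
                              anneal_s = 15, extend_s = 30, final_s = 300) {
  steps <- data.frame(
    block = c(1L, 2L, 2L, 2L, 3L),
    temperature_c = c(denature_c, denature_c, anneal_c, extend_c, extend_c),
    hold_s = c(init_s, denature_s, anneal_s, extend_s, final_s),
    repeat_n = c(1L, cycles, cycles, cycles, 1L))
  new("ThermalProfile", steps = steps, lid_temperature_c = 105)
}

#' Compile the colony PCR instruction plan
#'
#' Pools one master mix (water + primers + 2x PCR mix, scaled with
#' overage by [buildMasterMix()]), dispenses it to every destination well
#' with a shared tip, then transfers each colony template with a fresh
#' tip. Picks are partitioned into consecutive 96-reaction destination
#' plates (row-major file order); template plate k serves destination
#' plate k. Thermocycling compiles to on-deck thermal steps only for a
#' single plate on an OT-2 with the thermocycler module; otherwise each
#' plate gets an operator pause for benchtop cycling.
#'
#' @param picks a [ColonyPickSheet-class].
#' @param recipe a [PcrRecipe-class].
#' @param deck a [DeckLayout-class]; default [planPcrDeck()].
#' @param overage master-mix overage; default 1.1.
#' @param profile PCR [ThermalProfile-class]; default
#'   [pcrThermalProfile()].
#' @return an [InstructionPlan-class].
#' @examples
#' picks <- makeColonyPickSheet(paste0("tu", 1:6), 2)
#' plan <- compileColonyPcr(picks, pcrRecipe("OT-2"))
#' countInstructions(plan)[["dispense"]]
#' @export
compileColonyPcr <- function(picks, recipe, deck = NULL, overage = 1.1,
                             profile = pcrThermalProfile()) {
  stopifnot(is(picks, "ColonyPickSheet"), is(recipe, "PcrRecipe"))
  e <- picks@entries
  n <- nrow(e)
  if (!n) parseError("colony pick sheet is empty")
  n_plates <- ceiling(n / 96)

  mmspec <- buildMasterMix(recipe@composition, n, overage)
  needs_reservoir <- mmspec@container != "1.5 mL tube"
  if (is.null(deck))
    deck <- planPcrDeck(recipe@platform, n,
                        needs_reservoir = needs_reservoir)
  types <- deckLabwareTypes(deck)

  dest_plates <- paste0("pcr_plate_", seq_len(n_plates))
  tmpl_plates <- paste0("colony_plate_", seq_len(n_plates))
  missing <- setdiff(c(dest_plates, tmpl_plates), names(types))
  if (length(missing))
    capacityError(sprintf(
      "%d colony PCR reactions need %s on deck (%d x 96-well plates max per run)",
      n, paste(missing, collapse = ", "),
      sum(grepl("^pcr_plate_", names(types))) * 96L))

  mix_lab <- if (needs_reservoir) "mix_reservoir" else "reagent_rack"
  mix_well <- if (needs_reservoir) "A1" else "B1"
  if (needs_reservoir && !"mix_reservoir" %in% names(types))
    layoutError("pooled master mix needs a reservoir but the deck has none")

  plate_of <- (seq_len(n) - 1L) %/% 96L + 1L
  dest_lab <- dest_plates[plate_of]
  tmpl_lab <- tmpl_plates[plate_of]

  registry <- new.env(parent = emptyenv())
  registry[["reagent_rack|A1"]] <- "water"
  registry[["reagent_rack|A2"]] <- "primers"
  registry[["reagent_rack|A3"]] <- "twofold_mix"
  for (i in seq_len(n))
    registry[[paste0(tmpl_lab[i], "|", e$template_well[i])]] <-
      paste0("template_", e$construct_name[i])

  plans <- lapply(seq_len(n), function(i)
    buildPcrReaction(e[i, ], recipe, template_labware = tmpl_lab[i]))
  names(plans) <- paste0(dest_lab, "|", e$destination_well)

  em <- newEmitter(deck)
  em$stageStart("pcr_setup")
  em$setTemp("temperature_module", 4, "chill reagent rack")
  src_well <- c(water = "A1", primers = "A2", twofold_mix = "A3")
  for (i in seq_len(nrow(recipe@composition)))
    em$transfer("reagent_rack",
                src_well[[recipe@composition$component[i]]],
                mix_lab, mix_well,
                recipe@composition$volume_ul[i] * n * overage,
                cm = sprintf("master mix: %s",
                             recipe@composition$component[i]))
  em$mixAt(mix_lab, mix_well,
           min(platformPipettes(deck@platform)$large$max,
               recipe@master_mix_volume * n * overage / 2),
           cm = "homogenize PCR master mix")
  em$distribute(mix_lab, mix_well, dest_lab, e$destination_well,
                rep(recipe@master_mix_volume, n),
                cm = "distribute PCR master mix")
  for (i in seq_len(n))
    em$transfer(tmpl_lab[i], e$template_well[i], dest_lab[i],
                e$destination_well[i], recipe@template_volume,
                mix_after = min(platformPipettes(deck@platform)$small$max,
                                (recipe@master_mix_volume +
                                 recipe@template_volume) / 2),
                cm = sprintf("template %s", e$construct_name[i]))
  em$stageEnd()

  em$stageStart("thermocycle")
  onboard <- "thermocycler" %in% deck@modules && n_plates == 1L
  if (onboard) {
    em$thermal(profile, "thermocycler")
  } else {
    for (k in seq_len(n_plates))
      em$pause(sprintf(
        "seal %s and run the colony PCR program on a benchtop thermocycler",
        dest_plates[k]))
  }
  em$stageEnd()

  res <- em$result()
  init <- computeInitialContents(res$instructions, registry)
  new("InstructionPlan", deck = deck, instructions = res$instructions,
      stages = res$stages, initial_contents = init, reactions = plans)
}

#' Count instructions by kind
#'
#' Tallies every instruction kind plus a grand total (the count of all
#' atomic robot commands in the plan).
#'
#' @param plan an [InstructionPlan-class].
#' @return named integer vector over all instruction kinds plus `total`.
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 2, seed = 1)
#' countInstructions(compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2")))
#' @export
countInstructions <- function(plan) {
  stopifnot(is(plan, "InstructionPlan"))
  k <- factor(instructions(plan)$kind, levels = instructionKinds)
  counts <- table(k)
  out <- stats::setNames(as.integer(counts), names(counts))
  c(out, total = sum(out))
}
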