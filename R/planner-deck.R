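#' @include AllClasses.R
NULL

## nominal well/tube capacities (uL) by labware type, used by the virtual
## robot's overfill rule
labwareCapacity <- function(type) {
  switch(type,
    "96_well_pcr_plate" = 200,
    "96_well_flat_plate" = 360,
    "tube_rack_2ml" = 2000,
    "temperature_module" = 2000,  # 24-tube aluminum block of 2 mL tubes
    "mix_reservoir" = 15000,
    "6_well_agar_plate" = 16000,
    "tip_rack" = 0,
    "trash" = 1e9,
    200
  )
}

## occupant constructor
occ <- function(type, labware_id) list(type = type, labware_id = labware_id)

#' Allocate deck slots for the Golden Gate cloning workflow
#'
#' On the OT-2 the thermocycler module occupies four of the 11 addressable
#' slots (7, 8, 10, 11) and holds the reaction plate; a temperature module
#' carrying the cold reagent rack takes one more; the remainder goes to
#' tip racks, DNA source plates and agar plates. Without the on-deck
#' thermocycler (benchtop cycling), those four slots are freed, the
#' reaction plate takes an ordinary slot, and thermal stages compile to
#' operator pauses. The Flex deck is modeled as 12 addressable slots and
#' never hosts the thermocycler here (Flex runs cycle on benchtop
#' machines).
#'
#' @param platform `"OT-2"` or `"Flex"`.
#' @param n_assemblies number of assemblies in the run (<= 96).
#' @param use_onboard_thermocycler logical; OT-2 only.
#' @param n_agar_plates 6-well agar plates on deck (plating swaps plates
#'   via operator pauses when more are needed).
#' @param n_tip_racks tip racks on deck; default 2 (tips are refilled via
#'   operator pauses when exhausted).
#' @param source_labware_ids labware ids of the DNA source plates placed
#'   on deck; default toolkit + custom parts plate.
#' @return a [DeckLayout-class].
#' @examples
#' planDeck("OT-2", 19, use_onboard_thermocycler = TRUE, n_agar_plates = 2)
#' @export
planDeck <- function(platform = c("OT-2", "Flex"), n_assemblies,
                     use_onboard_thermocycler = platform == "OT-2",
                     n_agar_plates = 2L, n_tip_racks = 2L,
                     source_labware_ids = c("toolkit_plate",
                                            "custom_plate")) {
  platform <- match.arg(platform)
  if (n_assemblies > 96L)
    capacityError(sprintf(
      "%d assemblies exceed the 96-assembly capacity of one run",
      n_assemblies))
  if (platform == "Flex" && use_onboard_thermocycler)
    layoutError("the on-deck thermocycler is not supported on Flex; use benchtop cycling")

  ids <- deckSlotIds(platform)
  slots <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) slots[[i]] <- "empty"
  modules <- "temperature_module"

  tc_slots <- character()
  if (use_onboard_thermocycler) {
    tc_slots <- c("7", "8", "10", "11")
    for (s in tc_slots) slots[[s]] <- occ("thermocycler", "thermocycler")
    # the reaction plate sits inside the cycler; expose it on slot 7
    slots[["7"]] <- occ("96_well_pcr_plate", "reaction_plate")
    modules <- c(modules, "thermocycler")
  }
  free <- setdiff(ids, tc_slots)

  want <- list(occ("temperature_module", "reagent_rack"))
  if (!use_onboard_thermocycler)
    want <- c(want, list(occ("96_well_pcr_plate", "reaction_plate")))
  for (k in seq_len(n_tip_racks))
    want <- c(want, list(occ("tip_rack", paste0("tip_rack_", k))))
  for (id in source_labware_ids)
    want <- c(want, list(occ("96_well_flat_plate", id)))
  for (k in seq_len(n_agar_plates))
    want <- c(want, list(occ("6_well_agar_plate", paste0("agar_plate_", k))))

  if (length(want) > length(free))
    layoutError(sprintf(
      "deck layout infeasible on %s: %d labware/modules requested but only %d free slots%s (short by %d)",
      platform, length(want), length(free),
      if (length(tc_slots)) sprintf(" (thermocycler occupies %d of %d)",
                                    length(tc_slots), length(ids)) else "",
      length(want) - length(free)))
  for (k in seq_along(want)) slots[[free[k]]] <- want[[k]]

  tip_rows <- which(vapply(slots, function(s)
    !identical(s, "empty") && s$type == "tip_rack", logical(1)))
  tip_racks <- data.frame(
    slot = names(slots)[tip_rows],
    labware_id = vapply(slots[tip_rows], `[[`, character(1), "labware_id"),
    capacity = 96L, stringsAsFactors = FALSE)
  rownames(tip_racks) <- NULL
  new("DeckLayout", platform = platform, slots = slots, modules = modules,
      tip_racks = tip_racks)
}

#' Allocate deck slots for the colony PCR workflow
#'
#' One reagent tube rack (on the temperature module), one colony template
#' plate and one destination PCR plate per 96-pick block, a mix reservoir
#' when the pooled master mix escalates past a 1.5 mL tube, and tip
#' racks. With benchtop thermocyclers declared, up to three destination
#' plates (288 reactions) fit on the OT-2 deck.
#'
#' @param platform `"OT-2"` or `"Flex"`.
#' @param n_picks number of colony PCR reactions.
#' @param use_onboard_thermocycler logical; only honored for a single
#'   destination plate on the OT-2.
#' @param n_tip_racks tip racks; default 2.
#' @param needs_reservoir logical, force a mix reservoir slot.
#' @return a [DeckLayout-class].
#' @export
planPcrDeck <- function(platform = c("OT-2", "Flex"), n_picks,
                        use_onboard_thermocycler = FALSE,
                        n_tip_racks = 2L, needs_reservoir = n_picks > 96L) {
  platform <- match.arg(platform)
  n_plates <- max(1L, ceiling(n_picks / 96))
  ids <- deckSlotIds(platform)
  slots <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) slots[[i]] <- "empty"
  modules <- "temperature_module"

  tc_slots <- character()
  if (use_onboard_thermocycler && platform == "OT-2" && n_plates == 1L) {
    tc_slots <- c("7", "8", "10", "11")
    for (s in tc_slots) slots[[s]] <- occ("thermocycler", "thermocycler")
    # the destination plate sits inside the cycler; expose it on slot 7
    slots[["7"]] <- occ("96_well_pcr_plate", "pcr_plate_1")
    modules <- c(modules, "thermocycler")
  }
  free <- setdiff(ids, tc_slots)

  want <- list(occ("temperature_module", "reagent_rack"))
  if (needs_reservoir)
    want <- c(want, list(occ("mix_reservoir", "mix_reservoir")))
  for (k in seq_len(n_tip_racks))
    want <- c(want, list(occ("tip_rack", paste0("tip_rack_", k))))
  for (k in seq_len(n_plates))
    want <- c(want, list(occ("96_well_flat_plate", paste0("colony_plate_", k))))
  dest_on_deck <- if (length(tc_slots)) n_plates - 1L else n_plates
  for (k in seq_len(dest_on_deck))
    want <- c(want, list(occ("96_well_pcr_plate", paste0("pcr_plate_", k))))

  if (length(want) > length(free))
    capacityError(sprintf(
      "%d colony PCR reactions need %d labware slots but only %d are free on %s (short by %d)",
      n_picks, length(want), length(free), platform,
      length(want) - length(free)))
  for (k in seq_along(want)) slots[[free[k]]] <- want[[k]]

  tip_rows <- which(vapply(slots, function(s)
    !identical(s, "empty") && s$type == "tip_rack", logical(1)))
  tip_racks <- data.frame(
    slot = names(slots)[tip_rows],
    labware_id = vapply(slots[tip_rows], `[[`, character(1), "labware_id"),
    capacity = 96L, stringsAsFactors = FALSE)
  rownames(tip_racks) <- NULL
  new("DeckLayout", platform = platform, slots = slots, modules = modules,
      tip_racks = tip_racks)
}

## labware id -> labware type, from a DeckLayout; thermocycler hosts the
## reaction plate / pcr plate, handled by the compiler's registry
deckLabwareTypes <- function(deck) {
  tys <- character()
  for (s in deck@slots) {
    if (identical(s, "empty")) next
    tys[s$labware_id] <- s$type
  }
  tys
}

#' Compute droplet positions for agar plating
#'
#' Deterministic center + concentric-ring pattern inside one well of a
#' 6-well agar plate: spot 1 at the well center, remaining spots on rings
#' working inward from the well radius minus the edge margin, each ring
#' holding as many equally spaced spots as the minimum spacing allows.
#' Defaults reproduce the validated plating: 13 spots, 4.5 µL droplets
#' (2.5 µL on Flex), dispense height z = 5 mm above the agar.
#'
#' @param n_spots number of droplet positions (>= 1).
#' @param well_radius_mm,edge_margin_mm agar well geometry; defaults
#'   17 mm radius, 3 mm margin.
#' @param droplet_volume_ul droplet volume; default 4.5.
#' @param z_mm dispense height; default 5.
#' @param min_spacing_mm minimum pairwise spot distance; default 6.
#' @return a [PlatingLayout-class] whose positions satisfy all pairwise
#'   spacing and radius constraints.
#' @examples
#' platingLayout()          # 13 positions
#' platingLayout(n_spots = 1)
#' @export
platingLayout <- function(n_spots = 13L, well_radius_mm = 17,
                          edge_margin_mm = 3, droplet_volume_ul = 4.5,
                          z_mm = 5, min_spacing_mm = 6) {
  stopifnot(n_spots >= 1L)
  rmax <- well_radius_mm - edge_margin_mm
  if (rmax <= 0) layoutError("edge margin leaves no usable agar surface")

  # ring radii from the rim inward, one spacing apart; the center is its
  # own "ring" when it stays a spacing away from the innermost ring
  radii <- if (rmax >= min_spacing_mm)
    seq(rmax, min_spacing_mm, by = -min_spacing_mm) else numeric(0)
  cap <- vapply(radii, function(r)
    max(1L, as.integer(floor(pi / asin(min(1, min_spacing_mm / (2 * r)))))),
    integer(1))
  capacity <- 1L + sum(cap)
  if (n_spots > capacity)
    layoutError(sprintf(
      "%d spots cannot be placed with %.1f mm spacing inside a %.1f mm radius (capacity %d)",
      n_spots, min_spacing_mm, rmax, capacity))

  pos <- data.frame(x_mm = 0, y_mm = 0)
  remaining <- n_spots - 1L
  for (j in seq_along(radii)) {
    if (remaining <= 0L) break
    k <- min(cap[j], remaining)
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    pos <- rbind(pos, data.frame(x_mm = radii[j] * cos(ang),
                                 y_mm = radii[j] * sin(ang)))
    remaining <- remaining - k
  }
  # keep spot 1 = center first, rings follow outside-in
  new("PlatingLayout", positions = pos,
      droplet_volume_ul = droplet_volume_ul, z_mm = z_mm,
      well_radius_mm = well_radius_mm, edge_margin_mm = edge_margin_mm,
      min_spacing_mm = min_spacing_mm)
}
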