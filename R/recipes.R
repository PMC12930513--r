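#' @include AllClasses.R
NULL

#' Platform recipe presets
#'
#' `goldenGateRecipe()` returns the Golden Gate reaction constants for a
#' platform. OT-2: 10 µL total, 50 fmol of each plasmid (entry parts and
#' backbone), 0.5 µL BsaI + 0.5 µL T4 ligase, master mix distributed
#' first. Flex: 12 µL total, 25 fmol, 1.2 µL Golden Gate enzyme mix,
#' buffer and water dispensed first, then plasmids, then enzymes. The
#' ligase buffer is dosed to 1x final from a 10x stock by default. Every
#' constant is overridable.
#'
#' @param platform `"OT-2"` or `"Flex"`.
#' @param total_volume,dna_amount_fmol,enzyme_components,buffer_stock_fold,dispense_order
#'   overrides of the platform defaults (see slots of
#'   [GoldenGateRecipe-class]).
#' @param mass_per_bp average double-stranded base-pair mass in
#'   g·mol⁻¹·bp⁻¹ used for molar dosing; default 650.
#' @param fixed_dna_volume set to a µL value to dose every DNA part at a
#'   fixed volume instead of by molarity (for normalized stocks whose
#'   concentrations are not recorded); default `NA` (molar dosing).
#' @return a [GoldenGateRecipe-class].
#' @examples
#' goldenGateRecipe("OT-2")
#' goldenGateRecipe("Flex")
#' @export
goldenGateRecipe <- function(platform = c("OT-2", "Flex"),
                             total_volume = NULL, dna_amount_fmol = NULL,
                             enzyme_components = NULL,
                             buffer_stock_fold = 10,
                             dispense_order = NULL,
                             mass_per_bp = 650,
                             fixed_dna_volume = NA_real_) {
  platform <- match.arg(platform)
  if (platform == "OT-2") {
    total_volume <- total_volume %||% 10
    dna_amount_fmol <- dna_amount_fmol %||% 50
    enzyme_components <- enzyme_components %||% data.frame(
      name = c("BsaI", "T4_ligase"), volume_ul = c(0.5, 0.5),
      stringsAsFactors = FALSE)
    dispense_order <- dispense_order %||% "master_mix_first"
  } else {
    total_volume <- total_volume %||% 12
    dna_amount_fmol <- dna_amount_fmol %||% 25
    enzyme_components <- enzyme_components %||% data.frame(
      name = "GG_enzyme_mix", volume_ul = 1.2, stringsAsFactors = FALSE)
    dispense_order <- dispense_order %||% "buffer_water_first"
  }
  new("GoldenGateRecipe", platform = platform, total_volume = total_volume,
      dna_amount_fmol = dna_amount_fmol,
      enzyme_components = enzyme_components,
      buffer_stock_fold = buffer_stock_fold,
      dispense_order = dispense_order, mass_per_bp = mass_per_bp,
      fixed_dna_volume = fixed_dna_volume)
}

#' @rdname goldenGateRecipe
#' @description `pcrRecipe()` returns the colony PCR constants: OT-2 uses
#'   9 µL master mix + 1 µL colony template (10 µL reactions), Flex 13 µL
#'   + 2 µL (15 µL reactions). The master mix per reaction is 2x PCR mix
#'   at half the total reaction volume, plus primers, plus water.
#' @param master_mix_volume,template_volume µL per reaction (platform
#'   defaults above).
#' @param primer_volume µL of pooled primer pair per reaction; default 1.
#' @export
pcrRecipe <- function(platform = c("OT-2", "Flex"),
                      master_mix_volume = NULL, template_volume = NULL,
                      primer_volume = 1) {
  platform <- match.arg(platform)
  if (platform == "OT-2") {
    master_mix_volume <- master_mix_volume %||% 9
    template_volume <- template_volume %||% 1
  } else {
    master_mix_volume <- master_mix_volume %||% 13
    template_volume <- template_volume %||% 2
  }
  total <- master_mix_volume + template_volume
  comp <- data.frame(
    component = c("twofold_mix", "primers", "water"),
    volume_ul = c(total / 2, primer_volume,
                  master_mix_volume - total / 2 - primer_volume),
    stringsAsFactors = FALSE)
  new("PcrRecipe", platform = platform,
      master_mix_volume = master_mix_volume,
      template_volume = template_volume, composition = comp)
}

#' Load a recipe preset, optionally overridden from a config file
#'
#' Presets: `ot2_goldengate`, `flex_goldengate`, `ot2_colonypcr`,
#' `flex_colonypcr`. A YAML/JSON config may override any constant by name
#' (e.g. `total_volume: 15`, `cycles: 30`).
#'
#' @param preset preset name.
#' @param config optional path to a YAML/JSON override file.
#' @return a [GoldenGateRecipe-class] or [PcrRecipe-class].
#' @export
recipePreset <- function(preset = c("ot2_goldengate", "flex_goldengate",
                                    "ot2_colonypcr", "flex_colonypcr"),
                         config = NULL) {
  preset <- match.arg(preset)
  ov <- list()
  if (!is.null(config)) {
    if (!file.exists(config))
      parseError(sprintf("config file not found: %s", config))
    ov <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    ov <- ov[[preset]] %||% ov
  }
  platform <- if (startsWith(preset, "ot2")) "OT-2" else "Flex"
  if (grepl("goldengate", preset)) {
    ec <- if (!is.null(ov$enzyme_components))
      as.data.frame(ov$enzyme_components, stringsAsFactors = FALSE) else NULL
    goldenGateRecipe(platform,
                     total_volume = ov$total_volume,
                     dna_amount_fmol = ov$dna_amount_fmol,
                     enzyme_components = ec,
                     buffer_stock_fold = ov$buffer_stock_fold %||% 10,
                     dispense_order = ov$dispense_order,
                     mass_per_bp = ov$mass_per_bp %||% 650,
                     fixed_dna_volume = ov$fixed_dna_volume %||% NA_real_)
  } else {
    pcrRecipe(platform,
              master_mix_volume = ov$master_mix_volume,
              template_volume = ov$template_volume,
              primer_volume = ov$primer_volume %||% 1)
  }
}

#' Volume of a DNA stock delivering a molar amount
#'
#' Converts a target molar amount of double-stranded DNA into a pipetting
#' volume: `volume_ul = amount_fmol * length_bp * mass_per_bp * 1e-6 /
#' concentration`, with `mass_per_bp` the average base-pair mass
#' (650 g·mol⁻¹·bp⁻¹ by convention). E.g. 50 fmol of a 2000 bp plasmid is
#' 65 ng; at 65 ng/µL that is 1.0 µL.
#'
#' @param amount_fmol target amount, fmol (>= 0).
#' @param concentration stock concentration, ng/µL (> 0).
#' @param length_bp construct length, bp (>= 1).
#' @param mass_per_bp g·mol⁻¹·bp⁻¹; default 650.
#' @return volume in µL.
#' @examples
#' dnaVolumeForAmount(50, 65, 2000)    # 1.0
#' dnaVolumeForAmount(25, 48.75, 3000) # 1.0
#' @export
dnaVolumeForAmount <- function(amount_fmol, concentration, length_bp,
                               mass_per_bp = 650) {
  if (any(is.na(concentration)) || any(concentration == 0))
    stop("cannot dose by amount; supply fixed volume ",
         "(stock concentration is missing or zero)")
  stopifnot(all(concentration > 0), all(length_bp >= 1),
            all(amount_fmol >= 0))
  amount_fmol * length_bp * mass_per_bp * 1e-6 / concentration
}

#' Build the per-well reaction plan for one Golden Gate assembly
#'
#' Doses the ligase buffer at total/`buffer_stock_fold`, the enzymes at
#' their fixed recipe volumes, and every plasmid (backbone first, then the
#' ordered parts) at the recipe's molar amount via [dnaVolumeForAmount()]
#' (or at the recipe's fixed volume in fixed-volume mode); water absorbs
#' the remainder so the plan closes exactly on the recipe total. If the
#' fixed components plus DNA exceed the total volume the stocks are too
#' dilute and an over-volume error lists every per-part dose.
#'
#' @param design a validated [AssemblyDesign-class].
#' @param recipe a [GoldenGateRecipe-class].
#' @param sources list of [PlateMap-class] objects.
#' @return a [ReactionPlan-class].
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' d <- AssemblyDesign("tu", "backbone_1", c("2_1", "3_1", "4_1"), "A1")
#' buildGgReaction(d, goldenGateRecipe("OT-2"), list(tk))
#' @export
buildGgReaction <- function(design, recipe, sources) {
  stopifnot(is(design, "AssemblyDesign"), is(recipe, "GoldenGateRecipe"))
  buffer <- recipe@total_volume / recipe@buffer_stock_fold
  comp <- data.frame(
    source_labware = "reagent_rack",
    source_well = NA_character_,
    component = c("ligase_buffer", recipe@enzyme_components$name),
    volume_ul = c(buffer, recipe@enzyme_components$volume_ul),
    stringsAsFactors = FALSE)

  plasmids <- c(design@backbone, design@parts)
  dna <- lapply(plasmids, function(p) {
    h <- resolvePart(p, sources)
    if (is.character(h)) grammarError(h)
    vol <- if (!is.na(recipe@fixed_dna_volume)) recipe@fixed_dna_volume
    else dnaVolumeForAmount(recipe@dna_amount_fmol,
                            h$record$concentration_ng_per_ul,
                            h$record$length_bp, recipe@mass_per_bp)
    data.frame(source_labware = h$labware, source_well = h$well,
               component = p, volume_ul = vol, stringsAsFactors = FALSE)
  })
  dna <- do.call(rbind, dna)
  comp <- rbind(comp, dna)

  water <- recipe@total_volume - sum(comp$volume_ul)
  if (water < -1e-9) {
    detail <- paste(sprintf("%s %.3f uL", dna$component, dna$volume_ul),
                    collapse = ", ")
    stop(mcpError("mcp_overvolume_error", sprintf(
      "over-volume: fixed components + DNA (%.3f uL) exceed the %.1f uL reaction; per-part doses: %s (dilute stocks?)",
      sum(comp$volume_ul), recipe@total_volume, detail)))
  }
  new("ReactionPlan", destination_well = design@destination_well,
      components = comp, water_topup = max(water, 0),
      total_volume = recipe@total_volume)
}

#' Scale shared components into a master mix
#'
#' Each component total is per-reaction volume x `n` x `overage`, reported
#' at 0.1 µL resolution (round half up). The pooled volume picks the
#' smallest sufficient container (1.5 mL tube, 15 mL tube, or reservoir);
#' exceeding 90% of a 1.5 mL tube's nominal volume escalates with a
#' warning recorded on the spec.
#'
#' @param per_reaction data.frame (`component`, `volume_ul`) per reaction,
#'   or a single named numeric vector.
#' @param n number of reactions (>= 1).
#' @param overage overage factor (>= 1); default 1.1.
#' @return a [MasterMixSpec-class].
#' @examples
#' buildMasterMix(data.frame(component = "pcr_mix", volume_ul = 9),
#'                n = 19)  # 188.1 uL
#' @export
buildMasterMix <- function(per_reaction, n, overage = 1.1) {
  if (is.numeric(per_reaction))
    per_reaction <- data.frame(component = names(per_reaction),
                               volume_ul = unname(per_reaction),
                               stringsAsFactors = FALSE)
  stopifnot(n >= 1, overage >= 1)
  totals <- data.frame(
    component = per_reaction$component,
    volume_ul = roundHalfUp(per_reaction$volume_ul * n * overage, 1L),
    stringsAsFactors = FALSE)
  pooled <- sum(totals$volume_ul)
  safe_15 <- 1500 * 0.9
  safe_15ml <- 15000 * 0.9
  container <- if (pooled <= safe_15) "1.5 mL tube"
  else if (pooled <= safe_15ml) "15 mL tube" else "reservoir"
  warning_msg <- if (pooled > safe_15)
    sprintf("pooled master mix (%.1f uL) exceeds a 1.5 mL tube's safe fill (%.0f uL); use a %s",
            pooled, safe_15, container) else ""
  new("MasterMixSpec", n_reactions = as.integer(n),
      overage_factor = overage, per_reaction = per_reaction,
      component_totals = totals, container = container,
      container_warning = warning_msg)
}

#' Golden Gate thermal profile
#'
#' Default program: one block of 37 °C for 120 s then 16 °C for 300 s,
#' cycled 25 times (digestion/ligation), followed by a single 60 °C hold
#' for 300 s to denature the enzymes. Cycle count, temperatures and holds
#' are overridable for other Type IIS enzymes.
#'
#' @param recipe a [GoldenGateRecipe-class] (reserved for
#'   platform-specific overrides; the default profile is shared).
#' @param cycles digestion/ligation cycle count; default 25.
#' @param digest_c,digest_s,ligate_c,ligate_s,final_c,final_s temperatures
#'   (°C) and holds (s) of the cycled and final steps.
#' @param lid_temperature_c thermocycler lid temperature; default 105.
#' @return a [ThermalProfile-class]; total duration of the default is
#'   25 x (120 + 300) + 300 = 10800 s.
#' @examples
#' totalDuration(ggThermalProfile())  # 10800
#' @export
ggThermalProfile <- function(recipe = goldenGateRecipe("OT-2"), cycles = 25,
                             digest_c = 37, digest_s = 120,
                             ligate_c = 16, ligate_s = 300,
                             final_c = 60, final_s = 300,
                             lid_temperature_c = 105) {
  steps <- data.frame(
    block = c(1L, 1L, 2L),
    temperature_c = c(digest_c, ligate_c, final_c),
    hold_s = c(digest_s, ligate_s, final_s),
    repeat_n = c(cycles, cycles, 1L))
  new("ThermalProfile", steps = steps,
      lid_temperature_c = lid_temperature_c)
}

#' Heat-shock profile for on-deck E. coli transformation
#'
#' Config-only defaults (the on-deck thermocycler performs the heat
#' shock): 4 °C hold, 42 °C shock for 30 s, 4 °C recovery hold.
#'
#' @param shock_c,shock_s shock temperature (°C) and duration (s).
#' @param hold_c,pre_s,post_s cold-hold temperature and pre/post hold
#'   durations (s).
#' @return a [ThermalProfile-class].
#' @export
heatShockProfile <- function(shock_c = 42, shock_s = 30, hold_c = 4,
                             pre_s = 300, post_s = 120) {
  steps <- data.frame(
    block = c(1L, 2L, 3L),
    temperature_c = c(hold_c, shock_c, hold_c),
    hold_s = c(pre_s, shock_s, post_s),
    repeat_n = c(1L, 1L, 1L))
  new("ThermalProfile", steps = steps, lid_temperature_c = 40)
}

#' Build the two-component plan for one colony PCR reaction
#'
#' Exactly two components: the pooled master mix (from the mix tube) then
#' the colony template (from the template plate). A template volume of 0
#' denotes a negative-control reaction containing only master mix.
#'
#' @param pick one-row entry of a [ColonyPickSheet-class] (data.frame with
#'   `template_well` and `destination_well`).
#' @param recipe a [PcrRecipe-class].
#' @param template_labware labware id of the colony template plate.
#' @param template_volume override of the recipe template volume (use 0
#'   for a negative control).
#' @return a [ReactionPlan-class] totalling mix + template.
#' @examples
#' pick <- data.frame(construct_name = "tu1", template_well = "A1",
#'                    primer_pair = "scr1", destination_well = "A1")
#' buildPcrReaction(pick, pcrRecipe("OT-2"))  # 9 + 1 = 10 uL
#' @export
buildPcrReaction <- function(pick, recipe,
                             template_labware = "colony_plate_1",
                             template_volume = NULL) {
  stopifnot(is(recipe, "PcrRecipe"))
  tv <- template_volume %||% recipe@template_volume
  comp <- data.frame(
    source_labware = "mix_tube", source_well = NA_character_,
    component = "pcr_master_mix", volume_ul = recipe@master_mix_volume,
    stringsAsFactors = FALSE)
  if (tv > 0)
    comp <- rbind(comp, data.frame(
      source_labware = template_labware, source_well = pick$template_well,
      component = paste0("template_", pick$construct_name),
      volume_ul = tv, stringsAsFactors = FALSE))
  new("ReactionPlan", destination_well = pick$destination_well,
      components = comp, water_topup = 0,
      total_volume = recipe@master_mix_volume + tv)
}
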