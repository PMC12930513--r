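#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("wells", "PlateMap", function(x) x@wells)

#' @rdname accessors
#' @export
setMethod("labwareId", "PlateMap", function(x) x@labware_id)

#' @rdname accessors
#' @export
setMethod("plateFormat", "PlateMap", function(x) x@plate_format)

#' @rdname accessors
#' @export
setMethod("instructions", "InstructionPlan", function(x) x@instructions)

#' @rdname accessors
#' @export
setMethod("deck", "InstructionPlan", function(x) x@deck)

#' @rdname accessors
#' @export
setMethod("stages", "InstructionPlan", function(x) x@stages)

#' @rdname accessors
#' @export
setMethod("initialContents", "InstructionPlan", function(x) x@initial_contents)

#' @rdname accessors
#' @export
setMethod("reactionPlans", "InstructionPlan", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("violations", "SimReport", function(x) x@violations)

#' @rdname accessors
#' @export
setMethod("finalWells", "SimReport", function(x) x@final_wells)

#' @rdname accessors
#' @export
setMethod("tipsConsumed", "SimReport", function(x) x@tips_consumed)

#' @rdname accessors
#' @export
setMethod("componentTable", "ReactionPlan", function(x) x@components)

#' @rdname accessors
#' @export
setMethod("waterTopup", "ReactionPlan", function(x) x@water_topup)

#' @rdname accessors
#' @export
setMethod("totalDuration", "ThermalProfile", function(x) {
  s <- x@steps
  sum(vapply(split(s, s$block), function(b) b$repeat_n[1L] * sum(b$hold_s),
             numeric(1)))
})

#' @rdname accessors
#' @export
setMethod("passed", "ValidationReport", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("findings", "ValidationReport", function(x) x@findings)

## ---- show methods ----------------------------------------------------------

setMethod("show", "PlateMap", function(object) {
  cat(sprintf("PlateMap '%s' (%s): %d occupied well%s\n",
              object@labware_id, object@plate_format, nrow(object@wells),
              if (nrow(object@wells) == 1L) "" else "s"))
  if (nrow(object@wells)) {
    print(utils::head(object@wells, 6L), row.names = FALSE)
    if (nrow(object@wells) > 6L)
      cat(sprintf("... and %d more\n", nrow(object@wells) - 6L))
  }
})

setMethod("show", "AssemblyDesign", function(object) {
  cat(sprintf("AssemblyDesign '%s': backbone %s + [%s] -> %s\n",
              object@construct_name, object@backbone,
              paste(object@parts, collapse = ", "),
              object@destination_well))
})

setMethod("show", "ColonyPickSheet", function(object) {
  cat(sprintf("ColonyPickSheet: %d pick%s across %d destination plate%s\n",
              nrow(object@entries),
              if (nrow(object@entries) == 1L) "" else "s",
              max(1L, ceiling(nrow(object@entries) / 96)),
              if (nrow(object@entries) <= 96L) "" else "s"))
})

setMethod("show", "ToolkitSchema", function(object) {
  cat(sprintf("ToolkitSchema '%s': slots [%s]; backbones [%s]; dropout %s\n",
              object@toolkit_name,
              paste(object@slot_order, collapse = ", "),
              paste(object@backbone_types, collapse = ", "),
              object@dropout_marker))
  for (p in names(object@equivalence_groups))
    cat(sprintf("  %s <=> %s\n",
                paste(object@equivalence_groups[[p]], collapse = "+"), p))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport '%s': %s\n", object@design_name,
              if (object@status) "pass" else "FAIL"))
  if (nrow(object@findings))
    for (i in seq_len(nrow(object@findings)))
      cat(sprintf("  [%s] %s\n", object@findings$severity[i],
                  object@findings$message[i]))
})

setMethod("show", "GoldenGateRecipe", function(object) {
  cat(sprintf(
    "GoldenGateRecipe (%s): %.1f uL total, %.0f fmol/part, %s; %s\n",
    object@platform, object@total_volume, object@dna_amount_fmol,
    paste(sprintf("%s %.1f uL", object@enzyme_components$name,
                  object@enzyme_components$volume_ul), collapse = " + "),
    object@dispense_order))
})

setMethod("show", "PcrRecipe", function(object) {
  cat(sprintf("PcrRecipe (%s): %.0f uL master mix + %.0f uL template = %.0f uL\n",
              object@platform, object@master_mix_volume,
              object@template_volume,
              object@master_mix_volume + object@template_volume))
})

setMethod("show", "ReactionPlan", function(object) {
  cat(sprintf("ReactionPlan -> %s: %d components + %.2f uL water = %.2f uL\n",
              object@destination_well, nrow(object@components),
              object@water_topup, object@total_volume))
})

setMethod("show", "ThermalProfile", function(object) {
  s <- object@steps
  for (b in unique(s$block)) {
    rows <- s[s$block == b, ]
    cat(sprintf("  [%s] x%d\n",
                paste(sprintf("%g C / %g s", rows$temperature_c, rows$hold_s),
                      collapse = ", "),
                rows$repeat_n[1L]))
  }
  cat(sprintf("  lid %g C; total %g s\n", object@lid_temperature_c,
              totalDuration(object)))
})

setMethod("show", "MasterMixSpec", function(object) {
  cat(sprintf("MasterMixSpec: %d rxn x %.2f overage -> %.1f uL (%s)\n",
              object@n_reactions, object@overage_factor,
              sum(object@component_totals$volume_ul), object@container))
  if (nzchar(object@container_warning))
    cat("  warning:", object@container_warning, "\n")
})

setMethod("show", "DeckLayout", function(object) {
  cat(sprintf("DeckLayout (%s): modules [%s]\n", object@platform,
              paste(object@modules, collapse = ", ")))
  for (id in names(object@slots)) {
    occ <- object@slots[[id]]
    if (identical(occ, "empty")) cat(sprintf("  slot %s: empty\n", id))
    else cat(sprintf("  slot %s: %s (%s)\n", id, occ$labware_id, occ$type))
  }
})

setMethod("show", "PlatingLayout", function(object) {
  cat(sprintf(
    "PlatingLayout: %d spots, %.1f uL droplets, z = %.1f mm, r = %.0f mm\n",
    nrow(object@positions), object@droplet_volume_ul, object@z_mm,
    object@well_radius_mm))
})

setMethod("show", "InstructionPlan", function(object) {
  cat(sprintf("InstructionPlan (%s): %d instructions in %d stages\n",
              object@deck@platform, nrow(object@instructions),
              nrow(object@stages)))
  if (nrow(object@stages))
    for (i in seq_len(nrow(object@stages)))
      cat(sprintf("  %-16s %d..%d\n", object@stages$stage[i],
                  object@stages$start[i], object@stages$end[i]))
})

setMethod("show", "SimReport", function(object) {
  cat(sprintf("SimReport: %d violation%s; %d tips consumed; %d wells tracked\n",
              nrow(object@violations),
              if (nrow(object@violations) == 1L) "" else "s",
              object@tips_consumed,
              length(unique(paste(object@final_wells$labware,
                                  object@final_wells$well)))))
  if (nrow(object@violations))
    print(utils::head(object@violations, 10L), row.names = FALSE)
})
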