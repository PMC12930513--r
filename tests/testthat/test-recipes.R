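# independent hand oracle for the fmol -> uL conversion
oracleDnaVolume <- function(amount, conc, len, mbp = 650) {
  grams_per_mol <- len * mbp
  nanograms <- amount * 1e-15 * grams_per_mol * 1e9
  nanograms / conc
}

test_that("molar dosing matches the mass-arithmetic oracle", {
  expect_equal(dnaVolumeForAmount(50, 65, 2000), 1.0)
  expect_equal(dnaVolumeForAmount(25, 48.75, 3000), 1.0)
  expect_equal(dnaVolumeForAmount(0, 123, 4567), 0)

  set.seed(101)
  amount <- runif(200, 1, 100)
  conc <- runif(200, 10, 500)
  len <- sample.int(9000, 200) + 999
  expect_equal(dnaVolumeForAmount(amount, conc, len),
               oracleDnaVolume(amount, conc, len), tolerance = 1e-12)
})

test_that("molar dosing is linear in amount and length, inverse in concentration", {
  v0 <- dnaVolumeForAmount(10, 80, 2500)
  expect_equal(dnaVolumeForAmount(30, 80, 2500), 3 * v0)
  expect_equal(dnaVolumeForAmount(10, 80, 7500), 3 * v0)
  expect_equal(dnaVolumeForAmount(10, 240, 2500), v0 / 3)
  expect_error(dnaVolumeForAmount(10, 0, 2500), "fixed volume")
})

test_that("platform presets carry the published reaction constants", {
  ot2 <- goldenGateRecipe("OT-2")
  expect_equal(ot2@total_volume, 10)
  expect_equal(ot2@dna_amount_fmol, 50)
  expect_equal(ot2@enzyme_components$volume_ul, c(0.5, 0.5))
  expect_equal(ot2@dispense_order, "master_mix_first")

  flex <- goldenGateRecipe("Flex")
  expect_equal(flex@total_volume, 12)
  expect_equal(flex@dna_amount_fmol, 25)
  expect_equal(flex@enzyme_components$volume_ul, 1.2)
  expect_equal(flex@dispense_order, "buffer_water_first")

  expect_equal(pcrRecipe("OT-2")@master_mix_volume, 9)
  expect_equal(pcrRecipe("OT-2")@template_volume, 1)
  expect_equal(pcrRecipe("Flex")@master_mix_volume, 13)
  expect_equal(pcrRecipe("Flex")@template_volume, 2)
  # 2x mix is half the total reaction volume
  comp <- pcrRecipe("Flex")@composition
  expect_equal(comp$volume_ul[comp$component == "twofold_mix"], 15 / 2)
})

test_that("OT-2 reaction plan: unit doses close to 10 uL with 4 uL water", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  plan <- buildGgReaction(d, goldenGateRecipe("OT-2"), list(plate))
  comp <- componentTable(plan)
  expect_equal(comp$volume_ul[comp$component == "ligase_buffer"], 1.0)
  expect_equal(comp$volume_ul[comp$component == "BsaI"], 0.5)
  expect_equal(comp$volume_ul[comp$component == "T4_ligase"], 0.5)
  dna <- comp[!comp$component %in% c("ligase_buffer", "BsaI", "T4_ligase"), ]
  expect_equal(nrow(dna), 4L)
  expect_equal(dna$volume_ul, rep(1.0, 4L))
  expect_equal(waterTopup(plan), 4.0)
  expect_equal(sum(comp$volume_ul) + waterTopup(plan), 10)
})

test_that("Flex reaction plan: 0.5 uL doses of 7 plasmids leave 6.1 uL water", {
  plate <- unitDosePlate(c("backbone", "2", "3a", "3b", "4a", "4b", "x"),
                         amount = 25, dose_ul = 0.5)
  w <- wells(plate)
  d <- AssemblyDesign("six", w$part_name[1L], w$part_name[2:7], "A1")
  plan <- buildGgReaction(d, goldenGateRecipe("Flex"), list(plate))
  comp <- componentTable(plan)
  expect_equal(comp$volume_ul[comp$component == "ligase_buffer"], 1.2)
  expect_equal(comp$volume_ul[comp$component == "GG_enzyme_mix"], 1.2)
  dna <- comp[comp$source_labware != "reagent_rack", ]
  expect_equal(sum(dna$volume_ul), 3.5)
  expect_equal(waterTopup(plan), 6.1)
})

test_that("dilute stocks trigger an over-volume error listing doses", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50,
                         dose_ul = 9)
  w <- wells(plate)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  err <- tryCatch(buildGgReaction(d, goldenGateRecipe("OT-2"), list(plate)),
                  error = identity)
  expect_s3_class(err, "mcp_overvolume_error")
  expect_match(conditionMessage(err), "over-volume")
  expect_match(conditionMessage(err), "9.000")
})

test_that("fixed-volume mode doses every part at the configured volume", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50,
                         dose_ul = 3)  # concentrations irrelevant below
  w <- wells(plate)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  rec <- goldenGateRecipe("OT-2", fixed_dna_volume = 1)
  plan <- buildGgReaction(d, rec, list(plate))
  dna <- componentTable(plan)[componentTable(plan)$source_labware !=
                              "reagent_rack", ]
  expect_equal(dna$volume_ul, rep(1, 4L))
  expect_equal(waterTopup(plan), 4)
})

test_that("reaction plans always close on the recipe total (volume closure)", {
  for (seed in 1:20) {
    tk <- makeToolkitPlate(fixtureSpec(seed))
    ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 4, seed = seed)
    for (platform in c("OT-2", "Flex")) {
      rec <- goldenGateRecipe(platform)
      for (d in ds) {
        plan <- buildGgReaction(d, rec, list(tk))
        expect_equal(sum(componentTable(plan)$volume_ul) + waterTopup(plan),
                     rec@total_volume, tolerance = 1e-9)
      }
    }
  }
})

# mirror of the documented reporting rule, kept independent of the package
roundHalfUpForTest <- function(x) floor(x * 10 + 0.5) / 10

test_that("master mix scales with count and overage at 0.1 uL resolution", {
  mm <- buildMasterMix(c(pcr_mix = 9), n = 19, overage = 1.1)
  expect_equal(mm@component_totals$volume_ul, 188.1)
  expect_equal(mm@container, "1.5 mL tube")
  expect_equal(mm@container_warning, "")

  ident <- buildMasterMix(c(x = 7.3), n = 1, overage = 1.0)
  expect_equal(ident@component_totals$volume_ul, 7.3)

  big <- buildMasterMix(c(pcr_mix = 13), n = 96, overage = 1.1)
  expect_equal(big@component_totals$volume_ul, 1372.8)
  expect_match(big@container_warning, "1.5 mL tube")
  expect_false(big@container == "1.5 mL tube")

  # exact scaling at overage 1.0
  set.seed(7)
  per <- runif(5, 0.5, 12)
  for (n in c(1L, 8L, 96L)) {
    mm <- buildMasterMix(stats::setNames(per, paste0("c", 1:5)), n, 1.0)
    expect_equal(mm@component_totals$volume_ul,
                 roundHalfUpForTest(per * n))
  }
})

test_that("Golden Gate thermal profile cycles 37/16 then denatures at 60", {
  prof <- ggThermalProfile()
  s <- prof@steps
  cyc <- s[s$block == 1L, ]
  expect_equal(nrow(cyc), 2L)
  expect_equal(cyc$temperature_c, c(37, 16))
  expect_equal(cyc$hold_s, c(120, 300))
  expect_equal(unique(cyc$repeat_n), 25)
  fin <- s[s$block == 2L, ]
  expect_equal(fin$temperature_c, 60)
  expect_equal(fin$hold_s, 300)
  expect_equal(totalDuration(prof), 10800)

  short <- ggThermalProfile(cycles = 5)
  expect_equal(unique(short@steps$repeat_n[short@steps$block == 1L]), 5)
  expect_equal(totalDuration(short), 5 * 420 + 300)
})

test_that("colony PCR reactions are exactly master mix plus template", {
  pick <- data.frame(construct_name = "tu1", template_well = "A1",
                     primer_pair = "scr", destination_well = "B2")
  ot2 <- buildPcrReaction(pick, pcrRecipe("OT-2"))
  expect_equal(nrow(componentTable(ot2)), 2L)
  expect_equal(componentTable(ot2)$volume_ul, c(9, 1))
  expect_equal(ot2@total_volume, 10)

  flex <- buildPcrReaction(pick, pcrRecipe("Flex"))
  expect_equal(componentTable(flex)$volume_ul, c(13, 2))
  expect_equal(flex@total_volume, 15)

  neg <- buildPcrReaction(pick, pcrRecipe("OT-2"), template_volume = 0)
  expect_equal(nrow(componentTable(neg)), 1L)
  expect_equal(neg@total_volume, 9)
})
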