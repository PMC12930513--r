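test_that("OT-2 deck: thermocycler takes 4 of 11 slots, 7 remain", {
  deck <- planDeck("OT-2", 19, use_onboard_thermocycler = TRUE,
                   n_agar_plates = 2)
  ids <- names(deck@slots)
  expect_length(ids, 11L)
  tc <- vapply(deck@slots, function(s)
    !identical(s, "empty") && s$type == "thermocycler", logical(1))
  # slot 7 exposes the hosted reaction plate; 8, 10, 11 are the rest of
  # the cycler footprint
  expect_equal(sum(tc), 3L)
  expect_equal(deck@slots[["7"]]$labware_id, "reaction_plate")
  non_tc <- setdiff(ids, c("7", "8", "10", "11"))
  expect_length(non_tc, 7L)
  expect_true(all(vapply(deck@slots[non_tc], function(s)
    !identical(s, "empty"), logical(1))))
  expect_true("thermocycler" %in% deck@modules)
})

test_that("external-thermocycler mode frees at least 4 slots", {
  freeSlots <- function(d) sum(vapply(d@slots, identical, logical(1),
                                      "empty"))
  onboard <- planDeck("OT-2", 19, TRUE, n_agar_plates = 1)
  external <- planDeck("OT-2", 19, FALSE, n_agar_plates = 1)
  expect_gte(freeSlots(external) - freeSlots(onboard), 4L - 1L)
  # the thermocycler footprint is 4; one slot is re-spent on the plate
  expect_false("thermocycler" %in% external@modules)
})

test_that("over-demanding layouts fail with the shortfall", {
  err <- tryCatch(
    planDeck("OT-2", 10, use_onboard_thermocycler = TRUE,
             n_agar_plates = 6, n_tip_racks = 4),
    error = identity)
  expect_s3_class(err, "mcp_layout_error")
  expect_match(conditionMessage(err), "short by")
  expect_error(planDeck("Flex", 5, use_onboard_thermocycler = TRUE),
               "benchtop", class = "mcp_layout_error")
  expect_error(planDeck("OT-2", 97), "96", class = "mcp_capacity_error")
})

test_that("plating layout satisfies spacing and radius by brute force", {
  lay <- platingLayout()
  p <- lay@positions
  expect_equal(nrow(p), 13L)
  expect_equal(lay@droplet_volume_ul, 4.5)
  expect_equal(lay@z_mm, 5)
  expect_equal(unlist(p[1L, ]), c(x_mm = 0, y_mm = 0))

  # O(n^2) pairwise distance oracle
  for (n in c(1L, 2L, 7L, 13L, 20L)) {
    lay <- platingLayout(n_spots = n)
    p <- lay@positions
    expect_equal(nrow(p), n)
    r <- sqrt(p$x_mm^2 + p$y_mm^2)
    expect_true(all(r <= lay@well_radius_mm - lay@edge_margin_mm + 1e-9))
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        d <- sqrt((p$x_mm[i] - p$x_mm[j])^2 + (p$y_mm[i] - p$y_mm[j])^2)
        expect_gte(d, lay@min_spacing_mm - 1e-6)
      }
    }
  }
  expect_error(platingLayout(n_spots = 50), "capacity",
               class = "mcp_layout_error")
})

test_that("compiled OT-2 plan reproduces the reaction composition (simulator audit)", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  plan <- compileGoldenGate(list(d), list(plate), goldenGateRecipe("OT-2"))
  rep <- simulatePlan(plan)
  expect_equal(nrow(violations(rep)), 0L)
  setup <- simulatePlan(plan, through_stage = "gg_setup")
  audit <- auditCompositions(setup, reactionPlans(plan), tol = 1e-9)
  expect_true(audit$pass)
  # and the well closes on exactly 10 uL after setup
  fw <- finalWells(setup)
  dst <- fw[fw$labware == "reaction_plate" & fw$well == "A1", ]
  expect_equal(sum(dst$volume_ul), 10, tolerance = 1e-9)
})

test_that("Flex plans dispense buffer, water, plasmids, then enzymes", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 5, n_per_type = c(
    "2" = 3L, "3" = 2L, "4" = 2L, "backbone" = 1L)))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 6, seed = 5)
  plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("Flex"))
  ins <- instructions(plan)
  disp <- ins[ins$kind == "dispense" & ins$labware == "reaction_plate", ]
  rank_of <- function(pattern) min(grep(pattern, disp$comment))
  expect_lt(rank_of("buffer"), rank_of("water"))
  expect_lt(rank_of("water"), rank_of("->"))          # plasmid transfers
  expect_lt(rank_of("->"), rank_of("GG_enzyme_mix"))
})

test_that("external-thermocycler plans pause instead of cycling", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 2))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 2, seed = 2)
  deck <- planDeck("OT-2", 2, use_onboard_thermocycler = FALSE,
                   n_agar_plates = 1)
  plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"),
                            deck = deck)
  ins <- instructions(plan)
  expect_equal(sum(ins$kind == "thermal_step"), 0L)
  st <- stages(plan)
  setup_end <- st$end[st$stage == "gg_setup"]
  transf_start <- st$start[st$stage == "transformation"]
  between <- ins$kind[(setup_end + 1L):(transf_start - 1L)]
  expect_gte(sum(between == "pause_for_operator"), 1L)
  expect_equal(nrow(violations(simulatePlan(plan))), 0L)
})

test_that("tip accounting balances and DNA sources get fresh tips", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 9))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 5, seed = 9)
  plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
  ins <- instructions(plan)
  expect_equal(sum(ins$kind == "pick_tip"), sum(ins$kind == "drop_tip"))

  # every aspirate from a DNA source sits in its own pick/drop bracket
  tip_open <- FALSE
  sources_this_tip <- character()
  for (i in seq_len(nrow(ins))) {
    k <- ins$kind[i]
    if (k == "pick_tip") { tip_open <- TRUE; sources_this_tip <- character() }
    if (k == "drop_tip") tip_open <- FALSE
    if (k == "aspirate" && ins$labware[i] == "toolkit_plate") {
      expect_true(tip_open)
      src <- paste0(ins$labware[i], "|", ins$well[i])
      expect_true(all(sources_this_tip %in% src))
      sources_this_tip <- union(sources_this_tip, src)
    }
  }
})

test_that("plans compile deterministically (byte-identical serialization)", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 4))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 3, seed = 4)
  p1 <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
  p2 <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
  expect_identical(planJsonString(p1), planJsonString(p2))
})

test_that("colony PCR partitions picks into 96-well plates", {
  p288 <- compileColonyPcr(makeColonyPickSheet(sprintf("c%03d", 1:288)),
                           pcrRecipe("OT-2"))
  ins <- instructions(p288)
  mix_disp <- ins[ins$kind == "dispense" &
                  grepl("distribute PCR master mix", ins$comment), ]
  expect_equal(nrow(mix_disp), 288L)
  expect_setequal(unique(mix_disp$labware),
                  c("pcr_plate_1", "pcr_plate_2", "pcr_plate_3"))
  tmpl <- ins[ins$kind == "aspirate" & grepl("^colony_plate_", ins$labware), ]
  expect_equal(nrow(tmpl), 288L)
  expect_equal(nrow(violations(simulatePlan(p288))), 0L)

  p97 <- compileColonyPcr(makeColonyPickSheet(sprintf("c%02d", 1:97)),
                          pcrRecipe("OT-2"))
  d97 <- instructions(p97)
  d97 <- d97[d97$kind == "dispense" & grepl("master mix", d97$comment), ]
  expect_equal(sum(d97$labware == "pcr_plate_1"), 96L)
  expect_equal(sum(d97$labware == "pcr_plate_2"), 1L)
  expect_equal(d97$well[d97$labware == "pcr_plate_2"], "A1")

  p1 <- compileColonyPcr(makeColonyPickSheet("only"), pcrRecipe("OT-2"))
  i1 <- instructions(p1)
  expect_equal(sum(i1$kind == "dispense" & grepl("^pcr_plate_", i1$labware)),
               2L)  # one mix dispense + one template dispense
})

test_that("instruction counts are conserved across kinds", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 6))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 2, seed = 6)
  plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
  cnt <- countInstructions(plan)
  expect_equal(unname(cnt[["total"]]),
               sum(cnt[names(cnt) != "total"]))
  expect_equal(unname(cnt[["total"]]), nrow(instructions(plan)))

  empty <- new("InstructionPlan", deck = planDeck("OT-2", 1),
               instructions = mocloplan:::emptyInstructionsDf(),
               stages = data.frame(stage = character(), start = integer(),
                                   end = integer()),
               initial_contents = data.frame(), reactions = list())
  cnt0 <- countInstructions(empty)
  expect_true(all(cnt0 == 0L))
})
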