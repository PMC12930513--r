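# hand-built miniature plans exercise each simulator rule in isolation
miniDeck <- function() planDeck("OT-2", 1, use_onboard_thermocycler = FALSE,
                                n_agar_plates = 1)

miniPlan <- function(rows, stage = "gg_setup") {
  if (!length(rows)) {
    ins <- mocloplan:::emptyInstructionsDf()
    return(new("InstructionPlan", deck = miniDeck(), instructions = ins,
               stages = data.frame(stage = character(), start = integer(),
                                   end = integer()),
               initial_contents = data.frame(
                 labware = character(), well = character(),
                 component = character(), volume_ul = numeric()),
               reactions = list()))
  }
  ins <- do.call(rbind, lapply(rows, function(r) {
    base <- list(kind = r$kind, pipette = r$pipette %||% "p20_single_gen2",
                 labware = r$labware %||% NA_character_,
                 well = r$well %||% NA_character_,
                 volume_ul = r$volume %||% NA_real_,
                 x_mm = NA_real_, y_mm = NA_real_, z_mm = NA_real_,
                 comment = "")
    as.data.frame(base, stringsAsFactors = FALSE)
  }))
  stages <- if (length(rows))
    data.frame(stage = stage, start = 1L, end = length(rows))
  else data.frame(stage = character(), start = integer(), end = integer())
  new("InstructionPlan", deck = miniDeck(), instructions = ins,
      stages = stages, initial_contents = data.frame(
        labware = character(), well = character(), component = character(),
        volume_ul = numeric()), reactions = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

init1 <- data.frame(labware = "toolkit_plate", well = "A1",
                    component = "partX", volume_ul = 10,
                    stringsAsFactors = FALSE)

test_that("an empty plan leaves the ledger at its initial state", {
  plan <- miniPlan(list())
  rep <- simulatePlan(plan, init1)
  expect_equal(nrow(violations(rep)), 0L)
  fw <- finalWells(rep)
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$volume_ul, 10)
  expect_equal(fw$component, "partX")
})

test_that("each simulator rule fires at the offending instruction", {
  # R1: over-aspiration
  over <- miniPlan(list(
    list(kind = "pick_tip"),
    list(kind = "aspirate", labware = "toolkit_plate", well = "A1",
         volume = 20)))
  v <- violations(simulatePlan(over, init1))
  expect_equal(v$rule, "R1")
  expect_equal(v$instruction_index, 2L)

  # R3: tipless transfer
  tipless <- miniPlan(list(
    list(kind = "aspirate", labware = "toolkit_plate", well = "A1",
         volume = 5)))
  expect_equal(violations(simulatePlan(tipless, init1))$rule, "R3")

  # R4: dispense differs from held volume
  mismatch <- miniPlan(list(
    list(kind = "pick_tip"),
    list(kind = "aspirate", labware = "toolkit_plate", well = "A1",
         volume = 5),
    list(kind = "dispense", labware = "reaction_plate", well = "B1",
         volume = 3)))
  v4 <- violations(simulatePlan(mismatch, init1))
  expect_equal(v4$rule, "R4")
  expect_equal(v4$instruction_index, 3L)

  # R5: aspirate from a well never declared
  ghost <- miniPlan(list(
    list(kind = "pick_tip"),
    list(kind = "aspirate", labware = "toolkit_plate", well = "H12",
         volume = 1)))
  expect_equal(violations(simulatePlan(ghost, init1))$rule, "R5")

  # R2: overfill past labware capacity (PCR plate: 200 uL)
  fill <- c(list(list(kind = "pick_tip", pipette = "p300_single_gen2")),
            unlist(lapply(1:2, function(i) list(
              list(kind = "aspirate", pipette = "p300_single_gen2",
                   labware = "toolkit_plate", well = "A1", volume = 150),
              list(kind = "dispense", pipette = "p300_single_gen2",
                   labware = "reaction_plate", well = "B1", volume = 150))),
              recursive = FALSE))
  big_init <- init1; big_init$volume_ul <- 500
  v2 <- violations(simulatePlan(miniPlan(fill), big_init))
  expect_equal(v2$rule, "R2")
  expect_equal(v2$instruction_index, 5L)

  # unknown labware is a hard error, not a violation
  mal <- miniPlan(list(
    list(kind = "pick_tip"),
    list(kind = "aspirate", labware = "no_such_plate", well = "A1",
         volume = 1)))
  expect_error(simulatePlan(mal, init1), "malformed plan")
})

test_that("aspiration from mixtures removes components proportionally", {
  init <- data.frame(
    labware = c("toolkit_plate", "toolkit_plate"),
    well = c("A1", "A1"), component = c("red", "blue"),
    volume_ul = c(6, 2), stringsAsFactors = FALSE)
  plan <- miniPlan(list(
    list(kind = "pick_tip"),
    list(kind = "aspirate", labware = "toolkit_plate", well = "A1",
         volume = 4),
    list(kind = "dispense", labware = "reaction_plate", well = "C3",
         volume = 4),
    list(kind = "drop_tip")))
  rep <- simulatePlan(plan, init)
  expect_equal(nrow(violations(rep)), 0L)
  fw <- finalWells(rep)
  dst <- fw[fw$labware == "reaction_plate", ]
  expect_equal(dst$volume_ul[dst$component == "red"], 3)
  expect_equal(dst$volume_ul[dst$component == "blue"], 1)
  src <- fw[fw$labware == "toolkit_plate", ]
  expect_equal(sum(src$volume_ul), 4)
})

test_that("liquid is conserved and reports are idempotent", {
  tk <- makeToolkitPlate(fixtureSpec(seed = 13))
  ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 4, seed = 13)
  plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
  r1 <- simulatePlan(plan)
  r2 <- simulatePlan(plan)
  expect_identical(finalWells(r1), finalWells(r2))
  expect_identical(violations(r1), violations(r2))
  expect_equal(sum(finalWells(r1)$volume_ul),
               sum(initialContents(plan)$volume_ul), tolerance = 1e-9)
})

test_that("the audit flags a deleted part transfer by name and well", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  plan <- compileGoldenGate(list(d), list(plate), goldenGateRecipe("OT-2"))
  ins <- instructions(plan)
  victim_part <- w$part_name[w$part_type == "3"]
  victim_src <- w$well[w$part_type == "3"]
  kill <- which(ins$kind %in% c("aspirate", "dispense") &
                !is.na(ins$well) &
                (ins$well == victim_src & ins$labware == "toolkit_plate" |
                 ins$kind == "dispense" & grepl(victim_part, ins$comment)))
  mutated <- plan
  mutated@instructions <- ins[-kill, , drop = FALSE]
  st <- mutated@stages
  for (k in seq_len(nrow(st))) {
    st$end[k] <- st$end[k] - sum(kill <= st$end[k])
    st$start[k] <- st$start[k] - sum(kill < st$start[k])
  }
  mutated@stages <- st

  audit <- auditCompositions(
    simulatePlan(mutated, initialContents(plan),
                 through_stage = "gg_setup"),
    reactionPlans(plan))
  expect_false(audit$pass)
  expect_true(victim_part %in% audit$diffs$component)
  expect_true("A1" %in% audit$diffs$well)

  # degenerate bound: infinite tolerance always passes
  loose <- auditCompositions(
    simulatePlan(mutated, initialContents(plan),
                 through_stage = "gg_setup"),
    reactionPlans(plan), tol = Inf)
  expect_true(loose$pass)
})
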