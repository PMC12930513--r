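ytk <- ytkLevel1Schema()

test_that("a promoter/CDS/terminator TU passes YTK Level-1 validation", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  d <- AssemblyDesign("tu1", w$part_name[w$part_type == "backbone"],
                      w$part_name[match(c("2", "3", "4"), w$part_type)],
                      "A1")
  vr <- validateDesign(d, ytk, list(plate))
  expect_true(passed(vr))
  expect_equal(nrow(findings(vr)), 0L)
})

test_that("sub-slot equivalences accept the six-part design", {
  plate <- unitDosePlate(c("backbone", "2", "3a", "3b", "4a", "4b"),
                         amount = 25)
  w <- wells(plate)
  d <- AssemblyDesign("six", w$part_name[1L], w$part_name[2:6], "A1")
  expect_true(passed(validateDesign(d, ytk, list(plate))))
})

test_that("slot-order violations and unresolvable parts fail validation", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  bb <- w$part_name[w$part_type == "backbone"]
  p2 <- w$part_name[w$part_type == "2"]
  p3 <- w$part_name[w$part_type == "3"]
  p4 <- w$part_name[w$part_type == "4"]

  # terminator before CDS
  bad_order <- AssemblyDesign("x", bb, c(p2, p4, p3), "A1")
  vr <- validateDesign(bad_order, ytk, list(plate))
  expect_false(passed(vr))
  expect_match(findings(vr)$message[findings(vr)$severity == "error"],
               "slot order")

  ghost <- AssemblyDesign("y", bb, c(p2, "no_such_part", p4), "A1")
  vr2 <- validateDesign(ghost, ytk, list(plate))
  expect_false(passed(vr2))
  expect_match(paste(findings(vr2)$message, collapse = " "), "not found")

  # non-backbone used as backbone
  vr3 <- validateDesign(AssemblyDesign("z", p2, c(p2, p3, p4), "A1"),
                        ytk, list(plate))
  expect_false(passed(vr3))
})

test_that("validation is permutation-sensitive for different-type parts", {
  plate <- unitDosePlate(c("backbone", "2", "3a", "3b", "4a", "4b"),
                         amount = 25)
  w <- wells(plate)
  parts <- w$part_name[2:6]
  base <- AssemblyDesign("ok", w$part_name[1L], parts, "A1")
  expect_true(passed(validateDesign(base, ytk, list(plate))))
  for (i in 1:4) for (j in (i + 1):5) {
    swapped <- parts
    swapped[c(i, j)] <- swapped[c(j, i)]
    d <- AssemblyDesign("swap", w$part_name[1L], swapped, "A1")
    expect_false(passed(validateDesign(d, ytk, list(plate))),
                 info = sprintf("transposition %d<->%d should fail", i, j))
  }
})

test_that("parts duplicated across maps are ambiguous unless records agree", {
  plate <- unitDosePlate(c("backbone", "2", "3", "4"), amount = 50)
  w <- wells(plate)
  dup_same <- PlateMap("custom_plate", "96-well", wells(plate)[2L, ])
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  expect_true(passed(validateDesign(d, ytk, list(plate, dup_same))))

  conflicting <- wells(plate)[2L, ]
  conflicting$concentration_ng_per_ul <- 999
  dup_diff <- PlateMap("custom_plate", "96-well", conflicting)
  vr <- validateDesign(d, ytk, list(plate, dup_diff))
  expect_false(passed(vr))
  expect_match(paste(findings(vr)$message, collapse = " "), "ambiguous")
})

test_that("zero-concentration stocks warn without failing", {
  w <- wells(unitDosePlate(c("backbone", "2", "3", "4"), amount = 50))
  w$concentration_ng_per_ul[w$part_type == "3"] <- 0
  plate <- PlateMap("toolkit_plate", "96-well", w)
  d <- AssemblyDesign("tu", w$part_name[1L], w$part_name[2:4], "A1")
  vr <- validateDesign(d, ytk, list(plate))
  expect_true(passed(vr))
  expect_true(any(findings(vr)$severity == "warning"))
})

test_that("combinatorial expansion equals the analytic product", {
  expect_length(expandCombinatorial(list("2" = c("pA", "pB"), "3" = "gfp"),
                                    "bb"), 2L)

  # 8 x 10 = 80 fits; 8 x 10 x 2 = 160 does not
  ch80 <- list("2" = paste0("p", 1:8), "3a" = paste0("sp", 1:10))
  expect_length(expandCombinatorial(ch80, "bb"), 80L)
  ch160 <- c(ch80, list("4a" = c("tagA", "tagB")))
  expect_error(expandCombinatorial(ch160, "bb"), "160",
               class = "mcp_capacity_error")

  one <- expandCombinatorial(list("2" = "pA", "3" = "gfp"), "bb",
                             naming_pattern = "{backbone}_{2}_{3}")
  expect_length(one, 1L)
  expect_equal(one[[1]]@construct_name, "bb_pA_gfp")
})

test_that("every expanded design passes validation under its schema", {
  plate <- makeToolkitPlate(fixtureSpec(
    seed = 11, n_per_type = c("2" = 3L, "3" = 2L, "4" = 2L,
                              "backbone" = 1L)))
  w <- wells(plate)
  choices <- list("2" = w$part_name[w$part_type == "2"],
                  "3" = w$part_name[w$part_type == "3"],
                  "4" = w$part_name[w$part_type == "4"])
  designs <- expandCombinatorial(choices, w$part_name[w$part_type ==
                                                      "backbone"])
  expect_length(designs, 3L * 2L * 2L)
  for (d in designs)
    expect_true(passed(validateDesign(d, ytk, list(plate))))
  # lexicographic: first slot varies slowest
  expect_equal(designs[[1]]@parts[1L], choices[["2"]][1L])
  expect_equal(designs[[12]]@parts[1L], choices[["2"]][3L])
})

test_that("toolkit schemas round-trip through YAML", {
  p <- tempfile(fileext = ".yaml")
  writeToolkitSchema(ytk, p)
  back <- readToolkitSchema(p)
  expect_equal(back@slot_order, ytk@slot_order)
  expect_equal(back@equivalence_groups, ytk@equivalence_groups)
  expect_equal(back@dropout_marker, "GFP-dropout")
})
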