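#' @include AllClasses.R planner-deck.R
NULL

#' Execute an instruction plan on the virtual robot
#'
#' Deterministically applies every instruction in order against a per-well
#' volume/composition ledger seeded from the plan's (or caller-supplied)
#' initial contents, and records rule violations:
#' \describe{
#'   \item{R1}{over-aspiration — aspirating (or mixing) more than the well
#'     holds;}
#'   \item{R2}{overfill — a dispense pushes a well past its labware's
#'     nominal capacity;}
#'   \item{R3}{tipless transfer — aspirate/dispense/mix without a tip on
#'     the pipette;}
#'   \item{R4}{held-volume mismatch — dispensing a different volume than
#'     the tip holds, or aspirating while already holding liquid;}
#'   \item{R5}{aspirating from a well never declared (neither initial
#'     contents nor a previous dispense).}
#' }
#' Aspiration from a mixed well removes each component in proportion to
#' its share of the well volume; liquid is conserved exactly across
#' aspirate/dispense pairs (no evaporation or residual-tip model).
#' Referencing labware absent from the deck is a hard error (malformed
#' plan), not a violation.
#'
#' @param plan an [InstructionPlan-class].
#' @param initial data.frame (`labware`, `well`, `component`,
#'   `volume_ul`); defaults to the plan's own `initialContents()`.
#' @param through_stage optional stage name: execute only up to the end
#'   of that stage (e.g. `"gg_setup"` to audit assembled reactions before
#'   transformation and plating alter the wells).
#' @return a [SimReport-class].
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 2, seed = 1)
#' plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
#' simulatePlan(plan)
#' @export
simulatePlan <- function(plan, initial = initialContents(plan),
                         through_stage = NULL) {
  stopifnot(is(plan, "InstructionPlan"))
  ins <- instructions(plan)
  if (!is.null(through_stage)) {
    st <- stages(plan)
    if (!through_stage %in% st$stage)
      stop("unknown stage: ", through_stage)
    ins <- ins[seq_len(st$end[st$stage == through_stage][1L]), ,
               drop = FALSE]
  }
  types <- deckLabwareTypes(deck(plan))
  known_lab <- c(names(types), "trash")

  wells_env <- new.env(parent = emptyenv())  # key -> named numeric composition
  for (i in seq_len(nrow(initial))) {
    key <- paste0(initial$labware[i], "|", initial$well[i])
    cur <- wells_env[[key]] %||% numeric()
    cm <- initial$component[i]
    cur[cm] <- (if (cm %in% names(cur)) cur[[cm]] else 0) +
      initial$volume_ul[i]
    wells_env[[key]] <- cur
  }

  tips <- list()          # pipette -> named numeric held composition
  has_tip <- character()  # pipettes currently carrying a tip
  tips_consumed <- 0L
  vio_i <- integer(); vio_rule <- character(); vio_msg <- character()
  violate <- function(i, rule, msg) {
    vio_i <<- c(vio_i, i); vio_rule <<- c(vio_rule, rule)
    vio_msg <<- c(vio_msg, msg)
  }

  liquid_kinds <- c("aspirate", "dispense", "mix")
  for (i in seq_len(nrow(ins))) {
    k <- ins$kind[i]
    p <- ins$pipette[i]
    lab <- ins$labware[i]
    wl <- ins$well[i]
    v <- ins$volume_ul[i]
    if (k %in% liquid_kinds && !lab %in% known_lab)
      stop("malformed plan: instruction ", i, " references unknown labware '",
           lab, "'")
    key <- paste0(lab, "|", wl)

    if (k == "pick_tip") {
      tips_consumed <- tips_consumed + 1L
      has_tip <- union(has_tip, p)
      tips[[p]] <- numeric()
    } else if (k == "drop_tip") {
      has_tip <- setdiff(has_tip, p)
      tips[[p]] <- NULL
    } else if (k == "aspirate") {
      if (!p %in% has_tip) {
        violate(i, "R3", sprintf("aspirate without a tip on %s", p))
      } else {
        held <- tips[[p]] %||% numeric()
        if (sum(held) > 1e-9) {
          violate(i, "R4", sprintf(
            "aspirate while %s already holds %.3f uL", p, sum(held)))
        } else {
          cur <- wells_env[[key]]
          if (is.null(cur)) {
            violate(i, "R5", sprintf(
              "aspirate from undeclared well %s/%s", lab, wl))
          } else if (sum(cur) < v - 1e-9) {
            violate(i, "R1", sprintf(
              "over-aspiration: %.3f uL requested from %s/%s holding %.3f uL",
              v, lab, wl, sum(cur)))
          } else {
            frac <- v / sum(cur)
            taken <- cur * frac
            wells_env[[key]] <- cur - taken
            tips[[p]] <- taken
          }
        }
      }
    } else if (k == "dispense") {
      if (!p %in% has_tip) {
        violate(i, "R3", sprintf("dispense without a tip on %s", p))
      } else {
        held <- tips[[p]] %||% numeric()
        if (abs(sum(held) - v) > 1e-9) {
          violate(i, "R4", sprintf(
            "dispense of %.3f uL but tip holds %.3f uL", v, sum(held)))
        } else {
          cur <- wells_env[[key]] %||% numeric()
          for (cm in names(held))
            cur[cm] <- (if (cm %in% names(cur)) cur[[cm]] else 0) + held[[cm]]
          wells_env[[key]] <- cur
          tips[[p]] <- numeric()
          cap <- labwareCapacity(types[[lab]] %||% "trash")
          if (sum(cur) > cap + 1e-9)
            violate(i, "R2", sprintf(
              "overfill: %s/%s holds %.3f uL, capacity %.0f uL",
              lab, wl, sum(cur), cap))
        }
      }
    } else if (k == "mix") {
      if (!p %in% has_tip) {
        violate(i, "R3", sprintf("mix without a tip on %s", p))
      } else {
        cur <- wells_env[[key]]
        if (is.null(cur)) {
          violate(i, "R5", sprintf("mix in undeclared well %s/%s", lab, wl))
        } else if (sum(cur) < v - 1e-9) {
          violate(i, "R1", sprintf(
            "mix volume %.3f uL exceeds the %.3f uL in %s/%s",
            v, sum(cur), lab, wl))
        }
        # mixing is composition-neutral in the nominal model
      }
    }
    # move / thermal_step / pause_for_operator / set_temperature do not
    # touch the liquid ledger
  }

  keys <- ls(wells_env)
  rows <- lapply(keys, function(k) {
    comp <- wells_env[[k]]
    comp <- comp[comp > 1e-12]
    if (!length(comp)) return(NULL)
    lw <- strsplit(k, "|", fixed = TRUE)[[1L]]
    data.frame(labware = lw[1L], well = lw[2L], component = names(comp),
               volume_ul = unname(comp), stringsAsFactors = FALSE)
  })
  final <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(final))
    final <- data.frame(labware = character(), well = character(),
                        component = character(), volume_ul = numeric(),
                        stringsAsFactors = FALSE)
  final <- final[order(final$labware, final$well, final$component), ,
                 drop = FALSE]
  rownames(final) <- NULL
  new("SimReport", final_wells = final,
      violations = data.frame(instruction_index = vio_i, rule = vio_rule,
                              message = vio_msg, stringsAsFactors = FALSE),
      tips_consumed = tips_consumed)
}

#' Audit simulated well compositions against expected reaction plans
#'
#' Compares, for every expected [ReactionPlan-class], the simulated final
#' composition of its destination well component-for-component (the
#' plan's `water_topup` is audited as component `"water"`). Components
#' pooled en route (e.g. a PCR master mix assembled from water, primers
#' and 2x mix) can be aggregated onto the expected component name via
#' `aggregate`.
#'
#' @param report a [SimReport-class].
#' @param expected named list of [ReactionPlan-class]; names are
#'   `"labware|well"` keys (as produced by the compilers), or bare well
#'   labels resolved against `default_labware`.
#' @param tol per-component tolerance, µL; default 1e-9.
#' @param aggregate named list: expected component name -> character
#'   vector of simulated component names summed into it.
#' @param default_labware labware for unnamed/bare-well entries.
#' @return list with `pass` (logical) and `diffs` (data.frame of every
#'   component mismatch: labware, well, component, expected, simulated).
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' ds <- makeCombinationSet(tk, ytkLevel1Schema(), n = 2, seed = 1)
#' plan <- compileGoldenGate(ds, list(tk), goldenGateRecipe("OT-2"))
#' auditCompositions(simulatePlan(plan), reactionPlans(plan))$pass
#' @export
auditCompositions <- function(report, expected, tol = 1e-9,
                              aggregate = NULL,
                              default_labware = "reaction_plate") {
  stopifnot(is(report, "SimReport"))
  fw <- finalWells(report)
  d_lab <- character(); d_well <- character(); d_comp <- character()
  d_exp <- numeric(); d_sim <- numeric()
  note <- function(lab, wl, cm, ex, si) {
    d_lab <<- c(d_lab, lab); d_well <<- c(d_well, wl)
    d_comp <<- c(d_comp, cm); d_exp <<- c(d_exp, ex); d_sim <<- c(d_sim, si)
  }

  keys <- names(expected)
  for (i in seq_along(expected)) {
    rp <- expected[[i]]
    key <- keys[i] %||% ""
    if (!nzchar(key) || !grepl("|", key, fixed = TRUE))
      key <- paste0(default_labware, "|", rp@destination_well)
    lw <- strsplit(key, "|", fixed = TRUE)[[1L]]
    sim <- fw[fw$labware == lw[1L] & fw$well == lw[2L], , drop = FALSE]
    simv <- stats::setNames(sim$volume_ul, sim$component)

    want <- stats::setNames(rp@components$volume_ul, rp@components$component)
    if (rp@water_topup > 0)
      want["water"] <- (if ("water" %in% names(want)) want[["water"]] else 0) +
        rp@water_topup
    for (cm in names(want)) {
      got <- if (!is.null(aggregate) && cm %in% names(aggregate))
        sum(simv[intersect(aggregate[[cm]], names(simv))])
      else if (cm %in% names(simv)) simv[[cm]] else 0
      if (abs(got - want[[cm]]) > tol)
        note(lw[1L], lw[2L], cm, want[[cm]], got)
    }
    # components present in the well but absent from the plan (beyond the
    # aggregated ones and later-stage additions) are not flagged: the
    # audit certifies the reaction was assembled, later stages may add to
    # the well (competent cells)
  }
  diffs <- data.frame(labware = d_lab, well = d_well, component = d_comp,
                      expected = d_exp, simulated = d_sim,
                      stringsAsFactors = FALSE)
  list(pass = nrow(diffs) == 0L, diffs = diffs)
}
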