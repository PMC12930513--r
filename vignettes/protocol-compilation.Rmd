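---
title: "Compiling Golden Gate cloning protocols for liquid handlers"
author: "mocloplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling Golden Gate cloning protocols for liquid handlers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocloplan)
```

## The problem

Golden Gate / MoClo assembly builds plasmids by combining typed DNA parts
(promoters, CDSs, terminators, and their sub-slot variants) with a backbone
in a one-pot Type IIS digestion–ligation reaction. Setting up tens of such
reactions by hand — each with its own molarity-matched DNA volumes, a shared
master mix, thermocycling, transformation and plating — is slow and
error-prone. `mocloplan` compiles this workflow, plus the follow-up colony
PCR screen, into an ordered stream of atomic liquid-handler instructions
for the Opentrons OT-2 and Flex, and verifies every compiled plan with a
deterministic virtual robot before any script is emitted.

The pipeline is: three user CSVs (a fixed toolkit plate map, a custom parts
plate map, a combinations table) → grammar validation against a toolkit
schema → per-well reaction recipes → deck layout → instruction plan →
virtual-robot verification → artifacts (plan JSON, destination plate map,
Opentrons protocol script, simulation report). Colony PCR takes a picked
colony sheet instead and produces per-plate reaction maps.

## Reaction arithmetic

Each plasmid (entry parts and the backbone alike) is dosed by molar
amount. The dose volume follows from the average double-stranded base-pair
mass $m_{bp}$:

$$ V[\mu L] \;=\; \frac{a[\mathrm{fmol}] \cdot L[\mathrm{bp}] \cdot m_{bp}
   \cdot 10^{-6}}{c[\mathrm{ng}/\mu L]}, \qquad m_{bp} = 650\;
   \mathrm{g\,mol^{-1}\,bp^{-1}}. $$

$m_{bp} = 650$ is the lab convention for double-stranded DNA; the exact
sequence-dependent value (≈ 618 · bp + 36) differs by under 5 %, well
inside pipetting accuracy, and is configurable for groups that prefer it.
Platform presets:

| constant | OT-2 | Flex |
|---|---|---|
| reaction volume | 10 µL | 12 µL |
| DNA per part | 50 fmol | 25 fmol |
| enzymes | BsaI 0.5 µL + T4 ligase 0.5 µL | Golden Gate enzyme mix 1.2 µL |
| dispense order | master mix first, then parts | buffer + water, parts, enzymes |
| plating droplet | 4.5 µL | 2.5 µL |
| colony PCR | 9 µL mix + 1 µL template | 13 µL mix + 2 µL template |

The ligase buffer is dosed to 1× final from a 10× stock (the vendor
standard; the stock fold is a parameter). Water absorbs the remainder so
every reaction closes exactly on the recipe total; a closure within
10⁻⁹ µL is a class invariant of `ReactionPlan`, and stocks too dilute to
fit their dose raise an over-volume error listing every per-part volume.

Because molar doses vary with each stock's concentration, the per-well
water top-up is generally not uniform. The OT-2's "master mix first" order
therefore pools buffer + enzymes (adding water to the pool only when the
top-up is uniform, as in fixed-volume mode) and dispenses remaining water
per well. Fixed-volume mode (`fixed_dna_volume`) covers normalized part
libraries whose concentrations are not recorded: every part gets the same
configured volume (default 1 µL).

Master mixes scale as per-reaction volume × n × overage. The overage
default is 10 % — unstated by most bench protocols but required for
feasibility with multi-dispense — and totals are *reported* at 0.1 µL
(round half up) while the pooled *transfers* use the exact product, so the
pooled component ratio equals the per-reaction recipe exactly and the
composition audit can hold at 10⁻⁹ µL. A pool above 90 % of a 1.5 mL
tube's nominal volume escalates to the next container with a recorded
warning (the 90 % safe-fill leaves mixing headroom).

The assembly thermal profile is 25 cycles of 37 °C/2 min (digestion) +
16 °C/5 min (ligation), then 60 °C/5 min to denature the enzymes
(10 800 s total); cycle count and temperatures are parameters because
other Type IIS enzymes need different optima. Heat-shock transformation
parameters (42 °C / 30 s between 4 °C holds) and competent-cell volume
(20 µL) are config-only defaults: the on-deck thermocycler performs the
shock, but the primary literature rarely prints these numbers and labs
tune them locally.

## Toolkit grammar

Designs are validated structurally, not at sequence level: part-type
labels are what plate maps carry, and fusion-site fidelity is out of
scope. A design passes when every name resolves to exactly one source
well (a part present on both plates is accepted only if the records
agree), the backbone has an allowed backbone type, and the ordered part
types spell the schema's slot order exactly once — where an equivalence
group lets a contiguous sub-slot run stand for its parent slot (YTK
3a + 3b ⇔ 3, 4a + 4b ⇔ 4, which is how six-part secretion constructs
pass the same three-slot grammar). Validation is deliberately skippable
(`validate = FALSE`) since some users trust their combination tables;
a 0 ng/µL stock is a warning, not an error, because it only precludes
molar dosing. Two schemas ship built-in (YTK Level 1, STK Level 1 with
promoter/RBS/0C-CDS/terminator slots); arbitrary schemas load from YAML.

## Deck allocation and instruction granularity

On the OT-2, the thermocycler module occupies slots 7, 8, 10, 11 of the
11 addressable slots and hosts the reaction plate; the temperature module
(one slot) chills a 24-tube reagent rack; the rest goes to tip racks,
source plates and agar plates, and infeasible demands fail with the exact
shortfall. Without the on-deck cycler those four slots are freed, the
reaction plate takes an ordinary slot, and every thermal stage compiles
to a `pause_for_operator` for benchtop cycling. The Flex deck is modeled
as 12 addressable slots and always cycles off-deck, matching how the
platform is typically run for this workflow.

An *instruction* is one atomic robot command: `pick_tip`, `drop_tip`,
`aspirate`, `dispense`, `mix`, `move`, `thermal_step`,
`pause_for_operator`, `set_temperature`. A `move` precedes every
positioned action (a liquid operation at a new location, a tip pickup, a
tip drop), mirroring the gantry command stream a liquid handler actually
executes; consecutive operations at the same position do not re-move.
Tip policy: a fresh tip per DNA source and per destination-well mix (the
standard contamination rule), a shared tip for repeated dispenses of one
reagent from one source. Tips and agar plates beyond the deck's capacity
are handled the way operators actually run long protocols — a pause
instruction asks for fresh racks/plates and the stream continues.

Plating uses a deterministic center + concentric-ring pattern: ring radii
step inward from the well radius minus an edge margin (defaults 17 mm −
3 mm) in units of the minimum spot spacing (6 mm), each ring holding as
many equally spaced spots as that spacing allows; the defaults give the
validated 13 positions at 4.5 µL (OT-2) / 2.5 µL (Flex) dispensed
z = 5 mm above the agar. Geometry is checked by construction *and* by an
O(n²) pairwise-distance validity invariant.

## The virtual robot as verification oracle

`simulatePlan()` executes a plan against a per-well volume/composition
ledger seeded from the plan's required initial contents (computed by
replaying the stream: peak net draw per source well plus a 5 µL dead
volume). Five rules are checked — over-aspiration, overfill past labware
capacity, tipless transfer, held-volume mismatch, aspiration from an
undeclared well — and aspiration from a mixture removes components
proportionally, the simplest physically consistent model and sufficient
for a composition audit. Volumes are nominal: residual tip films, air
gaps, and evaporation are not modeled, so a clean simulation certifies
bookkeeping (the right volumes from the right wells in the right order),
not pipetting physics. `auditCompositions()` then compares each
destination's simulated composition against its `ReactionPlan` at
10⁻⁹ µL, taken at the end of the setup stage (later stages legitimately
add cells to and plate droplets from the same wells). Every compiled plan
must pass both checks; the CLI refuses to emit artifacts otherwise.

## Synthetic fixtures: what they do and do not emulate

`fixtureSpec()`/`makeToolkitPlate()` stand in for a replicated Addgene
toolkit plate: parts named `<type>_<index>`, filled row-major, with
concentrations drawn uniformly from 100–300 ng/µL (routine miniprep
yields — a range under which every 50 fmol dose of a 2–5 kb plasmid fits
a 10 µL reaction) and lengths from 2000–5000 bp (typical entry-vector
sizes). One integer seed fixes everything. The generator emulates the
*bookkeeping* properties of real inputs — typed parts, plausible
stoichiometry, valid combinations — and none of the biology: no
sequences, no overhang compatibility, no assembly efficiency. Passing
tests therefore demonstrate that compilation, arithmetic and simulation
are correct, not that any particular assembly will yield colonies; the
published wet-lab success rates are explicitly outside what this package
can reproduce.

Test-bench problem sizes were chosen to exercise every code path at
desk scale: single-TU runs of ~19 designs, the 62-design six-part
secretion panel (which alone compiles to >5000 instructions), 96-design
capacity runs, and 288-reaction colony PCR across three plates.

## Numerical and design choices

* All volumes are µL as doubles; comparisons use a 10⁻⁹ µL tolerance —
  far below pipettable resolution, so closure failures indicate logic
  errors, not rounding.
* CSV dialect is fixed (UTF-8, comma, `.` decimal) to avoid silent locale
  bugs; every parse error carries the 1-based data-row number.
* Well labels are SBS row-letter + 1-based column; auto-assigned
  destinations fill row-major (A1, A2, …), and plate maps are stored and
  written in that order, making writes byte-stable and row order in input
  files irrelevant.
* Sheets with more than 96 colony picks span consecutive 96-row
  destination-plate blocks in file order; destination-well uniqueness is
  enforced within each block, and template plate *k* serves destination
  plate *k*.
* Serialized plans are deterministic (no timestamps, fixed key order,
  full-precision numbers); the emitted Opentrons script embeds the plan
  JSON verbatim between markers as data — not generated control flow — so
  script and plan cannot drift apart and the equivalence is testable
  without a Python parser.
* Primer pairs on a pick sheet are metadata: one master mix is pooled per
  run (matching the published workflow); runs needing different mixes per
  primer pair should be compiled as separate runs.

## Known limitations

No motion planning or collision checking; no labware calibration; no
enzyme-unit arithmetic (units are metadata); no ligation kinetics or
overhang-fidelity prediction; one droplet per construct by default
(configurable) although real plates often receive several; the Flex deck
model omits the staging area and gripper moves. The emitted protocol
script targets the Opentrons API v2 dialect but is validated here only
for structural equivalence with the plan, not by an Opentrons runtime.

## A worked example

```{r example}
tk <- makeToolkitPlate(fixtureSpec(seed = 1))
designs <- makeCombinationSet(tk, ytkLevel1Schema(), n = 19, seed = 1)
plan <- compileGoldenGate(designs, list(tk), goldenGateRecipe("OT-2"),
                          schema = ytkLevel1Schema())
countInstructions(plan)
report <- simulatePlan(plan)
report
auditCompositions(simulatePlan(plan, through_stage = "gg_setup"),
                  reactionPlans(plan))$pass
```
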