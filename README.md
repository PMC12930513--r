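# mocloplan

**Golden Gate cloning protocol compilation and virtual liquid-handler
verification for Opentrons OT-2 and Flex.**

Combinatorial MoClo/Golden Gate cloning — dozens of typed DNA parts
assembled into up to 96 constructs per run, transformed, plated and
screened by colony PCR — is a bookkeeping problem as much as a biology
problem. `mocloplan` is for synthetic-biology labs that run this workflow
on an Opentrons robot: from three CSVs (a fixed toolkit plate map, a
custom parts plate map, and a combinations table) it computes validated
per-well reaction recipes, allocates the deck, compiles the full ordered
instruction stream (assembly setup → thermocycling → E. coli
transformation → agar plating, plus a colony PCR workflow), verifies the
plan instruction-by-instruction on a deterministic virtual robot, and
only then emits a robot-ready protocol script.

## The core model

Every plasmid is dosed by molar amount. For a target of $a$ fmol of a
part of length $L$ bp at stock concentration $c$ ng/µL:

$$ V = \frac{a \cdot L \cdot m_{bp} \cdot 10^{-6}}{c}\ \mu L,
   \qquad m_{bp} = 650\ \mathrm{g\,mol^{-1}\,bp^{-1}} $$

Platform presets: OT-2 reactions are 10 µL with 50 fmol per part, 0.5 µL
BsaI + 0.5 µL T4 ligase, 1× ligase buffer from a 10× stock, master mix
distributed first; Flex reactions are 12 µL with 25 fmol and 1.2 µL
enzyme mix, buffer and water dispensed first, then plasmids, then
enzymes. Water closes every reaction exactly on the recipe total (a
validity invariant at 10⁻⁹ µL). Assemblies cycle 25× (37 °C/2 min +
16 °C/5 min) then 60 °C/5 min; transformations are plated as 4.5 µL
droplets (2.5 µL on Flex) at 13 spots per agar well, 5 mm above the
agar. Colony PCR is 9 + 1 µL (OT-2) or 13 + 2 µL (Flex), up to three
96-well plates per run with benchtop cyclers.

The virtual robot replays each compiled plan against a per-well
volume/composition ledger, checking over-aspiration, overfill, tipless
transfers, held-volume mismatches and undeclared sources, then audits
every destination well against its reaction recipe at 10⁻⁹ µL.

## A worked example

```r
library(mocloplan)

tk      <- makeToolkitPlate(fixtureSpec(seed = 1))   # synthetic YTK plate
designs <- makeCombinationSet(tk, ytkLevel1Schema(), n = 19, seed = 1)
plan    <- compileGoldenGate(designs, list(tk), goldenGateRecipe("OT-2"),
                             schema = ytkLevel1Schema())
plan
#> InstructionPlan (OT-2): 1245 instructions in 4 stages
#>   gg_setup         1..913
#>   thermocycle      914..917
#>   transformation   918..1092
#>   plating          1093..1245

reactionPlans(plan)[[1]]
#> ReactionPlan -> A1: 7 components + 5.65 uL water = 10.00 uL

simulatePlan(plan)
#> SimReport: 0 violations; 139 tips consumed; 51 wells tracked

auditCompositions(simulatePlan(plan, through_stage = "gg_setup"),
                  reactionPlans(plan))$pass
#> [1] TRUE
```

The 19 assemblies compile to 1245 atomic instructions (tip handling,
gantry moves, 155 aspirate/dispense pairs, thermal steps and one
operator pause for an agar-plate swap). The first reaction doses its
four plasmids at 50 fmol each (1.05, 0.31, 0.58 and 0.40 µL given their
stock concentrations), 1 µL 10× buffer, the two enzymes, and 5.65 µL
water — closing exactly on 10 µL, which the simulator confirms
component-for-component.

From a shell, the same pipeline (and fixture generation) runs through the
CLI wrapper:

```sh
Rscript inst/scripts/mocloplan.R make-fixtures --out fx --preset ytk_tu
Rscript inst/scripts/mocloplan.R compile-goldengate \
    --platform ot2 --toolkit fx/toolkit_plate.csv \
    --combinations fx/combinations.csv --out run1
Rscript inst/scripts/mocloplan.R simulate --plan run1/goldengate_plan.json
```

writing `goldengate_plan.json`, `goldengate_protocol.py` (Opentrons API
v2, with the plan inlined as data), `reaction_plate_map.csv` and
`goldengate_sim_report.json`. Exit codes distinguish parse (2), grammar
(3), capacity (4) and simulation (5) failures.

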