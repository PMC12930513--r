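Package: mocloplan
Title: Golden Gate Assembly Protocol Compilation and Virtual
    Liquid-Handler Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiles validated Golden Gate / MoClo cloning protocols for
    Opentrons OT-2 and Flex liquid handlers from CSV plate maps and
    assembly combination tables. Computes molarity-based reaction recipes,
    master mixes and thermal profiles, allocates deck layouts, and emits
    ordered instruction plans for assembly, transformation, agar plating
    and colony PCR. Every compiled plan is verified with a deterministic
    virtual-robot simulator that tracks per-well volumes and compositions,
    before robot-ready protocol scripts are written.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'planner-deck.R'
    'virtual-robot.R'
    'recipes.R'
    'planner-compile.R'
    'serialize.R'
    'cli.R'
    'design-io.R'
    'fixtures.R'
    'grammar.R'
    'methods-accessors.R'
    'utils-wells.R'
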