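# Shared in-code fixtures: plates whose stock concentrations are chosen so
# that molar doses come out at round volumes, making expected component
# tables exact.

# concentration (ng/uL) at which `amount` fmol of `len` bp is `vol` uL
concForDose <- function(amount, len, vol) amount * len * 650e-6 / vol

# plate with one backbone + parts of the given types, each dosed at
# exactly `dose_ul` under `amount` fmol
unitDosePlate <- function(types, amount, dose_ul = 1,
                          len = c(2000L, 2400L, 3100L, 2800L, 3500L,
                                  4200L, 2200L, 2600L),
                          labware_id = "toolkit_plate") {
  n <- length(types)
  len <- rep_len(len, n)
  data.frame(
    well = wellLabels("96-well")[seq_len(n)],
    part_name = paste0(types, "_u", seq_len(n)),
    part_type = types,
    concentration_ng_per_ul = concForDose(amount, len, dose_ul),
    length_bp = len,
    stringsAsFactors = FALSE) |>
    (\(w) PlateMap(labware_id, "96-well", w))()
}

# write designs to a temp combinations CSV and return the path
tempCombinationsCsv <- function(designs) {
  p <- tempfile(fileext = ".csv")
  writeCombinations(designs, p)
  p
}

tempPlateCsv <- function(map) {
  p <- tempfile(fileext = ".csv")
  writePlateMap(map, p)
  p
}
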