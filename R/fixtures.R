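#' @include AllClasses.R
NULL

#' Specification for synthetic toolkit fixtures
#'
#' Defines the deterministic generator that emulates a toolkit source
#' plate (the role of an Addgene-distributed MoClo/YTK plate replicated as
#' a working 96-well stock) plus user parts: how many parts of each
#' MoClo type to create, and the ranges stock concentrations and lengths
#' are drawn from. One seed fixes all randomness.
#'
#' Defaults mirror a typical Level-1 working plate: parts of types 2, 3,
#' 4 (with 3a/3b/4a/4b sub-slots available on request) plus backbones;
#' miniprepped stocks of 100-300 ng/µL and entry plasmids of 2000-5000 bp
#' (routine miniprep yields and entry-vector sizes; at these ranges every
#' molar dose fits the reaction volume while still exercising the
#' molarity arithmetic across a 3-fold concentration span).
#'
#' @param seed integer seed fixing all randomness.
#' @param n_per_type named integer vector: part-type label -> count.
#' @param conc_range ng/µL range stocks are drawn from (uniform).
#' @param len_range bp range lengths are drawn from (uniform integers).
#' @return an object of class `FixtureSpec` (a validated list).
#' @seealso [makeToolkitPlate()], [makeCombinationSet()]
#' @export
fixtureSpec <- function(seed = 1L,
                        n_per_type = c("2" = 19L, "3" = 1L, "4" = 1L,
                                       "backbone" = 1L),
                        conc_range = c(100, 300),
                        len_range = c(2000L, 5000L)) {
  stopifnot(length(seed) == 1L, all(conc_range > 0), all(len_range >= 1),
            diff(conc_range) >= 0, diff(len_range) >= 0,
            !is.null(names(n_per_type)), all(n_per_type >= 0))
  structure(list(seed = as.integer(seed),
                 n_per_type = n_per_type,
                 conc_range = conc_range,
                 len_range = as.integer(len_range)),
            class = "FixtureSpec")
}

#' Generate a synthetic toolkit source plate
#'
#' Fills a 96-well plate row-major with parts named `<type>_<index>`,
#' concentrations and lengths drawn uniformly from the spec's ranges.
#' Deterministic for a given seed.
#'
#' @param spec a [fixtureSpec()].
#' @param labware_id labware name; default `"toolkit_plate"`.
#' @return a [PlateMap-class].
#' @examples
#' makeToolkitPlate(fixtureSpec(seed = 42))
#' @export
makeToolkitPlate <- function(spec, labware_id = "toolkit_plate") {
  stopifnot(inherits(spec, "FixtureSpec"))
  total <- sum(spec$n_per_type)
  if (total > 96L)
    capacityError(sprintf(
      "fixture requests %d parts, more than one 96-well plate holds", total))
  set.seed(spec$seed)
  types <- rep(names(spec$n_per_type), spec$n_per_type)
  idx <- unlist(lapply(spec$n_per_type, seq_len), use.names = FALSE)
  conc <- stats::runif(total, spec$conc_range[1L], spec$conc_range[2L])
  len <- sample.int(spec$len_range[2L] - spec$len_range[1L] + 1L, total,
                    replace = TRUE) + spec$len_range[1L] - 1L
  wells_df <- data.frame(
    well = wellLabels("96-well")[seq_len(total)],
    part_name = paste(types, idx, sep = "_"),
    part_type = types,
    concentration_ng_per_ul = round(conc, 1),
    length_bp = as.integer(len),
    stringsAsFactors = FALSE)
  PlateMap(labware_id, "96-well", wells_df)
}

#' Generate a valid combination set over a toolkit plate
#'
#' Samples `n` assembly designs, each drawing one part per schema slot
#' (sub-slot equivalence runs are used when the plate carries sub-slot
#' parts instead of the parent type) plus a backbone. Every returned
#' design passes [validateDesign()] against the generating schema by
#' construction. Destinations are assigned row-major.
#'
#' @param plate a [PlateMap-class] from [makeToolkitPlate()].
#' @param schema a [ToolkitSchema-class].
#' @param n number of designs (0 allowed).
#' @param seed integer seed.
#' @param name_prefix construct-name prefix; default `"assembly"`.
#' @return list of [AssemblyDesign-class].
#' @examples
#' tk <- makeToolkitPlate(fixtureSpec(seed = 1))
#' designs <- makeCombinationSet(tk, ytkLevel1Schema(), n = 19, seed = 1)
#' length(designs)
#' @export
makeCombinationSet <- function(plate, schema, n, seed = 1L,
                               name_prefix = "assembly") {
  stopifnot(is(plate, "PlateMap"), is(schema, "ToolkitSchema"), n >= 0)
  if (n > 96L)
    capacityError(sprintf(
      "%d combinations exceed the 96-assembly capacity of one run", n))
  w <- wells(plate)
  by_type <- split(w$part_name, w$part_type)
  backbones <- unlist(by_type[schema@backbone_types], use.names = FALSE)
  if (!length(backbones))
    grammarError("fixture plate has no backbone-typed part")
  set.seed(seed)
  auto <- wellLabels("96-well")
  designs <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- character()
    for (s in schema@slot_order) {
      pool <- by_type[[s]]
      if (length(pool)) {
        parts <- c(parts, pool[sample.int(length(pool), 1L)])
      } else {
        # spell the slot through its equivalence run
        run <- schema@equivalence_groups[[s]]
        if (is.null(run) || !all(run %in% names(by_type)))
          grammarError(sprintf(
            "fixture plate carries no part for slot '%s' (nor its sub-slots)", s))
        for (sub in run) {
          pool <- by_type[[sub]]
          parts <- c(parts, pool[sample.int(length(pool), 1L)])
        }
      }
    }
    bb <- backbones[sample.int(length(backbones), 1L)]
    designs[[i]] <- AssemblyDesign(sprintf("%s_%d", name_prefix, i), bb,
                                   parts, auto[i])
  }
  designs
}

#' Generate a colony-pick sheet for a set of constructs
#'
#' Assigns `picks_per_construct` colonies to each construct, template
#' wells row-major on (possibly several) colony plates, destinations
#' row-major on the PCR plates, one shared screening primer pair.
#'
#' @param constructs character vector of construct names.
#' @param picks_per_construct colonies picked per construct; default 1.
#' @param primer_pair primer pair id; default `"scr_F/scr_R"`.
#' @return a [ColonyPickSheet-class].
#' @examples
#' makeColonyPickSheet(paste0("tu", 1:6), picks_per_construct = 2)
#' @export
makeColonyPickSheet <- function(constructs, picks_per_construct = 1L,
                                primer_pair = "scr_F/scr_R") {
  n <- length(constructs) * picks_per_construct
  labels <- wellLabels("96-well")
  pos <- seq_len(n)
  entries <- data.frame(
    construct_name = rep(constructs, each = picks_per_construct),
    template_well = labels[(pos - 1L) %% 96L + 1L],
    primer_pair = primer_pair,
    destination_well = labels[(pos - 1L) %% 96L + 1L],
    stringsAsFactors = FALSE)
  ColonyPickSheet(entries)
}
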