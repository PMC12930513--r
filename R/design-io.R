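#' @include AllClasses.R
NULL

## read a CSV with a mandatory header; returns data.frame of characters
readCsvStrict <- function(source, required_cols, what) {
  df <- tryCatch(
    utils::read.csv(source, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) parseError(sprintf("cannot read %s CSV: %s", what,
                                           conditionMessage(e)))
  )
  missing <- setdiff(required_cols, colnames(df))
  if (length(missing))
    parseError(sprintf("%s CSV is missing column(s): %s", what,
                       paste(missing, collapse = ", ")))
  df
}

numOrNA <- function(x) {
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a part plate map from CSV
#'
#' Parses the part-map dialect (`well,part_name,part_type,
#' concentration_ng_per_ul,length_bp`) into a [PlateMap-class]. Blank rows
#' are skipped; row order in the file never affects the result (wells are
#' stored row-major). Duplicate well labels, malformed labels, negative
#' concentrations and non-integer lengths are hard errors carrying the
#' 1-based data-row number.
#'
#' @param source file path or connection of the CSV.
#' @param plate_format labware format tag, default `"96-well"`
#'   (`"24-well"` for reagent tube racks).
#' @param labware_id labware name recorded on the map; defaults to the
#'   file name without extension (or `"plate"` for connections).
#' @return a [PlateMap-class].
#' @seealso [writePlateMap()], the inverse.
#' @examples
#' csv <- textConnection(
#'   "well,part_name,part_type,concentration_ng_per_ul,length_bp
#' A1,pTDH3,2,60,2400
#' B1,sfGFP,3,55,3100")
#' readPlateMap(csv, labware_id = "demo")
#' @export
readPlateMap <- function(source, plate_format = "96-well",
                         labware_id = NULL) {
  if (is.null(labware_id))
    labware_id <- if (is.character(source))
      sub("\\.[^.]*$", "", basename(source)) else "plate"
  cols <- colnames(emptyWellsDf())
  df <- readCsvStrict(source, cols, "part map")
  keep <- nzchar(df$well) | nzchar(df$part_name)
  df <- df[keep, , drop = FALSE]
  rows <- which(keep)   # 1-based data-row numbers in the file
  labels <- wellLabels(plate_format)
  seen <- character()
  out <- emptyWellsDf()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$well %in% labels)
      parseError(sprintf("malformed well label '%s' for %s format",
                         r$well, plate_format), row = rows[i])
    if (r$well %in% seen)
      parseError(sprintf("duplicate well label '%s'", r$well), row = rows[i])
    seen <- c(seen, r$well)
    if (!nzchar(r$part_name))
      parseError("empty part_name", row = rows[i])
    conc <- numOrNA(r$concentration_ng_per_ul)
    if (!is.na(conc) && conc < 0)
      parseError(sprintf("negative concentration (%s)", r$concentration_ng_per_ul),
                 row = rows[i])
    lenraw <- numOrNA(r$length_bp)
    if (!is.na(lenraw) && (lenraw < 1 || lenraw != floor(lenraw)))
      parseError(sprintf("length_bp must be a positive integer (got %s)",
                         r$length_bp), row = rows[i])
    out <- rbind(out, data.frame(
      well = r$well, part_name = r$part_name, part_type = r$part_type,
      concentration_ng_per_ul = conc,
      length_bp = if (is.na(lenraw)) NA_integer_ else as.integer(lenraw),
      stringsAsFactors = FALSE))
  }
  PlateMap(labware_id, plate_format, out)
}

#' Write a plate map to CSV
#'
#' Emits the part-map dialect; rows are sorted row-major by well label so
#' repeated writes of the same map are byte-identical, and
#' `readPlateMap(writePlateMap(x))` round-trips exactly.
#'
#' @param map a [PlateMap-class].
#' @param sink file path or connection.
#' @return invisibly, the path/connection written.
#' @export
writePlateMap <- function(map, sink) {
  stopifnot(is(map, "PlateMap"))
  w <- wells(map)
  out <- data.frame(
    well = w$well, part_name = w$part_name, part_type = w$part_type,
    concentration_ng_per_ul = ifelse(is.na(w$concentration_ng_per_ul), "",
                                     formatC(w$concentration_ng_per_ul,
                                             format = "fg", digits = 15)),
    length_bp = ifelse(is.na(w$length_bp), "", as.character(w$length_bp)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(sink)
}

#' Read assembly combinations from CSV
#'
#' Parses the combinations dialect (`construct_name,backbone,part_1,...,
#' part_8[,destination_well]`). Trailing blank part cells are allowed;
#' designs are returned in file order. When the destination column is
#' absent (or blank), destination wells are auto-assigned row-major in the
#' 96-well reaction plate (A1, A2, ...). More than 96 rows is a capacity
#' error; a row with no parts is a hard error.
#'
#' @param source file path or connection.
#' @return list of [AssemblyDesign-class] objects.
#' @examples
#' csv <- textConnection(
#'   "construct_name,backbone,part_1,part_2,part_3
#' tu1,pWS064,pTDH3,sfGFP,tTDH1")
#' readCombinations(csv)
#' @export
readCombinations <- function(source) {
  df <- readCsvStrict(source, c("construct_name", "backbone"), "combinations")
  part_cols <- grep("^part_[0-9]+$", colnames(df), value = TRUE)
  if (!length(part_cols))
    parseError("combinations CSV has no part_N columns")
  part_cols <- part_cols[order(as.integer(sub("part_", "", part_cols)))]
  keep <- nzchar(df$construct_name) | nzchar(df$backbone)
  df <- df[keep, , drop = FALSE]
  rows <- which(keep)
  if (nrow(df) > 96L)
    capacityError(sprintf(
      "%d assembly combinations exceed the 96-assembly capacity of one run",
      nrow(df)))
  has_dest <- "destination_well" %in% colnames(df)
  auto <- wellLabels("96-well")
  seen_names <- character(); seen_dest <- character()
  designs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!nzchar(r$construct_name))
      parseError("empty construct_name", row = rows[i])
    if (r$construct_name %in% seen_names)
      parseError(sprintf("duplicate construct_name '%s'", r$construct_name),
                 row = rows[i])
    seen_names <- c(seen_names, r$construct_name)
    parts <- unlist(r[part_cols], use.names = FALSE)
    parts <- parts[nzchar(parts)]
    if (!length(parts))
      parseError("combination row has no parts", row = rows[i])
    dest <- if (has_dest && nzchar(r$destination_well)) r$destination_well
            else auto[i]
    if (!isValidWell(dest, "96-well"))
      parseError(sprintf("malformed destination well '%s'", dest),
                 row = rows[i])
    if (dest %in% seen_dest)
      parseError(sprintf("duplicate destination well '%s'", dest),
                 row = rows[i])
    seen_dest <- c(seen_dest, dest)
    designs[[i]] <- AssemblyDesign(r$construct_name, r$backbone, parts, dest)
  }
  designs
}

#' Write assembly combinations to CSV
#'
#' Inverse of [readCombinations()]; pads part columns to the widest design
#' and always writes the destination column.
#'
#' @param designs list of [AssemblyDesign-class].
#' @param sink file path or connection.
#' @return invisibly, the sink.
#' @export
writeCombinations <- function(designs, sink) {
  npart <- if (length(designs)) max(vapply(designs, function(d)
    length(d@parts), integer(1))) else 1L
  rows <- lapply(designs, function(d) {
    parts <- c(d@parts, rep("", npart - length(d@parts)))
    c(construct_name = d@construct_name, backbone = d@backbone,
      stats::setNames(parts, paste0("part_", seq_len(npart))),
      destination_well = d@destination_well)
  })
  out <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                       stringsAsFactors = FALSE)
  if (!length(designs))
    out <- as.data.frame(stats::setNames(
      rep(list(character()), npart + 3L),
      c("construct_name", "backbone", paste0("part_", seq_len(npart)),
        "destination_well")))
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(sink)
}

#' Read a colony-pick sheet from CSV
#'
#' Parses the pick dialect (`construct_name,template_well,primer_pair,
#' destination_well`). Sheets longer than 96 rows span several destination
#' plates (consecutive 96-row blocks in file order); destination wells
#' must be unique within each block.
#'
#' @param source file path or connection.
#' @return a [ColonyPickSheet-class].
#' @export
readColonyPicks <- function(source) {
  need <- c("construct_name", "template_well", "primer_pair",
            "destination_well")
  df <- readCsvStrict(source, need, "colony picks")
  keep <- nzchar(df$construct_name) | nzchar(df$template_well)
  df <- df[keep, , drop = FALSE]
  rows <- which(keep)
  seen <- character()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!isValidWell(r$template_well, "96-well"))
      parseError(sprintf("malformed template well '%s'", r$template_well),
                 row = rows[i])
    if (!isValidWell(r$destination_well, "96-well"))
      parseError(sprintf("malformed destination well '%s'",
                         r$destination_well), row = rows[i])
    key <- paste((i - 1L) %/% 96L, r$destination_well)
    if (key %in% seen)
      parseError(sprintf("duplicate destination PCR well '%s'",
                         r$destination_well), row = rows[i])
    seen <- c(seen, key)
  }
  rownames(df) <- NULL
  ColonyPickSheet(df[, need, drop = FALSE])
}

#' Write a colony-pick sheet to CSV
#'
#' @param sheet a [ColonyPickSheet-class].
#' @param sink file path or connection.
#' @return invisibly, the sink.
#' @export
writeColonyPicks <- function(sheet, sink) {
  stopifnot(is(sheet, "ColonyPickSheet"))
  utils::write.csv(sheet@entries, sink, row.names = FALSE, quote = FALSE)
  invisible(sink)
}
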