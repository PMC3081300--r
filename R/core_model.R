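# Core data model: long-format tables for indicator observations, reference
# states, indicator metadata and spatial units, with validation, CSV/JSON
# readers/writers and the documentation-flag (delta) lattice.

# Separator used to build composite cell keys; chosen so it can never occur in
# user-supplied identifiers read from CSV/JSON text fields.
.CELL_SEP <- "\x1f"

.SOURCE_LEVELS <- c("monitoring", "model", "expert")
.KIND_LEVELS <- c("continuous", "discrete")
.REF_TAGS <- c("carrying_capacity", "max_sustainable", "past_knowledge",
               "precautionary", "pristine", "best_index", "traditional")
.SCALING_MODELS <- c("optimal", "minimal", "maximal")

#' Composite cell identifier
#'
#' Builds the canonical key for an (indicator, ecosystem, unit, date) cell.
#' Used internally to align simulation matrices, weight tables and records.
#'
#' @param indicator_id,ecosystem_id,unit_id,date vectors, recycled.
#' @return character vector of keys.
#' @keywords internal
cell_id <- function(indicator_id, ecosystem_id, unit_id, date) {
  paste(indicator_id, ecosystem_id, unit_id, date, sep = .CELL_SEP)
}

.cell_label <- function(indicator_id, ecosystem_id, unit_id, date) {
  sprintf("(indicator=%s, ecosystem=%s, unit=%s, date=%s)",
          indicator_id, ecosystem_id, unit_id, date)
}

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Assemble and validate a Nature Index dataset
#'
#' Bundles the four long-format input tables into a validated dataset object.
#' All cross-table referential-integrity checks run here: every observation
#' must have a reference state and indicator metadata, quartiles must be
#' ordered, all values non-negative, reference values positive, ecosystem
#' membership fractions must sum to one per indicator, and rows sharing a
#' `duplication_group` must carry identical elicited values (they represent a
#' single expert elicitation copied to several localities).
#'
#' @param records data frame of observations, one row per documented
#'   (indicator, ecosystem, unit, date) cell, with columns `indicator_id`,
#'   `ecosystem_id`, `unit_id`, `date` (integer year), `mean_value`, `q25`,
#'   `q75` (non-negative, in the indicator's natural units), `source`
#'   (`monitoring`/`model`/`expert`), `variable_kind`
#'   (`continuous`/`discrete`) and optional `duplication_group`.
#' @param references data frame with one row per (indicator, ecosystem,
#'   unit): `ref_value` (> 0), `definition_tag` (operational definition of
#'   the reference state) and `scaling_model`
#'   (`optimal`/`minimal`/`maximal`). A reference applies to every date.
#' @param meta indicator metadata, one row per (indicator, ecosystem) pair
#'   with positive membership: `membership` (fraction in \[0, 1\], summing
#'   to 1 over ecosystems for each indicator), `group_id` (trophic or
#'   functional group) and logical `extra_representative`.
#' @param units spatial units, one row per (unit, ecosystem): `total_area`
#'   (> 0, km^2) and `ecosystem_area` (>= 0, <= total area).
#' @param dates optional integer vector of study dates; defaults to the
#'   dates present in `records`.
#' @return an object of class `ni_dataset`: a list with elements `records`,
#'   `references`, `meta`, `units` and `dates`.
#' @examples
#' ds <- generate_dataset(ni_generator_config(n_units = 2, n_indicators = 3,
#'                                            seed = 1))$dataset
#' ds
#' @export
ni_dataset <- function(records, references, meta, units, dates = NULL) {
  records <- as.data.frame(records)
  references <- as.data.frame(references)
  meta <- as.data.frame(meta)
  units <- as.data.frame(units)

  .need_cols(records, c("indicator_id", "ecosystem_id", "unit_id", "date",
                        "mean_value", "q25", "q75", "source",
                        "variable_kind"), "records")
  .need_cols(references, c("indicator_id", "ecosystem_id", "unit_id",
                           "ref_value", "definition_tag", "scaling_model"),
             "references")
  .need_cols(meta, c("indicator_id", "ecosystem_id", "membership",
                     "group_id", "extra_representative"), "meta")
  .need_cols(units, c("unit_id", "ecosystem_id", "total_area",
                      "ecosystem_area"), "units")
  if (is.null(records$duplication_group))
    records$duplication_group <- rep(NA_character_, nrow(records))
  records$duplication_group[!is.na(records$duplication_group) &
                              records$duplication_group == ""] <- NA_character_
  records$date <- as.integer(records$date)
  for (cc in c("mean_value", "q25", "q75"))
    records[[cc]] <- as.numeric(records[[cc]])
  references$ref_value <- as.numeric(references$ref_value)
  meta$membership <- as.numeric(meta$membership)
  meta$extra_representative <- as.logical(meta$extra_representative)
  units$total_area <- as.numeric(units$total_area)
  units$ecosystem_area <- as.numeric(units$ecosystem_area)

  lab <- function(r) .cell_label(r$indicator_id, r$ecosystem_id, r$unit_id,
                                 r$date)
  if (nrow(records)) {
    bad <- which(!records$source %in% .SOURCE_LEVELS)
    if (length(bad))
      stop("unknown source tag(s): ",
           paste(unique(records$source[bad]), collapse = ", "), call. = FALSE)
    bad <- which(!records$variable_kind %in% .KIND_LEVELS)
    if (length(bad))
      stop("unknown variable_kind: ",
           paste(unique(records$variable_kind[bad]), collapse = ", "),
           call. = FALSE)
    vals <- c(records$mean_value, records$q25, records$q75)
    if (any(!is.finite(vals)) || any(vals < 0)) {
      i <- which(records$mean_value < 0 | records$q25 < 0 | records$q75 < 0 |
                   !is.finite(records$mean_value) | !is.finite(records$q25) |
                   !is.finite(records$q75))[1]
      stop("negative or non-finite observation value at ",
           lab(records[i, ]), call. = FALSE)
    }
    i <- which(records$q25 > records$q75)
    if (length(i))
      stop("q25 > q75 at ", lab(records[i[1], ]), call. = FALSE)
    ids <- cell_id(records$indicator_id, records$ecosystem_id,
                   records$unit_id, records$date)
    if (anyDuplicated(ids)) {
      i <- which(duplicated(ids))[1]
      stop("duplicate observation for cell ", lab(records[i, ]),
           call. = FALSE)
    }
  }

  if (any(!is.finite(references$ref_value) | references$ref_value <= 0))
    stop("reference values must be positive and finite", call. = FALSE)
  if (any(!references$scaling_model %in% .SCALING_MODELS))
    stop("unknown scaling_model in references", call. = FALSE)
  if (any(!references$definition_tag %in% .REF_TAGS))
    stop("unknown reference definition_tag: ",
         paste(setdiff(unique(references$definition_tag), .REF_TAGS),
               collapse = ", "), call. = FALSE)
  rkey <- paste(references$indicator_id, references$ecosystem_id,
                references$unit_id, sep = .CELL_SEP)
  if (anyDuplicated(rkey))
    stop("more than one reference state for one (indicator, ecosystem, unit)",
         call. = FALSE)

  if (any(meta$membership < 0 | meta$membership > 1))
    stop("membership fractions must lie in [0, 1]", call. = FALSE)
  msum <- tapply(meta$membership, meta$indicator_id, sum)
  off <- which(abs(msum - 1) > 1e-6)
  if (length(off))
    stop("ecosystem membership fractions do not sum to 1 for indicator(s): ",
         paste(names(msum)[off], collapse = ", "), call. = FALSE)
  if (any(!nzchar(meta$group_id)) || anyNA(meta$group_id))
    stop("every indicator needs a non-empty group_id", call. = FALSE)

  if (any(units$total_area <= 0))
    stop("unit total_area must be positive", call. = FALSE)
  if (any(units$ecosystem_area < 0))
    stop("ecosystem_area must be non-negative", call. = FALSE)
  if (any(units$ecosystem_area > units$total_area + 1e-9))
    stop("ecosystem_area exceeds total_area for unit ",
         units$unit_id[which(units$ecosystem_area >
                               units$total_area + 1e-9)[1]], call. = FALSE)
  ta <- tapply(units$total_area, units$unit_id, function(x)
    diff(range(x)))
  if (any(ta > 1e-9))
    stop("inconsistent total_area across rows of one unit", call. = FALSE)

  # cross-table integrity
  if (nrow(records)) {
    mr <- match(paste(records$indicator_id, records$ecosystem_id,
                      records$unit_id, sep = .CELL_SEP), rkey)
    if (anyNA(mr)) {
      i <- which(is.na(mr))[1]
      stop("missing reference state for documented cell ",
           lab(records[i, ]), call. = FALSE)
    }
    mkey <- paste(meta$indicator_id, meta$ecosystem_id, sep = .CELL_SEP)
    mm <- match(paste(records$indicator_id, records$ecosystem_id,
                      sep = .CELL_SEP), mkey)
    if (anyNA(mm) || any(meta$membership[mm] <= 0)) {
      i <- which(is.na(mm) | meta$membership[mm] <= 0)[1]
      stop("missing indicator metadata (ecosystem membership) for cell ",
           lab(records[i, ]), call. = FALSE)
    }
    if (any(!records$unit_id %in% units$unit_id))
      stop("record references unknown spatial unit: ",
           setdiff(records$unit_id, units$unit_id)[1], call. = FALSE)
    # one duplication group = one elicitation
    dg <- records$duplication_group
    for (g in unique(dg[!is.na(dg)])) {
      rows <- records[!is.na(dg) & dg == g, ]
      if (nrow(unique(rows[, c("indicator_id", "ecosystem_id", "date",
                               "mean_value", "q25", "q75",
                               "variable_kind")])) != 1L)
        stop("duplication_group '", g,
             "' mixes different elicited values; duplicated rows must be ",
             "identical copies of one elicitation", call. = FALSE)
    }
  }

  dates <- sort(unique(as.integer(c(dates, records$date))))
  structure(list(records = records, references = references, meta = meta,
                 units = units, dates = dates),
            class = "ni_dataset")
}

#' @export
print.ni_dataset <- function(x, ...) {
  cat("Nature Index dataset\n")
  cat(sprintf("  %d observations (%d indicators, %d ecosystems, %d units, dates %s)\n",
              nrow(x$records), length(unique(x$meta$indicator_id)),
              length(unique(x$meta$ecosystem_id)),
              length(unique(x$units$unit_id)),
              paste(x$dates, collapse = ", ")))
  src <- table(factor(x$records$source, .SOURCE_LEVELS))
  cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = " "),
      "\n")
  invisible(x)
}

#' Documentation flags over the full cell lattice
#'
#' Expands the lattice of all (indicator, ecosystem, unit, date) combinations
#' implied by the metadata and unit tables — indicator x ecosystem pairs with
#' positive membership, crossed with units where the ecosystem is present
#' (positive area) and with the study dates — and flags each cell with
#' delta = 1 if an observation exists and 0 otherwise. Undocumented cells
#' carry zero weight everywhere downstream: absence of data is interpreted as
#' "nothing reported", never as a zero observation.
#'
#' @param dataset an [ni_dataset()].
#' @param dates dates spanning the lattice; defaults to `dataset$dates`.
#' @return data frame with columns `indicator_id`, `ecosystem_id`,
#'   `unit_id`, `date`, `delta` (0/1).
#' @export
documentation_flags <- function(dataset, dates = dataset$dates) {
  stopifnot(inherits(dataset, "ni_dataset"))
  meta <- dataset$meta[dataset$meta$membership > 0, ]
  un <- dataset$units[dataset$units$ecosystem_area > 0, ]
  pairs <- merge(meta[, c("indicator_id", "ecosystem_id")],
                 un[, c("unit_id", "ecosystem_id")], by = "ecosystem_id")
  if (!nrow(pairs) || !length(dates)) {
    return(data.frame(indicator_id = character(), ecosystem_id = character(),
                      unit_id = character(), date = integer(),
                      delta = integer()))
  }
  lat <- merge(pairs, data.frame(date = as.integer(dates)))
  lat <- lat[order(lat$indicator_id, lat$ecosystem_id, lat$unit_id,
                   lat$date), c("indicator_id", "ecosystem_id", "unit_id",
                                "date")]
  rownames(lat) <- NULL
  rec_ids <- cell_id(dataset$records$indicator_id,
                     dataset$records$ecosystem_id,
                     dataset$records$unit_id, dataset$records$date)
  lat$delta <- as.integer(cell_id(lat$indicator_id, lat$ecosystem_id,
                                  lat$unit_id, lat$date) %in% rec_ids)
  lat
}

# ---------------------------------------------------------------------------
# Readers / writers.  CSV: four files records.csv / references.csv / meta.csv
# / units.csv in one directory.  JSON: a single document with four arrays.
# Numeric columns are serialized with 17 significant digits so a write/read
# round trip reproduces every double bit-identically.

.NUM_COLS <- list(records = c("mean_value", "q25", "q75"),
                  references = "ref_value",
                  meta = "membership",
                  units = c("total_area", "ecosystem_area"))

.fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[is.na(x)] <- NA_character_
  out
}

#' Read a Nature Index dataset
#'
#' Reads either a directory containing `records.csv`, `references.csv`,
#' `meta.csv` and `units.csv` (UTF-8, comma separated, `.` decimal) or a
#' single JSON file with arrays `records`, `references`, `meta`, `units`.
#' The assembled dataset passes through full [ni_dataset()] validation.
#'
#' @param path directory of CSV files, or path to a `.json` file.
#' @param schema optional named list renaming non-standard input columns,
#'   e.g. `list(records = c(mean_value = "mean"))` maps input column
#'   `"mean"` onto `mean_value`.
#' @return an `ni_dataset`.
#' @examples
#' # a small generated example study (3 ecosystems x 6 units x 4 dates,
#' # synthetic data; its ground truth sits alongside in truth.csv)
#' path <- system.file("extdata", "synthetic_example",
#'                     package = "natureindex")
#' read_ni(path)
#' @export
read_ni <- function(path, schema = NULL) {
  if (dir.exists(path)) {
    tabs <- lapply(c(records = "records", references = "references",
                     meta = "meta", units = "units"), function(nm) {
      f <- file.path(path, paste0(nm, ".csv"))
      if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
      utils::read.csv(f, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = "")
    })
  } else if (file.exists(path)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("records", "references", "meta", "units")
    if (!all(need %in% names(doc)))
      stop("JSON document must contain arrays: ",
           paste(need, collapse = ", "), call. = FALSE)
    tabs <- lapply(doc[need], as.data.frame)
  } else stop("no such file or directory: ", path, call. = FALSE)

  for (nm in names(schema)) {
    ren <- schema[[nm]]
    idx <- match(ren, names(tabs[[nm]]))
    names(tabs[[nm]])[idx[!is.na(idx)]] <- names(ren)[!is.na(idx)]
  }
  for (nm in names(.NUM_COLS))
    for (cc in intersect(.NUM_COLS[[nm]], names(tabs[[nm]])))
      tabs[[nm]][[cc]] <- as.numeric(tabs[[nm]][[cc]])
  if ("extra_representative" %in% names(tabs$meta))
    tabs$meta$extra_representative <-
      as.logical(toupper(as.character(tabs$meta$extra_representative)))
  ni_dataset(tabs$records, tabs$references, tabs$meta, tabs$units)
}

#' Write a Nature Index dataset
#'
#' Inverse of [read_ni()]: writes the four tables either as CSV files into a
#' directory or as one JSON document, preserving doubles to full precision so
#' that `read_ni(write_ni(ds, path))` reproduces every field exactly.
#'
#' @param dataset an `ni_dataset`.
#' @param path target directory (CSV) or file path ending in `.json`.
#' @param format `"csv"` or `"json"`; guessed from `path` by default.
#' @return `path`, invisibly.
#' @export
write_ni <- function(dataset, path,
                     format = if (grepl("\\.json$", path)) "json" else "csv") {
  stopifnot(inherits(dataset, "ni_dataset"))
  format <- match.arg(format, c("csv", "json"))
  tabs <- dataset[c("records", "references", "meta", "units")]
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tabs)) {
      tb <- tabs[[nm]]
      for (cc in intersect(.NUM_COLS[[nm]], names(tb)))
        tb[[cc]] <- .fmt_num(tb[[cc]])
      utils::write.csv(tb, file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    }
  } else {
    jsonlite::write_json(tabs, path, dataframe = "rows", digits = I(17),
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}
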