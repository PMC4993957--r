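#' Canonical medium component names
#'
#' The nine medium components optimized for flavonoid production by
#' *Phellinus igniarius*, in the fixed canonical order used throughout the
#' package: glucose, maltose, mannitol, corn powder, yeast extract, cupric
#' sulfate, sodium chloride, ferrous sulfate, vitamin B1. All chromosomes,
#' bound boxes and dataset columns index components in this order.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' medium_components()
medium_components <- function() {
  c("glucose", "maltose", "mannitol", "corn_powder", "yeast",
    "cupric_sulfate", "sodium_chloride", "ferrous_sulfate", "vitamin_b1")
}

# short CSV headers <-> canonical names (header order = canonical order)
.ferm_headers <- c(
  glucose = "Glu", maltose = "Mal", mannitol = "Mann", corn_powder = "CP",
  yeast = "Yeast", cupric_sulfate = "CS", sodium_chloride = "SC",
  ferrous_sulfate = "FS", vitamin_b1 = "VB1", total_flavonoids = "TF"
)

.target_column <- "total_flavonoids"

.all_columns <- function(has_target = TRUE) {
  if (has_target) c(medium_components(), .target_column) else medium_components()
}

#' Validate a fermentation dataset
#'
#' Checks the structural invariants of a condition-to-yield table: all nine
#' component columns present in canonical order, all concentrations
#' non-negative and finite, and (if present) strictly positive total
#' flavonoid yields.
#'
#' @param data A data.frame of fermentation records.
#' @param has_target Logical; require the `total_flavonoids` column.
#' @return `data`, invisibly, with columns reordered canonically.
#' @export
validate_dataset <- function(data, has_target = "total_flavonoids" %in% names(data)) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame of fermentation records")
  if (nrow(data) < 1L) stop("dataset must contain at least one record")
  wanted <- .all_columns(has_target)
  missing <- setdiff(wanted, names(data))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in wanted) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not numeric")
    if (anyNA(v) || any(!is.finite(v))) stop("column '", col, "' contains missing or non-finite values")
  }
  comp <- as.matrix(data[medium_components()])
  if (any(comp < 0)) stop("negative concentration found; all component concentrations must be >= 0")
  if (has_target && any(data[[.target_column]] <= 0)) {
    stop("total_flavonoids must be > 0 for every labeled record")
  }
  invisible(data[, wanted, drop = FALSE])
}

# map raw CSV headers (short or canonical) onto canonical names;
# errors name every unrecognized / missing column
.map_headers <- function(headers, has_target) {
  wanted <- .all_columns(has_target)
  short <- .ferm_headers[wanted]
  mapped <- character(length(headers))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (h %in% wanted) {
      mapped[i] <- h
    } else {
      hit <- names(.ferm_headers)[match(toupper(h), toupper(.ferm_headers))]
      if (is.na(hit) || !(hit %in% wanted)) {
        stop("unrecognized column '", h, "'; expected columns: ",
             paste(short, collapse = ", "))
      }
      mapped[i] <- hit
    }
  }
  if (anyDuplicated(mapped)) stop("duplicated column(s): ",
                                  paste(unique(mapped[duplicated(mapped)]), collapse = ", "))
  missing <- setdiff(wanted, mapped)
  if (length(missing)) {
    stop("missing required column(s): ", paste(.ferm_headers[missing], collapse = ", "))
  }
  mapped
}

#' Load a fermentation condition table from CSV
#'
#' Reads a comma-separated table with one row per fermentation experiment.
#' The header must name the nine component columns (either the short forms
#' `Glu, Mal, Mann, CP, Yeast, CS, SC, FS, VB1` or the canonical long names)
#' plus, when `has_target = TRUE`, the yield column `TF` /
#' `total_flavonoids` in micrograms per milliliter. Parsing uses the `.`
#' decimal separator regardless of locale. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param has_target Logical; whether a yield column is required (default
#'   `TRUE`). When `FALSE` a present yield column is an error.
#' @param provenance Optional free-text provenance tag attached to the
#'   result as attribute `"provenance"`.
#' @return A data.frame with canonical column names in canonical order.
#' @export
load_dataset <- function(path, has_target = TRUE, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) < 1L) stop("dataset must contain at least one record")
  mapped <- .map_headers(names(raw), has_target)
  names(raw) <- mapped
  out <- raw[, .all_columns(has_target), drop = FALSE]
  for (col in names(out)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric value '", out[[col]][bad[1]], "' in column '",
           .ferm_headers[[col]], "', row ", bad[1])
    }
    out[[col]] <- v
  }
  rownames(out) <- NULL
  out <- validate_dataset(out, has_target)
  attr(out, "provenance") <- provenance
  out
}

#' Write a fermentation condition table to CSV
#'
#' Inverse of [load_dataset()]: writes the short canonical header
#' (`Glu,...,TF`) and the values as R's shortest exact decimal strings, so
#' that a write/re-load round trip reproduces the numeric values exactly.
#'
#' @param data A validated fermentation data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  out <- data
  for (col in names(out)) out[[col]] <- as.character(out[[col]])
  names(out) <- .ferm_headers[names(data)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "fermga")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)
  p
}

#' Packaged training table: 25 measured fermentation conditions
#'
#' The 25 condition-to-yield records used to train the surrogate: nine
#' component concentrations per record plus the measured total flavonoid
#' yield (740--1610 ug/mL). The rows were selected from a large shake-flask
#' screening campaign as the best-producing conditions. Values are stored
#' exactly as published, with scientific-notation yields expanded to plain
#' numbers (e.g. 1.52E+03 -> 1520). Concentration columns are treated as
#' unitless "values as printed": the published unit labels are mutually
#' inconsistent between the table, the search bounds and the summary text,
#' and min-max scaling makes the surrogate invariant to the choice.
#'
#' @return A 25-row data.frame with canonical columns and a `"provenance"`
#'   attribute.
#' @export
#' @examples
#' d <- table1_fixture()
#' nrow(d)
#' range(d$total_flavonoids)
table1_fixture <- function() {
  d <- load_dataset(.fixture_path("table1_conditions.csv"), has_target = TRUE,
                    provenance = paste(
                      "25 best-producing shake-flask fermentation conditions;",
                      "concentrations as printed (unit labels inconsistent in source),",
                      "yields in ug/mL"))
  d
}

#' Packaged optimized-condition table: 10 reported GA optima
#'
#' The 10 published optimized fermentation conditions with their
#' surrogate-predicted flavonoid yields (~2200 ug/mL). Column headers are
#' preserved exactly as printed. Note a documented anomaly: the printed
#' `SC` (sodium chloride) column holds values 0.22--0.55 and the printed
#' `FS` (ferrous sulfate) column holds 9.74--9.99, i.e. the two columns
#' appear swapped relative to the stated search bounds (NaCl 0--10,
#' FeSO4 0--0.5) and to the published per-component averages. The fixture
#' keeps the printed headers; interpretation is left to the caller. The
#' printed VB1 values (~1.0--1.11) also exceed the stated VB1 bound (0--0.1).
#'
#' @return A 10-row data.frame with canonical columns and a `"provenance"`
#'   attribute.
#' @export
#' @examples
#' table2_fixture()$total_flavonoids
table2_fixture <- function() {
  load_dataset(.fixture_path("table2_optimized.csv"), has_target = TRUE,
               provenance = paste(
                 "10 published GA-optimized conditions; printed SC/FS columns",
                 "appear swapped vs the stated NaCl/FeSO4 bounds; VB1 values",
                 "exceed the stated 0-0.1 bound; yields are surrogate",
                 "predictions in ug/mL, not wet-lab measurements"))
}

#' Published per-component averages for the optimized conditions
#'
#' The per-component averages quoted in the source publication's results
#' text for the 10 optimized conditions, keyed by canonical column name
#' (with the sodium-chloride / ferrous-sulfate values attached to the
#' components the text names, not to the anomalous printed table headers).
#' Four of them (corn powder, yeast, cupric sulfate, vitamin B1) are not
#' arithmetically consistent with the printed table cells under any
#' rounding; [summarize_results()] can flag these discrepancies.
#'
#' @return Named numeric vector over the nine components plus
#'   `total_flavonoids`.
#' @export
table2_reported_means <- function() {
  c(glucose = 15.1, maltose = 15.264, mannitol = 29.83, corn_powder = 5.23,
    yeast = 5.14, cupric_sulfate = 0.18, sodium_chloride = 9.89,
    ferrous_sulfate = 0.3, vitamin_b1 = 1.03, total_flavonoids = 2200)
}

#' Per-column arithmetic means
#'
#' Exact arithmetic mean of every column of a fermentation dataset. No
#' rounding is applied; presentation rounding is the caller's concern.
#' Row order is irrelevant.
#'
#' @param data A fermentation data.frame.
#' @return Named numeric vector of column means.
#' @export
#' @examples
#' column_means(table2_fixture())[["maltose"]]  # 15.264
column_means <- function(data) {
  data <- validate_dataset(data)
  colMeans(as.matrix(data))
}
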