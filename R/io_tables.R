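# Readers/writers for the five table kinds: plate series, plate maps,
# host-range matrices, antibiograms, breakpoint tables. All delimited text
# (comma or tab, auto-detected on read, chosen by extension on write:
# .csv => comma, anything else => tab), UTF-8, LF, deterministic row order.

CALL_LEVELS <- c("no_lysis", "reduced_growth", "lysis")

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_table_auto <- function(path) {
  readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    na = c("", "NA"))
}

write_delim_auto <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(x, path, delim = delim, na = "NA", eol = "\n",
                     progress = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# ---- plate series + map -----------------------------------------------------

#' Validate a plate map
#'
#' Checks the well-annotation invariants: control wells have no phage and
#' no MOI; infected wells have both; replicate numbers are positive
#' integers.
#'
#' @param map Data frame with columns `well`, `strain`, `phage`, `moi`,
#'   `replicate`, `role` (`role` one of `"control"`, `"infected"`).
#' @return The map, invisibly, as a tibble.
#' @export
validate_plate_map <- function(map) {
  require_columns(map, c("well", "strain", "phage", "moi", "replicate", "role"),
                  "plate map")
  map <- tibble::as_tibble(map)
  if (anyDuplicated(map$well)) {
    abort_validation(sprintf(
      "duplicate well id(s) in plate map: %s",
      paste(unique(map$well[duplicated(map$well)]), collapse = ", ")))
  }
  bad_role <- !map$role %in% c("control", "infected")
  if (any(bad_role)) {
    abort_validation(sprintf("unknown role for well(s): %s",
                             paste(map$well[bad_role], collapse = ", ")))
  }
  ctrl <- map$role == "control"
  bad <- (ctrl & (!is.na(map$phage) | !is.na(map$moi))) |
    (!ctrl & (is.na(map$phage) | is.na(map$moi)))
  if (any(bad)) {
    abort_validation(sprintf(
      "well(s) violate control/infected annotation rules (control <=> no phage, no MOI): %s",
      paste(map$well[bad], collapse = ", ")))
  }
  if (any(!is.na(map$moi) & map$moi <= 0)) {
    abort_validation("MOI must be positive for infected wells.")
  }
  if (any(is.na(map$replicate) | map$replicate < 1 |
            map$replicate != round(map$replicate))) {
    abort_validation("replicate must be an integer >= 1 for every well.")
  }
  invisible(map)
}

#' Read a plate-reader series and its plate map
#'
#' Reads a long-format plate-reader export (one row per well and time
#' point) together with a plate map assigning each well to a strain,
#' phage, MOI, replicate and role. Comma- and tab-delimited files are
#' accepted interchangeably.
#'
#' @param series_path Path to the series table; columns `time_h` (hours),
#'   `well`, `od600`.
#' @param map_path Path to the plate map; columns `well`, `strain`,
#'   `phage`, `moi`, `replicate`, `role`. `phage`/`moi` are `NA` for
#'   control wells.
#' @return A `plate_data` object: a list with tibbles `series` and `map`.
#'   Every well in the series must appear in the map.
#' @export
#' @examples
#' sim <- simulate_plate(
#'   tibble::tibble(phage = "P1", strain = "S1", truth = "lysis"),
#'   seed = 1)
#' f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
#' write_plate(sim, f1, f2)
#' plate <- read_plate(f1, f2)
#' plate$map
read_plate <- function(series_path, map_path) {
  series <- read_table_auto(series_path)
  require_columns(series, c("time_h", "well", "od600"), "plate series")
  map <- read_table_auto(map_path)
  map$phage <- as.character(map$phage)
  map$strain <- as.character(map$strain)
  map$well <- as.character(map$well)
  series$well <- as.character(series$well)
  plate_data(series, map)
}

#' Assemble plate data from in-memory tables
#'
#' @param series Tibble with columns `time_h`, `well`, `od600`.
#' @param map Tibble with the plate-map columns (see [read_plate()]).
#' @return A `plate_data` object.
#' @export
plate_data <- function(series, map) {
  require_columns(series, c("time_h", "well", "od600"), "plate series")
  map <- validate_plate_map(map)
  series <- tibble::as_tibble(series)[, c("time_h", "well", "od600")]
  unmapped <- setdiff(unique(series$well), map$well)
  if (length(unmapped) > 0) {
    abort_validation(sprintf("well(s) present in series but absent from map: %s",
                             paste(unmapped, collapse = ", ")))
  }
  # per-well monotonicity check (also catches duplicate time stamps)
  split_series <- split(series, series$well)
  for (w in names(split_series)) {
    tt <- split_series[[w]]$time_h
    if (any(diff(tt) <= 0)) {
      abort_data(sprintf("non-monotone or duplicated times in well '%s'.", w))
    }
  }
  if (any(series$od600 < 0, na.rm = TRUE)) {
    abort_validation("negative OD600 values in series.")
  }
  structure(list(series = series, map = map), class = "plate_data")
}

#' @export
print.plate_data <- function(x, ...) {
  cat(sprintf("<plate_data> %d wells, %d strains, %d phages, %d time points\n",
              length(unique(x$series$well)),
              length(unique(x$map$strain)),
              length(unique(stats::na.omit(x$map$phage))),
              length(unique(x$series$time_h))))
  invisible(x)
}

#' Extract growth curves from plate data
#'
#' @param plate A `plate_data` object.
#' @return Named list of [growth_curve()] objects, one per well.
#' @export
plate_curves <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  purrr::map(split(plate$series, plate$series$well), function(df) {
    growth_curve(df$time_h, df$od600, well_id = df$well[1])
  })
}

#' Write plate data to delimited files
#'
#' @param plate A `plate_data` object.
#' @param series_path,map_path Output paths (`.csv` writes commas,
#'   otherwise tabs).
#' @return Invisibly, the plate.
#' @export
write_plate <- function(plate, series_path, map_path) {
  stopifnot(inherits(plate, "plate_data"))
  write_delim_auto(plate$series, series_path)
  write_delim_auto(plate$map, map_path)
  invisible(plate)
}

# ---- host-range matrices ----------------------------------------------------

decode_calls <- function(x, assay) {
  x_chr <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    x_chr,
    c("0", "no_lysis") ~ "no_lysis",
    c("1", "reduced_growth") ~ "reduced_growth",
    c("2", "lysis") ~ "lysis",
    NA ~ NA_character_
  )
  bad <- !is.na(x_chr) & is.na(out)
  if (any(bad)) {
    abort_format(sprintf("unknown host-range call token(s): %s",
                         paste(unique(x_chr[bad]), collapse = ", ")))
  }
  if (assay == "PKA" && any(out == "reduced_growth", na.rm = TRUE)) {
    abort_validation("PKA matrices cannot contain 'reduced_growth' calls.")
  }
  out
}

#' Construct a host-range matrix
#'
#' A phages-by-strains grid of susceptibility calls. DPA (plaque assay)
#' matrices use three levels (`no_lysis`, `reduced_growth`, `lysis`); PKA
#' (planktonic killing assay) matrices use two (`no_lysis`, `lysis`).
#' Missing cells (`NA`) are excluded from every count and denominator.
#'
#' @param calls Character matrix (rows = strains, columns = phages) of
#'   call tokens, or integer codes 0/1/2. Row and column names are the
#'   strain and phage names.
#' @param assay `"DPA"` or `"PKA"`.
#' @param strain_meta Optional named character vector mapping strain name
#'   to an infection category (wound, urinary tract, ...).
#' @return A `host_range_matrix` object.
#' @export
#' @examples
#' m <- host_range_matrix(
#'   matrix(c("lysis", "no_lysis", "lysis", "lysis"), nrow = 2,
#'          dimnames = list(c("S1", "S2"), c("P1", "P2"))),
#'   assay = "DPA")
#' coverage_summary(m)
host_range_matrix <- function(calls, assay = c("DPA", "PKA"),
                              strain_meta = NULL) {
  assay <- match.arg(assay)
  if (!is.matrix(calls)) abort_validation("`calls` must be a matrix.")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort_validation("`calls` must carry strain rownames and phage colnames.")
  }
  if (anyDuplicated(rownames(calls))) {
    abort_validation("duplicate strain names in host-range matrix.")
  }
  if (anyDuplicated(colnames(calls))) {
    abort_validation("duplicate phage names in host-range matrix.")
  }
  decoded <- matrix(decode_calls(calls, assay), nrow = nrow(calls),
                    dimnames = dimnames(calls))
  if (!is.null(strain_meta)) {
    strain_meta <- strain_meta[intersect(names(strain_meta), rownames(calls))]
  }
  structure(list(calls = decoded, assay = assay, strain_meta = strain_meta),
            class = "host_range_matrix")
}

#' @export
print.host_range_matrix <- function(x, ...) {
  n_na <- sum(is.na(x$calls))
  cat(sprintf("<host_range_matrix> %s: %d strains x %d phages%s\n",
              x$assay, nrow(x$calls), ncol(x$calls),
              if (n_na > 0) sprintf(" (%d missing cells)", n_na) else ""))
  tab <- table(factor(x$calls, levels = CALL_LEVELS))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.host_range_matrix <- function(x, ...) {
  tibble::tibble(
    strain = rep(rownames(x$calls), times = ncol(x$calls)),
    phage = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.vector(x$calls)
  )
}

#' Build a host-range matrix from a long call table
#'
#' @param df Data frame with columns `strain`, `phage`, `call`.
#' @inheritParams host_range_matrix
#' @return A `host_range_matrix`.
#' @export
as_host_range_matrix <- function(df, assay = c("DPA", "PKA"),
                                 strain_meta = NULL) {
  require_columns(df, c("strain", "phage", "call"), "host-range call table")
  strains <- unique(df$strain)
  phages <- unique(df$phage)
  m <- matrix(NA_character_, nrow = length(strains), ncol = length(phages),
              dimnames = list(strains, phages))
  dup <- duplicated(df[, c("strain", "phage")])
  if (any(dup)) abort_validation("duplicate (strain, phage) pairs in call table.")
  m[cbind(match(df$strain, strains), match(df$phage, phages))] <-
    as.character(df$call)
  host_range_matrix(m, assay = assay, strain_meta = strain_meta)
}

#' Read a host-range matrix from a delimited file
#'
#' First column holds strain names; remaining columns are phages. Cells
#' may be integer codes (0 = no lysis, 1 = reduced growth, 2 = lysis) or
#' text tokens, case-insensitively; `NA` marks untested cells.
#'
#' @param path Path to a CSV/TSV file.
#' @inheritParams host_range_matrix
#' @return A `host_range_matrix`.
#' @export
read_host_range <- function(path, assay = c("DPA", "PKA"),
                            strain_meta = NULL) {
  assay <- match.arg(assay)
  df <- read_table_auto(path)
  if (ncol(df) < 2) abort_format("host-range table needs a strain column and at least one phage column.")
  strains <- as.character(df[[1]])
  if (anyDuplicated(strains)) {
    abort_validation(sprintf(
      "duplicate strain row(s) in host-range table: %s",
      paste(unique(strains[duplicated(strains)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- strains
  host_range_matrix(m, assay = assay, strain_meta = strain_meta)
}

#' Write a host-range matrix
#'
#' Canonical encoding: lowercase snake_case text tokens, strains and
#' phages in stored order, `NA` for missing cells.
#'
#' @param x A `host_range_matrix`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_host_range <- function(x, path) {
  stopifnot(inherits(x, "host_range_matrix"))
  df <- tibble::as_tibble(x$calls, rownames = "strain")
  write_delim_auto(df, path)
  invisible(x)
}

# ---- antibiograms and breakpoints -------------------------------------------

#' Read an antibiogram table
#'
#' Long format: one row per strain and antibiotic, zone diameter of the
#' disc-diffusion inhibition zone in millimetres.
#'
#' @param path Path to a CSV/TSV with columns `strain`, `antibiotic`,
#'   `zone_mm`.
#' @return Tibble with those columns, validated (0 <= zone <= 60 mm).
#' @export
read_antibiogram <- function(path) {
  df <- read_table_auto(path)
  validate_antibiogram(df)
}

#' Validate an antibiogram table
#'
#' @param df Data frame with columns `strain`, `antibiotic`, `zone_mm`.
#' @return The validated tibble.
#' @export
validate_antibiogram <- function(df) {
  require_columns(df, c("strain", "antibiotic", "zone_mm"), "antibiogram")
  df <- tibble::as_tibble(df)
  if (any(is.na(df$zone_mm)) || any(df$zone_mm < 0) || any(df$zone_mm > 60)) {
    abort_validation("zone diameters must be between 0 and 60 mm.")
  }
  if (anyDuplicated(df[, c("strain", "antibiotic")])) {
    abort_validation("duplicate (strain, antibiotic) rows in antibiogram.")
  }
  df
}

#' Read a breakpoint table
#'
#' Zone-diameter breakpoints in the EUCAST style: a strain is susceptible
#' (S) when the zone is at least `s_min_mm`, resistant (R) when it is
#' below `r_max_mm`, intermediate otherwise. `lead` flags the lead
#' substance of each antibiotic class used for MRGN classification.
#'
#' @param path Path to a CSV/TSV with columns `antibiotic`, `abx_class`,
#'   `lead`, `s_min_mm`, `r_max_mm`.
#' @return Validated tibble.
#' @export
read_breakpoints <- function(path) {
  df <- read_table_auto(path)
  validate_breakpoints(df)
}

#' Validate a breakpoint table
#'
#' @param df Data frame with the breakpoint columns (see
#'   [read_breakpoints()]).
#' @return The validated tibble, `lead` coerced to logical.
#' @export
validate_breakpoints <- function(df) {
  require_columns(df, c("antibiotic", "abx_class", "lead", "s_min_mm", "r_max_mm"),
                  "breakpoint table")
  df <- tibble::as_tibble(df)
  df$lead <- as.logical(df$lead)
  if (any(df$s_min_mm < df$r_max_mm)) {
    abort_validation("breakpoints inverted: s_min_mm must be >= r_max_mm.")
  }
  leads_per_class <- df |>
    dplyr::filter(.data$lead) |>
    dplyr::count(.data$abx_class)
  if (any(leads_per_class$n > 1)) {
    abort_validation("at most one lead substance per antibiotic class.")
  }
  if (anyDuplicated(df$antibiotic)) {
    abort_validation("duplicate antibiotic rows in breakpoint table.")
  }
  df
}

#' Write an antibiogram / breakpoint table
#'
#' @param df The validated tibble.
#' @param path Output path.
#' @return Invisibly, `df`.
#' @export
write_antibiogram <- function(df, path) {
  write_delim_auto(validate_antibiogram(df), path)
  invisible(df)
}

#' @rdname write_antibiogram
#' @export
write_breakpoints <- function(df, path) {
  write_delim_auto(validate_breakpoints(df), path)
  invisible(df)
}

#' Bundled synthetic breakpoint table
#'
#' A small, synthetic EUCAST-style zone-diameter breakpoint table for
#' Pseudomonas aeruginosa-like panels, covering the four MRGN lead
#' substances (piperacillin, ceftazidime, meropenem, ciprofloxacin) plus
#' two combination agents. The diameters are plausible illustration
#' values, not any official breakpoint release; real analyses must supply
#' the versioned EUCAST table in use.
#'
#' @return Validated breakpoint tibble.
#' @export
synthetic_breakpoints <- function() {
  read_breakpoints(system.file("extdata", "breakpoints_synthetic.tsv",
                               package = "phagekit", mustWork = TRUE))
}
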