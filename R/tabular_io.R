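## CSV schemas shared by every pipeline stage. All files are comma-separated
## UTF-8 with a required header row, `.` decimal mark, scientific notation
## accepted. Column names are fixed snake_case identifiers matched
## case-insensitively on read. Reading is all-or-nothing: any malformed cell
## or violated invariant aborts before anything is returned.

mnp_schemas <- list(
  conditions = list(
    required = c("mwco_kda", "time_min", "force_g", "z_ave_nm",
                 "count_rate_kcps", "pdi", "zeta_mv", "conductivity"),
    optional = character(),
    character_cols = character()
  ),
  titration = list(
    required = c("q_mol_per_l", "intensity"),
    optional = character(),
    character_cols = character()
  ),
  energy_frames = list(
    required = c("frame", "vdw", "ele", "gb", "surf"),
    optional = "internal",
    character_cols = character()
  ),
  sweep = list(
    required = c("x", "z_ave_nm"),
    optional = "count_rate_kcps",
    character_cols = character()
  ),
  composition = list(
    required = c("component", "group", "mean", "sd", "n"),
    optional = character(),
    character_cols = c("component", "group")
  )
)

# Read one of the five schemas: header check, case-insensitive column
# matching, per-cell numeric validation with row index in the error.
read_schema <- function(path, schema_name) {
  schema <- mnp_schemas[[schema_name]]
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  missing <- setdiff(schema$required, names(raw))
  if (length(missing)) {
    stop_input("%s: missing required column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  keep <- intersect(c(schema$required, schema$optional), names(raw))
  out <- raw[, keep, drop = FALSE]
  for (col in setdiff(keep, schema$character_cols)) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad) == 0L) bad <- which(is.na(vals))
    if (any(is.na(vals))) {
      stop_input("%s: non-numeric or missing value in column '%s' at data row %d",
                 path, col, bad[1L])
    }
    out[[col]] <- vals
  }
  out
}

# Write full double precision so read(write(x)) is the identity to < 1e-12.
write_schema <- function(df, path, schema_name) {
  schema <- mnp_schemas[[schema_name]]
  missing <- setdiff(schema$required, names(df))
  if (length(missing)) {
    stop_input("cannot write %s table: missing column(s) %s",
               schema_name, paste(missing, collapse = ", "))
  }
  keep <- intersect(c(schema$required, schema$optional), names(df))
  df <- df[, keep, drop = FALSE]
  for (col in setdiff(keep, schema$character_cols)) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_condition_table <- function(df, context = "condition table") {
  if (nrow(df) == 0L) stop_input("%s: no data rows", context)
  pos_cols <- c("mwco_kda", "time_min", "force_g", "z_ave_nm",
                "count_rate_kcps", "conductivity")
  for (col in pos_cols) {
    if (any(df[[col]] <= 0)) {
      stop_input("%s: column '%s' must be strictly positive (row %d)",
                 context, col, which(df[[col]] <= 0)[1L])
    }
  }
  if (any(df$pdi < 0 | df$pdi > 1)) {
    stop_input("%s: pdi must lie in [0, 1] (row %d)",
               context, which(df$pdi < 0 | df$pdi > 1)[1L])
  }
  key <- paste(df$mwco_kda, df$time_min, df$force_g)
  if (anyDuplicated(key)) {
    stop_input("%s: duplicate (mwco_kda, time_min, force_g) triple at row %d",
               context, anyDuplicated(key))
  }
  df
}

#' Read a separation-condition measurement table
#'
#' One row per separation condition (ultrafiltration membrane cut-off x
#' centrifugation time x centrifugal force) with its dynamic light scattering
#' read-outs. Columns: `mwco_kda`, `time_min`, `force_g`, `z_ave_nm`,
#' `count_rate_kcps`, `pdi`, `zeta_mv`, `conductivity`. Sizes, rates and
#' conductivities must be strictly positive, `pdi` must lie in `[0, 1]`, the
#' zeta potential may be negative, and the condition triple must be unique.
#' Reading is all-or-nothing: a schema or validation failure loads nothing.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with the eight schema columns, row order preserved.
#' @seealso [write_condition_table()], [gen_condition_table()], [run_topsis()]
#' @export
read_condition_table <- function(path) {
  validate_condition_table(read_schema(path, "conditions"), context = path)
}

#' @rdname read_condition_table
#' @param df A condition table, e.g. from [gen_condition_table()].
#' @export
write_condition_table <- function(df, path) {
  validate_condition_table(df)
  write_schema(df, path, "conditions")
}

#' Read or write a fluorescence titration table
#'
#' Columns `q_mol_per_l` (quencher concentration, mol/L, strictly increasing)
#' and `intensity` (fluorescence, arbitrary units, positive). The
#' quencher-free intensity F0 is not part of the file; it accompanies the
#' series separately (see [titration_series()]).
#'
#' @param path Path to a CSV file.
#' @return `read_titration_table()` returns a two-column `data.frame`.
#' @export
read_titration_table <- function(path) {
  df <- read_schema(path, "titration")
  if (nrow(df) < 2L) stop_input("%s: titration needs at least 2 rows", path)
  if (any(diff(df$q_mol_per_l) <= 0)) {
    stop_input("%s: q_mol_per_l must be strictly increasing", path)
  }
  if (any(df$intensity <= 0)) {
    stop_input("%s: intensity must be strictly positive", path)
  }
  df
}

#' @rdname read_titration_table
#' @param df A titration table.
#' @export
write_titration_table <- function(df, path) write_schema(df, path, "titration")

#' Read or write a per-frame MM/GBSA component-energy table
#'
#' Columns `frame`, `vdw`, `ele`, `gb`, `surf` and optionally `internal`, all
#' energies in kcal/mol. One row per trajectory frame.
#'
#' @param path Path to a CSV file.
#' @return `read_energy_frames()` returns a `data.frame`, one row per frame.
#' @seealso [aggregate_components()], [gen_energy_frames()]
#' @export
read_energy_frames <- function(path) {
  df <- read_schema(path, "energy_frames")
  if (nrow(df) == 0L) stop_input("%s: no frames", path)
  df
}

#' @rdname read_energy_frames
#' @param df An energy-frame table.
#' @export
write_energy_frames <- function(df, path) write_schema(df, path, "energy_frames")

#' Read or write a stability sweep table
#'
#' Columns `x` (the swept variable: temperature in deg C, pH, or storage day)
#' and `z_ave_nm`, optionally `count_rate_kcps`. `x` must be strictly
#' monotone (increasing or decreasing, so heating and cooling sweeps both
#' load).
#'
#' @param path Path to a CSV file.
#' @param axis Axis label attached to the resulting series; one of
#'   `"temperature_C"`, `"pH"`, `"day"`.
#' @return `read_sweep_table()` returns a `data.frame`.
#' @seealso [sweep_series()], [sweep_delta()]
#' @export
read_sweep_table <- function(path, axis = "temperature_C") {
  df <- read_schema(path, "sweep")
  if (nrow(df) < 2L) stop_input("%s: sweep needs at least 2 rows", path)
  d <- diff(df$x)
  if (!(all(d > 0) || all(d < 0))) {
    stop_input("%s: x must be strictly monotone", path)
  }
  attr(df, "axis") <- match.arg(axis, c("temperature_C", "pH", "day"))
  df
}

#' @rdname read_sweep_table
#' @param df A sweep table.
#' @export
write_sweep_table <- function(df, path) write_schema(df, path, "sweep")

#' Read or write a composition summary table
#'
#' Per-component, per-group summary statistics: columns `component`, `group`,
#' `mean`, `sd`, `n` (concentrations in ug/mg). Used for two-group Welch
#' comparisons from summary statistics.
#'
#' @param path Path to a CSV file.
#' @return `read_composition_table()` returns a `data.frame`.
#' @seealso [compare_composition_table()], [welch_t_from_summary()]
#' @export
read_composition_table <- function(path) {
  df <- read_schema(path, "composition")
  if (any(df$sd < 0)) stop_input("%s: sd must be nonnegative", path)
  if (any(df$n < 2 | df$n != floor(df$n))) {
    stop_input("%s: n must be an integer >= 2", path)
  }
  df
}

#' @rdname read_composition_table
#' @param df A composition summary table.
#' @export
write_composition_table <- function(df, path) write_schema(df, path, "composition")

mnp_criteria <- c("z_ave", "count_rate", "pdi", "zeta_abs", "conductivity")

#' Run configuration for the TOPSIS ranking stage
#'
#' `default_config()` returns the study defaults: criteria ordered
#' `z_ave, count_rate, pdi, zeta_abs, conductivity`, weights
#' `0.15, 0.20, 0.25, 0.15, 0.25` (PDI and conductivity weighted highest —
#' dispersion uniformity and purification efficiency matter most for a clean
#' nanoparticle fraction), and directions `cost, benefit, cost, benefit,
#' cost`: small size, low polydispersity and low residual conductivity are
#' favourable, while high count rate and large |zeta| are favourable.
#'
#' `read_config()` reads a JSON file with any subset of the keys `weights`,
#' `directions`, `criteria_order`, `rounding_tolerance`, `seed`; omitted keys
#' take the defaults. An empty file (or `{}`) yields `default_config()`.
#'
#' @param path Path to a JSON configuration file.
#' @return A list of class `mnp_config` with elements `criteria_order`,
#'   `weights`, `directions`, `rounding_tolerance`, `seed`.
#' @examples
#' cfg <- default_config()
#' cfg$weights
#' @export
default_config <- function() {
  validate_config(list(
    criteria_order = mnp_criteria,
    weights = c(0.15, 0.20, 0.25, 0.15, 0.25),
    directions = c("cost", "benefit", "cost", "benefit", "cost"),
    rounding_tolerance = 0.001,
    seed = 0L
  ))
}

validate_config <- function(cfg) {
  cfg$criteria_order <- as.character(cfg$criteria_order)
  n <- length(cfg$criteria_order)
  if (n < 1L) stop_input("config: criteria_order must be non-empty")
  if (anyDuplicated(cfg$criteria_order)) {
    stop_input("config: duplicate criterion name")
  }
  cfg$weights <- as.numeric(cfg$weights)
  if (length(cfg$weights) != n) {
    stop_input("config: %d weights for %d criteria", length(cfg$weights), n)
  }
  if (any(!is.finite(cfg$weights)) || any(cfg$weights <= 0)) {
    stop_input("config: every weight must be strictly positive")
  }
  if (abs(sum(cfg$weights) - 1) > 1e-9) {
    stop_input("config: weights must sum to 1 (got %.12g)", sum(cfg$weights))
  }
  cfg$directions <- as.character(cfg$directions)
  if (length(cfg$directions) != n) {
    stop_input("config: %d directions for %d criteria",
               length(cfg$directions), n)
  }
  bad <- setdiff(cfg$directions, c("benefit", "cost"))
  if (length(bad)) {
    stop_input("config: unknown direction label '%s' (use benefit/cost)", bad[1L])
  }
  cfg$rounding_tolerance <- as.numeric(cfg$rounding_tolerance %||% 0.001)
  if (!is.finite(cfg$rounding_tolerance) || cfg$rounding_tolerance < 0) {
    stop_input("config: rounding_tolerance must be nonnegative")
  }
  seed <- cfg$seed %||% 0L
  if (!is_count(seed)) stop_input("config: seed must be a nonnegative integer")
  cfg$seed <- as.integer(seed)
  structure(cfg[c("criteria_order", "weights", "directions",
                  "rounding_tolerance", "seed")],
            class = "mnp_config")
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nzchar(trimws(txt))) {
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) stop_input("config %s: invalid JSON: %s",
                                            path, conditionMessage(e)))
  } else {
    list()
  }
  if (length(user) && is.null(names(user))) {
    stop_input("config %s: expected a JSON object", path)
  }
  cfg <- unclass(default_config())
  for (key in intersect(names(user), names(cfg))) cfg[[key]] <- user[[key]]
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop_input("config %s: unknown key '%s'", path, unknown[1L])
  }
  validate_config(cfg)
}

#' @export
print.mnp_config <- function(x, ...) {
  cat("Run configuration (", length(x$criteria_order), " criteria)\n", sep = "")
  print(data.frame(criterion = x$criteria_order, weight = x$weights,
                   direction = x$directions), row.names = FALSE)
  cat("rounding_tolerance:", x$rounding_tolerance, " seed:", x$seed, "\n")
  invisible(x)
}
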