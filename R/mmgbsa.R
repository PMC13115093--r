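## MM/GBSA bookkeeping. Endpoint binding free energy decomposed as
##   dE_gas  = dE_internal + dE_vdw + dE_ele
##   dG_solv = dG_GB + dG_SA
##   dG_bind = dE_gas + dG_solv
## with the nonpolar term dG_SA = gamma * dSASA (gamma = 0.0072
## kcal mol^-1 A^-2 by convention). The entropic term -TdS is deliberately
## absent, as is usual for relative single-trajectory MM/GBSA estimates;
## dE_internal defaults to 0 because internal terms cancel in the
## single-trajectory scheme.

#' Per-component MM/GBSA energies
#'
#' @param vdw Van der Waals interaction energy (kcal/mol).
#' @param ele Electrostatic interaction energy (kcal/mol).
#' @param gb Polar (generalized Born) solvation free energy (kcal/mol).
#' @param surf Nonpolar (surface-area) solvation free energy (kcal/mol).
#' @param internal Internal (bond/angle/torsion) energy (kcal/mol);
#'   defaults to 0, the single-trajectory convention.
#' @return A list of class `energy_components`.
#' @seealso [derive_totals()], [aggregate_components()]
#' @export
energy_components <- function(vdw, ele, gb, surf, internal = 0) {
  vals <- c(vdw = vdw, ele = ele, gb = gb, surf = surf, internal = internal)
  if (any(!is.finite(vals))) stop_input("energy components must all be finite")
  structure(as.list(vals), class = "energy_components")
}

as_energy_components <- function(x) {
  if (inherits(x, "energy_components")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    req <- c("vdw", "ele", "gb", "surf")
    if (!all(req %in% names(x))) {
      stop_input("named energy vector must contain %s", paste(req, collapse = ", "))
    }
    return(energy_components(x[["vdw"]], x[["ele"]], x[["gb"]], x[["surf"]],
                             if ("internal" %in% names(x)) x[["internal"]] else 0))
  }
  stop_input("expected an energy_components object or a named numeric vector")
}

#' @export
print.energy_components <- function(x, ...) {
  v <- unlist(x)
  cat("Energy components (kcal/mol):\n")
  print(round(v, 4))
  invisible(x)
}

#' Aggregate per-frame component energies
#'
#' Arithmetic mean and standard error of each energy component over
#' trajectory frames. With a single frame the mean is that frame and the
#' standard error is 0 by convention.
#'
#' @param frames A `data.frame` of per-frame energies with columns `vdw`,
#'   `ele`, `gb`, `surf` and optionally `internal` (see
#'   [read_energy_frames()] / [gen_energy_frames()]).
#' @return A list with elements `mean` (an [energy_components()]), `sem`
#'   (named numeric vector) and `n_frames`.
#' @export
aggregate_components <- function(frames) {
  comps <- c("vdw", "ele", "gb", "surf")
  if (!is.data.frame(frames) || !all(comps %in% names(frames))) {
    stop_input("frames must be a data.frame with columns %s",
               paste(comps, collapse = ", "))
  }
  n <- nrow(frames)
  if (n < 1L) stop_input("empty energy-frame table")
  if ("internal" %in% names(frames)) comps <- c(comps, "internal")
  mu <- vapply(frames[comps], mean, numeric(1))
  sem <- if (n == 1L) {
    stats::setNames(rep(0, length(comps)), comps)
  } else {
    vapply(frames[comps], function(v) stats::sd(v) / sqrt(n), numeric(1))
  }
  mean_ec <- energy_components(mu[["vdw"]], mu[["ele"]], mu[["gb"]], mu[["surf"]],
                               if ("internal" %in% comps) mu[["internal"]] else 0)
  list(mean = mean_ec, sem = sem, n_frames = n)
}

#' Derive gas, solvation and binding totals
#'
#' Exact floating-point sums of the stored components:
#' `gas = internal + vdw + ele`, `solv = gb + surf`, `bind = gas + solv`.
#'
#' @param components An [energy_components()] object (or named numeric
#'   vector with at least `vdw`, `ele`, `gb`, `surf`).
#' @return A list of class `decomposed_energy` with elements `components`,
#'   `gas`, `solv`, `bind` (kcal/mol).
#' @examples
#' derive_totals(energy_components(vdw = -27.76, ele = -1.71,
#'                                 gb = 3.07, surf = -3.91))$bind  # -30.31
#' @export
derive_totals <- function(components) {
  components <- as_energy_components(components)
  gas <- components$internal + components$vdw + components$ele
  solv <- components$gb + components$surf
  structure(list(components = components, gas = gas, solv = solv,
                 bind = gas + solv),
            class = "decomposed_energy")
}

#' @export
print.decomposed_energy <- function(x, ...) {
  cat("MM/GBSA decomposition (kcal/mol):\n")
  v <- c(unlist(x$components), gas = x$gas, solv = x$solv, bind = x$bind)
  print(round(v, 4))
  cat("(entropic term -TdS not included)\n")
  invisible(x)
}

#' Nonpolar solvation free energy from a surface-area change
#'
#' `dG_SA = gamma * dSASA`, the linear surface-area model for the nonpolar
#' solvation term. The default surface tension gamma = 0.0072 assumes
#' kcal mol^-1 per square Angstrom with the SASA change in square
#' Angstroms.
#'
#' @param delta_sasa Solvent-accessible surface-area change (A^2).
#' @param gamma Surface-tension coefficient (kcal mol^-1 A^-2).
#' @return Nonpolar solvation free energy (kcal/mol).
#' @examples
#' nonpolar_solvation(100)  # 0.72
#' @export
nonpolar_solvation <- function(delta_sasa, gamma = 0.0072) {
  if (any(!is.finite(delta_sasa)) || any(!is.finite(gamma))) {
    stop_input("delta_sasa and gamma must be finite")
  }
  gamma * delta_sasa
}

#' Endpoint binding free energy
#'
#' The standard endpoint difference
#' `dG_bind = dG_complex - (dG_receptor + dG_ligand)`. (Some write-ups
#' typeset this with the parenthesis dropped; the implementation always
#' subtracts both the receptor and the ligand terms.)
#'
#' @param complex,receptor,ligand `decomposed_energy` objects from
#'   [derive_totals()].
#' @return Binding free energy (kcal/mol).
#' @export
binding_from_endpoints <- function(complex, receptor, ligand) {
  for (x in list(complex, receptor, ligand)) {
    if (!inherits(x, "decomposed_energy")) {
      stop_input("all three arguments must be decomposed_energy objects")
    }
  }
  complex$bind - (receptor$bind + ligand$bind)
}

#' Validate a printed energy-decomposition table
#'
#' Checks each labelled column of a published MM/GBSA table for additivity:
#' the printed gas, solvation and binding totals must agree with the sums
#' recomputed from the printed components (`gas = internal + vdw + ele`,
#' `solv = gb + surf`, `bind = vdw + ele + gb + surf + internal`) within
#' `tolerance`. The default 0.015 kcal/mol reflects 2-decimal rounding of
#' the printed entries.
#'
#' @param table A `data.frame` with columns `label`, `vdw`, `ele`, `gb`,
#'   `surf`, optionally `internal`, and printed totals `gas`, `solv`,
#'   `bind`.
#' @param tolerance Nonnegative tolerance (kcal/mol).
#' @return An object of class `decomposition_validation` with per-label
#'   checks and an overall `pass` flag.
#' @seealso [bsa_energy_table()] for the published reference table.
#' @export
validate_decomposition_table <- function(table, tolerance = 0.015) {
  req <- c("label", "vdw", "ele", "gb", "surf", "gas", "solv", "bind")
  if (!all(req %in% names(table))) {
    stop_input("decomposition table must have columns %s",
               paste(req, collapse = ", "))
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop_input("tolerance must be a single nonnegative number")
  }
  internal <- if ("internal" %in% names(table)) table$internal else 0
  gas_re <- internal + table$vdw + table$ele
  solv_re <- table$gb + table$surf
  bind_re <- gas_re + solv_re
  rows <- data.frame(
    label = table$label,
    gas_error = abs(gas_re - table$gas),
    solv_error = abs(solv_re - table$solv),
    bind_error = abs(bind_re - table$bind)
  )
  rows$pass <- rows$gas_error <= tolerance & rows$solv_error <= tolerance &
    rows$bind_error <= tolerance
  structure(list(rows = rows, tolerance = tolerance,
                 n_failed = sum(!rows$pass), pass = all(rows$pass)),
            class = "decomposition_validation")
}

#' @export
print.decomposition_validation <- function(x, ...) {
  cat("Energy-decomposition additivity check at tolerance", x$tolerance,
      "kcal/mol\n")
  print(x$rows, row.names = FALSE, digits = 4)
  cat(if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
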