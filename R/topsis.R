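## TOPSIS (Technique for Order Preference by Similarity to Ideal Solution)
## over separation-condition read-outs. Six steps: decision matrix ->
## vector normalisation -> weighting -> ideal solutions -> Euclidean
## separations -> closeness coefficient and ranking. Criteria carry explicit
## benefit/cost directions: for a cost criterion (Z-average, PDI,
## conductivity) the positive ideal takes the column minimum.

#' Build a decision matrix from condition records
#'
#' Assembles the m x 5 decision matrix for ranking separation conditions.
#' Columns follow the configured criteria order (default `z_ave`,
#' `count_rate`, `pdi`, `zeta_abs`, `conductivity`); the zeta criterion
#' stores the absolute value of the zeta potential, since only the magnitude
#' of the electrostatic repulsion matters for colloidal stability.
#'
#' @param records A condition `data.frame` (see [read_condition_table()]),
#'   at least 2 rows.
#' @param config An `mnp_config`, e.g. [default_config()].
#' @return A list of class `decision_matrix` with elements `labels` (the
#'   (mwco_kda, time_min, force_g) triples, input order preserved), `values`
#'   (numeric matrix), `criteria`, `directions`, `weights`.
#' @export
build_decision_matrix <- function(records, config = default_config()) {
  config <- validate_config(unclass(config))
  records <- validate_condition_table(records)
  if (nrow(records) < 2L) {
    stop_input("TOPSIS needs at least 2 alternatives; got %d", nrow(records))
  }
  source_col <- c(z_ave = "z_ave_nm", count_rate = "count_rate_kcps",
                  pdi = "pdi", zeta_abs = "zeta_mv",
                  conductivity = "conductivity")
  unknown <- setdiff(config$criteria_order, names(source_col))
  if (length(unknown)) {
    stop_input("unknown criterion '%s' in criteria_order", unknown[1L])
  }
  values <- sapply(config$criteria_order, function(crit) {
    v <- records[[source_col[[crit]]]]
    if (crit == "zeta_abs") abs(v) else v
  })
  values <- matrix(as.numeric(values), nrow = nrow(records),
                   dimnames = list(NULL, config$criteria_order))
  if (any(!is.finite(values))) stop_input("decision matrix contains non-finite values")
  structure(list(
    labels = records[, c("mwco_kda", "time_min", "force_g")],
    values = values,
    criteria = config$criteria_order,
    directions = stats::setNames(config$directions, config$criteria_order),
    weights = stats::setNames(config$weights, config$criteria_order)
  ), class = "decision_matrix")
}

#' TOPSIS computation steps
#'
#' The individual steps of the TOPSIS procedure, exposed so each is
#' independently checkable. [run_topsis()] composes them.
#'
#' * `topsis_normalize()`: vector (Euclidean) column normalisation,
#'   `Z_ij = X_ij / sqrt(sum_i X_ij^2)`; every non-degenerate column of the
#'   result has unit Euclidean norm.
#' * `apply_weights()`: `U_ij = Z_ij * w_j`.
#' * `ideal_solutions()`: per criterion, the positive ideal `A+` takes the
#'   column maximum for a benefit criterion and the column minimum for a
#'   cost criterion; the negative ideal `A-` takes the opposite extreme.
#' * `separation_distances()`: Euclidean distances of each row from `A+`
#'   and `A-`.
#' * `closeness()`: `C_i = d_i- / (d_i+ + d_i-)`, in `[0, 1]`; if both
#'   distances are 0 (all alternatives identical) `C_i = 0.5` with a
#'   warning, the continuity limit along `d+ = d-`.
#' * `rank_alternatives()`: rank 1 is the largest closeness; ties share the
#'   smallest applicable rank (competition ranking) and are reported in the
#'   `"ties"` attribute.
#'
#' @param x Numeric m x n matrix of criterion values (m alternatives).
#' @param normalized,weighted Numeric m x n matrices from the previous step.
#' @param weights Positive per-criterion weights, length n.
#' @param directions Per-criterion labels, `"benefit"` or `"cost"`.
#' @param ideals A list with elements `pos` and `neg` from `ideal_solutions()`.
#' @param d_pos,d_neg Nonnegative separation vectors, length m.
#' @param C Numeric closeness vector.
#' @return `topsis_normalize()`, `apply_weights()`: a matrix;
#'   `ideal_solutions()`: `list(pos, neg)`; `separation_distances()`:
#'   `list(d_pos, d_neg)`; `closeness()`: a numeric vector in `[0, 1]`;
#'   `rank_alternatives()`: an integer vector, a permutation of `1..m` when
#'   there are no ties.
#' @name topsis_steps
NULL

#' @rdname topsis_steps
#' @export
topsis_normalize <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(colSums(x^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    nm <- colnames(x)[zero[1L]] %||% as.character(zero[1L])
    stop_input("cannot normalize: column '%s' is all zeros", nm)
  }
  sweep(x, 2L, norms, "/")
}

#' @rdname topsis_steps
#' @export
apply_weights <- function(normalized, weights) {
  normalized <- as.matrix(normalized)
  if (length(weights) != ncol(normalized)) {
    stop_input("%d weights for %d columns", length(weights), ncol(normalized))
  }
  sweep(normalized, 2L, weights, "*")
}

#' @rdname topsis_steps
#' @export
ideal_solutions <- function(weighted, directions) {
  weighted <- as.matrix(weighted)
  if (length(directions) != ncol(weighted)) {
    stop_input("%d directions for %d columns", length(directions), ncol(weighted))
  }
  bad <- setdiff(directions, c("benefit", "cost"))
  if (length(bad)) stop_input("unknown direction label '%s'", bad[1L])
  hi <- apply(weighted, 2L, max)
  lo <- apply(weighted, 2L, min)
  cost <- directions == "cost"
  pos <- ifelse(cost, lo, hi)
  neg <- ifelse(cost, hi, lo)
  names(pos) <- names(neg) <- colnames(weighted)
  list(pos = pos, neg = neg)
}

#' @rdname topsis_steps
#' @export
separation_distances <- function(weighted, ideals) {
  weighted <- as.matrix(weighted)
  if (length(ideals$pos) != ncol(weighted) || length(ideals$neg) != ncol(weighted)) {
    stop_input("ideal vectors do not match matrix width")
  }
  list(
    d_pos = sqrt(rowSums(sweep(weighted, 2L, ideals$pos, "-")^2)),
    d_neg = sqrt(rowSums(sweep(weighted, 2L, ideals$neg, "-")^2))
  )
}

#' @rdname topsis_steps
#' @export
closeness <- function(d_pos, d_neg) {
  if (length(d_pos) != length(d_neg)) stop_input("distance vectors differ in length")
  if (any(d_pos < 0) || any(d_neg < 0)) stop_input("separation distances must be nonnegative")
  tot <- d_pos + d_neg
  C <- ifelse(tot == 0, 0.5, d_neg / ifelse(tot == 0, 1, tot))
  if (any(tot == 0)) {
    warning("d+ = d- = 0 for ", sum(tot == 0),
            " alternative(s); closeness set to 0.5")
  }
  C
}

#' @rdname topsis_steps
#' @export
rank_alternatives <- function(C) {
  if (any(!is.finite(C))) stop_input("closeness must be finite")
  r <- as.integer(rank(-C, ties.method = "min"))
  dup <- unique(r[duplicated(r)])
  ties <- lapply(dup, function(v) which(r == v))
  names(ties) <- as.character(dup)
  attr(r, "ties") <- ties
  r
}

#' Rank separation conditions by TOPSIS
#'
#' Runs the full six-step TOPSIS procedure on a condition table: decision
#' matrix (with |zeta|) -> vector normalisation -> weighting -> benefit/cost
#' ideal solutions -> Euclidean separations -> closeness and ranking. The
#' result is deterministic in the input.
#'
#' @param records A condition `data.frame` (>= 2 rows) or a
#'   `decision_matrix`.
#' @param config An `mnp_config`; ignored when `records` is already a
#'   `decision_matrix`.
#' @return An object of class `topsis`: a list with the `decision_matrix`
#'   fields plus `normalized`, `weighted`, `ideal_pos`, `ideal_neg`,
#'   `d_pos`, `d_neg`, `closeness`, `rank` and `ties`. Use
#'   `as.data.frame()` for a per-alternative results table, and
#'   `summary()` for the top of the ranking.
#' @examples
#' tab <- gen_condition_table(condition_design(), seed = 7)
#' fit <- run_topsis(tab)
#' head(as.data.frame(fit)[order(as.data.frame(fit)$rank), ])
#' @export
run_topsis <- function(records, config = default_config()) {
  dm <- if (inherits(records, "decision_matrix")) records
        else build_decision_matrix(records, config)
  Z <- topsis_normalize(dm$values)
  U <- apply_weights(Z, dm$weights)
  ideals <- ideal_solutions(U, dm$directions)
  d <- separation_distances(U, ideals)
  C <- closeness(d$d_pos, d$d_neg)
  r <- rank_alternatives(C)
  structure(c(dm, list(
    normalized = Z, weighted = U,
    ideal_pos = ideals$pos, ideal_neg = ideals$neg,
    d_pos = d$d_pos, d_neg = d$d_neg,
    closeness = C, rank = as.integer(r), ties = attr(r, "ties")
  )), class = "topsis")
}

#' @export
as.data.frame.topsis <- function(x, ...) {
  cbind(x$labels,
        data.frame(d_pos = x$d_pos, d_neg = x$d_neg,
                   closeness = x$closeness, rank = x$rank))
}

#' @export
print.topsis <- function(x, n = 5L, ...) {
  m <- length(x$closeness)
  cat("TOPSIS ranking of", m, "alternatives over",
      length(x$criteria), "criteria\n")
  cat("criteria: ", paste0(x$criteria, " (", x$directions, ", w=",
                           format(x$weights), ")", collapse = ", "), "\n", sep = "")
  df <- as.data.frame(x)
  df <- df[order(df$rank), ]
  cat("top", min(n, m), "alternatives:\n")
  print(utils::head(df, n), row.names = FALSE, digits = 4)
  if (length(x$ties)) {
    cat("ties at rank(s):", paste(names(x$ties), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.topsis <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$rank), ]
  structure(list(table = df, ties = object$ties,
                 criteria = object$criteria, weights = object$weights,
                 directions = object$directions),
            class = "summary.topsis")
}

#' @export
print.summary.topsis <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$ties)) cat("ties at rank(s):", paste(names(x$ties), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a printed closeness table
#'
#' Checks a published TOPSIS results table for internal consistency: for
#' each row, the closeness recomputed as `d- / (d+ + d-)` must agree with
#' the printed closeness within `tolerance`, and the printed ranking must
#' equal the ordering by descending printed closeness. The default tolerance
#' 0.001 reflects 4-decimal rounding of the printed separations.
#'
#' @param table A `data.frame` with columns `d_pos`, `d_neg`, `c_printed`,
#'   `rank_printed` (extra columns are carried through).
#' @param tolerance Nonnegative per-row tolerance on the closeness identity.
#' @return An object of class `closeness_validation`: a list with `rows`
#'   (per-row recomputation, absolute error and pass flag), `rank_ok`,
#'   `n_failed` and `pass`.
#' @seealso [wtmp_ranking_table()] for the published reference table.
#' @export
validate_closeness_table <- function(table, tolerance = 0.001) {
  req <- c("d_pos", "d_neg", "c_printed", "rank_printed")
  if (!all(req %in% names(table))) {
    stop_input("closeness table must have columns %s", paste(req, collapse = ", "))
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop_input("tolerance must be a single nonnegative number")
  }
  c_re <- closeness(table$d_pos, table$d_neg)
  err <- abs(c_re - table$c_printed)
  rows <- cbind(table,
                data.frame(c_recomputed = c_re, abs_error = err,
                           pass = err <= tolerance))
  rank_ok <- all(table$rank_printed[order(-table$c_printed)] ==
                 sort(table$rank_printed))
  structure(list(rows = rows, tolerance = tolerance,
                 n_failed = sum(!rows$pass), rank_ok = rank_ok,
                 pass = all(rows$pass) && rank_ok),
            class = "closeness_validation")
}

#' @export
print.closeness_validation <- function(x, ...) {
  cat("Closeness-identity validation of", nrow(x$rows), "rows at tolerance",
      x$tolerance, "\n")
  cat("rows failing |d-/(d+ + d-) - C| <= tol:", x$n_failed, "\n")
  cat("printed ranking matches descending C:", x$rank_ok, "\n")
  cat(if (x$pass) "PASS" else "FAIL", "\n")
  if (x$n_failed) {
    print(x$rows[!x$rows$pass, ], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
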