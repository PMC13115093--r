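## Seeded generators that emulate every input table the pipeline consumes.
## All are pure functions of (design, seed): the same pair always returns the
## same data, and the caller's RNG stream is left untouched.

scale_levels <- function(v, levels) {
  r <- range(levels)
  if (diff(r) == 0) return(rep(0, length(v)))
  2 * (v - r[1L]) / diff(r) - 1
}

#' Design of a factorial separation-condition experiment
#'
#' Describes a full factorial membrane cut-off x centrifugal force x time
#' design together with the mean model and noise level of each dynamic light
#' scattering criterion. The default is the 2 x 5 x 3 = 30-condition design
#' used to screen micro-nanoparticle isolation: membranes of 30 and 100 kDa,
#' forces 2000-6000 g, times 10/20/30 min.
#'
#' Each criterion's mean is `baseline + effects`, where the effects are
#' additive linear trends in the factor levels rescaled to `[-1, 1]`. The
#' default trends encode the qualitative behaviour of ultrafiltration
#' retentates: the looser 100 kDa membrane passes more small charged solutes,
#' giving smaller, more uniform particles (lower Z-average and PDI), higher
#' count rate, larger |zeta| and lower conductivity.
#'
#' @param mwco_levels Membrane molecular-weight cut-offs (kDa).
#' @param force_levels Relative centrifugal forces (x g).
#' @param time_levels Centrifugation times (min).
#' @param baseline Named per-criterion means (criteria `z_ave_nm`,
#'   `count_rate_kcps`, `pdi`, `zeta_mv`, `conductivity`).
#' @param effects Named list; for each criterion a numeric vector with
#'   elements `mwco`, `force`, `time` giving the additive change across the
#'   rescaled factor range.
#' @param noise_sd Named per-criterion Gaussian measurement noise SDs.
#' @return A list of class `condition_design`.
#' @seealso [gen_condition_table()]
#' @export
condition_design <- function(mwco_levels = c(30, 100),
                             force_levels = c(2000, 3000, 4000, 5000, 6000),
                             time_levels = c(10, 20, 30),
                             baseline = c(z_ave_nm = 320, count_rate_kcps = 250,
                                          pdi = 0.38, zeta_mv = -20,
                                          conductivity = 1.6),
                             effects = list(
                               z_ave_nm = c(mwco = -60, force = -25, time = 15),
                               count_rate_kcps = c(mwco = 80, force = 30, time = -15),
                               pdi = c(mwco = -0.10, force = -0.04, time = 0.03),
                               zeta_mv = c(mwco = -5, force = -1.5, time = 0.5),
                               conductivity = c(mwco = -0.5, force = -0.15, time = 0.08)
                             ),
                             noise_sd = c(z_ave_nm = 10, count_rate_kcps = 8,
                                          pdi = 0.015, zeta_mv = 0.8,
                                          conductivity = 0.04)) {
  for (lv in list(mwco_levels, force_levels, time_levels)) {
    if (length(lv) < 1L || any(!is.finite(lv)) || any(lv <= 0)) {
      stop_input("condition_design: factor levels must be positive and non-empty")
    }
  }
  crit <- c("z_ave_nm", "count_rate_kcps", "pdi", "zeta_mv", "conductivity")
  if (!all(crit %in% names(baseline)) || !all(crit %in% names(effects)) ||
      !all(crit %in% names(noise_sd))) {
    stop_input("condition_design: baseline, effects and noise_sd must name all of: %s",
               paste(crit, collapse = ", "))
  }
  if (any(noise_sd[crit] < 0)) stop_input("condition_design: noise_sd must be nonnegative")
  structure(list(mwco_levels = mwco_levels, force_levels = force_levels,
                 time_levels = time_levels, baseline = baseline[crit],
                 effects = effects[crit], noise_sd = noise_sd[crit]),
            class = "condition_design")
}

#' Generate a synthetic separation-condition table
#'
#' Draws one record per factorial cell of a [condition_design()]: criterion
#' value = baseline + additive factor trends + Gaussian noise. PDI is clipped
#' to `[0, 1]` after noise and strictly-positive quantities are floored at a
#' small positive value so every table satisfies the schema invariants.
#'
#' @param design A [condition_design()].
#' @param seed Integer seed; the same (design, seed) pair always yields the
#'   same table.
#' @return A condition `data.frame` (see [read_condition_table()]), rows
#'   ordered mwco (slowest) x time x force (fastest).
#' @examples
#' tab <- gen_condition_table(condition_design(), seed = 42)
#' nrow(tab)  # 30
#' @export
gen_condition_table <- function(design = condition_design(), seed) {
  stopifnot(inherits(design, "condition_design"))
  grid <- expand.grid(force_g = design$force_levels,
                      time_min = design$time_levels,
                      mwco_kda = design$mwco_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("mwco_kda", "time_min", "force_g")]
  rownames(grid) <- NULL
  m <- nrow(grid)
  s_mwco <- scale_levels(grid$mwco_kda, design$mwco_levels)
  s_force <- scale_levels(grid$force_g, design$force_levels)
  s_time <- scale_levels(grid$time_min, design$time_levels)
  with_seed(seed, {
    for (crit in names(design$baseline)) {
      eff <- design$effects[[crit]]
      mu <- design$baseline[[crit]] +
        eff[["mwco"]] / 2 * s_mwco +
        eff[["force"]] / 2 * s_force +
        eff[["time"]] / 2 * s_time
      grid[[crit]] <- mu + stats::rnorm(m, 0, design$noise_sd[[crit]])
    }
    grid
  })
  grid$pdi <- pmin(pmax(grid$pdi, 0), 1)
  for (crit in c("z_ave_nm", "count_rate_kcps", "conductivity")) {
    grid[[crit]] <- pmax(grid[[crit]], 1e-6)
  }
  validate_condition_table(grid, context = "generated condition table")
}

#' Design of a fluorescence titration
#'
#' Parameters of a synthetic quenching titration: quencher-free intensity
#' `f0`, the concentration grid, the true quenching/binding constants, and a
#' multiplicative noise level. Defaults follow a serum-albumin/polyphenol
#' titration: concentrations spanning 1e-8 to 1e-6 mol/L and constants of
#' the order 1e6-1e7 L/mol.
#'
#' @param f0 Quencher-free fluorescence intensity (a.u.), positive.
#' @param q_grid Strictly increasing nonnegative quencher concentrations
#'   (mol/L); the first value may be 0.
#' @param ksv_true True Stern-Volmer constant (L/mol).
#' @param ka_true True apparent binding constant (L/mol).
#' @param n_true True number of binding sites (dimensionless).
#' @param noise_cv Fractional coefficient of variation of the multiplicative
#'   lognormal intensity noise; 0 gives noiseless data.
#' @return A list of class `titration_design`.
#' @seealso [gen_titration()], [stern_volmer_fit()], [double_log_fit()]
#' @export
titration_design <- function(f0 = 8608,
                             q_grid = seq(1e-8, 1e-6, length.out = 12),
                             ksv_true = 7.6e6, ka_true = 1.43e6, n_true = 1,
                             noise_cv = 0.01) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0) {
    stop_input("titration_design: f0 must be a single positive number")
  }
  if (length(q_grid) < 3L || any(q_grid < 0) || any(diff(q_grid) <= 0)) {
    stop_input("titration_design: q_grid must be >= 3 strictly increasing nonnegative values")
  }
  if (ksv_true <= 0 || ka_true <= 0 || n_true <= 0) {
    stop_input("titration_design: ksv_true, ka_true and n_true must be positive")
  }
  if (noise_cv < 0) stop_input("titration_design: noise_cv must be nonnegative")
  structure(list(f0 = f0, q_grid = q_grid, ksv_true = ksv_true,
                 ka_true = ka_true, n_true = n_true, noise_cv = noise_cv),
            class = "titration_design")
}

#' Generate a synthetic quenching titration
#'
#' Under `law = "stern_volmer"` intensities follow `F = F0 / (1 + Ksv [Q])`;
#' under `law = "binding_site"` they follow `F = F0 / (1 + Ka [Q]^n)`.
#' Measurement noise is multiplicative lognormal with unit mean and
#' coefficient of variation `noise_cv` (intensities stay positive). F0 is
#' returned noise-free.
#'
#' @param design A [titration_design()].
#' @param law `"stern_volmer"` or `"binding_site"`.
#' @param seed Integer seed.
#' @return A [titration_series()].
#' @examples
#' des <- titration_design(noise_cv = 0)
#' ser <- gen_titration(des, "stern_volmer", seed = 1)
#' coef(stern_volmer_fit(ser))
#' @export
gen_titration <- function(design = titration_design(),
                          law = c("stern_volmer", "binding_site"), seed) {
  stopifnot(inherits(design, "titration_design"))
  law <- match.arg(law)
  q <- design$q_grid
  f <- switch(law,
    stern_volmer = design$f0 / (1 + design$ksv_true * q),
    binding_site = design$f0 / (1 + design$ka_true * q^design$n_true)
  )
  if (design$noise_cv > 0) {
    s <- sqrt(log1p(design$noise_cv^2))
    f <- with_seed(seed, f * stats::rlnorm(length(f), meanlog = -s^2 / 2, sdlog = s))
  }
  titration_series(f0 = design$f0, q = q, f = f)
}

#' Generate per-frame MM/GBSA component energies
#'
#' Each component (`vdw`, `ele`, `gb`, `surf`, and `internal` when nonzero in
#' `means`) is drawn independently per frame from a Gaussian with the given
#' mean and SD, emulating the frame-to-frame fluctuation of trajectory
#' energies.
#'
#' @param means An [energy_components()] object (kcal/mol).
#' @param sds Named nonnegative per-component SDs (kcal/mol); components not
#'   named get SD 0.
#' @param n_frames Number of frames, at least 1.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `frame`, `vdw`, `ele`, `gb`, `surf`
#'   (and `internal` if applicable).
#' @seealso [aggregate_components()]
#' @export
gen_energy_frames <- function(means, sds = c(vdw = 2, ele = 1, gb = 1, surf = 0.5),
                              n_frames, seed) {
  means <- as_energy_components(means)
  if (!is_count(n_frames) || n_frames < 1) {
    stop_input("gen_energy_frames: n_frames must be a positive integer")
  }
  comps <- c("vdw", "ele", "gb", "surf")
  if (means$internal != 0) comps <- c(comps, "internal")
  sd_full <- stats::setNames(rep(0, length(comps)), comps)
  sd_full[intersect(names(sds), comps)] <- sds[intersect(names(sds), comps)]
  if (any(sd_full < 0)) stop_input("gen_energy_frames: sds must be nonnegative")
  out <- data.frame(frame = seq_len(n_frames))
  with_seed(seed, {
    for (comp in comps) {
      out[[comp]] <- stats::rnorm(n_frames, means[[comp]], sd_full[[comp]])
    }
    out
  })
  out
}

#' Generate a synthetic stability sweep
#'
#' `shape = "linear"` ramps the response linearly from `baseline` at the
#' first grid point to `baseline + delta` at the last; `shape = "threshold"`
#' stays flat at `baseline` and jumps to `baseline + delta` after the knot,
#' emulating an abrupt aggregation onset. Gaussian noise is added on top.
#'
#' @param x_grid Strictly monotone swept values (>= 2 points).
#' @param baseline Positive starting response.
#' @param delta Total planted change (may be negative).
#' @param shape `"linear"` or `"threshold"`.
#' @param noise_sd Nonnegative Gaussian noise SD.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param knot Threshold location; defaults to the midpoint of `x_grid`.
#' @param axis,ylabel,label Passed to [sweep_series()].
#' @return A [sweep_series()].
#' @export
gen_sweep <- function(x_grid, baseline, delta, shape = c("linear", "threshold"),
                      noise_sd = 0, seed = 0, knot = NULL,
                      axis = "temperature_C", ylabel = "z_ave_nm",
                      label = "synthetic") {
  shape <- match.arg(shape)
  if (length(x_grid) < 2L) stop_input("gen_sweep: need at least 2 x points")
  if (noise_sd < 0) stop_input("gen_sweep: noise_sd must be nonnegative")
  y <- switch(shape,
    linear = baseline + delta * (x_grid - x_grid[1L]) /
      (x_grid[length(x_grid)] - x_grid[1L]),
    threshold = {
      if (is.null(knot)) knot <- (min(x_grid) + max(x_grid)) / 2
      baseline + delta * as.numeric(x_grid > knot)
    }
  )
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  sweep_series(x = x_grid, y = pmax(y, 1e-6), axis = axis,
               ylabel = ylabel, label = label)
}

#' Generate raw replicates from composition summaries
#'
#' For each (component, group) summary row, draws `n` Gaussian replicates
#' with the stated mean and SD, emulating the triplicate measurements behind
#' a published summary table. An SD of exactly 0 yields constant replicates
#' (the noiseless limit); negative SDs are rejected.
#'
#' @param summaries A composition summary `data.frame` (columns `component`,
#'   `group`, `mean`, `sd`, `n`).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `component`, `group`, `replicate`,
#'   `value`.
#' @seealso [welch_t_from_replicates()]
#' @export
gen_composition <- function(summaries, seed) {
  req <- c("component", "group", "mean", "sd", "n")
  if (!all(req %in% names(summaries))) {
    stop_input("gen_composition: summaries must have columns %s",
               paste(req, collapse = ", "))
  }
  if (any(summaries$sd < 0)) stop_input("gen_composition: sd must be nonnegative")
  if (any(summaries$n < 2)) stop_input("gen_composition: n must be >= 2 per group")
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(summaries)), function(i) {
      row <- summaries[i, ]
      data.frame(component = row$component, group = row$group,
                 replicate = seq_len(row$n),
                 value = stats::rnorm(row$n, row$mean, row$sd))
    })
    do.call(rbind, pieces)
  })
}
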