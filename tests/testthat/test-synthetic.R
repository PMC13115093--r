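test_that("generators are pure functions of (design, seed)", {
  des <- condition_design()
  expect_identical(gen_condition_table(des, seed = 42),
                   gen_condition_table(des, seed = 42))
  expect_false(identical(gen_condition_table(des, seed = 42),
                         gen_condition_table(des, seed = 43)))

  tdes <- titration_design()
  expect_identical(gen_titration(tdes, "stern_volmer", seed = 5),
                   gen_titration(tdes, "stern_volmer", seed = 5))

  ec <- energy_components(-27.76, -1.71, 3.07, -3.91)
  expect_identical(gen_energy_frames(ec, n_frames = 20, seed = 9),
                   gen_energy_frames(ec, n_frames = 20, seed = 9))

  summ <- wtmp_composition_table()[, c("component", "group", "mean", "sd", "n")]
  expect_identical(gen_composition(summ, seed = 13), gen_composition(summ, seed = 13))

  # the caller's RNG stream is not disturbed
  set.seed(1)
  before <- .Random.seed
  invisible(gen_condition_table(des, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("the default condition design is the 2 x 5 x 3 factorial", {
  tab <- gen_condition_table(condition_design(), seed = 1)
  expect_equal(nrow(tab), 30L)
  expect_setequal(unique(tab$mwco_kda), c(30, 100))
  expect_setequal(unique(tab$force_g), c(2000, 3000, 4000, 5000, 6000))
  expect_setequal(unique(tab$time_min), c(10, 20, 30))
  expect_false(anyDuplicated(tab[, 1:3]) > 0)
})

test_that("noiseless condition tables equal baseline plus effects and respect bounds", {
  des <- condition_design(noise_sd = c(z_ave_nm = 0, count_rate_kcps = 0,
                                       pdi = 0, zeta_mv = 0, conductivity = 0))
  a <- gen_condition_table(des, seed = 1)
  b <- gen_condition_table(des, seed = 999)
  expect_equal(a, b)  # noiseless => seed-independent values
  # the all-high cell carries exactly half of each effect above baseline
  row <- a[a$mwco_kda == 100 & a$time_min == 30 & a$force_g == 6000, ]
  eff <- des$effects
  expect_equal(row$z_ave_nm,
               des$baseline[["z_ave_nm"]] + (eff$z_ave_nm[["mwco"]] +
                 eff$z_ave_nm[["force"]] + eff$z_ave_nm[["time"]]) / 2)
  # heavy noise never pushes pdi out of [0,1] or sizes below zero
  noisy <- gen_condition_table(
    condition_design(noise_sd = c(z_ave_nm = 500, count_rate_kcps = 500,
                                  pdi = 0.8, zeta_mv = 10, conductivity = 3)),
    seed = 7)
  expect_true(all(noisy$pdi >= 0 & noisy$pdi <= 1))
  expect_true(all(noisy$z_ave_nm > 0 & noisy$count_rate_kcps > 0 &
                  noisy$conductivity > 0))
})

test_that("noiseless titrations follow the generating quenching laws exactly", {
  des <- titration_design(ksv_true = 1e6, noise_cv = 0,
                          q_grid = c(0, 1e-7, 5e-7, 1e-6))
  sv <- gen_titration(des, "stern_volmer", seed = 0)
  expect_equal(sv$f[1], des$f0)                       # quencher-free limit
  expect_equal(des$f0 / sv$f[4], 2)                   # Ksv * Q = 1 doubles F0/F
  expect_equal(des$f0 / sv$f, 1 + des$ksv_true * sv$q)

  bs <- gen_titration(titration_design(ka_true = 2e6, n_true = 1.3, noise_cv = 0),
                      "binding_site", seed = 0)
  expect_equal(bs$f0 / bs$f, 1 + 2e6 * bs$q^1.3)
  expect_error(gen_titration(des, "mass_action", seed = 0))
})

test_that("energy-frame generation hits its moments and the noiseless limit", {
  ec <- energy_components(-27.76, -1.71, 3.07, -3.91)
  still <- gen_energy_frames(ec, sds = c(vdw = 0, ele = 0, gb = 0, surf = 0),
                             n_frames = 8, seed = 1)
  expect_equal(unique(still$vdw), ec$vdw)
  expect_equal(unique(still$surf), ec$surf)

  big <- gen_energy_frames(ec, sds = c(vdw = 1, ele = 1, gb = 1, surf = 1),
                           n_frames = 10000, seed = 4)
  agg <- aggregate_components(big)
  for (comp in c("vdw", "ele", "gb", "surf")) {
    expect_lt(abs(agg$mean[[comp]] - ec[[comp]]), 0.05)
  }
  expect_error(gen_energy_frames(ec, n_frames = 0, seed = 1),
               class = "mnp_input_error")
})

test_that("sweep generation plants its deltas by construction", {
  lin <- gen_sweep(seq(10, 70, 10), baseline = 300, delta = 38,
                   shape = "linear", noise_sd = 0, seed = 1)
  m <- sweep_delta(lin)
  expect_equal(m$endpoint_delta, 38)
  expect_equal(m$range, 38)

  flat <- gen_sweep(c(1, 3, 5, 7), baseline = 400, delta = 0,
                    shape = "linear", noise_sd = 0, seed = 1)
  expect_equal(sweep_delta(flat)$range, 0)

  th <- gen_sweep(seq(0, 40, 5), baseline = 300, delta = -120,
                  shape = "threshold", noise_sd = 0, seed = 1, knot = 20)
  expect_equal(sweep_delta(th)$range, 120)
  expect_equal(th$y[th$x <= 20], rep(300, sum(th$x <= 20)))
  expect_error(gen_sweep(10, 300, 38, "linear", 0, 1), class = "mnp_input_error")
})

test_that("composition replicates honour their summaries", {
  summ <- data.frame(component = "protein", group = c("WTC", "WTMP"),
                     mean = c(379, 412), sd = c(0, 0), n = c(3L, 3L))
  reps <- gen_composition(summ, seed = 1)
  expect_equal(reps$value, rep(c(379, 412), each = 3))
  expect_error(gen_composition(transform(summ, sd = -1), seed = 1),
               class = "mnp_input_error")
  expect_error(gen_composition(transform(summ, n = 1L), seed = 1),
               class = "mnp_input_error")
})

test_that("simulated triplicates give Welch p-values consistent with the summary route", {
  # protein summaries; median simulated p across seeds should sit near the
  # summary-statistics p (same sampling model)
  p_summary <- welch_t_from_summary(379, 14, 3, 412, 12, 3)$p_two_sided
  summ <- data.frame(component = "protein", group = c("WTC", "WTMP"),
                     mean = c(379, 412), sd = c(14, 12), n = c(3L, 3L))
  ps <- vapply(1:200, function(s) {
    reps <- gen_composition(summ, seed = s)
    welch_t_from_replicates(reps$value[reps$group == "WTC"],
                            reps$value[reps$group == "WTMP"])$p_two_sided
  }, numeric(1))
  expect_lt(abs(log10(stats::median(ps)) - log10(p_summary)), 0.5)
})
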