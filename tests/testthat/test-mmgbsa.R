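test_that("derive_totals reproduces the published decomposition columns", {
  ref <- bsa_energy_table()
  for (i in seq_len(nrow(ref))) {
    dec <- derive_totals(energy_components(ref$vdw[i], ref$ele[i],
                                           ref$gb[i], ref$surf[i]))
    expect_equal(dec$gas, ref$gas[i], tolerance = 0.015)
    expect_equal(dec$solv, ref$solv[i], tolerance = 0.015)
    expect_equal(dec$bind, ref$bind[i], tolerance = 0.015)
  }
  # exact identities by construction
  dec <- derive_totals(energy_components(-27.76, -1.71, 3.07, -3.91))
  expect_identical(dec$gas, -27.76 + -1.71 + 0)
  expect_identical(dec$solv, 3.07 + -3.91)
  expect_identical(dec$bind, dec$gas + dec$solv)
  zero <- derive_totals(energy_components(0, 0, 0, 0))
  expect_equal(c(zero$gas, zero$solv, zero$bind), c(0, 0, 0))
  expect_error(energy_components(NaN, 0, 0, 0), class = "mnp_input_error")
})

test_that("aggregation over frames returns means and standard errors", {
  one <- data.frame(frame = 1, vdw = -27.7, ele = -1.7, gb = 3.1, surf = -3.9)
  agg1 <- aggregate_components(one)
  expect_equal(agg1$mean$vdw, -27.7)
  expect_equal(unname(agg1$sem), rep(0, 4))

  const <- one[rep(1, 10), ]
  const$frame <- 1:10
  expect_equal(unname(aggregate_components(const)$sem), rep(0, 4))

  ec <- energy_components(-50.37, -3.31, 7.21, -6.12)
  frames <- gen_energy_frames(ec, sds = c(vdw = 1, ele = 1, gb = 1, surf = 1),
                              n_frames = 10000, seed = 21)
  agg <- aggregate_components(frames)
  for (comp in c("vdw", "ele", "gb", "surf")) {
    expect_lt(abs(agg$mean[[comp]] - ec[[comp]]), 3 * agg$sem[[comp]] + 1e-12)
  }
  expect_error(aggregate_components(one[0, ]), class = "mnp_input_error")
})

test_that("the nonpolar solvation term is gamma times the SASA change", {
  expect_equal(nonpolar_solvation(100), 0.72)
  expect_equal(nonpolar_solvation(0), 0)
  # inversion round-trip against a published surf value
  dsasa <- -3.91 / 0.0072
  expect_equal(nonpolar_solvation(dsasa), -3.91, tolerance = 1e-12)
  expect_equal(nonpolar_solvation(250, gamma = 0.005), 1.25)
})

test_that("endpoint binding energy subtracts both receptor and ligand", {
  cx <- derive_totals(energy_components(-80, -5, 10, -9))
  rc <- derive_totals(energy_components(-30, -2, 4, -3))
  lg <- derive_totals(energy_components(-10, -1, 2, -1))
  expect_equal(binding_from_endpoints(cx, rc, lg),
               cx$bind - rc$bind - lg$bind)
  zero <- derive_totals(energy_components(0, 0, 0, 0))
  expect_equal(binding_from_endpoints(cx, zero, zero), cx$bind)

  set.seed(33)
  for (i in 1:20) {
    v <- stats::rnorm(12)
    cxi <- derive_totals(energy_components(v[1], v[2], v[3], v[4]))
    rci <- derive_totals(energy_components(v[5], v[6], v[7], v[8]))
    lgi <- derive_totals(energy_components(v[9], v[10], v[11], v[12]))
    # brute force: componentwise difference, then total
    diff_comp <- energy_components(v[1] - v[5] - v[9], v[2] - v[6] - v[10],
                                   v[3] - v[7] - v[11], v[4] - v[8] - v[12])
    expect_equal(binding_from_endpoints(cxi, rci, lgi),
                 derive_totals(diff_comp)$bind, tolerance = 1e-12)
  }
  # complex assembled exactly from its parts binds with energy 0
  parts <- derive_totals(energy_components(-40, -3, 6, -4))
  expect_equal(binding_from_endpoints(parts, derive_totals(energy_components(-30, -2, 4, -3)),
                                      derive_totals(energy_components(-10, -1, 2, -1))),
               0, tolerance = 1e-12)
})

test_that("the decomposition validator passes the published table and flags perturbations", {
  ref <- bsa_energy_table()
  v <- validate_decomposition_table(ref, tolerance = 0.015)
  expect_true(v$pass)
  expect_equal(v$n_failed, 0L)

  bad <- ref
  bad$bind[2] <- bad$bind[2] + 0.1
  vb <- validate_decomposition_table(bad, tolerance = 0.015)
  expect_false(vb$pass)
  expect_equal(which(!vb$rows$pass), 2L)

  exact <- data.frame(label = "syn", vdw = -1.25, ele = 0.5, gb = 2, surf = -3)
  exact$gas <- exact$vdw + exact$ele
  exact$solv <- exact$gb + exact$surf
  exact$bind <- exact$gas + exact$solv
  expect_true(validate_decomposition_table(exact, tolerance = 1e-12)$pass)
})
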