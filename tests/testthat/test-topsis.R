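test_that("the decision matrix stores |zeta| and preserves input order", {
  recs <- fixture_conditions(4)
  recs$zeta_mv <- c(-25, -20, 15, -18)
  dm <- build_decision_matrix(recs)
  expect_equal(dm$values[, "zeta_abs"], c(25, 20, 15, 18))
  expect_equal(dm$labels$force_g, recs$force_g)
  expect_equal(dim(dm$values), c(4L, 5L))
  expect_error(build_decision_matrix(recs[1, ]), class = "mnp_input_error")

  thirty <- gen_condition_table(condition_design(), seed = 2)
  expect_equal(dim(build_decision_matrix(thirty)$values), c(30L, 5L))
})

test_that("vector normalisation produces unit-norm columns", {
  expect_equal(topsis_normalize(cbind(c(3, 4)))[, 1], c(0.6, 0.8))
  expect_equal(topsis_normalize(cbind(rep(7, 4)))[, 1], rep(0.5, 4))
  X <- matrix(stats::runif(150, 0.1, 10), 30, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  Z <- topsis_normalize(X)
  expect_equal(unname(sqrt(colSums(Z^2))), rep(1, 5), tolerance = 1e-12)
  X[, 2] <- 0
  expect_error(topsis_normalize(X), "c2", class = "mnp_input_error")
})

test_that("weighting, ideals, distances and closeness follow their definitions", {
  Z <- diag(5)
  w <- c(0.15, 0.20, 0.25, 0.15, 0.25)
  expect_equal(apply_weights(Z, w), diag(w))
  expect_equal(apply_weights(Z, rep(1 / 5, 5)), Z / 5)

  U <- cbind(a = c(0.1, 0.3), b = c(0.1, 0.3))
  id <- ideal_solutions(U, c("benefit", "cost"))
  expect_equal(unname(id$pos), c(0.3, 0.1))
  expect_equal(unname(id$neg), c(0.1, 0.3))
  expect_error(ideal_solutions(U, c("benefit", "sideways")),
               class = "mnp_input_error")

  d <- separation_distances(rbind(c(0, 0)), list(pos = c(3, 4), neg = c(0, 0)))
  expect_equal(d$d_pos, 5)
  expect_equal(d$d_neg, 0)

  expect_equal(closeness(0.0262, 0.0746), 0.7404, tolerance = 0.001)
  expect_equal(closeness(0.2, 0), 0)
  expect_equal(closeness(0.3, 0.3), 0.5)
  expect_warning(expect_equal(closeness(0, 0), 0.5), "0.5")
  expect_error(closeness(-0.1, 0.2), class = "mnp_input_error")
})

test_that("ranking uses the competition convention and reports ties", {
  expect_equal(as.vector(rank_alternatives(c(0.2, 0.9, 0.5))), c(3L, 1L, 2L))
  r <- rank_alternatives(c(0.4, 0.4, 0.4))
  expect_equal(as.vector(r), c(1L, 1L, 1L))
  expect_equal(attr(r, "ties")[["1"]], 1:3)
})

test_that("run_topsis agrees with an independent six-step oracle on random matrices", {
  set.seed(20240901)
  for (case in 1:120) {
    m <- sample(2:5, 1)
    n <- sample(1:4, 1)
    X <- matrix(stats::runif(m * n, 0.05, 20), m, n)
    w <- stats::runif(n, 0.1, 1)
    w <- w / sum(w)
    dirs <- sample(c("benefit", "cost"), n, replace = TRUE)
    res <- run_topsis(make_dm(X, w, dirs))
    ora <- oracle_topsis(X, w, dirs)
    expect_equal(unname(res$normalized), ora$Z, tolerance = 1e-10)
    expect_equal(unname(res$weighted), ora$U, tolerance = 1e-10)
    expect_equal(unname(res$ideal_pos), ora$Ap, tolerance = 1e-10)
    expect_equal(unname(res$ideal_neg), ora$An, tolerance = 1e-10)
    expect_equal(res$d_pos, ora$dp, tolerance = 1e-10)
    expect_equal(res$d_neg, ora$dn, tolerance = 1e-10)
    expect_equal(res$closeness, ora$C, tolerance = 1e-10)
    expect_equal(res$rank, ora$rank)
    expect_true(all(res$closeness >= 0 & res$closeness <= 1))
  }
})

test_that("closeness is invariant to positive rescaling of a criterion column", {
  recs <- gen_condition_table(condition_design(), seed = 8)
  base <- run_topsis(recs)
  scaled <- recs
  scaled$conductivity <- scaled$conductivity * 1000  # e.g. unit change
  rescaled <- run_topsis(scaled)
  expect_equal(rescaled$closeness, base$closeness, tolerance = 1e-12)
  expect_equal(rescaled$rank, base$rank)
})

test_that("permuting alternatives permutes labels but not label-to-closeness mapping", {
  recs <- gen_condition_table(condition_design(), seed = 12)
  perm <- sample(nrow(recs))
  a <- run_topsis(recs)
  b <- run_topsis(recs[perm, ])
  expect_equal(b$closeness, a$closeness[perm], tolerance = 1e-12)
  expect_equal(b$labels$force_g, a$labels$force_g[perm])
})

test_that("a planted dominant alternative always ranks first", {
  cfg <- default_config()
  for (seed in c(1, 2, 3, 4, 5)) {
    recs <- gen_condition_table(condition_design(), seed = seed)
    # best value in each criterion direction: small size/pdi/conductivity,
    # large count rate and |zeta|
    recs[7, c("z_ave_nm", "pdi", "conductivity")] <-
      c(min(recs$z_ave_nm) * 0.5, min(recs$pdi) * 0.5, min(recs$conductivity) * 0.5)
    recs$count_rate_kcps[7] <- max(recs$count_rate_kcps) * 2
    recs$zeta_mv[7] <- -max(abs(recs$zeta_mv)) * 2
    res <- run_topsis(recs, cfg)
    expect_equal(res$rank[7], 1L)
    expect_true(all(res$closeness[7] > res$closeness[-7]))
  }
})

test_that("the published closeness table passes validation and a perturbed one fails", {
  ref <- wtmp_ranking_table()
  v <- validate_closeness_table(ref, tolerance = 0.001)
  expect_true(v$pass)
  expect_equal(v$n_failed, 0L)
  expect_true(v$rank_ok)

  bad <- ref
  bad$c_printed[1] <- 0.9
  vb <- validate_closeness_table(bad, tolerance = 0.001)
  expect_false(vb$pass)
  expect_equal(which(!vb$rows$pass), 1L)

  # exact synthetic rows pass at zero tolerance
  dp <- c(0.1, 0.2, 0.3)
  dn <- c(0.3, 0.2, 0.1)
  syn <- data.frame(d_pos = dp, d_neg = dn, c_printed = dn / (dp + dn),
                    rank_printed = c(1L, 2L, 3L))
  expect_true(validate_closeness_table(syn, tolerance = 1e-12)$pass)
})
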