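# Independent oracles, written as explicit element-wise loops so they share
# no code path with the package implementation.

# Literal six-step TOPSIS: normalise, weight, pick ideals by direction,
# Euclidean separations, closeness, competition rank.
oracle_topsis <- function(X, weights, directions) {
  m <- nrow(X)
  n <- ncol(X)
  Z <- matrix(0, m, n)
  for (j in seq_len(n)) {
    nrm <- sqrt(sum(X[, j]^2))
    for (i in seq_len(m)) Z[i, j] <- X[i, j] / nrm
  }
  U <- matrix(0, m, n)
  for (j in seq_len(n)) for (i in seq_len(m)) U[i, j] <- Z[i, j] * weights[j]
  Ap <- numeric(n)
  An <- numeric(n)
  for (j in seq_len(n)) {
    if (directions[j] == "benefit") {
      Ap[j] <- max(U[, j]); An[j] <- min(U[, j])
    } else {
      Ap[j] <- min(U[, j]); An[j] <- max(U[, j])
    }
  }
  dp <- numeric(m)
  dn <- numeric(m)
  for (i in seq_len(m)) {
    dp[i] <- sqrt(sum((U[i, ] - Ap)^2))
    dn[i] <- sqrt(sum((U[i, ] - An)^2))
  }
  C <- numeric(m)
  for (i in seq_len(m)) C[i] <- dn[i] / (dp[i] + dn[i])
  list(Z = Z, U = U, Ap = Ap, An = An, dp = dp, dn = dn, C = C,
       rank = as.integer(rank(-C, ties.method = "min")))
}

# Wrap an arbitrary numeric matrix as a decision_matrix so run_topsis can
# consume matrices outside the five-criterion schema.
make_dm <- function(X, weights, directions) {
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  structure(list(
    labels = data.frame(alt = seq_len(nrow(X))),
    values = X,
    criteria = colnames(X),
    directions = stats::setNames(directions, colnames(X)),
    weights = stats::setNames(weights, colnames(X))
  ), class = "decision_matrix")
}

# Closed-form simple-regression slope/intercept.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Small valid condition table built in code.
fixture_conditions <- function(n = 4) {
  data.frame(
    mwco_kda = rep(c(30, 100), length.out = n),
    time_min = rep(c(10, 20), each = ceiling(n / 2))[seq_len(n)],
    force_g = 1000 + 1000 * seq_len(n),
    z_ave_nm = seq(300, 300 + 10 * (n - 1), by = 10),
    count_rate_kcps = seq(200, 200 + 5 * (n - 1), by = 5),
    pdi = seq(0.2, 0.4, length.out = n),
    zeta_mv = seq(-25, -18, length.out = n),
    conductivity = seq(1.2, 1.8, length.out = n)
  )
}
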