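# Independent reference implementations used to cross-check the package.
# These deliberately use different formulations than the package code.

# Tetrachromat receptor-noise-limited distance, written out term by term as
# published for four receptor classes (receptors 1..4 = u, s, m, l).
oracle_tetra_jnd <- function(qa, qb, e) {
  df <- log(qa / qb)
  e1 <- e[1]; e2 <- e[2]; e3 <- e[3]; e4 <- e[4]
  f1 <- df[1]; f2 <- df[2]; f3 <- df[3]; f4 <- df[4]
  num <- (e1 * e2)^2 * (f4 - f3)^2 +
    (e1 * e3)^2 * (f4 - f2)^2 +
    (e1 * e4)^2 * (f3 - f2)^2 +
    (e2 * e3)^2 * (f4 - f1)^2 +
    (e2 * e4)^2 * (f3 - f1)^2 +
    (e3 * e4)^2 * (f2 - f1)^2
  den <- (e1 * e2 * e3)^2 + (e1 * e2 * e4)^2 +
    (e1 * e3 * e4)^2 + (e2 * e3 * e4)^2
  unname(sqrt(num / den))
}

# Dominant eigenvector by power iteration.
oracle_power_iteration <- function(V, iters = 500) {
  v <- rep(1, ncol(V)) / sqrt(ncol(V))
  for (i in seq_len(iters)) {
    v <- V %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}

# Plain hand-written trapezoid rule.
oracle_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Cook's distance from its definition, per observation.
oracle_cooks <- function(fit) {
  X <- stats::model.matrix(fit)
  h <- diag(X %*% solve(crossprod(X)) %*% t(X))
  p <- ncol(X)
  s2 <- sum(stats::resid(fit)^2) / fit$df.residual
  stats::resid(fit)^2 * h / (p * s2 * (1 - h)^2)
}

# Fixture: a small cohort-like table with both sexes and populations.
make_null_specimens <- function(n_per_cell = 12, n_pops = 3, seed = 1) {
  cfg <- scenario_config(n_populations = n_pops,
                         n_per_pop_per_sex = n_per_cell,
                         honesty_slope = 0, seed = seed)
  make_cohort(cfg)$specimens
}
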