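# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain double/triple loops over the definitions.

oracle_marginal_ecdf <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) sum(x <= x[i]) / n, numeric(1))
}

oracle_joint_count <- function(u, v) {
  n <- length(u)
  vapply(seq_len(n), function(i) sum(u <= u[i] & v <= v[i]), integer(1))
}

# Direct evaluation of the weighted sup-norm statistic at observed points,
# excluding points where F_u * F_v = 1.
oracle_gps_statistic <- function(u, v) {
  n <- length(u)
  best <- -Inf
  for (i in seq_len(n)) {
    fu <- sum(u <= u[i]) / n
    fv <- sum(v <= v[i]) / n
    fuv <- sum(u <= u[i] & v <= v[i]) / n
    denom2 <- fu * fv - fu^2 * fv^2
    if (denom2 <= 0) next
    t <- sqrt(n / log(n)) * abs(fuv - fu * fv) / sqrt(denom2)
    if (t > best) best <- t
  }
  best
}

# Classical Hoeffding D (x30) with midranks and half-credit ties.
oracle_hoeffding <- function(u, v) {
  n <- length(u)
  phi <- function(a, b) if (a < b) 1 else if (a == b) 0.5 else 0
  R <- rank(u, ties.method = "average")
  S <- rank(v, ties.method = "average")
  cc <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      s <- s + phi(u[j], u[i]) * phi(v[j], v[i])
    }
    cc[i] <- s
  }
  D1 <- sum(cc * (cc - 1))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * cc)
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# Random p-value vectors with controllable tie structure.
random_tied_vector <- function(n, n_distinct = NULL) {
  if (is.null(n_distinct) || is.na(n_distinct)) {
    runif(n)
  } else {
    sample(runif(n_distinct), n, replace = TRUE)
  }
}

# Random valid overlap design row.
random_overlap_design <- function(label_k = "k", label_l = "l") {
  k0 <- sample(100:50000, 1)
  k1 <- sample(50:20000, 1)
  l0 <- sample(100:50000, 1)
  l1 <- sample(50:20000, 1)
  tibble::tibble(
    study_k = label_k, study_l = label_l,
    n0_shared_controls = sample(0:min(k0, l0), 1),
    n1_shared_cases = sample(0:min(k1, l1), 1),
    k_controls = k0, k_cases = k1, l_controls = l0, l_cases = l1
  )
}

# Small synthetic summary-statistic TSVs for io tests.
write_sumstats_fixture <- function(path, df) {
  readr::write_tsv(df, path)
  path
}
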