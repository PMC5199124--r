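# Shared fixtures and independent oracles for the test suite.

# Best label agreement between a clustering and ground truth, maximized over
# label permutations (k <= 4 in our tests, exhaustive search is fine).
label_agreement <- function(labels, truth) {
  labels <- as.integer(factor(labels))
  truth <- as.integer(factor(truth))
  k <- max(labels, truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[labels] == truth))
  best
}

# Independent brute-force oracle for the KL ensemble distance: plain R double
# loop, no shared code with the package's nearest-neighbor path.
brute_kl_oracle <- function(xi, xj, pseudo = 0.5) {
  n_i <- nrow(xi); n_j <- nrow(xj); n <- n_i + n_j
  pooled <- rbind(xi, xj)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(pooled, 2, mu), 2, sdv, "/")
  ids <- rep(c(1L, 2L), c(n_i, n_j))
  same <- 0L
  for (a in seq_len(n)) {
    dbest <- Inf; jbest <- NA
    for (b in seq_len(n)) {
      if (a == b) next
      dd <- sum((z[a, ] - z[b, ])^2)
      if (dd < dbest) { dbest <- dd; jbest <- b }
    }
    if (ids[jbest] == ids[a]) same <- same + 1L
  }
  p_obs <- (same + pseudo) / (n + 2 * pseudo)
  p_null <- (n_i * (n_i - 1) + n_j * (n_j - 1)) / (n * (n - 1))
  p_obs * log(p_obs / p_null) + (1 - p_obs) * log((1 - p_obs) / (1 - p_null))
}

# One synthetic cell with a known theta*, preprocessed; cached across tests.
fixture_cell <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    proto <- stimulus_protocol(atp = 10, t_on = 30, duration = 480,
                               dt_out = 2)
    # a strong-negative-feedback cell: responsive but fast-decaying, which
    # keeps the ABC acceptance region broad enough for a desk-scale budget
    set.seed(310)
    pop <- sample_population(default_regimes(), 1)
    rend <- render_traces(pop$thetas, proto, noise_spec(), seed = 302)
    tr <- calcium_trace(rend$traces[1, ], dt = 2, stim_index = 16,
                        cell_id = "fixture")
    pre <- preprocess_trace(tr)
    pre$theta_true <- pop$thetas[1, ]
    pre$protocol <- proto
    cache <<- pre
    pre
  }
})

# Three regimes that differ only in the IP3R feedback constants d1/d5/dinh,
# with balanced membership; used by the clustering fast-path tests.
feedback_regimes <- function() {
  list(regime_spec("SP", c(d1 = -0.4, d5 = -0.5, dinh = +0.5), 0.1),
       regime_spec("SN", c(d1 = +0.4, dinh = -0.5), 0.1),
       regime_spec("WP", c(d5 = +0.5), 0.1))
}

balanced_population <- function(per_regime = 4, seed = 61) {
  regs <- feedback_regimes()
  set.seed(seed)
  thetas <- do.call(rbind, lapply(regs, function(rg)
    sample_population(list(rg), per_regime)$thetas))
  list(thetas = thetas,
       truth = rep(vapply(regs, `[[`, character(1), "name"),
                   each = per_regime))
}
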