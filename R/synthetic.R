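#' Parameter regime specification
#'
#' A regime is a log10-normal cloud in parameter space: a named set of mean
#' offsets from the reference values, a within-regime spread, and a
#' population weight.
#'
#' @param name Regime label.
#' @param offsets Named numeric vector of per-parameter log10 mean shifts
#'   (parameters not named get offset 0).
#' @param spread Within-regime log10 SD; either a scalar applied to all 17
#'   parameters or a full named vector.
#' @param weight Population fraction (weights are renormalized across the
#'   regime list).
#' @return Object of class `regime_spec`.
#' @export
regime_spec <- function(name, offsets = numeric(0), spread = 0.1,
                        weight = 1) {
  pn <- calci_param_names()
  off <- stats::setNames(rep(0, 17L), pn)
  if (length(offsets)) {
    stopifnot(!is.null(names(offsets)), all(names(offsets) %in% pn))
    off[names(offsets)] <- offsets
  }
  if (length(spread) == 1L) spread <- stats::setNames(rep(spread, 17L), pn)
  stopifnot(all(spread >= 0), weight > 0)
  structure(list(name = name, offsets = off, spread = spread[pn],
                 weight = weight), class = "regime_spec")
}

#' Default three-regime population
#'
#' Encodes the three cell states distinguished chiefly by the IP3R feedback
#' constants: strong positive feedback (low `d5`: stronger calcium
#' activation; high `dinh`: weaker inactivation), strong negative feedback
#' (low `dinh`: stronger inactivation, with elevated receptor/PLC gain),
#' and weak positive feedback (high `d5`). Offsets are +/-0.5 log10 on the
#' feedback constants with a within-regime spread of 0.1 log10.
#'
#' @param spread Within-regime log10 SD.
#' @return List of three [regime_spec()]s with equal weights.
#' @export
default_regimes <- function(spread = 0.1) {
  list(
    regime_spec("strong_positive", c(d5 = -0.5, dinh = +0.5), spread, 1 / 3),
    regime_spec("strong_negative", c(dinh = -0.5, k_plc = +0.3), spread, 1 / 3),
    regime_spec("weak_positive", c(d5 = +0.5), spread, 1 / 3)
  )
}

#' Measurement-noise specification
#'
#' @param sigma_meas Additive iid Gaussian measurement noise SD (uM).
#' @param hf_amp Amplitude (uM) of the high-frequency nuisance component -
#'   fast calcium fluctuations the deterministic model does not capture.
#' @param hf_freq Center frequency (Hz) of the nuisance band; must sit above
#'   the preprocessing cutoff and below Nyquist to emulate removable
#'   structure.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_meas = 0.02, hf_amp = 0.02, hf_freq = 0.2) {
  stopifnot(sigma_meas >= 0, hf_amp >= 0, hf_freq >= 0)
  structure(list(sigma_meas = sigma_meas, hf_amp = hf_amp,
                 hf_freq = hf_freq), class = "noise_spec")
}

#' Sample ground-truth parameter vectors for a population
#'
#' Assigns each cell to a regime (multinomial by weight) and draws its theta
#' from the regime's log10-normal, truncated by re-draw to the prior box.
#'
#' @param regimes List of [regime_spec()]s.
#' @param n_cells Number of cells.
#' @param seed Optional seed.
#' @param prior_halfwidth Truncation box half-width (log10).
#' @return List with `thetas` (n_cells x 17 matrix), `regime` (factor of
#'   regime names), `regimes`.
#' @export
sample_population <- function(regimes, n_cells, seed = NULL,
                              prior_halfwidth = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cells >= 1, length(regimes) >= 1)
  w <- vapply(regimes, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  rnames <- vapply(regimes, `[[`, character(1), "name")
  assign <- sample.int(length(regimes), n_cells, replace = TRUE, prob = w)
  thetas <- matrix(NA_real_, n_cells, 17L,
                   dimnames = list(NULL, calci_param_names()))
  for (i in seq_len(n_cells)) {
    rg <- regimes[[assign[i]]]
    repeat {
      th <- rnorm(17L, rg$offsets, rg$spread)
      if (all(abs(th) <= prior_halfwidth)) break
    }
    thetas[i, ] <- th
  }
  list(thetas = thetas, regime = factor(rnames[assign], levels = rnames),
       regimes = regimes)
}

#' Render noisy traces from ground-truth parameters
#'
#' Simulates each cell's calcium response and corrupts it with a band-limited
#' high-frequency nuisance component (a sinusoid with per-cell random
#' frequency jitter and phase) plus iid Gaussian measurement noise. The
#' protocol's pre-stimulus segment provides the baseline frames.
#'
#' @param thetas Matrix of log10 parameter vectors (one row per cell).
#' @param protocol A [stimulus_protocol()] (includes the baseline via
#'   `t_on`).
#' @param noise A [noise_spec()].
#' @param basal_ca Resting calcium (uM).
#' @param seed Optional seed.
#' @param max_resample Simulation failures are re-drawn this many times by
#'   jittering theta within the regime spread (0.05 log10) before erroring.
#' @return List of class `synthetic_population`: `traces` (n_cells x n_time
#'   matrix of noisy calcium), `clean` (noiseless simulations), `thetas`
#'   (possibly resampled), `times`, `protocol`, `noise`, `resampled`
#'   (integer count per cell).
#' @export
render_traces <- function(thetas, protocol = stimulus_protocol(),
                          noise = noise_spec(), basal_ca = 0.1, seed = NULL,
                          max_resample = 20L) {
  if (!is.null(seed)) set.seed(seed)
  n_cells <- nrow(thetas)
  nt <- floor(protocol$duration / protocol$dt_out + 1e-9) + 1
  traces <- matrix(NA_real_, n_cells, nt)
  clean <- matrix(NA_real_, n_cells, nt)
  resampled <- integer(n_cells)
  times <- (seq_len(nt) - 1) * protocol$dt_out
  for (i in seq_len(n_cells)) {
    th <- thetas[i, ]
    sim <- simulate_trace(th, protocol, basal_ca = basal_ca)
    while (sim_failed(sim)) {
      resampled[i] <- resampled[i] + 1L
      if (resampled[i] > max_resample)
        stop("cell ", i, ": simulation kept failing after resampling")
      th <- thetas[i, ] + rnorm(17L, 0, 0.05)
      th <- pmin(pmax(th, -1), 1)
      sim <- simulate_trace(th, protocol, basal_ca = basal_ca)
    }
    thetas[i, ] <- th
    clean[i, ] <- sim$values
    f <- noise$hf_freq * runif(1, 0.8, 1.2)
    hf <- noise$hf_amp * sin(2 * pi * f * times + runif(1, 0, 2 * pi))
    traces[i, ] <- sim$values + hf + rnorm(nt, 0, noise$sigma_meas)
  }
  rownames(traces) <- rownames(clean) <- sprintf("cell%03d", seq_len(n_cells))
  structure(list(traces = traces, clean = clean, thetas = thetas,
                 times = times, protocol = protocol, noise = noise,
                 resampled = resampled),
            class = "synthetic_population")
}

#' Generate a complete synthetic population
#'
#' Convenience wrapper: [sample_population()] then [render_traces()].
#'
#' @param n_cells Number of cells.
#' @param regimes List of [regime_spec()]s.
#' @param protocol,noise,basal_ca,seed See [render_traces()].
#' @return A `synthetic_population` with ground-truth `thetas` and `regime`.
#' @export
#' @examples
#' pop <- synthesize_population(4, seed = 1)
#' dim(pop$traces)
synthesize_population <- function(n_cells, regimes = default_regimes(),
                                  protocol = stimulus_protocol(),
                                  noise = noise_spec(), basal_ca = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- sample_population(regimes, n_cells)
  rend <- render_traces(pop$thetas, protocol, noise, basal_ca)
  rend$regime <- pop$regime
  rend$regimes <- regimes
  rend
}

#' Draw an idealized posterior ensemble around a regime mean
#'
#' Fast-path generator for clustering tests: instead of running the full
#' ABC-SMC fit, draws `n` particles from a Gaussian centered on a cell's true
#' theta with a given posterior spread. Mimics a converged ensemble.
#'
#' @param theta Center (length-17 log10 vector).
#' @param n Particles.
#' @param spread Posterior SD (log10); scalar or per-parameter.
#' @return A particle matrix usable wherever a `parameter_ensemble` is.
#' @export
idealized_ensemble <- function(theta, n = 200, spread = 0.08) {
  if (length(spread) == 1L) spread <- rep(spread, length(theta))
  m <- matrix(rnorm(n * length(theta), rep(theta, each = n),
                    rep(spread, each = n)), n, length(theta))
  colnames(m) <- calci_param_names()[seq_len(ncol(m))]
  m
}
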