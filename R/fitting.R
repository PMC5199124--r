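#' Goodness-of-fit score configuration
#'
#' @param deriv_weight Relative weight of the first-derivative term. The
#'   derivative term emphasizes the shape of the transient over its absolute
#'   level.
#' @return Object of class `score_config`.
#' @export
score_config <- function(deriv_weight = 1) {
  stopifnot(deriv_weight >= 0)
  structure(list(deriv_weight = deriv_weight), class = "score_config")
}

#' Score a simulation against processed data
#'
#' Sum of squared errors between the two series plus `deriv_weight` times the
#' sum of squared errors between their first differences:
#' \deqn{score = \sum_t (s_t - d_t)^2 + w \sum_t (\Delta s_t - \Delta d_t)^2}
#' Zero iff the series are identical. A failed simulation scores `Inf`.
#'
#' @param sim Simulated series, or a [simulate_trace()] result (possibly a
#'   failure object).
#' @param data Processed data series (same grid).
#' @param cfg A [score_config()].
#' @return Nonnegative scalar; `Inf` for failed simulations.
#' @export
score_trace <- function(sim, data, cfg = score_config()) {
  if (sim_failed(sim)) return(Inf)
  if (inherits(sim, "calcium_trace")) sim <- sim$values
  if (inherits(data, "calcium_trace")) data <- data$values
  if (length(sim) != length(data)) stop("sim and data must share a grid")
  r <- sim - data
  s <- sum(r * r)
  if (cfg$deriv_weight > 0) {
    rd <- diff(sim) - diff(data)
    s <- s + cfg$deriv_weight * sum(rd * rd)
  }
  s
}

#' ABC-SMC configuration
#'
#' @param n_particles Accepted-sample size per iteration (and per run).
#' @param quantile Threshold-update fraction: each iteration's threshold is
#'   this score-quantile of the previous accepted population (default 0.9,
#'   i.e. the new threshold discards the worst decile's level).
#' @param prior_halfwidth Half-range of the log10-uniform prior box around
#'   the reference values (default 1: two orders of magnitude total).
#' @param max_iterations Iteration cap; hitting it without reaching the final
#'   threshold flags the ensemble as non-fitted.
#' @param kernel_scale Perturbation-kernel variance multiplier; the kernel is
#'   component-wise Gaussian with variance `kernel_scale * 2 * var` of the
#'   previous population.
#' @param epsilon_prelim Acceptance threshold of the first iteration
#'   (default `Inf`: the first `n_particles` simulable draws are kept).
#' @param polish_iterations Extra rejection passes at `epsilon_final` after
#'   the schedule first reaches it (default 6). Pure adaptive rejection
#'   explores locally around the previous population; a few refresh passes at
#'   the final threshold decorrelate the sample from the descent path so that
#'   two independent runs mix over the whole acceptance region.
#' @param max_proposals Per-iteration proposal budget as a multiple of
#'   `n_particles`; exhausting it means "threshold unreachable".
#' @param batch Proposals simulated per inner batch.
#' @return Object of class `smc_config`.
#' @export
smc_config <- function(n_particles = 500, quantile = 0.9,
                       prior_halfwidth = 1, max_iterations = 30,
                       kernel_scale = 0.5, epsilon_prelim = Inf,
                       polish_iterations = 6, max_proposals = 400,
                       batch = 100) {
  stopifnot(n_particles >= 2, quantile > 0, quantile < 1,
            prior_halfwidth > 0, max_iterations >= 1, kernel_scale > 0,
            polish_iterations >= 0)
  structure(list(n_particles = as.integer(n_particles), quantile = quantile,
                 prior_halfwidth = prior_halfwidth,
                 max_iterations = as.integer(max_iterations),
                 kernel_scale = kernel_scale,
                 epsilon_prelim = epsilon_prelim,
                 polish_iterations = as.integer(polish_iterations),
                 max_proposals = max_proposals, batch = as.integer(batch)),
            class = "smc_config")
}

#' ABC rejection sampling
#'
#' Draws proposals from `propose`, scores each with `score_fn`, and keeps
#' those scoring at or below `epsilon` until `n` particles are accepted.
#'
#' @param propose Function `(m)` returning an `m x d` matrix of proposals.
#' @param score_fn Function mapping one parameter vector (a row) to a
#'   nonnegative score; `Inf` means a failed simulation.
#' @param epsilon Acceptance threshold.
#' @param n Number of particles to accept.
#' @param max_proposals Total proposal budget.
#' @param batch Proposals per batch.
#' @return List with `particles` (n x d), `scores`, `n_proposed`, and
#'   `status` (`"ok"` or `"threshold unreachable"`; in the latter case the
#'   particles collected so far are returned).
#' @export
rejection_sample <- function(propose, score_fn, epsilon, n,
                             max_proposals = 1e5, batch = 100) {
  stopifnot(n >= 1, epsilon >= 0)
  d <- ncol(propose(1L))
  acc <- matrix(NA_real_, n, d)
  scs <- numeric(n)
  got <- 0L
  proposed <- 0L
  while (got < n) {
    if (proposed >= max_proposals)
      return(list(particles = acc[seq_len(got), , drop = FALSE],
                  scores = scs[seq_len(got)],
                  n_proposed = as.integer(proposed),
                  status = "threshold unreachable"))
    m <- min(batch, max_proposals - proposed)
    th <- propose(m)
    proposed <- proposed + m
    for (i in seq_len(m)) {
      s <- score_fn(th[i, ])
      if (is.finite(s) && s <= epsilon) {
        got <- got + 1L
        acc[got, ] <- th[i, ]
        scs[got] <- s
        if (got == n) break
      }
    }
  }
  list(particles = acc, scores = scs, n_proposed = as.integer(proposed),
       status = "ok")
}

# Gaussian perturbation-kernel proposal around a previous population:
# uniformly resample a particle, add componentwise N(0, kernel_scale*2*var),
# and re-propose anything outside the prior box (never clip).
kernel_propose <- function(pop, kernel_scale, halfwidth) {
  d <- ncol(pop)
  sds <- sqrt(pmax(kernel_scale * 2 * apply(pop, 2, var), 1e-12))
  function(m) {
    out <- matrix(NA_real_, m, d)
    need <- seq_len(m)
    while (length(need)) {
      idx <- sample.int(nrow(pop), length(need), replace = TRUE)
      prop <- pop[idx, , drop = FALSE] +
        matrix(rnorm(length(need) * d, 0, rep(sds, each = length(need))),
               length(need), d)
      ok <- rowSums(abs(prop) > halfwidth) == 0
      out[need[ok], ] <- prop[ok, , drop = FALSE]
      need <- need[!ok]
    }
    out
  }
}

#' Fit one cell by ABC-SMC
#'
#' Sequential Monte Carlo around the ABC rejection sampler. Iteration 0
#' proposes from the log10-uniform prior box; each later iteration proposes
#' from the previous accepted population perturbed by a Gaussian kernel, with
#' the acceptance threshold set to the `quantile` score-quantile of the
#' previous population (never below `epsilon_final`). The run succeeds when
#' all particles score at or below `epsilon_final`.
#'
#' @param data Processed `calcium_trace` (stimulus-truncated; frame 1 is the
#'   basal point), or a plain numeric vector with `dt` taken from `protocol`.
#' @param epsilon_final Per-cell final acceptance threshold from
#'   [noise_floor()].
#' @param cfg An [smc_config()].
#' @param protocol A [stimulus_protocol()]; only `atp` is used, the grid and
#'   onset are taken from the data (stimulus at t = 0).
#' @param score_cfg A [score_config()].
#' @param free Integer indices of the parameters allowed to vary; others stay
#'   at their reference values. Default all 17.
#' @param run_id Run label (dual runs use 1 and 2).
#' @param seed Optional seed fixing the whole run.
#' @param score_fn Optional replacement scoring closure `(theta) -> score`
#'   (for toy problems and tests); when supplied, no ODE is simulated.
#' @param reference Reference parameter set.
#' @return Object of class `parameter_ensemble`: list with `particles`
#'   (n x length(free) log10 matrix, columns named), `scores`,
#'   `epsilon_final`, `cell_id`, `run_id`, `iterations_used`, `fitted`
#'   (logical), `n_proposed`, `thresholds` (per-iteration schedule), `free`.
#' @export
fit_cell <- function(data, epsilon_final, cfg = smc_config(),
                     protocol = stimulus_protocol(), score_cfg = score_config(),
                     free = seq_len(17L), run_id = 1L, seed = NULL,
                     score_fn = NULL, reference = calci_reference_params()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(epsilon_final >= 0)
  d <- length(free)
  cell_id <- "cell"
  if (is.null(score_fn)) {
    if (inherits(data, "calcium_trace")) {
      vals <- data$values
      dt <- data$dt
      cell_id <- data$cell_id
    } else {
      vals <- as.numeric(data)
      dt <- protocol$dt_out
    }
    basal <- vals[1]
    fit_proto <- stimulus_protocol(atp = protocol$atp, t_on = 0,
                                   duration = (length(vals) - 1) * dt,
                                   dt_out = dt)
    theta_full <- rep(0, 17L)
    score_fn <- function(th) {
      theta_full[free] <- th
      sim <- simulate_trace(theta_full, fit_proto, basal_ca = basal,
                            reference = reference)
      score_trace(sim, vals, score_cfg)
    }
  }
  hw <- cfg$prior_halfwidth
  prior_propose <- function(m) matrix(runif(m * d, -hw, hw), m, d)
  budget <- cfg$max_proposals * cfg$n_particles
  thresholds <- numeric(0)

  res <- rejection_sample(prior_propose, score_fn, cfg$epsilon_prelim,
                          cfg$n_particles, max_proposals = budget,
                          batch = cfg$batch)
  n_proposed <- res$n_proposed
  iterations <- 1L
  fitted <- FALSE
  status <- res$status
  polish_left <- cfg$polish_iterations
  while (status == "ok") {
    if (all(res$scores <= epsilon_final)) {
      fitted <- TRUE
      if (polish_left == 0L) break
      polish_left <- polish_left - 1L
    }
    if (iterations >= cfg$max_iterations + cfg$polish_iterations) break
    eps <- max(quantile(res$scores, cfg$quantile, names = FALSE),
               epsilon_final)
    thresholds <- c(thresholds, eps)
    prop <- kernel_propose(res$particles, cfg$kernel_scale, hw)
    res2 <- rejection_sample(prop, score_fn, eps, cfg$n_particles,
                             max_proposals = budget, batch = cfg$batch)
    n_proposed <- n_proposed + res2$n_proposed
    iterations <- iterations + 1L
    status <- res2$status
    if (status == "ok") res <- res2 else break
  }
  # a polish pass that ran out of budget must not erase an achieved fit
  if (fitted) status <- "ok"
  particles <- res$particles
  colnames(particles) <- calci_param_names()[free]
  structure(list(particles = particles, scores = res$scores,
                 epsilon_final = epsilon_final, cell_id = cell_id,
                 run_id = run_id, iterations_used = iterations,
                 fitted = fitted, n_proposed = n_proposed,
                 thresholds = thresholds, free = free, status = status),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf(
    "<parameter_ensemble> %s run %s: %d particles (%d-D), %d iterations, %s\n",
    x$cell_id, x$run_id, nrow(x$particles), ncol(x$particles),
    x$iterations_used,
    if (x$fitted) sprintf("fitted (eps_final=%.3g)", x$epsilon_final)
    else paste0("NOT fitted (", x$status, ")")))
  invisible(x)
}
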