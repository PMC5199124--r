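#' @useDynLib calcistate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile var median sd pchisq cutree
#'   hclust as.dist
NULL

# Frozen parameter order. Everything downstream (priors, ensembles, CSV
# columns) uses this ordering; do not reorder.
.PARAM_NAMES <- c(
  "d1", "d5", "dinh", "a2", "v_ip3r", "v_serca", "k_serca",
  "k_plc", "k_r", "k_plc_deg", "v_ip3_prod", "k_plc_half", "n_hill",
  "k_ip3_deg", "c_er", "ca_tot", "beta_buf"
)

#' Names of the 17 model parameters, in frozen order
#'
#' The order defines the layout of every parameter vector and ensemble matrix
#' in the package.
#'
#' @return Character vector of length 17.
#' @export
calci_param_names <- function() .PARAM_NAMES

#' Reference kinetic parameter values
#'
#' Reference (natural-scale) values for the 17 kinetic constants of the
#' calcium-response model. IP3R gating constants (`d1`, `d5`, `dinh`, `a2`)
#' and the ER:cytosol scaling follow the simplified two-variable reduction of
#' the De Young-Keizer receptor model; SERCA and buffering values follow the
#' Lemon-style plasma-membrane-free formulation; receptor/PLC/IP3 turnover
#' rates are set so a 10 uM ATP step yields a sharp sub-minute calcium rise
#' decaying to an elevated plateau over a 15-minute acquisition.
#'
#' @details Units: `d1`, `d5`, `dinh`, `k_serca`, `ca_tot` in uM;
#'   `a2` in 1/(uM s); `v_ip3r`, `k_r`, `k_plc_deg`, `k_ip3_deg` in 1/s;
#'   `v_serca`, `v_ip3_prod` in uM/s; `k_plc` in a.u./(uM s); `k_plc_half`
#'   in a.u.; `n_hill`, `c_er`, `beta_buf` dimensionless.
#'
#' @return Named numeric vector of length 17 in the frozen parameter order.
#' @export
#' @examples
#' ref <- calci_reference_params()
#' ref[["d1"]]
calci_reference_params <- function() {
  c(
    d1         = 0.13,    # IP3R IP3-activation equilibrium constant (uM)
    d5         = 0.08234, # IP3R calcium-activation equilibrium constant (uM)
    dinh       = 1.049,   # IP3R calcium-inactivation equilibrium constant (uM)
    a2         = 0.2,     # IP3R inactivation gating rate (1/(uM s))
    v_ip3r     = 6.0,     # maximal IP3R channel flux rate (1/s)
    v_serca    = 0.9,     # SERCA maximal pump rate (uM/s)
    k_serca    = 0.1,     # SERCA half-saturation (uM)
    k_plc      = 0.05,    # receptor-mediated PLC activation gain (a.u./(uM s))
    k_r        = 0.004,   # receptor desensitization rate (1/s)
    k_plc_deg  = 0.1,     # PLC deactivation rate (1/s)
    v_ip3_prod = 0.3,     # maximal IP3 production rate (uM/s)
    k_plc_half = 1.0,     # PLC level at half-maximal IP3 production (a.u.)
    n_hill     = 2.0,     # Hill coefficient of IP3 production
    k_ip3_deg  = 0.06,    # IP3 linear degradation rate (1/s)
    c_er       = 0.185,   # ER:cytosol volume/scaling factor
    ca_tot     = 2.0,     # total conserved calcium (uM, cytosolic volume)
    beta_buf   = 0.1      # calcium buffering factor (fraction free)
  )[.PARAM_NAMES]
}

#' Stimulus protocol
#'
#' @param atp Ligand (ATP) concentration in uM; the stimulus is a step at
#'   `t_on` whose effective drive decays exponentially with the receptor
#'   desensitization rate.
#' @param t_on Stimulus onset time (s).
#' @param duration Total simulated/acquired time (s).
#' @param dt_out Output sampling interval (s).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(atp = 10, t_on = 30, duration = 930,
                              dt_out = 2) {
  stopifnot(atp >= 0, t_on >= 0, duration > t_on, dt_out > 0)
  structure(list(atp = atp, t_on = t_on, duration = duration,
                 dt_out = dt_out), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %g uM ATP at t=%gs, %gs total @ dt=%gs\n",
              x$atp, x$t_on, x$duration, x$dt_out))
  invisible(x)
}

# theta (log10 fold-change, frozen order) -> natural-scale named vector
theta_to_natural <- function(theta, reference = calci_reference_params()) {
  stopifnot(length(theta) == 17L, all(is.finite(theta)))
  p <- reference * 10^theta
  names(p) <- .PARAM_NAMES
  p
}

#' Model right-hand side
#'
#' Time derivatives of the four state variables (ip3, plc, ca, h) at a given
#' state and time. The PLC activation term is multiplied by the ligand step
#' and the exponential receptor-desensitization factor; IP3 production is a
#' Hill function of PLC with linear degradation; the calcium flux balances
#' IP3R release (Li-Rinzel open probability), an ER leak closed at the rest
#' state, and SERCA pumping, scaled by the single buffering factor; ER
#' calcium is eliminated through the conserved-total constraint.
#'
#' @param state Numeric length-4 vector `c(ip3, plc, ca, h)`.
#' @param t Time (s).
#' @param params Named natural-scale parameter vector (17 values, frozen
#'   order).
#' @param protocol A [stimulus_protocol()].
#' @param basal_ca Resting cytosolic calcium (uM) used to close the ER leak.
#' @return Numeric length-4 derivative vector (per second).
#' @export
calci_rhs <- function(state, t, params, protocol, basal_ca = 0.1) {
  params <- params[.PARAM_NAMES]
  calci_rhs_cpp(as.numeric(state), t, as.numeric(params),
                protocol$atp, protocol$t_on, basal_ca)
}

#' Pre-stimulus rest state
#'
#' The unstimulated fixed point used as the integration initial condition:
#' with no ligand there is no PLC activity and no IP3, cytosolic calcium sits
#' at the measured basal level (ER leak balances SERCA by construction), and
#' the gating variable sits at its equilibrium `dinh / (dinh + ca)`.
#'
#' @param params Named natural-scale parameter vector.
#' @param basal_ca Resting cytosolic calcium (uM), typically the first point
#'   of the processed trace.
#' @return Named numeric vector `c(ip3, plc, ca, h)`, or an error if no
#'   admissible rest state exists (ER calcium not above cytosolic).
#' @export
find_rest_state <- function(params, basal_ca) {
  stopifnot(basal_ca > 0)
  params <- params[.PARAM_NAMES]
  ca_er0 <- (params[["ca_tot"]] - basal_ca) / params[["c_er"]]
  if (!is.finite(ca_er0) || ca_er0 <= basal_ca)
    stop("no admissible rest state: implied ER calcium not above cytosolic")
  c(ip3 = 0, plc = 0, ca = basal_ca,
    h = params[["dinh"]] / (params[["dinh"]] + basal_ca))
}

#' Simulate a calcium trace
#'
#' Integrates the model from the rest state and returns the cytosolic calcium
#' sampled on the output grid. Deterministic given its inputs. Integration
#' failures (step underflow, runaway or conservation-violating states,
#' non-positive parameters) are reported via `status`, never as an error, so
#' the ABC sampler can score them as rejections.
#'
#' @param theta Length-17 vector of log10 fold-changes from the reference
#'   parameters (a `ParameterVector`), or NULL with `params` given.
#' @param protocol A [stimulus_protocol()].
#' @param basal_ca Resting calcium (uM).
#' @param params Optional natural-scale parameter vector overriding `theta`.
#' @param reference Reference parameter set for the fold-change mapping.
#' @param rtol,atol Integrator tolerances.
#' @param full_state If TRUE attach the full 4-column state matrix.
#' @return A `calcium_trace` (see [calcium_trace()]) with attribute
#'   `status` `"ok"`, or a list with `status = "failed"` on solver failure.
#' @export
#' @examples
#' tr <- simulate_trace(rep(0, 17), stimulus_protocol())
#' max(tr$values)
simulate_trace <- function(theta = NULL, protocol = stimulus_protocol(),
                           basal_ca = 0.1, params = NULL,
                           reference = calci_reference_params(),
                           rtol = 1e-6, atol = 1e-9, full_state = FALSE) {
  if (is.null(params)) params <- theta_to_natural(theta, reference)
  params <- params[.PARAM_NAMES]
  res <- calci_simulate_cpp(as.numeric(params), protocol$atp, protocol$t_on,
                            protocol$duration, protocol$dt_out, basal_ca,
                            rtol, atol, 2e6)
  if (res$status != 0)
    return(structure(list(values = NULL, status = "failed"),
                     class = "calci_sim_failure"))
  tr <- calcium_trace(values = res$states[, 3], dt = protocol$dt_out,
                      stim_index = as.integer(round(protocol$t_on /
                                                      protocol$dt_out)) + 1L,
                      cell_id = "sim")
  attr(tr, "status") <- "ok"
  attr(tr, "times") <- res$times
  if (full_state) {
    colnames(res$states) <- c("ip3", "plc", "ca", "h")
    attr(tr, "states") <- res$states
  }
  tr
}

#' Did a simulation fail?
#' @param x Result of [simulate_trace()].
#' @return TRUE if the integrator reported failure.
#' @export
sim_failed <- function(x) inherits(x, "calci_sim_failure")
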