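# Deterministic mass-action model of the three-reaction ligase mechanism:
#   (1) self-adenylation     E + pppA -> EpA + PPi          v1 = k1 (1+alpha R) E pppA
#   (2) adenylyl transfer    EpA + pD -> E + AppD           v2 = k2 (1+alpha R) EpA pD
#   (3) ligation             AppD + R -> RpD + pA  (E cat.) v3 = k3 E AppD R
# Only the free (non-adenylated) enzyme E catalyzes reaction 3: the adenylated
# enzyme cannot execute the joining step, which is what starves ligation when
# self-adenylation outruns adenylyl transfer. Units are uM and minutes.

SPECIES <- c("E", "EpA", "pppA", "PPi", "pD", "AppD", "R", "RpD", "pA")

#' Rate constants of the three-reaction ligase model
#'
#' @param k1 Self-adenylation rate constant (uM^-1 min^-1).
#' @param k2 Adenylyl-transfer rate constant (uM^-1 min^-1).
#' @param k3 Ligation rate constant (uM^-2 min^-1; reaction 3 is modeled as a
#'   single trimolecular step with the free enzyme as catalyst).
#' @param alpha Acceptor-stimulation coefficient (uM^-1): reactions 1 and 2
#'   are multiplied by `(1 + alpha * R)`; 0 disables stimulation.
#' @param epa0_frac Fraction of enzyme initially adenylated, in `[0, 1]`
#'   (enzyme preparations are typically partially adenylated).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k2, k3, alpha = 0, epa0_frac = 0) {
  for (v in list(k1 = k1, k2 = k2, k3 = k3, alpha = alpha)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0) stop_arg("rate constants must be single non-negative numbers")
  }
  if (epa0_frac < 0 || epa0_frac > 1) stop_arg("epa0_frac must be in [0, 1]")
  structure(list(k1 = k1, k2 = k2, k3 = k3, alpha = alpha, epa0_frac = epa0_frac),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: k1=%g k2=%g k3=%g alpha=%g epa0_frac=%g (uM, min)\n",
              x$k1, x$k2, x$k3, x$alpha, x$epa0_frac))
  invisible(x)
}

#' Preset parameter sets for the two enzyme classes
#'
#' The rate constants are invented model constants (no rates are available for
#' these enzymes); each preset is defined by the qualitative behavior it must
#' reproduce under the default assay-scale initial condition (2 uM enzyme,
#' donor and acceptor):
#' * `adenylation_proficient` (CircLigase II / TS2126-like): self-adenylation
#'   and adenylyl transfer are fast, so the 5'-phosphorylated donor is
#'   depleted (>90% converted to AppD+RpD) within 60 min at 500 uM ATP, the
#'   ligation product plateaus early, and less ATP gives more product.
#' * `adenylation_deficient` (SDL-like): self-adenylation is slow (modeled as
#'   low `k1`), the adenylated donor stays below 10% of the donor total at
#'   480 min, and product accumulates with time at every ATP concentration.
#'
#' @param profile Which preset.
#' @return A `kinetic_params`.
#' @export
preset_params <- function(profile = c("adenylation_proficient", "adenylation_deficient")) {
  profile <- match.arg(profile)
  switch(profile,
    adenylation_proficient = kinetic_params(k1 = 0.5, k2 = 1, k3 = 0.2,
                                            alpha = 0.5, epa0_frac = 0.2),
    adenylation_deficient  = kinetic_params(k1 = 1e-6, k2 = 1.5e-3, k3 = 1,
                                            alpha = 0.5, epa0_frac = 0.2))
}

#' Initial state for a ligation time course
#'
#' @param params A `kinetic_params` (supplies `epa0_frac`).
#' @param E_tot Total enzyme (uM); the default assay uses enzyme in excess of
#'   the donor, split into free and adenylated forms by `epa0_frac`.
#' @param pD 5'-phosphorylated donor (uM).
#' @param R Acceptor (uM).
#' @param atp ATP (uM).
#' @return A named state vector over the nine species.
#' @export
kinetic_init <- function(params, E_tot = 2, pD = 2, R = 2, atp = 500) {
  if (any(c(E_tot, pD, R, atp) < 0)) stop_arg("initial concentrations must be >= 0")
  c(E = E_tot * (1 - params$epa0_frac), EpA = E_tot * params$epa0_frac,
    pppA = atp, PPi = 0, pD = pD, AppD = 0, R = R, RpD = 0, pA = 0)
}

deriv_core <- function(s, p) {
  stim <- 1 + p$alpha * s[["R"]]
  v1 <- p$k1 * stim * s[["E"]] * s[["pppA"]]
  v2 <- p$k2 * stim * s[["EpA"]] * s[["pD"]]
  v3 <- p$k3 * s[["E"]] * s[["AppD"]] * s[["R"]]
  c(E = -v1 + v2, EpA = v1 - v2, pppA = -v1, PPi = v1,
    pD = -v2, AppD = v2 - v3, R = -v3, RpD = v3, pA = v3)
}

#' Rate of change of every species
#'
#' Mass-action derivative field of the three-reaction mechanism. By
#' construction `dE + dEpA = 0`, `dpD + dAppD + dRpD = 0`, `dR + dRpD = 0`
#' and `dEpA + dAppD + dpA + dpppA = 0` (AMP-moiety balance).
#'
#' @param state Named concentration vector (see [kinetic_init()]); all >= 0.
#' @param params A `kinetic_params`.
#' @return Named vector of derivatives (uM/min).
#' @export
ligase_derivatives <- function(state, params) {
  if (!all(SPECIES %in% names(state))) {
    stop_arg("state must name the species ", paste(SPECIES, collapse = ", "))
  }
  if (any(state < 0)) stop_data("negative concentration in state: ",
                                names(state)[which(state < 0)[1L]])
  deriv_core(state[SPECIES], params)
}

#' Integrate a ligation time course
#'
#' Adaptive stiff integration (deSolve::lsoda) of the three-reaction model.
#' Default tolerances keep the four conservation sums (enzyme, donor,
#' acceptor, AMP moiety) within 1e-8 relative drift; tiny integrator
#' undershoots below 0 are clipped to 0 inside the rate evaluation only.
#'
#' @param params A `kinetic_params`.
#' @param init Initial state (default [kinetic_init()] with the assay-scale
#'   concentrations).
#' @param t_end End time in minutes.
#' @param n_points Number of (evenly spaced) output times, including 0.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `ligation_timecourse`: `time` plus one
#'   column per species.
#' @export
simulate_kinetics <- function(params, init = kinetic_init(params), t_end = 480,
                              n_points = 201L, rtol = 1e-9, atol = 1e-12) {
  if (t_end <= 0) stop_arg("t_end must be > 0")
  times <- seq(0, t_end, length.out = n_points)
  f <- function(t, y, parms) {
    if (any(y < -1e-6)) stop_data("integration failure: state went negative at t=", signif(t, 4))
    list(deriv_core(pmax(y, 0), parms))
  }
  out <- deSolve::lsoda(init[SPECIES], times, f, params, rtol = rtol, atol = atol,
                        maxsteps = 100000L)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0) {
    stop_data("integration failure: lsoda istate=", istate[1L])
  }
  tc <- as.data.frame(out)
  names(tc)[1L] <- "time"
  class(tc) <- c("ligation_timecourse", "data.frame")
  tc
}

#' Conservation sums along a time course
#'
#' @param tc A `ligation_timecourse`.
#' @return Data frame with `time` and the four conserved sums: `enzyme`
#'   (E+EpA), `donor` (pD+AppD+RpD), `acceptor` (R+RpD) and `amp`
#'   (EpA+AppD+pA+pppA).
#' @export
conservation_sums <- function(tc) {
  data.frame(time = tc$time,
             enzyme = tc$E + tc$EpA,
             donor = tc$pD + tc$AppD + tc$RpD,
             acceptor = tc$R + tc$RpD,
             amp = tc$EpA + tc$AppD + tc$pA + tc$pppA)
}

#' Maximum relative drift of the conservation sums
#'
#' For each conserved sum, the maximum deviation from its initial value,
#' relative to that value (absolute when the initial value is 0).
#'
#' @param tc A `ligation_timecourse`.
#' @return A single number: the worst relative drift across the four sums.
#' @export
conservation_drift <- function(tc) {
  cs <- conservation_sums(tc)
  max(vapply(c("enzyme", "donor", "acceptor", "amp"), function(nm) {
    s <- cs[[nm]]
    if (abs(s[1L]) > 0) max(abs(s - s[1L])) / abs(s[1L]) else max(abs(s))
  }, numeric(1)))
}

#' Endpoint yields across ATP concentrations
#'
#' One simulation per ATP level under a shared initial condition; reports the
#' ligation product, adenylated donor and unreacted donor at `t_end`.
#'
#' @param params A `kinetic_params`.
#' @param atp_levels ATP concentrations in uM.
#' @param t_end End time in minutes.
#' @param E_tot,pD,R Shared initial concentrations (uM).
#' @param n_points Output grid size per simulation.
#' @return Data frame: `atp`, `RpD`, `AppD`, `pD`.
#' @export
atp_titration <- function(params, atp_levels = c(0, 50, 500), t_end = 480,
                          E_tot = 2, pD = 2, R = 2, n_points = 201L) {
  if (length(atp_levels) == 0L) stop_arg("atp_levels must be non-empty")
  rows <- lapply(atp_levels, function(a) {
    tc <- simulate_kinetics(params, kinetic_init(params, E_tot, pD, R, atp = a),
                            t_end = t_end, n_points = n_points)
    last <- tc[nrow(tc), ]
    data.frame(atp = a, RpD = last$RpD, AppD = last$AppD, pD = last$pD)
  })
  do.call(rbind, rows)
}
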