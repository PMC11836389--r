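#' NONOate donor specification
#'
#' Describes a diazeniumdiolate (NONOate) NO donor by its first-order release
#' half-life and NO stoichiometry. Three donors commonly used to set
#' steady-state NO levels in enzyme assays are built in: DEA/NO (short-acting,
#' t1/2 = 16 min, 1.5 mol NO per mol donor), Sper/NO (t1/2 = 230 min, 2 NO)
#' and DETA/NO (slow, t1/2 = 57 h, 2 NO). Half-lives apply at the assay
#' temperature they were characterised at; no Arrhenius correction is applied.
#'
#' @param name Donor identifier. One of `"dea"`, `"sper"`, `"deta"` for the
#'   built-in donors, or any string when `half_life` and `no_equivalents` are
#'   given explicitly.
#' @param half_life Release half-life in seconds. Required for custom donors;
#'   overrides the built-in value when supplied.
#' @param no_equivalents Moles of NO released per mole of donor.
#' @param note Free-text note (e.g. the temperature the half-life applies to).
#'
#' @return An object of class `donor_spec`: a list with fields `name`,
#'   `half_life` (s), `no_equivalents`, `note`.
#' @examples
#' donor_spec("sper")
#' donor_spec("custom", half_life = 3600, no_equivalents = 2)
#' @export
donor_spec <- function(name, half_life = NULL, no_equivalents = NULL, note = NULL) {
  builtin <- list(
    dea  = list(half_life = 16 * 60,      no_equivalents = 1.5, note = "25 C"),
    sper = list(half_life = 230 * 60,     no_equivalents = 2,   note = "25 C"),
    deta = list(half_life = 57 * 3600,    no_equivalents = 2,   note = "37 C")
  )
  key <- tolower(name)
  if (key %in% names(builtin)) {
    half_life <- half_life %||% builtin[[key]]$half_life
    no_equivalents <- no_equivalents %||% builtin[[key]]$no_equivalents
    note <- note %||% builtin[[key]]$note
  }
  if (is.null(half_life) || is.null(no_equivalents)) {
    abort("custom donors need both `half_life` and `no_equivalents`")
  }
  if (!is.numeric(half_life) || length(half_life) != 1L || !is.finite(half_life) ||
      half_life <= 0) {
    abort("`half_life` must be a single positive number (seconds)")
  }
  if (!is.numeric(no_equivalents) || length(no_equivalents) != 1L ||
      !is.finite(no_equivalents) || no_equivalents <= 0) {
    abort("`no_equivalents` must be a single positive number")
  }
  structure(
    list(name = name, half_life = as.numeric(half_life),
         no_equivalents = as.numeric(no_equivalents), note = note),
    class = "donor_spec"
  )
}

#' @export
print.donor_spec <- function(x, ...) {
  cat(sprintf("<donor_spec> %s: t1/2 = %g s, %g NO equivalents\n",
              x$name, x$half_life, x$no_equivalents))
  invisible(x)
}

#' Kinetic parameters for NO autooxidation
#'
#' Parameters of the aqueous NO consumption model. NO autooxidation
#' (4NO + O2 -> 4NO2-) is third order overall with rate `k_aut [NO]^2 [O2]`;
#' with `no_per_o2 = 4` NO is consumed at four times that rate and O2 at that
#' rate, the textbook stoichiometry. Internal units are micromolar and
#' seconds, so the literature rate constant 2e6 M^-2 s^-1 becomes the default
#' `k_aut = 2e-6` uM^-2 s^-1.
#'
#' @param k_aut Autooxidation rate constant, uM^-2 s^-1.
#' @param no_per_o2 NO:O2 consumption stoichiometry (1, 2 or 4).
#' @param o2_initial Initial dissolved O2, uM (air-saturated buffer ~ 220 uM).
#' @param temperature_note Free-text note.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()
#' @export
kinetic_params <- function(k_aut = 2e-6, no_per_o2 = 4, o2_initial = 220,
                           temperature_note = "room temperature, air-saturated") {
  if (!is.numeric(k_aut) || length(k_aut) != 1L || !is.finite(k_aut) || k_aut <= 0) {
    abort("`k_aut` must be a single positive number (uM^-2 s^-1)")
  }
  if (!no_per_o2 %in% c(1, 2, 4)) {
    abort("`no_per_o2` must be 1, 2 or 4")
  }
  if (!is.numeric(o2_initial) || length(o2_initial) != 1L || !is.finite(o2_initial) ||
      o2_initial < 0) {
    abort("`o2_initial` must be a single non-negative number (uM)")
  }
  structure(
    list(k_aut = as.numeric(k_aut), no_per_o2 = as.numeric(no_per_o2),
         o2_initial = as.numeric(o2_initial), temperature_note = temperature_note),
    class = "kinetic_params"
  )
}

#' First-order decay constant of an NO donor
#'
#' `k = ln(2) / half_life`, the rate constant of first-order donor
#' decomposition.
#'
#' @param donor A [donor_spec()].
#' @return Decay constant in s^-1.
#' @examples
#' decay_constant(donor_spec("dea")) # ln(2)/960 = 7.22e-4 s^-1
#' @export
decay_constant <- function(donor) {
  stopifnot(inherits(donor, "donor_spec"))
  log(2) / donor$half_life
}

#' Simulate donor decomposition and NO autooxidation
#'
#' Integrates the donor/NO/O2 system: the donor decays first order
#' (`d[D]/dt = -k1 [D]`), NO is released at `k1 [D] e_NO` and consumed by
#' autooxidation at `s k_aut [O2] [NO]^2` where `s = no_per_o2`, and O2 is
#' consumed at one molecule per `s` NO (`d[O2]/dt = -k_aut [O2] [NO]^2`).
#' O2 is a dynamic state, not a constant. Cumulative oxidised NO is tracked
#' so that mass balance `e_NO (dose - [D]) = [NO] + consumed` holds at every
#' output time.
#'
#' The integrator is [deSolve::lsoda()] (stiff-capable, adaptive) at relative
#' tolerance 1e-8 and absolute tolerance 1e-6 uM. Tiny negative excursions
#' within the absolute tolerance are clipped to zero; larger ones raise an
#' error.
#'
#' @param donor A [donor_spec()].
#' @param dose Initial donor concentration, uM.
#' @param params A [kinetic_params()].
#' @param duration Simulation span, seconds.
#' @param output_step Output grid spacing, seconds.
#'
#' @return A tibble of class `no_timecourse` with columns `time_s`,
#'   `donor_uM`, `no_uM`, `o2_uM`, `no_consumed_uM`, and attributes `dose`,
#'   `donor`, `params`.
#' @examples
#' tc <- simulate_no(donor_spec("sper"), dose = 165, duration = 3 * 3600)
#' summarize_steady_state(tc)
#' @export
simulate_no <- function(donor, dose, params = kinetic_params(),
                        duration, output_step = 10) {
  stopifnot(inherits(donor, "donor_spec"), inherits(params, "kinetic_params"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    abort("`dose` must be a single non-negative number (uM)")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort("`duration` must be a single positive number (seconds)")
  }
  k1 <- decay_constant(donor)
  e  <- donor$no_equivalents
  s  <- params$no_per_o2
  k  <- params$k_aut
  atol <- 1e-6
  times <- unique(c(seq(0, duration, by = output_step), duration))

  deriv <- function(t, y, parms) {
    ox <- k * y[["o2"]] * y[["no"]]^2   # rate of the termolecular reaction
    list(c(
      donor = -k1 * y[["donor"]],
      no    = k1 * y[["donor"]] * e - s * ox,
      o2    = -ox,
      cons  = s * ox
    ))
  }
  y0 <- c(donor = dose, no = 0, o2 = params$o2_initial, cons = 0)
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed (lsoda istate = %d)",
                  attr(sol, "istate")[1]))
  }
  sol <- as.data.frame(sol)
  state <- as.matrix(sol[, c("donor", "no", "o2", "cons")])
  if (any(state < -atol)) {
    abort(sprintf(
      "negative state excursion beyond tolerance (min = %.3g uM)", min(state)))
  }
  state[state < 0] <- 0

  out <- tibble(
    time_s = sol$time,
    donor_uM = state[, "donor"],
    no_uM = state[, "no"],
    o2_uM = state[, "o2"],
    no_consumed_uM = state[, "cons"]
  )
  structure(out,
            class = c("no_timecourse", class(out)),
            dose = dose, donor = donor, params = params)
}

#' Quasi-steady-state NO concentration (closed form)
#'
#' Analytic balance of NO release against autooxidation: at steady state
#' `k1 [D] e_NO = s k_aut [O2] [NO]^2`, giving
#' `[NO]_qss = sqrt(k1 [D] e_NO / (s k_aut [O2]))`. Serves as an independent
#' oracle for the full ODE solution wherever the donor decays slowly compared
#' with the NO relaxation time.
#'
#' @param donor A [donor_spec()].
#' @param dose_at_t Current donor concentration, uM.
#' @param params A [kinetic_params()].
#' @return Quasi-steady-state NO concentration, uM.
#' @examples
#' quasi_steady_state_no(donor_spec("sper"), 165) # ~ 3.1 uM
#' quasi_steady_state_no(donor_spec("deta"), 100) # ~ 0.62 uM
#' @export
quasi_steady_state_no <- function(donor, dose_at_t, params = kinetic_params()) {
  stopifnot(inherits(donor, "donor_spec"), inherits(params, "kinetic_params"))
  if (any(dose_at_t < 0)) abort("`dose_at_t` must be non-negative")
  if (params$o2_initial <= 0) {
    abort("steady state is unbounded at zero O2 (no consumption path)")
  }
  k1 <- decay_constant(donor)
  sqrt(k1 * dose_at_t * donor$no_equivalents /
         (params$no_per_o2 * params$k_aut * params$o2_initial))
}

#' Summarise steady-state NO over a time window
#'
#' The operational steady-state NO of an assay: the trapezoidal time-average of the
#' simulated free NO over a window (default the full simulated span), plus
#' the peak concentration and its time.
#'
#' @param tc A `no_timecourse` from [simulate_no()].
#' @param window Length-2 numeric `(t_start, t_end)` in seconds, within the
#'   simulated span. Default: full span.
#' @return A tibble with one row: `mean_no_uM`, `peak_no_uM`,
#'   `time_of_peak_s`, `window_start_s`, `window_end_s`.
#' @export
summarize_steady_state <- function(tc, window = NULL) {
  stopifnot(inherits(tc, "no_timecourse"))
  window <- window %||% range(tc$time_s)
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    abort("`window` must be numeric (t_start, t_end) with t_start < t_end")
  }
  if (window[1] < min(tc$time_s) - 1e-9 || window[2] > max(tc$time_s) + 1e-9) {
    abort("`window` must lie within the simulated span")
  }
  keep <- tc$time_s >= window[1] & tc$time_s <= window[2]
  t <- tc$time_s[keep]
  y <- tc$no_uM[keep]
  if (length(t) < 2L) abort("window contains fewer than two samples")
  mean_no <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    (t[length(t)] - t[1])
  tibble(
    mean_no_uM = mean_no,
    peak_no_uM = max(y),
    time_of_peak_s = t[which.max(y)],
    window_start_s = window[1],
    window_end_s = window[2]
  )
}

#' Convert a donor-denominated IC50 into an NO-denominated IC50
#'
#' Half-inhibitory doses of NONOate donors are assay artefacts: the same
#' donor dose yields very different free NO depending on half-life and assay
#' duration. This runs the release/autooxidation simulation at the donor
#' IC50 for the assay duration and reports the steady-state NO summary over
#' the full assay window; the time-averaged NO is the NO-denominated IC50.
#'
#' @param donor A [donor_spec()].
#' @param donor_ic50 Donor-denominated IC50, uM.
#' @param params A [kinetic_params()].
#' @param assay_duration Assay length, seconds.
#' @param output_step Simulation output grid, seconds.
#' @return A one-row tibble as from [summarize_steady_state()].
#' @examples
#' # Sper/NO donor IC50 of 165 uM over a 3 h assay corresponds to ~3 uM NO
#' donor_ic50_to_no_ic50(donor_spec("sper"), 165, assay_duration = 3 * 3600)
#' @export
donor_ic50_to_no_ic50 <- function(donor, donor_ic50, params = kinetic_params(),
                                  assay_duration, output_step = 10) {
  if (!is.numeric(donor_ic50) || length(donor_ic50) != 1L || donor_ic50 < 0) {
    abort("`donor_ic50` must be a single non-negative number (uM)")
  }
  tc <- simulate_no(donor, donor_ic50, params, assay_duration, output_step)
  summarize_steady_state(tc)
}
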