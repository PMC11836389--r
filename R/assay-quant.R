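#' Four-parameter logistic value
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^((LogIC50 - X) * Hill))` with
#' `X = log10(dose)`. Negative Hill encodes responses that decrease with
#' dose (inhibition curves).
#'
#' @param dose Dose(s), same concentration unit as `10^log_ic50`.
#' @param bottom,top Lower/upper response asymptotes.
#' @param log_ic50 log10 of the half-maximal dose.
#' @param hill Hill slope (sign encodes direction).
#' @return Response value(s).
#' @export
fourpl <- function(dose, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(dose)) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model to a dose-response table. Starting
#' values come from the data (asymptotes from the response extremes, LogIC50
#' from the dose nearest mid-response, Hill sign from the response direction)
#' and the fit is bounded (Hill in \[-10, 10\]) via
#' [minpack.lm::nlsLM()] Levenberg-Marquardt least squares. At
#' `X = LogIC50` the fitted curve passes through `(Top + Bottom) / 2` by
#' construction.
#'
#' @param data A data frame of doses and responses.
#' @param dose,response Column names (strings) holding dose (> 0) and
#'   response. Defaults `"dose"`, `"response"`.
#' @return An object of class `fourpl_fit`: list with `bottom`, `top`,
#'   `log_ic50`, `hill_slope`, `ic50` (= 10^log_ic50), `rss`, `converged`,
#'   `n`, `data`, and the underlying `fit`. Methods: [tidy()], [glance()],
#'   [autoplot()], `predict()`.
#' @examples
#' d <- tibble::tibble(dose = 10^seq(0, 3.5, 0.5),
#'                     response = fourpl(dose, 0, 100, log10(165), -1))
#' fit_4pl(d)
#' @export
fit_4pl <- function(data, dose = "dose", response = "response") {
  stopifnot(is.data.frame(data))
  if (!all(c(dose, response) %in% names(data))) {
    abort(sprintf("columns `%s` and `%s` must exist", dose, response))
  }
  x <- data[[dose]]
  y <- data[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0)) abort("doses must be positive (log scale)")
  if (length(unique(x)) < 5L) abort("need at least 5 distinct doses")
  if (diff(range(y)) < sqrt(.Machine$double.eps) * (abs(mean(y)) + 1)) {
    abort("responses are constant: IC50 is unidentifiable")
  }
  lx <- log10(x)
  # direction: does response rise or fall with dose?
  slope_sign <- sign(stats::cov(lx, y))
  if (slope_sign == 0) slope_sign <- 1
  bottom0 <- min(y); top0 <- max(y)
  mid <- (bottom0 + top0) / 2
  log_ic50_0 <- lx[which.min(abs(y - mid))]
  start <- list(bottom = bottom0, top = top0, log_ic50 = log_ic50_0,
                hill = slope_sign * 1)
  span <- top0 - bottom0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - lx) * hill)),
      start = start,
      lower = c(bottom = bottom0 - 2 * span, top = top0 - 2 * span,
                log_ic50 = min(lx) - 3, hill = -10),
      upper = c(bottom = bottom0 + 2 * span, top = top0 + 2 * span,
                log_ic50 = max(lx) + 3, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("4PL fit failed to converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  structure(
    list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
         log_ic50 = unname(cf["log_ic50"]), hill_slope = unname(cf["hill"]),
         ic50 = unname(10^cf["log_ic50"]),
         rss = sum(stats::resid(fit)^2),
         converged = isTRUE(fit$convInfo$isConv) || inherits(fit, "nls"),
         n = length(y),
         data = tibble(dose = x, response = y),
         fit = fit),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> IC50 = %.4g, Hill = %.3g, Bottom = %.4g, Top = %.4g (n = %d, RSS = %.3g)\n",
    x$ic50, x$hill_slope, x$bottom, x$top, x$n, x$rss))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  fourpl(dose, object$bottom, object$top, object$log_ic50, object$hill_slope)
}

#' @rdname fit_4pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "log_ic50", "hill_slope", "ic50"),
    estimate = c(x$bottom, x$top, x$log_ic50, x$hill_slope, x$ic50)
  )
}

#' @rdname fit_4pl
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill_slope = x$hill_slope, rss = x$rss,
         converged = x$converged, nobs = x$n)
}

#' MALDI adduct fractions
#'
#' Per-adduct proportions from an integrated MALDI-TOF peak-intensity table:
#' each cytosine form (5mC ~ m/z 2424.6, 5hmC ~ 2440.6, 5fC ~ 2438.6,
#' 5caC ~ 2454.6 for the assay oligo) is quantified as its peak intensity
#' divided by the summed intensity of all adducts. Input is the
#' already-integrated intensity table; raw spectrum processing (baselining,
#' centroiding, peak annotation) is upstream vendor software territory.
#'
#' @param peaks A data frame with columns `adduct` and `intensity`
#'   (non-negative, at least one positive), or a named numeric vector.
#' @return A tibble `adduct`, `intensity`, `fraction`; fractions sum to 1.
#' @examples
#' maldi_fractions(c(`5mC` = 300, `5hmC` = 100, `5fC` = 50, `5caC` = 50))
#' @export
maldi_fractions <- function(peaks) {
  if (is.numeric(peaks) && !is.null(names(peaks))) {
    peaks <- tibble(adduct = names(peaks), intensity = unname(peaks))
  }
  stopifnot(is.data.frame(peaks))
  if (!all(c("adduct", "intensity") %in% names(peaks))) {
    abort("`peaks` needs columns `adduct` and `intensity`")
  }
  if (any(peaks$intensity < 0) || any(!is.finite(peaks$intensity))) {
    abort("intensities must be finite and non-negative")
  }
  total <- sum(peaks$intensity)
  if (total <= 0) abort("all intensities are zero: fractions undefined")
  tibble(adduct = peaks$adduct, intensity = peaks$intensity,
         fraction = peaks$intensity / total)
}

#' Linear standard-curve calibration
#'
#' Ordinary least-squares calibration line through standards (e.g. sodium
#' nitrite standards of a Griess assay), inverted at the unknown signal(s).
#' Inverted concentrations below zero are clipped to 0 and flagged
#' `below_range`.
#'
#' @param standards A data frame with columns `concentration` and `signal`
#'   (>= 2 standards, non-constant signal).
#' @param unknown_signal Signal value(s) to invert.
#' @return A tibble `signal`, `concentration`, `below_range`.
#' @examples
#' std <- tibble::tibble(concentration = c(0, 10, 20), signal = c(0, .1, .2))
#' linear_calibration(std, 0.15)
#' @export
linear_calibration <- function(standards, unknown_signal) {
  stopifnot(is.data.frame(standards))
  if (!all(c("concentration", "signal") %in% names(standards))) {
    abort("`standards` needs columns `concentration` and `signal`")
  }
  if (nrow(standards) < 2L || length(unique(standards$signal)) < 2L) {
    abort("need >= 2 standards with distinct signals")
  }
  fit <- lm(signal ~ concentration, data = standards)
  b <- coef(fit)
  if (abs(b[["concentration"]]) < sqrt(.Machine$double.eps)) {
    abort("calibration slope is zero: singular design")
  }
  conc <- (unknown_signal - b[["(Intercept)"]]) / b[["concentration"]]
  tibble(signal = unknown_signal,
         concentration = pmax(conc, 0),
         below_range = conc < 0)
}
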