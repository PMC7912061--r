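#' Percent enzyme inhibition from paired absorbances
#'
#' Colorimetric inhibition assays report an uninhibited control absorbance
#' (100% initial activity) and a sample absorbance with inhibitor present;
#' inhibition is the fractional drop: `(control - sample) / control * 100`.
#' Values can exceed 100% or be negative with noisy plates; they are
#' returned as computed, not clipped.
#'
#' @param activity_control Absorbance of the uninhibited control (> 0).
#' @param activity_sample Absorbance with inhibitor (>= 0). Recycled
#'   against `activity_control`.
#' @return Percent inhibition, same length as the longer input.
#' @examples
#' percent_inhibition(0.80, 0.20) # 75
#' @export
percent_inhibition <- function(activity_control, activity_sample) {
  if (any(activity_control <= 0)) abort("`activity_control` must be positive")
  if (any(activity_sample < 0)) abort("`activity_sample` must be non-negative")
  (activity_control - activity_sample) / activity_control * 100
}

#' Fit an IC50 to a dose-response curve
#'
#' Primary method: least-squares fit of the four-parameter log-logistic
#' `y = bottom + (top - bottom) / (1 + (ic50 / x)^h)` with `bottom` and
#' `top` fixed (0 and 100 by default — percent inhibition is bounded and a
#' handful of doses cannot constrain four parameters), optimising
#' `log10(ic50)` and the Hill slope `h` by Levenberg-Marquardt. Fallback
#' (used automatically when only two doses are given or the fit does not
#' converge): log-linear interpolation between the two observations
#' straddling 50%. The method actually used is recorded in the result.
#'
#' @param data Data frame with columns `concentration` (positive, mg/mL)
#'   and `inhibition` (percent).
#' @param bottom,top Fixed asymptotes in percent.
#' @return An object of class `ic50_fit`: a list with `ic50`, `hill_slope`,
#'   `bottom`, `top`, `method` (`"loglogistic"` or `"interpolation"`),
#'   `residual_sse`, `n` and the input `data`. Supports [tidy()],
#'   [glance()], `predict()` and [autoplot()].
#' @examples
#' doses <- 10^seq(-2, 1, length.out = 8)
#' curve <- simulate_dose_response(ic50 = 0.3, hill = 1, doses = doses,
#'                                 noise_sd = 0, seed = 1)
#' glance(fit_ic50(curve))
#' @export
fit_ic50 <- function(data, bottom = 0, top = 100) {
  for (col in c("concentration", "inhibition")) {
    if (!col %in% names(data)) abort(sprintf("`data` must have a `%s` column", col))
  }
  x <- data$concentration
  y <- data$inhibition
  if (any(x <= 0)) abort("concentrations must be strictly positive")
  if (length(unique(x)) < 2) abort("need at least 2 distinct concentrations")
  half <- (bottom + top) / 2

  fit <- NULL
  if (length(unique(x)) >= 3) {
    start <- list(logc = log10(stats::weighted.mean(x, 1 / (1 + abs(y - half)))),
                  h = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(h * (logc - log10(x)))),
        start = start, control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    out <- list(ic50 = 10^unname(cf["logc"]), hill_slope = unname(cf["h"]),
                bottom = bottom, top = top, method = "loglogistic",
                residual_sse = sum(stats::residuals(fit)^2))
  } else {
    # interpolation fallback: adjacent dose pair straddling 50% on log scale
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    cross <- which(ys[-length(ys)] < half & ys[-1] >= half)
    if (length(cross) == 0) {
      abort("IC50 not identifiable from data: inhibition never crosses 50%")
    }
    i <- cross[1]; j <- i + 1L
    frac <- (half - ys[i]) / (ys[j] - ys[i])
    logc <- log10(xs[i]) + frac * (log10(xs[j]) - log10(xs[i]))
    out <- list(ic50 = 10^logc, hill_slope = NA_real_, bottom = bottom,
                top = top, method = "interpolation", residual_sse = NA_real_)
  }
  out$n <- length(x)
  out$data <- as_tibble(data[c("concentration", "inhibition")])
  structure(out, class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit (%s): ic50 = %.4g, hill = %s, n = %d\n",
              x$method, x$ic50,
              ifelse(is.na(x$hill_slope), "NA", sprintf("%.3g", x$hill_slope)),
              x$n))
  invisible(x)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  x <- (newdata %||% object$data)$concentration
  h <- if (is.na(object$hill_slope)) 1 else object$hill_slope
  object$bottom + (object$top - object$bottom) / (1 + (object$ic50 / x)^h)
}

#' @rdname fit_ic50
#' @param x An `ic50_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ic50_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill_slope", "bottom", "top"),
         estimate = c(x$ic50, x$hill_slope, x$bottom, x$top))
}

#' @rdname fit_ic50
#' @exportS3Method generics::glance
glance.ic50_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill_slope = x$hill_slope, method = x$method,
         residual_sse = x$residual_sse, n = x$n)
}

#' pH-stat degree of hydrolysis
#'
#' Degree of hydrolysis (DH, %) from base consumption at constant pH:
#' `DH = B * N_B * alpha_inv / (M_P * h_tot) * 100`, where `B` (mL) is the
#' volume of NaOH consumed, `N_B` (eq/L) its normality (so `B * N_B` is in
#' meq), `alpha_inv` = 1/alpha the average reciprocal dissociation of the
#' liberated alpha-amino groups at the working pH and temperature, `M_P`
#' (g) the protein mass in the reactor and `h_tot` (meq/g) the total
#' number of peptide bonds per gram of the substrate protein. `alpha_inv`
#' and `h_tot` are substrate/condition-specific and must be supplied.
#'
#' @param B mL of NaOH consumed (>= 0).
#' @param N_B Normality of the NaOH, eq/L (> 0).
#' @param alpha_inv Reciprocal average dissociation factor (> 0).
#' @param M_P Grams of protein in the reaction (> 0).
#' @param h_tot Total peptide bonds, meq per g protein (> 0).
#' @return DH in percent. Vectorised over `B`.
#' @examples
#' degree_of_hydrolysis(B = 5, N_B = 1, alpha_inv = 1.2, M_P = 10, h_tot = 8)
#' @export
degree_of_hydrolysis <- function(B, N_B, alpha_inv, M_P, h_tot) {
  if (any(B < 0)) abort("`B` must be non-negative")
  for (nm in c("N_B", "alpha_inv", "M_P", "h_tot")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("`%s` must be strictly positive", nm))
    }
  }
  B * N_B * alpha_inv / (M_P * h_tot) * 100
}

#' Hydrolysate recovery, dosing and composition arithmetic
#'
#' `percent_yield()`: mass recovered as a percentage of input mass.
#' `enzyme_substrate_ratio()`: enzyme volume per substrate weight as a
#' percentage (v/w, mL per g). `protein_from_nitrogen()`: crude protein
#' from total nitrogen via a Kjeldahl/Dumas conversion factor.
#'
#' @param recovered_mass Grams recovered (>= 0).
#' @param input_mass Grams of starting material (> 0).
#' @return A percentage.
#' @examples
#' percent_yield(3.98, 44) # 9.05
#' enzyme_substrate_ratio(1.76, 44) # 4
#' protein_from_nitrogen(10.4784) # 65.49
#' @export
percent_yield <- function(recovered_mass, input_mass) {
  if (any(input_mass <= 0)) abort("`input_mass` must be positive")
  if (any(recovered_mass < 0)) abort("`recovered_mass` must be non-negative")
  round_mass(recovered_mass / input_mass * 100, 2)
}

#' @rdname percent_yield
#' @param enzyme_volume mL of enzyme preparation (>= 0).
#' @param substrate_mass g of substrate (> 0).
#' @export
enzyme_substrate_ratio <- function(enzyme_volume, substrate_mass) {
  if (any(substrate_mass <= 0)) abort("`substrate_mass` must be positive")
  if (any(enzyme_volume < 0)) abort("`enzyme_volume` must be non-negative")
  enzyme_volume / substrate_mass * 100
}

#' @rdname percent_yield
#' @param nitrogen_pct Total nitrogen, percent by mass (0-16; 16% N is the
#'   all-protein bound).
#' @param factor Nitrogen-to-protein conversion factor (default 6.25).
#' @export
protein_from_nitrogen <- function(nitrogen_pct, factor = 6.25) {
  if (any(nitrogen_pct < 0) || any(nitrogen_pct > 16)) {
    abort("`nitrogen_pct` must be between 0 and 16")
  }
  nitrogen_pct * factor
}
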