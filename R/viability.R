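# Plate-reader viability analysis: vehicle/blank normalization,
# four-parameter-logistic dose-response fitting, censored absolute IC50
# and Bliss-independence combination enhancement.

#' Default dose grids for the two study drugs
#'
#' The printed monotherapy designs: dasatinib at 50, 100, 200, 500, 1000
#' and 5000 nM; TBB at 10, 20, 50, 100, 200 and 500 uM.
#'
#' @param drug `"dasatinib"` or `"tbb"`.
#' @return list with `doses` (numeric) and `unit`.
#' @examples
#' default_dose_grid("dasatinib")$doses
#' @export
default_dose_grid <- function(drug = c("dasatinib", "tbb")) {
  drug <- match.arg(tolower(drug), c("dasatinib", "tbb"))
  switch(drug,
         dasatinib = list(doses = c(50, 100, 200, 500, 1000, 5000),
                          unit = "nM"),
         tbb = list(doses = c(10, 20, 50, 100, 200, 500), unit = "uM"))
}

#' Four-parameter logistic viability curve
#'
#' `v(c) = lower + (upper - lower) / (1 + (c / ec50)^hill)`: viability
#' decreases from `upper` (no drug) towards `lower` (saturating drug) with
#' inflection at `ec50` and steepness `hill`.
#'
#' @param conc concentration(s), > 0.
#' @param lower,upper asymptote viabilities.
#' @param ec50 inflection concentration.
#' @param hill slope (> 0).
#' @return Viability at `conc`.
#' @export
fourpl <- function(conc, lower, upper, ec50, hill) {
  lower + (upper - lower) / (1 + (conc / ec50)^hill)
}

#' Construct a dose-response object directly
#'
#' @param drug drug label.
#' @param viability data.frame with columns `dose`, `replicate`,
#'   `viability` (fraction of vehicle).
#' @param unit concentration unit.
#' @param vehicle_mean,blank_mean optional absorbance summaries.
#' @return Object of class `dose_response`.
#' @export
dose_response <- function(drug, viability, unit = "nM",
                          vehicle_mean = NA_real_, blank_mean = NA_real_) {
  assert_columns(viability, c("dose", "replicate", "viability"),
                 "viability table")
  if (any(viability$dose <= 0)) stop_ks("doses must be positive")
  if (any(!is.finite(viability$viability))) {
    stop_ks("viabilities must be finite")
  }
  doses <- sort(unique(viability$dose))
  structure(list(drug = drug, unit = unit, doses = doses,
                 viability = viability[order(viability$dose,
                                             viability$replicate), ,
                                       drop = FALSE],
                 vehicle_mean = vehicle_mean, blank_mean = blank_mean),
            class = "dose_response")
}

#' Normalize a raw plate table to viabilities
#'
#' Converts raw absorbances to fraction-of-vehicle viability:
#' `(absorbance - mean blank) / (mean vehicle - mean blank)`.  Replicates
#' are preserved, not pre-averaged.  Wells darker than the blank produce
#' negative viabilities, which are retained (with a warning) so that curve
#' fits see the full data.
#'
#' @param raw long-format data.frame with columns `drug`, `dose`, `unit`,
#'   `replicate`, `absorbance`, `role` (`"blank"`, `"vehicle"` or
#'   `"treated"`).
#' @param drug optional drug label to subset on when the table holds
#'   several drugs.
#' @return A [dose_response()].
#' @export
normalize_plate <- function(raw, drug = NULL) {
  assert_columns(raw, c("drug", "dose", "unit", "replicate", "absorbance",
                        "role"), "plate table")
  if (!is.null(drug)) raw <- raw[raw$drug == drug, , drop = FALSE]
  if (nrow(raw) == 0) stop_ks("plate table is empty")
  drug_lab <- as.character(raw$drug[1])
  blank <- raw$absorbance[raw$role == "blank"]
  vehicle <- raw$absorbance[raw$role == "vehicle"]
  if (length(blank) == 0) stop_ks("plate has no blank wells")
  if (length(vehicle) == 0) stop_ks("plate has no vehicle-control wells")
  b <- mean(blank); v <- mean(vehicle)
  if (v <= b) {
    stop_ks("uninterpretable plate: mean vehicle absorbance (%.4g) <= mean blank (%.4g)",
            v, b)
  }
  treated <- raw[raw$role == "treated", , drop = FALSE]
  viab <- (treated$absorbance - b) / (v - b)
  if (any(viab < 0)) {
    warning(sprintf("%d well(s) below blank: negative viabilities retained",
                    sum(viab < 0)))
  }
  dose_response(drug_lab,
                data.frame(dose = treated$dose, replicate = treated$replicate,
                           viability = viab, stringsAsFactors = FALSE),
                unit = as.character(raw$unit[1]),
                vehicle_mean = v, blank_mean = b)
}

#' Fit a four-parameter logistic curve to a dose-response
#'
#' Bounded least squares (`lower` in \[0, 1\], `upper` in \[0.5, 1.5\],
#' `ec50` in \[min dose / 10, max dose x 10\], `hill` in (0, 10\]) via
#' L-BFGS-B from three deterministic initializations (EC50 at the geometric
#' mean of the dose grid, at the dose whose mean viability is nearest the
#' half-response level, and at the median dose).  On optimizer failure the
#' best-effort parameters are returned with `converged = FALSE`.
#'
#' @param dr a [dose_response()] with >= 4 distinct doses.
#' @return Object of class `fit_result`: list with `lower`, `upper`,
#'   `ec50`, `hill`, `rss`, `converged`, `ic50` (`NA` when not reached),
#'   `ic50_reached`, `dose_range`, `drug`, `unit`.
#' @export
fit_4pl <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  if (length(dr$doses) < 4) stop_ks("need >= 4 distinct doses to fit a 4PL")
  conc <- dr$viability$dose
  y <- dr$viability$viability
  if (any(!is.finite(y))) stop_ks("viabilities must be finite")

  lo <- c(lower = 0, upper = 0.5, log_ec50 = log(min(dr$doses) / 10),
          hill = 1e-3)
  hi <- c(lower = 1, upper = 1.5, log_ec50 = log(max(dr$doses) * 10),
          hill = 10)
  obj <- function(par) {
    pred <- fourpl(conc, par[1], par[2], exp(par[3]), par[4])
    sum((y - pred)^2)
  }
  clamp <- function(x, a, b) pmin(pmax(x, a), b)

  mean_by_dose <- tapply(y, conc, mean)
  lower0 <- clamp(min(mean_by_dose), 0, 1)
  upper0 <- clamp(max(mean_by_dose), 0.5, 1.5)
  half <- (lower0 + upper0) / 2
  ec50_half <- as.numeric(names(mean_by_dose))[
    which.min(abs(mean_by_dose - half))]
  starts <- list(
    c(lower0, upper0, log(exp(mean(log(dr$doses)))), 1),
    c(lower0, upper0, log(ec50_half), 1),
    c(lower0, upper0, log(median(dr$doses)), 2)
  )
  best <- NULL
  for (s in starts) {
    s <- clamp(s, lo, hi)
    f <- tryCatch(optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) {
    fit <- list(lower = lower0, upper = upper0,
                ec50 = exp(mean(log(dr$doses))), hill = 1, rss = obj(
                  c(lower0, upper0, mean(log(dr$doses)), 1)),
                converged = FALSE)
  } else {
    fit <- list(lower = unname(best$par[1]), upper = unname(best$par[2]),
                ec50 = unname(exp(best$par[3])), hill = unname(best$par[4]),
                rss = best$value, converged = best$convergence == 0)
  }
  fit$dose_range <- range(dr$doses)
  fit$drug <- dr$drug
  fit$unit <- dr$unit
  class(fit) <- "fit_result"
  fit$ic50 <- ic50_from_fit(fit)
  fit$ic50_reached <- !is.na(fit$ic50)
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  ic <- if (is.na(x$ic50)) "not reached" else sprintf("%.4g %s", x$ic50, x$unit)
  cat(sprintf("4PL fit (%s): lower %.3f, upper %.3f, ec50 %.4g %s, hill %.3f; IC50 %s%s\n",
              x$drug, x$lower, x$upper, x$ec50, x$unit, x$hill, ic,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Absolute IC50 from a fitted curve, censored when not reached
#'
#' Solves `fitted viability = 0.5` in closed form:
#' `ic50 = ec50 * ((upper - 0.5) / (0.5 - lower))^(1/hill)`.  Returns
#' `NA_real_` ("not reached") when the curve never attains viability 0.5
#' within the tested dose range — in particular whenever the lower
#' asymptote is at or above 0.5, the situation in which a drug's IC50
#' cannot be calculated despite a measurable viability decrease.
#'
#' @param fit a `fit_result` (or any list with `lower`, `upper`, `ec50`,
#'   `hill`).
#' @param dose_range the tested concentration range; defaults to the range
#'   stored on the fit.
#' @return The absolute IC50 concentration, or `NA_real_` when not reached.
#' @export
ic50_from_fit <- function(fit, dose_range = fit$dose_range) {
  if (is.null(dose_range)) stop_ks("dose_range required")
  if (fit$lower >= 0.5 || fit$upper <= 0.5) return(NA_real_)
  ic <- fit$ec50 * ((fit$upper - 0.5) / (0.5 - fit$lower))^(1 / fit$hill)
  if (ic < dose_range[1] || ic > dose_range[2]) return(NA_real_)
  ic
}

#' Bliss-independence combination enhancement analysis
#'
#' For each dose of drug A shared between the monotherapy and combination
#' series (drug B held at a fixed dose, e.g. its IC50), computes the Bliss
#' expected combination viability `v_mono_a * v_mono_b` and the excess
#' `bliss_expected - v_combo`.  The combination is flagged as enhanced when
#' the excess exceeds `excess_threshold` at `min_doses` or more doses.  The
#' statistic reported is enhancement (Bliss excess); assessing true synergy
#' requires monotherapy IC50s for both drugs and is out of reach when one
#' drug's IC50 is not reached.
#'
#' @param mono_a [dose_response()] for drug A alone.
#' @param v_mono_b monotherapy viability of drug B at its fixed dose.
#' @param combo [dose_response()] for drug A with drug B fixed; its doses
#'   must be a subset of `mono_a`'s.
#' @param excess_threshold Bliss excess counted as enhancement at a dose.
#' @param min_doses number of enhanced doses required to set the flag.
#' @param schedule free-text schedule metadata (recorded, not used in the
#'   computation), e.g. `"drug B 30 min before drug A"`.
#' @return Object of class `combination_result`: list with `table` (per-dose
#'   `dose`, `v_mono_a`, `v_mono_b`, `v_combo`, `bliss_expected`, `excess`,
#'   `enhanced`), `enhancement_flag`, `statistic`
#'   (`"enhancement (Bliss excess)"`), `schedule`.
#' @export
analyze_combination <- function(mono_a, v_mono_b, combo,
                                excess_threshold = 0.1, min_doses = 2,
                                schedule = NULL) {
  stopifnot(inherits(mono_a, "dose_response"),
            inherits(combo, "dose_response"))
  if (!is.finite(v_mono_b)) stop_ks("v_mono_b must be a finite viability")
  shared <- intersect(combo$doses, mono_a$doses)
  if (length(shared) == 0) {
    stop_ks("no shared doses between monotherapy and combination series")
  }
  mean_at <- function(dr, d) {
    mean(dr$viability$viability[dr$viability$dose == d])
  }
  tab <- do.call(rbind, lapply(sort(shared), function(d) {
    va <- mean_at(mono_a, d)
    vc <- mean_at(combo, d)
    bliss <- va * v_mono_b
    data.frame(dose = d, v_mono_a = va, v_mono_b = v_mono_b, v_combo = vc,
               bliss_expected = bliss, excess = bliss - vc,
               stringsAsFactors = FALSE)
  }))
  tab$enhanced <- tab$excess > excess_threshold
  structure(list(table = tab,
                 enhancement_flag = sum(tab$enhanced) >= min_doses,
                 statistic = "enhancement (Bliss excess)",
                 schedule = schedule),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("%s: %s at %d/%d doses\n", x$statistic,
              if (x$enhancement_flag) "enhanced" else "not enhanced",
              sum(x$table$enhanced), nrow(x$table)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$schedule)) cat("schedule:", x$schedule, "\n")
  invisible(x)
}
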