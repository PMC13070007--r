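# Deterministic downstream assay summaries: flow quadrant percentages,
# patient malignant fraction, drug-to-antibody ratio, and 4PL IC50 fits.

#' Flow-cytometry quadrant percentages
#'
#' Percentages of the four TRBC1/TRBC2 co-staining populations of normal
#' T cells (TRBC1-only, TRBC2-only, dual positive, dual negative).
#' @param counts numeric vector of four non-negative cell counts, in the
#'   order \code{trbc1_only, trbc2_only, dual_pos, dual_neg} (names kept
#'   if supplied).
#' @return percentages summing to 100.
#' @examples
#' quadrant_percentages(c(298, 660, 21, 21))
#' @export
quadrant_percentages <- function(counts) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stopf("total cell count must be positive")
  if (is.null(names(counts)))
    names(counts) <- c("trbc1_only", "trbc2_only", "dual_pos", "dual_neg")
  100 * counts / total
}

#' Malignant fraction of circulating T cells
#'
#' Percentage of T cells with the malignant phenotype (TRBC2+ CD26-)
#' among all T cells.
#' @param cancer malignant T cell count.
#' @param total_T total T cell count (> 0, >= \code{cancer}).
#' @return percentage on [0, 100].
#' @examples
#' malignant_fraction(4074, 18481)   # ~22%
#' malignant_fraction(38837, 39521)  # ~98%
#' @export
malignant_fraction <- function(cancer, total_T) {
  stopifnot(cancer >= 0, total_T > 0, cancer <= total_T)
  100 * cancer / total_T
}

#' Drug-to-antibody ratio as an area-weighted average
#'
#' DAR = sum(load * area) / sum(area) over the integrated chromatogram
#' peaks, each labeled with an integer drug load.
#' @param drug_load integer drug loads (>= 0), one per peak.
#' @param area non-negative integrated peak areas (sum > 0).
#' @return the weighted-average DAR (lies within [min load, max load]).
#' @examples
#' dar_weighted_average(c(2, 4, 6), c(1, 2, 1))  # 4
#' @export
dar_weighted_average <- function(drug_load, area) {
  stopifnot(length(drug_load) == length(area), all(area >= 0))
  if (any(drug_load < 0) || any(drug_load != round(drug_load)))
    stopf("drug loads must be non-negative integers")
  if (sum(area) <= 0) stopf("total peak area must be positive")
  sum(drug_load * area) / sum(area)
}

# 4PL response: bottom + (top - bottom) / (1 + (x / ic50)^hill).
# hill > 0 gives a curve decreasing in dose.
fourpl_response <- function(x, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' \code{y = bottom + (top - bottom) / (1 + (x/IC50)^hill)} by
#' Levenberg-Marquardt with data-driven starts (IC50 on the log scale,
#' several Hill starts of both signs). The fit is reported with
#' \code{top >= bottom} (the sign of \code{hill} absorbs the
#' orientation); IC50 is in the dose units, so rescaling doses rescales
#' IC50 linearly.
#'
#' @param dose dose levels (> 0); at least 5 distinct values spanning the
#'   transition.
#' @param response responses (e.g. viability as fraction of untreated
#'   control).
#' @return object of class \code{fourpl_fit}: \code{top}, \code{bottom},
#'   \code{hill}, \code{ic50}, \code{sse}, data and fitted values.
#' @export
fit_4pl <- function(dose, response) {
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 5L)
    stopf("need at least 5 distinct dose levels")
  if (stats::sd(response) == 0)
    stopf("flat response: no dose-response transition to fit")
  top0 <- max(response); bot0 <- min(response)
  # dose whose response is nearest the half-way point, as the IC50 start
  mid <- (top0 + bot0) / 2
  i0 <- which.min(abs(response - mid))
  starts <- expand.grid(lic50 = log(c(dose[i0], exp(mean(log(dose))))),
                        hill = c(-2, -1, 1, 2))
  resid_fn <- function(p) {
    response - fourpl_response(dose, p[1], p[2], exp(p[3]), p[4])
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(top0, bot0, starts$lic50[i],
                                 starts$hill[i]),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   message = fit$message)
  }
  if (is.null(best)) stopf("4PL fit failed to converge from all starts")
  p <- best$par
  top <- p[1]; bottom <- p[2]; ic50 <- exp(p[3]); hill <- p[4]
  if (top < bottom) {  # canonical orientation: top >= bottom
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  if (abs(hill) < 1e-4)
    stopf("degenerate 4PL fit: Hill slope ~ 0 (no transition)")
  fitted_vals <- fourpl_response(dose, top, bottom, ic50, hill)
  structure(list(top = top, bottom = bottom, hill = hill, ic50 = ic50,
                 sse = best$sse, df = length(dose) - 4L,
                 info = best$info, message = best$message,
                 data = data.frame(dose = dose, response = response),
                 fitted_values = fitted_vals),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  IC50 = %.4g (dose units); Hill = %.3g\n", x$ic50, x$hill))
  cat(sprintf("  top = %.4g, bottom = %.4g; SSE = %.4g\n", x$top,
              x$bottom, x$sse))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, hill = object$hill,
    ic50 = object$ic50)
}

#' @export
fitted.fourpl_fit <- function(object, ...) object$fitted_values

#' @export
residuals.fourpl_fit <- function(object, ...) {
  object$data$response - object$fitted_values
}

#' Predict responses from a fitted 4PL model
#' @param object a \code{fourpl_fit}.
#' @param newdata data.frame with a \code{dose} column (default: fitted
#'   data).
#' @param ... unused.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  fourpl_response(newdata$dose, object$top, object$bottom, object$ic50,
                  object$hill)
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  d <- x$data
  xs <- exp(seq(log(min(d$dose)), log(max(d$dose)), length.out = 200))
  graphics::plot(d$dose, d$response, log = "x", pch = 16,
                 xlab = "Dose", ylab = "Response",
                 main = sprintf("4PL fit: IC50 = %.3g", x$ic50), ...)
  graphics::lines(xs, fourpl_response(xs, x$top, x$bottom, x$ic50,
                                      x$hill), col = 2, lwd = 1.5)
  graphics::abline(v = x$ic50, lty = 3)
  invisible(x)
}
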