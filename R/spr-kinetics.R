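# 1:1 Langmuir SPR kinetics: multi-cycle sensorgram simulation, global
# nonlinear fitting with shared (ka, kd, Rmax), and the exponential
# dissociation-fraction model.

#' Kinetic parameters of a 1:1 interaction
#'
#' @param ka association rate constant, 1/(M*s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax saturation response, RU.
#' @return list of class \code{kinetic_params}; \code{KD} (= kd/ka) is in
#'   molar, \code{KD_nM} in nM.
#' @export
kinetic_params <- function(ka, kd, Rmax) {
  stopifnot(ka > 0, kd > 0, Rmax > 0)
  structure(list(ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka,
                 KD_nM = 1e9 * kd / ka),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("ka = %.4g 1/(M*s), kd = %.4g 1/s, KD = %.4g nM, Rmax = %.4g RU\n",
              x$ka, x$kd, x$KD_nM, x$Rmax))
  invisible(x)
}

#' Serial dilution series of analyte concentrations
#'
#' Repeated division by \code{fold} from \code{top} down to the last
#' value at or above \code{floor} (within a 1e-6 relative slack). The
#' default multi-cycle protocol (threefold from 1,000 nM to 4.1 nM) gives
#' six concentrations.
#' @param top highest concentration, nM.
#' @param fold dilution factor (> 1).
#' @param floor lowest concentration kept, nM.
#' @return decreasing numeric vector of concentrations, nM.
#' @examples
#' dilution_series(1000, 3, 4.1)
#' @export
dilution_series <- function(top = 1000, fold = 3, floor = 4.1) {
  stopifnot(top > 0, floor > 0, top >= floor, fold > 1)
  n <- base::floor(log(top / (floor * (1 - 1e-6))) / log(fold)) + 1L
  top / fold^(seq_len(n) - 1L)
}

#' Injection schedule for multi-cycle kinetics
#'
#' @param concentrations analyte concentrations, nM (strictly decreasing).
#' @param t_contact association (contact) time, s.
#' @param t_dissoc dissociation time, s.
#' @param sampling_hz sampling rate, Hz.
#' @export
injection_schedule <- function(concentrations = dilution_series(),
                               t_contact = 60, t_dissoc = 300,
                               sampling_hz = 1) {
  stopifnot(all(concentrations > 0), !is.unsorted(rev(concentrations),
                                                  strictly = TRUE),
            t_contact > 0, t_dissoc > 0, sampling_hz > 0)
  structure(list(concentrations = concentrations, t_contact = t_contact,
                 t_dissoc = t_dissoc, sampling_hz = sampling_hz),
            class = "injection_schedule")
}

# Noiseless 1:1 Langmuir response at times t (s) for one concentration
# C_nM. Association: R = Req*(1 - exp(-(ka*C + kd)*t)) with
# Req = Rmax*C/(C + KD); dissociation: exponential decay from R(t_contact).
langmuir_response <- function(t, C_nM, ka, kd, Rmax, t_contact) {
  C <- C_nM * 1e-9
  KD <- kd / ka
  Req <- Rmax * C / (C + KD)
  kobs <- ka * C + kd
  R_tc <- Req * (1 - exp(-kobs * t_contact))
  ifelse(t <= t_contact,
         Req * (1 - exp(-kobs * t)),
         R_tc * exp(-kd * (t - t_contact)))
}

#' Simulate multi-cycle 1:1 Langmuir sensorgrams
#'
#' One association/dissociation trace per concentration, with optional
#' additive Gaussian noise.
#' @param params a \code{\link{kinetic_params}}.
#' @param schedule an \code{\link{injection_schedule}}.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed integer seed (recorded in the output attributes).
#' @return data.frame with columns \code{curve_id}, \code{concentration}
#'   (nM), \code{time} (s), \code{response} (RU); attribute \code{"seed"}.
#' @export
simulate_sensorgrams <- function(params, schedule, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "injection_schedule"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, schedule$t_contact + schedule$t_dissoc,
           by = 1 / schedule$sampling_hz)
  out <- do.call(rbind, lapply(seq_along(schedule$concentrations),
                               function(i) {
    C <- schedule$concentrations[i]
    r <- langmuir_response(t, C, params$ka, params$kd, params$Rmax,
                           schedule$t_contact)
    if (noise_sd > 0) r <- r + stats::rnorm(length(t), 0, noise_sd)
    data.frame(curve_id = sprintf("c%02d", i), concentration = C,
               time = t, response = r, stringsAsFactors = FALSE)
  }))
  attr(out, "seed") <- seed
  attr(out, "t_contact") <- schedule$t_contact
  out
}

# Profiled-Rmax objective: the 1:1 model is linear in Rmax, so for fixed
# (ka, kd) the optimal Rmax has the closed form <g, y> / <g, g> where g is
# the unit-Rmax model. Reduces the global fit to 2 free parameters.
profile_rmax <- function(lka, lkd, curves, t_contact) {
  g <- langmuir_response(curves$time, curves$concentration, 10^lka,
                         10^lkd, 1, t_contact)
  gg <- sum(g * g)
  if (gg <= 0) return(list(Rmax = 0, resid = curves$response))
  Rmax <- sum(g * curves$response) / gg
  list(Rmax = Rmax, resid = curves$response - Rmax * g)
}

#' Globally fit the 1:1 Langmuir model to multi-cycle sensorgrams
#'
#' Nonlinear least squares over all curves jointly, sharing (ka, kd,
#' Rmax). Rmax is profiled out in closed form (the model is linear in
#' it); (log10 ka, log10 kd) are fitted by Levenberg-Marquardt
#' (\code{minpack.lm}) from a multistart grid (default 5x5, log-spaced
#' over ka in [1e3, 1e7] 1/(M*s) and kd in [1e-5, 1e-1] 1/s), refining
#' the best starts.
#'
#' @param curves data.frame with columns \code{time}, \code{response},
#'   \code{concentration} (nM) and \code{curve_id} (as produced by
#'   \code{\link{simulate_sensorgrams}}).
#' @param t_contact association time, s (default: attribute of
#'   \code{curves}, else 60).
#' @param ka_grid,kd_grid multistart grid values.
#' @param n_refine number of best grid starts refined by
#'   Levenberg-Marquardt.
#' @return object of class \code{spr_fit}: fitted \code{ka}, \code{kd},
#'   \code{KD} (M), \code{KD_nM}, \code{Rmax}, \code{sse}, degrees of
#'   freedom, convergence diagnostics and the data.
#' @export
fit_1to1 <- function(curves, t_contact = NULL,
                     ka_grid = 10^seq(3, 7, length.out = 5),
                     kd_grid = 10^seq(-5, -1, length.out = 5),
                     n_refine = 3L) {
  need <- c("time", "response", "concentration", "curve_id")
  stopifnot(all(need %in% names(curves)))
  if (length(unique(curves$concentration)) < 2L)
    stopf("global 1:1 fit needs >= 2 analyte concentrations")
  t_contact <- t_contact %||% attr(curves, "t_contact") %||% 60
  starts <- expand.grid(lka = log10(ka_grid), lkd = log10(kd_grid))
  sse0 <- vapply(seq_len(nrow(starts)), function(i) {
    sum(profile_rmax(starts$lka[i], starts$lkd[i], curves,
                     t_contact)$resid^2)
  }, numeric(1))
  refine <- utils::head(order(sse0), n_refine)
  resid_fn <- function(p) profile_rmax(p[1], p[2], curves, t_contact)$resid
  best <- NULL
  for (i in refine) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(starts$lka[i], starts$lkd[i]),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   message = fit$message)
  }
  if (is.null(best))
    stopf("1:1 fit failed to converge from all %d starts", nrow(starts))
  pr <- profile_rmax(best$par[1], best$par[2], curves, t_contact)
  ka <- 10^best$par[1]; kd <- 10^best$par[2]
  fitted_vals <- curves$response - pr$resid
  structure(list(ka = ka, kd = kd, KD = kd / ka, KD_nM = 1e9 * kd / ka,
                 Rmax = pr$Rmax, sse = best$sse,
                 df = nrow(curves) - 3L, info = best$info,
                 message = best$message, t_contact = t_contact,
                 data = curves, fitted_values = fitted_vals),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit (multi-cycle kinetics)\n")
  cat(sprintf("  ka   = %.4g 1/(M*s)\n  kd   = %.4g 1/s\n", x$ka, x$kd))
  cat(sprintf("  KD   = %.4g nM\n  Rmax = %.4g RU\n", x$KD_nM, x$Rmax))
  cat(sprintf("  SSE  = %.4g on %d curves (%d points)\n", x$sse,
              length(unique(x$data$curve_id)), nrow(x$data)))
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(ka = object$ka, kd = object$kd, KD = object$KD, Rmax = object$Rmax)
}

#' @export
summary.spr_fit <- function(object, ...) {
  rmse <- sqrt(object$sse / object$df)
  out <- list(coefficients = coef(object), KD_nM = object$KD_nM,
              sse = object$sse, rmse = rmse, df = object$df,
              info = object$info, message = object$message)
  class(out) <- "summary.spr_fit"
  out
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit\n")
  print(x$coefficients)
  cat(sprintf("KD = %.4g nM; residual SE %.4g RU on %d df (%s)\n",
              x$KD_nM, x$rmse, x$df, x$message))
  invisible(x)
}

#' @export
fitted.spr_fit <- function(object, ...) object$fitted_values

#' @export
residuals.spr_fit <- function(object, ...) {
  object$data$response - object$fitted_values
}

#' Predict sensorgram responses from a fitted 1:1 model
#' @param object an \code{spr_fit}.
#' @param newdata data.frame with \code{time} and \code{concentration}
#'   (nM) columns; default = the fitted data.
#' @param ... unused.
#' @export
predict.spr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  langmuir_response(newdata$time, newdata$concentration, object$ka,
                    object$kd, object$Rmax, object$t_contact)
}

#' @export
plot.spr_fit <- function(x, ...) {
  d <- x$data
  ids <- unique(d$curve_id)
  graphics::plot(d$time, d$response, type = "n",
                 xlab = "Time (s)", ylab = "Response (RU)",
                 main = sprintf("1:1 fit: KD = %.3g nM", x$KD_nM), ...)
  for (i in seq_along(ids)) {
    sel <- d$curve_id == ids[i]
    graphics::points(d$time[sel], d$response[sel], col = "grey60",
                     pch = 16, cex = 0.3)
    graphics::lines(d$time[sel], x$fitted_values[sel], col = i, lwd = 1.5)
  }
  graphics::abline(v = x$t_contact, lty = 3)
  invisible(x)
}

#' Fraction of antibody-antigen complex remaining after time t
#'
#' Exponential first-order dissociation: exp(-kd * t). With the off-rate
#' 0.0013 1/s, about 45.8% of complexes remain after 600 s.
#' @param kd dissociation rate constant, 1/s (>= 0).
#' @param t elapsed time, s (>= 0).
#' @return fraction on [0, 1].
#' @examples
#' fraction_remaining(0.0013, 600)
#' @export
fraction_remaining <- function(kd, t) {
  stopifnot(all(kd >= 0), all(t >= 0))
  exp(-kd * t)
}
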