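#' Inversion-recovery spin-echo protocol
#'
#' @param tis_ms inversion times (ms)
#' @param tr_ms repetition time (ms)
#' @return object of class `ir_se_protocol`
#' @export
ir_se_protocol <- function(tis_ms = c(50, 350, 650, 950, 1250, 1550, 1850, 2150),
                           tr_ms = 8000) {
  stopifnot(all(diff(tis_ms) > 0), tr_ms > max(tis_ms))
  structure(list(tis_ms = tis_ms, tr_ms = tr_ms), class = "ir_se_protocol")
}

#' T1rho-prepared spin-echo protocol
#'
#' @param tsls_ms spin-lock durations (ms)
#' @param sla_hz spin-lock amplitude (Hz, metadata)
#' @return object of class `t1rho_se_protocol`
#' @export
t1rho_se_protocol <- function(tsls_ms = c(2, 14, 26, 38, 50, 62, 74, 86),
                              sla_hz = 150) {
  stopifnot(all(diff(tsls_ms) > 0))
  structure(list(tsls_ms = tsls_ms, sla_hz = sla_hz),
            class = "t1rho_se_protocol")
}

#' IR spin-echo signal equation
#' @param t1,m0 tissue parameters (ms, a.u.)
#' @param ti,tr inversion/repetition times (ms)
#' @return model signal
#' @export
ir_se_signal <- function(t1, m0, ti, tr) {
  m0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1))
}

#' Two-parameter Levenberg-Marquardt fit of IR spin-echo data
#'
#' Fits S(TI) = M0 (1 - 2 exp(-TI/T1) + exp(-TR/T1)) to signed signals (or
#' |S| with `magnitude = TRUE` for magnitude-reconstructed references).
#' Initialisation: T1 = TI of the minimum |signal| / ln 2, M0 = max
#' |signal|.
#'
#' @param signals per-TI signal values
#' @param protocol [ir_se_protocol()]
#' @param init optional list(t1, m0) override
#' @param magnitude fit |model| to magnitude data
#' @return list with t1 (ms), m0, converged, fit (the nls object)
#' @export
fit_ir_se <- function(signals, protocol = ir_se_protocol(), init = NULL,
                      magnitude = FALSE) {
  ti <- protocol$tis_ms; tr <- protocol$tr_ms
  stopifnot(length(signals) == length(ti), length(ti) >= 3)
  if (is.null(init))
    init <- list(t1 = ti[which.min(abs(signals))] / log(2),
                 m0 = max(abs(signals)))
  df <- data.frame(s = signals, ti = ti)
  fo <- if (magnitude)
    s ~ abs(m0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1)))
  else
    s ~ m0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1))
  fit <- try(minpack.lm::nlsLM(
    fo, data = df, start = list(t1 = init$t1, m0 = init$m0),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(t1 = NA_real_, m0 = NA_real_, converged = FALSE, fit = NULL))
  co <- stats::coef(fit)
  list(t1 = unname(co["t1"]), m0 = unname(co["m0"]),
       converged = fit$convInfo$isConv %||% TRUE, fit = fit)
}

#' Log-linear mono-exponential T1rho fit
#'
#' Linear least squares on log S vs TSL for S = M0 exp(-TSL/T1rho);
#' T1rho = -1/slope, M0 = exp(intercept). Non-positive signals are excluded
#' from the log; fewer than two remaining points is an error.
#'
#' @param signals per-TSL signal values
#' @param protocol [t1rho_se_protocol()]
#' @return list with t1rho (ms), m0, n_used
#' @export
fit_t1rho_monoexp <- function(signals, protocol = t1rho_se_protocol()) {
  tsl <- protocol$tsls_ms
  stopifnot(length(signals) == length(tsl))
  ok <- signals > 0
  if (sum(ok) < 2)
    stop("fewer than two positive signals for the log-linear fit",
         call. = FALSE)
  fit <- stats::lm(log(signals[ok]) ~ tsl[ok])
  sl <- unname(stats::coef(fit)[2])
  list(t1rho = -1 / sl, m0 = exp(unname(stats::coef(fit)[1])),
       n_used = sum(ok))
}
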