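#' Fit the unidirectional kinetic model to a metabolite time series
#'
#' Two-stage nonlinear least squares for the apparent conversion rate
#' constants. Stage 1 fits the pyruvate channel from its maximum onward
#' with a mono-exponential \eqn{S_P(t) = S_0 \exp(-\tilde\rho_P (t - t_m))},
#' estimating the observed pyruvate amplitude and its effective decay rate
#' (conversion + relaxation + RF loss combined; no relaxation assumption is
#' needed for the products' rate constants). Stage 2 fits the lactate and
#' alanine channels with the precursor parameters fixed:
#' \deqn{S_X(t) = k_{PX} S_0 \frac{e^{-\tilde\rho_X \tau} -
#'   e^{-\tilde\rho_P \tau}}{\tilde\rho_P - \tilde\rho_X} + X_0
#'   e^{-\tilde\rho_X \tau}}
#' where \eqn{\tilde\rho_X} uses the product's effective relaxation rate
#' (fixed by default, or freed) plus the RF-loss term, and \eqn{X_0} absorbs
#' any product signal already present at the fit start. A joint mode fits
#' all channels simultaneously.
#'
#' Bounds are enforced (rate constants in [0, 1] /s), optimization is
#' Levenberg-Marquardt with multiple starts, and standard errors come from
#' the residual Jacobian.
#'
#' @param series A [metabolite_series()] (or data.frame with columns
#'   `time_s`, `pyruvate`, `lactate`, `alanine`).
#' @param acq The [acq_params()] under which the series was acquired.
#' @param mode `"sequential"` (default two-stage scheme) or `"joint"`.
#' @param fix_r1l,fix_r1a Effective relaxation rates (1/s) assumed for
#'   lactate and alanine, excluding RF loss. Defaults 1/30 s.
#' @param free_decays If `TRUE`, the product relaxation rates are fitted
#'   rather than fixed (ill-conditioned for short, noisy series).
#' @param n_starts Number of Levenberg-Marquardt starts (perturbed
#'   initializations) guarding against local minima.
#' @return An object of class `kinetic_fit`: list with `estimates`
#'   (k_pl_per_s, k_pa_per_s, r1p_eff_per_s, p0, plus freed decays),
#'   `se` (matching standard errors), `rss`, `converged`, `fixed` (map of
#'   fixed parameter values), `n_used`, `fit_start_index`.
#' @examples
#' acq <- acq_params()
#' truth <- kinetic_params(k_pl_per_s = 0.0125, k_pa_per_s = 0.0098)
#' fit <- fit_kinetics(forward_model(truth, acq), acq)
#' fit$estimates[c("k_pl_per_s", "k_pa_per_s")]
#' @export
fit_kinetics <- function(series, acq, mode = c("sequential", "joint"),
                         fix_r1l = 1 / 30, fix_r1a = 1 / 30,
                         free_decays = FALSE, n_starts = 3) {
  mode <- match.arg(mode)
  series <- as_metabolite_series(series)
  stopifnot(inherits(acq, "acq_params"))
  if (max(series$pyruvate) <= 0)
    stop("pyruvate channel has no positive signal; nothing to fit")

  theta <- deg2rad(acq$flip_deg)
  rf <- -log(cos(theta)) / acq$tr_s

  imax <- which.max(series$pyruvate)
  if (imax == nrow(series))
    stop("pyruvate maximum at the last transient; no decay to fit ",
         "(acquisition ended before or at bolus peak)")
  idx <- imax:nrow(series)
  tau <- series$time_s[idx] - series$time_s[imax]
  pyr <- series$pyruvate[idx]
  lac <- series$lactate[idx]
  ala <- series$alanine[idx]

  # ---- stage 1: pyruvate amplitude and effective decay ----
  pos <- pyr > 0
  rho_init <- if (sum(pos) >= 3) {
    max(1e-4, -unname(stats::coef(stats::lm(log(pyr[pos]) ~ tau[pos]))[2]))
  } else 1 / 40 + rf
  s1 <- .lm_multistart(
    par = c(s0 = max(pyr), rho_p = rho_init),
    fn = function(p) pyr - p[1] * exp(-p[2] * tau),
    lower = c(1e-12, 1e-6), upper = c(Inf, 10), n_starts = n_starts)
  s0 <- s1$par[1]; rho_p <- s1$par[2]

  rho_l0 <- fix_r1l + rf
  rho_a0 <- fix_r1a + rf

  if (mode == "sequential" && !free_decays) {
    fl <- .fit_product(lac, tau, s0, rho_p, rho_x = rho_l0,
                       free_rho = FALSE, n_starts = n_starts)
    fa <- .fit_product(ala, tau, s0, rho_p, rho_x = rho_a0,
                       free_rho = FALSE, n_starts = n_starts)
    est <- c(k_pl_per_s = unname(fl$par["k"]),
             k_pa_per_s = unname(fa$par["k"]),
             r1p_eff_per_s = unname(
               rho_p - rf - fl$par["k"] - fa$par["k"]),
             p0 = unname(s0 / sin(theta)))
    se <- c(k_pl_per_s = unname(fl$se["k"]), k_pa_per_s = unname(fa$se["k"]),
            r1p_eff_per_s = unname(sqrt(s1$se["rho_p"]^2 +
                                          fl$se["k"]^2 + fa$se["k"]^2)),
            p0 = unname(s1$se["s0"] / sin(theta)))
    rss <- s1$rss + fl$rss + fa$rss
    conv <- s1$converged && fl$converged && fa$converged
  } else if (mode == "sequential") {
    fl <- .fit_product(lac, tau, s0, rho_p, rho_x = rho_l0,
                       free_rho = TRUE, n_starts = n_starts)
    fa <- .fit_product(ala, tau, s0, rho_p, rho_x = rho_a0,
                       free_rho = TRUE, n_starts = n_starts)
    est <- c(k_pl_per_s = unname(fl$par["k"]),
             k_pa_per_s = unname(fa$par["k"]),
             r1p_eff_per_s = unname(rho_p - rf - fl$par["k"] - fa$par["k"]),
             r1l_eff_per_s = unname(fl$par["rho"] - rf),
             r1a_eff_per_s = unname(fa$par["rho"] - rf),
             p0 = unname(s0 / sin(theta)))
    se <- c(k_pl_per_s = unname(fl$se["k"]), k_pa_per_s = unname(fa$se["k"]),
            r1p_eff_per_s = unname(sqrt(s1$se["rho_p"]^2 +
                                          fl$se["k"]^2 + fa$se["k"]^2)),
            r1l_eff_per_s = unname(fl$se["rho"]),
            r1a_eff_per_s = unname(fa$se["rho"]),
            p0 = unname(s1$se["s0"] / sin(theta)))
    rss <- s1$rss + fl$rss + fa$rss
    conv <- s1$converged && fl$converged && fa$converged
  } else {
    jf <- .fit_joint(pyr, lac, ala, tau, s0, rho_p, rho_l0, rho_a0,
                     n_starts = n_starts)
    est <- c(k_pl_per_s = unname(jf$par["k_pl"]),
             k_pa_per_s = unname(jf$par["k_pa"]),
             r1p_eff_per_s = unname(jf$par["rho_p"] - rf -
                                      jf$par["k_pl"] - jf$par["k_pa"]),
             p0 = unname(jf$par["s0"] / sin(theta)))
    se <- c(k_pl_per_s = unname(jf$se["k_pl"]),
            k_pa_per_s = unname(jf$se["k_pa"]),
            r1p_eff_per_s = unname(jf$se["rho_p"]),
            p0 = unname(jf$se["s0"] / sin(theta)))
    rss <- jf$rss
    conv <- jf$converged
  }

  structure(list(
    estimates = est, se = se, rss = rss, converged = conv,
    fixed = if (free_decays) c(rf_loss_per_s = rf)
            else c(r1l_eff_per_s = fix_r1l, r1a_eff_per_s = fix_r1a,
                   rf_loss_per_s = rf),
    mode = mode, n_used = length(idx), fit_start_index = imax,
    fit_start_time_s = series$time_s[imax],
    series = series, acq = acq), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Unidirectional kinetic fit (%s mode)%s\n", x$mode,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  kPL = %.5g +/- %.2g /s\n",
              x$estimates["k_pl_per_s"], x$se["k_pl_per_s"]))
  cat(sprintf("  kPA = %.5g +/- %.2g /s\n",
              x$estimates["k_pa_per_s"], x$se["k_pa_per_s"]))
  cat(sprintf("  R1P_eff = %.5g /s, p0 = %.5g, rss = %.4g, n = %d (from transient %d)\n",
              x$estimates["r1p_eff_per_s"], x$estimates["p0"], x$rss,
              x$n_used, x$fit_start_index))
  invisible(x)
}

#' Plot a kinetic fit against its data
#'
#' Base-graphics overlay of the measured pyruvate/lactate/alanine
#' amplitudes and the fitted model curves.
#'
#' @param x A `kinetic_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kinetic_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$time_s, s$pyruvate, pch = 1, col = "black",
                 xlab = "time (s)", ylab = "signal (a.u.)", ...)
  graphics::points(s$time_s, s$lactate, pch = 2, col = "firebrick")
  graphics::points(s$time_s, s$alanine, pch = 3, col = "steelblue")
  acq <- x$acq
  pars <- kinetic_params(
    k_pl_per_s = unname(x$estimates["k_pl_per_s"]),
    k_pa_per_s = unname(x$estimates["k_pa_per_s"]),
    r1p_eff_per_s = max(0, unname(x$estimates["r1p_eff_per_s"])),
    r1l_eff_per_s = unname(x$fixed["r1l_eff_per_s"] %||% (1 / 30)),
    r1a_eff_per_s = unname(x$fixed["r1a_eff_per_s"] %||% (1 / 30)),
    p0 = unname(x$estimates["p0"]),
    t0_s = x$fit_start_time_s)
  fitline <- forward_model(pars, acq)
  graphics::lines(fitline$time_s, fitline$pyruvate, col = "black")
  graphics::lines(fitline$time_s, fitline$lactate, col = "firebrick")
  graphics::lines(fitline$time_s, fitline$alanine, col = "steelblue")
  graphics::legend("topright", c("pyruvate", "lactate", "alanine"),
                   col = c("black", "firebrick", "steelblue"),
                   pch = 1:3, lty = 1, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

# Product-channel model: k * s0 * rise(tau) + x0 * exp(-rho_x tau).
.fit_product <- function(y, tau, s0, rho_p, rho_x, free_rho, n_starts) {
  if (all(y == 0)) {
    nm <- if (free_rho) c("k", "x0", "rho") else c("k", "x0")
    z <- stats::setNames(rep(0, length(nm)), nm)
    if (free_rho) z["rho"] <- rho_x
    return(list(par = z, se = stats::setNames(rep(0, length(nm)), nm),
                rss = 0, converged = TRUE))
  }
  if (free_rho) {
    .lm_multistart(
      par = c(k = 0.01, x0 = max(0, y[1]), rho = rho_x),
      fn = function(p) y - (p[1] * s0 * .rise(tau, rho_p, p[3]) +
                              p[2] * exp(-p[3] * tau)),
      lower = c(0, 0, 1e-6), upper = c(1, Inf, 10), n_starts = n_starts)
  } else {
    .lm_multistart(
      par = c(k = 0.01, x0 = max(0, y[1])),
      fn = function(p) y - (p[1] * s0 * .rise(tau, rho_p, rho_x) +
                              p[2] * exp(-rho_x * tau)),
      lower = c(0, 0), upper = c(1, Inf), n_starts = n_starts)
  }
}

.fit_joint <- function(pyr, lac, ala, tau, s0, rho_p, rho_l, rho_a,
                       n_starts) {
  .lm_multistart(
    par = c(s0 = s0, rho_p = rho_p, k_pl = 0.01, k_pa = 0.01),
    fn = function(p) {
      c(pyr - p[1] * exp(-p[2] * tau),
        lac - p[3] * p[1] * .rise(tau, p[2], rho_l),
        ala - p[4] * p[1] * .rise(tau, p[2], rho_a))
    },
    lower = c(1e-12, 1e-6, 0, 0), upper = c(Inf, 10, 1, 1),
    n_starts = n_starts)
}

# Bounded Levenberg-Marquardt with perturbed restarts; SEs from the
# Jacobian at the best solution.
.lm_multistart <- function(par, fn, lower, upper, n_starts = 3) {
  best <- NULL
  starts <- list(par)
  facs <- c(0.3, 3, 0.1, 10)
  if (n_starts > 1) {
    for (j in seq_len(min(n_starts, length(facs) + 1) - 1)) {
      cap <- ifelse(is.finite(upper), upper, pmax(par, 1) * 100)
      p <- pmin(pmax(par * facs[j], lower), cap)
      starts[[j + 1]] <- stats::setNames(p, names(par))
    }
  }
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 * max(1, best$rss))
      best <- list(fit = res, rss = rss)
  }
  if (is.null(best))
    return(list(par = par, se = par * NA_real_, rss = Inf,
                converged = FALSE))
  fit <- best$fit
  p <- stats::setNames(stats::coef(fit), names(par))
  np <- length(p); nr <- length(fit$fvec)
  sigma2 <- if (nr > np) best$rss / (nr - np) else 0
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) p * NA_real_ else {
    d <- diag(covm); d[d < 0] <- 0
    stats::setNames(sqrt(d), names(par))
  }
  list(par = p, se = se, rss = best$rss,
       converged = fit$info %in% 1:4)
}
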