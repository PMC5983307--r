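#' Construct an arterial input function model
#'
#' The parametric form is the three-exponential bolus model
#' \deqn{C_I(t) = [A_1 (t-\tau) - A_2 - A_3] e^{\lambda_1 (t-\tau)} +
#'       A_2 e^{\lambda_2 (t-\tau)} + A_3 e^{\lambda_3 (t-\tau)}}
#' for \eqn{t > \tau} and 0 otherwise, with all \eqn{\lambda_i < 0}: a
#' sharp bolus peak followed by bi-exponential washout.  The sampled form
#' interpolates linearly between supplied (time, activity) pairs and is 0
#' before the first sample.
#'
#' @param form "feng3exp" or "sampled".
#' @param params for feng3exp: named vector with `A1` (Bq/cc/s), `A2`, `A3`
#'   (Bq/cc), `l1`, `l2`, `l3` (1/s, negative) and `tau` (s).
#' @param times,values samples for the sampled form (s, Bq/cc).
#' @return an [AIFModel-class].
#' @examples
#' aif <- defaultAIF()
#' evalAIF(aif, c(0, 60, 600))
#' @export
aifModel <- function(form = c("feng3exp", "sampled"), params = numeric(),
                     times = numeric(), values = numeric()) {
  form <- match.arg(form)
  new("AIFModel", form = form, params = params,
      times = as.numeric(times), values = as.numeric(values))
}

#' @describeIn aifModel a physiologically plausible default bolus AIF
#'   (peak about 3.3 kBq/cc shortly after a 30 s post-scan-start injection,
#'   washing out to a slowly decaying tail of about 40 Bq/cc).
#' @export
defaultAIF <- function() {
  aifModel("feng3exp",
           params = c(A1 = 800, A2 = 20, A3 = 21,
                      l1 = -0.05, l2 = -0.001, l3 = -1e-4, tau = 30))
}

#' Evaluate an arterial input function
#'
#' @param aif an [AIFModel-class].
#' @param t times (s), each >= 0.
#' @return activity concentration (Bq/cc) at each `t`; 0 before the delay.
#' @export
evalAIF <- function(aif, t) {
  stopifnot(is(aif, "AIFModel"))
  if (aif@form == "feng3exp") {
    p <- aif@params
    u <- t - p[["tau"]]
    out <- ifelse(u <= 0, 0,
                  (p[["A1"]] * u - p[["A2"]] - p[["A3"]]) * exp(p[["l1"]] * u) +
                    p[["A2"]] * exp(p[["l2"]] * u) +
                    p[["A3"]] * exp(p[["l3"]] * u))
    as.numeric(out)
  } else if (aif@form == "sampled") {
    out <- approx(aif@times, aif@values, xout = t, rule = 2)$y
    out[t < aif@times[1]] <- 0
    as.numeric(out)
  } else {
    stop("unknown AIF form: ", aif@form)   # guarded again for corrupt objects
  }
}

#' Image-derived arterial input function
#'
#' Fits the three-exponential bolus model to the mean blood-region TAC of a
#' reconstructed image sequence (typically a conventional-MAP prepass), the
#' region of interest given by voxel indices.  Frame averages are
#' decay-corrected before the fit, since the parametric AIF lives in
#' decay-corrected units.
#'
#' @param images an [ImageSeries-class].
#' @param bloodMask voxel indices of the blood region.
#' @return an [AIFModel-class] of form "feng3exp".
#' @export
imageDerivedAIF <- function(images, bloodMask) {
  sched <- images@schedule
  a <- colMeans(images@values[bloodMask, , drop = FALSE])
  dur <- frameDurations(sched)
  lam <- decayConstant(sched)
  ## decay correction: divide by the frame-averaged decay factor
  dc <- if (lam == 0) rep(1, length(dur)) else
    vapply(seq_along(dur), function(m) {
      (exp(-lam * sched@start[m]) - exp(-lam * sched@end[m])) / (lam * dur[m])
    }, numeric(1))
  acorr <- a / dc
  w <- tacFitWeights(sched, pmax(acorr, max(acorr) * 1e-3))
  fitAIF(frameMidpoints(sched), acorr, weights = w)
}

#' Fit the three-exponential bolus model to a sampled blood curve
#'
#' Weighted least-squares fit of the feng3exp form to a measured or
#' image-derived blood TAC, via Levenberg-Marquardt with a coarse
#' delay search.  Used for image-derived input functions, where the blood
#' curve comes from a region of interest in conventionally reconstructed
#' images.
#'
#' @param times,values the sampled blood curve (s, Bq/cc).
#' @param weights optional per-sample weights (default 1).
#' @param tauGrid candidate delays (s) for the coarse search.
#' @return an [AIFModel-class] of form "feng3exp".
#' @export
fitAIF <- function(times, values, weights = NULL,
                   tauGrid = seq(0, 120, by = 5)) {
  stopifnot(length(times) == length(values), length(times) >= 7)
  if (is.null(weights)) weights <- rep(1, length(times))
  sw <- sqrt(weights)
  peak <- max(values)
  best <- NULL
  for (tau in tauGrid) {
    start <- c(A1 = peak / 20, A2 = peak / 50, A3 = peak / 50,
               l1 = -0.05, l2 = -0.001, l3 = -1e-4)
    resid <- function(p) {
      m <- aifModel("feng3exp", params = c(p, tau = tau))
      sw * (values - evalAIF(m, times))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid,
                         lower = c(0, 0, 0, -1, -0.1, -0.01),
                         upper = c(Inf, Inf, Inf, -1e-4, -1e-6, -1e-8),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit$par)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, par = fit$par, tau = tau)
  }
  if (is.null(best)) stop("AIF fit failed for every candidate delay")
  aifModel("feng3exp", params = c(best$par, tau = best$tau))
}
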