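# Repolarization restitution: wall-mean RT as a function of paced cycle
# length, fitted per ventricle, with the interventricular divergence report.

#' Fit per-ventricle repolarization restitution curves
#'
#' Builds restitution points (RR, wall-mean RT) for the RV and LV from a
#' list of repolarization fields measured at different paced cycle lengths
#' and fits a straight line per ventricle by least squares (an exponential
#' fit is available as an option; four protocol points cannot constrain
#' more). The divergence report gives the predicted LV - RV difference at
#' each observed RR and the slope difference \eqn{\beta_{LV} - \beta_{RV}}:
#' a steeper LV curve means interventricular dispersion of repolarization
#' grows at long cycle lengths.
#'
#' @param fields list of [rt_field()] objects at distinct \code{rr_ms}, or
#'   a data.frame with columns \code{rr_ms}, \code{rv_rt_ms},
#'   \code{lv_rt_ms} (e.g. published wall means).
#' @param model \code{"linear"} (default) or \code{"exponential"}
#'   (\eqn{RT = a - b e^{-rr/\tau}}, fitted by \code{nls}).
#' @return object of class \code{restitution_fit} with methods
#'   \code{print}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{plot}. Elements: \code{points} (ventricle, rr_ms, mean_rt_ms),
#'   \code{fits} (per-ventricle intercept/slope), \code{divergence}
#'   (rr_ms, lv_minus_rv_ms), \code{slope_difference}, \code{model}.
#' @export
#' @examples
#' pts <- data.frame(rr_ms = c(600, 750, 1000, 1200),
#'                   rv_rt_ms = c(330, 376, 392, 403),
#'                   lv_rt_ms = c(363, 413, 464, 480))
#' fit <- restitution(pts)
#' coef(fit)
restitution <- function(fields, model = c("linear", "exponential")) {
  model <- match.arg(model)
  pts <- if (is.data.frame(fields)) {
    stopifnot(all(c("rr_ms", "rv_rt_ms", "lv_rt_ms") %in% names(fields)))
    rbind(data.frame(ventricle = "RV", rr_ms = fields$rr_ms,
                     mean_rt_ms = fields$rv_rt_ms),
          data.frame(ventricle = "LV", rr_ms = fields$rr_ms,
                     mean_rt_ms = fields$lv_rt_ms))
  } else {
    do.call(rbind, lapply(fields, function(f) {
      stopifnot(inherits(f, "rt_field"))
      ws <- wall_summaries(f)
      if (!all(c("RV", "LV") %in% ws$wall)) {
        stop("both ventricles must have accepted electrodes at RR ", f$rr_ms)
      }
      data.frame(ventricle = c("RV", "LV"), rr_ms = f$rr_ms,
                 mean_rt_ms = ws$rt_mean[match(c("RV", "LV"), ws$wall)])
    }))
  }
  pts <- pts[order(pts$ventricle, pts$rr_ms), ]
  rownames(pts) <- NULL
  if (length(unique(pts$rr_ms)) < 2L) {
    stop("slope undefined: need >= 2 distinct RR values")
  }
  fit_one <- function(v) {
    d <- pts[pts$ventricle == v, ]
    if (model == "linear") {
      fm <- stats::lm(mean_rt_ms ~ rr_ms, data = d)
      c(intercept_ms = unname(stats::coef(fm)[1]),
        slope_ms_per_ms = unname(stats::coef(fm)[2]))
    } else {
      fm <- stats::nls(mean_rt_ms ~ a - b * exp(-rr_ms / tau), data = d,
                       start = list(a = max(d$mean_rt_ms) + 20,
                                    b = 2 * diff(range(d$mean_rt_ms)),
                                    tau = diff(range(d$rr_ms)) / 2),
                       algorithm = "port",  # robust to a zero-residual fit
                       control = stats::nls.control(maxiter = 500))
      p <- stats::coef(fm)
      c(a_ms = unname(p["a"]), b_ms = unname(p["b"]), tau_ms = unname(p["tau"]))
    }
  }
  fits <- list(RV = fit_one("RV"), LV = fit_one("LV"))
  obj <- structure(list(points = pts, fits = fits, model = model),
                   class = "restitution_fit")
  rr_obs <- sort(unique(pts$rr_ms))
  obj$divergence <- data.frame(
    rr_ms = rr_obs,
    lv_minus_rv_ms = predict(obj, rr_obs, "LV") - predict(obj, rr_obs, "RV"))
  obj$slope_difference <- if (model == "linear") {
    unname(fits$LV["slope_ms_per_ms"] - fits$RV["slope_ms_per_ms"])
  } else NA_real_
  obj
}

#' @rdname restitution
#' @param ... passed through.
#' @export
build_restitution <- function(fields, ...) restitution(fields, ...)

#' @export
coef.restitution_fit <- function(object, ...) {
  do.call(rbind, object$fits)
}

#' @export
predict.restitution_fit <- function(object, rr_ms = NULL,
                                    ventricle = c("LV", "RV"), ...) {
  ventricle <- match.arg(ventricle)
  if (is.null(rr_ms)) {
    rr_ms <- object$points$rr_ms[object$points$ventricle == ventricle]
  }
  p <- object$fits[[ventricle]]
  if (object$model == "linear") {
    unname(p["intercept_ms"] + p["slope_ms_per_ms"] * rr_ms)
  } else {
    unname(p["a_ms"] - p["b_ms"] * exp(-rr_ms / p["tau_ms"]))
  }
}

#' @export
residuals.restitution_fit <- function(object, ...) {
  pts <- object$points
  pts$mean_rt_ms - vapply(seq_len(nrow(pts)), function(i) {
    predict(object, pts$rr_ms[i], pts$ventricle[i])
  }, numeric(1))
}

#' @export
print.restitution_fit <- function(x, ...) {
  cat("Repolarization restitution fit (", x$model, ")\n", sep = "")
  print(round(coef(x), 4))
  if (x$model == "linear") {
    cat(sprintf("slope difference (LV - RV): %.4f ms/ms\n", x$slope_difference))
  }
  cat("LV - RV divergence at observed RR:\n")
  print(x$divergence, row.names = FALSE)
  invisible(x)
}

#' @export
plot.restitution_fit <- function(x, ...) {
  pts <- x$points
  rr <- seq(min(pts$rr_ms), max(pts$rr_ms), length.out = 100)
  graphics::plot(pts$rr_ms, pts$mean_rt_ms,
                 pch = ifelse(pts$ventricle == "LV", 19, 1),
                 xlab = "RR interval (ms)", ylab = "mean RT (ms)",
                 main = "RT restitution", ...)
  graphics::lines(rr, predict(x, rr, "LV"), lty = 1)
  graphics::lines(rr, predict(x, rr, "RV"), lty = 2)
  graphics::legend("topleft", c("LV", "RV"), pch = c(19, 1), lty = 1:2,
                   bty = "n")
  invisible(x)
}
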