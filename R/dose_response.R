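#' Four-parameter logistic curve
#'
#' \deqn{V(d) = bottom + \frac{top - bottom}{1 + (d/ic50)^{hill}}}
#' Defined at \eqn{d = 0} (where \eqn{V = top} for \eqn{hill > 0}), so zero
#' doses are fitted, not dropped.
#'
#' @param dose dose vector (same units as \code{ic50}).
#' @param top,bottom response asymptotes (percent viability).
#' @param ic50 half-maximal inhibitory concentration.
#' @param hill Hill slope.
#' @return Predicted response.
#' @export
fourpl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Percent viability from blank-corrected absorbances
#'
#' \deqn{100 \times (A_{treated} - A_{blank}) / (A_{control} - A_{blank})}
#' Vectorized over treated wells; the control and blank terms are typically
#' per-plate means.
#'
#' @param treated_abs treated-well absorbance(s).
#' @param control_abs control absorbance (scalar or matching length).
#' @param blank_abs blank absorbance (scalar or matching length).
#' @return Percent viability.
#' @examples
#' percent_viability(0.45, 0.90, 0.05)  # ~47.06
#' @export
percent_viability <- function(treated_abs, control_abs, blank_abs) {
  corrected_control <- control_abs - blank_abs
  if (any(corrected_control <= 0))
    stop("non-positive corrected control absorbance: bad plate")
  100 * (treated_abs - blank_abs) / corrected_control
}

#' Absolute IC50 of a fitted four-parameter logistic curve
#'
#' The dose at which the fitted curve crosses \code{level} percent viability
#' (default 50, i.e. half-maximal inhibition relative to the untreated
#' control). For control-normalized viability this is the conventional
#' reported IC50; it coincides with the curve-midpoint \code{ic50} parameter
#' exactly when \code{top = 100} and \code{bottom = 0}. Unlike the midpoint
#' parameter it stays well-determined when the lower plateau lies outside
#' the tested dose range, where \code{bottom} and \code{ic50} trade off.
#'
#' @param par named coefficients \code{top}, \code{bottom}, \code{ic50},
#'   \code{hill}.
#' @param level viability level in percent (default 50).
#' @return The crossing dose, or \code{NA} if the curve never reaches
#'   \code{level}.
#' @export
absolute_ic50 <- function(par, level = 50) {
  top <- par[["top"]]; bottom <- par[["bottom"]]
  if (!(top > level && bottom < level)) return(NA_real_)
  r <- (top - bottom) / (level - bottom) - 1
  par[["ic50"]] * r^(1 / par[["hill"]])
}

#' Convert a long-format MTT plate table to per-well viability
#'
#' Expects columns \code{dose_uM}, \code{timepoint_h}, \code{replicate},
#' \code{absorbance}, \code{role} (one of \code{blank}, \code{control},
#' \code{treated}; controls are the untreated dose-0 wells). Correction uses
#' the per-timepoint mean blank, and the viability denominator the mean
#' corrected control.
#'
#' @param plate long plate data.frame.
#' @param timepoint_h timepoint to extract (default: the only one present).
#' @return data.frame with \code{dose}, \code{replicate}, \code{viability}.
#' @export
plate_viability <- function(plate, timepoint_h = NULL) {
  need <- c("dose_uM", "timepoint_h", "replicate", "absorbance", "role")
  missing <- setdiff(need, names(plate))
  if (length(missing))
    stop("plate table missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(timepoint_h)) {
    tps <- unique(plate$timepoint_h)
    if (length(tps) > 1L)
      stop("multiple timepoints present; pick one via timepoint_h")
    timepoint_h <- tps
  }
  p <- plate[plate$timepoint_h == timepoint_h, , drop = FALSE]
  blanks <- p$absorbance[p$role == "blank"]
  controls <- p$absorbance[p$role == "control"]
  if (!length(blanks)) stop("no blank wells at timepoint ", timepoint_h)
  if (!length(controls)) stop("no control wells at timepoint ", timepoint_h)
  blank_mean <- mean(blanks)
  control_mean <- mean(controls)
  wells <- p[p$role %in% c("control", "treated"), , drop = FALSE]
  data.frame(
    dose = wells$dose_uM,
    replicate = wells$replicate,
    viability = percent_viability(wells$absorbance, control_mean, blank_mean),
    stringsAsFactors = FALSE
  )
}

#' Fit a four-parameter logistic dose-response model
#'
#' Bounded Levenberg-Marquardt least squares on per-well viability with a
#' deterministic initializer: \code{top} = maximum dose-mean viability,
#' \code{bottom} = minimum dose-mean viability, \code{ic50} = the dose whose
#' mean response is nearest to midway between them, \code{hill} = 1. Bounds:
#' \code{bottom >= 0}, \code{top <= 120}, \code{hill} in [0.1, 10]. Parameter
#' standard errors come from the curvature at the optimum.
#'
#' Two IC50s are reported: the curve-midpoint \code{ic50} parameter, and
#' \code{ic50_abs}, the dose at which the fitted curve crosses 50 percent
#' viability (see \code{\link{absolute_ic50}}) - the conventional summary for
#' control-normalized viability and the better-determined one when the lower
#' plateau is not reached within the tested doses. Both carry a
#' replicate-resampling bootstrap SD (within-dose case resampling, fixed
#' seed): \code{ic50_sd_boot} and \code{ic50_abs_sd_boot}.
#'
#' Data whose dose-mean response never drops \code{min_span} points below its
#' maximum are flagged \code{no_inhibition} and not fitted: a flat profile
#' carries no information about an IC50.
#'
#' @param formula model formula, response ~ dose, e.g.
#'   \code{viability ~ dose}.
#' @param data data.frame containing the formula variables; at least 4
#'   distinct doses including 0 are expected.
#' @param min_span minimum drop (viability points) between the largest and
#'   smallest dose-mean response required to attempt a fit (default 15).
#' @param boot number of bootstrap resamples for the IC50 SD (default 199;
#'   0 disables).
#' @param boot_seed RNG seed for the bootstrap (default 19); the global RNG
#'   state is left untouched.
#' @return An object of class \code{"fourpl"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{plot}, \code{simulate}, \code{confint}.
#' @examples
#' d <- data.frame(dose = rep(c(0, 25, 50, 100, 200, 400), each = 2))
#' d$viability <- fourpl(d$dose, 100, 0, 115, 1.5)
#' coef(fit_4pl(viability ~ dose, d))
#' @export
fit_4pl <- function(formula, data, min_span = 15, boot = 199L,
                    boot_seed = 19L) {
  mf <- stats::model.frame(formula, data)
  viability <- mf[[1L]]
  dose <- mf[[2L]]
  if (!all(is.finite(viability)) || !all(is.finite(dose)))
    stop("non-finite dose or viability values")
  if (any(dose < 0)) stop("doses must be non-negative")
  doses <- sort(unique(dose))
  if (length(doses) < 4L) stop("at least 4 distinct doses required")

  means <- tapply(viability, dose, mean)
  mean_doses <- as.numeric(names(means))
  span <- max(means) - min(means)

  obj <- list(
    call = match.call(),
    formula = formula,
    data = data.frame(dose = dose, viability = viability),
    dose_means = data.frame(
      dose = mean_doses, mean = as.numeric(means),
      sd = as.numeric(tapply(viability, dose, stats::sd)),
      n = as.integer(tapply(viability, dose, length))),
    converged = FALSE, no_inhibition = FALSE, ic50_in_range = NA,
    coefficients = c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                     hill = NA_real_),
    se = c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
           hill = NA_real_),
    vcov = NULL, sigma = NA_real_, df.residual = length(viability) - 4L,
    ic50_abs = NA_real_, ic50_sd_boot = NA_real_,
    ic50_abs_sd_boot = NA_real_, diagnostics = NULL)
  class(obj) <- "fourpl"

  if (span < min_span) {
    obj$no_inhibition <- TRUE
    obj$diagnostics <- sprintf(
      "dose-mean response span %.1f < %.1f viability points; no inhibition",
      span, min_span)
    return(obj)
  }

  fit <- fit_4pl_engine(dose, viability, means)
  if (is.null(fit)) {
    obj$diagnostics <- "Levenberg-Marquardt fit failed to converge"
    return(obj)
  }
  obj$converged <- TRUE
  obj$coefficients <- fit$par
  obj$sigma <- sqrt(fit$deviance / max(1L, length(viability) - 4L))
  vc <- tryCatch(obj$sigma^2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc)) {
    dimnames(vc) <- list(names(fit$par), names(fit$par))
    obj$vcov <- vc
    obj$se <- sqrt(pmax(diag(vc), 0))[names(obj$coefficients)]
  }
  pos <- doses[doses > 0]
  obj$ic50_in_range <- obj$coefficients[["ic50"]] >= min(pos) &&
    obj$coefficients[["ic50"]] <= max(doses)
  obj$ic50_abs <- absolute_ic50(obj$coefficients)

  if (boot > 0L) {
    idx_by_dose <- split(seq_along(dose), dose)
    boot_ic50 <- boot_abs <- numeric(boot)
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(boot_seed)
    for (b in seq_len(boot)) {
      idx <- unlist(lapply(idx_by_dose, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      d_b <- dose[idx]; v_b <- viability[idx]
      fit_b <- fit_4pl_engine(d_b, v_b, tapply(v_b, d_b, mean))
      boot_ic50[b] <- if (is.null(fit_b)) NA_real_ else fit_b$par[["ic50"]]
      boot_abs[b] <- if (is.null(fit_b)) NA_real_ else
        absolute_ic50(fit_b$par)
    }
    obj$ic50_sd_boot <- stats::sd(boot_ic50, na.rm = TRUE)
    obj$ic50_abs_sd_boot <- stats::sd(boot_abs, na.rm = TRUE)
  }
  obj
}

# bounded LM fit on the raw nls.lm optimizer (robust to a zero-residual
# perfect fit, unlike the nls wrapper); returns NULL on failure.
# means = named per-dose means, used only for the deterministic initializer.
fit_4pl_engine <- function(dose, viability, means) {
  mean_doses <- as.numeric(names(means))
  top0 <- max(means); bottom0 <- min(means)
  mid <- (top0 + bottom0) / 2
  pos <- mean_doses[mean_doses > 0]
  ic50_0 <- if (length(pos))
    pos[which.min(abs(means[as.character(pos)] - mid))] else 1
  dmax <- max(dose)
  dmin_pos <- min(dose[dose > 0])
  resid_fun <- function(p)
    viability - fourpl(dose, p[["top"]], p[["bottom"]], p[["ic50"]],
                       p[["hill"]])
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(top = top0, bottom = min(bottom0, top0 - 1), ic50 = ic50_0,
              hill = 1),
      lower = c(top = 0, bottom = 0, ic50 = dmin_pos / 1e3, hill = 0.1),
      upper = c(top = 120, bottom = 120, ic50 = dmax * 1e3, hill = 10),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4 || !is.finite(fit$deviance))
    return(NULL)
  fit
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (x$no_inhibition) {
    cat("  NO INHIBITION:", x$diagnostics, "\n")
    return(invisible(x))
  }
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  co <- x$coefficients
  cat(sprintf("  top    = %.*g %%\n", digits, co[["top"]]))
  cat(sprintf("  bottom = %.*g %%\n", digits, co[["bottom"]]))
  cat(sprintf("  IC50 (curve midpoint) = %.*g", digits, co[["ic50"]]))
  if (!is.na(x$ic50_sd_boot))
    cat(sprintf(" +/- %.*g (bootstrap SD)", 2, x$ic50_sd_boot))
  cat(" µM\n")
  cat(sprintf("  IC50 (50%% viability) = %.*g", digits, x$ic50_abs))
  if (!is.na(x$ic50_abs_sd_boot))
    cat(sprintf(" +/- %.*g (bootstrap SD)", 2, x$ic50_abs_sd_boot))
  cat(" µM\n")
  cat(sprintf("  hill   = %.*g\n", digits, co[["hill"]]))
  if (isFALSE(x$ic50_in_range))
    cat("  warning: IC50 outside the tested dose range\n")
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
vcov.fourpl <- function(object, ...) object$vcov

#' @export
fitted.fourpl <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, nrow(object$data)))
  co <- object$coefficients
  fourpl(object$data$dose, co[["top"]], co[["bottom"]], co[["ic50"]],
         co[["hill"]])
}

#' @export
residuals.fourpl <- function(object, ...)
  object$data$viability - fitted(object)

#' Predict viability at new doses from a 4PL fit
#' @param object a \code{fourpl} fit.
#' @param newdata data.frame with a \code{dose} column (default: the fitted
#'   doses).
#' @param ... unused.
#' @return Predicted percent viability.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  co <- object$coefficients
  fourpl(dose, co[["top"]], co[["bottom"]], co[["ic50"]], co[["hill"]])
}

#' @export
summary.fourpl <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(fit = object, coefficients = tab,
                 sigma = object$sigma, df = object$df.residual),
            class = "summary.fourpl")
}

#' @export
print.summary.fourpl <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    cat("\nParameters:\n")
    stats::printCoefmat(x$coefficients)
    cat(sprintf("\nResidual SD: %.3f on %d degrees of freedom\n",
                x$sigma, x$df))
  }
  invisible(x)
}

#' @export
confint.fourpl <- function(object, parm, level = 0.95, ...) {
  if (!object$converged) stop("no confidence intervals for a non-converged fit")
  co <- object$coefficients
  if (missing(parm)) parm <- names(co)
  z <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  out <- cbind(co[parm] - z * object$se[parm], co[parm] + z * object$se[parm])
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' Simulate viability datasets from a 4PL fit
#'
#' Draws Gaussian replicates around the fitted curve using the residual SD,
#' at the fitted design's doses.
#'
#' @param object a converged \code{fourpl} fit.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed (optional).
#' @param ... unused.
#' @return data.frame of \code{nsim} simulated viability columns plus
#'   \code{dose}.
#' @export
simulate.fourpl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(dose = object$data$dose), out)
}

#' Plot a 4PL dose-response fit
#'
#' Dose-mean viability with SD bars and the fitted curve on a log-dose axis;
#' dose 0 is displayed at a pseudo-log position half a dilution step below
#' the smallest positive dose.
#'
#' @param x a \code{fourpl} fit.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.fourpl <- function(x, ...) {
  dm <- x$dose_means
  pos <- sort(unique(dm$dose[dm$dose > 0]))
  zero_at <- if (length(pos) >= 2L) pos[1L]^2 / pos[2L] else pos[1L] / 4
  px <- ifelse(dm$dose == 0, zero_at, dm$dose)
  graphics::plot(px, dm$mean, log = "x", xlab = "dose (µM, log scale)",
                 ylab = "viability (%)",
                 ylim = range(c(dm$mean - dm$sd, dm$mean + dm$sd, 0, 100),
                              na.rm = TRUE), pch = 19, ...)
  graphics::arrows(px, dm$mean - dm$sd, px, dm$mean + dm$sd,
                   angle = 90, code = 3, length = 0.03)
  if (x$converged) {
    grid <- exp(seq(log(zero_at), log(max(dm$dose)), length.out = 200))
    co <- x$coefficients
    graphics::lines(grid, fourpl(grid, co[["top"]], co[["bottom"]],
                                 co[["ic50"]], co[["hill"]]))
  }
  invisible(x)
}
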