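# Numerical reduction of the free-radical hemolysis (KRL) assay: T50
# extraction, percent change versus control, Trolox-equivalent expression.

as_hemolysis <- function(x) {
  if (inherits(x, "hemolysis_curve")) return(x)
  if (is.data.frame(x) && all(c("time_min", "hemolysis_pct") %in% names(x)))
    return(structure(list(time_min = x$time_min,
                          hemolysis_pct = x$hemolysis_pct,
                          label = "sample"),
                     class = "hemolysis_curve"))
  stop("expected a hemolysis_curve or a data.frame(time_min, hemolysis_pct)")
}

median3 <- function(y) {
  if (length(y) < 3) return(y)
  out <- y
  for (i in 2:(length(y) - 1)) out[i] <- stats::median(y[(i - 1):(i + 1)])
  out
}

#' Time to 50% hemolysis
#'
#' Linear interpolation between the two samples bracketing the first upward
#' crossing of 50% hemolysis. If noise produces multiple crossings, the
#' curve is smoothed with a 3-point median filter, the first crossing of
#' the smoothed curve is used, and the result is flagged.
#'
#' @param curve a `hemolysis_curve` or
#'   `data.frame(time_min, hemolysis_pct)`.
#' @param level crossing level in percent (default 50).
#' @return A list of class `t50_result`: `t50_min` and `flag` (`NA` or
#'   `"multiple crossings; smoothed"`).
#' @export
t50_hemolysis <- function(curve, level = 50) {
  h <- as_hemolysis(curve)
  t <- h$time_min; y <- h$hemolysis_pct
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  crossings <- function(y) which(y[-length(y)] < level & y[-1] >= level)
  up <- crossings(y)
  flag <- NA_character_
  if (!length(up)) {
    if (y[1] >= level)
      stop("curve starts at or above ", level, "%: no upward crossing")
    stop("curve never reaches ", level, "% hemolysis (max ",
         round(max(y), 2), "%)")
  }
  if (length(up) > 1) {
    y <- median3(y)
    up2 <- crossings(y)
    if (length(up2)) up <- up2
    flag <- "multiple crossings; smoothed"
  }
  i <- up[1]
  t50 <- t[i] + (level - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
  structure(list(t50_min = t50, flag = flag), class = "t50_result")
}

#' Percent change in T50 relative to a control
#'
#' Positive values mean the sample delayed hemolysis (antioxidant effect);
#' negative values mean it accelerated it (prooxidant effect).
#'
#' @param sample_t50 sample T50 (min).
#' @param control_t50 control T50 (min), > 0.
#' @return Percent change, `100 (sample - control) / control`.
#' @export
percent_change_t50 <- function(sample_t50, control_t50) {
  if (control_t50 <= 0) stop("control T50 must be > 0")
  100 * (sample_t50 - control_t50) / control_t50
}

#' Express an antioxidant effect in Trolox equivalents
#'
#' Inverts a Trolox calibration (delta-T50 as a function of Trolox mass) at
#' the sample's T50 delay by linear interpolation, then divides by the mass
#' of nano-emulsion tested.
#'
#' @param delta_t50_min sample T50 delay over control (min).
#' @param calibration `data.frame(trolox_mg, delta_t50_min)`, strictly
#'   monotone increasing in both columns (a blank point at the origin is
#'   customary).
#' @param ne_mass_g grams of nano-emulsion tested, > 0.
#' @return Trolox equivalent in mg per g of nano-emulsion.
#' @export
trolox_equivalent <- function(delta_t50_min, calibration, ne_mass_g) {
  stopifnot(is.data.frame(calibration),
            all(c("trolox_mg", "delta_t50_min") %in% names(calibration)),
            ne_mass_g > 0)
  cal <- calibration[order(calibration$trolox_mg), ]
  if (any(diff(cal$delta_t50_min) <= 0) || any(diff(cal$trolox_mg) <= 0))
    stop("calibration must be strictly monotone increasing")
  rng <- range(cal$delta_t50_min)
  if (delta_t50_min < rng[1] || delta_t50_min > rng[2])
    stop(sprintf("delta T50 %.3g min outside calibration range [%.3g, %.3g]",
                 delta_t50_min, rng[1], rng[2]))
  mg <- stats::approx(cal$delta_t50_min, cal$trolox_mg,
                      xout = delta_t50_min)$y
  mg / ne_mass_g
}

#' Full antioxidant summary of a sample against its control
#'
#' @param sample a sample hemolysis curve.
#' @param control the control (no nano-emulsion) curve from the same run.
#' @param trolox_calibration optional `data.frame(trolox_mg,
#'   delta_t50_min)`; Trolox equivalents are reported only when supplied.
#' @param ne_mass_g grams of nano-emulsion tested.
#' @return An object of class `antioxidant_result`: `t50_min`,
#'   `control_t50_min`, `percent_change`, `trolox_mg_per_g` (NA without a
#'   calibration), `flags`.
#' @export
antioxidant_summary <- function(sample, control, trolox_calibration = NULL,
                                ne_mass_g = 1) {
  ts <- t50_hemolysis(sample)
  tc <- t50_hemolysis(control)
  pc <- percent_change_t50(ts$t50_min, tc$t50_min)
  te <- NA_real_
  if (!is.null(trolox_calibration))
    te <- trolox_equivalent(ts$t50_min - tc$t50_min, trolox_calibration,
                            ne_mass_g)
  flags <- c(ts$flag, tc$flag)
  structure(list(t50_min = ts$t50_min, control_t50_min = tc$t50_min,
                 percent_change = pc, trolox_mg_per_g = te,
                 flags = flags[!is.na(flags)]),
            class = "antioxidant_result")
}

#' @export
print.antioxidant_result <- function(x, ...) {
  cat(sprintf("T50 = %.2f min (control %.2f min): %+.2f%%\n",
              x$t50_min, x$control_t50_min, x$percent_change))
  if (!is.na(x$trolox_mg_per_g))
    cat(sprintf("Trolox equivalent: %.2f mg per g of NE\n", x$trolox_mg_per_g))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
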