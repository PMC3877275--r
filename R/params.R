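#' Bioenergetics parameter set for juvenile walleye pollock
#'
#' Builds the parameter list governing consumption, respiration and waste in
#' the Wisconsin-type bioenergetics model. Defaults are the juvenile pollock
#' parameterization used throughout the package: an allometric maximum
#' consumption (`alpha_c`, `beta_c`) with a dome-shaped temperature scaling
#' (`q_c`, optimum `t_co`, maximum `t_cm`), allometric respiration (`a_r`,
#' `b_r`) with its own temperature dome (`q_r`, `t_ro`, `t_rm`), fixed
#' proportional losses to egestion (`f_a`, proportion of consumed energy),
#' excretion (`u_a`) and specific dynamic action (`d_s`) (both proportions of
#' assimilated energy), an active-metabolism multiplier (`a_m`) and the
#' oxycalorific coefficient (`o2cal`, J per g O2) converting respired oxygen
#' to energy.
#'
#' @param alpha_c Intercept of the allometric function for consumption
#'   (g prey per g fish per day at 1 g and optimal temperature).
#' @param beta_c Slope (exponent) of the allometric consumption function;
#'   negative, so per-gram consumption declines with fish weight.
#' @param q_c,t_co,t_cm Temperature-dependence coefficient, optimum (deg C)
#'   and maximum (deg C) temperature for consumption.
#' @param a_r,b_r Intercept and slope of the allometric respiration function
#'   (g O2 per g per day).
#' @param q_r,t_ro,t_rm Temperature-dependence coefficient, optimum and
#'   maximum temperature (deg C) for respiration.
#' @param d_s Proportion of assimilated energy lost to specific dynamic
#'   action.
#' @param a_m Multiplier for active metabolism.
#' @param f_a Proportion of consumed energy lost to egestion.
#' @param u_a Proportion of assimilated energy lost to excretion.
#' @param o2cal Oxycalorific coefficient, J per g O2.
#'
#' @return An object of class `bioen_params` (a named list).
#' @examples
#' p <- bioen_params()
#' p$t_cm  # 15 deg C: no consumption at or above this temperature
#' @export
bioen_params <- function(alpha_c = 0.119, beta_c = -0.46,
                         q_c = 2.6, t_co = 10, t_cm = 15,
                         a_r = 0.0075, b_r = -0.251,
                         q_r = 2.6, t_ro = 13, t_rm = 18,
                         d_s = 0.125, a_m = 2,
                         f_a = 0.15, u_a = 0.11,
                         o2cal = 13560) {
  p <- list(alpha_c = alpha_c, beta_c = beta_c,
            q_c = q_c, t_co = t_co, t_cm = t_cm,
            a_r = a_r, b_r = b_r,
            q_r = q_r, t_ro = t_ro, t_rm = t_rm,
            d_s = d_s, a_m = a_m, f_a = f_a, u_a = u_a,
            o2cal = o2cal)
  for (nm in names(p)) stopifnot_scalar_number(p[[nm]], nm)
  if (p$t_co >= p$t_cm) stop("t_co must be < t_cm", call. = FALSE)
  if (p$t_ro >= p$t_rm) stop("t_ro must be < t_rm", call. = FALSE)
  for (nm in c("d_s", "f_a", "u_a")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (p$f_a + 0 > 1) stop("f_a must be <= 1", call. = FALSE)
  if (p$u_a + p$d_s > 1) {
    stop("u_a + d_s must be <= 1 (proportions of assimilated energy)",
         call. = FALSE)
  }
  structure(p, class = "bioen_params")
}

#' @export
print.bioen_params <- function(x, ...) {
  cat("Wisconsin bioenergetics parameters (juvenile pollock)\n")
  cat(sprintf("  Cmax: alpha=%g W^%g, f(T): Q=%g, Topt=%g, Tmax=%g degC\n",
              x$alpha_c, x$beta_c, x$q_c, x$t_co, x$t_cm))
  cat(sprintf("  R:    %g*%g W^%g, f(T): Q=%g, Topt=%g, Tmax=%g degC\n",
              x$a_m, x$a_r, x$b_r, x$q_r, x$t_ro, x$t_rm))
  cat(sprintf("  waste: egestion %g of C; excretion %g, SDA %g of (C - F)\n",
              x$f_a, x$u_a, x$d_s))
  cat(sprintf("  oxycalorific coefficient: %g J/g O2\n", x$o2cal))
  invisible(x)
}
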