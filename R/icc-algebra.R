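#' Variance components of a generating mechanism
#'
#' Bundles the five variance parameters of the repeated measures ANOVA (RM)
#' or random coefficients (RC) generating mechanism for a multiple-period
#' parallel group-randomized trial, together with the mechanism and the data
#' structure (cross-sectional or cohort).
#'
#' Under the RM mechanism \code{sigma2_tg} is the variance of the
#' time-by-group random intercepts and \code{sigma2_tm} the variance of the
#' time-by-member random intercepts; with one observation per member per
#' occasion the latter is indistinguishable from residual error and must be
#' zero.  Under the RC mechanism the same two slots hold the group-level and
#' member-level random \emph{slope} variances (per unit time squared).
#'
#' @param sigma2_g group-level random intercept variance (outcome units^2).
#' @param sigma2_tg time-by-group variance (RM) or group slope variance (RC).
#' @param sigma2_m member-level random intercept variance; must be 0 for
#'   cross-sectional data.
#' @param sigma2_tm time-by-member variance (RM; must be 0, see Details) or
#'   member slope variance (RC).
#' @param sigma2_e residual error variance.
#' @param mechanism \code{"RM"} or \code{"RC"}.
#' @param structure \code{"cross-sectional"} or \code{"cohort"}.
#'
#' @return An object of class \code{"variance_components"}: a named list of
#'   the five variances plus \code{mechanism} and \code{structure}.
#' @examples
#' vc <- variance_components(1, 1, sigma2_e = 18,
#'                           mechanism = "RM", structure = "cross-sectional")
#' wpicc(vc)  # 0.10
#' @export
variance_components <- function(sigma2_g, sigma2_tg, sigma2_m = 0,
                                sigma2_tm = 0, sigma2_e,
                                mechanism = c("RM", "RC"),
                                structure = c("cross-sectional", "cohort")) {
  mechanism <- match.arg(mechanism)
  structure <- match.arg(structure)
  v <- c(sigma2_g = sigma2_g, sigma2_tg = sigma2_tg, sigma2_m = sigma2_m,
         sigma2_tm = sigma2_tm, sigma2_e = sigma2_e)
  if (!all(is.finite(v)))
    stop("all variance components must be finite numbers", call. = FALSE)
  if (any(v < 0))
    stop("generating variance components must be nonnegative; got ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  if (structure == "cross-sectional" && (sigma2_m != 0 || sigma2_tm != 0))
    stop("cross-sectional structure requires sigma2_m = sigma2_tm = 0",
         call. = FALSE)
  if (mechanism == "RM" && sigma2_tm != 0)
    stop("with one observation per member per occasion the RM time-by-member ",
         "variance cannot be distinguished from residual error; set ",
         "sigma2_tm = 0", call. = FALSE)
  structure(
    list(sigma2_g = sigma2_g, sigma2_tg = sigma2_tg, sigma2_m = sigma2_m,
         sigma2_tm = sigma2_tm, sigma2_e = sigma2_e,
         mechanism = mechanism, structure = structure),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$mechanism, ", ", x$structure, ")\n", sep = "")
  lab <- if (x$mechanism == "RM")
    c("group", "time x group", "member", "time x member", "residual")
  else
    c("group intercept", "group slope", "member intercept", "member slope",
      "residual")
  v <- unlist(x[1:5])
  for (i in seq_along(v))
    cat(sprintf("  %-16s %g\n", lab[i], v[i]))
  s <- correlation_summary(x)
  cat(sprintf("  WPICC %.6g  BPICC %.6g  CAC %.6g", s$wpicc, s$bpicc, s$cac))
  if (!is.na(s$iac)) cat(sprintf("  IAC %.6g", s$iac))
  cat("\n")
  invisible(x)
}

total_variance <- function(vc) {
  vc$sigma2_g + vc$sigma2_tg + vc$sigma2_m + vc$sigma2_tm + vc$sigma2_e
}

check_nonneg <- function(vc) {
  v <- unlist(vc[c("sigma2_g", "sigma2_tg", "sigma2_m", "sigma2_tm",
                   "sigma2_e")])
  if (any(v < 0))
    warning("negative variance component(s) passed through the correlation ",
            "formulas unchanged", call. = FALSE)
}

#' Within-period intracluster correlation
#'
#' WPICC implied by a set of variance components under the repeated measures
#' ANOVA definitions: the correlation between outcomes of two different
#' members of the same group in the same period,
#' \deqn{(\sigma^2_g + \sigma^2_{tg}) /
#'       (\sigma^2_g + \sigma^2_{tg} + \sigma^2_m + \sigma^2_{tm} +
#'        \sigma^2_e).}
#' For cross-sectional data the member terms are zero.  For RC-mechanism
#' components the same definitional mapping is applied (group slope variance
#' in place of the time-by-group variance); the actual time-varying
#' correlation of RC data is not summarized here.
#'
#' @param vc a \code{\link{variance_components}} object.
#' @return The WPICC, a dimensionless value in \[0, 1\] for nonnegative
#'   components.
#' @examples
#' wpicc(variance_components(1, 1, sigma2_e = 18))  # 0.10
#' @export
wpicc <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  tot <- total_variance(vc)
  if (tot <= 0 && !any(unlist(vc[1:5]) < 0))
    stop("WPICC undefined: total variance is zero", call. = FALSE)
  check_nonneg(vc)
  (vc$sigma2_g + vc$sigma2_tg) / tot
}

#' Between-period intracluster correlation
#'
#' BPICC implied by a set of variance components: the correlation between
#' outcomes of two different members of the same group in two different
#' periods, \eqn{\sigma^2_g / \mathrm{total\ variance}}.  Constant over time
#' under the RM mechanism (the RC between-period correlation varies with
#' time and is out of scope).
#'
#' @inheritParams wpicc
#' @return The BPICC, dimensionless.
#' @export
bpicc <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  tot <- total_variance(vc)
  if (tot <= 0 && !any(unlist(vc[1:5]) < 0))
    stop("BPICC undefined: total variance is zero", call. = FALSE)
  check_nonneg(vc)
  vc$sigma2_g / tot
}

#' Cluster autocorrelation
#'
#' Correlation between a group's population means at two different periods:
#' \eqn{CAC = \sigma^2_g / (\sigma^2_g + \sigma^2_{tg})}, equivalently the
#' ratio BPICC / WPICC.
#'
#' @param x either a \code{\link{variance_components}} object or the group
#'   variance \eqn{\sigma^2_g} as a number.
#' @param sigma2_tg the time-by-group (or group slope) variance, required
#'   when \code{x} is numeric.
#' @return The CAC, dimensionless.
#' @examples
#' cac(1, 1)     # 0.50
#' cac(1, 0.10)  # 0.909..., reported as 0.91
#' @export
cac <- function(x, sigma2_tg = NULL) {
  if (inherits(x, "variance_components")) {
    sigma2_g <- x$sigma2_g
    sigma2_tg <- x$sigma2_tg
  } else {
    sigma2_g <- x
    if (is.null(sigma2_tg))
      stop("supply sigma2_tg when the first argument is numeric",
           call. = FALSE)
  }
  den <- sigma2_g + sigma2_tg
  if (den == 0)
    stop("CAC undefined: sigma2_g + sigma2_tg is zero", call. = FALSE)
  if (sigma2_g < 0 || sigma2_tg < 0)
    warning("negative variance component(s) passed through the correlation ",
            "formulas unchanged", call. = FALSE)
  sigma2_g / den
}

#' Individual autocorrelation
#'
#' Correlation between the outcomes of the same member at two different
#' periods, \eqn{IAC = \sigma^2_m / (\sigma^2_m + \sigma^2_{tm} +
#' \sigma^2_e)}.  Defined only for cohort data (cross-sectional designs
#' measure each member once).
#'
#' @param x either a \code{\link{variance_components}} object (must be
#'   cohort) or the member variance \eqn{\sigma^2_m} as a number.
#' @param sigma2_tm,sigma2_e remaining variances when \code{x} is numeric.
#' @return The IAC, dimensionless.
#' @examples
#' iac(12.6, 0, 5.4)    # 0.70
#' iac(12.6, 1, 4.4)    # 0.70
#' @export
iac <- function(x, sigma2_tm = NULL, sigma2_e = NULL) {
  if (inherits(x, "variance_components")) {
    if (x$structure != "cohort")
      stop("IAC is not defined for cross-sectional data", call. = FALSE)
    sigma2_m <- x$sigma2_m
    sigma2_tm <- x$sigma2_tm
    sigma2_e <- x$sigma2_e
  } else {
    sigma2_m <- x
    if (is.null(sigma2_tm) || is.null(sigma2_e))
      stop("supply sigma2_tm and sigma2_e when the first argument is numeric",
           call. = FALSE)
  }
  den <- sigma2_m + sigma2_tm + sigma2_e
  if (den == 0)
    stop("IAC undefined: sigma2_m + sigma2_tm + sigma2_e is zero",
         call. = FALSE)
  if (sigma2_m < 0 || sigma2_tm < 0 || sigma2_e < 0)
    warning("negative variance component(s) passed through the correlation ",
            "formulas unchanged", call. = FALSE)
  sigma2_m / den
}

#' All four correlation summaries at once
#'
#' @inheritParams wpicc
#' @return A list with \code{wpicc}, \code{bpicc}, \code{cac} and \code{iac}
#'   (\code{NA} for cross-sectional data, where the IAC is undefined).
#' @export
correlation_summary <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  list(wpicc = wpicc(vc), bpicc = bpicc(vc), cac = cac(vc),
       iac = if (vc$structure == "cohort") iac(vc) else NA_real_)
}

#' Solve variance components from correlation targets
#'
#' Inverts the WPICC / CAC / IAC formulas: given target correlations and the
#' anchored group-level variances, returns the member-level and residual
#' variances that reproduce the targets exactly.  This is the inverse
#' problem used to build a simulation grid from nominal ICCs: with anchors
#' \eqn{\sigma^2_g = \sigma^2_{tg} = 1}, a WPICC of 0.10 / 0.01 / 0.001
#' yields cross-sectional residual variances 18 / 198 / 1998, and with an
#' IAC of 0.70 the cohort RM solution at WPICC 0.10 is
#' \eqn{(\sigma^2_m, \sigma^2_e) = (12.6, 5.4)}.
#'
#' Cross-sectionally only \eqn{\sigma^2_e} is solved.  For cohort data
#' \eqn{(\sigma^2_m, \sigma^2_e)} are solved from the IAC with
#' \eqn{\sigma^2_{tm}} held fixed (0 under RM; the member slope variance
#' under RC, by default equal to the group slope anchor).
#'
#' @param target_wpicc target within-period ICC, in (0, 1).
#' @param target_iac target individual autocorrelation (cohort only).
#' @param target_cac optional consistency check: must equal
#'   \code{cac(sigma2_g, sigma2_tg)} implied by the anchors.
#' @param sigma2_g,sigma2_tg anchored group-level variances.
#' @param sigma2_tm fixed time-by-member / member slope variance.
#' @param mechanism,structure as in \code{\link{variance_components}}.
#' @return A \code{\link{variance_components}} object whose summaries
#'   reproduce the targets to within 1e-12 relative error.
#' @examples
#' solve_components(0.10, target_iac = 0.70, structure = "cohort")
#' @export
solve_components <- function(target_wpicc, target_iac = NULL,
                             target_cac = NULL,
                             sigma2_g = 1, sigma2_tg = 1,
                             sigma2_tm = NULL,
                             mechanism = c("RM", "RC"),
                             structure = c("cross-sectional", "cohort")) {
  mechanism <- match.arg(mechanism)
  structure <- match.arg(structure)
  if (!is.finite(target_wpicc) || target_wpicc <= 0 || target_wpicc > 1)
    stop("infeasible target: WPICC must lie in (0, 1]", call. = FALSE)
  gsum <- sigma2_g + sigma2_tg
  if (gsum <= 0)
    stop("anchors must satisfy sigma2_g + sigma2_tg > 0", call. = FALSE)
  if (!is.null(target_cac)) {
    implied <- sigma2_g / gsum
    if (abs(implied - target_cac) > 1e-12 * max(1, abs(target_cac)))
      stop(sprintf(paste0("infeasible target: CAC is fixed by the anchors ",
                          "(implied %.12g, requested %.12g); change ",
                          "sigma2_g/sigma2_tg"), implied, target_cac),
           call. = FALSE)
  }
  if (is.null(sigma2_tm))
    sigma2_tm <- if (mechanism == "RC" && structure == "cohort") sigma2_tg else 0
  # member + time-by-member + residual variance implied by the WPICC target
  q <- gsum * (1 - target_wpicc) / target_wpicc
  if (structure == "cross-sectional") {
    if (!is.null(target_iac))
      stop("IAC target is not applicable to cross-sectional data",
           call. = FALSE)
    return(variance_components(sigma2_g, sigma2_tg, 0, 0, sigma2_e = q,
                               mechanism = mechanism, structure = structure))
  }
  if (is.null(target_iac))
    stop("cohort structure requires a target IAC", call. = FALSE)
  if (target_iac < 0 || target_iac >= 1)
    stop("infeasible target: IAC must lie in [0, 1)", call. = FALSE)
  sigma2_m <- target_iac * q
  sigma2_e <- q - sigma2_m - sigma2_tm
  if (sigma2_e < 0)
    stop(sprintf(paste0("infeasible target: WPICC %.4g and IAC %.4g leave ",
                        "residual variance %.4g < 0 with sigma2_tm = %.4g; ",
                        "lower the IAC or the fixed sigma2_tm"),
                 target_wpicc, target_iac, sigma2_e, sigma2_tm),
         call. = FALSE)
  variance_components(sigma2_g, sigma2_tg, sigma2_m, sigma2_tm, sigma2_e,
                      mechanism = mechanism, structure = structure)
}
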