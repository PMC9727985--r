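#' Analytic model names
#'
#' The four analytic model families applied to multiple-period parallel GRT
#' data, each available with or without the time-varying group random
#' effect ("time x group" vs "intercept only" variants):
#' \describe{
#'   \item{rm_vc}{categorical time; group and time-by-group random
#'     intercepts with a variance components (VC) G matrix; cohort data add
#'     a compound symmetric (CS) R matrix at the member level.}
#'   \item{rm_un}{categorical time; cross-sectional data use an
#'     unstructured (UN) G matrix over the time-varying group effects
#'     (absorbing the time-invariant group variance) and are fitted on the
#'     group means; cohort data use a VC G matrix plus a UN R matrix at the
#'     member level.}
#'   \item{rc}{linear time; random group intercept and slope with a UN(2)
#'     covariance; cohort data add a member intercept and slope UN(2)
#'     block.}
#'   \item{saturated}{categorical time; only time-varying random effects,
#'     with a UN G matrix over the five periods; cross-sectional R is
#'     diagonal-unstructured UN(1), cohort R is UN; fitted on the group
#'     means.  Has no intercept-only variant.}
#' }
#'
#' @param family one of \code{"rm_vc"}, \code{"rm_un"}, \code{"rc"},
#'   \code{"saturated"}.
#' @param timexgroup logical; \code{FALSE} selects the "intercept only"
#'   variant that omits the time-varying group random effect.  Invalid for
#'   the saturated model, which contains only time-varying random effects.
#' @param structure \code{"cross-sectional"} or \code{"cohort"}.
#' @return An object of class \code{"analytic_model"}.
#' @export
analytic_model <- function(family = c("rm_vc", "rm_un", "rc", "saturated"),
                           timexgroup = TRUE,
                           structure = c("cross-sectional", "cohort")) {
  family <- match.arg(family)
  structure <- match.arg(structure)
  if (family == "saturated" && !timexgroup)
    stop("the saturated model contains only time x group random effects; ",
         "an intercept-only variant does not exist", call. = FALSE)
  base::structure(list(family = family, timexgroup = timexgroup,
                       structure = structure),
                  class = "analytic_model")
}

#' Build the full model specification for an analytic model name
#'
#' Expands an \code{\link{analytic_model}} name into the complete
#' specification fitted by \code{\link{reml_fit}}: time coding, random
#' effect levels, G and R covariance structure kinds, fitting level
#' (individual observations or group means) and degrees-of-freedom method.
#' \code{make_spec} is pure: the same name always yields the identical
#' specification.
#'
#' Cross-sectional \code{rm_un} (time x group) and both saturated variants
#' are fitted on the group-period means by default, which yields the same
#' interaction F-test p-values as the individual-level fit on balanced data
#' at a fraction of the cost; set \code{fitting_level = "individual"} to
#' force the individual-level formulation.
#'
#' @param model an \code{\link{analytic_model}}, or a family string passed
#'   on to \code{analytic_model()}.
#' @param df_method \code{"KR"} (Kenward-Roger, default) or \code{"BW"}
#'   (between-within).
#' @param fitting_level optional override of the default fitting level.
#' @param ... passed to \code{\link{analytic_model}} when \code{model} is a
#'   string.
#' @return An object of class \code{"model_spec"}.
#' @examples
#' make_spec("rc", structure = "cohort")
#' @export
make_spec <- function(model, df_method = c("KR", "BW"),
                      fitting_level = NULL, ...) {
  if (is.character(model)) model <- analytic_model(model, ...)
  stopifnot(inherits(model, "analytic_model"))
  df_method <- match.arg(df_method)
  fam <- model$family
  cross <- model$structure == "cross-sectional"
  txg <- model$timexgroup
  time_coding <- if (fam == "rc") "linear" else "categorical"
  default_level <- if ((fam == "rm_un" && cross && txg) || fam == "saturated")
    "group_mean" else "individual"
  level <- if (is.null(fitting_level)) default_level
  else match.arg(fitting_level, c("individual", "group_mean"))
  g_structure <- switch(fam,
    rm_vc = "VC",
    rm_un = if (cross) (if (txg) "UN" else "VC") else "VC",
    rc = if (txg) "UN" else "VC",
    saturated = "UN")
  r_structure <- switch(fam,
    rm_vc = if (cross) "VC" else "CS",
    rm_un = if (cross) "VC" else "UN",
    rc = "VC",
    saturated = if (cross) "UN1" else "UN")
  random_levels <- c(
    if (fam != "saturated") "group_intercept",
    if (txg) "time_by_group",
    if (!cross && fam == "rc") c("member_intercept", "time_by_member"),
    if (!cross && fam != "rc") "member_intercept")
  base::structure(
    list(family = fam, timexgroup = txg, structure = model$structure,
         time_coding = time_coding, random_levels = random_levels,
         g_structure = g_structure, r_structure = r_structure,
         fitting_level = level, df_method = df_method, unbounded = TRUE),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "Analytic model: %s (%s), %s\n  time coding %s, G %s, R %s, fit at %s level, %s df\n",
    model_label(x$family), if (x$timexgroup) "time x group" else "intercept only",
    x$structure, x$time_coding, x$g_structure,
    if (is.null(x$r_structure)) "-" else x$r_structure,
    sub("_", " ", x$fitting_level), x$df_method))
  invisible(x)
}

model_label <- function(family) {
  switch(family, rm_vc = "RM-ANOVA with VC", rm_un = "RM-ANOVA with UN",
         rc = "RC", saturated = "Saturated", residual_only = "Residual only")
}

#' Number of free covariance parameters of a model specification
#'
#' Counts the covariance parameters of the individual-level formulation of
#' an analytic model at a given number of periods.  For models fitted on
#' group means by default, the group-mean formulation count is attached as
#' attribute \code{"mean_model"} (the within- and between-period
#' variance-covariance parameters collapse to one free symmetric matrix for
#' the period means).
#'
#' @param spec a \code{\link{model_spec}} (or \code{\link{analytic_model}}).
#' @param n_periods number of periods; the canonical five-period design by
#'   default.
#' @return Integer count, possibly with a \code{"mean_model"} attribute.
#' @examples
#' count_cov_params(make_spec("saturated", structure = "cohort"))  # 30 (15)
#' @export
count_cov_params <- function(spec, n_periods = 5) {
  if (inherits(spec, "analytic_model")) spec <- make_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  tv <- seq_len(n_periods) - 1
  ind <- length(model_bases(spec, n_periods, tv, level = "individual"))
  out <- as.integer(ind)
  if (spec$fitting_level == "group_mean" ||
      ((spec$family %in% c("rm_un", "saturated")) &&
       spec$structure == "cross-sectional" && spec$timexgroup) ||
      spec$family == "saturated") {
    mm <- length(model_bases(spec, n_periods, tv, level = "group_mean"))
    attr(out, "mean_model") <- as.integer(mm)
  }
  out
}

#' List the analytic model registry
#'
#' @param n_periods periods used for the parameter counts.
#' @return A data frame with one row per (family, variant, structure):
#'   G/R structures, fitting level and covariance parameter counts
#'   (individual level, with the group-mean count in parentheses in the
#'   \code{label} column where that formulation is the default).
#' @export
list_models <- function(n_periods = 5) {
  rows <- list()
  for (structure in c("cross-sectional", "cohort"))
    for (family in c("rm_vc", "rm_un", "rc", "saturated"))
      for (txg in c(TRUE, FALSE)) {
        if (family == "saturated" && !txg) next
        spec <- make_spec(family, timexgroup = txg, structure = structure)
        np <- count_cov_params(spec, n_periods)
        mm <- attr(np, "mean_model")
        rows[[length(rows) + 1]] <- data.frame(
          family = family, model = model_label(family),
          timexgroup = txg, structure = structure,
          g_matrix = spec$g_structure,
          r_matrix = if (is.null(spec$r_structure)) "-" else spec$r_structure,
          fitting_level = spec$fitting_level,
          n_cov_params = as.integer(np),
          n_cov_params_mean = if (is.null(mm)) NA_integer_ else mm,
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

# ---- covariance basis construction ---------------------------------------
#
# Every analytic model's marginal covariance for one group block of m
# members x t periods has the form  J_m (x) A  +  I_m (x) B  with t x t
# matrices A (group-level random effects, shared by all members) and B
# (member-level random effects and residual error), and is *linear* in its
# covariance parameters.  A basis is a list of (A_k, B_k) pairs, one per
# free parameter.  NULL slots mean a zero matrix.

sym_basis <- function(t) {
  # t(t+1)/2 symmetric elementwise basis matrices E_jj and (E_jj'+E_j'j)
  out <- list()
  for (j in seq_len(t))
    for (k in j:t) {
      M <- matrix(0, t, t)
      M[j, k] <- M[k, j] <- 1
      out[[length(out) + 1]] <- list(M = M, name = sprintf("un_%d_%d", j, k))
    }
  out
}

rc_bases <- function(t, tv) {
  # intercept, intercept-slope covariance, slope: UN(2) on (1, t_j)
  one <- matrix(1, t, t)
  ot <- outer(rep(1, t), tv)
  list(var_int = one, cov_int_slope = ot + t(ot), var_slope = outer(tv, tv))
}

# Returns a named list of list(A = , B = ) basis pairs for the model at the
# requested fitting level.
model_bases <- function(spec, t, tv, level = spec$fitting_level) {
  J <- matrix(1, t, t)
  I <- diag(t)
  add <- function(lst, name, A = NULL, B = NULL) {
    lst[[name]] <- list(A = A, B = B)
    lst
  }
  b <- list()
  if (length(spec$random_levels) == 0 && level == "individual")
    return(add(b, "sigma2_e", B = I))
  if (level == "group_mean") {
    # period means of one group: one free symmetric t x t covariance (the
    # group-level UN matrix and the member/residual terms are aliased)
    for (e in sym_basis(t)) b <- add(b, e$name, B = e$M)
    return(b)
  }
  fam <- spec$family
  cross <- spec$structure == "cross-sectional"
  txg <- spec$timexgroup
  if (fam == "rm_vc") {
    b <- add(b, "sigma2_g", A = J)
    if (txg) b <- add(b, "sigma2_tg", A = I)
    if (!cross) b <- add(b, "cs_cov", B = J)
    b <- add(b, "sigma2_e", B = I)
  } else if (fam == "rm_un") {
    if (cross) {
      if (txg) {
        # UN over the five time-varying group effects; the time-invariant
        # group variance is aliased into this matrix
        for (e in sym_basis(t)) b <- add(b, e$name, A = e$M)
      } else b <- add(b, "sigma2_g", A = J)
      b <- add(b, "sigma2_e", B = I)
    } else {
      b <- add(b, "sigma2_g", A = J)
      if (txg) b <- add(b, "sigma2_tg", A = I)
      for (e in sym_basis(t)) b <- add(b, e$name, B = e$M)
    }
  } else if (fam == "rc") {
    g <- rc_bases(t, tv)
    if (txg) {
      b <- add(b, "sigma2_g", A = g$var_int)
      b <- add(b, "cov_g", A = g$cov_int_slope)
      b <- add(b, "sigma2_tlg", A = g$var_slope)
    } else b <- add(b, "sigma2_g", A = g$var_int)
    if (!cross) {
      b <- add(b, "sigma2_m", B = g$var_int)
      if (txg) {
        b <- add(b, "cov_m", B = g$cov_int_slope)
        b <- add(b, "sigma2_tlm", B = g$var_slope)
      } else {
        # intercept-only cohort RC: the member slope is retained but
        # independent of the member intercept (4 covariance parameters)
        b <- add(b, "sigma2_tlm", B = g$var_slope)
      }
    }
    b <- add(b, "sigma2_e", B = I)
  } else {                                      # saturated, individual level
    for (e in sym_basis(t)) b <- add(b, paste0("g_", e$name), A = e$M)
    if (cross) {
      for (j in seq_len(t)) {
        M <- matrix(0, t, t); M[j, j] <- 1
        b <- add(b, sprintf("r_var_%d", j), B = M)
      }
    } else {
      for (e in sym_basis(t)) b <- add(b, paste0("r_", e$name), B = e$M)
    }
  }
  b
}

#' Residual-only model specification
#'
#' The degenerate analytic model with no random effects (independent
#' errors): REML reduces to ordinary least squares with
#' \eqn{\hat\sigma^2_e = RSS/(n - \mathrm{rank}\,X)}, and the
#' Kenward-Roger adjustment vanishes with denominator df exactly
#' \eqn{n - \mathrm{rank}\,X}.  Useful as a reference limit.
#'
#' @param structure data structure label.
#' @param time_coding \code{"categorical"} or \code{"linear"}.
#' @param df_method \code{"KR"} or \code{"BW"}.
#' @return A \code{model_spec} with an empty random-effects list.
#' @export
residual_only_spec <- function(structure = c("cross-sectional", "cohort"),
                               time_coding = c("categorical", "linear"),
                               df_method = c("KR", "BW")) {
  base::structure(list(family = "residual_only", timexgroup = FALSE,
                       structure = match.arg(structure),
                       time_coding = match.arg(time_coding),
                       random_levels = character(0),
                       g_structure = "none", r_structure = "VC",
                       fitting_level = "individual",
                       df_method = match.arg(df_method), unbounded = TRUE),
                  class = "model_spec")
}

# Fixed-effects design for one group in condition l (t x p), shared by all
# members of the group.  Categorical coding: intercept, condition dummies,
# period dummies (reference period 1), interaction dummies; linear coding:
# intercept, condition dummies, time, time x condition.
condition_design <- function(cond, n_conditions, t, tv, time_coding) {
  cdum <- if (n_conditions > 1)
    matrix(as.numeric(cond == seq(2, n_conditions)), t, n_conditions - 1,
           byrow = TRUE) else NULL
  if (time_coding == "categorical") {
    pdum <- diag(t)[, -1, drop = FALSE]
    inter <- if (n_conditions > 1 && t > 1)
      do.call(cbind, lapply(seq(2, n_conditions), function(l)
        pdum * as.numeric(cond == l))) else NULL
    X <- cbind(1, cdum, pdum, inter)
    colnames(X) <- c("(Intercept)",
                     if (n_conditions > 1) paste0("cond", 2:n_conditions),
                     if (t > 1) paste0("period", 2:t),
                     if (n_conditions > 1 && t > 1)
                       as.vector(outer(paste0("period", 2:t),
                                       paste0(":cond", 2:n_conditions),
                                       paste0)))
  } else {
    inter <- if (n_conditions > 1)
      do.call(cbind, lapply(seq(2, n_conditions), function(l)
        tv * as.numeric(cond == l))) else NULL
    X <- cbind(1, cdum, tv, inter)
    colnames(X) <- c("(Intercept)",
                     if (n_conditions > 1) paste0("cond", 2:n_conditions),
                     "time",
                     if (n_conditions > 1)
                       paste0("time:cond", 2:n_conditions))
  }
  X
}

#' Contrast matrix for the time-by-condition interaction
#'
#' Rows select the interaction coefficients of the fixed-effects design
#' built by \code{\link{build_matrices}}: \eqn{(t-1)(c-1)} rows under
#' categorical time coding, \eqn{c-1} under linear coding.
#'
#' @param spec a \code{\link{model_spec}} (only the time coding is used).
#' @param design a \code{\link{design_config}}.
#' @return A q x p contrast matrix.
#' @export
interaction_contrast <- function(spec, design) {
  t <- design$n_periods
  cnd <- design$n_conditions
  X <- condition_design(1, cnd, t, design$time_values, spec$time_coding)
  p <- ncol(X)
  idx <- grep(":cond", colnames(X))
  L <- matrix(0, length(idx), p)
  L[cbind(seq_along(idx), idx)] <- 1
  colnames(L) <- colnames(X)
  L
}
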