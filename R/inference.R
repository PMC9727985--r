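# Small-sample F-tests of the time-by-condition interaction.
#
# Kenward-Roger: the adjusted covariance of the fixed effects and the
# scaled-F denominator degrees of freedom are obtained by moment matching
# of the Wald statistic, using the inverse expected REML information as the
# covariance of the covariance-parameter estimates.  All covariance
# structures fitted here are linear in their parameters, so the
# second-derivative term of the adjustment vanishes and the original
# (1997) and improved (2009) constructions coincide; both method labels
# are accepted.

new_interaction_test <- function(f, ndf, ddf, p, method, note = NULL) {
  structure(list(f_stat = f, ndf = ndf, ddf = ddf, p_value = p,
                 method = method, note = note),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("interaction test unavailable:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("F(%g, %.4g) = %.5g, p = %.5g  [%s]\n",
              x$ndf, x$ddf, x$f_stat, x$p_value, x$method))
  invisible(x)
}

test_unavailable <- function(method, note) {
  new_interaction_test(NA_real_, NA_integer_, NA_real_, NA_real_, method,
                       note = note)
}

#' Kenward-Roger test of the time-by-condition interaction
#'
#' Computes the Kenward-Roger small-sample adjusted covariance of the fixed
#' effects and the scaled F-test of the contrast (by default the
#' time-by-condition interaction): the adjusted Wald statistic is moment
#' matched to an F distribution, yielding a scale factor and a possibly
#' fractional denominator df.  In a model with no random effects the
#' adjustment vanishes and the denominator df equals the residual df
#' \eqn{n - \mathrm{rank}(X)} exactly.
#'
#' @param fit a converged \code{\link{reml_fit}} result.
#' @param contrast optional q x p contrast matrix; defaults to the
#'   interaction contrast of the fitted model.
#' @param method \code{"kr2"} (default) or \code{"kr1"}; identical for the
#'   covariance structures fitted here (all linear in their parameters).
#' @return An object of class \code{"interaction_test"} with fields
#'   \code{f_stat}, \code{ndf}, \code{ddf} (fractional, never rounded),
#'   \code{p_value} and \code{method}.  If the covariance-parameter
#'   information matrix is singular the result carries a diagnostic
#'   \code{note} and \code{NA} values instead of raising an error.
#' @export
kr_adjust <- function(fit, contrast = NULL, method = c("kr2", "kr1")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "grt_fit"))
  if (!isTRUE(fit$converged))
    return(test_unavailable("KR", "model fit did not converge"))
  ss <- fit$ss
  ev <- reml_eval(fit$vtheta_hat, ss, "kr")
  if (is.null(ev))
    return(test_unavailable("KR", "marginal covariance not positive definite"))
  k <- length(fit$vtheta_hat)
  W <- tryCatch(solve(ev$info), error = function(e) NULL)
  if (is.null(W))
    return(test_unavailable("KR",
                            "singular covariance-parameter information matrix"))
  Phi <- ev$beta_cov
  if (is.null(contrast))
    contrast <- interaction_contrast(fit$spec, ss$design)
  L <- contrast
  q <- nrow(L)
  # adjusted covariance: Phi + 2 Phi [sum_ij W_ij (Q_ij - P_i Phi P_j)] Phi
  Lam <- matrix(0, ss$p, ss$p)
  PhiP <- lapply(ev$AC, function(M) Phi %*% M %*% Phi)   # Phi P_i Phi
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (W[i, j] == 0) next
      Lam <- Lam + W[i, j] * (ev$Q[[(i - 1) * k + j]] -
                                ev$AC[[i]] %*% Phi %*% ev$AC[[j]])
    }
  PhiA <- Phi + 2 * Phi %*% Lam %*% Phi
  # moment matching of the Wald statistic
  LPL <- L %*% Phi %*% t(L)
  Theta <- t(L) %*% solve(LPL, L)
  Ti <- lapply(seq_len(k), function(i) Theta %*% PhiP[[i]])
  a <- vapply(Ti, function(M) sum(diag(M)), numeric(1))
  A1 <- drop(t(a) %*% W %*% a)
  A2 <- 0
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (W[i, j] == 0) next
      A2 <- A2 + W[i, j] * sum(Ti[[i]] * t(Ti[[j]]))
    }
  Bq <- (A1 + 6 * A2) / (2 * q)
  g <- ((q + 1) * A1 - (q + 4) * A2) / ((q + 2) * A2)
  c1 <- g / (3 * q + 2 * (1 - g))
  c2 <- (q - g) / (3 * q + 2 * (1 - g))
  c3 <- (q + 2 - g) / (3 * q + 2 * (1 - g))
  Estar <- 1 / (1 - A2 / q)
  Vstar <- (2 / q) * (1 + c1 * Bq) / ((1 - c2 * Bq)^2 * (1 - c3 * Bq))
  rho <- Vstar / (2 * Estar^2)
  lb <- drop(L %*% ev$beta)
  Fadj <- drop(crossprod(lb, solve(L %*% PhiA %*% t(L), lb))) / q
  ddf <- 4 + (q + 2) / (q * rho - 1)
  lambda <- ddf / (Estar * (ddf - 2))
  if (!is.finite(ddf) || !is.finite(lambda) || ddf <= 0 || lambda <= 0) {
    # degenerate moment match (e.g. no information in the adjustment
    # directions): fall back to the unadjusted residual-df F
    ddf <- ss$n - ss$p
    lambda <- 1
  }
  Fstar <- max(lambda * Fadj, 0)
  p <- stats::pf(Fstar, q, ddf, lower.tail = FALSE)
  new_interaction_test(Fstar, q, ddf, p, "KR")
}

#' Between-within test of the time-by-condition interaction
#'
#' Design-based denominator degrees of freedom: the residual df are
#' partitioned at the group (cluster) level.  Contrasts of effects that are
#' constant within a group (condition) receive the between-group df
#' \eqn{G - \mathrm{rank}(X_{between})}; contrasts of effects that vary
#' within a group (time, time-by-condition) receive the remaining
#' within-group residual df.  The F statistic is the unadjusted Wald
#' statistic at the REML estimates; df are deterministic integers.
#'
#' @inheritParams kr_adjust
#' @return An \code{"interaction_test"} object with \code{method = "BW"}.
#' @export
bw_df <- function(fit, contrast = NULL) {
  stopifnot(inherits(fit, "grt_fit"))
  if (!isTRUE(fit$converged))
    return(test_unavailable("BW", "model fit did not converge"))
  ss <- fit$ss
  if (is.null(contrast))
    contrast <- interaction_contrast(fit$spec, ss$design)
  L <- contrast
  q <- nrow(L)
  # columns constant across periods within each condition block are
  # "between" columns (intercept, condition)
  between_col <- vapply(seq_len(ss$p), function(j)
    all(vapply(ss$Xt, function(X) length(unique(X[, j])) == 1, logical(1))),
    logical(1))
  rank_between <- qr(do.call(rbind, lapply(ss$Xt, function(X)
    X[1, between_col, drop = FALSE])))$rank
  df_between <- ss$G - rank_between
  df_within <- (ss$n - ss$p) - df_between
  within_contrast <- any(abs(L[, !between_col, drop = FALSE]) > 0)
  ddf <- if (within_contrast) df_within else df_between
  Phi <- fit$beta_cov
  lb <- drop(L %*% fit$beta_hat)
  Fst <- drop(crossprod(lb, solve(L %*% Phi %*% t(L), lb))) / q
  p <- stats::pf(Fst, q, ddf, lower.tail = FALSE)
  new_interaction_test(Fst, q, ddf, p, "BW")
}

#' Test the time-by-condition interaction of a fit
#'
#' Dispatches to \code{\link{kr_adjust}} or \code{\link{bw_df}} according
#' to the df method of the model specification.
#'
#' @inheritParams kr_adjust
#' @param df_method optional override (\code{"KR"} or \code{"BW"}).
#' @return An \code{"interaction_test"} object.
#' @export
test_interaction <- function(fit, contrast = NULL, df_method = NULL) {
  method <- if (!is.null(df_method)) df_method else fit$spec$df_method
  if (toupper(method) == "KR") kr_adjust(fit, contrast)
  else bw_df(fit, contrast)
}
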