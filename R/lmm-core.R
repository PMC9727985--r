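# REML estimation for balanced multiple-period parallel GRT mixed models.
#
# For every analytic model in the registry the marginal covariance of one
# group block (m members x t periods, canonical period-within-member order)
# is V = J_m (x) A + I_m (x) B, linear in the covariance parameters.  The
# spectral split of J_m gives two strata: S1 = mA + B carried by the
# member-mean direction (multiplicity 1) and B carried by the member
# deviations (multiplicity m - 1).  All likelihood quantities therefore
# reduce to t x t algebra over per-group sufficient statistics: the
# period-mean vector of each group and the pooled within-group scatter
# matrix.  Estimation is by Fisher scoring on the REML criterion with
# unconstrained ("nobound") covariance parameters; the only requirement on
# an iterate is that both strata be positive definite.

#' Build design matrices and covariance basis for a model fit
#'
#' Validates balance, reorders the data into the canonical layout and
#' returns the per-condition fixed-effects design blocks, the covariance
#' basis (one pair of t x t matrices per free parameter) and the sufficient
#' statistics consumed by \code{\link{reml_fit}}.
#'
#' @param data a \code{trial_data} object (see \code{\link{simulate_trial}}
#'   and \code{\link{read_trial_csv}}).
#' @param spec a \code{\link{model_spec}}.
#' @return A list with elements \code{Xt} (per-condition t x p design
#'   blocks), \code{bases}, \code{ybar} (t x G matrix of group period
#'   means), \code{Wsum} (pooled within-group scatter), \code{cond}
#'   (condition of each group), \code{m}, \code{t}, \code{G}, \code{n},
#'   \code{p} and the design.
#' @export
build_matrices <- function(data, spec) {
  stopifnot(inherits(data, "trial_data"), inherits(spec, "model_spec"))
  design <- attr(data, "design")
  if (is.null(design))
    stop("trial_data is missing its design attribute; read it with ",
         "read_trial_csv() or build it with simulate_trial()", call. = FALSE)
  if (spec$fitting_level == "group_mean" && design$members_per_group > 1)
    data <- group_mean_reduce(data)
  design <- attr(data, "design")
  t <- design$n_periods
  m <- design$members_per_group
  tv <- design$time_values
  nc <- design$n_conditions
  G <- design$groups_per_condition * nc
  if (design$groups_per_condition < 2)
    stop("at least two groups per condition are required", call. = FALSE)
  if (nrow(data) != G * m * t)
    stop(sprintf("unbalanced data: expected %d rows (c*g*m*t), found %d",
                 G * m * t, nrow(data)), call. = FALSE)
  # canonical order: group, member, period (cross-sectional: group, period,
  # sample index within cell); exactly one row per member x period
  ord <- if (design$structure == "cohort")
    order(data$group_id, data$member_id, data$period)
  else
    order(data$group_id, data$period, data$member_id)
  if (anyDuplicated(paste(data$member_id, data$period)))
    stop("duplicate member x period rows", call. = FALSE)
  d <- data[ord, , drop = FALSE]
  grp <- unique(d$group_id)
  cond <- d$condition[match(grp, d$group_id)]
  if (any(tabulate(match(d$group_id, grp), length(grp)) != m * t))
    stop("unbalanced data: groups differ in size", call. = FALSE)
  # t x m x G array of outcomes
  Y <- if (design$structure == "cohort")
    array(d$y, c(t, m, G))
  else
    aperm(array(d$y, c(m, t, G)), c(2, 1, 3))
  ybar <- apply(Y, c(1, 3), mean)                            # t x G
  if (m > 1) {
    dev <- matrix(Y - aperm(array(ybar, c(t, G, m)), c(1, 3, 2)), nrow = t)
    Wsum <- tcrossprod(dev)
  } else Wsum <- matrix(0, t, t)
  Xt <- lapply(seq_len(nc), function(l)
    condition_design(l, nc, t, tv, spec$time_coding))
  p <- ncol(Xt[[1]])
  bases <- model_bases(spec, t, tv,
                       level = if (spec$fitting_level == "group_mean")
                         "group_mean" else "individual")
  list(Xt = Xt, bases = bases, ybar = ybar, Wsum = Wsum,
       cond = cond, group_ids = grp, m = m, t = t, G = G,
       n = G * m * t, p = p, design = design, spec = spec)
}

# Evaluate REML pieces at theta.  Returns NULL if a stratum is not positive
# definite.  what: "loglik" | "grad" | "kr" (grad + info + KR arrays).
reml_eval <- function(theta, ss, what = "grad") {
  t <- ss$t; m <- ss$m; G <- ss$G
  bases <- ss$bases
  k <- length(bases)
  A <- matrix(0, t, t); B <- matrix(0, t, t)
  for (i in seq_len(k)) {
    if (!is.null(bases[[i]]$A)) A <- A + theta[i] * bases[[i]]$A
    if (!is.null(bases[[i]]$B)) B <- B + theta[i] * bases[[i]]$B
  }
  S1 <- m * A + B
  cS1 <- tryCatch(chol(S1), error = function(e) NULL)
  if (is.null(cS1)) return(NULL)
  S1inv <- chol2inv(cS1)
  ldS1 <- 2 * sum(log(diag(cS1)))
  if (m > 1) {
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(NULL)
    Binv <- chol2inv(cB)
    ldB <- 2 * sum(log(diag(cB)))
  } else { Binv <- NULL; ldB <- 0 }
  nc <- length(ss$Xt)
  gcount <- tabulate(ss$cond, nc)
  H <- lapply(ss$Xt, function(X) S1inv %*% X)                # t x p
  C <- matrix(0, ss$p, ss$p)
  for (l in seq_len(nc))
    C <- C + m * gcount[l] * crossprod(ss$Xt[[l]], H[[l]])
  cC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(cC)) return(NULL)
  Cinv <- chol2inv(cC)
  ldC <- 2 * sum(log(diag(cC)))
  rhs <- numeric(ss$p)
  for (l in seq_len(nc)) {
    sel <- ss$cond == l
    if (any(sel))
      rhs <- rhs + m * crossprod(H[[l]], rowSums(ss$ybar[, sel, drop = FALSE]))
  }
  beta <- drop(Cinv %*% rhs)
  ebar <- ss$ybar
  for (l in seq_len(nc)) {
    sel <- ss$cond == l
    if (any(sel))
      ebar[, sel] <- ebar[, sel] - drop(ss$Xt[[l]] %*% beta)
  }
  Fq <- S1inv %*% ebar                                       # t x G
  q1 <- m * sum(ebar * Fq)
  q2 <- if (m > 1) sum(Binv * ss$Wsum) else 0
  ll <- -0.5 * (G * ldS1 + G * (m - 1) * ldB + ldC + q1 + q2 +
                  (ss$n - ss$p) * log(2 * pi))
  out <- list(theta = theta, loglik = ll, beta = beta, beta_cov = Cinv,
              S1 = S1, B = B, S1inv = S1inv, Binv = Binv, ebar = ebar)
  if (what == "loglik") return(out)

  S1k <- lapply(bases, function(b) {
    M <- matrix(0, t, t)
    if (!is.null(b$A)) M <- M + m * b$A
    if (!is.null(b$B)) M <- M + b$B
    M
  })
  U <- lapply(S1k, function(M) S1inv %*% M)
  TB <- if (m > 1) Binv %*% ss$Wsum %*% Binv else NULL
  Vb <- if (m > 1)
    lapply(bases, function(b) if (is.null(b$B)) NULL else Binv %*% b$B)
  else NULL
  # per-parameter X-side arrays
  Hk <- lapply(seq_len(k), function(i)
    lapply(seq_len(nc), function(l) S1k[[i]] %*% H[[l]]))    # t x p
  Gk <- lapply(seq_len(k), function(i)
    lapply(seq_len(nc), function(l) S1inv %*% Hk[[i]][[l]]))
  # AC_i = m sum_l g_l X_l' S1inv S1k_i S1inv X_l  = m sum_l g_l H_l' S1k_i H_l
  AC <- lapply(seq_len(k), function(i) {
    M <- matrix(0, ss$p, ss$p)
    for (l in seq_len(nc))
      M <- M + m * gcount[l] * crossprod(H[[l]], Hk[[i]][[l]])
    M
  })
  grad <- numeric(k)
  for (i in seq_len(k)) {
    t1 <- G * (sum(diag(U[[i]])) +
                 (m - 1) * (if (is.null(Vb) || is.null(Vb[[i]])) 0
                            else sum(diag(Vb[[i]]))))
    t2 <- sum(Cinv * AC[[i]])
    t3 <- m * sum(Fq * (S1k[[i]] %*% Fq)) +
      (if (m > 1 && !is.null(bases[[i]]$B)) sum(bases[[i]]$B * TB) else 0)
    grad[i] <- -0.5 * (t1 - t2 - t3)
  }
  info <- matrix(0, k, k)
  Q <- if (what == "kr") vector("list", k * k) else NULL
  for (i in seq_len(k))
    for (j in i:k) {
      tr1 <- sum(U[[i]] * t(U[[j]]))
      tr2 <- if (m > 1 && !is.null(Vb[[i]]) && !is.null(Vb[[j]]))
        sum(Vb[[i]] * t(Vb[[j]])) else 0
      Bij <- matrix(0, ss$p, ss$p)
      for (l in seq_len(nc))
        Bij <- Bij + m * gcount[l] * crossprod(Hk[[i]][[l]], Gk[[j]][[l]])
      tr3 <- 2 * sum(Cinv * Bij)
      tr4 <- sum((Cinv %*% AC[[i]]) * t(Cinv %*% AC[[j]]))
      info[i, j] <- info[j, i] <-
        0.5 * (G * tr1 + G * (m - 1) * tr2 - tr3 + tr4)
      if (what == "kr") {
        Q[[(i - 1) * k + j]] <- Bij
        if (i != j) {
          Bji <- matrix(0, ss$p, ss$p)
          for (l in seq_len(nc))
            Bji <- Bji + m * gcount[l] * crossprod(Hk[[j]][[l]], Gk[[i]][[l]])
          Q[[(j - 1) * k + i]] <- Bji
        }
      }
    }
  out$grad <- grad
  out$info <- info
  if (what == "kr") {
    out$AC <- AC
    out$Q <- Q
  }
  out
}

# method-of-moments starting values: least-squares projection of the
# stratum estimates onto the (linear) covariance basis
reml_start <- function(ss) {
  t <- ss$t; m <- ss$m; G <- ss$G
  nc <- length(ss$Xt)
  gcount <- tabulate(ss$cond, nc)
  C0 <- matrix(0, ss$p, ss$p); rhs <- numeric(ss$p)
  for (l in seq_len(nc)) {
    sel <- ss$cond == l
    C0 <- C0 + gcount[l] * crossprod(ss$Xt[[l]])
    if (any(sel))
      rhs <- rhs + crossprod(ss$Xt[[l]], rowSums(ss$ybar[, sel, drop = FALSE]))
  }
  beta0 <- tryCatch(solve(C0, rhs), error = function(e) NULL)
  if (is.null(beta0))
    stop("rank-deficient fixed-effects design", call. = FALSE)
  ebar <- ss$ybar
  for (l in seq_len(nc)) {
    sel <- ss$cond == l
    if (any(sel)) ebar[, sel] <- ebar[, sel] - drop(ss$Xt[[l]] %*% beta0)
  }
  S1hat <- m * tcrossprod(ebar) / max(G - nc, 1)
  k <- length(ss$bases)
  if (m > 1) {
    Bhat <- ss$Wsum / (G * (m - 1))
    Xls <- matrix(0, 2 * t * t, k)
    yls <- c(as.vector(S1hat), sqrt(m - 1) * as.vector(Bhat))
    for (i in seq_len(k)) {
      b <- ss$bases[[i]]
      S1i <- matrix(0, t, t); Bi <- matrix(0, t, t)
      if (!is.null(b$A)) S1i <- S1i + m * b$A
      if (!is.null(b$B)) { S1i <- S1i + b$B; Bi <- b$B }
      Xls[, i] <- c(as.vector(S1i), sqrt(m - 1) * as.vector(Bi))
    }
  } else {
    Xls <- vapply(ss$bases, function(b) {
      S1i <- matrix(0, t, t)
      if (!is.null(b$A)) S1i <- S1i + b$A
      if (!is.null(b$B)) S1i <- S1i + b$B
      as.vector(S1i)
    }, numeric(t * t))
    yls <- as.vector(S1hat)
  }
  theta0 <- tryCatch(drop(qr.solve(Xls, yls)), error = function(e) NULL)
  if (is.null(theta0) || !all(is.finite(theta0)))
    theta0 <- fallback_start(ss)
  theta0
}

fallback_start <- function(ss) {
  vy <- (m_ss <- ss$m) * sum(ss$ybar^2) / (ss$t * ss$G) +
    sum(diag(ss$Wsum)) / max(ss$G * ss$t * (ss$m - 1), 1)
  diag_par <- vapply(ss$bases, function(b)
    sum(diag(if (is.null(b$A)) matrix(0, ss$t, ss$t) else b$A)) +
      sum(diag(if (is.null(b$B)) matrix(0, ss$t, ss$t) else b$B)) > 0,
    logical(1))
  theta <- numeric(length(ss$bases))
  theta[diag_par] <- max(vy, 1e-3) / max(sum(diag_par), 1)
  theta
}

#' Fit a linear mixed analytic model by unconstrained REML
#'
#' Maximizes the REML criterion over unconstrained covariance parameters
#' ("nobound": negative variance estimates are allowed, only positive
#' definiteness of the assembled marginal covariance is enforced at
#' accepted iterates) by Fisher scoring with step halving, starting from a
#' method-of-moments projection.  The GLS fixed-effect estimates at the
#' optimum and everything needed for Kenward-Roger or between-within
#' interaction tests are returned.
#'
#' @param data a \code{trial_data} object.
#' @param spec a \code{\link{model_spec}} (see \code{\link{make_spec}}).
#' @param start optional numeric vector of starting covariance parameters.
#' @param control list: \code{max_iter} (default 200), \code{tol_loglik}
#'   (relative log-likelihood change, default 1e-10), \code{tol_grad}
#'   (default 1e-6).
#' @return An object of class \code{"grt_fit"} with components
#'   \code{beta_hat}, \code{vtheta_hat} (named covariance parameters),
#'   \code{reml_loglik}, \code{beta_cov}, \code{converged}, \code{n_iter},
#'   \code{gradient_norm}, \code{boundary_note} (TRUE when a variance-type
#'   parameter is negative) and the sufficient statistics used.
#'   A fit that fails to converge is returned with
#'   \code{converged = FALSE}, never raised as an error.
#' @examples
#' vc <- variance_components(1, 1, sigma2_e = 18)
#' d  <- simulate_rm(design_config(groups_per_condition = 5,
#'                                 members_per_group = 10), vc, seed = 7)
#' f  <- reml_fit(d, make_spec("rm_vc"))
#' f$vtheta_hat
#' @export
reml_fit <- function(data, spec, start = NULL, control = list()) {
  ctl <- utils::modifyList(list(max_iter = 200L, tol_loglik = 1e-10,
                                tol_grad = 1e-6), control)
  ss <- build_matrices(data, spec)
  theta0 <- if (!is.null(start)) start else reml_start(ss)
  fit <- scoring_run(theta0, ss, ctl)
  if (is.null(fit) || !fit$converged) {
    # one perturbed deterministic restart before declaring failure
    theta1 <- fallback_start(ss)
    theta1 <- 0.5 * theta1 + 0.5 * abs(theta0) * 1.2
    fit2 <- scoring_run(theta1, ss, ctl)
    if (!is.null(fit2) && (is.null(fit) || fit2$converged ||
                           fit2$loglik > fit$loglik)) fit <- fit2
  }
  if (is.null(fit))
    return(structure(list(converged = FALSE, reml_loglik = NA_real_,
                          spec = spec, ss = ss), class = "grt_fit"))
  vt <- fit$theta
  names(vt) <- names(ss$bases)
  # a parameter is variance-like iff its basis matrices are PSD (variances
  # J, I, E_jj, tau tau'; covariances have indefinite bases)
  psd <- function(M) is.null(M) || min(eigen(M, symmetric = TRUE,
                                             only.values = TRUE)$values) >=
    -1e-10
  var_like <- vapply(ss$bases, function(b)
    psd(b$A) && psd(b$B) && !(is.null(b$A) && is.null(b$B)), logical(1))
  structure(list(
    beta_hat = stats::setNames(fit$beta, colnames(ss$Xt[[1]])),
    vtheta_hat = vt,
    reml_loglik = fit$loglik,
    beta_cov = fit$beta_cov,
    converged = fit$converged,
    n_iter = fit$n_iter,
    gradient_norm = fit$gradient_norm,
    boundary_note = any(vt[var_like] < 0),
    spec = spec, ss = ss), class = "grt_fit")
}

scoring_run <- function(theta, ss, ctl) {
  ev <- reml_eval(theta, ss, "grad")
  if (is.null(ev)) {
    # shrink toward a safe diagonal start until positive definite
    safe <- fallback_start(ss)
    for (w in c(0.5, 0.8, 0.95, 1)) {
      ev <- reml_eval((1 - w) * theta + w * safe, ss, "grad")
      if (!is.null(ev)) { theta <- (1 - w) * theta + w * safe; break }
    }
    if (is.null(ev)) return(NULL)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(solve(ev$info + diag(1e-8 * max(abs(diag(ev$info))),
                                            length(ev$grad)), ev$grad),
                       error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    ok <- FALSE
    h <- 1
    for (half in 1:30) {
      cand <- ev$theta + h * step
      ev2 <- reml_eval(cand, ss, "grad")
      if (!is.null(ev2) && is.finite(ev2$loglik) &&
          ev2$loglik >= ev$loglik - 1e-12 * (1 + abs(ev$loglik))) {
        ok <- TRUE
        break
      }
      h <- h / 2
    }
    if (!ok) break
    dll <- ev2$loglik - ev$loglik
    ev <- ev2
    if (abs(dll) <= ctl$tol_loglik * (1 + abs(ev$loglik)) &&
        max(abs(ev$grad)) <= ctl$tol_grad * (1 + abs(ev$loglik))) {
      converged <- TRUE
      break
    }
  }
  list(theta = ev$theta, beta = ev$beta, beta_cov = ev$beta_cov,
       loglik = ev$loglik, converged = converged, n_iter = iter,
       gradient_norm = sqrt(sum(ev$grad^2)))
}

#' @export
print.grt_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("grt_fit: NOT converged\n")
    if (!is.na(x$reml_loglik))
      cat(sprintf("  last REML log-likelihood %.4f\n", x$reml_loglik))
    return(invisible(x))
  }
  s <- x$spec
  cat(sprintf("REML fit: %s (%s), %s data, %s level\n",
              model_label(s$family),
              if (s$timexgroup) "time x group" else "intercept only",
              s$structure, sub("_", " ", s$fitting_level)))
  cat(sprintf("  REML log-likelihood %.4f (%d iterations)\n",
              x$reml_loglik, x$n_iter))
  cat("  covariance parameters:\n")
  print(round(x$vtheta_hat, 6))
  if (x$boundary_note)
    cat("  note: negative variance estimate(s) (unconstrained REML)\n")
  cat("  fixed effects:\n")
  print(round(x$beta_hat, 6))
  invisible(x)
}

#' Reduce a trial dataset to group-period means
#'
#' Averages member outcomes within each group x period cell.  Requires
#' equal group sizes; on balanced data the interaction F-test from the
#' group-mean formulation of the saturated and cross-sectional
#' unstructured RM-ANOVA models equals the individual-level one.
#'
#' @param data a \code{trial_data} object.
#' @return A \code{trial_data} object with one row per group x period
#'   (members_per_group = 1).
#' @export
group_mean_reduce <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  design <- attr(data, "design")
  sizes <- table(data$group_id, data$period)
  if (length(unique(as.vector(sizes))) != 1)
    stop("group sizes are unequal; the group-mean formulation is only ",
         "equivalent to the individual-level fit for equal group sizes",
         call. = FALSE)
  agg <- stats::aggregate(data$y,
                          by = list(group_id = data$group_id,
                                    period = data$period), mean)
  cond <- data$condition[match(agg$group_id, data$group_id)]
  df <- data.frame(member_id = agg$group_id, group_id = agg$group_id,
                   condition = cond, period = agg$period,
                   time = design$time_values[agg$period], y = agg$x,
                   stringsAsFactors = FALSE)
  df <- df[order(df$group_id, df$period), ]
  rownames(df) <- NULL
  d2 <- design
  d2$members_per_group <- 1L
  d2$structure <- "cross-sectional"
  new_trial_data(df, d2, attr(data, "mechanism"))
}
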