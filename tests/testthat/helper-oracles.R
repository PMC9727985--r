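# Shared fixtures and independent oracles.
#
# dense_reml() evaluates the REML log-likelihood by the direct
# multivariate-normal formula with the full n x n marginal covariance,
# independently of the blocked stratum algebra in the package.

dense_reml <- function(d, spec, theta) {
  design <- attr(d, "design")
  t <- design$n_periods
  tv <- design$time_values
  nc <- design$n_conditions
  bases <- grtsim:::model_bases(
    spec, t, tv,
    level = if (spec$fitting_level == "group_mean") "group_mean"
    else "individual")
  if (spec$fitting_level == "group_mean") {
    d <- group_mean_reduce(d)
    design <- attr(d, "design")
  }
  m <- design$members_per_group
  ord <- if (design$structure == "cohort")
    order(d$group_id, d$member_id, d$period)
  else order(d$group_id, d$period, d$member_id)
  d <- d[ord, ]
  grp <- unique(d$group_id)
  G <- length(grp)
  J <- matrix(1, m, m)
  I <- diag(m)
  Vg <- matrix(0, m * t, m * t)
  for (i in seq_along(bases)) {
    A <- bases[[i]]$A
    B <- bases[[i]]$B
    if (design$structure == "cohort") {
      # rows ordered member-major (period fastest)
      if (!is.null(A)) Vg <- Vg + theta[i] * kronecker(J, A)
      if (!is.null(B)) Vg <- Vg + theta[i] * kronecker(I, B)
    } else {
      # rows ordered period-major (member fastest)
      if (!is.null(A)) Vg <- Vg + theta[i] * kronecker(A, J)
      if (!is.null(B)) Vg <- Vg + theta[i] * kronecker(B, I)
    }
  }
  V <- kronecker(diag(G), Vg)
  cond <- d$condition[match(grp, d$group_id)]
  X <- do.call(rbind, lapply(seq_len(G), function(g) {
    Xt <- grtsim:::condition_design(cond[g], nc, t, tv, spec$time_coding)
    if (design$structure == "cohort")
      Xt[rep(seq_len(t), times = m), , drop = FALSE]
    else Xt[rep(seq_len(t), each = m), , drop = FALSE]
  }))
  y <- d$y
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  beta <- solve(C, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(C)$modulus +
                       t(e) %*% Vi %*% e + (n - p) * log(2 * pi)))
}

# a parameter point at which every structure in the zoo is positive
# definite: project two fixed well-conditioned PD matrices onto the basis
pd_theta <- function(ss, shift = 0) {
  t <- ss$t
  set.seed(1234 + shift)
  R1 <- crossprod(matrix(rnorm(t * t), t)) + diag(t)
  R2 <- crossprod(matrix(rnorm(t * t), t)) + 2 * diag(t)
  k <- length(ss$bases)
  th <- numeric(k)
  nm <- names(ss$bases)
  for (i in seq_len(k)) {
    b <- ss$bases[[i]]
    if (grepl("un_", nm[i])) {
      jk <- as.integer(strsplit(sub(".*un_", "", nm[i]), "_")[[1]])
      M <- if (!is.null(b$A)) R1 else R2
      th[i] <- M[jk[1], jk[2]]
    } else if (grepl("^r_var", nm[i])) th[i] <- 2 + 0.3 * i
    else if (grepl("cov", nm[i])) th[i] <- 0.2
    else th[i] <- 1 + 0.1 * i +
        4 * (nm[i] %in% c("sigma2_e", "sigma2_m"))
  }
  th
}

small_cohort_data <- function(seed = 5) {
  vc <- variance_components(1, 1, 12.6, 0, 5.4, "RM", "cohort")
  simulate_rm(design_config(groups_per_condition = 3, members_per_group = 4,
                            n_periods = 3, structure = "cohort"),
              vc, seed = seed)
}

small_cross_data <- function(seed = 7) {
  vc <- variance_components(1, 1, sigma2_e = 18)
  simulate_rm(design_config(groups_per_condition = 3, members_per_group = 4,
                            n_periods = 3), vc, seed = seed)
}

all_model_names <- function(structure) {
  out <- list()
  for (fam in c("rm_vc", "rm_un", "rc", "saturated"))
    for (txg in c(TRUE, FALSE)) {
      if (fam == "saturated" && !txg) next
      out[[length(out) + 1]] <- analytic_model(fam, timexgroup = txg,
                                               structure = structure)
    }
  out
}
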