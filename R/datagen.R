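#' Design configuration for a balanced parallel trial
#'
#' Describes the balanced two-condition multiple-period parallel design:
#' number of conditions, periods (with their time values), groups per
#' condition and members per group, and whether members are measured once
#' (cross-sectional: a fresh set of members each period) or followed over
#' time (cohort).
#'
#' @param n_conditions number of study conditions (condition 1 is control).
#' @param n_periods number of measurement periods.
#' @param time_values strictly increasing numeric time values, one per
#'   period.  Defaults to \code{0:(n_periods - 1)}.
#' @param groups_per_condition groups randomized to each condition.
#' @param members_per_group members measured per group per period.
#' @param structure \code{"cross-sectional"} or \code{"cohort"}.
#' @return An object of class \code{"design_config"}.
#' @examples
#' design_config(groups_per_condition = 10, members_per_group = 40)
#' @export
design_config <- function(n_conditions = 2, n_periods = 5,
                          time_values = NULL,
                          groups_per_condition, members_per_group,
                          structure = c("cross-sectional", "cohort")) {
  structure <- match.arg(structure)
  if (is.null(time_values)) time_values <- seq_len(n_periods) - 1
  stopifnot(n_conditions >= 1, n_periods >= 1, groups_per_condition >= 1,
            members_per_group >= 1)
  if (length(time_values) != n_periods || any(diff(time_values) <= 0))
    stop("time_values must be strictly increasing with one value per period",
         call. = FALSE)
  base::structure(
    list(n_conditions = as.integer(n_conditions),
         n_periods = as.integer(n_periods),
         time_values = as.numeric(time_values),
         groups_per_condition = as.integer(groups_per_condition),
         members_per_group = as.integer(members_per_group),
         structure = structure),
    class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(paste0("Parallel GRT design: %d conditions x %d groups x %d ",
                     "members, %d periods (t = %s), %s\n"),
              x$n_conditions, x$groups_per_condition, x$members_per_group,
              x$n_periods, paste(x$time_values, collapse = ","), x$structure))
  invisible(x)
}

#' Fixed effects of the generating model
#'
#' All fixed effects default to zero, the null configuration used for a
#' type I error study.  Under categorical (RM) time coding the time main
#' effects and time-by-condition interactions are given per period with the
#' reference constraints (period 1 and control condition fixed at 0)
#' enforced; under linear (RC) coding a common slope and per-condition slope
#' differences are given.
#'
#' @param mu baseline control-condition mean.
#' @param condition numeric vector of condition effects, length
#'   \code{n_conditions}; first element must be 0.
#' @param time period effects: length \code{n_periods} with first element 0
#'   (categorical coding) or a single slope (linear coding).
#' @param interaction time-by-condition effects: an
#'   \code{n_periods x n_conditions} matrix with first row and first column
#'   0 (categorical), or a length-\code{n_conditions} vector of slope
#'   differences with first element 0 (linear).
#' @return An object of class \code{"fixed_effects"}.
#' @export
fixed_effects <- function(mu = 0, condition = NULL, time = NULL,
                          interaction = NULL) {
  structure(list(mu = mu, condition = condition, time = time,
                 interaction = interaction),
            class = "fixed_effects")
}

# Resolve the fixed-effects object into a per-(period, condition) mean
# matrix (t x c), validating the reference-level constraints.
fixed_effect_means <- function(fx, design, mechanism) {
  t <- design$n_periods
  cnd <- design$n_conditions
  tv <- design$time_values
  if (is.null(fx)) fx <- fixed_effects()
  cond <- fx$condition
  if (is.null(cond)) cond <- numeric(cnd)
  if (length(cond) != cnd || cond[1] != 0)
    stop("condition effects must have length n_conditions with C_1 = 0",
         call. = FALSE)
  if (mechanism == "RM") {
    tim <- fx$time
    if (is.null(tim)) tim <- numeric(t)
    if (length(tim) != t || tim[1] != 0)
      stop("categorical time effects must have length n_periods with T_1 = 0",
           call. = FALSE)
    inter <- fx$interaction
    if (is.null(inter)) inter <- matrix(0, t, cnd)
    inter <- as.matrix(inter)
    if (!all(dim(inter) == c(t, cnd)) || any(inter[1, ] != 0) ||
        any(inter[, 1] != 0))
      stop("categorical interaction must be t x c with first row/column 0",
           call. = FALSE)
    mu_jc <- fx$mu + outer(tim, cond, "+") + inter
  } else {
    slope <- fx$time
    if (is.null(slope)) slope <- 0
    if (length(slope) != 1)
      stop("linear coding takes a single time slope", call. = FALSE)
    dslope <- fx$interaction
    if (is.null(dslope)) dslope <- numeric(cnd)
    if (length(dslope) != cnd || dslope[1] != 0)
      stop("linear interaction is a length-c vector of slope differences ",
           "with first element 0", call. = FALSE)
    mu_jc <- fx$mu + outer(tv * slope, cond, "+") +
      outer(tv, dslope)
  }
  mu_jc
}

check_vc_design <- function(vc, design) {
  if (vc$structure != design$structure)
    stop(sprintf("variance components are %s but the design is %s",
                 vc$structure, design$structure), call. = FALSE)
}

new_trial_data <- function(df, design, mechanism) {
  attr(df, "design") <- design
  attr(df, "mechanism") <- mechanism
  class(df) <- c("trial_data", "data.frame")
  df
}

#' @export
print.trial_data <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Trial data: %d observations (%s mechanism)\n",
              nrow(x), attr(x, "mechanism")))
  if (!is.null(d)) print(d)
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

# Shared scaffolding: one row per member x period in canonical order
# (condition, group, member, period).  Cross-sectional member ids encode
# the period of entry so ids are globally unique under one schema.
trial_frame <- function(design) {
  cnd <- design$n_conditions
  g <- design$groups_per_condition
  m <- design$members_per_group
  t <- design$n_periods
  cohort <- design$structure == "cohort"
  cond <- rep(seq_len(cnd), each = g * m * t)
  grp <- rep(rep(seq_len(g), each = m * t), times = cnd)
  mem <- rep(rep(seq_len(m), each = t), times = cnd * g)
  per <- rep(seq_len(t), times = cnd * g * m)
  group_id <- sprintf("c%dg%02d", cond, grp)
  member_id <- if (cohort)
    sprintf("%sm%03d", group_id, mem)
  else
    sprintf("%sp%dm%03d", group_id, per, mem)
  data.frame(member_id = member_id, group_id = group_id, condition = cond,
             period = per, time = design$time_values[per],
             y = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate trial data under the repeated measures ANOVA mechanism
#'
#' Draws outcomes \eqn{Y = \mu_{jl} + G_{kl} + TG_{jkl} + M_{ikl} +
#' \epsilon_{ijkl}} with independent normal random effects: a group
#' intercept, a time-by-group intercept per period, a member intercept
#' (cohort only) and residual error.  Cross-sectional data draw a fresh set
#' of members each period.
#'
#' @param design a \code{\link{design_config}}.
#' @param vc a \code{\link{variance_components}} object with
#'   \code{mechanism = "RM"} and structure matching the design.
#' @param fx optional \code{\link{fixed_effects}}; defaults to all zero
#'   (generation under the null).
#' @param seed integer seed; identical inputs give bit-identical data.
#' @return A \code{trial_data} data frame with columns \code{member_id},
#'   \code{group_id}, \code{condition}, \code{period}, \code{time},
#'   \code{y}.
#' @examples
#' vc <- variance_components(1, 1, sigma2_e = 18)
#' d  <- simulate_rm(design_config(groups_per_condition = 4,
#'                                 members_per_group = 5), vc, seed = 1)
#' @export
simulate_rm <- function(design, vc, fx = NULL, seed) {
  stopifnot(inherits(design, "design_config"),
            inherits(vc, "variance_components"))
  if (vc$mechanism != "RM")
    stop("simulate_rm requires RM-mechanism variance components",
         call. = FALSE)
  check_vc_design(vc, design)
  mu_jc <- fixed_effect_means(fx, design, "RM")
  df <- trial_frame(design)
  set.seed(as.integer(seed))
  cnd <- design$n_conditions; g <- design$groups_per_condition
  m <- design$members_per_group; t <- design$n_periods
  ng <- cnd * g
  gidx <- rep(seq_len(ng), each = m * t)           # group index per row
  G <- rnorm(ng, 0, sqrt(vc$sigma2_g))
  TG <- matrix(rnorm(ng * t, 0, sqrt(vc$sigma2_tg)), ng, t)
  y <- mu_jc[cbind(df$period, df$condition)] + G[gidx] +
    TG[cbind(gidx, df$period)]
  if (design$structure == "cohort") {
    midx <- rep(seq_len(ng * m), each = t)
    M <- rnorm(ng * m, 0, sqrt(vc$sigma2_m))
    y <- y + M[midx]
  }
  y <- y + rnorm(nrow(df), 0, sqrt(vc$sigma2_e))
  df$y <- y
  new_trial_data(df, design, "RM")
}

#' Simulate trial data under the random coefficients mechanism
#'
#' Draws outcomes \eqn{Y = \mu_{jl} + G_{kl} + T_{(lin)}G_{kl} t_j + M_{ikl}
#' + T_{(lin)}M_{ikl} t_j + \epsilon} with independent normal group and
#' member intercepts and slopes.  Intercepts and slopes are drawn
#' independently by default; \code{rho_g} / \code{rho_m} introduce an
#' intercept-slope correlation at the group / member level.
#'
#' @inheritParams simulate_rm
#' @param vc a \code{\link{variance_components}} with
#'   \code{mechanism = "RC"}: \code{sigma2_tg} is the group slope variance
#'   and \code{sigma2_tm} the member slope variance.
#' @param rho_g,rho_m intercept-slope correlations (default 0).
#' @return A \code{trial_data} data frame.
#' @export
simulate_rc <- function(design, vc, fx = NULL, seed, rho_g = 0, rho_m = 0) {
  stopifnot(inherits(design, "design_config"),
            inherits(vc, "variance_components"))
  if (vc$mechanism != "RC")
    stop("simulate_rc requires RC-mechanism variance components",
         call. = FALSE)
  check_vc_design(vc, design)
  stopifnot(abs(rho_g) <= 1, abs(rho_m) <= 1)
  mu_jc <- fixed_effect_means(fx, design, "RC")
  df <- trial_frame(design)
  set.seed(as.integer(seed))
  cnd <- design$n_conditions; g <- design$groups_per_condition
  m <- design$members_per_group; t <- design$n_periods
  ng <- cnd * g
  gidx <- rep(seq_len(ng), each = m * t)
  G <- rnorm(ng, 0, sqrt(vc$sigma2_g))
  Sg <- rho_g * sqrt(vc$sigma2_tg / max(vc$sigma2_g, .Machine$double.eps)) * G +
    sqrt(1 - rho_g^2) * rnorm(ng, 0, sqrt(vc$sigma2_tg))
  y <- mu_jc[cbind(df$period, df$condition)] + G[gidx] + Sg[gidx] * df$time
  if (design$structure == "cohort") {
    midx <- rep(seq_len(ng * m), each = t)
    M <- rnorm(ng * m, 0, sqrt(vc$sigma2_m))
    Sm <- rho_m * sqrt(vc$sigma2_tm / max(vc$sigma2_m, .Machine$double.eps)) * M +
      sqrt(1 - rho_m^2) * rnorm(ng * m, 0, sqrt(vc$sigma2_tm))
    y <- y + M[midx] + Sm[midx] * df$time
  }
  y <- y + rnorm(nrow(df), 0, sqrt(vc$sigma2_e))
  df$y <- y
  new_trial_data(df, design, "RC")
}

#' Simulate trial data
#'
#' Dispatches to \code{\link{simulate_rm}} or \code{\link{simulate_rc}}
#' according to the mechanism of \code{vc}.
#'
#' @inheritParams simulate_rm
#' @param ... passed to the mechanism-specific simulator.
#' @return A \code{trial_data} data frame.
#' @export
simulate_trial <- function(design, vc, fx = NULL, seed, ...) {
  if (vc$mechanism == "RM") simulate_rm(design, vc, fx, seed)
  else simulate_rc(design, vc, fx, seed, ...)
}

#' Method-of-moments correlation estimates from simulated datasets
#'
#' Pools ANOVA-type moment estimators of the within-period ICC, cluster
#' autocorrelation and (cohort) individual autocorrelation across one or
#' more datasets, under the RM-ANOVA definitional mapping.  Used to verify
#' that the simulator reproduces its configured correlation targets; the
#' Monte Carlo standard errors are the across-dataset standard deviations
#' of the per-dataset estimates divided by \eqn{\sqrt{n_{datasets}}}.
#'
#' Per dataset the estimators are: within-cell (group x period) pooled
#' variance \eqn{\hat\sigma^2_w}; between-group variance of cell means
#' within periods minus \eqn{\hat\sigma^2_w / m} for the group-level
#' variance sum; the average cross-period covariance of group cell means
#' and (cohort) of member outcomes for the CAC / IAC components.
#'
#' Correlation ratios are formed by pooling the unbiased variance-component
#' estimates across datasets before taking the ratio (a mean of
#' per-dataset ratios would carry a finite-sample ratio bias); the Monte
#' Carlo standard errors are leave-one-dataset-out jackknife estimates.
#'
#' @param datasets a \code{trial_data} object or a list of them (all from
#'   the same design).
#' @return A list with elements \code{wpicc}, \code{cac}, \code{iac} (each
#'   \code{list(estimate, se)}; IAC is \code{NA} for cross-sectional data)
#'   and \code{n_datasets}.
#' @export
empirical_moments <- function(datasets) {
  if (inherits(datasets, "trial_data")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  per_ds <- lapply(datasets, moments_one)
  comp <- function(field) vapply(per_ds, `[[`, numeric(1), field)
  s2_gsum <- comp("s2_gsum"); s2_w <- comp("s2_w")
  s2_g <- comp("s2_g"); s2_m <- comp("s2_m")
  ratio <- function(num, den) {
    if (all(is.na(num))) return(list(estimate = NA_real_, se = NA_real_))
    n <- length(num)
    est <- mean(num) / mean(den)
    if (n == 1) return(list(estimate = est, se = NA_real_))
    loo <- (sum(num) - num) / (sum(den) - den)
    list(estimate = est,
         se = sqrt((n - 1) / n * sum((loo - mean(loo))^2)))
  }
  list(wpicc = ratio(s2_gsum, s2_gsum + s2_w),
       cac = ratio(s2_g, s2_gsum),
       iac = ratio(s2_m, s2_w),
       n_datasets = length(datasets))
}

moments_one <- function(d) {
  design <- attr(d, "design")
  m <- design$members_per_group
  t <- design$n_periods
  nc <- design$n_conditions
  if (design$groups_per_condition < 2)
    stop("moment estimators need at least two groups per condition",
         call. = FALSE)
  # center at period x condition cell means so nonzero fixed effects do not
  # leak into the variance components
  cellkey <- interaction(d$period, d$condition, drop = TRUE)
  yc <- d$y - stats::ave(d$y, cellkey)
  G <- design$groups_per_condition * nc
  # t x m x G array of centered outcomes: rows periods, columns members
  # (cross-sectional "members" are the i-th individual sampled per period)
  if (design$structure == "cohort") {
    ord <- order(d$group_id, d$member_id, d$period)
    grand <- array(yc[ord], c(t, m, G))
  } else {
    ord <- order(d$group_id, d$period, d$member_id)
    grand <- aperm(array(yc[ord], c(m, t, G)), c(2, 1, 3))
  }
  cellmean <- apply(grand, c(1, 3), mean)                     # t x G
  gmat <- t(cellmean)                                         # G x t
  dev <- grand - aperm(array(cellmean, c(t, G, m)), c(1, 3, 2))
  # pooled within-cell variance: sigma2_m + sigma2_tm + sigma2_e (cohort)
  # or sigma2_e (cross-sectional); df = G*t*(m-1)
  s2_w <- sum(dev^2) / (G * t * (m - 1))
  # per-period variance of group means within condition, df = G - nc:
  # sigma2_g + sigma2_tg + s2_w / m
  v_between <- mean(colSums(gmat^2) / (G - nc))
  s2_gsum <- v_between - s2_w / m
  wp <- s2_gsum / (s2_gsum + s2_w)
  # cross-period covariance of group means: sigma2_g (+ sigma2_m / m cohort)
  cp <- crossprod(gmat) / (G - nc)                             # t x t
  c1 <- mean(cp[upper.tri(cp)])
  if (design$structure == "cohort") {
    # same-member cross-period covariance of within-cell deviations:
    # E[sum over members] = G*(m-1)*sigma2_m per period pair
    devm <- matrix(dev, nrow = t)                              # t x (m*G)
    mp <- tcrossprod(devm) / (G * (m - 1))
    s2_m <- mean(mp[upper.tri(mp)])
    s2_g <- c1 - s2_m / m
  } else {
    s2_g <- c1
    s2_m <- NA_real_
  }
  list(s2_w = s2_w, s2_gsum = s2_gsum, s2_g = s2_g, s2_m = s2_m,
       wpicc = wp)
}
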