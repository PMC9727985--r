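# Monte Carlo estimation of type I error rates over scenario grids.

#' Define a Monte Carlo scenario
#'
#' One cell of a simulation study: a design, a generating mechanism with
#' its variance components, the analytic models to apply, the replication
#' count and significance level, and a base seed.  Fixed effects default
#' to all-zero (generation under the null hypothesis of no
#' time-by-condition interaction), so the rejection proportion estimates
#' the type I error rate.
#'
#' @param design a \code{\link{design_config}}.
#' @param vc a \code{\link{variance_components}} object (its mechanism
#'   selects the simulator).
#' @param models list of \code{\link{analytic_model}} / \code{model_spec}
#'   objects, or character family names (expanded with the scenario's
#'   structure).
#' @param n_reps number of replications.
#' @param alpha nominal significance level.
#' @param base_seed integer; every replication seed is derived from it (see
#'   \code{\link{replication_seed}}), so any single replication can be
#'   replayed in isolation.
#' @param df_method \code{"KR"} or \code{"BW"}.
#' @param fx optional nonzero \code{\link{fixed_effects}} (turns the study
#'   into a power estimate).
#' @param label optional scenario label carried into the results table.
#' @return An object of class \code{"mc_scenario"}.
#' @export
mc_scenario <- function(design, vc, models, n_reps = 300, alpha = 0.05,
                        base_seed = 1, df_method = c("KR", "BW"), fx = NULL,
                        label = NULL) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(design, "design_config"),
            inherits(vc, "variance_components"), n_reps >= 1,
            alpha > 0, alpha <= 1)
  specs <- lapply(models, function(mod) {
    if (inherits(mod, "model_spec")) return(mod)
    if (is.character(mod))
      mod <- analytic_model(mod, structure = design$structure)
    make_spec(mod, df_method = df_method)
  })
  structure(list(design = design, vc = vc, specs = specs,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 base_seed = as.integer(base_seed), df_method = df_method,
                 fx = fx, label = label),
            class = "mc_scenario")
}

#' Seed of a single replication
#'
#' Deterministic derivation of the per-replication simulation seed from a
#' scenario base seed, kept below 2^31 so any flagged replication can be
#' replayed with \code{simulate_trial(..., seed = replication_seed(s, r))}.
#'
#' @param base_seed scenario base seed.
#' @param rep replication index (1-based).
#' @return An integer seed.
#' @export
replication_seed <- function(base_seed, rep) {
  as.integer((as.double(base_seed) * 48271 + as.double(rep) * 16807) %%
               2147483647)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Run one Monte Carlo scenario
#'
#' For each replication: simulate a dataset under the scenario's mechanism,
#' fit every analytic model by unconstrained REML, test the
#' time-by-condition interaction with the scenario's df method and record
#' whether \eqn{p \le \alpha}.  Rejection rates are computed over converged
#' fits only; non-convergent replications are counted and reported.
#'
#' @param s an \code{\link{mc_scenario}}.
#' @param keep_pvalues logical; attach the per-replication p-value matrix.
#' @param verbose print per-scenario progress.
#' @return A data frame with one row per analytic model: scenario
#'   descriptors, \code{n_reps}, \code{n_failed}, \code{rejection_rate},
#'   Wilson 95\% interval bounds.  Attribute \code{"pvalues"} holds the
#'   replication x model p-value matrix when requested.
#' @examples
#' \donttest{
#' vc <- variance_components(1, 1, sigma2_e = 18)
#' s <- mc_scenario(design_config(groups_per_condition = 5,
#'                                members_per_group = 10),
#'                  vc, models = list("rm_vc"), n_reps = 20, base_seed = 3)
#' run_scenario(s)
#' }
#' @export
run_scenario <- function(s, keep_pvalues = FALSE, verbose = FALSE) {
  stopifnot(inherits(s, "mc_scenario"))
  nm <- length(s$specs)
  pvals <- matrix(NA_real_, s$n_reps, nm)
  colnames(pvals) <- vapply(s$specs, spec_id, character(1))
  for (r in seq_len(s$n_reps)) {
    d <- simulate_trial(s$design, s$vc, fx = s$fx,
                        seed = replication_seed(s$base_seed, r))
    for (j in seq_len(nm)) {
      fit <- reml_fit(d, s$specs[[j]])
      if (isTRUE(fit$converged)) {
        tst <- test_interaction(fit)
        pvals[r, j] <- tst$p_value
      }
    }
    if (verbose && r %% 50 == 0)
      message(sprintf("  replication %d/%d", r, s$n_reps))
  }
  rows <- lapply(seq_len(nm), function(j) {
    sp <- s$specs[[j]]
    p <- pvals[, j]
    nconv <- sum(!is.na(p))
    nrej <- sum(p <= s$alpha, na.rm = TRUE)
    rate <- if (nconv > 0) nrej / nconv else NA_real_
    ci <- wilson_interval(nrej, nconv)
    data.frame(label = if (is.null(s$label)) NA_character_ else s$label,
               mechanism = s$vc$mechanism, structure = s$design$structure,
               g = s$design$groups_per_condition,
               m = s$design$members_per_group,
               t = s$design$n_periods,
               wpicc = wpicc(s$vc), cac = cac(s$vc),
               iac = if (s$vc$structure == "cohort") iac(s$vc) else NA_real_,
               model = sp$family, timexgroup = sp$timexgroup,
               df_method = sp$df_method, alpha = s$alpha,
               n_reps = s$n_reps, n_failed = s$n_reps - nconv,
               rejection_rate = rate, ci_low = ci[1], ci_high = ci[2],
               base_seed = s$base_seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (keep_pvalues) attr(out, "pvalues") <- pvals
  out
}

spec_id <- function(sp) {
  paste0(sp$family, if (!sp$timexgroup) "_intercept_only", "_", sp$df_method)
}

#' Run a grid of scenarios
#'
#' Executes each scenario in turn and stacks the tidy result rows.  A
#' failing scenario is recorded (one row with \code{NA} rate and the error
#' message in \code{label}) and the run continues.
#'
#' @param scenarios a list of \code{\link{mc_scenario}} objects, or a path
#'   to a YAML/JSON configuration file (see
#'   \code{\link{read_grid_config}}).
#' @param verbose print per-scenario progress.
#' @return A data frame, one row per scenario x analytic model; identical
#'   for identical seeds.
#' @export
grid_run <- function(scenarios, verbose = FALSE) {
  if (is.character(scenarios)) scenarios <- read_grid_config(scenarios)
  if (inherits(scenarios, "mc_scenario")) scenarios <- list(scenarios)
  out <- list()
  for (i in seq_along(scenarios)) {
    s <- scenarios[[i]]
    if (verbose)
      message(sprintf("scenario %d/%d (%s %s, g=%d, WPICC=%.4g)", i,
                      length(scenarios), s$vc$mechanism, s$design$structure,
                      s$design$groups_per_condition, wpicc(s$vc)))
    res <- tryCatch(run_scenario(s, verbose = verbose),
                    error = function(e)
                      data.frame(label = paste("scenario failed:",
                                               conditionMessage(e)),
                                 stringsAsFactors = FALSE))
    out[[i]] <- res
  }
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(df) {
    for (miss in setdiff(nm, names(df))) df[[miss]] <- NA
    df[nm]
  })
  do.call(rbind, out)
}
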