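# Enzyme-kinetics fitting: the Hill velocity equation, the
# noncompetitive-inhibition extension, inhibition-constant fold changes,
# catalytic efficiency, and combined-inhibitor activity surfaces.

#' Hill velocity equation
#'
#' `v = V_max * S^H / (K_m^H + S^H)`: velocity as a function of substrate
#' concentration with cooperativity `H`.
#'
#' @param S Substrate concentration (uM).
#' @param V_max Maximal velocity.
#' @param K_m Michaelis (half-saturation) constant (uM).
#' @param H Hill coefficient.
#' @return Velocity, same length as `S`.
#' @export
hill_velocity <- function(S, V_max, K_m, H) {
  V_max * S^H / (K_m^H + S^H)
}

#' Noncompetitive inhibition velocity equation
#'
#' `v = V_max * S^H / ((K_m^H + S^H) * (1 + (I/K_i)^h_I))`: the Hill
#' equation scaled by a noncompetitive inhibition term. With the default
#' inhibitor exponent `h_I = 1` the term is the classical `1 + I/K_i`; the
#' exponent is configurable because hyperbolic and sigmoidal inhibitor
#' binding are both seen in practice.
#'
#' @inheritParams hill_velocity
#' @param I Inhibitor concentration (uM).
#' @param K_i Inhibition constant (uM).
#' @param h_I Inhibitor-term exponent (default 1).
#' @return Velocity, same length as `S`/`I`.
#' @export
inhibition_velocity <- function(S, I, V_max, K_m, H, K_i, h_I = 1) {
  hill_velocity(S, V_max, K_m, H) / (1 + (I / K_i)^h_I)
}

.r_squared <- function(obs, fitted) {
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

.kinetic_fit <- function(estimates, se, r2, residuals, model, fit) {
  structure(list(estimates = estimates, se = se, r_squared = r2,
                 residuals = residuals, model = model,
                 poor_fit = r2 < 0.95, fit = fit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit (%s): %s | R^2 = %.4f%s\n", x$model,
              paste(names(x$estimates),
                    signif(x$estimates, 4), sep = "=", collapse = ", "),
              x$r_squared, if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}

# Multi-start nonlinear least squares on log-parameters (positivity by
# construction). `starts` is a list of named numeric vectors on the natural
# scale; the best-converged fit by residual sum of squares wins.
.fit_log_nls <- function(formula_fn, data, starts) {
  best <- NULL
  errors <- character(0)
  for (st in starts) {
    lst <- as.list(log(st))
    names(lst) <- paste0("l", names(st))
    fit <- tryCatch(
      minpack.lm::nlsLM(formula_fn, data = data, start = lst,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best))
    stop("fit failure: no start converged (",
         paste(unique(errors), collapse = "; "), ")")
  best
}

.log_spaced_starts <- function(base, n_starts, factors = c(0.3, 1, 3)) {
  starts <- list(base)
  grid <- expand.grid(lapply(base, function(v) v * factors))
  for (i in seq_len(nrow(grid))) {
    st <- stats::setNames(as.numeric(grid[i, ]), names(base))
    if (!isTRUE(all.equal(st, base))) starts[[length(starts) + 1L]] <- st
  }
  starts[seq_len(min(length(starts), n_starts))]
}

#' Fit the Hill equation to uninhibited velocity data
#'
#' Nonlinear least squares on log-parameters (Levenberg-Marquardt) with
#' method-of-moments initial values and log-spaced multi-starts. Fits with
#' `R^2 < 0.95` are flagged poor.
#'
#' @param data Data frame with columns `substrate_uM` and `velocity`; rows
#'   with `inhibitor_uM > 0`, if present, are dropped. At least 5 distinct
#'   substrate concentrations are required.
#' @param n_starts Maximum number of starting points (default 10).
#' @return A `kinetic_fit` with estimates `V_max`, `K_m`, `H`.
#' @export
fit_hill <- function(data, n_starts = 10) {
  if ("inhibitor_uM" %in% names(data)) data <- data[data$inhibitor_uM == 0, ]
  data <- data[data$substrate_uM > 0, ]
  if (length(unique(data$substrate_uM)) < 5L)
    stop("need >= 5 distinct substrate concentrations to fit the Hill model")
  vmax0 <- max(data$velocity)
  if (vmax0 <= 0) stop("fit failure: no positive velocities")
  half <- vmax0 / 2
  km0 <- data$substrate_uM[which.min(abs(data$velocity - half))]
  base <- c(V_max = vmax0 * 1.05, K_m = max(km0, 1e-6), H = 1.5)
  fit <- .fit_log_nls(
    velocity ~ exp(lV_max) * substrate_uM^exp(lH) /
      (exp(lK_m)^exp(lH) + substrate_uM^exp(lH)),
    data, .log_spaced_starts(base, n_starts))
  cf <- exp(stats::coef(fit))
  names(cf) <- sub("^l", "", names(cf))
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  se <- cf * se_log[paste0("l", names(cf))]
  names(se) <- names(cf)
  resid <- data$velocity - stats::fitted(fit)
  .kinetic_fit(cf[c("V_max", "K_m", "H")], se[c("V_max", "K_m", "H")],
               .r_squared(data$velocity, stats::fitted(fit)),
               resid, "eq1", fit)
}

#' Fit the noncompetitive-inhibition model with fixed Hill coefficient
#'
#' Fits `v = V_max * S^H / ((K_m^H + S^H) * (1 + I/K_i))` with `H` held at
#' the value estimated from the uninhibited (Hill-equation) fit.
#'
#' @param data Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `velocity`; at least two distinct inhibitor levels including 0.
#' @param H Fixed Hill coefficient, or a `kinetic_fit` from [fit_hill].
#' @param n_starts Maximum number of starting points (default 10).
#' @param h_I Inhibitor-term exponent (default 1; see
#'   [inhibition_velocity]).
#' @return A `kinetic_fit` with estimates `V_max`, `K_m`, `H` (fixed),
#'   `K_i`.
#' @export
fit_inhibition <- function(data, H, n_starts = 10, h_I = 1) {
  if (inherits(H, "kinetic_fit")) H <- H$estimates[["H"]]
  data <- data[data$substrate_uM > 0, ]
  inh <- unique(data$inhibitor_uM)
  if (all(data$inhibitor_uM == 0))
    stop("unidentifiable K_i: all rows have inhibitor concentration 0")
  if (length(inh) < 2L || !any(inh == 0))
    stop("need >= 2 distinct inhibitor concentrations including 0")
  d0 <- data[data$inhibitor_uM == 0, ]
  vmax0 <- max(d0$velocity)
  km0 <- d0$substrate_uM[which.min(abs(d0$velocity - vmax0 / 2))]
  # moment start for K_i: v(I)/v(0) = 1/(1 + I/K_i) at matched substrate
  v0_by_s <- tapply(d0$velocity, d0$substrate_uM, mean)
  di <- data[data$inhibitor_uM > 0, ]
  ratio <- di$velocity / as.numeric(v0_by_s[as.character(di$substrate_uM)])
  ki_each <- di$inhibitor_uM / pmax(1 / pmax(ratio, 1e-6) - 1, 1e-6)
  ki0 <- stats::median(ki_each, na.rm = TRUE)
  if (!is.finite(ki0) || ki0 <= 0) ki0 <- stats::median(di$inhibitor_uM)
  base <- c(V_max = vmax0 * 1.05, K_m = max(km0, 1e-6), K_i = ki0)
  env_H <- H; env_hI <- h_I
  fit <- .fit_log_nls(
    velocity ~ exp(lV_max) * substrate_uM^env_H /
      (exp(lK_m)^env_H + substrate_uM^env_H) /
      (1 + (inhibitor_uM / exp(lK_i))^env_hI),
    cbind(data, env_H = env_H, env_hI = env_hI),
    .log_spaced_starts(base, n_starts))
  cf <- exp(stats::coef(fit))
  names(cf) <- sub("^l", "", names(cf))
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  se <- cf * se_log[paste0("l", names(cf))]
  names(se) <- names(cf)
  est <- c(cf["V_max"], cf["K_m"], H = H, cf["K_i"])
  sev <- c(se["V_max"], se["K_m"], H = NA_real_, se["K_i"])
  .kinetic_fit(est, sev, .r_squared(data$velocity, stats::fitted(fit)),
               data$velocity - stats::fitted(fit), "eq2", fit)
}

#' Inhibition-constant fold change between mutant and wild type
#'
#' Ratio of mean `K_i` (mutant over wild type) with a Welch t-test on
#' log-transformed `K_i` across replicate fits (ratios are multiplicative,
#' hence the log scale).
#'
#' @param fits_mutant,fits_wt Lists of `kinetic_fit` objects (or numeric
#'   `K_i` vectors) for replicate datasets.
#' @return List with `ratio`, `p` (`NA` when either group has a single
#'   replicate), `ki_mutant`, `ki_wt`.
#' @export
fold_change <- function(fits_mutant, fits_wt) {
  get_ki <- function(fits) {
    if (is.numeric(fits)) return(fits)
    if (inherits(fits, "kinetic_fit")) fits <- list(fits)
    vapply(fits, function(f) f$estimates[["K_i"]], 0)
  }
  km <- get_ki(fits_mutant); kw <- get_ki(fits_wt)
  ratio <- mean(km) / mean(kw)
  p <- if (length(km) >= 2L && length(kw) >= 2L) {
    if (stats::sd(log(km)) == 0 && stats::sd(log(kw)) == 0 &&
        isTRUE(all.equal(mean(log(km)), mean(log(kw))))) 1
    else stats::t.test(log(km), log(kw))$p.value
  } else NA_real_
  list(ratio = ratio, p = p, ki_mutant = km, ki_wt = kw)
}

#' Catalytic efficiency from a kinetic fit
#'
#' `k_cat = V_max / [E]` with the enzyme concentration computed from the
#' assay mass, volume, and the (user-supplied) molar mass;
#' efficiency is `k_cat / K_m`.
#'
#' @param fit A `kinetic_fit` (or list with `estimates`).
#' @param enzyme_mass_ug Enzyme mass in the assay (micrograms).
#' @param volume_ul Assay volume (microliters).
#' @param molar_mass Enzyme molar mass (g/mol).
#' @return List: `enzyme_uM`, `k_cat` (velocity-units per uM enzyme),
#'   `efficiency` (`k_cat / K_m`, per uM per velocity time unit).
#' @export
catalytic_efficiency <- function(fit, enzyme_mass_ug, volume_ul,
                                 molar_mass) {
  if (enzyme_mass_ug <= 0 || volume_ul <= 0 || molar_mass <= 0)
    stop("invalid input: mass, volume and molar mass must be positive")
  e_uM <- enzyme_mass_ug * 1e6 / (molar_mass * volume_ul)
  k_cat <- fit$estimates[["V_max"]] / e_uM
  list(enzyme_uM = e_uM, k_cat = k_cat,
       efficiency = k_cat / fit$estimates[["K_m"]])
}

#' Relative-activity surface over a two-inhibitor grid
#'
#' Evaluates `v(S, I_A, I_G) / v(S, 0, 0)` under independent multiplicative
#' noncompetitive terms, `1 / ((1 + I_A/K_iA) * (1 + I_G/K_iG))`; the ratio
#' is substrate-independent, so the surface characterizes the enzyme's
#' resistance to simultaneous inhibition (e.g. AMP 0-500 uM against
#' Glc-6-P 0-5000 uM).
#'
#' @param K_i_a Inhibition constant for the first inhibitor (uM).
#' @param K_i_g Inhibition constant for the second inhibitor (uM).
#' @param a_range,g_range Concentration grids (uM), each starting at 0.
#' @return Matrix of relative activities in `(0, 1]`, rows indexed by
#'   `a_range`, columns by `g_range`; cell (0,0) is exactly 1.
#' @export
activity_grid <- function(K_i_a, K_i_g,
                          a_range = seq(0, 500, length.out = 11),
                          g_range = seq(0, 5000, length.out = 11)) {
  if (length(a_range) == 0L || length(g_range) == 0L)
    stop("invalid input: empty concentration range")
  if (K_i_a <= 0 || K_i_g <= 0)
    stop("invalid input: inhibition constants must be positive")
  m <- outer(1 / (1 + a_range / K_i_a), 1 / (1 + g_range / K_i_g))
  dimnames(m) <- list(a_range, g_range)
  m
}

#' Simulate and refit inhibition-constant fold changes
#'
#' Parameter-recovery study for the two-equation fitting pipeline: for each
#' seed, wild-type and mutant velocity datasets are simulated from the
#' noncompetitive model (mutant `K_i` = `fold * ki_wt`), each on a grid of
#' `n_substrate` substrate levels spanning 0.2-5x `K_m` and `n_inhibitor`
#' inhibitor levels (0 plus a log-spaced span of 0.2-5x the genotype's own
#' `K_i`), with multiplicative Gaussian noise. The Hill coefficient is
#' estimated from the uninhibited rows and held fixed in the inhibition
#' fit; the fitted mutant/wild-type `K_i` ratio is recorded per seed.
#'
#' @param fold True fold change of the mutant `K_i` over wild type.
#' @param ki_wt Wild-type `K_i` (uM; default 20, an AMP-site scale; use
#'   e.g. 200 for a Glc-6-P-site scale).
#' @param V_max,K_m,H Shared generating parameters (defaults 1, 50 uM, 2).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Replicates per grid point (default 3).
#' @param n_substrate,n_inhibitor Grid sizes (default 8 x 8).
#' @param n_seeds Number of simulated dataset pairs (default 20).
#' @param seed Base integer seed; per-run seeds are derived from it.
#' @return List with `ratios` (per seed), `median_ratio`, and the true
#'   `fold`.
#' @export
simulate_ki_recovery <- function(fold, ki_wt = 20, V_max = 1, K_m = 50,
                                 H = 2, noise_cv = 0.05, n_replicates = 3,
                                 n_substrate = 8, n_inhibitor = 8,
                                 n_seeds = 20, seed = 1) {
  s_levels <- exp(seq(log(0.2 * K_m), log(5 * K_m),
                      length.out = n_substrate))
  base <- (as.integer(seed) %% 1000000L) * 1000L
  run_one <- function(ki, run_seed) {
    i_levels <- c(0, exp(seq(log(0.2 * ki), log(5 * ki),
                             length.out = n_inhibitor - 1)))
    des <- kinetic_design(s_levels, i_levels,
                          true_params = list(V_max = V_max, K_m = K_m,
                                             H = H, K_i = ki),
                          noise_cv = noise_cv,
                          n_replicates = n_replicates, seed = run_seed)
    dat <- gen_kinetic_data(des, model = "eq2")
    h <- fit_hill(dat)
    fit_inhibition(dat, h)$estimates[["K_i"]]
  }
  ratios <- vapply(seq_len(n_seeds), function(k) {
    ki_w <- run_one(ki_wt, base + 2L * k)
    ki_m <- run_one(ki_wt * fold, base + 2L * k + 1L)
    ki_m / ki_w
  }, 0)
  list(ratios = ratios, median_ratio = stats::median(ratios), fold = fold)
}

#' Read a velocity table from CSV
#'
#' @param path CSV with columns `substrate_uM`, `inhibitor_uM`,
#'   `replicate`, `velocity`.
#' @return Data frame.
#' @export
read_kinetic_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("substrate_uM", "inhibitor_uM", "replicate", "velocity")
  if (!all(req %in% names(d)))
    stop("kinetic CSV must have columns: ", paste(req, collapse = ", "))
  if (any(d$substrate_uM < 0) || any(d$inhibitor_uM < 0))
    stop("invalid data: negative concentrations")
  d
}
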