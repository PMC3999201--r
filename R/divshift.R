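# Diversification model selection on chronograms: constant-rate pure-birth
# and birth-death fits, piecewise pure-birth (2- and 3-rate) fits with
# shifts at observed branching times, the delta-AIC_rc statistic with a
# simulated critical value, posterior-ensemble shift summaries, and the
# Magallon-Sanderson net diversification estimators.
#
# All model log-likelihoods drop the same combinatorial constants, so AIC
# values are comparable across models on the same tree.

new_rate_fit <- function(model, rates, shift_ages, extinction_fraction,
                         logL, n_params, n) {
  structure(
    list(model = model, rates = rates, shift_ages = shift_ages,
         extinction_fraction = extinction_fraction, logL = logL,
         n_params = n_params, aic = -2 * logL + 2 * n_params, n = n),
    class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL %.4f, AIC %.4f\n", x$model, x$logL, x$aic))
  cat(sprintf("  rates (old->young): %s\n",
              paste(sprintf("%.5g", x$rates), collapse = ", ")))
  if (length(x$shift_ages) > 0L) {
    cat(sprintf("  shift ages: %s\n",
                paste(sprintf("%.5g", x$shift_ages), collapse = ", ")))
  }
  if (!is.null(x$extinction_fraction) && !is.na(x$extinction_fraction)) {
    cat(sprintf("  extinction fraction: %.4f\n", x$extinction_fraction))
  }
  invisible(x)
}

# sufficient statistics shared by the fits
bt_stats <- function(x) {
  bt <- branching_times(x)
  n <- bt$n
  t <- unname(bt$ages)              # t_2 .. t_n, decreasing
  xk <- unname(bt$durations)        # x_2 .. x_n
  S <- sum(seq(2L, n) * xk)         # total lineage-time below the crown
  list(bt = bt, n = n, t = t, xk = xk, S = S)
}

#' Fit a constant-rate pure-birth (Yule) model
#'
#' Conditioned on the crown event, the log-likelihood is
#' `(n - 2) log(lambda) - lambda * S` with `S = sum_k k x_k` the total
#' lineage-time, maximized in closed form at `lambda = (n - 2) / S`.
#'
#' @param x a `chronogram`, `phylo` or [branching_times()] object with
#'   >= 3 tips.
#' @return a `rate_fit` (1 parameter).
#' @export
fit_pure_birth <- function(x) {
  s <- bt_stats(x)
  if (s$n < 3L) stopf("pure-birth fit needs >= 3 tips")
  if (s$S <= 0) stopf("degenerate input: zero total lineage-time")
  lambda <- (s$n - 2L) / s$S
  logL <- (s$n - 2L) * log(lambda) - lambda * s$S
  new_rate_fit("pureBirth", rates = lambda, shift_ages = numeric(0),
               extinction_fraction = NA_real_, logL = logL, n_params = 1L,
               n = s$n)
}

# log-likelihood of the reconstructed constant birth-death process,
# parameterized by net rate r and extinction fraction a = mu/lambda;
# written in overflow-safe form (equals the pure-birth expression at a = 0)
bd_loglik <- function(r, a, n, t, S) {
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  (n - 2L) * log(r) - r * S + n * log1p(-a) - 2 * sum(log1p(-a * exp(-r * t)))
}

#' Fit a constant-rate birth-death model to branching times
#'
#' Maximizes the reconstructed-process likelihood over the net
#' diversification rate `r = lambda - mu` and extinction fraction
#' `a = mu / lambda` (multi-start box-constrained optimization; the
#' pure-birth solution seeds one start, so the fit never falls below the
#' nested pure-birth likelihood).
#'
#' @inheritParams fit_pure_birth
#' @return a `rate_fit` (2 parameters) whose `rates` holds the net rate
#'   `r` and `extinction_fraction` holds `a`.
#' @export
fit_bd_constant <- function(x) {
  s <- bt_stats(x)
  if (s$n < 3L) stopf("birth-death fit needs >= 3 tips")
  pb <- fit_pure_birth(x)
  obj <- function(par) {
    ll <- bd_loglik(exp(par[[1L]]), par[[2L]], s$n, s$t, s$S)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  starts <- rbind(c(log(pb$rates), 0),
                  c(log(pb$rates / 2), 0.5),
                  c(log(pb$rates / 5), 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = c(log(1e-10), 0), upper = c(log(1e10), 1 - 1e-9),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("fit-failure: birth-death optimization did not converge")
  new_rate_fit("bd", rates = exp(best$par[[1L]]), shift_ages = numeric(0),
               extinction_fraction = best$par[[2L]], logL = -best$value,
               n_params = 2L, n = s$n)
}

# per-epoch profile contribution: E events over lineage-time LT
epoch_ll <- function(E, LT) {
  out <- numeric(length(E))
  pos <- E > 0 & LT > 0
  out[pos] <- E[pos] * (log(E[pos] / LT[pos]) - 1)
  out[E > 0 & LT <= 0] <- -Inf
  out
}

#' Fit a pure-birth model with 2 or 3 epoch rates
#'
#' Shift ages are searched exhaustively over the observed branching times
#' (the event at a shift age closes the older epoch); within each epoch
#' the rate MLE is events / lineage-time.  AIC counts `2k - 1` parameters
#' (k rates plus k - 1 shift ages).
#'
#' @inheritParams fit_pure_birth
#' @param k number of epochs, 2 or 3; needs `n >= k + 2` tips.
#' @return a `rate_fit` with `rates` oldest epoch first and `shift_ages`
#'   decreasing.
#' @export
fit_yule_k_rate <- function(x, k = 2L) {
  if (!(k %in% c(2L, 3L))) stopf("`k` must be 2 or 3")
  s <- bt_stats(x)
  n <- s$n
  if (n < k + 2L) stopf("yule-%d-rate fit needs >= %d tips", k, k + 2L)
  # cumulative events / lineage-time at boundary index j in 2..(n+1):
  # boundary j means "shift at age t_j" (j = 2: crown; j = n+1: present)
  LTcum <- c(0, cumsum(seq(2L, n) * s$xk))          # index by j - 1
  names(LTcum) <- NULL
  ecum <- function(j) ifelse(j >= n + 1L, n - 2L, j - 2L)
  ltcum <- function(j) LTcum[pmin(j, n + 1L) - 1L]
  t_of <- function(j) s$t[j - 1L]                    # t_j, j in 2..n
  best <- NULL
  if (k == 2L) {
    for (j in seq(3L, n)) {
      E <- c(ecum(j), n - 2L - ecum(j))
      LT <- c(ltcum(j), s$S - ltcum(j))
      ll <- sum(epoch_ll(E, LT))
      if (!is.finite(ll)) next
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, rates = E / pmax(LT, .Machine$double.eps),
                     shifts = t_of(j))
      }
    }
  } else {
    for (j1 in seq(3L, n - 1L)) {
      j2 <- seq(j1 + 1L, n)
      ok <- t_of(j2) < t_of(j1)                      # strictly decreasing ages
      if (!any(ok)) next
      j2 <- j2[ok]
      E1 <- ecum(j1); LT1 <- ltcum(j1)
      E2 <- ecum(j2) - E1; LT2 <- ltcum(j2) - LT1
      E3 <- (n - 2L) - ecum(j2); LT3 <- s$S - ltcum(j2)
      ll <- epoch_ll(rep(E1, length(j2)), rep(LT1, length(j2))) +
        epoch_ll(E2, LT2) + epoch_ll(E3, LT3)
      fin <- which(is.finite(ll))
      if (length(fin) == 0L) next
      imax <- fin[which.max(ll[fin])]
      if (is.null(best) || ll[imax] > best$ll) {
        jj <- j2[imax]
        E <- c(E1, ecum(jj) - E1, (n - 2L) - ecum(jj))
        LT <- c(LT1, ltcum(jj) - LT1, s$S - ltcum(jj))
        best <- list(ll = ll[imax],
                     rates = E / pmax(LT, .Machine$double.eps),
                     shifts = c(t_of(j1), t_of(jj)))
      }
    }
  }
  if (is.null(best)) stopf("fit-failure: no admissible shift placement")
  new_rate_fit(sprintf("yule%drate", k), rates = unname(best$rates),
               shift_ages = unname(best$shifts),
               extinction_fraction = NA_real_, logL = best$ll,
               n_params = 2L * k - 1L, n = n)
}

#' Delta-AIC between best rate-constant and best rate-variable model
#'
#' Fits the constant-rate pure-birth and birth-death models and the 2- and
#' 3-rate pure-birth models, and returns
#' `delta_aic_rc = AIC(best constant) - AIC(best variable)`; positive
#' values favor rate variation.
#'
#' @inheritParams fit_pure_birth
#' @param variable which rate-variable models to consider: `"best"`
#'   (default, min AIC of the 2- and 3-rate fits), `"yule2"` or `"yule3"`.
#' @return list with `delta_aic_rc`, `best_constant`, `best_variable` and
#'   all four `fits`.
#' @export
delta_aic_rc <- function(x, variable = c("best", "yule2", "yule3")) {
  variable <- match.arg(variable)
  s <- bt_stats(x)
  if (s$n < 5L) stopf("delta_aic_rc needs >= 5 tips")
  fits <- list(pureBirth = fit_pure_birth(s$bt),
               bd = fit_bd_constant(s$bt),
               yule2rate = fit_yule_k_rate(s$bt, 2L),
               yule3rate = fit_yule_k_rate(s$bt, 3L))
  const <- fits[c("pureBirth", "bd")]
  vars <- switch(variable,
                 best = fits[c("yule2rate", "yule3rate")],
                 yule2 = fits["yule2rate"],
                 yule3 = fits["yule3rate"])
  bc <- const[[which.min(vapply(const, `[[`, numeric(1), "aic"))]]
  bv <- vars[[which.min(vapply(vars, `[[`, numeric(1), "aic"))]]
  list(delta_aic_rc = bc$aic - bv$aic, best_constant = bc, best_variable = bv,
       fits = fits)
}

#' Critical delta-AIC from constant-rate simulations
#'
#' Fits the best constant-rate model to `x`, simulates `n_sim` trees of the
#' same tip count under its maximum-likelihood parameters, computes
#' [delta_aic_rc()] for each, and returns the `alpha` quantile of the null
#' distribution.
#'
#' @inheritParams delta_aic_rc
#' @param n_sim number of null simulations.
#' @param alpha quantile returned (0.95: the conventional critical value).
#' @param seed RNG seed.
#' @return list with `critical`, the vector of null `delta_values`, the
#'   `null_model` fit used for simulation, `alpha` and `n_sim`.
#' @export
critical_delta_aic <- function(x, n_sim = 1000L, alpha = 0.95, seed = NULL,
                               variable = c("best", "yule2", "yule3")) {
  variable <- match.arg(variable)
  s <- bt_stats(x)
  pb <- fit_pure_birth(s$bt)
  bd <- fit_bd_constant(s$bt)
  null_fit <- if (bd$aic < pb$aic) bd else pb
  vals <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      tr <- tryCatch({
        if (null_fit$model == "pureBirth") {
          sim_yule(s$n, null_fit$rates)
        } else {
          a <- null_fit$extinction_fraction
          lam <- null_fit$rates / (1 - a)
          sim_bd(s$n, lam, lam * a)
        }
      }, error = function(e) NULL)
      if (is.null(tr)) return(NA_real_)
      tryCatch(delta_aic_rc(tr, variable = variable)$delta_aic_rc,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  skipped <- sum(is.na(vals))
  if (skipped > 0.05 * n_sim) {
    stopf("critical_delta_aic: %d/%d null replicates failed", skipped, n_sim)
  }
  list(critical = unname(stats::quantile(vals, alpha, na.rm = TRUE)),
       delta_values = vals, null_model = null_fit, alpha = alpha,
       n_sim = n_sim, n_skipped = skipped)
}

#' Rate-shift analysis over an ensemble of trees
#'
#' Draws `n_sample` trees (e.g. from a posterior sample), fits the constant
#' and rate-variable models to each, classifies every fitted shift as a
#' rate increase or decrease (younger epoch rate vs older), and summarizes
#' shift ages (mean and 2.5/97.5% quantile CIs) together with the fraction
#' of trees whose delta-AIC_rc exceeds the simulated critical value.
#'
#' @param trees list of trees (each coercible to `chronogram`).
#' @param n_sample number of trees to analyse.
#' @param seed RNG seed (tree sampling and null simulations).
#' @param n_sim null simulations for the critical value.
#' @param alpha critical-value quantile.
#' @param variable rate-variable model class passed to [delta_aic_rc()].
#' @param critical_mode `"pooled"` (one critical value, simulated under the
#'   across-tree median constant-rate fit; default) or `"per_tree"`.
#' @param replace sample trees with replacement.
#' @return an object of class `shift_report`; see [print.shift_report()].
#' @export
ensemble_shift_analysis <- function(trees, n_sample = 100L, seed = NULL,
                                    n_sim = 1000L, alpha = 0.95,
                                    variable = c("best", "yule2", "yule3"),
                                    critical_mode = c("pooled", "per_tree"),
                                    replace = FALSE) {
  variable <- match.arg(variable)
  critical_mode <- match.arg(critical_mode)
  seed <- if (is.null(seed)) NULL else as.integer(seed)
  sampled <- sample_trees(trees, n = n_sample, seed = seed, replace = replace)
  rows <- vector("list", length(sampled))
  inc_ages <- numeric(0); dec_ages <- numeric(0)
  const_rates <- numeric(length(sampled))
  for (i in seq_along(sampled)) {
    res <- delta_aic_rc(sampled[[i]], variable = variable)
    bv <- res$best_variable
    shift_type <- character(0)
    if (length(bv$shift_ages) > 0L) {
      shift_type <- ifelse(bv$rates[-1L] > bv$rates[-length(bv$rates)],
                           "increase", "decrease")
      inc_ages <- c(inc_ages, bv$shift_ages[shift_type == "increase"])
      dec_ages <- c(dec_ages, bv$shift_ages[shift_type == "decrease"])
    }
    const_rates[i] <- res$best_constant$rates
    rows[[i]] <- data.frame(
      tree = attr(sampled, "indices")[[i]],
      n = res$best_constant$n,
      constant_model = res$best_constant$model,
      variable_model = bv$model,
      delta_aic_rc = res$delta_aic_rc,
      shift1_age = if (length(bv$shift_ages) >= 1L) bv$shift_ages[[1L]] else NA_real_,
      shift1_type = if (length(shift_type) >= 1L) shift_type[[1L]] else NA_character_,
      shift2_age = if (length(bv$shift_ages) >= 2L) bv$shift_ages[[2L]] else NA_real_,
      shift2_type = if (length(shift_type) >= 2L) shift_type[[2L]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  per_tree <- do.call(rbind, rows)
  crit_seed <- if (is.null(seed)) NULL else seed + 1L
  if (critical_mode == "pooled") {
    ref <- sampled[[which.min(abs(const_rates - stats::median(const_rates)))]]
    crit <- critical_delta_aic(ref, n_sim = n_sim, alpha = alpha,
                               seed = crit_seed, variable = variable)
    critical <- crit$critical
    per_tree$critical <- critical
  } else {
    criticals <- vapply(seq_along(sampled), function(i) {
      critical_delta_aic(sampled[[i]], n_sim = n_sim, alpha = alpha,
                         seed = if (is.null(crit_seed)) NULL else crit_seed + i,
                         variable = variable)$critical
    }, numeric(1))
    per_tree$critical <- criticals
    critical <- stats::median(criticals)
  }
  exceed <- mean(per_tree$delta_aic_rc > per_tree$critical)
  ci <- function(v) {
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, c(0.025, 0.975)))
  }
  structure(
    list(per_tree = per_tree,
         increase_mean = if (length(inc_ages)) mean(inc_ages) else NA_real_,
         increase_ci = ci(inc_ages),
         decrease_mean = if (length(dec_ages)) mean(dec_ages) else NA_real_,
         decrease_ci = ci(dec_ages),
         critical = critical,
         exceedance_fraction = exceed,
         n_exceed = sum(per_tree$delta_aic_rc > per_tree$critical),
         n_sample = length(sampled),
         alpha = alpha, n_sim = n_sim, variable = variable,
         critical_mode = critical_mode, seed = seed),
    class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("Rate-shift ensemble: %d trees (%s variable models)\n",
              x$n_sample, x$variable))
  cat(sprintf("  increase shifts: mean %.3g Myr (95%% CI %.3g-%.3g)\n",
              x$increase_mean, x$increase_ci[[1L]], x$increase_ci[[2L]]))
  cat(sprintf("  decrease shifts: mean %.3g Myr (95%% CI %.3g-%.3g)\n",
              x$decrease_mean, x$decrease_ci[[1L]], x$decrease_ci[[2L]]))
  cat(sprintf("  critical delta-AIC_rc (alpha %.2f): %.3f; %d/%d trees exceed (%.2f)\n",
              x$alpha, x$critical, x$n_exceed, x$n_sample,
              x$exceedance_fraction))
  invisible(x)
}

#' Magallon-Sanderson net diversification rate estimators
#'
#' Net diversification `r = lambda - mu` from a standing species count `n`
#' and a clade age `t`, given a relative extinction fraction
#' `epsilon = mu / lambda`.  Stem mode uses
#' `r = log(n (1 - eps) + eps) / t`; crown mode uses the whole-clade
#' estimator
#' `r = (1/t) * (log(n (1 - eps^2) / 2 + 2 eps +
#'   (1 - eps) * sqrt(n (n eps^2 - 8 eps + 2 n eps + n)) / 2) - log 2)`.
#'
#' @param n extant species (or delimited entity) count, >= 2.
#' @param t clade age in Myr (crown or stem age according to `mode`).
#' @param epsilon extinction fraction(s) in `[0, 1)`; may be a vector.
#' @param mode `"crown"` (default) or `"stem"`.
#' @return an object of class `rate_estimate`: list with the estimate(s)
#'   `r` (lineages / lineage / Myr) and the inputs.
#' @examples
#' magallon_sanderson(47, 140, epsilon = c(0, 0.9))$r
#' @export
magallon_sanderson <- function(n, t, epsilon = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (!is_count(n, min = 2L)) stopf("`n` must be an integer >= 2")
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) stopf("`t` must be > 0")
  if (any(epsilon < 0) || any(epsilon >= 1)) {
    stopf("`epsilon` must be in [0, 1)")
  }
  r <- if (mode == "stem") {
    log(n * (1 - epsilon) + epsilon) / t
  } else {
    disc <- pmax(n * (n * epsilon^2 - 8 * epsilon + 2 * n * epsilon + n), 0)
    (log(n * (1 - epsilon^2) / 2 + 2 * epsilon +
           (1 - epsilon) * sqrt(disc) / 2) - log(2)) / t
  }
  structure(list(r = unname(r), n = n, t = t, epsilon = epsilon, mode = mode),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Net diversification (%s mode, n = %d, t = %g Myr):\n",
              x$mode, x$n, x$t))
  for (i in seq_along(x$epsilon)) {
    cat(sprintf("  epsilon = %.2g -> r = %.4g lineages/lineage/Myr\n",
                x$epsilon[[i]], x$r[[i]]))
  }
  invisible(x)
}
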