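#' Pointwise log-likelihood matrix
#'
#' Recomputes, for every stored posterior draw, the log-likelihood of every
#' observed trial (the observation unit of the LOOIC comparison) under that
#' draw's individual-level parameters.
#'
#' @param fit An [fit_advice_rl()] result.
#' @param cohort The cohort (or session list) the fit was computed on.
#' @return Numeric matrix, draws x observations, with attribute `obs_id`
#'   (`participant:trial` labels).
#' @export
pointwise_loglik_matrix <- function(fit, cohort) {
  stopifnot(inherits(fit, "advice_rl_fit"))
  sessions <- as_session_list(cohort)
  ids <- vapply(sessions, function(s) s$participant_id, "")
  if (!identical(ids, fit$participant_ids))
    stop("cohort sessions do not match the fitted participants",
         call. = FALSE)
  levels <- fit$phrasing_levels
  pk <- pack_model(fit$model, levels)
  fc <- frame_coding(fit$frame)
  subj <- lapply(sessions, function(s) pack_session(s$trials, levels))
  nip <- nrow(fit$param_table)
  d <- fit$draws
  n_draws <- dim(d)[1] * dim(d)[2]
  theta <- matrix(d[, , -(seq_len(2 * nip)), drop = FALSE],
                  nrow = n_draws)
  m <- cpp_loglik_matrix(lapply(subj, `[[`, "mat"),
                         lapply(subj, `[[`, "rew"),
                         theta, nip, pk$idx, pk$fict_self, pk$fict_adv,
                         fc$frame_code, pk$literal, fc$v_self_init)
  attr(m, "obs_id") <- unlist(lapply(sessions, function(s)
    paste(s$participant_id, s$trials$trial_index, sep = ":")))
  m
}

# Generalized Pareto fit to tail exceedances (Zhang & Stephens 2009
# profile-likelihood estimator with the weak prior regularisation on k).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), 1.0)
  l_theta <- n * (log(-theta / k_j) - k_j - 1)
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # regularise k toward 0.5 with a weak prior of 10 pseudo-observations
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

psis_smooth <- function(lw) {
  # lw: log importance ratios for one observation (length S)
  s <- length(lw)
  lw <- lw - max(lw)
  n_tail <- ceiling(0.2 * s)
  if (n_tail < 5L) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_idx <- ord[(s - n_tail + 1L):s]  # ascending within the tail
  cutpoint <- lw[ord[s - n_tail]]
  exceed <- exp(lw[tail_idx]) - exp(cutpoint)
  if (all(exceed <= 0) || stats::sd(exceed) == 0)
    return(list(lw = lw, k = -Inf))
  fitp <- gpd_fit(exceed[exceed > 0])
  qq <- qgpd((seq_len(n_tail) - 0.5) / n_tail, fitp$k, fitp$sigma)
  lw[tail_idx] <- log(exp(cutpoint) + qq)  # rank-matched replacement
  lw <- pmin(lw, 0)  # truncate at the maximum raw weight (= exp(0))
  list(lw = lw, k = fitp$k)
}

#' Pareto-smoothed importance-sampling leave-one-out estimate
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out cross-validation from a draws-by-observations
#' log-likelihood matrix: per observation the importance ratios are the
#' reciprocal likelihoods, the largest 20% of ratios are replaced by
#' quantiles of a generalized Pareto distribution fitted to them, and the
#' smoothed weights are used in a self-normalised estimate. The tail shape
#' parameter k is reported per observation; values above 0.7 indicate an
#' unreliable estimate and trigger a warning.
#'
#' @param ll Matrix of pointwise log-likelihoods (draws x observations),
#'   e.g. from [pointwise_loglik_matrix()].
#' @return Object of class `loo_result` with `elpd_loo`, `looic`
#'   (`-2 * elpd_loo`), `pointwise_elpd`, `pareto_k`, `n_observations`.
#' @export
psis_loo <- function(ll) {
  ll <- as.matrix(ll)
  if (any(!is.finite(ll))) stop("non-finite log-likelihoods", call. = FALSE)
  s <- nrow(ll)
  if (s < 100L)
    warning("fewer than 100 draws; PSIS-LOO estimates will be noisy")
  n <- ncol(ll)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    pointwise[i] <- log_sum_exp(sm$lw + ll[, i]) - log_sum_exp(sm$lw)
    k[i] <- sm$k
  }
  n_bad <- sum(k > 0.7)
  if (n_bad > 0)
    warning(n_bad, " observation(s) with Pareto k > 0.7; ",
            "LOO estimate may be unreliable")
  elpd <- sum(pointwise)
  structure(list(elpd_loo = elpd, looic = -2 * elpd,
                 pointwise_elpd = pointwise, pareto_k = k,
                 n_observations = n),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d observations: elpd_loo = %.1f, LOOIC = %.1f\n",
              x$n_observations, x$elpd_loo, x$looic))
  cat(sprintf("  Pareto k: max %.2f, %d above 0.7\n",
              max(x$pareto_k), sum(x$pareto_k > 0.7)))
  invisible(x)
}

#' Rank models by LOOIC
#'
#' Orders models by ascending LOOIC (smaller is better) and reports, for
#' each model, the pointwise elpd difference to the best model and its
#' standard error.
#'
#' @param results Named list of [psis_loo()] results computed over
#'   identical observations.
#' @return Data frame with columns `model`, `looic`, `elpd_loo`,
#'   `elpd_diff` (relative to the best model), `se_diff`.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  n_obs <- vapply(results, function(r) r$n_observations, 1L)
  if (length(unique(n_obs)) != 1L)
    stop("models were evaluated on different observation sets",
         call. = FALSE)
  looic <- vapply(results, function(r) r$looic, 1.0)
  ord <- order(looic, names(results))
  results <- results[ord]
  best <- results[[1L]]
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    d <- r$pointwise_elpd - best$pointwise_elpd
    data.frame(model = names(results)[i], looic = r$looic,
               elpd_loo = r$elpd_loo,
               elpd_diff = sum(d),
               se_diff = if (i == 1L) 0 else sqrt(length(d) * stats::var(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trial-by-trial posterior predictive check
#'
#' For `n_rep` posterior draws (subsampled without replacement), every
#' participant's choices are re-simulated on their own recorded
#' environment trace with that draw's individual parameters; per trial the
#' across-participant mean green-choice rate is computed, and the central
#' credible band across replicates is compared with the observed per-trial
#' means.
#'
#' @param fit An [fit_advice_rl()] result.
#' @param cohort The fitted cohort (or session list).
#' @param n_rep Number of posterior replicates (default 200).
#' @param seed Integer seed for subsampling and simulation.
#' @param nominal_level Credible-band level (default 0.95).
#' @return Object of class `ppc_result`: data frame `series` (`trial`,
#'   `observed`, `lower`, `upper`), plus `coverage` (fraction of trials
#'   whose observed mean falls inside the band) and `nominal_level`.
#' @export
posterior_predictive_check <- function(fit, cohort, n_rep = 200L, seed = 1L,
                                       nominal_level = 0.95) {
  stopifnot(inherits(fit, "advice_rl_fit"))
  n_rep <- as.integer(n_rep)
  if (n_rep < 1L) stop("n_rep must be >= 1", call. = FALSE)
  sessions <- as_session_list(cohort)
  ids <- vapply(sessions, function(s) s$participant_id, "")
  if (!identical(ids, fit$participant_ids))
    stop("cohort sessions do not match the fitted participants",
         call. = FALSE)
  nt <- unique(vapply(sessions, function(s) nrow(s$trials), 1L))
  if (length(nt) != 1L)
    stop("sessions must share a common trial count", call. = FALSE)
  levels <- fit$phrasing_levels
  pk <- pack_model(fit$model, levels)
  fc <- frame_coding(fit$frame)
  env_mats <- lapply(sessions, function(s) {
    tr <- s$trials
    cbind(correct_green = as.integer(tr$correct_card == "green"),
          advice_green = as.integer(tr$advice_card == "green"),
          advice_correct = as.integer(tr$advice_correct),
          phr = match(tr$phrasing, levels) - 1L)
  })
  nip <- nrow(fit$param_table)
  d <- fit$draws
  n_draws <- dim(d)[1] * dim(d)[2]
  theta <- matrix(d[, , -(seq_len(2 * nip)), drop = FALSE], nrow = n_draws)
  rates <- with_seed(seed, {
    pick <- sample.int(n_draws, min(n_rep, n_draws))
    cpp_simulate_rates(env_mats, theta[pick, , drop = FALSE], nip, pk$idx,
                       pk$fict_self, pk$fict_adv, fc$frame_code, pk$literal,
                       fc$v_self_init)
  })
  alpha <- (1 - nominal_level) / 2
  lower <- apply(rates, 2, stats::quantile, alpha)
  upper <- apply(rates, 2, stats::quantile, 1 - alpha)
  obs <- rowMeans(vapply(sessions,
                         function(s) as.numeric(s$trials$choice == "green"),
                         numeric(nt)))
  series <- data.frame(trial = seq_len(nt), observed = obs,
                       lower = lower, upper = upper, row.names = NULL)
  structure(list(series = series,
                 coverage = mean(obs >= lower & obs <= upper),
                 nominal_level = nominal_level, n_rep = n_rep),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d replicates, %.0f%% band)\n",
              x$n_rep, 100 * x$nominal_level))
  cat(sprintf("  per-trial coverage of the observed mean: %.3f\n",
              x$coverage))
  invisible(x)
}

#' @export
plot.ppc_result <- function(x, ...) {
  s <- x$series
  graphics::plot(s$trial, s$observed, type = "n", ylim = c(0, 1),
                 xlab = "Trial", ylab = "P(choose green)",
                 main = sprintf("Posterior predictive check (coverage %.2f)",
                                x$coverage), ...)
  graphics::polygon(c(s$trial, rev(s$trial)), c(s$lower, rev(s$upper)),
                    col = "grey85", border = NA)
  graphics::points(s$trial, s$observed, pch = 16, cex = 0.6)
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares posterior point estimates with the ground-truth parameters
#' stored in a synthetic cohort: per parameter, the bias (mean estimate
#' minus truth), root-mean-square error, and the across-participant
#' correlation between truth and estimate. Condition-specific parameters
#' are reported per condition and additionally pooled across conditions
#' (rows with `condition = "(all)"`), the pooled correlation measuring
#' rank recovery over the parameter's full range.
#'
#' @param cohort A [generate_cohort()] result carrying `true_params`.
#' @param fit The corresponding [fit_advice_rl()] result.
#' @return Data frame with columns `parameter`, `condition`, `bias`,
#'   `rmse`, `correlation`, `correlation_defined`.
#' @export
parameter_recovery <- function(cohort, fit) {
  sessions <- as_session_list(cohort)
  if (any(vapply(sessions, function(s) is.null(s$true_params), TRUE)))
    stop("cohort carries no ground-truth parameters", call. = FALSE)
  pm <- fit$participant_means
  pt <- fit$param_table
  truth <- t(vapply(sessions, function(s) s$true_params[colnames(pm)],
                    numeric(ncol(pm))))
  rec_row <- function(par_label, cond, tr, es) {
    corr_def <- stats::sd(es) > 0 && stats::sd(tr) > 0
    data.frame(parameter = par_label, condition = cond,
               bias = mean(es - tr), rmse = sqrt(mean((es - tr)^2)),
               correlation = if (corr_def) stats::cor(tr, es) else NA_real_,
               correlation_defined = corr_def, stringsAsFactors = FALSE)
  }
  base <- sub("\\[.*\\]$", "", pt$name)
  rows <- lapply(seq_len(nrow(pt)), function(k)
    rec_row(base[k], ifelse(is.na(pt$condition[k]), "", pt$condition[k]),
            truth[, pt$name[k]], pm[, pt$name[k]]))
  pooled <- lapply(unique(base[!is.na(pt$condition)]), function(b) {
    cols <- pt$name[base == b]
    rec_row(b, "(all)", as.vector(truth[, cols]), as.vector(pm[, cols]))
  })
  out <- do.call(rbind, c(rows, pooled))
  rownames(out) <- NULL
  out
}

#' Simulate replicated cohorts from a fitted model
#'
#' Draws posterior parameter vectors and replays each participant's
#' recorded environment, returning replicated per-trial group mean
#' green-choice rates (the PPC statistic).
#'
#' @param object An `advice_rl_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param cohort The fitted cohort.
#' @param ... Unused.
#' @return Matrix `nsim` x trials of replicated group mean rates.
#' @export
simulate.advice_rl_fit <- function(object, nsim = 1, seed = 1L,
                                   cohort, ...) {
  sessions <- as_session_list(cohort)
  levels <- object$phrasing_levels
  pk <- pack_model(object$model, levels)
  fc <- frame_coding(object$frame)
  env_mats <- lapply(sessions, function(s) {
    tr <- s$trials
    cbind(as.integer(tr$correct_card == "green"),
          as.integer(tr$advice_card == "green"),
          as.integer(tr$advice_correct),
          match(tr$phrasing, levels) - 1L)
  })
  nip <- nrow(object$param_table)
  d <- object$draws
  n_draws <- dim(d)[1] * dim(d)[2]
  theta <- matrix(d[, , -(seq_len(2 * nip)), drop = FALSE], nrow = n_draws)
  with_seed(seed, {
    pick <- sample.int(n_draws, min(nsim, n_draws))
    cpp_simulate_rates(env_mats, theta[pick, , drop = FALSE], nip, pk$idx,
                       pk$fict_self, pk$fict_adv, fc$frame_code, pk$literal,
                       fc$v_self_init)
  })
}
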