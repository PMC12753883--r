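#' Configure the MCMC sampler
#'
#' The hierarchical model is sampled by an adaptive Metropolis-within-Gibbs
#' scheme (see the methods vignette). `n_iterations` counts *stored* draws
#' per chain, of which the first `warmup_fraction` are discarded as warmup;
#' between stored draws the underlying random-walk chain advances `thin`
#' full parameter sweeps, so the total number of sweeps per chain is
#' `n_iterations * thin`.
#'
#' @param n_chains Number of chains (>= 2). Default 4.
#' @param n_iterations Stored iterations per chain (warmup included).
#'   Default 4000, matching the reference configuration; reduced runs
#'   (e.g. 1000) are adequate for recovery studies.
#' @param warmup_fraction Fraction of iterations discarded as warmup,
#'   in (0,1). Default 0.5.
#' @param thin Sweeps of the underlying chain per stored draw. Default 25.
#' @param seed Integer seed controlling the whole fit.
#' @param rhat_threshold Convergence bar for the split Gelman-Rubin
#'   statistic. Default 1.01.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iterations = 4000L,
                           warmup_fraction = 0.5, thin = 25L, seed = 1L,
                           rhat_threshold = 1.01) {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  if (n_chains < 2L) stop("n_chains must be >= 2", call. = FALSE)
  if (warmup_fraction <= 0 || warmup_fraction >= 1)
    stop("warmup_fraction must lie in (0, 1)", call. = FALSE)
  if (n_iterations < 4L) stop("n_iterations too small", call. = FALSE)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 warmup_fraction = warmup_fraction, thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "sampler_config")
}

fit_param_names <- function(pt, ids) {
  c(sprintf("mu[%s]", pt$name), sprintf("sigma[%s]", pt$name),
    as.vector(t(outer(ids, pt$name,
                      function(i, p) sprintf("theta[%s,%s]", i, p)))))
}

#' Fit a model hierarchically to a cohort
#'
#' Estimates all group-level and individual-level parameters of a model by
#' MCMC under the hierarchical prior: group means uniform over the
#' parameter bounds (\[0,1\] for learning rates and advice weights, \[0,3\]
#' for inverse temperatures), group standard deviations half-Cauchy (scale
#' 1, or 3 for temperatures), and individual parameters normal around the
#' group mean truncated to the bounds. Condition-specific parameters (the
#' advice weight and advice learning rate) receive separate group-level
#' distributions per phrasing condition. The likelihood is the Bernoulli
#' probability of each recorded choice under the model.
#'
#' @param cohort A `cohort_data` object or a list of [session_data()]
#'   sharing one frame.
#' @param model A [model_spec()] (defaults to the generating model when a
#'   cohort is supplied).
#' @param sampler A [sampler_config()].
#' @return Object of class `advice_rl_fit` with elements `draws` (array
#'   iterations x chains x parameters, post-warmup only),
#'   `participant_means`, `group_means`, `diagnostics` (split R-hat per
#'   parameter), `model`, `sampler`, plus the session metadata needed by
#'   downstream checks.
#' @seealso [posterior_point_estimates()], [rhat()], [psis_loo()],
#'   [posterior_predictive_check()]
#' @export
fit_advice_rl <- function(cohort, model = NULL, sampler = sampler_config()) {
  sessions <- as_session_list(cohort)
  if (length(sessions) == 0L) stop("empty cohort", call. = FALSE)
  frame <- unique(vapply(sessions, function(s) s$frame, ""))
  if (length(frame) != 1L)
    stop("all sessions must share one frame; fit frames separately",
         call. = FALSE)
  if (is.null(model)) {
    if (inherits(cohort, "cohort_data")) model <- cohort$group_config$model
    else stop("model must be given when fitting raw sessions", call. = FALSE)
  }
  stopifnot(inherits(model, "model_spec"), inherits(sampler, "sampler_config"))

  levels <- sort(unique(unlist(lapply(sessions,
                                      function(s) unique(s$trials$phrasing)))))
  pt <- model_parameters(model, levels)
  nip <- nrow(pt)
  ns <- length(sessions)
  pk <- pack_model(model, levels)
  fc <- frame_coding(frame)
  subj <- lapply(sessions, function(s) pack_session(s$trials, levels))
  subj_mats <- lapply(subj, `[[`, "mat")
  subj_rews <- lapply(subj, `[[`, "rew")
  ids <- vapply(sessions, function(s) s$participant_id, "")

  # parameter pairs whose roles mirror under prediction-error sign
  # (asymmetric learning rates); the sampler proposes exchanging them
  swap_pairs <- matrix(integer(0), nrow = 2)
  if (model$self_symmetry == "asymmetric")
    swap_pairs <- cbind(swap_pairs,
                        match(c("alpha_c_pos", "alpha_c_neg"), pt$name) - 1L)
  if (model$advice_symmetry == "asymmetric")
    for (lv in levels)
      swap_pairs <- cbind(swap_pairs,
                          match(sprintf(c("alpha_a_pos[%s]",
                                          "alpha_a_neg[%s]"), lv),
                                pt$name) - 1L)
  storage.mode(swap_pairs) <- "integer"

  n_iter <- sampler$n_iterations
  n_warm_iter <- floor(n_iter * sampler$warmup_fraction)
  n_keep <- n_iter - n_warm_iter
  thin <- max(1L, sampler$thin)
  n_sweeps <- n_iter * thin
  n_warmup <- n_warm_iter * thin

  chains <- with_seed(sampler$seed, {
    lapply(seq_len(sampler$n_chains), function(ch) {
      mid <- (pt$lower + pt$upper) / 2
      span <- pt$upper - pt$lower
      mu0 <- pmin(pt$upper - 0.05 * span,
                  pmax(pt$lower + 0.05 * span,
                       mid + 0.25 * span * stats::rnorm(nip)))
      sig0 <- (0.05 + 0.15 * stats::runif(nip)) *
        ifelse(pt$kind == "tau", 3, 1)
      theta0 <- t(vapply(seq_len(ns), function(j)
        rtrunc_norm(nip, mu0, sig0, pt$lower, pt$upper), numeric(nip)))
      res <- cpp_fit_chain(subj_mats, subj_rews, theta0, mu0, sig0,
                           pt$lower, pt$upper, pt$sd_prior_scale,
                           pk$idx, pk$fict_self, pk$fict_adv,
                           fc$frame_code, pk$literal, fc$v_self_init,
                           n_sweeps, n_warmup, thin, swap_pairs)
      res$draws
    })
  })

  pnames <- fit_param_names(pt, ids)
  draws <- array(NA_real_,
                 dim = c(n_keep, sampler$n_chains, length(pnames)),
                 dimnames = list(iteration = NULL,
                                 chain = seq_len(sampler$n_chains),
                                 parameter = pnames))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]

  diagnostics <- apply(draws, 3, rhat_matrix)
  flat <- matrix(draws, nrow = n_keep * sampler$n_chains,
                 dimnames = list(NULL, pnames))
  est <- colMeans(flat)
  pm <- matrix(est[-(seq_len(2 * nip))], nrow = ns, byrow = TRUE,
               dimnames = list(ids, pt$name))
  gm <- data.frame(
    parameter = pt$name,
    mean = est[seq_len(nip)],
    sd_group = est[nip + seq_len(nip)],
    ci_low = apply(flat[, seq_len(nip), drop = FALSE], 2,
                   stats::quantile, 0.025),
    ci_high = apply(flat[, seq_len(nip), drop = FALSE], 2,
                    stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(draws = draws, participant_means = pm, group_means = gm,
                 diagnostics = diagnostics, model = model, sampler = sampler,
                 frame = frame, phrasing_levels = levels,
                 participant_ids = ids, param_table = pt),
            class = "advice_rl_fit")
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Computes the split potential-scale-reduction factor: each chain is
#' halved, and the between- and within-half variances are combined in the
#' usual way. Draws that are constant across all chains return exactly 1.
#'
#' @param x An `advice_rl_fit`, or a matrix with one column per chain.
#' @param parameter Optional parameter name when `x` is a fit; when
#'   omitted, a named vector over all parameters is returned.
#' @return Numeric R-hat value(s).
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "advice_rl_fit")) {
    if (is.null(parameter)) return(x$diagnostics)
    if (!parameter %in% dimnames(x$draws)$parameter)
      stop("unknown parameter '", parameter, "'", call. = FALSE)
    return(rhat_matrix(x$draws[, , parameter]))
  }
  rhat_matrix(as.matrix(x))
}

rhat_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("rhat needs at least 2 chains", call. = FALSE)
  n <- nrow(m)
  if (n < 4L) stop("rhat needs at least 4 draws per chain", call. = FALSE)
  half <- n %/% 2L
  splits <- cbind(m[seq_len(half), , drop = FALSE],
                  m[half + seq_len(half), , drop = FALSE])
  w <- mean(apply(splits, 2, stats::var))
  if (w == 0) return(1.0)  # constant across all chains
  b <- half * stats::var(colMeans(splits))
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

#' Posterior point estimates per participant
#'
#' Arithmetic means over all post-warmup draws of every individual-level
#' parameter, exported as a tidy table.
#'
#' @param fit An [fit_advice_rl()] result.
#' @return Data frame with columns `participant`, `parameter`, `condition`,
#'   `estimate`.
#' @export
posterior_point_estimates <- function(fit) {
  stopifnot(inherits(fit, "advice_rl_fit"))
  pm <- fit$participant_means
  pt <- fit$param_table
  out <- expand.grid(participant = rownames(pm), parameter = pt$name,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$condition <- pt$condition[match(out$parameter, pt$name)]
  out$estimate <- as.numeric(pm[cbind(out$participant, out$parameter)])
  out
}

#' @export
print.advice_rl_fit <- function(x, ...) {
  cat(sprintf("Hierarchical fit of model %s (%d participants, frame '%s')\n",
              x$model$name, nrow(x$participant_means), x$frame))
  cat(sprintf("  %d chains x %d stored iterations (thin %d), seed %d\n",
              x$sampler$n_chains, x$sampler$n_iterations, x$sampler$thin,
              x$sampler$seed))
  cat(sprintf("  max split R-hat = %.4f (threshold %.3f)\n",
              max(x$diagnostics), x$sampler$rhat_threshold))
  invisible(x)
}

#' @export
summary.advice_rl_fit <- function(object, ...) {
  gm <- object$group_means
  gm$rhat_mu <- object$diagnostics[sprintf("mu[%s]", gm$parameter)]
  out <- list(model = object$model$name, group_means = gm,
              max_rhat = max(object$diagnostics),
              converged = max(object$diagnostics) <
                object$sampler$rhat_threshold)
  class(out) <- "summary.advice_rl_fit"
  out
}

#' @export
print.summary.advice_rl_fit <- function(x, ...) {
  cat(sprintf("Model %s — group-level posterior summaries\n", x$model))
  print(x$group_means, digits = 3)
  cat(sprintf("max split R-hat %.4f — %s\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.advice_rl_fit <- function(object, level = c("participant", "group"),
                               ...) {
  level <- match.arg(level)
  if (level == "participant") object$participant_means
  else stats::setNames(object$group_means$mean, object$group_means$parameter)
}
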