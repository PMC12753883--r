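#' Specify one of the eight delta-rule advice-taking models
#'
#' The model family crosses two choices for the self-learning process
#' (single vs. fictitious updating; symmetric vs. asymmetric learning
#' rates) with the same two choices for the advice-learning process.
#' The eight named members are:
#'
#' | name | self update | self rates | advice update | advice rates |
#' |------|-------------|------------|---------------|--------------|
#' | M1   | single      | symmetric  | single        | symmetric    |
#' | M2a  | fictitious  | symmetric  | single        | symmetric    |
#' | M2b  | single      | symmetric  | fictitious    | symmetric    |
#' | M2c  | fictitious  | symmetric  | fictitious    | symmetric    |
#' | M3a  | single      | asymmetric | single        | symmetric    |
#' | M3b  | single      | symmetric  | single        | asymmetric   |
#' | M3c  | single      | asymmetric | single        | asymmetric   |
#' | M4   | fictitious  | asymmetric | fictitious    | symmetric    |
#'
#' Fictitious updating also revises the unchosen card (or the unfollowed
#' advice option) using the counterfactual outcome implied by the fact that
#' exactly one card is correct per trial. Asymmetric learning uses separate
#' rates for positive and negative prediction errors.
#'
#' @param name Model name, one of `"M1","M2a","M2b","M2c","M3a","M3b",
#'   "M3c","M4"`.
#' @param combination_mode How the advice-based and self-based choice
#'   probabilities are combined: `"normalized"` (default; mixture of valid
#'   probabilities, see [choice_probability()]) or `"literal_clipped"`
#'   (signed combination clipped into \[1e-6, 1-1e-6\]).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, combination_mode = c("normalized",
                                                  "literal_clipped")) {
  combination_mode <- match.arg(combination_mode)
  flags <- switch(name,
    M1  = c("single", "symmetric",  "single", "symmetric"),
    M2a = c("fictitious", "symmetric", "single", "symmetric"),
    M2b = c("single", "symmetric", "fictitious", "symmetric"),
    M2c = c("fictitious", "symmetric", "fictitious", "symmetric"),
    M3a = c("single", "asymmetric", "single", "symmetric"),
    M3b = c("single", "symmetric", "single", "asymmetric"),
    M3c = c("single", "asymmetric", "single", "asymmetric"),
    M4  = c("fictitious", "asymmetric", "fictitious", "symmetric"),
    stop("unknown model name '", name, "'; expected M1, M2a, M2b, M2c, ",
         "M3a, M3b, M3c or M4", call. = FALSE)
  )
  structure(list(name = name,
                 self_update = flags[1], self_symmetry = flags[2],
                 advice_update = flags[3], advice_symmetry = flags[4],
                 combination_mode = combination_mode),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: self %s/%s, advice %s/%s (%s combination)\n",
              x$name, x$self_update, x$self_symmetry,
              x$advice_update, x$advice_symmetry, x$combination_mode))
  invisible(x)
}

#' Free-parameter layout of a model
#'
#' Enumerates the free parameters of a model given the phrasing conditions:
#' self learning rate(s) (`alpha_c`, or `alpha_c_pos`/`alpha_c_neg` when
#' asymmetric), one advice learning rate per phrasing condition
#' (`alpha_a[cond]`, split into `alpha_a_pos[cond]`/`alpha_a_neg[cond]` when
#' asymmetric), the two softmax inverse temperatures `tau_c` and `tau_a`,
#' and one advice reference weight per condition (`omega[cond]`). Learning
#' rates and weights live in \[0,1\], inverse temperatures in \[0,3\].
#'
#' @param spec A [model_spec()].
#' @param phrasing_levels Character vector of phrasing condition labels.
#' @return Data frame with columns `name`, `kind` (`alpha`, `tau`, `omega`),
#'   `condition` (`NA` for shared parameters), `lower`, `upper`, and
#'   `sd_prior_scale` (half-Cauchy scale used for group-level spreads).
#' @export
model_parameters <- function(spec, phrasing_levels = c("positive",
                                                       "negative")) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- list()
  add <- function(name, kind, condition = NA_character_) {
    up <- if (kind == "tau") 3 else 1
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, condition = condition,
      lower = 0, upper = up, sd_prior_scale = if (kind == "tau") 3 else 1,
      stringsAsFactors = FALSE)
  }
  if (spec$self_symmetry == "symmetric") add("alpha_c", "alpha")
  else { add("alpha_c_pos", "alpha"); add("alpha_c_neg", "alpha") }
  for (lv in phrasing_levels) {
    if (spec$advice_symmetry == "symmetric") {
      add(sprintf("alpha_a[%s]", lv), "alpha", lv)
    } else {
      add(sprintf("alpha_a_pos[%s]", lv), "alpha", lv)
      add(sprintf("alpha_a_neg[%s]", lv), "alpha", lv)
    }
  }
  add("tau_c", "tau"); add("tau_a", "tau")
  for (lv in phrasing_levels) add(sprintf("omega[%s]", lv), "omega", lv)
  do.call(rbind, rows)
}

#' Outcome coding implied by a task frame
#'
#' Returns the reward codes, initial self-values, and the counterfactual
#' rule used by fictitious updating. In the mixed frame a correct choice
#' earns +1 and an incorrect one -1 with self-values starting at 0; in the
#' gain frame outcomes are +1/0 with values starting at 0.5; in the loss
#' frame 0/-1 starting at -0.5. Because exactly one card is correct per
#' trial, the unchosen card's counterfactual reward is `-R` (mixed),
#' `1 - R` (gain) or `-1 - R` (loss), where `R` is the obtained reward.
#' Advice outcomes are coded +1/-1 with advice values starting at 0 in all
#' frames.
#'
#' @param frame `"mixed"`, `"gain"` or `"loss"`.
#' @return List with `reward_correct`, `reward_incorrect`, `v_self_init`,
#'   `counterfactual` (a function of the obtained reward), and `frame_code`
#'   (integer used by compiled code).
#' @export
frame_coding <- function(frame) {
  switch(frame,
    mixed = list(reward_correct = 1, reward_incorrect = -1, v_self_init = 0,
                 counterfactual = function(R) -R, frame_code = 0L),
    gain = list(reward_correct = 1, reward_incorrect = 0, v_self_init = 0.5,
                counterfactual = function(R) 1 - R, frame_code = 1L),
    loss = list(reward_correct = 0, reward_incorrect = -1,
                v_self_init = -0.5,
                counterfactual = function(R) -1 - R, frame_code = 2L),
    stop("unknown frame '", frame, "'", call. = FALSE)
  )
}

#' Initial latent state of a learner
#'
#' @param frame Task frame (sets the initial self-values).
#' @return List with `v_self_green`, `v_self_blue`, `v_adv_follow`,
#'   `v_adv_unfollow`.
#' @export
initial_state <- function(frame) {
  fc <- frame_coding(frame)
  list(v_self_green = fc$v_self_init, v_self_blue = fc$v_self_init,
       v_adv_follow = 0, v_adv_unfollow = 0)
}

par_get <- function(params, name) {
  v <- params[[name]]
  if (is.null(v) || is.na(v))
    stop("parameter '", name, "' missing from parameter set", call. = FALSE)
  v
}

# Learning-rate lookups that honour the symmetry flags. Ties (PE == 0) use
# the negative-PE rate.
self_alpha <- function(spec, params, pe) {
  if (spec$self_symmetry == "symmetric") par_get(params, "alpha_c")
  else if (pe > 0) par_get(params, "alpha_c_pos")
  else par_get(params, "alpha_c_neg")
}

advice_alpha <- function(spec, params, phrasing, pe) {
  if (spec$advice_symmetry == "symmetric")
    par_get(params, sprintf("alpha_a[%s]", phrasing))
  else if (pe > 0) par_get(params, sprintf("alpha_a_pos[%s]", phrasing))
  else par_get(params, sprintf("alpha_a_neg[%s]", phrasing))
}

#' Delta-rule update of the card values
#'
#' Updates the chosen card's expected value by `alpha * (R - V)`, with the
#' learning rate chosen by the sign of the prediction error in asymmetric
#' models. Under fictitious updating the unchosen card is updated by the
#' same rule applied to its counterfactual reward (see [frame_coding()]).
#'
#' @param state Latent state (see [initial_state()]).
#' @param choice `"green"` or `"blue"`.
#' @param reward_self Obtained frame-coded reward.
#' @param spec A [model_spec()].
#' @param params Named list/vector of parameters (see [model_parameters()]).
#' @param frame Task frame.
#' @return Updated state.
#' @export
update_self_values <- function(state, choice, reward_self, spec, params,
                               frame) {
  fc <- frame_coding(frame)
  chosen <- if (choice == "green") "v_self_green" else "v_self_blue"
  other <- if (choice == "green") "v_self_blue" else "v_self_green"
  pe <- reward_self - state[[chosen]]
  state[[chosen]] <- state[[chosen]] + self_alpha(spec, params, pe) * pe
  if (spec$self_update == "fictitious") {
    r_cf <- fc$counterfactual(reward_self)
    pe2 <- r_cf - state[[other]]
    state[[other]] <- state[[other]] + self_alpha(spec, params, pe2) * pe2
  }
  state
}

#' Delta-rule update of the advice values
#'
#' The advice outcome is +1 when the advised card was correct and -1
#' otherwise; it is observed from feedback on every trial regardless of
#' whether the advice was followed, so the follow-value is always updated.
#' Under fictitious advice updating the unfollow-value is additionally
#' updated toward the negated advice outcome. The advice learning rate is
#' specific to the trial's phrasing condition (and to the prediction-error
#' sign in asymmetric advice models).
#'
#' @inheritParams update_self_values
#' @param advice_correct Logical; was the advised card the correct card?
#' @param phrasing Phrasing condition label of the trial.
#' @return Updated state.
#' @export
update_advice_values <- function(state, advice_correct, phrasing, spec,
                                 params) {
  r_a <- if (advice_correct) 1 else -1
  pe <- r_a - state$v_adv_follow
  state$v_adv_follow <- state$v_adv_follow +
    advice_alpha(spec, params, phrasing, pe) * pe
  if (spec$advice_update == "fictitious") {
    pe2 <- -r_a - state$v_adv_unfollow
    state$v_adv_unfollow <- state$v_adv_unfollow +
      advice_alpha(spec, params, phrasing, pe2) * pe2
  }
  state
}

#' Probability of choosing the green card
#'
#' Combines two softmax probabilities: the self-based probability
#' `P_c = logistic(tau_c * (V_green - V_blue))` and the advice-based
#' probability of following, `P_a = logistic(tau_a * (V_follow -
#' V_unfollow))`. In the default `normalized` mode the final probability is
#' the mixture `omega * A + (1 - omega) * P_c`, where `A` is `P_a` when the
#' advised card is green and `1 - P_a` otherwise; the result is a valid
#' probability for all in-bounds parameters and equals the literal signed
#' rule whenever the advice points to green. In `literal_clipped` mode the
#' signed rule `beta * omega * P_a + (1 - omega) * P_c` (with `beta = 1` for
#' green advice, `-1` otherwise) is evaluated as written and clipped to
#' \[1e-6, 1-1e-6\]. `omega` is taken from the trial's phrasing condition.
#'
#' @inheritParams update_self_values
#' @param advice_card The advised card, `"green"` or `"blue"`.
#' @param phrasing Phrasing condition label of the trial.
#' @param combination_mode `"normalized"` or `"literal_clipped"`.
#' @return Probability of choosing the green card.
#' @export
choice_probability <- function(state, advice_card, phrasing, params,
                               combination_mode = "normalized") {
  tau_c <- par_get(params, "tau_c")
  tau_a <- par_get(params, "tau_a")
  omega <- par_get(params, sprintf("omega[%s]", phrasing))
  p_c <- stats::plogis(tau_c * (state$v_self_green - state$v_self_blue))
  p_a <- stats::plogis(tau_a * (state$v_adv_follow - state$v_adv_unfollow))
  if (combination_mode == "normalized") {
    a <- if (advice_card == "green") p_a else 1 - p_a
    omega * a + (1 - omega) * p_c
  } else {
    beta <- if (advice_card == "green") 1 else -1
    p <- beta * omega * p_a + (1 - omega) * p_c
    min(max(p, 1e-6), 1 - 1e-6)
  }
}

#' Simulate one session of choices
#'
#' Runs a learner with the given model and parameters through an
#' environment trace: on each trial the choice probability is computed from
#' the current latent state, a choice is sampled, the outcome is revealed
#' and frame-coded, and both the self- and advice-value updates are
#' applied. Reproducible for a fixed seed.
#'
#' @param spec A [model_spec()].
#' @param params Named parameter list/vector covering
#'   [model_parameters()] for the environment's phrasing levels.
#' @param env An environment trace from [generate_environment()].
#' @param frame Task frame.
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the result.
#' @return A [session_data()] object whose `trials` include the choice,
#'   reward and bookkeeping columns.
#' @export
simulate_session <- function(spec, params, env, frame, seed,
                             participant_id = "sim") {
  stopifnot(inherits(spec, "model_spec"))
  check_params_cover(spec, params, unique(env$phrasing))
  fc <- frame_coding(frame)
  n <- nrow(env)
  choice <- character(n)
  reward <- numeric(n)
  u <- with_seed(seed, stats::runif(n))
  state <- initial_state(frame)
  for (t in seq_len(n)) {
    p_green <- choice_probability(state, env$advice_card[t], env$phrasing[t],
                                  params, spec$combination_mode)
    choice[t] <- if (u[t] < p_green) "green" else "blue"
    correct <- choice[t] == env$correct_card[t]
    reward[t] <- if (correct) fc$reward_correct else fc$reward_incorrect
    state <- update_self_values(state, choice[t], reward[t], spec, params,
                                frame)
    state <- update_advice_values(state, env$advice_card[t] ==
                                    env$correct_card[t],
                                  env$phrasing[t], spec, params)
  }
  trials <- data.frame(
    env, choice = choice,
    choice_correct = choice == env$correct_card,
    reward_self = reward,
    advice_correct = env$advice_card == env$correct_card,
    followed = choice == env$advice_card,
    stringsAsFactors = FALSE
  )
  class(trials) <- "data.frame"
  session_data(participant_id, frame, trials)
}

check_params_cover <- function(spec, params, levels) {
  needed <- model_parameters(spec, levels)$name
  missing <- needed[!vapply(needed, function(nm)
    !is.null(params[[nm]]) && !is.na(params[[nm]]), TRUE)]
  if (length(missing))
    stop("parameter(s) missing for configured phrasing level(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Per-trial log-likelihood of a recorded session
#'
#' Replays the value updates deterministically along the recorded choices
#' and outcomes and returns, for every trial, the log-probability of the
#' observed choice under the model. The sum is the session log-likelihood.
#' Probabilities are floored at 1e-12 before taking logs.
#'
#' @param spec A [model_spec()].
#' @param params Named parameter list/vector.
#' @param session A [session_data()] object.
#' @param method `"fast"` (compiled single-pass replay, the default) or
#'   `"reference"` (plain R replay using the exported update operations);
#'   the two agree to near machine precision and the reference path serves
#'   as an independent check.
#' @return Numeric vector of per-trial log-likelihood contributions.
#' @export
session_loglik <- function(spec, params, session,
                           method = c("fast", "reference")) {
  method <- match.arg(method)
  stopifnot(inherits(session, "session_data"))
  tr <- session$trials
  if (!identical(as.integer(tr$trial_index), seq_len(nrow(tr))))
    stop("session trials must be ordered with contiguous trial_index",
         call. = FALSE)
  levels <- sort(unique(tr$phrasing))
  check_params_cover(spec, params, levels)
  if (method == "fast") {
    pk <- pack_model(spec, levels)
    pv <- pack_params(spec, params, levels)
    dat <- pack_session(tr, levels)
    fc <- frame_coding(session$frame)
    return(as.numeric(cpp_session_loglik(
      dat$mat, dat$rew, pv, pk$idx, pk$fict_self, pk$fict_adv,
      fc$frame_code, pk$literal, fc$v_self_init)))
  }
  state <- initial_state(session$frame)
  out <- numeric(nrow(tr))
  for (t in seq_len(nrow(tr))) {
    p_green <- choice_probability(state, tr$advice_card[t], tr$phrasing[t],
                                  params, spec$combination_mode)
    p_obs <- if (tr$choice[t] == "green") p_green else 1 - p_green
    out[t] <- log(max(p_obs, 1e-12))
    state <- update_self_values(state, tr$choice[t], tr$reward_self[t],
                                spec, params, session$frame)
    state <- update_advice_values(state, tr$advice_correct[t],
                                  tr$phrasing[t], spec, params)
  }
  out
}

# ---- packing helpers shared with the compiled code ----------------------

# 0-based index map into the packed parameter vector:
# [ac_pos, ac_neg, tc, ta, aa_pos(levels...), aa_neg(levels...),
#  om(levels...)]; symmetric models point pos and neg at the same slot.
pack_model <- function(spec, levels) {
  pt <- model_parameters(spec, levels)
  pos <- function(nm) match(nm, pt$name) - 1L
  k <- length(levels)
  if (spec$self_symmetry == "symmetric") {
    ac_pos <- ac_neg <- pos("alpha_c")
  } else {
    ac_pos <- pos("alpha_c_pos"); ac_neg <- pos("alpha_c_neg")
  }
  if (spec$advice_symmetry == "symmetric") {
    aa_pos <- aa_neg <- vapply(levels, function(l)
      pos(sprintf("alpha_a[%s]", l)), 1L)
  } else {
    aa_pos <- vapply(levels, function(l) pos(sprintf("alpha_a_pos[%s]", l)), 1L)
    aa_neg <- vapply(levels, function(l) pos(sprintf("alpha_a_neg[%s]", l)), 1L)
  }
  om <- vapply(levels, function(l) pos(sprintf("omega[%s]", l)), 1L)
  list(idx = as.integer(c(ac_pos, ac_neg, pos("tau_c"), pos("tau_a"),
                          aa_pos, aa_neg, om)),
       n_cond = k,
       fict_self = as.integer(spec$self_update == "fictitious"),
       fict_adv = as.integer(spec$advice_update == "fictitious"),
       literal = as.integer(spec$combination_mode == "literal_clipped"),
       template = pt)
}

pack_params <- function(spec, params, levels) {
  pt <- model_parameters(spec, levels)
  vapply(pt$name, function(nm) as.numeric(par_get(params, nm)), 1.0)
}

pack_session <- function(tr, levels) {
  list(mat = cbind(choice_green = as.integer(tr$choice == "green"),
                   advice_green = as.integer(tr$advice_card == "green"),
                   advice_correct = as.integer(tr$advice_correct),
                   phr = match(tr$phrasing, levels) - 1L),
       rew = as.numeric(tr$reward_self))
}
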