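test_that("model names map to the fixed flag combinations", {
  flags <- function(m) unlist(model_spec(m)[c("self_update", "self_symmetry",
                                              "advice_update",
                                              "advice_symmetry")],
                              use.names = FALSE)
  expect_equal(flags("M1"), c("single", "symmetric", "single", "symmetric"))
  expect_equal(flags("M2a"), c("fictitious", "symmetric", "single",
                               "symmetric"))
  expect_equal(flags("M2b"), c("single", "symmetric", "fictitious",
                               "symmetric"))
  expect_equal(flags("M2c"), c("fictitious", "symmetric", "fictitious",
                               "symmetric"))
  expect_equal(flags("M3a"), c("single", "asymmetric", "single",
                               "symmetric"))
  expect_equal(flags("M3b"), c("single", "symmetric", "single",
                               "asymmetric"))
  expect_equal(flags("M3c"), c("single", "asymmetric", "single",
                               "asymmetric"))
  expect_equal(flags("M4"), c("fictitious", "asymmetric", "fictitious",
                              "symmetric"))
  expect_error(model_spec("M9"), "unknown model")
})

test_that("frame coding matches the outcome structure of each frame", {
  mx <- frame_coding("mixed")
  expect_equal(c(mx$reward_correct, mx$reward_incorrect, mx$v_self_init),
               c(1, -1, 0))
  expect_equal(mx$counterfactual(1), -1)   # sign flip under +/- coding

  gn <- frame_coding("gain")
  expect_equal(c(gn$reward_correct, gn$reward_incorrect, gn$v_self_init),
               c(1, 0, 0.5))
  expect_equal(gn$counterfactual(0), 1)    # exactly one card is correct

  ls <- frame_coding("loss")
  expect_equal(c(ls$reward_correct, ls$reward_incorrect, ls$v_self_init),
               c(0, -1, -0.5))
  expect_equal(ls$counterfactual(0), -1)   # forced by -1 - R
  expect_error(frame_coding("bonus"), "unknown frame")
})

test_that("self-value updates follow the delta rule with hand-checked values", {
  m1 <- model_spec("M1")
  pars <- make_params(m1, alpha_c = 0.5)
  st <- initial_state("mixed")
  st2 <- update_self_values(st, "green", 1, m1, pars, "mixed")
  expect_equal(st2$v_self_green, 0.5)      # 0 + 0.5 * (1 - 0)
  expect_equal(st2$v_self_blue, 0)         # single update leaves it alone

  m2a <- model_spec("M2a")
  p2 <- make_params(m2a, alpha_c = 0.5)
  st3 <- update_self_values(initial_state("mixed"), "green", 1, m2a, p2,
                            "mixed")
  expect_equal(st3$v_self_green, 0.5)
  expect_equal(st3$v_self_blue, -0.5)      # counterfactual -R update

  # asymmetric: V = 0.2, R = -1, PE = -1.2 < 0 uses the negative rate
  m3a <- model_spec("M3a")
  p3 <- make_params(m3a, alpha_c_pos = 0.6, alpha_c_neg = 0.3)
  st4 <- initial_state("mixed")
  st4$v_self_green <- 0.2
  st5 <- update_self_values(st4, "green", -1, m3a, p3, "mixed")
  expect_equal(st5$v_self_green, 0.2 + 0.3 * (-1.2))
})

test_that("advice-value updates use the observed advice outcome", {
  m1 <- model_spec("M1")
  pars <- make_params(m1, aa_pos = 0.4, aa_neg = 0.4)
  st <- update_advice_values(initial_state("mixed"), TRUE, "positive", m1,
                             pars)
  expect_equal(st$v_adv_follow, 0.4)       # 0 + 0.4 * (1 - 0)
  expect_equal(st$v_adv_unfollow, 0)

  m2b <- model_spec("M2b")
  st2 <- update_advice_values(initial_state("mixed"), TRUE, "positive", m2b,
                              make_params(m2b, aa_pos = 0.4, aa_neg = 0.4))
  expect_equal(st2$v_adv_unfollow, -0.4)   # counterfactual -R_a update

  pars3 <- make_params(m1, aa_pos = 0.25, aa_neg = 0.25)
  st3 <- initial_state("mixed")
  st3$v_adv_follow <- 0.5
  st4 <- update_advice_values(st3, FALSE, "positive", m1, pars3)
  expect_equal(st4$v_adv_follow, 0.5 + 0.25 * (-1 - 0.5))
})

test_that("choice probability combines the two softmax channels", {
  m1 <- model_spec("M1")
  st <- initial_state("mixed")
  # full symmetry: indifference regardless of omega
  pars <- make_params(m1, omega_pos = 0.7, omega_neg = 0.7)
  expect_equal(choice_probability(st, "green", "positive", pars), 0.5)

  # omega = 0: advice ignored in both modes
  st$v_self_green <- 0.8; st$v_adv_follow <- 1
  p0 <- make_params(m1, omega_pos = 0, omega_neg = 0)
  pc <- plogis(p0[["tau_c"]] * 0.8)
  expect_equal(choice_probability(st, "blue", "positive", p0), pc)
  expect_equal(choice_probability(st, "blue", "positive", p0,
                                  "literal_clipped"), pc)

  # hand-set channel probabilities: omega 0.2, advice blue,
  # P_a = 0.75, P_c = 0.6 -> 0.2*0.25 + 0.8*0.6 = 0.53
  ph <- make_params(m1, tau_c = 1, tau_a = 1, omega_pos = 0.2,
                    omega_neg = 0.2)
  st2 <- initial_state("mixed")
  st2$v_self_green <- qlogis(0.6)
  st2$v_adv_follow <- qlogis(0.75)
  expect_equal(choice_probability(st2, "blue", "positive", ph), 0.53)

  # literal mode can go negative and is clipped at the floor
  pl <- make_params(m1, tau_c = 1, tau_a = 1, omega_pos = 0.5,
                    omega_neg = 0.5)
  st3 <- initial_state("mixed")
  st3$v_self_green <- qlogis(0.3)
  st3$v_adv_follow <- qlogis(0.9)
  raw <- -1 * 0.5 * 0.9 + 0.5 * 0.3
  expect_lt(raw, 0)
  expect_equal(choice_probability(st3, "blue", "positive", pl,
                                  "literal_clipped"), 1e-6)
})

test_that("normalized combination needs no clipping and is monotone in omega", {
  m1 <- model_spec("M1")
  set.seed(42)
  for (i in 1:200) {
    st <- list(v_self_green = runif(1, -2, 2), v_self_blue = runif(1, -2, 2),
               v_adv_follow = runif(1, -1, 1),
               v_adv_unfollow = runif(1, -1, 1))
    om <- runif(1)
    pars <- make_params(m1, tau_c = runif(1, 0, 3), tau_a = runif(1, 0, 3),
                        omega_pos = om, omega_neg = om)
    adv <- sample(c("green", "blue"), 1)
    p <- choice_probability(st, adv, "positive", pars)
    expect_gte(p, 0); expect_lte(p, 1)
    # the advised-card probability moves with omega exactly when the advice
    # channel puts more mass on the advised card than the self channel does
    p_a <- plogis(pars[["tau_a"]] * (st$v_adv_follow - st$v_adv_unfollow))
    p_c <- plogis(pars[["tau_c"]] * (st$v_self_green - st$v_self_blue))
    q_self <- if (adv == "green") p_c else 1 - p_c
    if (abs(p_a - q_self) > 1e-6 && om < 0.9) {
      pars_hi <- pars
      pars_hi[c("omega[positive]", "omega[negative]")] <- om + 0.1
      p_hi <- choice_probability(st, adv, "positive", pars_hi)
      p_adv <- if (adv == "green") p else 1 - p
      p_adv_hi <- if (adv == "green") p_hi else 1 - p_hi
      if (p_a > q_self) expect_gt(p_adv_hi, p_adv)
      else expect_lt(p_adv_hi, p_adv)
    }
  }
})

test_that("simulation is seed-deterministic and respects degenerate settings", {
  m1 <- model_spec("M1")
  pars <- make_params(m1)
  env <- generate_environment(task_config(), seed = 1)
  s1 <- simulate_session(m1, pars, env, "mixed", seed = 9)
  s2 <- simulate_session(m1, pars, env, "mixed", seed = 9)
  expect_identical(s1, s2)

  # full advice reliance on a near-perfect adviser: late follow rate high
  cfg <- task_config(adviser_accuracy = 0.999, seed = 2)
  envh <- generate_environment(cfg)
  ph <- make_params(m1, omega_pos = 1, omega_neg = 1, tau_a = 3,
                    aa_pos = 0.5, aa_neg = 0.5)
  sh <- simulate_session(m1, ph, envh, "mixed", seed = 3)
  late <- sh$trials$followed[51:100]
  expect_gt(mean(late), 0.9)

  # omega = 0 reproduces a pure self-learner on the same seed stream
  p0 <- make_params(m1, omega_pos = 0, omega_neg = 0)
  s0 <- simulate_session(m1, p0, env, "mixed", seed = 4)
  p0b <- make_params(m1, omega_pos = 0, omega_neg = 0, aa_pos = 0.9,
                     aa_neg = 0.1)  # advice learning is irrelevant
  s0b <- simulate_session(m1, p0b, env, "mixed", seed = 4)
  expect_identical(s0$trials$choice, s0b$trials$choice)
})

test_that("session log-likelihood has the closed form under indifference", {
  m1 <- model_spec("M1")
  pars <- make_params(m1, tau_c = 0, tau_a = 0, omega_pos = 0,
                      omega_neg = 0)
  env <- generate_environment(task_config(), seed = 6)
  s <- simulate_session(m1, pars, env, "mixed", seed = 7)
  ll <- session_loglik(m1, pars, s)
  expect_equal(ll, rep(log(0.5), 100))
  expect_equal(sum(ll), 100 * log(0.5))
  # purity: two calls bit-identical
  expect_identical(ll, session_loglik(m1, pars, s))
})

test_that("compiled and reference likelihoods agree on random sessions", {
  set.seed(99)
  models <- c("M1", "M2a", "M2b", "M2c", "M3a", "M3b", "M3c", "M4")
  frames <- c("mixed", "gain", "loss")
  for (i in 1:50) {
    spec <- model_spec(sample(models, 1),
                       combination_mode = sample(c("normalized",
                                                   "literal_clipped"), 1))
    frame <- sample(frames, 1)
    pt <- model_parameters(spec, phr_levels)
    pars <- stats::setNames(runif(nrow(pt), 0.02, 0.98) *
                              ifelse(pt$kind == "tau", 3, 1), pt$name)
    env <- generate_environment(task_config(n_trials = 60, block_length = 20,
                                            frame = frame), seed = i)
    s <- simulate_session(spec, pars, env, frame, seed = 1000 + i)
    fast <- session_loglik(spec, pars, s, method = "fast")
    ref <- session_loglik(spec, pars, s, method = "reference")
    expect_equal(fast, ref, tolerance = 1e-12)
  }
})

test_that("the full model collapses to the basic model when constrained", {
  # M4 machinery with fictitious updating disabled and equal +/- rates must
  # reproduce M1 exactly
  m4c <- model_spec("M4")
  m4c$self_update <- "single"
  m4c$advice_update <- "single"
  m1 <- model_spec("M1")
  set.seed(123)
  for (i in 1:10) {
    env <- generate_environment(task_config(), seed = i)
    p1 <- make_params(m1, alpha_c = runif(1), aa_pos = runif(1),
                      aa_neg = runif(1), tau_c = runif(1, 0, 3),
                      tau_a = runif(1, 0, 3), omega_pos = runif(1),
                      omega_neg = runif(1))
    p4 <- make_params(m4c, alpha_c_pos = p1[["alpha_c"]],
                      alpha_c_neg = p1[["alpha_c"]],
                      aa_pos = p1[["alpha_a[positive]"]],
                      aa_neg = p1[["alpha_a[negative]"]],
                      tau_c = p1[["tau_c"]], tau_a = p1[["tau_a"]],
                      omega_pos = p1[["omega[positive]"]],
                      omega_neg = p1[["omega[negative]"]])
    s <- simulate_session(m1, p1, env, "mixed", seed = 50 + i)
    expect_equal(session_loglik(m4c, p4, s), session_loglik(m1, p1, s),
                 tolerance = 1e-12)
  }
})

test_that("self values converge to the coding-implied expectation", {
  # stationary p_green, single/symmetric updates, mixed frame: E[V_green]
  # approaches 2p - 1 when the green card is always chosen
  m1 <- model_spec("M1")
  pars <- make_params(m1, alpha_c = 0.1)
  set.seed(8)
  p <- 0.7
  v <- replicate(200, {
    st <- initial_state("mixed")
    for (t in 1:400) {
      r <- if (runif(1) < p) 1 else -1
      st <- update_self_values(st, "green", r, m1, pars, "mixed")
    }
    st$v_self_green
  })
  # stationary sd of V is ~sqrt(alpha/(2-alpha) * 4p(1-p)) ~ 0.21, so the
  # mean of 200 replicates has se ~ 0.015; allow 3 se
  expect_lt(abs(mean(v) - (2 * p - 1)), 0.045)
})
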