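make_session_with_choices <- function(id, followed_frac, correct_frac,
                                      seed = 1L) {
  env <- generate_environment(task_config(), seed = seed)
  n <- nrow(env)
  choice <- env$advice_card
  n_unfollow <- round((1 - followed_frac) * n)
  if (n_unfollow > 0) {
    flip <- seq_len(n_unfollow)
    choice[flip] <- ifelse(env$advice_card[flip] == "green", "blue", "green")
  }
  trials <- data.frame(env, choice = choice,
                       choice_correct = choice == env$correct_card,
                       reward_self = ifelse(choice == env$correct_card,
                                            1, -1),
                       advice_correct = env$advice_card == env$correct_card,
                       followed = choice == env$advice_card,
                       stringsAsFactors = FALSE)
  session_data(id, "mixed", trials)
}

test_that("condition summaries count accuracy and consistency correctly", {
  s_all <- make_session_with_choices("A", 1, NA, seed = 2)
  sm <- summarize_conditions(list(s_all))
  expect_true(all(sm$consistency == 1))

  s_mix <- make_session_with_choices("B", 0.7, NA, seed = 3)
  sm2 <- summarize_conditions(list(s_mix))
  total_follow <- sum(sm2$consistency * sm2$n_trials) / sum(sm2$n_trials)
  expect_equal(total_follow, 0.7)

  # all choices wrong: accuracy 0
  env <- generate_environment(task_config(), seed = 4)
  wrong <- ifelse(env$correct_card == "green", "blue", "green")
  tr <- data.frame(env, choice = wrong, choice_correct = FALSE,
                   reward_self = -1,
                   advice_correct = env$advice_card == env$correct_card,
                   followed = wrong == env$advice_card,
                   stringsAsFactors = FALSE)
  sm3 <- summarize_conditions(list(session_data("C", "mixed", tr)))
  expect_true(all(sm3$accuracy == 0))

  # order permutation within participant leaves summaries unchanged
  perm <- s_mix
  o <- sample(nrow(perm$trials))
  perm$trials <- perm$trials[o, ]
  perm$trials$trial_index <- seq_len(nrow(perm$trials))
  expect_equal(summarize_conditions(list(perm))[, c("accuracy",
                                                    "consistency")],
               sm2[, c("accuracy", "consistency")])
})

test_that("paired t matches hand arithmetic and is antisymmetric", {
  r0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # textbook: d = (1,2,3), mean 2, sd 1, t = 2/(1/sqrt(3)) = 2*sqrt(3)
  r1 <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r1$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r1$effect_size, 2, tolerance = 1e-12)
  expect_equal(r1$df, 2)

  r2 <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r2$statistic, -r1$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)

  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero-variance")
})

test_that("mixed ANOVA matches an independent textbook computation", {
  # 8 participants, 2 frames x 2 phrasings, hand-computable cell structure
  vals <- rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4),    # gain group
                c(2, 2), c(3, 3), c(4, 3), c(5, 4))    # loss group
  d <- data.frame(
    participant_id = rep(sprintf("S%d", 1:8), each = 2),
    frame = rep(c("gain", "loss"), each = 8),
    phrasing = rep(c("neg", "pos"), 8),
    val = as.vector(t(vals)))
  an <- mixed_anova(d, "val")

  # independent oracle: classical sums of squares for the balanced design
  grand <- mean(vals)
  subj_m <- rowMeans(vals)
  frame_m <- c(gain = mean(vals[1:4, ]), loss = mean(vals[5:8, ]))
  phr_m <- colMeans(vals)
  cell_m <- rbind(colMeans(vals[1:4, ]), colMeans(vals[5:8, ]))
  ss_frame <- 2 * 4 * sum((frame_m - grand)^2)
  ss_subj <- 2 * sum((subj_m - grand)^2) - ss_frame
  ss_phr <- 8 * sum((phr_m - grand)^2)
  ss_int <- 4 * sum((cell_m - outer(frame_m, phr_m, "+") + grand)^2)
  ss_wtot <- sum((vals - subj_m)^2)
  ss_err_w <- ss_wtot - ss_phr - ss_int
  f_phr <- (ss_phr / 1) / (ss_err_w / 6)
  f_frame <- (ss_frame / 1) / (ss_subj / 6)
  f_int <- (ss_int / 1) / (ss_err_w / 6)

  expect_equal(an$within$statistic, f_phr, tolerance = 1e-9)
  expect_equal(an$between$statistic, f_frame, tolerance = 1e-9)
  expect_equal(an$interaction$statistic, f_int, tolerance = 1e-9)
  expect_equal(an$within$df, c(1, 6))
  expect_equal(an$between$df, c(1, 6))
  # partial eta^2 from the same sums of squares
  expect_equal(an$within$effect_size, ss_phr / (ss_phr + ss_err_w),
               tolerance = 1e-9)
  expect_true(all(vapply(an, function(x) x$effect_size, 1.0) >= 0))
  expect_true(all(vapply(an, function(x) x$effect_size, 1.0) <= 1))
  expect_true(all(vapply(an, function(x) x$statistic, 1.0) >= 0))
})

test_that("all-equal cells give zero F throughout", {
  d <- data.frame(participant_id = rep(sprintf("S%d", 1:6), each = 2),
                  frame = rep(c("gain", "loss"), each = 6),
                  phrasing = rep(c("neg", "pos"), 6),
                  val = 3)
  an <- mixed_anova(d, "val")
  for (eff in an) expect_equal(eff$statistic, 0)
})

test_that("single-frame ANOVA equals the squared paired t", {
  set.seed(61)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    d <- data.frame(participant_id = rep(sprintf("S%d", 1:12), each = 2),
                    frame = "mixed",
                    phrasing = rep(c("neg", "pos"), 12),
                    val = as.vector(rbind(x, y)))
    an <- mixed_anova(d, "val")
    tt <- paired_t(x, y)
    expect_equal(an$within$statistic, tt$statistic^2, tolerance = 1e-9)
    expect_equal(an$within$kind, "rm_anova")
  }
})

test_that("unbalanced within-levels are rejected", {
  d <- data.frame(participant_id = c("S1", "S1", "S2"),
                  frame = "mixed", phrasing = c("neg", "pos", "neg"),
                  val = 1:3)
  expect_error(mixed_anova(d, "val"), "exactly one value")
})

test_that("the analysis battery covers every tabulated effect", {
  # two-frame shape from a parameter table (no MCMC needed)
  set.seed(62)
  co_g <- make_cohort(model_spec("M1"), n = 4L, seed = 63L,
                      task = task_config(frame = "gain"))
  co_l <- make_cohort(model_spec("M1"), n = 4L, seed = 64L,
                      task = task_config(frame = "loss"))
  sessions <- c(co_g$sessions, co_l$sessions)
  # distinct ids across the two frame groups
  for (i in 5:8) sessions[[i]]$participant_id <-
      sprintf("Q%03d", i)
  pt <- model_parameters(model_spec("M1"), phr_levels)
  est <- do.call(rbind, lapply(sessions, function(s)
    data.frame(participant = s$participant_id, parameter = pt$name,
               condition = pt$condition,
               estimate = runif(nrow(pt)), stringsAsFactors = FALSE)))
  res <- replicate_analysis(est, sessions)
  for (m in c("accuracy", "consistency", "omega", "alpha_a")) {
    eff <- res$effect[res$measure == m]
    expect_true(all(c("phrasing", "frame", "phrasing:frame") %in% eff),
                info = m)
  }
  # frame-wise simple effects present for the parameters
  expect_true(any(grepl("^gain:", res$effect[res$measure == "omega"])))
  expect_true(any(grepl("^loss:", res$effect[res$measure == "omega"])))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
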