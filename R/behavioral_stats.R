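#' Per-condition behavioural summaries
#'
#' Computes, for every participant and phrasing condition, the choice
#' accuracy (fraction of trials on which the chosen card was correct) and
#' the advice-choice consistency rate (fraction on which the chosen card
#' equalled the advised card).
#'
#' @param sessions A list of [session_data()] objects or a `cohort_data`.
#' @return Data frame with columns `participant_id`, `frame`, `phrasing`,
#'   `accuracy`, `consistency`, `n_trials`.
#' @export
summarize_conditions <- function(sessions) {
  sessions <- as_session_list(sessions)
  levels <- sort(unique(unlist(lapply(sessions,
                                      function(s) unique(s$trials$phrasing)))))
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(levels, function(lv) {
      tr <- s$trials[s$trials$phrasing == lv, , drop = FALSE]
      if (nrow(tr) == 0L)
        stop("participant ", s$participant_id, " has no trials in ",
             "condition '", lv, "'", call. = FALSE)
      data.frame(participant_id = s$participant_id, frame = s$frame,
                 phrasing = lv,
                 accuracy = mean(tr$choice_correct),
                 consistency = mean(tr$followed),
                 n_trials = nrow(tr), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

test_result <- function(kind, statistic, df, p_value, effect_size,
                        effect_ci, effect_label) {
  structure(list(kind = kind, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_ci = effect_ci, effect_label = effect_label),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(round(x$df, 1), collapse = ", ")
  stat_name <- if (x$kind == "paired_t") "t" else "F"
  cat(sprintf("%s: %s(%s) = %.3f, p = %.4g, %s = %.3f [%.3f, %.3f]\n",
              x$kind, stat_name, dfs, x$statistic, x$p_value,
              x$effect_label, x$effect_size, x$effect_ci[1], x$effect_ci[2]))
  invisible(x)
}

# CI for Cohen's dz via inversion of the noncentral-t distribution.
dz_ci <- function(t_stat, n, level = 0.95) {
  a <- (1 - level) / 2
  df <- n - 1
  bound <- function(p) {
    if (abs(t_stat) > 37) return(t_stat + stats::qnorm(p))  # normal appx
    f <- function(ncp) suppressWarnings(stats::pt(t_stat, df, ncp)) - p
    lo <- t_stat - 10 - 6 * sqrt(df)
    hi <- t_stat + 10 + 6 * sqrt(df)
    if (f(lo) < 0) return(lo)
    if (f(hi) > 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  c(bound(1 - a), bound(a)) / sqrt(n)
}

# CI for partial eta^2 via inversion of the noncentral-F distribution.
eta2_ci <- function(f_stat, df1, df2, level = 0.95) {
  a <- (1 - level) / 2
  bound <- function(p) {
    f <- function(ncp) stats::pf(f_stat, df1, df2, ncp) - p
    if (f(0) < 0) return(0)
    hi <- 10 * (f_stat + 1) * (df1 + df2)
    if (f(hi) > 0) return(hi)
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  ncp <- c(bound(1 - a), bound(a))
  ncp / (ncp + df1 + df2 + 1)
}

#' Paired-sample t-test with Cohen's dz
#'
#' Classical two-sided paired t-test on the within-participant differences,
#' reporting the standardized effect dz (mean difference over its standard
#' deviation) with a confidence interval obtained by inverting the
#' noncentral-t distribution.
#'
#' @param x,y Numeric vectors of per-participant values (equal length,
#'   >= 2).
#' @return A `test_result` with `kind = "paired_t"`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0 && mean(d) != 0)
    stop("zero-variance nonzero differences: t undefined", call. = FALSE)
  if (stats::sd(d) == 0)
    return(test_result("paired_t", 0, length(x) - 1, 1, 0, c(0, 0), "dz"))
  tt <- stats::t.test(x, y, paired = TRUE)
  dz <- mean(d) / stats::sd(d)
  test_result("paired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, dz, dz_ci(unname(tt$statistic), length(x)), "dz")
}

#' Repeated-measures / mixed-design ANOVA on condition summaries
#'
#' Runs the univariate mixed-design ANOVA with one within-participant
#' factor (phrasing) and, when the data span two frames, one
#' between-participant factor (frame): F, degrees of freedom, p and partial
#' eta-squared (with a noncentral-F confidence interval) for the within
#' main effect, the between main effect, and their interaction. With a
#' single frame the design degenerates to the one-factor repeated-measures
#' ANOVA, whose F equals the squared paired-t statistic.
#'
#' @param summaries Data frame in the shape of [summarize_conditions()]
#'   output (or any long table with the columns below).
#' @param dv Name of the dependent-variable column (e.g. `"consistency"`).
#' @param within Name of the within-participant factor column. Default
#'   `"phrasing"`.
#' @param between Name of the between-participant factor column. Default
#'   `"frame"`.
#' @return Named list of `test_result` objects: `within`, and for two-group
#'   data also `between` and `interaction`.
#' @export
mixed_anova <- function(summaries, dv, within = "phrasing",
                        between = "frame") {
  d <- data.frame(id = factor(summaries$participant_id),
                  w = factor(summaries[[within]]),
                  b = factor(summaries[[between]]),
                  y = summaries[[dv]])
  tab <- table(d$id, d$w)
  if (any(tab != 1L))
    stop("each participant needs exactly one value per within level",
         call. = FALSE)
  two_groups <- nlevels(d$b) > 1L
  if (two_groups) {
    fit <- stats::aov(y ~ b * w + Error(id / w), data = d)
  } else {
    fit <- stats::aov(y ~ w + Error(id / w), data = d)
  }
  sm <- summary(fit)
  get_stratum <- function(name) {
    s <- sm[[name]][[1]]
    rn <- trimws(rownames(s))
    list(tab = s, rn = rn)
  }
  mk <- function(tab, rn, effect, err_row, kind) {
    i <- match(effect, rn); j <- match(err_row, rn)
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[j, "Sum Sq"]
    f <- tab[i, "F value"]; df1 <- tab[i, "Df"]; df2 <- tab[j, "Df"]
    p <- tab[i, "Pr(>F)"]
    if (ss_e < 1e-12 * max(1, ss_r)) {  # no effect variance at all
      f <- 0; p <- 1
    }
    eta <- if (ss_e + ss_r == 0) 0 else ss_e / (ss_e + ss_r)
    test_result(kind, f, c(df1, df2), p, eta, eta2_ci(f, df1, df2),
                "partial_eta2")
  }
  if (two_groups) {
    s1 <- get_stratum("Error: id")
    s2 <- get_stratum("Error: id:w")
    list(within = mk(s2$tab, s2$rn, "w", "Residuals", "mixed_anova"),
         between = mk(s1$tab, s1$rn, "b", "Residuals", "mixed_anova"),
         interaction = mk(s2$tab, s2$rn, "b:w", "Residuals", "mixed_anova"))
  } else {
    s2 <- get_stratum("Error: id:w")
    list(within = mk(s2$tab, s2$rn, "w", "Residuals", "rm_anova"))
  }
}

#' Condition-level analysis battery
#'
#' Reproduces the full condition-level analysis on a fitted cohort:
#' accuracy and advice-choice consistency ANOVAs across phrasing (and
#' frame, when the sessions span a gain and a loss group), plus tests on
#' the fitted advice reference weight `omega` and advice learning rate
#' `alpha_a` — paired t-tests by phrasing in the single-frame shape,
#' mixed-design ANOVA with frame-wise simple-effect t-tests in the
#' two-frame shape.
#'
#' @param fit An [fit_advice_rl()] result, a list of such results (one per
#'   frame group), or a data frame of posterior point estimates in the
#'   shape of [posterior_point_estimates()] output.
#' @param sessions The analysed sessions (list or `cohort_data`, or a list
#'   of cohorts matching a list of fits).
#' @return Data frame with one row per effect: `measure`, `effect`,
#'   `kind`, `statistic`, `df1`, `df2`, `p_value`, `effect_size`,
#'   `ci_low`, `ci_high`.
#' @export
replicate_analysis <- function(fit, sessions) {
  if (inherits(fit, "advice_rl_fit")) fit <- list(fit)
  if (is.list(sessions) && inherits(sessions[[1]], "cohort_data")) {
    sessions <- unlist(lapply(sessions, as_session_list),
                       recursive = FALSE)
  } else {
    sessions <- as_session_list(sessions)
  }
  est <- if (is.data.frame(fit)) fit
  else do.call(rbind, lapply(fit, posterior_point_estimates))
  ids <- vapply(sessions, function(s) s$participant_id, "")
  if (!setequal(unique(est$participant), ids))
    stop("fitted participants do not match the sessions", call. = FALSE)

  beh <- summarize_conditions(sessions)
  frames <- unique(beh$frame)
  two_frames <- length(frames) > 1L
  levels <- sort(unique(beh$phrasing))
  frame_of <- stats::setNames(vapply(sessions, function(s) s$frame, ""), ids)

  rows <- list()
  push <- function(measure, effect, tr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, effect = effect, kind = tr$kind,
      statistic = tr$statistic, df1 = tr$df[1],
      df2 = if (length(tr$df) > 1) tr$df[2] else NA_real_,
      p_value = tr$p_value, effect_size = tr$effect_size,
      ci_low = tr$effect_ci[1], ci_high = tr$effect_ci[2],
      stringsAsFactors = FALSE)
  }
  for (m in c("accuracy", "consistency")) {
    an <- mixed_anova(beh, m)
    push(m, "phrasing", an$within)
    if (two_frames) {
      push(m, "frame", an$between)
      push(m, "phrasing:frame", an$interaction)
    }
  }
  # parameter tests on condition-specific estimates
  par_wide <- function(base) {
    e <- est[grepl(paste0("^", base, "\\["), est$parameter), ]
    out <- stats::reshape(e[, c("participant", "condition", "estimate")],
                          idvar = "participant", timevar = "condition",
                          direction = "wide")
    names(out) <- sub("^estimate\\.", "", names(out))
    out
  }
  for (base in c("omega", "alpha_a")) {
    w <- par_wide(base)
    if (nrow(w) == 0L) next
    if (!two_frames) {
      push(base, paste(levels, collapse = " vs "),
           paired_t(w[[levels[1]]], w[[levels[2]]]))
    } else {
      long <- do.call(rbind, lapply(levels, function(lv)
        data.frame(participant_id = w$participant, phrasing = lv,
                   frame = frame_of[w$participant], value = w[[lv]],
                   stringsAsFactors = FALSE)))
      an <- mixed_anova(long, "value")
      push(base, "phrasing", an$within)
      push(base, "frame", an$between)
      push(base, "phrasing:frame", an$interaction)
      for (fr in frames) {
        wf <- w[frame_of[w$participant] == fr, ]
        push(base, sprintf("%s: %s", fr, paste(levels, collapse = " vs ")),
             paired_t(wf[[levels[1]]], wf[[levels[2]]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
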