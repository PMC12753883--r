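#' Configure the probabilistic two-card advice task
#'
#' Defines the design constants of the card task: a session of `n_trials`
#' binary choices (green vs. blue card) in which the probability that the
#' green card is correct alternates between a high and a low value across
#' consecutive blocks, and a computerised adviser of fixed accuracy
#' recommends a card on every trial. Advice phrasing (e.g. positive
#' vs. negative wording) is interleaved within a session; the task frame
#' (how outcomes are coded) is a session-level property.
#'
#' @param n_trials Number of trials per session. Must be divisible by
#'   `block_length`. Default 100.
#' @param block_length Trials per probability block. Default 20 (five blocks
#'   of twenty in the default session).
#' @param p_green_high,p_green_low Green-card win probability in high and low
#'   blocks. Defaults 0.7 / 0.3. The schedule starts high and alternates.
#' @param adviser_accuracy Probability, constant across trials, that the
#'   advised card is the correct card. Default 0.6.
#' @param frame Outcome frame: `"mixed"` (reward for correct, loss for
#'   incorrect), `"gain"` (reward or nothing) or `"loss"` (nothing or loss).
#' @param phrasing_levels Distinct labels of the within-session advice
#'   phrasing conditions. Default `c("positive", "negative")`.
#' @param seed Integer seed attached to the configuration; used as the
#'   default seed by [generate_environment()].
#'
#' @return An object of class `task_config` (a validated list).
#' @seealso [build_block_schedule()], [generate_environment()]
#' @export
task_config <- function(n_trials = 100L, block_length = 20L,
                        p_green_high = 0.7, p_green_low = 0.3,
                        adviser_accuracy = 0.6,
                        frame = c("mixed", "gain", "loss"),
                        phrasing_levels = c("positive", "negative"),
                        seed = 1L) {
  frame <- match.arg(frame)
  n_trials <- as.integer(n_trials)
  block_length <- as.integer(block_length)
  if (n_trials < 1L || block_length < 1L)
    stop("n_trials and block_length must be positive counts", call. = FALSE)
  if (n_trials %% block_length != 0L)
    stop("n_trials (", n_trials, ") must be divisible by block_length (",
         block_length, ")", call. = FALSE)
  if (!(p_green_low > 0 && p_green_low < p_green_high && p_green_high < 1))
    stop("need 0 < p_green_low < p_green_high < 1", call. = FALSE)
  if (adviser_accuracy < 0.5 || adviser_accuracy >= 1)
    stop("adviser_accuracy must lie in [0.5, 1)", call. = FALSE)
  phrasing_levels <- as.character(phrasing_levels)
  if (length(phrasing_levels) < 1L || anyDuplicated(phrasing_levels))
    stop("phrasing_levels must be non-empty and distinct", call. = FALSE)
  structure(list(
    n_trials = n_trials, block_length = block_length,
    p_green_high = p_green_high, p_green_low = p_green_low,
    adviser_accuracy = adviser_accuracy, frame = frame,
    phrasing_levels = phrasing_levels, seed = as.integer(seed)
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration\n")
  cat(sprintf("  %d trials in blocks of %d (p_green %.2f / %.2f, starting high)\n",
              x$n_trials, x$block_length, x$p_green_high, x$p_green_low))
  cat(sprintf("  adviser accuracy %.2f, frame '%s'\n",
              x$adviser_accuracy, x$frame))
  cat("  phrasing levels:", paste(x$phrasing_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-trial green-card win probabilities
#'
#' Expands a task configuration into the trial-wise probability that the
#' green card is correct: the first block is at `p_green_high` and the value
#' alternates every `block_length` trials.
#'
#' @param config A [task_config()].
#' @return Numeric vector of length `config$n_trials`.
#' @export
build_block_schedule <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n_blocks <- config$n_trials %/% config$block_length
  p_block <- ifelse(seq_len(n_blocks) %% 2L == 1L,
                    config$p_green_high, config$p_green_low)
  rep(p_block, each = config$block_length)
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Balanced interleaving of phrasing labels within one block: every level gets
# floor(L/k) slots, remainders rotate across blocks, order shuffled.
balanced_phrasing_block <- function(levels, block_length, block_id) {
  k <- length(levels)
  base <- block_length %/% k
  extra <- block_length %% k
  counts <- rep(base, k)
  if (extra > 0) {
    first <- ((block_id - 1L) %% k) + 1L
    idx <- ((first - 1L + seq_len(extra) - 1L) %% k) + 1L
    counts[idx] <- counts[idx] + 1L
  }
  sample(rep(levels, times = counts))
}

#' Generate the hidden environment of one session
#'
#' Draws the per-trial correct card from the block schedule, the adviser's
#' recommendation (matching the correct card with probability
#' `adviser_accuracy`, otherwise the other card, independently per trial),
#' and a balanced random interleaving of the phrasing conditions.
#' The same configuration and seed always reproduce the same trace.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame of class `environment_trace` with columns
#'   `trial_index`, `block_id`, `p_green`, `correct_card`, `advice_card`,
#'   `phrasing`.
#' @export
generate_environment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  p_green <- build_block_schedule(config)
  n <- config$n_trials
  block_id <- rep(seq_len(n %/% config$block_length),
                  each = config$block_length)
  env <- with_seed(seed, {
    correct_green <- stats::runif(n) < p_green
    advice_match <- stats::runif(n) < config$adviser_accuracy
    phrasing <- unlist(lapply(unique(block_id), function(b)
      balanced_phrasing_block(config$phrasing_levels, config$block_length, b)))
    data.frame(
      trial_index = seq_len(n),
      block_id = block_id,
      p_green = p_green,
      correct_card = ifelse(correct_green, "green", "blue"),
      advice_card = ifelse(correct_green == advice_match, "green", "blue"),
      phrasing = phrasing,
      stringsAsFactors = FALSE
    )
  })
  class(env) <- c("environment_trace", "data.frame")
  env
}

#' Bundle one participant's trial records
#'
#' @param participant_id Identifier (coerced to character).
#' @param frame Task frame of the session.
#' @param trials Data frame of trial records ordered by `trial_index`.
#' @param true_params Optional named numeric vector of ground-truth
#'   parameters (filled by the synthetic-cohort generator).
#' @return An object of class `session_data`.
#' @export
session_data <- function(participant_id, frame, trials, true_params = NULL) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1L)
  if (!identical(trials$trial_index, seq_len(nrow(trials))))
    stop("trials must be ordered with contiguous 1-based trial_index",
         call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 frame = frame, trials = trials, true_params = true_params),
            class = "session_data")
}

session_csv_columns <- c("participant_id", "frame", "trial_index", "block_id",
                         "p_green", "phrasing", "correct_card", "advice_card",
                         "choice", "reward_self", "advice_correct", "followed")

#' Write sessions to a long-format trial-table CSV
#'
#' One row per trial; columns `participant_id, frame, trial_index, block_id,
#' p_green, phrasing, correct_card, advice_card, choice, reward_self,
#' advice_correct, followed`. [read_sessions()] inverts the operation
#' exactly.
#'
#' @param sessions A list of [session_data()] objects (a `cohort_data`
#'   object is also accepted).
#' @param path Output file path.
#' @export
write_sessions <- function(sessions, path) {
  sessions <- as_session_list(sessions)
  tabs <- lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(participant_id = s$participant_id, frame = s$frame,
               tr[, c("trial_index", "block_id", "p_green", "phrasing",
                      "correct_card", "advice_card", "choice")],
               reward_self = tr$reward_self,
               advice_correct = tr$advice_correct,
               followed = tr$followed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_session_list <- function(x) {
  if (inherits(x, "cohort_data")) return(x$sessions)
  if (inherits(x, "session_data")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "session_data")))
  x
}

#' Read sessions from a trial-table CSV
#'
#' Validates the schema (required columns, card/choice enum values, per
#' participant a contiguous 1-based `trial_index` without duplicates) and
#' reports the offending row on failure.
#'
#' @param path CSV file written by [write_sessions()] (or hand-assembled in
#'   the same schema).
#' @return A list of [session_data()] objects.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(session_csv_columns, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) stop("empty trial table", call. = FALSE)
  for (col in c("correct_card", "advice_card", "choice")) {
    bad <- which(!tab[[col]] %in% c("green", "blue"))
    if (length(bad))
      stop(sprintf("row %d: %s = '%s' is not 'green' or 'blue'",
                   bad[1], col, tab[[col]][bad[1]]), call. = FALSE)
  }
  bad_frame <- which(!tab$frame %in% c("mixed", "gain", "loss"))
  if (length(bad_frame))
    stop(sprintf("row %d: unknown frame '%s'", bad_frame[1],
                 tab$frame[bad_frame[1]]), call. = FALSE)
  ids <- unique(tab$participant_id)
  lapply(ids, function(id) {
    rows <- tab[tab$participant_id == id, , drop = FALSE]
    if (anyDuplicated(rows$trial_index)) {
      d <- rows$trial_index[duplicated(rows$trial_index)][1]
      stop(sprintf("participant %s: duplicated trial_index %d", id, d),
           call. = FALSE)
    }
    rows <- rows[order(rows$trial_index), , drop = FALSE]
    if (!identical(as.integer(rows$trial_index), seq_len(nrow(rows))))
      stop(sprintf("participant %s: trial_index not contiguous from 1", id),
           call. = FALSE)
    if (length(unique(rows$frame)) != 1L)
      stop(sprintf("participant %s: inconsistent frame", id), call. = FALSE)
    trials <- data.frame(
      trial_index = as.integer(rows$trial_index),
      block_id = as.integer(rows$block_id),
      p_green = rows$p_green,
      correct_card = rows$correct_card,
      advice_card = rows$advice_card,
      phrasing = rows$phrasing,
      choice = rows$choice,
      choice_correct = rows$choice == rows$correct_card,
      reward_self = rows$reward_self,
      advice_correct = as.logical(rows$advice_correct),
      followed = as.logical(rows$followed),
      stringsAsFactors = FALSE
    )
    session_data(id, rows$frame[1], trials)
  })
}
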