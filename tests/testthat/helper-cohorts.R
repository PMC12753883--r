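# Shared builders for the test suite. All fixtures are generated in code.

phr_levels <- c("positive", "negative")

# Named parameter vector for a model, with per-condition overrides like
# omega_pos/omega_neg and aa_pos/aa_neg.
make_params <- function(spec, alpha_c = 0.35, alpha_c_pos = 0.65,
                        alpha_c_neg = 0.15, aa_pos = 0.45, aa_neg = 0.45,
                        tau_c = 1.5, tau_a = 1.5, omega_pos = 0.3,
                        omega_neg = 0.2, levels = phr_levels) {
  pt <- model_parameters(spec, levels)
  v <- numeric(nrow(pt))
  names(v) <- pt$name
  for (nm in pt$name) {
    v[nm] <- switch(sub("\\[.*\\]$", "", nm),
      alpha_c = alpha_c, alpha_c_pos = alpha_c_pos,
      alpha_c_neg = alpha_c_neg,
      alpha_a = if (grepl("positive", nm)) aa_pos else aa_neg,
      alpha_a_pos = if (grepl("positive", nm)) aa_pos else aa_neg,
      alpha_a_neg = if (grepl("positive", nm)) aa_pos else aa_neg,
      tau_c = tau_c, tau_a = tau_a,
      omega = if (grepl("positive", nm)) omega_pos else omega_neg)
  }
  v
}

# Group means/sds vectors for group_config from the same shorthand.
make_group_means <- function(spec, ..., levels = phr_levels) {
  make_params(spec, ..., levels = levels)
}

make_group_sds <- function(spec, sd_rate = 0.05, sd_tau = 0.3,
                           levels = phr_levels) {
  pt <- model_parameters(spec, levels)
  stats::setNames(ifelse(pt$kind == "tau", sd_tau, sd_rate), pt$name)
}

make_cohort <- function(spec, n = 8L, seed = 1L, task = task_config(), ...) {
  means <- make_group_means(spec, ...)
  group_config(task$frame, n, means, make_group_sds(spec), spec, task,
               seed = seed) |> generate_cohort()
}

# The recovery-study cohort used by several acceptance checks: M1 generator,
# strongly separated advice weights, tight dispersion.
recovery_cohort <- function(seed = 11L, n = 20L) {
  m1 <- model_spec("M1")
  means <- make_group_means(m1, omega_pos = 0.8, omega_neg = 0.2,
                            alpha_c = 0.35, tau_c = 1.5, tau_a = 1.5)
  group_config("mixed", n, means, make_group_sds(m1), m1, task_config(),
               seed = seed) |> generate_cohort()
}

tiny_sampler <- function(seed = 1L) {
  sampler_config(n_chains = 2L, n_iterations = 200L, thin = 2L, seed = seed)
}
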