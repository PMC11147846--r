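# Shared small fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 14-parcel atlas covering all 7 networks (2 parcels each).
tiny_atlas <- function() {
  memo("tiny_atlas", function() {
    fc_atlas(sprintf("P%02d", 1:14), rep(yeo7_networks, each = 2))
  })
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 16, atlas = tiny_atlas(), t_len = 150,
         n_factors = 4, seed = 101L),
    list(...)
  )
  do.call(cohort_config, args)
}

# Small full cohort (eFC + SC + resampled + cognition).
tiny_cohort <- function() {
  memo("tiny_cohort", function() generate_cohort(tiny_config()))
}

# Mid-size DK-like cohort used by the heavier statistical checks.
mid_cohort <- function() {
  memo("mid_cohort", function() {
    generate_cohort(cohort_config(n_subjects = 40, t_len = 400, seed = 202L),
                    components = c("sc", "sc_resampled", "cognition"))
  })
}

# A random symmetric nonnegative integer "streamline count" matrix.
random_sc_counts <- function(p, seed = 1, max_count = 5000) {
  withr::with_seed(seed, {
    v <- round(exp(rnorm(p * (p - 1) / 2, 3, 1.5)))
    devectorize(pmin(v, max_count), p, diag = 0)
  })
}

fold_train_idx_for_test <- function(folds, f) which(folds$assignment != f)

# Independent textbook Pearson correlation (explicit sums, no cor()).
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
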