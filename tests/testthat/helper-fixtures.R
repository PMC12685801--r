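# Shared fixtures, built once per test run. Kept small: a 16^3 grid with
# the default 5 lobes is enough to exercise every pipeline stage.

fixture_config <- function(...) {
  args <- modifyList(list(grid_size = 16L, n_samples = 20L, seed = 123L),
                     list(...))
  do.call(phantom_config, args)
}

local({
  cfg <- fixture_config()
  assign("FIX_CFG", cfg, envir = topenv())
  assign("FIX_COHORT", generate_cohort(cfg), envir = topenv())
})

fixture_model <- function(seed = 5L, ...) {
  build_model(FIX_CFG, channels = 4L, blocks = 1L, d1 = 4L, d2 = 4L,
              seed = seed, ...)
}

# random unit-ish vectors for loss oracles
rvec <- function(n) rnorm(n)
rmat <- function(n, d) matrix(rnorm(n * d), n)

expect_close <- function(x, y, tol = 1e-6) {
  expect_lt(max(abs(ad_value(x) - ad_value(y))), tol)
}

# relative agreement used by the loss-oracle suite
rel_err <- function(a, b) {
  a <- ad_value(a); b <- ad_value(b)
  abs(a - b) / pmax(abs(a), abs(b), 1e-12)
}
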