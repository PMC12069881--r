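# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

zero_noise <- function() {
  noise_profile(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                drift_slope = 0, white_sd = 0)
}

small_spec <- function() {
  ensemble_spec(n_rounds = 10, rf_trees = 100, mlp_maxit = 100)
}

# zero-noise episode set + labelled windows + fitted selector
zn_windows <- function() {
  fixture("zn_windows", function() {
    eps <- generate_dataset(4, scenario_profile(1, noise = zero_noise()),
                            seed = 7)
    win <- collect_windows(eps, stride_s = 0.5)
    sel <- fit_selector(win$features, win$labels)
    list(eps = eps, win = win, sel = sel,
         x = apply_selector(sel, win$features))
  })
}

# default-noise windows (the standard study conditions)
dn_windows <- function() {
  fixture("dn_windows", function() {
    eps <- generate_dataset(8, scenario_profile(1), seed = 7)
    win <- collect_windows(eps, stride_s = 0.5)
    sel <- fit_selector(win$features, win$labels)
    list(eps = eps, win = win, sel = sel,
         x = apply_selector(sel, win$features))
  })
}

# clearly separable 32-dim two-class set for classifier unit tests
separable_set <- function(n = 120, seed = 42) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), length.out = n)
  x <- matrix(rnorm(n * 32, 0, 1), n, 32)
  x[y, 1:4] <- x[y, 1:4] + 4
  colnames(x) <- paste0("v", 1:32)
  list(x = x, y = y)
}

# tiny TD3 configuration for fast agent tests
tiny_td3 <- function(warmup = 50, ...) {
  td3_config(hidden = c(8, 8), batch_size = 16, warmup = warmup,
             buffer_cap = 5000, ...)
}
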