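# Independent oracles used across the suite. They never call the package's
# linear-algebra path: ordinary least squares goes through lm.fit (QR), and
# basis evaluation is re-derived from the trig formula inline.

# per-signal OLS of B (signals x trials) on channel design C (k x trials)
oracle_fit_weights <- function(B, C) {
  t(apply(B, 1, function(b) stats::lm.fit(t(C), b)$coefficients))
}

# per-trial least-squares channel estimate from weights W (signals x k)
oracle_invert <- function(W, B) {
  apply(B, 2, function(b) stats::lm.fit(W, b)$coefficients)
}

# brute-force channel-sum coverage on an n-point grid, straight from the
# raised-cosine formula
oracle_coverage <- function(k, exponent, n = 1000, period = 180) {
  th <- period * (seq_len(n) - 1) / n
  cent <- period * (0:(k - 1)) / k
  d <- outer(cent, th, function(a, b) {
    dd <- abs(a - b) %% period
    pmin(dd, period - dd)
  })
  v <- pmax(cos(pi * d / period), 0)^exponent
  colSums(v)
}

# small random fit/invert instance (signals x channels x trials)
random_instance <- function(n_signals, k, n_trials) {
  list(B = matrix(rnorm(n_signals * n_trials), n_signals),
       C = matrix(rnorm(k * n_trials), k),
       W = matrix(rnorm(n_signals * k), n_signals))
}

# a small, fast simulation configuration for pipeline tests
tiny_config <- function(seed = 11, noise_sd = 0, ...) {
  sim_config(n_voxels = 12, n_neurons = 15, n_trials_per_cell = 4,
             noise_sd = noise_sd, seed = seed, ...)
}

# random invertible channel transform with bounded condition number
random_transform <- function(k, max_kappa = 1e4) {
  repeat {
    m <- matrix(rnorm(k * k), k)
    s <- svd(m, nu = 0, nv = 0)$d
    if (max(s) / min(s) < max_kappa) return(m)
  }
}

# run the CLI in a child R process with the current library path
run_cli <- function(args, env = character()) {
  cli <- system.file("cli", "iem_workbench.R", package = "iemr")
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- suppressWarnings(system2(
    rscript, c(cli, args), stdout = TRUE, stderr = TRUE,
    env = c(sprintf("R_LIBS=%s", paste(.libPaths(), collapse = .Platform$path.sep)),
            env)))
  list(status = attr(res, "status") %||% 0L, output = paste(res, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
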