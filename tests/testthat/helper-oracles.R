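# Independent closed-form OLS oracle: explicit normal equations, no lm().
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Points lying exactly on Inhibition = K * lgC + b.
line_points <- function(K, b, lgc) {
  data.frame(concentration_mol_per_l = 10^lgc,
             inhibition_percent = K * lgc + b)
}

# A small random regression instance under a fixed seed.
random_instance <- function(seed, n = 20, p = 3, sd = 0.5) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n, p,
                              dimnames = list(NULL, paste0("x", seq_len(p)))))
    beta <- rnorm(p + 1)
    y <- drop(cbind(1, as.matrix(X)) %*% beta) + rnorm(n, 0, sd)
    list(X = X, y = y)
  })
}

# Noise-free generator configuration (all stochastic laws at their defaults).
noiseless_config <- function(...) {
  generator_config(slope_ratio_noise_sd = 0, dose_noise_sd = 0,
                   mixture_noise_sd = 0, hormesis = FALSE, ...)
}
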