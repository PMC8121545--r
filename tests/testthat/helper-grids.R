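# build a small posterior_grid with given axes and (optionally) weights
toy_grid <- function(t_values, s_values, prob = NULL) {
  g <- list(t_values = t_values, s_values = s_values,
            prob = if (is.null(prob)) {
              matrix(1 / (length(t_values) * length(s_values)),
                     length(t_values), length(s_values))
            } else prob / sum(prob))
  class(g) <- "posterior_grid"
  g
}

# a grid concentrated (numerically) on a single (t, s) cell
point_mass_grid <- function(t_values, s_values, t_at, s_at) {
  p <- matrix(0, length(t_values), length(s_values))
  p[match(t_at, t_values), match(s_at, s_values)] <- 1
  toy_grid(t_values, s_values, p)
}

# independent brute-force Bayes oracle: prior x product of per-trial
# Gaussian feedback likelihoods, evaluated cell by cell with dnorm()
oracle_posterior <- function(grid, trials) {
  p <- grid$prob
  for (k in seq_len(nrow(trials))) {
    f <- trials$f[k]; m <- trials$m[k]; v <- trials$v[k]
    for (i in seq_along(grid$t_values)) {
      for (j in seq_along(grid$s_values)) {
        tt <- grid$t_values[i]; ss <- grid$s_values[j]
        p[i, j] <- p[i, j] * dnorm(f, (m - tt) * ss, sqrt(v) * ss)
      }
    }
  }
  p / sum(p)
}

# minimal epoch_array filled with a constant, for constructed-waveform tests
const_epochs <- function(value = 0, n_epochs = 1L,
                         channels = c("FCz", "Pz"), n_samples = 500L) {
  epoch_array(array(value, c(n_epochs, length(channels), n_samples)),
              channels)
}
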