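# Shared fixtures, built in code.

# random 2x2 symmetric positive-definite matrix
rand_psd2 <- function(scale = 1) {
  a <- matrix(stats::rnorm(4), 2, 2)
  crossprod(a) + diag(0.1, 2) * scale
}

# random well-conditioned 2x2 system matrix
rand_forward <- function() {
  repeat {
    m <- matrix(stats::runif(4, -2, 2), 2, 2)
    if (abs(det(m)) > 0.3) {
      return(build_forward_matrix(m[, 1], m[, 2]))
    }
  }
}

# short synthetic config for cheap tests
quick_config <- function(...) {
  synthetic_config(duration_s = 10, ...)
}

# closed-form ensemble MSE of a linear estimator G under (Rrr, Rnn):
# MSE = tr(Rrr) - 2 tr(G F Rrr) + tr(G (F Rrr F' + Rnn) G')
ensemble_mse <- function(g, f, rrr, rnn) {
  f <- matrix(as.numeric(f), 2, 2)
  rrr <- matrix(as.numeric(rrr), 2, 2)
  rnn <- matrix(as.numeric(rnn), 2, 2)
  sum(diag(rrr)) - 2 * sum(diag(g %*% f %*% rrr)) +
    sum(diag(g %*% (f %*% rrr %*% t(f) + rnn) %*% t(g)))
}
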