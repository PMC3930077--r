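# Independent brute-force oracles, kept free of the package's pooling path:
# plain elementwise summation of the defining formulas.

bf_fixed <- function(thetas, ses) {
  w <- numeric(length(thetas)); num <- 0; den <- 0
  for (i in seq_along(thetas)) {
    w[i] <- 1 / (ses[i] * ses[i])
    num <- num + w[i] * thetas[i]
    den <- den + w[i]
  }
  th <- num / den
  Q <- 0
  for (i in seq_along(thetas)) Q <- Q + w[i] * (thetas[i] - th)^2
  df <- length(thetas) - 1
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(theta_hat = th, Q = Q, i_squared = i2, df = df)
}

bf_dl_tau2 <- function(thetas, ses) {
  o <- bf_fixed(thetas, ses)
  w <- 1 / ses^2
  max(0, (o$Q - o$df) / (sum(w) - sum(w^2) / sum(w)))
}
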