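# internal numeric helpers shared across the fitting and analysis code

# row-wise softmax of a matrix of log-weights; rows with all -Inf become uniform
softmax_rows <- function(logw) {
  m <- apply(logw, 1L, max)
  m[!is.finite(m)] <- 0
  w <- exp(logw - m)
  s <- rowSums(w)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    w[bad, ] <- 1
    s[bad] <- ncol(logw)
  }
  w / s
}

# cumulative sum shifted right by one (first element 0)
cumsum0 <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  c(0, cumsum(x))[seq_along(x)]
}

# sum of elements strictly after position i, for each i
revcumsum_excl <- function(x) {
  rev(cumsum0(rev(x)))
}

kl_beta <- function(a, b, a0, b0) {
  lbeta(a0, b0) - lbeta(a, b) +
    (a - a0) * digamma(a) + (b - b0) * digamma(b) -
    (a + b - a0 - b0) * digamma(a + b)
}

kl_gamma <- function(a1, b1, a0, b0) {
  (a1 - a0) * digamma(a1) - lgamma(a1) + lgamma(a0) +
    a0 * (log(b1) - log(b0)) + a1 * (b0 - b1) / b1
}

# KL between Normal-Gamma posteriors/priors parameterised as
# s ~ Gamma(shape, rate), mean | s ~ N(mu, 1 / (lambda * s))
kl_normal_gamma <- function(mu, lambda, shape, rate, mu0, lambda0, shape0, rate0) {
  kl_gamma(shape, rate, shape0, rate0) +
    0.5 * log(lambda / lambda0) + lambda0 / (2 * lambda) +
    0.5 * lambda0 * (shape / rate) * (mu - mu0)^2 - 0.5
}

# KL(Dirichlet(q) || Dirichlet(rep(rho0, L))) for q a vector
kl_dirichlet <- function(q, rho0) {
  L <- length(q)
  sq <- sum(q)
  lgamma(sq) - sum(lgamma(q)) - lgamma(L * rho0) + L * lgamma(rho0) +
    sum((q - rho0) * (digamma(q) - digamma(sq)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mvc <- function(..., class = "mvcoclust_error") {
  rlang::abort(paste0(...), class = unique(c(class, "mvcoclust_error")))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_mvc(...)
}
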