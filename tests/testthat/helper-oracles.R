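# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles and share
# no code with the implementation paths they check.

# Brute-force Kaplan-Meier product-limit median: walk distinct times in
# order; at each time the at-risk set counts every record (event or
# censored) with time >= t; return the first time the survival product
# drops to 0.5 or below.
oracle_km_median <- function(event_times, censor_times) {
  if (length(event_times) == 0L) return(NA_real_)
  s <- 1
  for (t in sort(unique(c(event_times, censor_times)))) {
    d <- sum(event_times == t)
    if (d > 0L) {
      n_risk <- sum(event_times >= t) + sum(censor_times >= t)
      s <- s * (1 - d / n_risk)
    }
    if (s <= 0.5 + 1e-12) return(as.numeric(t))
  }
  NA_real_
}

# Optimal-linear endpoint estimate of the upper limit, transcribed directly
# from the published weight equations: sightings sorted descending,
# tail-shape vhat = mean_i log((t_1 - t_k)/(t_1 - t_i)), weight matrix
# L[i,j] = G(2v + max(i,j)) G(v + min(i,j)) / (G(v + max(i,j)) G(min(i,j))),
# weights lambda = L^-1 e / (e' L^-1 e), estimate sum(lambda * t).
oracle_ole_upper <- function(x) {
  t <- sort(unique(x), decreasing = TRUE)
  k <- length(t)
  vhat <- 0
  for (i in 2:(k - 1)) vhat <- vhat + log((t[1] - t[k]) / (t[1] - t[i]))
  vhat <- vhat / (k - 1)
  L <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    a <- min(i, j); b <- max(i, j)
    L[i, j] <- exp(lgamma(2 * vhat + b) + lgamma(vhat + a) -
                     lgamma(vhat + b) - lgamma(a))
  }
  e <- rep(1, k)
  w <- solve(L) %*% e
  lambda <- w / as.numeric(t(e) %*% w)
  sum(lambda * t)
}
oracle_ole_lower <- function(x) -oracle_ole_upper(-x)

# Exact expectation of the minimum of n independent draws from the discrete
# uniform on a..b (with replacement): E[min] = (a-1) + sum_v P(min >= v).
oracle_discrete_uniform_emin <- function(a, b, n) {
  m <- b - a + 1
  (a - 1) + sum(((b - (a:b) + 1) / m)^n)
}

# Sample skewness (population moments form).
oracle_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (sqrt(mean((x - m)^2)))^3
}
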