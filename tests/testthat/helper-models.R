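# Shared fixtures: random generative models and brute-force oracles written
# directly from the definitions, independent of the package's vectorized
# implementations.

random_stochastic <- function(nrow, ncol) {
  m <- matrix(stats::runif(nrow * ncol, min = 0.05, max = 1), nrow, ncol)
  sweep(m, 2, colSums(m), "/")
}

random_model <- function() {
  list(A = random_stochastic(10, 9),
       B = lapply(1:9, function(i) random_stochastic(9, 9)),
       C = as.vector(random_stochastic(10, 1)),
       D = as.vector(random_stochastic(9, 1)),
       qs = as.vector(random_stochastic(9, 1)))
}

# exact categorical posterior by direct Bayes rule
oracle_posterior <- function(A, D, o) {
  w <- D * A[o, ]
  w / sum(w)
}

# expected free energy by explicit loops over (policy, outcome, state)
oracle_efe <- function(A, B, C, qs) {
  G <- numeric(9)
  for (p in 1:9) {
    qs_p <- numeric(9)
    for (s2 in 1:9) for (s1 in 1:9) qs_p[s2] <- qs_p[s2] + B[[p]][s2, s1] * qs[s1]
    qo_p <- numeric(10)
    for (o in 1:10) for (s2 in 1:9) qo_p[o] <- qo_p[o] + A[o, s2] * qs_p[s2]
    risk <- 0
    for (o in 1:10) risk <- risk + qo_p[o] * (log(qo_p[o]) - log(C[o]))
    amb <- 0
    for (s2 in 1:9) {
      h <- 0
      for (o in 1:10) {
        a <- max(A[o, s2], 1e-16)
        h <- h - a * log(a)
      }
      amb <- amb + qs_p[s2] * h
    }
    G[p] <- risk + amb
  }
  G
}

# naive double-loop distance coefficient
oracle_dc <- function(pos) {
  n <- nrow(pos)
  total <- 0
  for (i in 1:n) for (j in 1:n)
    total <- total + sqrt(sum((pos[i, ] - pos[j, ])^2))
  total / n
}

# small fast config for behavioral tests
quick_config <- function(...) {
  sim_config(n_ants = 5L, n_steps = 100L, snapshot_every = 50L, ...)
}
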