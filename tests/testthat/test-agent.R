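test_that("likelihood remapping is one-hot and matches the reallocation matrix", {
  lv <- c(1L, 1L, 1L, 10L, 1L, 1L, 1L, 1L, 1L)
  A <- remap_likelihood(lv)
  expect_equal(dim(A), c(10L, 9L))
  expect_equal(colSums(A), rep(1, 9))
  expect_equal(A[10, 4], 1)
  expect_equal(sum(A[1, ]), 8)
  expect_error(remap_likelihood(c(lv[-1], 11L)), "levels")

  # A is the local re-cut of the environment's reallocation matrix
  ar <- build_tmaze()
  set.seed(5)
  cells <- which(ar$walkable)
  ar$pheromone[sample(cells, 60)] <- sample(2:10, 60, replace = TRUE)
  M <- make_reallocation_matrix(ar)
  pos <- c(3L, 20L)
  w <- local_window(ar, pos)
  A2 <- remap_likelihood(w$levels)
  lin <- (pos[2] - 1L + c(0, 0, 1, 1, 1, 0, -1, -1, -1)) * ar$height +
    pos[1] + c(0, -1, -1, 0, 1, 1, 1, 0, -1)
  expect_equal(A2, t(M[lin, ]))
})

test_that("preference distributions: flat uniform, strict exponential in level", {
  flat <- build_preferences("flat")
  expect_equal(flat, rep(0.1, 10))
  strict <- build_preferences("strict", alpha = 0.5)
  expect_equal(sum(strict), 1)
  expect_true(all(diff(strict) > 0))
  expect_equal(strict[10] / strict[1], exp(4.5))
  expect_error(build_preferences("strict", alpha = 0), "alpha")
  expect_error(build_preferences("sloped"))
})

test_that("state inference equals the exact categorical posterior", {
  # uninformative likelihood returns the prior
  A_unif <- matrix(0.1, 10, 9)
  D <- c(0.5, rep(0.0625, 8))
  expect_equal(infer_states(A_unif, D, 3L), D)
  # unique consistent column -> one-hot posterior
  lv <- c(1L, 7L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  A <- remap_likelihood(lv)
  qs <- infer_states(A, rep(1 / 9, 9), 7L)
  expect_equal(qs[2], 1, tolerance = 1e-12)
  # k consistent columns under a uniform prior -> uniform over those k
  lv2 <- c(4L, 4L, 1L, 4L, 1L, 1L, 1L, 1L, 1L)
  qs2 <- infer_states(remap_likelihood(lv2), rep(1 / 9, 9), 4L)
  expect_equal(qs2[c(1, 2, 4)], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(qs2[-c(1, 2, 4)]), 0, tolerance = 1e-10)
  # randomized models against direct Bayes rule
  set.seed(101)
  for (i in 1:300) {
    m <- random_model()
    o <- sample(1:10, 1)
    expect_equal(infer_states(m$A, m$D, o), oracle_posterior(m$A, m$D, o),
                 tolerance = 1e-10)
  }
})

test_that("expected free energy matches the brute-force enumeration oracle", {
  set.seed(202)
  for (i in 1:300) {
    m <- random_model()
    expect_equal(expected_free_energy(m$A, m$B, m$C, m$qs),
                 oracle_efe(m$A, m$B, m$C, m$qs), tolerance = 1e-10)
  }
})

test_that("EFE special cases: flat indifference, deterministic sensing, gradient pull", {
  B <- make_transitions()
  qs <- c(1, rep(0, 8))
  # flat C with one-hot A: all policies equivalent
  lvls <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)
  A <- remap_likelihood(lvls)
  Gf <- expected_free_energy(A, B, build_preferences("flat"), qs)
  expect_equal(max(Gf) - min(Gf), 0, tolerance = 1e-12)
  # deterministic sensing: ambiguity 0 and G = -ln C(level at destination)
  C <- build_preferences("strict", 0.5)
  G <- expected_free_energy(A, B, C, qs)
  expect_equal(G, -log(C[lvls]), tolerance = 1e-9)
  # a single level-10 neighbor has strictly minimal G under strict C
  lv <- c(1L, 1L, 1L, 10L, 1L, 1L, 1L, 1L, 1L)
  G10 <- expected_free_energy(remap_likelihood(lv), B, C, qs)
  expect_equal(which.min(G10), 4L)
  expect_true(all(G10[-4] > G10[4]))
})

test_that("policy posterior masks walls, normalizes, and sharpens with gamma", {
  G0 <- rep(0, 9)
  feas <- rep(TRUE, 9)
  expect_equal(policy_posterior(G0, feas, gamma = 1), rep(1 / 9, 9))
  # log-space bonus arithmetic: ln 2 on one policy doubles its weight
  b <- rep(0, 9); b[5] <- log(2)
  q <- policy_posterior(G0, feas, gamma = 1, homing_bonus = b)
  expect_equal(q[5], 2 / 10, tolerance = 1e-12)
  expect_equal(q[1], 1 / 10, tolerance = 1e-12)
  # infeasible policies get exactly zero
  feas2 <- feas; feas2[c(2, 9)] <- FALSE
  q2 <- policy_posterior(G0, feas2, gamma = 1)
  expect_equal(q2[c(2, 9)], c(0, 0))
  expect_equal(sum(q2), 1)
  expect_error(policy_posterior(G0, rep(FALSE, 9), 1), "feasible")
  # gamma -> Inf concentrates on the argmin-G policy
  set.seed(9)
  G <- runif(9)
  q_hi <- policy_posterior(G, feas, gamma = 1e6)
  expect_equal(q_hi[which.min(G)], 1, tolerance = 1e-9)
  # precision monotonicity: argmin mass never decreases in gamma
  gammas <- c(0.5, 1, 2, 5, 10, 50)
  mass <- vapply(gammas, function(g)
    policy_posterior(G, feas, gamma = g)[which.min(G)], numeric(1))
  expect_true(all(diff(mass) >= -1e-12))
})

test_that("action sampling is categorical, reproducible, and argmax-capable", {
  onehot <- c(rep(0, 4), 1, rep(0, 4))
  s <- rng_stream(1)
  expect_true(all(replicate(20, sample_action(onehot, s)) == 5L))
  # uniform draws: each index close to n*p (binomial CI)
  s2 <- rng_stream(2)
  n <- 90000
  draws <- vapply(seq_len(n), function(i)
    sample_action(rep(1 / 9, 9), s2), integer(1))
  counts <- tabulate(draws, 9)
  expect_true(all(abs(counts - n / 9) <= 4 * sqrt(n * (1 / 9) * (8 / 9))))
  # fixed seed gives an identical draw sequence
  sa <- rng_stream(33); sb <- rng_stream(33)
  da <- replicate(50, sample_action(rep(1 / 9, 9), sa))
  expect_identical(da, replicate(50, sample_action(rep(1 / 9, 9), sb)))
  expect_equal(sample_action(c(0.3, 0.5, 0.2, rep(0, 6)), mode = "argmax"), 2L)
})

test_that("model pieces stay normalized after every operation", {
  set.seed(77)
  for (i in 1:50) {
    m <- random_model()
    o <- sample(1:10, 1)
    qs <- infer_states(m$A, m$D, o)
    expect_equal(sum(qs), 1, tolerance = 1e-12)
    G <- expected_free_energy(m$A, m$B, m$C, qs)
    qpi <- policy_posterior(G, rep(TRUE, 9), gamma = 2)
    expect_equal(sum(qpi), 1, tolerance = 1e-12)
  }
  mod <- make_generative_model()
  expect_equal(sum(mod$C), 1, tolerance = 1e-12)
  expect_equal(sum(mod$D), 1, tolerance = 1e-12)
  for (Bp in mod$B) expect_equal(colSums(Bp), rep(1, 9))
})
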