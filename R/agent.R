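# Per-step active-inference core of one forager. The generative model is a
# single-factor discrete MDP over the 9 cells of the agent's 3x3
# neighborhood (hidden states = policies = one-step relocations), with 10
# pheromone-level outcomes. The likelihood A is re-cut from the arena's
# reallocation matrix every step, which is what keeps sensing local.

PROB_FLOOR <- 1e-16

safe_log <- function(p) {
  p[p < PROB_FLOOR] <- PROB_FLOOR
  log(p)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Re-cut the agent's likelihood from a local window
#'
#' Builds the per-step likelihood A (10 outcome levels x 9 local states):
#' with unbiased sensing, column j is one-hot at the pheromone level of
#' window cell j. A equals the 9 corresponding rows of the environment's
#' reallocation matrix, transposed into columns.
#'
#' @param window_levels 9 pheromone levels in the canonical neighborhood
#'   order (see [local_window()]).
#' @return A 10x9 column-stochastic matrix.
#' @export
remap_likelihood <- function(window_levels) {
  if (length(window_levels) != N_POLICIES ||
      any(window_levels < 1L | window_levels > N_LEVELS))
    stop("`window_levels` must be 9 levels in 1..10", call. = FALSE)
  A <- matrix(0, N_LEVELS, N_POLICIES)
  A[cbind(window_levels, seq_len(N_POLICIES))] <- 1
  A
}

#' Pheromone preference distribution C
#'
#' `"flat"` gives a uniform distribution over the 10 levels (no preference:
#' the forager diffuses like a random walker). `"strict"` gives a
#' monotonically increasing preference, C(o) proportional to exp(alpha * o),
#' so denser trail pheromone is preferred.
#'
#' @param kind `"flat"` or `"strict"`.
#' @param alpha Slope of the strict preference (log-scale increment per
#'   level); must be positive for `"strict"`.
#' @return Numeric vector of length 10 summing to 1.
#' @examples
#' build_preferences("strict", alpha = 0.5)
#' @export
build_preferences <- function(kind = c("strict", "flat"), alpha = 0.5) {
  kind <- match.arg(kind)
  if (kind == "flat") return(rep(1 / N_LEVELS, N_LEVELS))
  if (alpha <= 0) stop("`alpha` must be positive for strict preferences",
                       call. = FALSE)
  w <- exp(alpha * seq_len(N_LEVELS))
  w / sum(w)
}

#' Canonical one-step transition matrices B
#'
#' Policy i deterministically relocates the agent to neighborhood cell i,
#' whatever the current state: B\[\[i\]\] has a row of ones at row i.
#'
#' @return List of nine 9x9 column-stochastic matrices.
#' @export
make_transitions <- function() {
  lapply(seq_len(N_POLICIES), function(i) {
    B <- matrix(0, N_POLICIES, N_POLICIES)
    B[i, ] <- 1
    B
  })
}

#' State inference by variational free energy minimization
#'
#' For this single-factor, single-step model the free-energy minimizer is
#' the exact categorical posterior: `qs = softmax(ln D + ln A[o, ])`, with
#' probabilities floored at 1e-16 before taking logs.
#'
#' @param A 10x9 likelihood matrix.
#' @param D Prior over the 9 local states.
#' @param observation Observed pheromone level, in 1..10.
#' @return Posterior `qs` over the 9 local states.
#' @export
infer_states <- function(A, D, observation) {
  if (observation < 1L || observation > N_LEVELS)
    stop("`observation` must be a level in 1..10", call. = FALSE)
  softmax(safe_log(D) + safe_log(A[observation, ]))
}

#' Expected free energy of the one-step relocation policies
#'
#' For each policy pi: predicted states `qs_pi = B_pi qs`, predicted
#' outcomes `qo_pi = A qs_pi`, and
#' `G(pi) = sum_o qo_pi(o) (ln qo_pi(o) - ln C(o))   [risk]
#'        + sum_s qs_pi(s) H(A[, s])                 [ambiguity]`
#' with H the Shannon entropy of column s of A, natural logs, and the
#' 1e-16 probability floor. Lower G is better.
#'
#' @param A 10x9 likelihood.
#' @param B List of nine 9x9 transition matrices (see [make_transitions()]).
#' @param C Preference distribution over the 10 outcome levels.
#' @param qs Current posterior over the 9 local states.
#' @return Numeric vector of 9 expected-free-energy values.
#' @export
expected_free_energy <- function(A, B, C, qs) {
  # stack the 9 transition matrices once: row block p of (Bstack %*% qs)
  # is the predicted state distribution under policy p
  Bstack <- if (is.matrix(B)) B else do.call(rbind, B)
  Qs <- matrix(Bstack %*% qs, nrow = N_POLICIES)  # states x policies
  Qo <- A %*% Qs                              # 10 x 9 predicted outcomes
  risk <- colSums(Qo * (safe_log(Qo) - safe_log(C)))
  H_A <- -colSums(A * safe_log(A))            # per-state outcome entropy
  ambiguity <- colSums(Qs * H_A)
  as.numeric(risk + ambiguity)
}

#' Posterior over policies
#'
#' Softmax of negative expected free energy at precision `gamma`, plus any
#' additive log-space bonus (the laden forager's homing bias enters here).
#' Infeasible policies (walls, grid edges) are masked out before
#' normalization, so wall-adjacent agents renormalize over feasible moves.
#'
#' @param G 9 expected-free-energy values.
#' @param feasible 9 logicals; at least one must be `TRUE`.
#' @param gamma Policy precision (positive scalar).
#' @param homing_bonus 9 additive log-space bonuses (defaults to zero).
#' @return Probability vector `qpi` over the 9 policies; infeasible policies
#'   get exactly 0.
#' @export
policy_posterior <- function(G, feasible, gamma = 1,
                             homing_bonus = rep(0, N_POLICIES)) {
  if (!any(feasible)) stop("no feasible policy", call. = FALSE)
  x <- -gamma * G + homing_bonus
  x[!feasible] <- -Inf
  x <- x - max(x)
  z <- exp(x)
  z / sum(z)
}

#' Sample an action from the policy posterior
#'
#' Categorical draw from `qpi` using the agent's own random stream, so runs
#' are reproducible under a fixed master seed. With `mode = "argmax"` the
#' minimum-G (maximum-probability) policy is selected deterministically,
#' ties broken by canonical order.
#'
#' @param qpi Probability vector over the 9 policies.
#' @param stream A `forage_stream` (or `NULL` for the session RNG).
#' @param mode `"sample"` (default) or `"argmax"`.
#' @return Policy index in 1..9.
#' @export
sample_action <- function(qpi, stream = NULL, mode = "sample") {
  if (identical(mode, "argmax")) return(which.max(qpi))
  if (!identical(mode, "sample"))
    stop("`mode` must be 'sample' or 'argmax'", call. = FALSE)
  u <- draw_runif(1L, stream)
  findInterval(u, cumsum(qpi), left.open = TRUE) + 1L
}

#' Assemble a forager's generative model
#'
#' Bundles the fixed pieces of the per-ant model: transition set B,
#' preferences C, state prior D (one-hot at "stay": the ant knows where it
#' is), policy precision gamma, and the laden homing-bias weight kappa.
#' The likelihood A is not stored: it is re-cut from the arena each step.
#'
#' @param preference `"strict"` or `"flat"`.
#' @param alpha Strict-preference slope.
#' @param gamma Policy precision.
#' @param kappa Homing-bias weight for laden foragers (log-space).
#' @param D Optional prior over the 9 local states.
#' @param action_mode `"sample"` or `"argmax"`.
#' @return An object of class `forage_model`.
#' @export
make_generative_model <- function(preference = c("strict", "flat"),
                                  alpha = 0.5, gamma = 1, kappa = 3,
                                  D = NULL,
                                  action_mode = c("sample", "argmax")) {
  preference <- match.arg(preference)
  action_mode <- match.arg(action_mode)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (is.null(D)) {
    D <- rep(0, N_POLICIES); D[1] <- 1
  }
  if (length(D) != N_POLICIES || abs(sum(D) - 1) > 1e-9)
    stop("`D` must be a distribution over the 9 local states", call. = FALSE)
  B <- make_transitions()
  structure(list(B = B, Bstack = do.call(rbind, B),
                 C = build_preferences(preference, alpha),
                 D = D, preference = preference, alpha = alpha,
                 gamma = gamma, kappa = kappa, action_mode = action_mode),
            class = "forage_model")
}

#' @export
print.forage_model <- function(x, ...) {
  cat(sprintf("<forage_model> %s preferences (alpha=%g), gamma=%g, kappa=%g, %s actions\n",
              x$preference, x$alpha, x$gamma, x$kappa, x$action_mode))
  invisible(x)
}
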