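# Fixture builders shared across test files. Everything is generated in
# code under a caller-supplied seed; no data files.

# random row-stochastic matrix (rows = n, cols = 5)
rand_simplex_rows <- function(n, concentration = 1) {
  g <- matrix(rgamma(n * 5L, shape = concentration), n, 5L)
  g / rowSums(g)
}

# a random, internally consistent energy problem instance
random_instance <- function(seed, n_epochs, params = energy_params()) {
  set.seed(seed)
  pred <- validate_probabilities(rand_simplex_rows(n_epochs))
  trans <- transition_matrix(rand_simplex_rows(5L))
  conf <- confusion_matrix(t(rand_simplex_rows(5L)))
  ctx <- energy_context(pred, trans, conf, params)
  list(pred = pred, trans = trans, conf = conf, ctx = ctx,
       state = argmax_decode(pred))
}

# all 5^T stage-code sequences, as a (5^T x T) integer matrix; row order
# matches the base-5 encoding used by anneal(record_states = TRUE):
# code = sum(s_t * 5^(t-1))
enumerate_states <- function(n_epochs) {
  grid <- do.call(expand.grid, rep(list(0:4), n_epochs))
  as.matrix(grid)
}

# total energy of every enumerated state (independent closed form:
# local terms plus every interior transition error counted twice)
enumerate_energies <- function(ctx, states) {
  T_ <- ncol(states)
  e <- numeric(nrow(states))
  for (t in seq_len(T_)) e <- e + ctx$local[t, states[, t] + 1L]
  if (T_ > 1L) for (t in seq_len(T_ - 1L)) {
    e <- e + 2 * ctx$trans_energy[cbind(states[, t] + 1L, states[, t + 1L] + 1L)]
  }
  e
}

# brute-force best HMM path: score all 5^T paths in log space, ties to
# the lexicographically smallest (= lowest stage codes first)
brute_viterbi <- function(pred, trans, prior) {
  T_ <- nrow(pred)
  states <- enumerate_states(T_)
  # expand.grid varies the first column fastest; reorder rows so that
  # lexicographic order breaks exact ties toward lower stage codes
  ord <- do.call(order, as.data.frame(states))
  states <- states[ord, , drop = FALSE]
  lp <- log(unclass(pred)); lt <- log(unclass(trans))
  score <- log(prior)[states[, 1] + 1L] + lp[cbind(1L, states[, 1] + 1L)]
  if (T_ > 1L) for (t in 2:T_) {
    score <- score + lt[cbind(states[, t - 1L] + 1L, states[, t] + 1L)] +
      lp[cbind(t, states[, t] + 1L)]
  }
  states[which.max(score), ]
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (oracle; independent of the package implementation)
wilcoxon_exact_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  grid <- do.call(expand.grid, rep(list(c(FALSE, TRUE)), n))
  v_all <- as.matrix(grid) %*% r
  mu <- n * (n + 1) / 4
  # two-sided: as extreme or more, measured by distance from the mean
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}
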