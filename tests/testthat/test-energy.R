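test_that("reciprocal error hits its anchors and is decreasing, convex, capped", {
  expect_identical(reciprocal_error(1, 0.1), 0)
  expect_identical(reciprocal_error(0, 0.1), 9)
  expect_equal(reciprocal_error(0.5, 0.1), 1 / 0.55 - 1, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.01)
  for (eps in c(0.05, 0.1, 0.5)) {
    f <- reciprocal_error(p, eps)
    expect_true(all(diff(f) < 0))                       # strictly decreasing
    expect_true(all(diff(diff(f)) > -1e-12))            # convex
    expect_true(all(f >= 0 & f <= 1 / eps - 1 + 1e-12)) # capped
  }
  expect_error(reciprocal_error(-0.1, 0.1), "\\[0, 1\\]")
  expect_error(reciprocal_error(0.5, 1), "\\(0, 1\\)")
})

# a T=3 instance with every consulted probability pinned by hand:
# state = argmax = (W, N2, R); the interior epoch reproduces the worked
# combination P_trans(in) = 0.1, P_trans(out) = 0.7, P_conf = 0.5,
# P_pred = 0.8
pinned_instance <- function(alpha = 0.5) {
  pred <- rbind(c(0.9, 0.1, 0.0, 0.0, 0.0),    # argmax W
                c(0.0, 0.1, 0.8, 0.1, 0.0),    # argmax N2, P_pred = 0.8
                c(0.0, 0.0, 0.2, 0.0, 0.8))    # argmax R
  trans <- rbind(c(0.5, 0.2, 0.1, 0.1, 0.1),   # W -> N2 = 0.1
                 c(0.2, 0.2, 0.2, 0.2, 0.2),
                 c(0.1, 0.1, 0.05, 0.05, 0.7), # N2 -> R = 0.7
                 c(0.2, 0.2, 0.2, 0.2, 0.2),
                 c(0.2, 0.2, 0.2, 0.2, 0.2))
  conf <- matrix(0.125, 5, 5); diag(conf) <- 0.5  # columns sum to 1, diag 0.5
  ctx <- energy_context(validate_probabilities(pred), transition_matrix(trans),
                        confusion_matrix(conf), energy_params(alpha = alpha))
  list(ctx = ctx, state = argmax_decode(pred))
}

test_that("epoch energy reproduces the worked interior-epoch value", {
  inst <- pinned_instance()
  # independent arithmetic: f(p) = 1/(0.9 p + 0.1) - 1 at eps = 0.1
  f <- function(p) 1 / (0.9 * p + 0.1) - 1
  expected <- 0.5 * (f(0.1) + f(0.7)) + 0.5 * (f(0.5) + f(0.8))
  expect_equal(epoch_energy(2, inst$state, inst$ctx), expected, tolerance = 1e-12)
  expect_equal(expected, 2.83536, tolerance = 1e-4)
})

test_that("energy is zero iff all consulted probabilities are one, capped at worst", {
  # constant-N1 one-hot predictions + identity matrices: every consulted
  # probability is 1, so the argmax state has energy exactly 0
  pred <- validate_probabilities(diag(5)[c(2, 2, 2), ])
  ctx <- energy_context(pred, transition_matrix(diag(5)), confusion_matrix(diag(5)))
  st <- argmax_decode(pred)
  expect_identical(total_energy(st, ctx), 0)
  expect_equal(vapply(1:3, epoch_energy, numeric(1), state = st, ctx = ctx),
               rep(0, 3))

  # all four consulted probabilities zero at an interior epoch: four terms
  # at the cap 9, each weighted 0.5 -> energy 18
  pred0 <- rbind(c(0.9, 0.1, 0, 0, 0),
                 c(0.5, 0.5, 0, 0, 0),   # argmax W, P_pred(N3) = 0
                 c(0.9, 0.1, 0, 0, 0))
  trans0 <- rbind(c(0.5, 0.5, 0, 0, 0),  # W -> N3 = 0
                  c(0.2, 0.2, 0.2, 0.2, 0.2),
                  c(0.2, 0.2, 0.2, 0.2, 0.2),
                  c(0, 0, 0, 0.5, 0.5),  # N3 -> W = 0
                  c(0.2, 0.2, 0.2, 0.2, 0.2))
  conf0 <- matrix(0.25, 5, 5); conf0[4, ] <- 0   # P_conf(N3 | anything) = 0
  ctx0 <- energy_context(validate_probabilities(pred0), transition_matrix(trans0),
                         confusion_matrix(conf0), energy_params())
  state0 <- hypnogram(c(0L, 3L, 0L))
  expect_equal(epoch_energy(2, state0, ctx0), 0.5 * 18 + 0.5 * 18, tolerance = 1e-12)
})

test_that("T = 1 total energy has no transition terms", {
  set.seed(5)
  inst <- random_instance(5, 1)
  st <- inst$state
  e <- total_energy(st, inst$ctx)
  expect_equal(e, inst$ctx$local[1, unclass(st)[1] + 1L], tolerance = 1e-12)
})

test_that("total energy is the sum of epoch energies", {
  inst <- random_instance(17, 6)
  st <- hypnogram(sample(0:4, 6, replace = TRUE))
  per <- vapply(1:6, epoch_energy, numeric(1), state = st, ctx = inst$ctx)
  expect_equal(total_energy(st, inst$ctx), sum(per), tolerance = 1e-12)
  expect_true(total_energy(st, inst$ctx) >= 0)
})

test_that("alpha extremes decouple the unused matrices", {
  set.seed(23)
  pred <- validate_probabilities(rand_simplex_rows(20))
  trans1 <- transition_matrix(rand_simplex_rows(5))
  trans2 <- transition_matrix(rand_simplex_rows(5))
  conf1 <- confusion_matrix(t(rand_simplex_rows(5)))
  conf2 <- confusion_matrix(t(rand_simplex_rows(5)))
  st <- hypnogram(sample(0:4, 20, replace = TRUE))
  # alpha = 1: confusion/prediction ignored
  e1a <- total_energy(st, energy_context(pred, trans1, conf1, energy_params(alpha = 1)))
  e1b <- total_energy(st, energy_context(pred, trans1, conf2, energy_params(alpha = 1)))
  expect_identical(e1a, e1b)
  # alpha = 0: transitions ignored
  e0a <- total_energy(st, energy_context(pred, trans1, conf1, energy_params(alpha = 0)))
  e0b <- total_energy(st, energy_context(pred, trans2, conf1, energy_params(alpha = 0)))
  expect_identical(e0a, e0b)
})

test_that("each transition error is counted exactly twice in the total", {
  inst <- random_instance(31, 3)
  ctx <- inst$ctx
  st <- hypnogram(c(1L, 4L, 2L))
  s <- c(1L, 4L, 2L) + 1L
  hand <- ctx$local[1, s[1]] + ctx$local[2, s[2]] + ctx$local[3, s[3]] +
    2 * ctx$trans_energy[s[1], s[2]] + 2 * ctx$trans_energy[s[2], s[3]]
  expect_equal(total_energy(st, ctx), hand, tolerance = 1e-12)
})
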