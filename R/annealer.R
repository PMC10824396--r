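# Stochastic single-site energy minimization. Each step picks one epoch
# from a Boltzmann (softmax) distribution over per-epoch energies, then
# resamples that epoch's stage from the 5-way softmax of -beta * deltaE.
# The proposal IS the update (the current stage, with deltaE = 0, is
# always a candidate); there is no separate acceptance test. The hot loop
# lives in C++ (src/anneal_loop.cpp); the R functions here define the
# identical math and are what the consistency tests exercise.

#' Annealing schedule
#'
#' @param beta_start,beta_end Initial and final inverse temperature,
#'   `0 < beta_start <= beta_end`. Defaults 0.1 and 10: early steps are
#'   near-uniform exploration, late steps near-greedy.
#' @param steps_per_epoch Positive factor `c`; the run makes
#'   `K = ceiling(c * T)` single-site steps, so each epoch is proposed
#'   about `c` times in expectation. Default 40.
#' @param steps Optional explicit step count overriding `steps_per_epoch`.
#' @param progression Schedule family; `"geometric"` (log-linear in beta)
#'   is the only one implemented.
#' @return A list with class `"anneal_schedule"`.
#' @export
anneal_schedule <- function(beta_start = 0.1, beta_end = 10,
                            steps_per_epoch = 40, steps = NULL,
                            progression = "geometric") {
  if (!is.finite(beta_start) || beta_start <= 0) stop("beta_start must be > 0")
  if (!is.finite(beta_end) || beta_end < beta_start) stop("beta_end must be >= beta_start")
  if (is.null(steps)) {
    if (!is.finite(steps_per_epoch) || steps_per_epoch <= 0) {
      stop("steps_per_epoch must be positive")
    }
  } else if (!is.finite(steps) || steps < 1) stop("steps must be >= 1")
  progression <- match.arg(progression, "geometric")
  structure(list(beta_start = beta_start, beta_end = beta_end,
                 steps_per_epoch = steps_per_epoch, steps = steps,
                 progression = progression),
            class = "anneal_schedule")
}

#' Materialize the per-step inverse temperatures
#'
#' @param schedule An [anneal_schedule()].
#' @param n_epochs Sequence length `T` (used when the schedule specifies a
#'   steps-per-epoch factor rather than an explicit step count).
#' @return Nondecreasing numeric vector of `K` beta values, geometric from
#'   `beta_start` to `beta_end`.
#' @export
#' @examples
#' make_schedule(anneal_schedule(0.1, 10, steps = 3))  # 0.1 1 10
make_schedule <- function(schedule, n_epochs) {
  if (!inherits(schedule, "anneal_schedule")) stop("schedule must be an anneal_schedule()")
  K <- if (!is.null(schedule$steps)) as.integer(schedule$steps) else {
    if (missing(n_epochs) || !is.finite(n_epochs) || n_epochs < 1) {
      stop("n_epochs required to derive the step count")
    }
    as.integer(ceiling(schedule$steps_per_epoch * n_epochs))
  }
  exp(seq(log(schedule$beta_start), log(schedule$beta_end), length.out = K))
}

#' Sample the epoch to update
#'
#' Draws one epoch index from the softmax over per-epoch energies. With
#' `sign_mode = "effective"` (default) the weight is `exp(+beta * E(t))`,
#' so high-energy (poorly explained) epochs are preferentially revisited;
#' `"literal"` uses `exp(-beta * E(t))`, which concentrates on epochs that
#' already have low energy. Both are exposed; see the methods vignette.
#'
#' @param state A [hypnogram()].
#' @param ctx An [energy_context()].
#' @param beta Inverse temperature, >= 0.
#' @param sign_mode `"effective"` or `"literal"`.
#' @return A 1-based epoch index.
#' @export
select_position <- function(state, ctx, beta, sign_mode = c("effective", "literal")) {
  sign_mode <- match.arg(sign_mode)
  e <- epoch_energies(state, ctx)
  if (any(!is.finite(e))) stop("non-finite epoch energy")
  sgn <- if (sign_mode == "effective") 1 else -1
  w <- exp(sgn * beta * e - max(sgn * beta * e))
  sample.int(length(e), 1L, prob = w)
}

#' Energy change of a single-site flip
#'
#' Change in [total_energy()] if epoch `t` switches to `new_stage`,
#' computed from only the (up to) three affected epoch energies
#' `t - 1, t, t + 1` (truncated at the boundaries). Contract: identical to
#' the full recomputation `total_energy(flipped) - total_energy(state)`.
#'
#' @param t Epoch index, 1-based.
#' @param new_stage Stage code in `0:4`.
#' @param state A [hypnogram()].
#' @param ctx An [energy_context()].
#' @return Signed energy difference; 0 for a null move.
#' @export
delta_energy <- function(t, new_stage, state, ctx) {
  s <- as_stage_codes(state)
  T_ <- length(s)
  if (t < 1L || t > T_) stop("epoch index out of range 1..", T_)
  new_stage <- as.integer(new_stage)
  if (new_stage < 0L || new_stage > 4L) stop("new_stage must be a code in 0..4")
  cur <- s[t]
  if (new_stage == cur) return(0)
  d <- ctx$local[t, new_stage + 1L] - ctx$local[t, cur + 1L]
  # each affected transition is counted twice in the total energy
  if (t > 1L) {
    d <- d + 2 * (ctx$trans_energy[s[t - 1L] + 1L, new_stage + 1L] -
                  ctx$trans_energy[s[t - 1L] + 1L, cur + 1L])
  }
  if (t < T_) {
    d <- d + 2 * (ctx$trans_energy[new_stage + 1L, s[t + 1L] + 1L] -
                  ctx$trans_energy[cur + 1L, s[t + 1L] + 1L])
  }
  d
}

#' Sample the new stage for an epoch
#'
#' Draws the replacement stage from the 5-way softmax of
#' `exp(-beta * deltaE)` over all stages (the current stage is included
#' with `deltaE = 0`, so it always carries the largest unnormalized weight
#' unless some alternative lowers the energy).
#'
#' @inheritParams delta_energy
#' @param beta Inverse temperature, >= 0.
#' @return The sampled stage code in `0:4` (possibly the current stage).
#' @export
propose_state <- function(t, state, ctx, beta) {
  d <- vapply(0:4, function(s) delta_energy(t, s, state, ctx), numeric(1))
  if (any(!is.finite(d))) stop("non-finite energy difference")
  w <- exp(-beta * (d - min(d)))
  sample.int(5L, 1L, prob = w) - 1L
}

#' Minimize a hypnogram's energy by simulated annealing
#'
#' Starts from the argmax candidate hypnogram and runs `K` single-site
#' steps of (select epoch, resample its stage), raising beta along the
#' schedule. Per-epoch energies are cached and patched at `t-1, t, t+1`
#' after each move, so a step costs O(T) for position selection and O(1)
#' for the proposal. The reported hypnogram is the best state visited
#' (standard annealing practice: the method can then never return a state
#' worse than its own trajectory, in particular never worse than the
#' argmax start).
#'
#' @param pred Matrix accepted by [validate_probabilities()].
#' @param trans A [transition_matrix()].
#' @param conf A [confusion_matrix()].
#' @param params An [energy_params()].
#' @param schedule An [anneal_schedule()].
#' @param seed Integer RNG seed; identical seed and inputs give a
#'   bit-identical run. `NULL` continues the session RNG stream.
#' @param sign_mode Position-selection sign, see [select_position()].
#' @param position_selection `"boltzmann"` (default) or `"uniform"`
#'   (every epoch equally likely; with a constant beta this makes the
#'   chain a random-scan Gibbs sampler of the Boltzmann distribution).
#' @param record_states If `TRUE` (only for `T <= 12`), also return the
#'   visited state after every step, encoded in base 5
#'   (`sum(stage_code * 5^(t-1))`) — used for sampler diagnostics.
#' @return A list with class `"anneal_run"`: `initial_state`,
#'   `final_state`, `best_state` (all [hypnogram()]s), `energy_trace`
#'   (length `K`, total energy after each step), `betas`, `positions`,
#'   `old_stages`, `new_stages` (the per-step moves; old = new marks a
#'   kept stage), `best_energy`, `initial_energy`, `accepted_moves`,
#'   `seed`, `params`, `schedule`, and optionally `state_trace`.
#' @export
anneal <- function(pred, trans, conf, params = energy_params(),
                   schedule = anneal_schedule(), seed = NULL,
                   sign_mode = c("effective", "literal"),
                   position_selection = c("boltzmann", "uniform"),
                   record_states = FALSE) {
  sign_mode <- match.arg(sign_mode)
  position_selection <- match.arg(position_selection)
  ctx <- energy_context(pred, trans, conf, params)
  T_ <- ctx$n_epochs
  betas <- make_schedule(schedule, T_)
  init <- as_stage_codes(ctx$pred_labels)
  if (record_states && T_ > 12L) stop("record_states supported only for T <= 12")
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- anneal_cpp(ctx$local, ctx$trans_energy, init, betas,
                    sign_mode == "effective",
                    position_selection == "uniform",
                    record_states)
  structure(list(
    seed = seed,
    initial_state = hypnogram(init),
    final_state = hypnogram(res$final_state),
    best_state = hypnogram(res$best_state),
    energy_trace = res$energy_trace,
    betas = betas,
    positions = res$positions,
    old_stages = res$old_stages,
    new_stages = res$new_stages,
    best_energy = res$best_energy,
    initial_energy = res$initial_energy,
    accepted_moves = res$accepted_moves,
    state_trace = res$state_trace,
    params = params, schedule = schedule, sign_mode = sign_mode
  ), class = "anneal_run")
}

#' @export
print.anneal_run <- function(x, ...) {
  cat("<anneal_run> ", length(x$initial_state), " epochs, ",
      length(x$energy_trace), " steps\n", sep = "")
  cat("  energy: initial ", format(x$initial_energy, digits = 6),
      " -> best ", format(x$best_energy, digits = 6),
      "  (", x$accepted_moves, " accepted moves)\n", sep = "")
  invisible(x)
}
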