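# Synthetic nights: Markov-chain ground-truth hypnograms plus emulated
# classifier probability matrices whose argmax error pattern follows a
# supplied confusion pattern. This gives every other module a fully
# self-contained, seeded test bed: no recordings, no trained models.

#' Default stage-transition matrix for synthetic nights
#'
#' Persistence-dominated dynamics (diagonal 0.86-0.92) with the remaining
#' mass mostly on adjacent-depth moves, the qualitative shape of empirical
#' sleep transition matrices: stages strongly tend to persist across
#' consecutive 30-s epochs, N3 is reached through N2, and direct W <-> N3
#' jumps essentially never occur. Exact values are configuration, not
#' claims about any dataset.
#'
#' @return A [transition_matrix()].
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    c(0.92, 0.05, 0.02, 0.00, 0.01),  # W
    c(0.06, 0.86, 0.05, 0.00, 0.03),  # N1
    c(0.01, 0.03, 0.90, 0.04, 0.02),  # N2
    c(0.00, 0.01, 0.07, 0.92, 0.00),  # N3
    c(0.02, 0.03, 0.04, 0.00, 0.91))  # R
  transition_matrix(m)
}

#' Default emulated-classifier confusion pattern
#'
#' Row-stochastic P(predicted | true) for the emulated classifier:
#' a mediocre single-epoch scorer with ~72% expected argmax accuracy under
#' the default transition dynamics. N1 is the hardest stage (recall 0.40,
#' confused with W, N2 and R), the usual failure mode of automatic
#' scorers; W is the easiest.
#'
#' @return A 5 x 5 row-stochastic matrix (rows = true stage, columns =
#'   predicted stage). Note this is NOT the column-normalized
#'   [confusion_matrix()] the energy uses; it is the generative error
#'   pattern of the synthetic classifier.
#' @export
default_confusion_target <- function() {
  m <- rbind(
    c(0.85, 0.08, 0.03, 0.01, 0.03),  # W
    c(0.20, 0.40, 0.22, 0.02, 0.16),  # N1
    c(0.03, 0.07, 0.75, 0.09, 0.06),  # N2
    c(0.01, 0.01, 0.25, 0.72, 0.01),  # N3
    c(0.05, 0.12, 0.10, 0.01, 0.72))  # R
  dimnames(m) <- list(stage_levels(), stage_levels())
  m
}

#' Synthetic benchmark configuration
#'
#' @param n_epochs Epochs per night; default 900 (7.5 h of 30-s epochs).
#' @param trans_true Generating [transition_matrix()].
#' @param initial_dist Length-5 initial stage distribution; default starts
#'   nights awake or drowsy, `(0.7, 0.2, 0.1, 0, 0)`.
#' @param conf_target 5 x 5 row-stochastic P(predicted | true) controlling
#'   the emulated classifier's error pattern.
#' @param sharpness Dirichlet concentration (> 0) controlling how peaked
#'   the emulated probability rows are; default 20 gives confident but not
#'   one-hot rows whose argmax almost always equals the drawn label.
#' @param n_nights Number of test nights; default 20.
#' @param n_heldout Nights reserved for matrix estimation; default 10.
#' @return A list with class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_epochs = 900L,
                             trans_true = default_transition_matrix(),
                             initial_dist = c(0.7, 0.2, 0.1, 0, 0),
                             conf_target = default_confusion_target(),
                             sharpness = 20,
                             n_nights = 20L,
                             n_heldout = 10L) {
  if (n_epochs < 1L) stop("n_epochs must be >= 1")
  if (n_nights < 1L) stop("n_nights must be >= 1")
  if (n_heldout < 1L) stop("n_heldout must be >= 1")
  if (length(initial_dist) != 5L || any(initial_dist < 0) ||
      abs(sum(initial_dist) - 1) > 1e-6) {
    stop("initial_dist must be a length-5 probability vector summing to 1")
  }
  if (!is.finite(sharpness) || sharpness <= 0) stop("sharpness must be > 0")
  if (!inherits(trans_true, "transition_matrix")) trans_true <- transition_matrix(trans_true)
  conf_target <- check_row_stochastic(conf_target, "conf_target")
  structure(list(n_epochs = as.integer(n_epochs), trans_true = trans_true,
                 initial_dist = initial_dist, conf_target = conf_target,
                 sharpness = sharpness, n_nights = as.integer(n_nights),
                 n_heldout = as.integer(n_heldout)),
            class = "synthetic_config")
}

#' Sample a ground-truth hypnogram from a Markov chain
#'
#' `s_1 ~ initial_dist`, `s_t | s_{t-1} ~ trans_true` row of the previous
#' stage.
#'
#' @param trans_true A [transition_matrix()].
#' @param initial_dist Length-5 initial distribution.
#' @param n_epochs Sequence length `T >= 1`.
#' @return A [hypnogram()].
#' @export
sample_hypnogram <- function(trans_true, initial_dist, n_epochs) {
  if (!inherits(trans_true, "transition_matrix")) trans_true <- transition_matrix(trans_true)
  if (length(initial_dist) != 5L || any(initial_dist < 0) ||
      abs(sum(initial_dist) - 1) > 1e-6) {
    stop("initial_dist must be a length-5 probability vector summing to 1")
  }
  if (n_epochs < 1L) stop("n_epochs must be >= 1")
  s <- integer(n_epochs)
  s[1L] <- sample.int(5L, 1L, prob = initial_dist) - 1L
  if (n_epochs > 1L) {
    tm <- unclass(trans_true)
    for (t in 2:n_epochs) s[t] <- sample.int(5L, 1L, prob = tm[s[t - 1L] + 1L, ]) - 1L
  }
  hypnogram(s)
}

#' Emulate a probabilistic classifier on a known hypnogram
#'
#' Two-step construction per epoch: (1) draw a "predicted" label from the
#' `conf_target` row of the true stage, so argmax errors follow the
#' supplied confusion pattern; (2) draw the probability row from a
#' Dirichlet distribution with concentration `sharpness * b`, where the
#' base-measure `b` puts mass 0.8 on the drawn label and 0.05 on each
#' other stage. As `sharpness` grows the rows concentrate on `b`, so the
#' row argmax equals the drawn label with probability approaching 1. This
#' gives direct control of the quantity the energy model consumes — the
#' confusion pattern — unlike additive noise on one-hot rows.
#'
#' @param truth A [hypnogram()].
#' @param conf_target 5 x 5 row-stochastic P(predicted | true).
#' @param sharpness Dirichlet concentration > 0.
#' @return A `"predicted_probabilities"` matrix (rows sum to 1).
#' @export
emulate_classifier <- function(truth, conf_target = default_confusion_target(),
                               sharpness = 20) {
  s <- as_stage_codes(truth)
  conf_target <- check_row_stochastic(conf_target, "conf_target")
  if (!is.finite(sharpness) || sharpness <= 0) stop("sharpness must be > 0")
  T_ <- length(s)
  labels <- integer(T_)
  for (t in seq_len(T_)) {
    labels[t] <- sample.int(5L, 1L, prob = conf_target[s[t] + 1L, ]) - 1L
  }
  base <- matrix(0.05, T_, 5L)
  base[cbind(seq_len(T_), labels + 1L)] <- 0.8
  g <- matrix(rgamma(T_ * 5L, shape = sharpness * base), T_, 5L)
  probs <- g / rowSums(g)
  validate_probabilities(probs)
}

#' Generate a full synthetic benchmark
#'
#' Draws `n_nights` test nights plus `n_heldout` held-out nights, then —
#' mirroring a train/validation protocol — estimates the transition matrix
#' from the held-out ground-truth hypnograms and the confusion matrix from
#' the held-out (truth, argmax prediction) pairs. The test nights never
#' feed the matrices.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the bundle is fully determined by it.
#' @return A list with class `"synthetic_benchmark"`: `nights` (a list of
#'   `list(truth, pred)` pairs), `trans` ([transition_matrix()] estimate),
#'   `conf` ([confusion_matrix()] estimate), `prior` (empirical stage
#'   prevalence of the held-out truths) and `config`.
#' @export
make_benchmark <- function(config = synthetic_config(), seed = NULL) {
  if (!inherits(config, "synthetic_config")) stop("config must be a synthetic_config()")
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw_night <- function() {
    truth <- sample_hypnogram(config$trans_true, config$initial_dist, config$n_epochs)
    pred <- emulate_classifier(truth, config$conf_target, config$sharpness)
    list(truth = truth, pred = pred)
  }
  heldout <- replicate(config$n_heldout, draw_night(), simplify = FALSE)
  nights <- replicate(config$n_nights, draw_night(), simplify = FALSE)
  trans <- estimate_transition_matrix(lapply(heldout, `[[`, "truth"))
  truth_all <- unlist(lapply(heldout, function(n) as_stage_codes(n$truth)))
  pred_all <- unlist(lapply(heldout, function(n) as_stage_codes(argmax_decode(n$pred))))
  conf <- estimate_confusion_matrix(truth_all, pred_all)
  prior <- tabulate(truth_all + 1L, nbins = 5L)
  prior <- prior / sum(prior)
  structure(list(nights = nights, trans = trans, conf = conf, prior = prior,
                 config = config),
            class = "synthetic_benchmark")
}
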