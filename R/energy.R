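# The energy model. Each consulted probability p contributes a
# reciprocal-error term f(p) = 1/((1-eps) p + eps) - 1, which is 0 at
# p = 1 and capped at 1/eps - 1 at p = 0. The per-epoch energy mixes the
# two neighbor transition terms (weight alpha) with the confusion and
# prediction terms (weight 1 - alpha); the hypnogram energy is the sum
# over epochs.

#' Energy parameters
#'
#' @param alpha Relative weight of the transition terms against the
#'   confusion + prediction terms, in `[0, 1]`. Default 0.5 (balanced).
#' @param eps_t,eps_p Cap constants in `(0, 1)` for the transition and the
#'   confusion/prediction reciprocal-error terms. They bound the error of a
#'   zero-probability event at `1/eps - 1` and set the steepness of the
#'   error curve (smaller eps, steeper curve). Defaults 0.1.
#' @return A list with class `"energy_params"`.
#' @export
energy_params <- function(alpha = 0.5, eps_t = 0.1, eps_p = 0.1) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!is.finite(eps_t) || eps_t <= 0 || eps_t >= 1) stop("eps_t must be in (0, 1)")
  if (!is.finite(eps_p) || eps_p <= 0 || eps_p >= 1) stop("eps_p must be in (0, 1)")
  structure(list(alpha = alpha, eps_t = eps_t, eps_p = eps_p),
            class = "energy_params")
}

#' Reciprocal error term
#'
#' The elementary energy contribution of a probability `p`:
#' `f(p) = 1 / ((1 - eps) * p + eps) - 1`. It is strictly decreasing and
#' convex on `[0, 1]`, zero at `p = 1`, and capped at `1/eps - 1` at
#' `p = 0`, so zero probabilities are legal inputs and the energy stays
#' finite.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @param eps Cap constant in `(0, 1)`.
#' @return Nonnegative energy values.
#' @export
#' @examples
#' reciprocal_error(1, 0.1)    # 0
#' reciprocal_error(0, 0.1)    # 9
reciprocal_error <- function(p, eps) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  if (!is.finite(eps) || eps <= 0 || eps >= 1) stop("eps must be in (0, 1)")
  1 / ((1 - eps) * p + eps) - 1
}

#' Build an energy context
#'
#' Bundles everything the energy needs: the predicted probabilities, the
#' transition and confusion matrices, the FIXED argmax candidate labels
#' (the confusion term always conditions on the classifier's original
#' argmax prediction, not on the evolving state), and the parameters.
#' Per-epoch confusion + prediction terms and the 5 x 5 transition-error
#' table are precomputed once, so epoch energies are table lookups.
#'
#' @param pred Matrix accepted by [validate_probabilities()].
#' @param trans A [transition_matrix()] (or 5 x 5 row-stochastic matrix).
#' @param conf A [confusion_matrix()] (or 5 x 5 column-stochastic matrix).
#' @param params An [energy_params()].
#' @return A list with class `"energy_context"`; fields include
#'   `pred_labels` (the argmax [hypnogram()]), `local` (`T x 5` matrix of
#'   `(1-alpha) * (e_conf + e_pred)` for every epoch/stage), and
#'   `trans_energy` (5 x 5 matrix of `alpha * e_trans`).
#' @export
energy_context <- function(pred, trans, conf, params = energy_params()) {
  pred <- validate_probabilities(unclass(pred))
  if (!inherits(trans, "transition_matrix")) trans <- transition_matrix(trans)
  if (!inherits(conf, "confusion_matrix")) conf <- confusion_matrix(conf)
  if (!inherits(params, "energy_params")) stop("params must be an energy_params()")
  labels <- argmax_decode(pred)
  T_ <- nrow(pred)
  # e_pred(t, s): reciprocal error of the predicted probability of stage s
  e_pred <- reciprocal_error(unclass(pred), params$eps_p)
  # e_conf(t, s) = f(P_conf(s | argmax label at t)): column of conf picked
  # by the fixed candidate label, identical for all epochs sharing a label
  conf_err <- reciprocal_error(unclass(conf), params$eps_p)
  e_conf <- t(conf_err[, as_stage_codes(labels) + 1L, drop = FALSE])
  local <- (1 - params$alpha) * (e_conf + e_pred)
  trans_energy <- params$alpha * reciprocal_error(unclass(trans), params$eps_t)
  structure(list(
    pred = pred, trans = trans, conf = conf, pred_labels = labels,
    params = params, n_epochs = T_,
    local = unname(local), trans_energy = unname(trans_energy)
  ), class = "energy_context")
}

#' Per-epoch energy
#'
#' Energy of epoch `t` under the current hypnogram state:
#' `alpha * (e_trans(in) + e_trans(out)) + (1 - alpha) * (e_conf + e_pred)`.
#' At the first epoch the incoming transition term is omitted, at the last
#' the outgoing term is omitted (missing neighbors contribute 0; nothing
#' is imputed or rescaled).
#'
#' @param t Epoch index, 1-based, in `1..T`.
#' @param state A [hypnogram()] of length `T`.
#' @param ctx An [energy_context()].
#' @return Nonnegative scalar energy.
#' @export
epoch_energy <- function(t, state, ctx) {
  s <- as_stage_codes(state)
  T_ <- length(s)
  if (T_ != ctx$n_epochs) stop("state length does not match context")
  if (length(t) != 1L || t < 1L || t > T_) stop("epoch index out of range 1..", T_)
  e <- ctx$local[t, s[t] + 1L]
  if (t > 1L) e <- e + ctx$trans_energy[s[t - 1L] + 1L, s[t] + 1L]
  if (t < T_) e <- e + ctx$trans_energy[s[t] + 1L, s[t + 1L] + 1L]
  e
}

#' Total hypnogram energy
#'
#' Sum of [epoch_energy()] over all epochs. Because each interior
#' transition appears in two epoch energies (outgoing for `t`, incoming
#' for `t + 1`), every transition error is counted exactly twice.
#'
#' @inheritParams epoch_energy
#' @return Nonnegative scalar; 0 iff every consulted probability equals 1.
#' @export
total_energy <- function(state, ctx) {
  sum(epoch_energies(state, ctx))
}

# internal: vector of all T epoch energies (vectorized lookups)
epoch_energies <- function(state, ctx) {
  s <- as_stage_codes(state)
  T_ <- length(s)
  if (T_ != ctx$n_epochs) stop("state length does not match context")
  e <- ctx$local[cbind(seq_len(T_), s + 1L)]
  if (T_ > 1L) {
    tr <- ctx$trans_energy[cbind(s[-T_] + 1L, s[-1L] + 1L)]
    e[-1L] <- e[-1L] + tr     # incoming term of epochs 2..T
    e[-T_] <- e[-T_] + tr     # outgoing term of epochs 1..T-1
  }
  e
}
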