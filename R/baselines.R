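# Comparison decoders: a post-hoc HMM (Viterbi) smoother that consumes the
# classifier's probability rows as per-epoch emission scores, and a naive
# modal (median-filter style) smoother.

#' Viterbi decoding of the classifier output under a transition model
#'
#' Treats the predicted probability rows as per-epoch emission
#' pseudo-likelihoods of an HMM whose transition matrix is `trans`, and
#' returns the maximum-probability stage path. Computed in log space;
#' zero probabilities become `-Inf`. Ties are broken toward the lowest
#' stage code.
#'
#' @param pred Matrix accepted by [validate_probabilities()].
#' @param trans A [transition_matrix()].
#' @param prior Length-5 initial stage distribution (sums to 1). Default
#'   uniform; in practice the empirical stage prevalence of the training
#'   hypnograms is a better choice.
#' @return A [hypnogram()].
#' @export
viterbi_decode <- function(pred, trans, prior = rep(0.2, 5)) {
  pred <- validate_probabilities(unclass(pred))
  if (!inherits(trans, "transition_matrix")) trans <- transition_matrix(trans)
  if (length(prior) != 5L || any(!is.finite(prior)) || any(prior < 0) ||
      abs(sum(prior) - 1) > 1e-6) {
    stop("prior must be a length-5 probability vector summing to 1")
  }
  T_ <- nrow(pred)
  if (any(rowSums(unclass(pred) > 0) == 0)) {
    stop("emission row with all-zero probabilities")
  }
  lp <- log(unclass(pred))
  lt <- log(unclass(trans))
  delta <- log(prior) + lp[1L, ]
  back <- matrix(0L, T_, 5L)
  if (T_ > 1L) {
    for (t in 2:T_) {
      # cand[i, j] = delta[i] + log trans(i -> j)
      cand <- delta + lt
      # which.max returns the first (lowest-code) maximizer
      back[t, ] <- apply(cand, 2L, which.max)
      delta <- cand[cbind(back[t, ], 1:5)] + lp[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  hypnogram(path - 1L)
}

#' Modal (median-filter style) smoothing of a hypnogram
#'
#' Replaces each epoch by the most frequent stage in its centered window
#' (truncated at the boundaries). A tie in the window keeps the original
#' stage, so the filter never invents a preference among equally frequent
#' stages.
#'
#' @param hyp A [hypnogram()].
#' @param window Odd window width >= 1. `window = 1` is the identity.
#' @return A [hypnogram()].
#' @export
median_smooth <- function(hyp, window = 3L) {
  s <- as_stage_codes(hyp)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (window == 1L) return(hypnogram(s))
  T_ <- length(s)
  half <- (window - 1L) %/% 2L
  out <- s
  for (t in seq_len(T_)) {
    win <- s[max(1L, t - half):min(T_, t + half)]
    cnt <- tabulate(win + 1L, nbins = 5L)
    top <- which(cnt == max(cnt))
    out[t] <- if (length(top) == 1L) top - 1L else s[t]
  }
  hypnogram(out)
}
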