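# Estimators for the two 5x5 matrices the energy model consumes:
# the stage-transition matrix (row-stochastic, from labeled hypnograms)
# and the confusion matrix (COLUMN-stochastic: P(true stage | predicted
# stage), from paired true/predicted sequences).

#' Estimate a stage-transition matrix from labeled hypnograms
#'
#' Counts every consecutive stage pair within each hypnogram (never across
#' recording boundaries, so concatenating nights introduces no spurious
#' transitions), optionally adds a pseudocount to every cell, and
#' row-normalizes. A source stage never observed (row total zero after the
#' pseudocount) gets a uniform row with a warning: an unobserved stage
#' carries no transition evidence.
#'
#' @param hypnograms A [hypnogram()] or a list of them.
#' @param pseudocount Nonnegative smoothing constant added to every cell
#'   before normalization. Default 0: structural zeros are informative —
#'   transitions that never occur should stay maximally expensive in the
#'   energy — so smoothing is opt-in.
#' @return A 5 x 5 row-stochastic matrix with class `"transition_matrix"`,
#'   rows = source stage at epoch t-1, columns = target stage at t.
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N1", "W"))
#' estimate_transition_matrix(list(h))
estimate_transition_matrix <- function(hypnograms, pseudocount = 0) {
  if (inherits(hypnograms, "hypnogram")) hypnograms <- list(hypnograms)
  if (!is.list(hypnograms) || length(hypnograms) == 0L) {
    stop("hypnograms must be a hypnogram or a non-empty list of hypnograms")
  }
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  counts <- matrix(0, 5L, 5L)
  usable <- FALSE
  for (h in hypnograms) {
    s <- as_stage_codes(h)
    if (length(s) < 2L) next
    usable <- TRUE
    from <- s[-length(s)] + 1L
    to <- s[-1L] + 1L
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  if (!usable) stop("no hypnogram with at least 2 epochs; cannot count transitions")
  counts <- counts + pseudocount
  totals <- rowSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning("stage(s) ", paste(stage_levels()[empty], collapse = ", "),
            " never observed as transition source; row(s) set to uniform")
    counts[empty, ] <- 1
    totals[empty] <- 5
  }
  m <- counts / totals
  dimnames(m) <- list(stage_levels(), stage_levels())
  structure(m, class = c("transition_matrix", "matrix", "array"))
}

#' Estimate a column-normalized confusion matrix
#'
#' Builds the 5 x 5 count matrix of (true stage, predicted stage) pairs —
#' rows = truth, columns = prediction — and normalizes each column to sum
#' to 1, so that entry (i, j) estimates P(true stage = i | predicted
#' stage = j): the relabeling evidence the energy's confusion term uses.
#'
#' @param true_stages,predicted_stages Equal-length stage sequences
#'   (hypnograms, codes, or labels).
#' @param fallback Policy for predicted stages never observed: `"uniform"`
#'   (default) fills the column with 0.2 each, with a warning — an
#'   unobserved predicted class carries no evidence, so its energy term
#'   should be uninformative rather than infinite.
#' @return A 5 x 5 column-stochastic matrix with class `"confusion_matrix"`.
#' @export
#' @examples
#' estimate_confusion_matrix(c("W", "W", "N1"), c("W", "N1", "N1"))
estimate_confusion_matrix <- function(true_stages, predicted_stages,
                                      fallback = c("uniform")) {
  fallback <- match.arg(fallback)
  tr <- as_stage_codes(true_stages)
  pr <- as_stage_codes(predicted_stages)
  if (length(tr) != length(pr)) {
    stop("true and predicted sequences differ in length (", length(tr),
         " vs ", length(pr), ")")
  }
  counts <- matrix(0, 5L, 5L)
  for (i in seq_along(tr)) counts[tr[i] + 1L, pr[i] + 1L] <- counts[tr[i] + 1L, pr[i] + 1L] + 1
  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning("predicted stage(s) ", paste(stage_levels()[empty], collapse = ", "),
            " never observed; column(s) set to uniform 0.2")
    counts[, empty] <- 1
    totals[empty] <- 5
  }
  m <- sweep(counts, 2L, totals, "/")
  dimnames(m) <- list(stage_levels(), stage_levels())
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Construct a transition matrix from known probabilities
#'
#' @param probs 5 x 5 row-stochastic matrix (rows sum to 1).
#' @return A `"transition_matrix"`.
#' @export
transition_matrix <- function(probs) {
  m <- check_row_stochastic(probs, "transition matrix")
  structure(m / rowSums(m), class = c("transition_matrix", "matrix", "array"))
}

#' Construct a confusion matrix from known conditional probabilities
#'
#' @param probs 5 x 5 column-stochastic matrix (columns sum to 1),
#'   entry (i, j) = P(true stage i | predicted stage j).
#' @return A `"confusion_matrix"`.
#' @export
confusion_matrix <- function(probs) {
  m <- as.matrix(probs)
  if (!all(dim(m) == c(5L, 5L))) stop("confusion matrix must be 5 x 5")
  if (any(!is.finite(m)) || any(m < -1e-6) || any(m > 1 + 1e-6)) {
    stop("confusion matrix entries must be probabilities in [0, 1]")
  }
  m[m < 0] <- 0; m[m > 1] <- 1
  if (any(abs(colSums(m) - 1) > 1e-6)) stop("confusion matrix columns must sum to 1")
  m <- sweep(m, 2L, colSums(m), "/")
  dimnames(m) <- list(stage_levels(), stage_levels())
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}
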