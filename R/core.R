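# Stage alphabet, hypnogram and probability-matrix containers, and the
# argmax candidate decoder. Stages follow the AASM convention with REM
# written "R"; integer codes are fixed so that N1..N3 keep their numerals:
# W = 0, N1 = 1, N2 = 2, N3 = 3, R = 4.

#' Sleep stage alphabet
#'
#' The five AASM sleep stages in the fixed order used throughout the
#' package: Wake (`W`), `N1`, `N2`, `N3` and REM (`R`). Integer codes are
#' `0:4` in that order, so the non-REM depths N1-N3 carry codes 1-3.
#'
#' @return Character vector of the five stage labels, in code order.
#' @export
#' @examples
#' stage_levels()
#' stage_code("N2")
#' stage_label(4L)
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' @rdname stage_levels
#' @param label Character vector of stage labels.
#' @return `stage_code`: integer codes in `0:4`.
#' @export
stage_code <- function(label) {
  idx <- match(label, stage_levels())
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    hint <- if ("REM" %in% bad) " (use \"R\" for REM)" else ""
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), hint,
         "; expected one of ", paste(stage_levels(), collapse = ", "))
  }
  idx - 1L
}

#' @rdname stage_levels
#' @param code Integer vector of stage codes in `0:4`.
#' @return `stage_label`: character labels.
#' @export
stage_label <- function(code) {
  if (any(!is.finite(code)) || any(code != as.integer(code)) ||
      any(code < 0L) || any(code > 4L)) {
    stop("stage codes must be integers in 0..4")
  }
  stage_levels()[as.integer(code) + 1L]
}

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of sleep stages at 30-second epoch resolution.
#' It is both the optimization variable of [anneal()] and the ground-truth
#' object of the evaluation functions.
#'
#' @param stages Integer stage codes in `0:4` or character stage labels.
#' @param epoch_seconds Epoch duration in seconds; fixed at 30.
#' @return An integer vector of stage codes with class `"hypnogram"`.
#' @export
#' @examples
#' hypnogram(c("W", "W", "N1", "N2", "N2", "N3", "R"))
hypnogram <- function(stages, epoch_seconds = 30) {
  if (length(stages) < 1L) stop("a hypnogram needs at least one epoch")
  if (epoch_seconds != 30) stop("epoch_seconds must be 30")
  codes <- if (is.character(stages) || is.factor(stages)) {
    stage_code(as.character(stages))
  } else {
    if (any(!is.finite(stages))) stop("stage codes must be finite")
    if (any(stages != as.integer(stages)) || any(stages < 0) || any(stages > 4)) {
      stop("stage codes must be integers in 0..4")
    }
    as.integer(stages)
  }
  structure(codes, class = "hypnogram", epoch_seconds = 30)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x), " epochs (", length(x) * 30 / 3600,
      " h)\n", sep = "")
  labs <- stage_label(unclass(x))
  if (length(x) > 20L) {
    cat(" ", paste(labs[1:20], collapse = " "), "...\n")
  } else {
    cat(" ", paste(labs, collapse = " "), "\n")
  }
  invisible(x)
}

#' Validate a predicted probability matrix
#'
#' Checks and lightly repairs a `T x 5` matrix of per-epoch stage
#' probabilities (rows = epochs, columns = stages in [stage_levels()]
#' order). Entries within `tolerance` of `[0, 1]` are clipped; rows whose
#' sum deviates from 1 by at most `tolerance` are renormalized with a
#' warning. Larger deviations are errors naming the offending row, since
#' silently rescaling badly scaled input would mask upstream bugs.
#'
#' @param probs Numeric matrix with 5 columns.
#' @param tolerance Maximum tolerated deviation of entries from `[0, 1]`
#'   and of row sums from 1. Default `1e-6`.
#' @return The validated matrix with class `"predicted_probabilities"` and
#'   columns named after the stages.
#' @export
#' @examples
#' p <- validate_probabilities(matrix(0.2, nrow = 3, ncol = 5))
validate_probabilities <- function(probs, tolerance = 1e-6) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 5L) stop("probability matrix must have 5 columns, got ", ncol(probs))
  if (nrow(probs) < 1L) stop("probability matrix must have at least one row")
  if (any(!is.finite(probs))) {
    bad <- which(!is.finite(probs), arr.ind = TRUE)[1L, 1L]
    stop("non-finite probability in row ", bad)
  }
  if (any(probs < -tolerance) || any(probs > 1 + tolerance)) {
    bad <- which(probs < -tolerance | probs > 1 + tolerance, arr.ind = TRUE)[1L, 1L]
    stop("probability outside [0, 1] beyond tolerance in row ", bad)
  }
  probs[probs < 0] <- 0
  probs[probs > 1] <- 1
  rs <- rowSums(probs)
  off <- abs(rs - 1)
  if (any(off > tolerance)) {
    bad <- which(off > tolerance)[1L]
    stop("row ", bad, " sums to ", format(rs[bad]),
         "; deviates from 1 by more than tolerance ", tolerance)
  }
  fix <- off > .Machine$double.eps * 8
  if (any(fix)) {
    warning(sum(fix), " row(s) renormalized (row sums deviated from 1 within tolerance)")
    probs[fix, ] <- probs[fix, , drop = FALSE] / rs[fix]
  }
  dimnames(probs) <- list(NULL, stage_levels())
  structure(probs, class = c("predicted_probabilities", "matrix", "array"))
}

#' Decode the argmax candidate hypnogram
#'
#' Picks, for every epoch, the stage with the highest predicted
#' probability — the candidate hypnogram any probabilistic classifier
#' implies. Ties are broken deterministically in favor of the lowest
#' stage code.
#'
#' @param pred A matrix accepted by [validate_probabilities()].
#' @return A [hypnogram()].
#' @export
#' @examples
#' p <- validate_probabilities(rbind(
#'   c(0.9, 0.05, 0.03, 0.01, 0.01),
#'   c(0.1, 0.15, 0.40, 0.05, 0.30)))
#' argmax_decode(p)   # W, N2
argmax_decode <- function(pred) {
  pred <- validate_probabilities(unclass(pred))
  hypnogram(max.col(pred, ties.method = "first") - 1L)
}

#' Normalize probability-matrix orientation to epochs-first
#'
#' Classifier exports sometimes store the probability matrix stages-first
#' (shape `5 x T`). This helper returns the internal epochs-first (`T x 5`)
#' orientation. A `5 x 5` matrix is ambiguous and requires an explicit
#' `orientation`.
#'
#' @param m Numeric matrix; one dimension must equal 5.
#' @param orientation One of `"auto"`, `"epochs-first"`, `"stages-first"`.
#' @return A `T x 5` matrix.
#' @export
transpose_orientation <- function(m, orientation = c("auto", "epochs-first", "stages-first")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(m)
  if (nrow(m) != 5L && ncol(m) != 5L) {
    stop("neither matrix dimension equals 5 (got ", nrow(m), " x ", ncol(m), ")")
  }
  if (nrow(m) == 5L && ncol(m) == 5L && orientation == "auto") {
    stop("5 x 5 matrix is ambiguous; pass orientation = \"epochs-first\" or \"stages-first\"")
  }
  flip <- switch(orientation,
    "stages-first" = TRUE,
    "epochs-first" = FALSE,
    "auto"         = nrow(m) == 5L)
  if (flip) t(m) else m
}

# internal: coerce to plain integer codes, validating range
as_stage_codes <- function(x) {
  if (inherits(x, "hypnogram")) return(as.integer(unclass(x)))
  unclass(hypnogram(x))
}

# internal: validate a 5x5 row-stochastic matrix
check_row_stochastic <- function(m, what, tol = 1e-6) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(5L, 5L))) stop(what, " must be 5 x 5")
  if (any(!is.finite(m)) || any(m < -tol) || any(m > 1 + tol)) {
    stop(what, " entries must be probabilities in [0, 1]")
  }
  m[m < 0] <- 0; m[m > 1] <- 1
  if (any(abs(rowSums(m) - 1) > tol)) stop(what, " rows must sum to 1")
  dimnames(m) <- list(stage_levels(), stage_levels())
  m
}
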