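# Sequence-labeling evaluation: accuracy, balanced accuracy (mean
# per-stage recall), macro F1, confusion reports, and paired Wilcoxon
# signed-rank testing with Holm-Bonferroni correction across comparisons.

#' Epoch-level accuracy
#'
#' @param truth,pred Equal-length stage sequences (hypnograms, codes or
#'   labels).
#' @return Fraction of epochs with matching stage.
#' @export
accuracy <- function(truth, pred) {
  tr <- as_stage_codes(truth); pr <- as_stage_codes(pred)
  if (length(tr) != length(pr)) stop("truth and pred differ in length")
  mean(tr == pr)
}

#' Balanced accuracy
#'
#' Unweighted mean of per-stage recall over the stages PRESENT in the
#' truth; absent stages are excluded (the common definition — a stage that
#' never occurs has undefined recall). Robust to stage prevalence
#' imbalance: improving only the dominant stage barely moves it.
#'
#' @inheritParams accuracy
#' @return Mean per-stage recall in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  tr <- as_stage_codes(truth); pr <- as_stage_codes(pred)
  if (length(tr) != length(pr)) stop("truth and pred differ in length")
  rec <- vapply(0:4, function(s) {
    n <- sum(tr == s)
    if (n == 0L) NA_real_ else sum(tr == s & pr == s) / n
  }, numeric(1))
  mean(rec, na.rm = TRUE)
}

#' Macro-averaged F1 score
#'
#' Per-stage F1 = 2PR / (P + R) with the 0/0 case defined as 0 (stated
#' explicitly because short recordings can miss stages entirely). The
#' macro average runs over stages present in truth or prediction.
#'
#' @inheritParams accuracy
#' @return A list: `macro` (the macro average) and `per_stage` (named
#'   length-5 vector, `NA` for stages absent from both sequences).
#' @export
macro_f1 <- function(truth, pred) {
  tr <- as_stage_codes(truth); pr <- as_stage_codes(pred)
  if (length(tr) != length(pr)) stop("truth and pred differ in length")
  f1 <- vapply(0:4, function(s) {
    tp <- sum(tr == s & pr == s)
    fp <- sum(tr != s & pr == s)
    fn <- sum(tr == s & pr != s)
    if (tp + fp + fn == 0L) return(NA_real_)   # stage absent everywhere
    if (tp == 0L) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  names(f1) <- stage_levels()
  list(macro = mean(f1, na.rm = TRUE), per_stage = f1)
}

#' Confusion report
#'
#' 5 x 5 table of epoch counts, rows = true stage, columns = predicted
#' stage, optionally row- or column-normalized. Column normalization uses
#' the same uniform fallback for empty columns as
#' [estimate_confusion_matrix()] (and row normalization the analogous
#' fallback), so the column-normalized report equals that estimator's
#' output.
#'
#' @inheritParams accuracy
#' @param normalize `"none"`, `"row"` or `"column"`.
#' @return A 5 x 5 matrix with stage dimnames.
#' @export
confusion_report <- function(truth, pred, normalize = c("none", "row", "column")) {
  normalize <- match.arg(normalize)
  tr <- as_stage_codes(truth); pr <- as_stage_codes(pred)
  if (length(tr) != length(pr)) stop("truth and pred differ in length")
  counts <- matrix(0, 5L, 5L, dimnames = list(stage_levels(), stage_levels()))
  for (i in seq_along(tr)) counts[tr[i] + 1L, pr[i] + 1L] <- counts[tr[i] + 1L, pr[i] + 1L] + 1
  if (normalize == "none") return(counts)
  margin <- if (normalize == "row") 1L else 2L
  totals <- apply(counts, margin, sum)
  empty <- totals == 0
  if (any(empty)) {
    warning("empty ", if (margin == 1L) "row(s)" else "column(s)", " ",
            paste(stage_levels()[empty], collapse = ", "), " set to uniform 0.2")
    if (margin == 1L) counts[empty, ] <- 1 else counts[, empty] <- 1
    totals[empty] <- 5
  }
  sweep(counts, margin, totals, "/")
}

#' Paired Wilcoxon signed-rank tests with Holm-Bonferroni correction
#'
#' For each labeled comparison, runs a two-sided paired Wilcoxon
#' signed-rank test on per-recording (before, after) metric values, then
#' applies the Holm step-down adjustment across all supplied comparisons
#' and flags adjusted p below `alpha_level`.
#'
#' Zero differences are dropped before ranking (the classical treatment);
#' tied absolute differences get mid-ranks. The exact null distribution is
#' used for n <= 25 untied differences; otherwise the normal approximation
#' with tie correction and continuity correction. A comparison whose
#' differences are all zero is reported as non-significant (p = 1) with a
#' warning rather than an error.
#'
#' @param comparisons Named list; each element a list or data frame with
#'   numeric components `before` and `after` of equal length (one value
#'   per recording).
#' @param alpha_level Family-wise significance level; default 0.05.
#' @return A data frame with one row per comparison: `comparison`, `n`
#'   (non-zero differences used), `statistic` (sum of positive ranks),
#'   `p_raw`, `p_adj` (Holm), `significant`.
#' @export
#' @examples
#' paired_wilcoxon_holm(list(
#'   acc = list(before = c(.70, .72, .71, .69, .73, .70),
#'              after  = c(.74, .75, .73, .72, .76, .74))))
paired_wilcoxon_holm <- function(comparisons, alpha_level = 0.05) {
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    stop("comparisons must be a named list")
  }
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    b <- as.numeric(cmp$before); a <- as.numeric(cmp$after)
    if (length(b) != length(a) || length(b) < 2L) {
      stop("comparison '", nm, "' needs equal-length before/after with >= 2 pairs")
    }
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0L) {
      warning("comparison '", nm, "': all differences zero; reported non-significant")
      return(data.frame(comparison = nm, n = 0L, statistic = NA_real_, p_raw = 1))
    }
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    ties <- any(duplicated(r))
    p <- if (!ties && n <= 25L) {
      pp <- if (v > n * (n + 1) / 4) {
        stats::psignrank(v - 1, n, lower.tail = FALSE)
      } else {
        stats::psignrank(v, n)
      }
      min(1, 2 * pp)
    } else {
      mu <- n * (n + 1) / 4
      tie_tab <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
      z <- v - mu
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)   # continuity correction
      min(1, 2 * stats::pnorm(-abs(z)))
    }
    data.frame(comparison = nm, n = n, statistic = v, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_adj < alpha_level
  rownames(out) <- NULL
  out
}
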