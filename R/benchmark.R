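# End-to-end benchmark on synthetic nights: decode every night with each
# requested method (argmax, median filter, Viterbi, energy annealing over
# an alpha grid), compute the metric battery, and test method-vs-argmax
# differences with paired Wilcoxon + Holm.

#' Decode one night with a named method
#'
#' Shared dispatcher of the benchmark and the command-line `decode`
#' subcommand.
#'
#' @param method One of `"argmax"`, `"median"`, `"viterbi"`, `"energy"`.
#' @param pred A `"predicted_probabilities"` matrix.
#' @param trans,conf,prior Matrices and stage prior, as produced by
#'   [make_benchmark()] or [read_matrices()]; unused entries may be `NULL`
#'   for methods that do not consume them.
#' @param params,schedule,seed,sign_mode Passed to [anneal()] for
#'   `method = "energy"`.
#' @param window Window width for `method = "median"`.
#' @return A [hypnogram()].
#' @export
decode_night <- function(method, pred, trans = NULL, conf = NULL,
                         prior = rep(0.2, 5), params = energy_params(),
                         schedule = anneal_schedule(), seed = NULL,
                         sign_mode = "effective", window = 3L) {
  switch(match.arg(method, c("argmax", "median", "viterbi", "energy")),
    argmax = argmax_decode(pred),
    median = median_smooth(argmax_decode(pred), window),
    viterbi = viterbi_decode(pred, trans, prior),
    energy = anneal(pred, trans, conf, params = params, schedule = schedule,
                    seed = seed, sign_mode = sign_mode)$best_state)
}

#' Run the synthetic benchmark
#'
#' Generates a seeded [make_benchmark()] bundle, decodes every night with
#' every method — the energy method once per value of `alpha_grid` — and
#' reports per-night metrics, per-method means, and paired Wilcoxon tests
#' (each method against the argmax baseline, Holm-adjusted as a family).
#'
#' @param config A [synthetic_config()].
#' @param methods Character vector of baseline methods to include besides
#'   the energy runs; subset of `"argmax"`, `"median"`, `"viterbi"`.
#'   `"argmax"` is always included (it is the comparison anchor).
#' @param alpha_grid Numeric vector of alpha values for the energy method;
#'   default `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param params Base [energy_params()]; `alpha` is overridden per grid
#'   point.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed determining the whole benchmark (data and
#'   annealing runs).
#' @param sign_mode Passed to [anneal()].
#' @return A list with class `"benchmark_report"`: `per_night` (data frame:
#'   night, method, accuracy, balanced_accuracy, macro_f1), `summary`
#'   (per-method means), `tests` (output of [paired_wilcoxon_holm()] on
#'   accuracy vs argmax), `config`, `seed`.
#' @export
run_benchmark <- function(config = synthetic_config(),
                          methods = c("argmax", "median", "viterbi"),
                          alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                          params = energy_params(),
                          schedule = anneal_schedule(),
                          seed = 1L, sign_mode = "effective") {
  methods <- unique(c("argmax", match.arg(methods,
      c("argmax", "median", "viterbi"), several.ok = TRUE)))
  if (length(alpha_grid) == 0L && length(methods) == 0L) stop("no methods requested")
  bench <- make_benchmark(config, seed = seed)
  alpha_label <- function(a) paste0("energy_alpha_", format(a))
  labels <- c(methods, vapply(alpha_grid, alpha_label, ""))
  rows <- list()
  for (i in seq_along(bench$nights)) {
    night <- bench$nights[[i]]
    for (m in methods) {
      dec <- decode_night(m, night$pred, bench$trans, bench$conf, bench$prior)
      rows[[length(rows) + 1L]] <- data.frame(
        night = i, method = m,
        accuracy = accuracy(night$truth, dec),
        balanced_accuracy = balanced_accuracy(night$truth, dec),
        macro_f1 = macro_f1(night$truth, dec)$macro)
    }
    for (a in alpha_grid) {
      p <- energy_params(alpha = a, eps_t = params$eps_t, eps_p = params$eps_p)
      dec <- decode_night("energy", night$pred, bench$trans, bench$conf,
                          params = p, schedule = schedule,
                          seed = seed + 1000L * i + round(100 * a),
                          sign_mode = sign_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        night = i, method = alpha_label(a),
        accuracy = accuracy(night$truth, dec),
        balanced_accuracy = balanced_accuracy(night$truth, dec),
        macro_f1 = macro_f1(night$truth, dec)$macro)
    }
  }
  per_night <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_night, per_night$method), function(d) {
    data.frame(method = d$method[1L],
               accuracy = mean(d$accuracy),
               balanced_accuracy = mean(d$balanced_accuracy),
               macro_f1 = mean(d$macro_f1))
  }))
  rownames(summary) <- NULL
  base <- per_night[per_night$method == "argmax", ]
  base <- base[order(base$night), ]
  cmp <- list()
  for (m in setdiff(labels, "argmax")) {
    d <- per_night[per_night$method == m, ]
    d <- d[order(d$night), ]
    cmp[[paste0(m, "_vs_argmax")]] <- list(before = base$accuracy,
                                           after = d$accuracy)
  }
  tests <- paired_wilcoxon_holm(cmp)
  structure(list(per_night = per_night, summary = summary, tests = tests,
                 config = config, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", x$config$n_nights, " nights x ",
      x$config$n_epochs, " epochs (seed ", x$seed, ")\n\n", sep = "")
  s <- x$summary
  s[, -1L] <- round(s[, -1L], 4)
  print(s, row.names = FALSE)
  cat("\nPaired Wilcoxon (accuracy vs argmax), Holm-adjusted:\n")
  t <- x$tests
  t$p_raw <- signif(t$p_raw, 3); t$p_adj <- signif(t$p_adj, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
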