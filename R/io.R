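# File round-tripping. Hypnograms and probability matrices travel as CSV
# (epoch indices 0-based, stage columns in fixed W,N1,N2,N3,R order);
# matrices and run manifests as self-describing JSON with the stage
# ordering embedded.

#' Read / write a hypnogram CSV
#'
#' Format: header `epoch,stage`, `epoch` a 0-based contiguous integer
#' index, `stage` a label in `W, N1, N2, N3, R`.
#'
#' @param path File path.
#' @return `read_hypnogram`: a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty hypnogram file: ", path)
  if (!identical(names(df)[1:2], c("epoch", "stage"))) {
    stop("expected header 'epoch,stage' in ", path)
  }
  expect <- seq_len(nrow(df)) - 1L
  if (!identical(as.integer(df$epoch), expect)) {
    bad <- which(as.integer(df$epoch) != expect)[1L]
    stop("epoch indices must be contiguous 0..T-1; first offending row ", bad,
         " has epoch ", df$epoch[bad])
  }
  hypnogram(stage_code(df$stage))
}

#' @rdname read_hypnogram
#' @param hyp A [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  s <- as_stage_codes(hyp)
  df <- data.frame(epoch = seq_along(s) - 1L, stage = stage_label(s))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a predicted probability CSV
#'
#' Epochs-first format: header `epoch,W,N1,N2,N3,R`, one row per epoch.
#' With `stages_first = TRUE` the transposed (5 x T) layout is accepted:
#' header `stage,e0,e1,...`, one row per stage in fixed order.
#'
#' @param path File path.
#' @param stages_first Is the file in the transposed stages-first layout?
#' @param tolerance Passed to [validate_probabilities()].
#' @return `read_probabilities`: a `"predicted_probabilities"` matrix.
#' @export
read_probabilities <- function(path, stages_first = FALSE, tolerance = 1e-6) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty probability file: ", path)
  if (stages_first) {
    if (names(df)[1L] != "stage" || !identical(df$stage, stage_levels())) {
      stop("stages-first file must have header 'stage,e0,...' with rows W,N1,N2,N3,R")
    }
    m <- transpose_orientation(as.matrix(df[, -1L, drop = FALSE]), "stages-first")
  } else {
    if (!identical(names(df), c("epoch", stage_levels()))) {
      stop("expected header 'epoch,", paste(stage_levels(), collapse = ","),
           "' in ", path)
    }
    m <- as.matrix(df[, stage_levels(), drop = FALSE])
  }
  storage.mode(m) <- "double"
  validate_probabilities(m, tolerance)
}

#' @rdname read_probabilities
#' @param pred A `"predicted_probabilities"` matrix.
#' @export
write_probabilities <- function(pred, path) {
  m <- unclass(validate_probabilities(unclass(pred)))
  df <- data.frame(epoch = seq_len(nrow(m)) - 1L,
                   apply(m, 2L, function(x) format(x, digits = 15, trim = TRUE)))
  names(df) <- c("epoch", stage_levels())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the transition + confusion matrix bundle as JSON
#'
#' The JSON embeds the stage ordering and the orientation conventions
#' (transition rows are source stages and sum to 1; confusion columns are
#' predicted stages and sum to 1), so files are self-describing.
#'
#' @param path File path.
#' @return `read_matrices`: list with `trans`, `conf`, and optional `prior`.
#' @export
read_matrices <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$stage_order, stage_levels())) {
    stop("matrix file stage order ", paste(x$stage_order, collapse = ","),
         " does not match ", paste(stage_levels(), collapse = ","))
  }
  out <- list(trans = transition_matrix(matrix(x$transition, 5L, 5L, byrow = TRUE)),
              conf = confusion_matrix(matrix(x$confusion, 5L, 5L, byrow = TRUE)))
  if (!is.null(x$prior)) out$prior <- as.numeric(x$prior)
  out
}

#' @rdname read_matrices
#' @param trans A [transition_matrix()].
#' @param conf A [confusion_matrix()].
#' @param prior Optional length-5 stage prevalence vector.
#' @export
write_matrices <- function(trans, conf, path, prior = NULL) {
  if (!inherits(trans, "transition_matrix")) trans <- transition_matrix(trans)
  if (!inherits(conf, "confusion_matrix")) conf <- confusion_matrix(conf)
  x <- list(
    stage_order = stage_levels(),
    orientation = list(
      transition = "row = source stage (t-1), column = target stage (t); rows sum to 1",
      confusion = "row = true stage, column = predicted stage; columns sum to 1 (P(true | predicted))"),
    transition = as.vector(t(unclass(trans))),   # flat, row-major
    confusion = as.vector(t(unclass(conf))))
  if (!is.null(prior)) x$prior <- prior
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI command records the inputs, parameters, seed and package
#' version needed to reproduce its output bit-exactly.
#'
#' @param path Output path (conventionally `<artifact>.manifest.json`).
#' @param command Command name.
#' @param inputs,parameters Named lists.
#' @param seed Integer seed or `NULL`.
#' @export
write_manifest <- function(path, command, inputs = list(), parameters = list(),
                           seed = NULL) {
  jsonlite::write_json(list(
    command = command,
    package = "sleepenergy",
    version = as.character(utils::packageVersion("sleepenergy")),
    seed = seed, inputs = inputs, parameters = parameters
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
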