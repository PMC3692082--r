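#' Fractional rank normalization of per-gene scores
#'
#' The SVM consumes rankings, not raw scores: each channel's per-gene scores
#' are replaced by fractional ranks `rank / n` in (0, 1], assigned so the
#' most target-like gene gets 1.  Ties receive the average of their ranks.
#' The output depends only on the ordering of the input, which removes the
#' scale and distribution differences between channels (and between
#' species or miRNA sets).
#'
#' @param scores Numeric vector of per-gene scores (length >= 2).
#' @param direction `"higher_is_target"` or `"lower_is_target"` (which end
#'   of the score scale marks a target).
#' @return Fractional ranks in (0, 1].
#' @export
rank_normalize <- function(scores, direction = c("higher_is_target", "lower_is_target")) {
  direction <- match.arg(direction)
  if (length(scores) < 2L) abort("rank normalization needs at least 2 genes")
  x <- if (direction == "lower_is_target") -scores else scores
  if (length(unique(x)) == 1L) {
    warn("all scores identical; every gene receives the midpoint rank")
  }
  rank(x, ties.method = "average") / length(x)
}

#' Rank-normalized per-gene feature table for the SVM
#'
#' @param channel_matrix Long score tibble from [build_channel_matrix()].
#' @param directions Named vector of per-channel directions (defaults:
#'   energy-channel occupancy sums and seed counts `higher_is_target`,
#'   mirSVR weighted sums `lower_is_target`).
#' @return Wide tibble: `gene`, `label`, one fractional-rank column per
#'   channel.
#' @export
channel_features <- function(channel_matrix, directions = CHANNEL_DIRECTIONS) {
  ranked <- channel_matrix |>
    group_by(.data$label, .data$channel) |>
    mutate(r = rank_normalize(.data$score, directions[[.data$channel[1]]])) |>
    ungroup()
  tidyr::pivot_wider(ranked[, c("gene", "label", "channel", "r")],
                     names_from = "channel", values_from = "r")
}

feature_channels <- function(features) intersect(CHANNELS, names(features))

#' Train the SVM integrating the channel rankings into a target probability
#'
#' Fits a probability-calibrated support vector machine on labelled genes
#' (targets vs non-targets, e.g. derived from Argonaute immunoprecipitation)
#' whose features are the per-channel fractional ranks.  Cross-validated
#' AUROC is computed on held-out folds before the final fit on all data.
#' Training is deterministic given `seed`.
#'
#' @param features Wide feature tibble from [channel_features()] (one row
#'   per gene; a `label` column, if present, must be constant).
#' @param labels Tibble (`gene`, `class`) with `class` in
#'   `{"target", "decoy"}`, or a logical vector along `features` rows
#'   (`TRUE` = target).
#' @param cost,gamma Radial-basis SVM hyperparameters (`gamma` defaults to
#'   1 / n_channels).
#' @param folds Cross-validation folds for the AUROC report.
#' @param seed RNG seed controlling fold assignment and probability
#'   calibration.
#' @return A `mirset_model` object.
#' @export
train_target_model <- function(features, labels, cost = 1, gamma = NULL,
                               folds = 5, seed = 1) {
  channels <- feature_channels(features)
  if (length(channels) == 0L) abort("no channel columns in `features`")
  if (is.logical(labels)) {
    stopifnot(length(labels) == nrow(features))
    y <- factor(ifelse(labels, "target", "decoy"), levels = c("decoy", "target"))
    df <- features
  } else {
    df <- inner_join(features, labels, by = "gene")
    if (nrow(df) == 0L) abort("no genes shared between `features` and `labels`")
    y <- factor(df$class, levels = c("decoy", "target"))
  }
  if (anyNA(y) || length(unique(y)) < 2L) {
    abort("training labels must contain both classes ('target' and 'decoy')")
  }
  x <- as.matrix(df[, channels, drop = FALSE])
  if (is.null(gamma)) gamma <- 1 / length(channels)

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(x)))
  resp <- integer(0); pred <- numeric(0)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    if (length(unique(y[!hold])) < 2L) next
    fit_f <- e1071::svm(x[!hold, , drop = FALSE], y[!hold], kernel = "radial",
                        cost = cost, gamma = gamma)
    dvm <- attr(predict(fit_f, x[hold, , drop = FALSE], decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1]
    # orient decision values toward the target class
    if (colnames(dvm)[1] == "decoy/target") dv <- -dv
    resp <- c(resp, as.integer(y[hold] == "target"))
    pred <- c(pred, dv)
  }
  cv_auc <- if (length(unique(resp)) == 2L) {
    as.numeric(pROC::auc(resp, pred, quiet = TRUE, direction = "<"))
  } else NA_real_

  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    probability = TRUE)
  structure(list(fit = fit, channels = channels,
                 directions = CHANNEL_DIRECTIONS[channels],
                 cost = cost, gamma = gamma, seed = seed, folds = folds,
                 cv_auc = cv_auc, n_train = nrow(x),
                 trained = format(Sys.Date())),
            class = "mirset_model")
}

#' @export
print.mirset_model <- function(x, ...) {
  cat("miRNA-set target model (radial SVM)\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  trained on", x$n_train, "genes; cross-validated AUROC",
      formatC(x$cv_auc, digits = 3, format = "f"), "\n")
  invisible(x)
}

#' Predict per-gene target probabilities
#'
#' @param object A `mirset_model`.
#' @param features Wide feature tibble (must contain every channel the model
#'   was trained on).
#' @param ... Unused.
#' @return Tibble with `gene` (and `label` when present in `features`) and
#'   `probability`, the SVM-calibrated probability that the gene is a
#'   functional target of the miRNA set.
#' @export
predict.mirset_model <- function(object, features, ...) {
  missing <- setdiff(object$channels, names(features))
  if (length(missing) > 0L) {
    abort(paste0("feature table lacks model channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(features[, object$channels, drop = FALSE])
  pr <- predict(object$fit, x, probability = TRUE)
  p <- attr(pr, "probabilities")[, "target"]
  keep <- intersect(c("gene", "label"), names(features))
  dplyr::bind_cols(features[, keep, drop = FALSE], tibble(probability = unname(p)))
}

#' Save / load a trained model
#'
#' The model file is a self-describing serialized object carrying the kernel
#' specification, fitted parameters, channel set and training seed; loading
#' restores it bit-identically.
#'
#' @param model A `mirset_model`.
#' @param path File path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mirset_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mirset_model")) abort("file does not contain a mirset model")
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained target model: one row per feature channel
#' @param x A `mirset_model`.
#' @param ... Unused.
#' @export
tidy.mirset_model <- function(x, ...) {
  tibble(channel = x$channels,
         direction = unname(x$directions[x$channels]))
}

#' One-row training summary of a target model
#' @param x A `mirset_model`.
#' @param ... Unused.
#' @export
glance.mirset_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_channels = length(x$channels),
         kernel = "radial", cost = x$cost, gamma = x$gamma,
         folds = x$folds, cv_auc = x$cv_auc, seed = x$seed)
}
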