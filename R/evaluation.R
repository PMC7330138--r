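#' Labeled five-set EEG dataset
#'
#' Container for the Bonn-style experimental layout: five sets `A`–`E` of
#' records, with the fixed class mapping A, B = normal; C, D = interictal;
#' E = ictal. All records within a set must share the same sampling rate;
#' differing record lengths within a set are tolerated with a warning.
#'
#' @param sets Named list with elements `A`–`E`, each a list of
#'   [ts_signal()] records (or numeric vectors, coerced with the fs of the
#'   first signal in the set, default 173.61).
#' @return An object of class `labeled_dataset`: a list with `sets` and
#'   `class_of_set`.
#' @examples
#' ds <- make_bonn_like(seed = 1, records_per_set = 2)
#' dataset_classes(ds)
#' @export
labeled_dataset <- function(sets) {
  ids <- c("A", "B", "C", "D", "E")
  if (!is.list(sets) || !setequal(names(sets), ids))
    stop("sets must be a named list with exactly the sets A, B, C, D, E; found: ",
         paste(names(sets), collapse = ", "))
  sets <- sets[ids]
  n_mixed <- 0L
  for (id in ids) {
    if (length(sets[[id]]) < 1L) stop("set ", id, " is empty")
    sets[[id]] <- lapply(sets[[id]], as_ts_signal)
    fs <- vapply(sets[[id]], function(s) s$fs, numeric(1))
    if (length(unique(fs)) > 1L)
      stop("records in set ", id, " have differing sampling rates")
    lens <- vapply(sets[[id]], function(s) length(s$samples), integer(1))
    if (length(unique(lens)) > 1L) n_mixed <- n_mixed + 1L
    cls <- set_class_map()[[id]]
    sets[[id]] <- lapply(sets[[id]], function(s) {
      s$label <- cls
      s
    })
  }
  if (n_mixed > 0L)
    warning(n_mixed, " set(s) contain records of differing lengths")
  structure(list(sets = sets, class_of_set = unlist(set_class_map())),
            class = "labeled_dataset")
}

set_class_map <- function() {
  list(A = "normal", B = "normal", C = "interictal", D = "interictal",
       E = "ictal")
}

#' @rdname labeled_dataset
#' @param data A `labeled_dataset`.
#' @export
dataset_classes <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  data$class_of_set
}

#' @export
print.labeled_dataset <- function(x, ...) {
  counts <- vapply(x$sets, length, integer(1))
  cat("<labeled_dataset>\n")
  for (id in names(x$sets)) {
    s1 <- x$sets[[id]][[1]]
    cat(sprintf("  %s (%s): %d records, %d samples @ %.6g Hz\n",
                id, x$class_of_set[[id]], counts[[id]],
                length(s1$samples), s1$fs))
  }
  invisible(x)
}

#' Rank-based AUC between two score groups
#'
#' The Mann-Whitney probability that a positive-group score exceeds a
#' negative-group score, with ties counted one half: equivalently the area
#' under the ROC curve of the scores. Computed from midranks, so it is
#' exact under ties and invariant under strictly monotone transforms of
#' the pooled scores.
#'
#' @param scores_negative,scores_positive Non-empty numeric score vectors.
#' @return The AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(1, 3), c(2, 4))  # 0.75
#' @export
rank_auc <- function(scores_negative, scores_positive) {
  if (length(scores_negative) == 0L || length(scores_positive) == 0L)
    stop("both score groups must be non-empty")
  if (anyNA(scores_negative) || anyNA(scores_positive))
    stop("scores must not contain NA")
  n0 <- length(scores_negative)
  n1 <- length(scores_positive)
  r <- rank(c(scores_negative, scores_positive))
  (sum(r[n0 + seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' @rdname rank_auc
#' @details `oriented_auc()` reports `max(AUC, 1 - AUC)` together with the
#'   direction in which the positive class scores, since whether pathology
#'   raises or lowers a given entropy differs by estimator.
#' @return `oriented_auc()`: a list with `auc` (in `[0.5, 1]`), `direction`
#'   (`"positive-high"` or `"positive-low"`), and the unoriented `auc_raw`.
#' @export
oriented_auc <- function(scores_negative, scores_positive) {
  a <- rank_auc(scores_negative, scores_positive)
  list(auc = max(a, 1 - a),
       direction = if (a >= 0.5) "positive-high" else "positive-low",
       auc_raw = a)
}

#' Per-record entropy features of a dataset
#'
#' Computes one entropy value per record on its prefix window. Records on
#' which the estimator fails (e.g. a constant window) are excluded with a
#' count kept in the `n_excluded` attribute.
#'
#' With `params$r_scope = "global"` the similarity width of the fuzzy and
#' modified-distribution estimators is resolved from the full record rather
#' than the analyzed window.
#'
#' @param data A [labeled_dataset()].
#' @param method Estimator name or scoring function (see
#'   [compute_entropy()]).
#' @param params An [entropy_params()].
#' @param window_s Window length in seconds; `NULL` analyzes full records.
#' @return A data frame with columns `set`, `record`, `class`, `value` and
#'   attribute `n_excluded`.
#' @export
entropy_features <- function(data, method = "mdist",
                             params = entropy_params(), window_s = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  rows <- list()
  n_excluded <- 0L
  for (id in names(data$sets)) {
    for (ri in seq_along(data$sets[[id]])) {
      rec <- data$sets[[id]][[ri]]
      win <- if (is.null(window_s)) rec else window_signal(rec, window_s)
      r <- if (!is.character(method) || method %in% c("fuzzy", "mdist")) {
        if (identical(params$r_scope, "global"))
          resolve_r(rec, params$r_factor)
        else NULL
      } else NULL
      value <- tryCatch(compute_entropy(win, method, params, r = r),
                        error = function(e) NA_real_)
      if (is.na(value)) {
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = id, record = ri, class = data$class_of_set[[id]],
        value = value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

contrast_groups <- function(contrast) {
  switch(contrast,
         "normal-vs-ictal" = list(neg = "normal", pos = "ictal"),
         "interictal-vs-ictal" = list(neg = "interictal", pos = "ictal"),
         "normal-vs-rest" = list(neg = "normal",
                                 pos = c("interictal", "ictal")),
         stop("unknown contrast: ", contrast,
              " (supported: normal-vs-ictal, interictal-vs-ictal, normal-vs-rest)"))
}

#' AUC sweep over window lengths and group contrasts
#'
#' For each estimator, contrast and window length, computes per-record
#' entropies on the prefix window and the oriented AUC between the two
#' groups. Supported contrasts: `"normal-vs-ictal"`,
#' `"interictal-vs-ictal"` and `"normal-vs-rest"` (normal against the
#' union of interictal and ictal).
#'
#' @param data A [labeled_dataset()].
#' @param methods Character vector of estimators (and/or scoring
#'   functions in a list).
#' @param params An [entropy_params()].
#' @param contrasts Character vector of contrast names.
#' @param window_lengths_s Numeric vector of window lengths in seconds.
#' @return A data frame with one row per method x contrast x window:
#'   columns `method`, `contrast`, `window_s`, `auc`, `direction`,
#'   `auc_raw`, `n_neg`, `n_pos`, `n_excluded`.
#' @export
auc_sweep <- function(data, methods = c("fuzzy", "dist", "mdist"),
                      params = entropy_params(),
                      contrasts = c("normal-vs-ictal",
                                    "interictal-vs-ictal",
                                    "normal-vs-rest"),
                      window_lengths_s = 1:23) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.list(methods)) methods <- as.list(methods)
  rows <- list()
  for (mi in seq_along(methods)) {
    method <- methods[[mi]]
    mname <- if (is.character(method)) method else
      if (!is.null(names(methods)[mi]) && nzchar(names(methods)[mi]))
        names(methods)[mi] else "custom"
    for (w in window_lengths_s) {
      feats <- entropy_features(data, method, params, window_s = w)
      for (ct in contrasts) {
        gr <- contrast_groups(ct)
        neg <- feats$value[feats$class %in% gr$neg]
        pos <- feats$value[feats$class %in% gr$pos]
        o <- oriented_auc(neg, pos)
        rows[[length(rows) + 1L]] <- data.frame(
          method = mname, contrast = ct, window_s = w,
          auc = o$auc, direction = o$direction, auc_raw = o$auc_raw,
          n_neg = length(neg), n_pos = length(pos),
          n_excluded = attr(feats, "n_excluded"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a single-threshold classifier on scores
#'
#' Exhaustively searches the midpoints between consecutive distinct
#' training scores (plus the two all-one-class extremes) in both
#' orientations and returns the cut maximizing the training objective.
#' The default objective is balanced accuracy — the mean of sensitivity
#' and specificity — which is insensitive to class imbalance and reduces
#' to plain accuracy on balanced data; `"accuracy"` maximizes raw training
#' accuracy instead. Ties prefer the lower threshold, and between
#' orientations the positive-scores-high direction.
#'
#' @param train_scores Numeric scores.
#' @param train_labels Logical (or 0/1) vector: `TRUE` for the positive
#'   class. Both classes must be present.
#' @param objective `"balanced"` or `"accuracy"`.
#' @return A list with `threshold`, `direction` (`"positive-high"` or
#'   `"positive-low"`), `value` (the achieved training objective) and
#'   `objective`.
#' @examples
#' fit_threshold(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))$threshold  # 5
#' @export
fit_threshold <- function(train_scores, train_labels,
                          objective = c("balanced", "accuracy")) {
  objective <- match.arg(objective)
  y <- as.logical(train_labels)
  if (length(y) != length(train_scores))
    stop("scores and labels must have equal length")
  if (anyNA(train_scores) || anyNA(y)) stop("scores/labels must not be NA")
  if (!any(y) || all(y))
    stop("both classes must be present in the training labels")
  s <- sort(unique(train_scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  score_of <- function(pred) {
    if (objective == "accuracy") return(mean(pred == y))
    (mean(pred[y]) + mean(!pred[!y])) / 2   # (sensitivity + specificity)/2
  }
  best <- list(threshold = NA_real_, direction = NA_character_,
               value = -Inf, objective = objective)
  for (dir in c("positive-high", "positive-low")) {
    for (thr in cand) {
      pred <- if (dir == "positive-high") train_scores > thr
              else train_scores < thr
      v <- score_of(pred)
      if (v > best$value + 1e-12) {
        best$threshold <- thr
        best$direction <- dir
        best$value <- v
      }
    }
  }
  best
}

apply_threshold <- function(scores, fit) {
  if (fit$direction == "positive-high") scores > fit$threshold
  else scores < fit$threshold
}

#' Confusion-matrix metrics
#'
#' Exact ratios: sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, accuracy `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return A list with `sensitivity`, `specificity` and `accuracy`.
#' @examples
#' confusion_metrics(TP = 74, TN = 95, FP = 5, FN = 6)
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (TP + FN == 0) stop("sensitivity undefined: TP + FN is zero")
  if (TN + FP == 0) stop("specificity undefined: TN + FP is zero")
  list(sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       accuracy = (TP + TN) / (TP + FP + TN + FN))
}

#' Leave-one-set-out cross-validation of a threshold classifier
#'
#' The five-fold scheme of the Bonn layout: each of the sets A-E serves
#' once as the held-out test set while a threshold on the entropy feature
#' is fit on the remaining four sets, with the ictal class positive. When
#' set E is held out the training data contain no ictal records; the fold
#' then falls back to fitting interictal (positive) against normal and is
#' flagged in the output.
#'
#' @param data A [labeled_dataset()].
#' @param method Estimator name or scoring function.
#' @param params An [entropy_params()].
#' @param window_s Window length in seconds (`NULL` = full records).
#' @param objective Threshold objective, see [fit_threshold()].
#' @return An object of class `entropy_cv`: list with `per_fold` (data
#'   frame: `test_set`, `threshold`, `direction`, `fallback`, `n_test`,
#'   `TP`, `TN`, `FP`, `FN`, `accuracy`), `pooled` (summed counts plus
#'   sensitivity/specificity/accuracy), `method`, `window_s`,
#'   `n_excluded`.
#' @export
cross_validate <- function(data, method = "mdist",
                           params = entropy_params(), window_s = NULL,
                           objective = c("balanced", "accuracy")) {
  stopifnot(inherits(data, "labeled_dataset"))
  objective <- match.arg(objective)
  feats <- entropy_features(data, method, params, window_s = window_s)
  folds <- list()
  for (id in names(data$sets)) {
    train <- feats[feats$set != id, ]
    test <- feats[feats$set == id, ]
    pos <- train$class == "ictal"
    fallback <- FALSE
    if (!any(pos)) {              # set E held out: no ictal training data
      fallback <- TRUE
      pos <- train$class == "interictal"
    }
    fit <- fit_threshold(train$value, pos, objective = objective)
    truth <- test$class == "ictal"
    pred <- apply_threshold(test$value, fit)
    folds[[id]] <- data.frame(
      test_set = id, threshold = fit$threshold, direction = fit$direction,
      fallback = fallback, n_test = nrow(test),
      TP = sum(pred & truth), TN = sum(!pred & !truth),
      FP = sum(pred & !truth), FN = sum(!pred & truth),
      accuracy = mean(pred == truth), stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, folds)
  rownames(per_fold) <- NULL
  pooled <- lapply(as.list(colSums(per_fold[, c("TP", "TN", "FP", "FN")])),
                   as.integer)
  pooled <- c(pooled, confusion_metrics(pooled$TP, pooled$TN, pooled$FP,
                                        pooled$FN))
  structure(list(per_fold = per_fold, pooled = pooled,
                 method = if (is.character(method)) method else "custom",
                 window_s = window_s, objective = objective,
                 n_excluded = attr(feats, "n_excluded")),
            class = "entropy_cv")
}

#' @export
print.entropy_cv <- function(x, ...) {
  cat(sprintf("<entropy_cv> %s, window = %s s, objective = %s\n",
              method_label(x$method),
              if (is.null(x$window_s)) "full record" else
                format(x$window_s), x$objective))
  print(x$per_fold, row.names = FALSE)
  with(x$pooled, cat(sprintf(
    "pooled: sensitivity %.4f, specificity %.4f, accuracy %.4f (TP %d TN %d FP %d FN %d)\n",
    sensitivity, specificity, accuracy, TP, TN, FP, FN)))
  if (any(x$per_fold$fallback))
    cat("note: fold(s) ", paste(x$per_fold$test_set[x$per_fold$fallback],
                                collapse = ", "),
        " had no ictal training data; threshold fit on interictal vs normal\n",
        sep = "")
  if (x$n_excluded > 0)
    cat("note: ", x$n_excluded, " record(s) excluded (entropy failure)\n",
        sep = "")
  invisible(x)
}
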