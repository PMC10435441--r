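#' Gradient-boosted tree hyperparameters
#'
#' The study fixes `max_depth = 2` and `learning_rate = 0.01` and leaves the
#' rest at library defaults; this package's defaults are 100 boosting rounds
#' and a minimum of 5 observations per leaf (suited to run-level sample sizes
#' in the tens; see the methods vignette).
#'
#' @param nrounds boosting rounds.
#' @param learning_rate shrinkage.
#' @param max_depth tree depth limit.
#' @param min_leaf minimum observations per leaf.
#' @param min_gain minimum split gain.
#' @return list of class `"gbt_params"`.
#' @export
gbt_params <- function(nrounds = 100, learning_rate = 0.01, max_depth = 2,
                       min_leaf = 5, min_gain = 0) {
  structure(list(nrounds = as.integer(nrounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), min_gain = min_gain),
            class = "gbt_params")
}

#' Fit / predict the boosted-tree binary classifier
#'
#' Deterministic gradient boosting with logistic loss, Newton leaf values and
#' depth-limited trees (no row or feature subsampling; ties broken by feature
#' index). `predict_gbt` returns the additive margin (log-odds); class 1 is
#' predicted for margin > 0.
#'
#' @param X numeric feature matrix (rows = windows).
#' @param y 0/1 labels.
#' @param params a [gbt_params()].
#' @return `fit_gbt`: model object of class `"gbt_model"`.
#' @export
fit_gbt <- function(X, y, params = gbt_params()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  m <- .gbt_fit_cpp(X, as.numeric(y), params$nrounds, params$learning_rate,
                    params$max_depth, params$min_leaf, params$min_gain)
  m$feature_names <- colnames(X)
  class(m) <- "gbt_model"
  m
}

#' @rdname fit_gbt
#' @param model a fitted `gbt_model`.
#' @export
predict_gbt <- function(model, X) {
  .gbt_predict_cpp(unclass(model), as.matrix(X))
}

#' Exact Shapley attributions for a boosted-tree model
#'
#' Path-dependent Shapley values computed exactly per tree by subset
#' enumeration over the (at most `max_depth + 1`) features a tree uses,
#' marginalizing absent features by training-cover fractions.
#'
#' @param model a `gbt_model`.
#' @param X matrix of rows to explain.
#' @return matrix (rows x features) of per-feature margin contributions.
#' @export
shap_values <- function(model, X) {
  phi <- .gbt_shap_cpp(unclass(model), as.matrix(X))
  colnames(phi) <- model$feature_names
  phi
}

#' Assemble the paired-window dataset at one gap
#'
#' For each run, one negative-class feature vector from the left (run-start)
#' window and one positive-class vector from the right (run-end) window, with
#' the two window centers `gap_s` apart and placed symmetrically inside the
#' run. Runs too short for the requested gap are skipped with a warning.
#'
#' @param recordings list of `ppg_recording`s.
#' @param gap_s center-to-center window separation, s; must be >= the window
#'   duration (otherwise the windows overlap).
#' @param window a [window_spec()].
#' @param ... passed to [extract_window_features()].
#' @return list of class `"window_pair_dataset"`: `X`, `y`, `run` (run index
#'   per row), `gap_s`.
#' @export
build_pair_dataset <- function(recordings, gap_s, window = window_spec(),
                               ...) {
  if (gap_s < window$duration_s)
    stop("windows overlap at gap ", gap_s, " s (< window duration)")
  rows <- list(); y <- integer(0); run <- integer(0)
  for (r in seq_along(recordings)) {
    rec <- recordings[[r]]
    D <- max(rec$data$time_s)
    if (gap_s > D - window$duration_s) {
      warning("run ", r, " too short for gap ", gap_s, " s; skipped")
      next
    }
    left <- ((D - window$duration_s) - gap_s) / 2
    fl <- extract_window_features(rec, left, window, ...)
    fr <- extract_window_features(rec, left + gap_s, window, ...)
    rows <- c(rows, list(fl, fr))
    y <- c(y, 0L, 1L)
    run <- c(run, r, r)
  }
  if (!length(rows)) stop("no run is long enough for gap ", gap_s, " s")
  structure(list(X = do.call(rbind, rows), y = y, run = run, gap_s = gap_s),
            class = "window_pair_dataset")
}

# deterministic grouped fold assignment: runs shuffled by seed, dealt round-robin
grouped_folds <- function(run_ids, folds, seed) {
  runs <- sort(unique(run_ids))
  if (length(runs) < folds)
    stop("need at least as many runs (", length(runs), ") as folds (", folds, ")")
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 11))
  shuffled <- sample(runs)
  fold_of_run <- setNames(rep(seq_len(folds), length.out = length(runs)),
                          shuffled)
  unname(fold_of_run[as.character(run_ids)])
}

#' Grouped cross-validated accuracy of the boosted classifier
#'
#' Runs are dealt into folds (all windows of a run share a fold, so no run
#' leaks between train and validation); accuracy is the pooled fraction of
#' correctly classified held-out windows.
#'
#' @param X,y,run_ids dataset rows, labels and run identifiers.
#' @param folds number of folds (the study used 4).
#' @param params a [gbt_params()].
#' @param seed fold-assignment seed.
#' @return list: `accuracy` (pooled), `fold_accuracy`.
#' @export
cv_accuracy <- function(X, y, run_ids, folds = 4, params = gbt_params(),
                        seed = 1) {
  fold <- grouped_folds(run_ids, folds, seed)
  correct <- logical(length(y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    model <- fit_gbt(X[tr, , drop = FALSE], y[tr], params)
    pred <- predict_gbt(model, X[te, , drop = FALSE]) > 0
    correct[te] <- pred == (y[te] == 1)
    fold_acc[f] <- mean(pred == (y[te] == 1))
  }
  list(accuracy = mean(correct), fold_accuracy = fold_acc)
}

#' The paired-window gap sweep
#'
#' Starting from the widest placement (first window at the run start, second
#' at the run end) the two windows are moved toward each other by
#' `window$step_s` per sweep step (half a step each), a classifier is trained
#' at every gap with grouped cross-validation, and the sweep stops before the
#' windows begin to overlap.
#'
#' @param recordings list of `ppg_recording`s (all at least `2 x` window
#'   duration long).
#' @param window a [window_spec()].
#' @param folds CV folds (study: 4).
#' @param params a [gbt_params()] (study: depth 2, learning rate 0.01).
#' @param seed governs fold assignment (and nothing else; fitting is
#'   deterministic).
#' @param ... passed to [extract_window_features()] (wavelengths,
#'   `include_freq`, ...).
#' @return object of class `"gap_sweep"`: data.frame `steps` (gap_s,
#'   accuracy), list `models` (one full-data model per gap), `feature_names`,
#'   `datasets` metadata.
#' @export
gap_sweep <- function(recordings, window = window_spec(), folds = 4,
                      params = gbt_params(), seed = 1, ...) {
  if (length(recordings) < 2 * folds)
    stop("need at least ", 2 * folds, " runs for ", folds, "-fold grouped CV")
  D <- min(vapply(recordings, function(r) max(r$data$time_s), 0))
  gaps <- seq(D - window$duration_s, window$duration_s, by = -window$step_s)
  if (!length(gaps)) stop("recordings too short for even one non-overlapping pair")

  # extract each needed window once (left/right starts across all gaps)
  cache <- new.env(parent = emptyenv())
  feats <- function(r, start) {
    key <- paste0(r, "@", round(start, 6))
    if (is.null(cache[[key]]))
      cache[[key]] <- extract_window_features(recordings[[r]], start, window,
                                              ...)
    cache[[key]]
  }
  steps <- data.frame(gap_s = gaps, accuracy = NA_real_)
  models <- vector("list", length(gaps))
  for (gi in seq_along(gaps)) {
    gap <- gaps[gi]
    left <- ((D - window$duration_s) - gap) / 2
    X <- do.call(rbind, unlist(lapply(seq_along(recordings), function(r)
      list(feats(r, left), feats(r, left + gap))), recursive = FALSE))
    y <- rep(c(0L, 1L), length(recordings))
    run <- rep(seq_along(recordings), each = 2)
    steps$accuracy[gi] <- cv_accuracy(X, y, run, folds, params, seed)$accuracy
    full <- fit_gbt(X, y, params)
    full$train_X <- X
    models[[gi]] <- full
  }
  structure(list(steps = steps, models = models,
                 feature_names = colnames(models[[1]]$train_X),
                 window = window, folds = folds, params = params, seed = seed),
            class = "gap_sweep")
}

#' @export
print.gap_sweep <- function(x, ...) {
  cat("<gap_sweep>", nrow(x$steps), "classifiers, gaps",
      max(x$steps$gap_s), "->", min(x$steps$gap_s), "s\n")
  cat("  CV accuracy:", paste(sprintf("%.2f", x$steps$accuracy),
                              collapse = " "), "\n")
  invisible(x)
}

#' Rank features by Shapley importance across the sweep's models
#'
#' Per model, the mean absolute Shapley attribution of every feature over the
#' model's training windows; the `top_k` features by overall mean importance
#' form the rows of the (features x models) table.
#'
#' @param sweep a [gap_sweep()] result.
#' @param top_k number of features to keep (study: 20); clipped with a
#'   warning if larger than the feature count.
#' @return list: `table` (top_k x models importance matrix, rows ordered by
#'   overall importance), `importance` (full features x models matrix).
#' @export
rank_features <- function(sweep, top_k = 20) {
  imp <- vapply(sweep$models, function(m)
    colMeans(abs(shap_values(m, m$train_X))), numeric(length(sweep$feature_names)))
  rownames(imp) <- sweep$feature_names
  colnames(imp) <- paste0("gap_", sweep$steps$gap_s, "s")
  if (top_k > nrow(imp)) {
    warning("top_k clipped to the feature count (", nrow(imp), ")")
    top_k <- nrow(imp)
  }
  ord <- order(rowMeans(imp), decreasing = TRUE)
  list(table = imp[ord[seq_len(top_k)], , drop = FALSE], importance = imp)
}
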