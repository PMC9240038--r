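#' Train an element classifier on per-bin representations
#'
#' Evaluates how well representations identify genomic elements. Two model
#' families are supported: `"boosted_tree"` fits one XGBoost classifier per
#' task (max depth 6, up to `nrounds` trees, early stopping after 20
#' stagnant rounds on an internal validation split), and
#' `"linear_multilabel"` fits a single linear layer with a sigmoid per task
#' (logistic regression on the shared features). Metrics are computed on
#' held-out folds of a seeded k-fold cross-validation and averaged.
#'
#' @param X Numeric matrix, one row per bin (e.g. a model's representation
#'   table without the padding row, or [read_representations()] output).
#' @param labels A `label_set` from [sample_negatives()], a data.frame with
#'   `bin` (0-based) and `label`, or a named list of those (multi-task).
#' @param kind `"boosted_tree"` or `"linear_multilabel"`.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment (default 1).
#' @param nrounds Maximum boosting rounds (default 5000).
#' @return A `metric_report` data.frame with one row per task: `map`,
#'   `auroc`, `accuracy`, `f1` and summed confusion counts, with the
#'   per-fold fitted models in attribute `models`.
#' @export
train_classifier <- function(X, labels, kind = c("boosted_tree", "linear_multilabel"),
                             folds = 5L, seed = 1L, nrounds = 5000L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.data.frame(labels)) labels <- list(task = labels)
  if (is.null(names(labels))) names(labels) <- paste0("task", seq_along(labels))
  for (ls in labels) {
    stopifnot(all(c("bin", "label") %in% names(ls)))
    if (length(unique(ls$label)) < 2)
      stop("labels must contain both classes")
    if (any(ls$bin < 0 | ls$bin >= nrow(X)))
      stop("label bins outside the representation table")
  }

  reports <- list(); models <- list()
  for (task in names(labels)) {
    ls <- labels[[task]]
    y <- as.integer(ls$label)
    Xi <- X[ls$bin + 1L, , drop = FALSE]
    fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(Xi))))
    fold_metrics <- list(); fold_models <- list()
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) next
      if (kind == "boosted_tree") {
        fit <- .fit_xgb(Xi[tr, , drop = FALSE], y[tr], seed, nrounds)
        sc <- predict(fit, xgboost::xgb.DMatrix(Xi[te, , drop = FALSE]))
      } else {
        df <- data.frame(y = y[tr], Xi[tr, , drop = FALSE])
        fit <- suppressWarnings(
          stats::glm(y ~ ., data = df, family = stats::binomial()))
        sc <- suppressWarnings(
          stats::predict(fit, newdata = data.frame(Xi[te, , drop = FALSE]),
                         type = "response"))
      }
      fold_metrics[[f]] <- classification_metrics(y[te], sc)
      fold_models[[f]] <- fit
    }
    if (!length(fold_metrics)) stop("no usable cross-validation fold for task ", task)
    agg <- function(nm) mean(vapply(fold_metrics, `[[`, numeric(1), nm))
    tot <- function(nm) sum(vapply(fold_metrics, `[[`, numeric(1), nm))
    reports[[task]] <- data.frame(
      task = task, map = agg("ap"), auroc = agg("auroc"),
      accuracy = agg("accuracy"), f1 = agg("f1"),
      tp = tot("tp"), fp = tot("fp"), tn = tot("tn"), fn = tot("fn"))
    models[[task]] <- fold_models
  }
  structure(do.call(rbind, c(reports, make.row.names = FALSE)),
            class = c("metric_report", "data.frame"),
            kind = kind, models = models, folds = folds, seed = seed)
}

.fit_xgb <- function(Xtr, ytr, seed, nrounds) {
  # hold out 20% of the training fold for early stopping
  val <- with_seed(seed + 1L, sample(length(ytr), max(2L, floor(0.2 * length(ytr)))))
  has_both <- length(unique(ytr[val])) == 2 && length(unique(ytr[-val])) == 2
  if (!has_both) val <- integer(0)
  dtr <- xgboost::xgb.DMatrix(Xtr[setdiff(seq_along(ytr), val), , drop = FALSE],
                              label = ytr[setdiff(seq_along(ytr), val)])
  evals <- list(train = dtr)
  if (length(val)) {
    dval <- xgboost::xgb.DMatrix(Xtr[val, , drop = FALSE], label = ytr[val])
    evals <- list(validation = dval)
  }
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 6,
                  eval_metric = "logloss", nthread = 1),
    data = dtr, nrounds = nrounds, evals = evals,
    early_stopping_rounds = if (length(val)) 20L else NULL,
    verbose = 0))
}

#' Write a metric report as TSV and JSON
#'
#' @param report A `metric_report` from [train_classifier()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @export
write_metric_report <- function(report, prefix) {
  data.table::fwrite(as.data.frame(report), paste0(prefix, ".tsv"), sep = "\t")
  jsonlite::write_json(as.data.frame(report), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
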