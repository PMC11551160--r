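# Exhaustive hyper-parameter grid search over the full pipeline. The default
# grid mirrors the published tuning experiment: nine learning rates crossed
# with the two hidden activations (18 cells), each scored by mean K-fold CV
# accuracy of encode -> PCA-per-fold -> train -> test.

#' Default hyper-parameter grid
#'
#' Nine learning rates (0.008, 0.009, 0.01, 0.02, ..., 0.07) crossed with the
#' ReLU and tanh hidden activations.
#'
#' @return named list of candidate vectors.
#' @export
default_grid <- function() {
  list(
    learning_rate = c(0.008, 0.009, 0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07),
    hidden_activation = c("relu", "tanh")
  )
}

#' Exhaustive grid search over DNN hyper-parameters
#'
#' Evaluates the full Cartesian product of the candidate values by mean
#' cross-validated accuracy of the complete pipeline and returns the best
#' configuration. Ties are broken towards the lower learning rate, then the
#' first-listed activation. A combination that fails to train is recorded as
#' a failed cell (NA accuracy plus the error message), not a fatal error.
#'
#' @param data a `labeled_dataset`.
#' @param grid named list of candidate vectors over `dnn_config` fields
#'   (default [default_grid()]).
#' @param cv_folds folds for the inner CV. Default 10.
#' @param seed fold-assignment seed. Default 1234.
#' @param encoder_cfg an `encoder_config`.
#' @param base_cfg `dnn_config` supplying every field the grid does not vary.
#' @param use_pca,n_components PCA stage settings as in [run_cv].
#' @return list with `best_config` (a `dnn_config`), `best_accuracy`, and
#'   `results` (data.frame: one row per cell with the varied fields,
#'   `accuracy`, `error`).
#' @export
grid_search <- function(data, grid = default_grid(), cv_folds = 10L,
                        seed = 1234L, encoder_cfg = encoder_config(),
                        base_cfg = dnn_config(), use_pca = TRUE,
                        n_components = 75) {
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)) ||
      any(!nzchar(names(grid)))) {
    stop("grid must be a non-empty named list of candidate vectors",
         call. = FALSE)
  }
  cells <- do.call(expand.grid,
                   c(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  acc <- rep(NA_real_, nrow(cells))
  err <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- tryCatch(
      do.call(dnn_config, utils::modifyList(strip_class(base_cfg),
                                            as.list(cells[i, , drop = FALSE]))),
      error = function(e) e
    )
    if (inherits(cfg, "error")) {
      err[i] <- conditionMessage(cfg)
      next
    }
    cv <- tryCatch(
      run_cv(data, encoder_cfg, use_pca = use_pca,
             n_components = n_components, model_cfg = cfg,
             folds = cv_folds, seed = seed),
      error = function(e) e
    )
    if (inherits(cv, "error")) err[i] <- conditionMessage(cv)
    else acc[i] <- cv$mean$accuracy
  }
  results <- cbind(cells, accuracy = acc, error = err)
  best <- select_best_cell(results)
  best_cfg <- do.call(dnn_config, utils::modifyList(
    strip_class(base_cfg), as.list(results[best, names(grid), drop = FALSE])))
  list(best_config = best_cfg,
       best_accuracy = results$accuracy[best],
       results = results)
}

strip_class <- function(cfg) {
  x <- unclass(cfg)
  x[c("hidden_sizes", "hidden_activation", "dropout_rate", "l2_lambda",
      "learning_rate", "epochs", "batch_size", "seed")]
}

#' Pick the winning grid cell
#'
#' Argmax of `accuracy` with the documented tie-break: among tied cells,
#' prefer the lower learning rate, then the earlier row (first-listed
#' activation). Failed cells (NA accuracy) never win.
#'
#' @param results a grid-search results data.frame with an `accuracy` column
#'   (and optionally `learning_rate`).
#' @return integer row index of the winning cell.
#' @export
select_best_cell <- function(results) {
  ok <- which(!is.na(results$accuracy))
  if (length(ok) == 0L) stop("every grid cell failed", call. = FALSE)
  best <- ok[results$accuracy[ok] == max(results$accuracy[ok])]
  if (length(best) > 1L && "learning_rate" %in% names(results)) {
    best <- best[results$learning_rate[best] == min(results$learning_rate[best])]
  }
  best[1L]
}

#' Reshape grid-search results into a learning-rate x activation table
#'
#' Produces the familiar tuning-table layout: one row per learning rate, one
#' accuracy column per activation.
#'
#' @param results results data.frame from [grid_search] with columns
#'   `learning_rate`, `hidden_activation`, `accuracy`.
#' @return data.frame in wide layout.
#' @export
grid_result_table <- function(results) {
  stopifnot(all(c("learning_rate", "hidden_activation", "accuracy")
                %in% names(results)))
  lrs <- sort(unique(results$learning_rate))
  acts <- unique(results$hidden_activation)
  out <- data.frame(learning_rate = lrs)
  for (a in acts) {
    out[[a]] <- vapply(lrs, function(lr) {
      v <- results$accuracy[results$learning_rate == lr &
                              results$hidden_activation == a]
      if (length(v) == 0L) NA_real_ else v[1L]
    }, numeric(1))
  }
  out
}
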