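# Hybrid feature fusion and PCA-based feature selection. The hybrid vector is
# the ordered concatenation k-mer, RC-k-mer, PseDNC, PseTNC, TAC, TCC, DCC
# (174 columns under the default configuration); PCA reduces it to 75
# components by default, fitted on training rows only.

#' Encode a single sequence as the hybrid feature vector
#'
#' @param seq an [rna_sequence] or residue string.
#' @param cfg an `encoder_config`.
#' @return named numeric vector (174 entries under defaults).
#' @export
encode_hybrid_one <- function(seq, cfg = encoder_config()) {
  c(encode_kmer(seq, cfg$kmer_k),
    encode_rc_kmer(seq, cfg$rc_kmer_k),
    encode_pse_dnc(seq),
    encode_pse_tnc(seq),
    encode_tac(seq, cfg),
    encode_tcc(seq, cfg),
    encode_dcc(seq, cfg))
}

#' Encode a dataset as a hybrid feature matrix
#'
#' Applies all seven encoders to every sequence and concatenates the blocks in
#' the fixed order k-mer, RC-k-mer, PseDNC, PseTNC, TAC, TCC, DCC. Any
#' per-sequence encoder failure is re-signalled with the sequence id attached.
#'
#' @param data a `labeled_dataset`, or a list of [rna_sequence].
#' @param cfg an `encoder_config`.
#' @param only optional name of a single encoder
#'   (`"kmer"`, `"rc_kmer"`, `"pse_dnc"`, `"pse_tnc"`, `"tac"`, `"tcc"`,
#'   `"dcc"`) for ablation runs; `NULL` (default) builds the full hybrid.
#' @return a `feature_matrix`: list with `ids`, `feature_names` and the
#'   numeric matrix `values` (rows = sequences).
#' @export
encode_hybrid <- function(data, cfg = encoder_config(), only = NULL) {
  if (inherits(data, "labeled_dataset")) {
    ids <- data$ids
    residues <- data$residues
  } else {
    ids <- vapply(data, `[[`, character(1), "id")
    residues <- vapply(data, `[[`, character(1), "residues")
  }
  enc <- if (is.null(only)) {
    function(res) encode_hybrid_one(res, cfg)
  } else {
    single_encoder(only, cfg)
  }
  rows <- lapply(seq_along(ids), function(i) {
    tryCatch(enc(residues[[i]]), error = function(e) {
      stop(sprintf("sequence '%s': %s", ids[[i]], conditionMessage(e)),
           call. = FALSE)
    })
  })
  nms <- names(rows[[1]])
  values <- do.call(rbind, lapply(rows, unname))
  colnames(values) <- nms
  rownames(values) <- NULL
  feature_matrix(ids, nms, values)
}

single_encoder <- function(name, cfg) {
  switch(name,
    kmer = function(res) encode_kmer(res, cfg$kmer_k),
    rc_kmer = function(res) encode_rc_kmer(res, cfg$rc_kmer_k),
    pse_dnc = encode_pse_dnc,
    pse_tnc = encode_pse_tnc,
    tac = function(res) encode_tac(res, cfg),
    tcc = function(res) encode_tcc(res, cfg),
    dcc = function(res) encode_dcc(res, cfg),
    stop(sprintf("unknown encoder '%s'", name), call. = FALSE)
  )
}

#' Feature matrix container
#'
#' @param ids ordered sequence identifiers.
#' @param feature_names ordered feature labels.
#' @param values numeric matrix, rows aligned to `ids`, columns to
#'   `feature_names`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(ids, feature_names, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(ids),
            ncol(values) == length(feature_names),
            all(is.finite(values)))
  dimnames(values) <- list(NULL, as.character(feature_names))
  structure(list(ids = as.character(ids),
                 feature_names = as.character(feature_names),
                 values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sequences x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

subset_matrix <- function(fm, idx) {
  feature_matrix(fm$ids[idx], fm$feature_names, fm$values[idx, , drop = FALSE])
}

#' Write / read a feature matrix as CSV
#'
#' First column `id`, then one column per feature, header row included.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path` invisibly (writer); a `feature_matrix` (reader).
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(id = fm$ids, fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_matrix(df[[1]], colnames(df)[-1],
                 as.matrix(df[, -1, drop = FALSE]))
}

#' Fit PCA on a training feature matrix
#'
#' Centred (by default unscaled) principal component analysis of the training
#' rows, with a deterministic sign convention: the largest-magnitude loading
#' of every component is positive, so serialized models are comparable across
#' runs. Fit PCA on training data only; inside cross-validation it must be
#' refitted per fold (see [run_cv]).
#'
#' @param train a `feature_matrix` of training rows.
#' @param n_components number of components to retain (default 75), or a
#'   fraction in (0, 1) interpreted as the minimum proportion of variance to
#'   retain.
#' @param standardize also scale columns to unit variance before PCA
#'   (correlation PCA). Default `FALSE` (covariance PCA).
#' @return object of class `pca_model` with `mean`, `scale`, `components`
#'   (n_components x n_features, orthonormal rows), `explained_variance`,
#'   `n_components`, `feature_names`.
#' @export
fit_pca <- function(train, n_components = 75, standardize = FALSE) {
  stopifnot(inherits(train, "feature_matrix"))
  x <- train$values
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows", call. = FALSE)
  max_nc <- min(nrow(x) - 1L, ncol(x))
  sds <- NULL
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = if (standardize) sds else FALSE)
  var_all <- pr$sdev^2
  if (n_components > 0 && n_components < 1) {
    cum <- cumsum(var_all) / sum(var_all)
    n_components <- which(cum >= n_components)[1]
  }
  n_components <- as.integer(n_components)
  if (n_components > max_nc) {
    stop(sprintf("n_components = %d exceeds min(rows - 1, features) = %d",
                 n_components, max_nc), call. = FALSE)
  }
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(
    mean = stats::setNames(pr$center, train$feature_names),
    scale = if (standardize) stats::setNames(sds, train$feature_names) else NULL,
    components = t(rot),
    explained_variance = var_all[seq_len(n_components)],
    n_components = n_components,
    feature_names = train$feature_names
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features (%.1f%% variance)\n",
              x$n_components, length(x$feature_names),
              100 * sum(x$explained_variance) /
                max(sum(x$explained_variance), .Machine$double.eps)))
  invisible(x)
}

#' Project a feature matrix onto a fitted PCA basis
#'
#' @param model a `pca_model`.
#' @param m a `feature_matrix` with exactly the feature names the model was
#'   fitted on (order-insensitive; columns are realigned).
#' @return a `feature_matrix` with columns `pc1..pcN`.
#' @export
transform_pca <- function(model, m) {
  stopifnot(inherits(model, "pca_model"), inherits(m, "feature_matrix"))
  if (!setequal(model$feature_names, m$feature_names)) {
    extra <- setdiff(m$feature_names, model$feature_names)
    missing <- setdiff(model$feature_names, m$feature_names)
    stop(sprintf(
      "feature-name mismatch: missing [%s]; unexpected [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  x <- m$values[, model$feature_names, drop = FALSE]
  x <- sweep(x, 2L, model$mean)
  if (!is.null(model$scale)) x <- sweep(x, 2L, model$scale, "/")
  scores <- x %*% t(model$components)
  feature_matrix(m$ids, paste0("pc", seq_len(model$n_components)), scores)
}

#' Reconstruct features from PCA scores
#'
#' Inverse projection used for reconstruction-error diagnostics.
#'
#' @param model a `pca_model`.
#' @param scores a `feature_matrix` of component scores from [transform_pca].
#' @return a `feature_matrix` in the original feature space.
#' @export
inverse_pca <- function(model, scores) {
  x <- scores$values %*% model$components
  if (!is.null(model$scale)) x <- sweep(x, 2L, model$scale, "*")
  x <- sweep(x, 2L, model$mean, "+")
  feature_matrix(scores$ids, model$feature_names, x)
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model a `pca_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `pca_model` (reader).
#' @export
write_pca_model <- function(model, path) {
  obj <- list(
    mean = unname(model$mean),
    scale = if (is.null(model$scale)) NULL else unname(model$scale),
    components = model$components,
    explained_variance = model$explained_variance,
    n_components = model$n_components,
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean = stats::setNames(obj$mean, obj$feature_names),
    scale = if (length(obj$scale) == 0L) NULL
            else stats::setNames(obj$scale, obj$feature_names),
    components = matrix(obj$components, nrow = obj$n_components),
    explained_variance = obj$explained_variance,
    n_components = obj$n_components,
    feature_names = obj$feature_names
  ), class = "pca_model")
}
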