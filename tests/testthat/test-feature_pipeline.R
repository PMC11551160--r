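test_that("hybrid matrix concatenates the seven blocks in order", {
  d <- small_signal_data(n_per_class = 5)
  fm <- encode_hybrid(d)
  expect_equal(dim(fm), c(10L, 174L))
  expect_equal(fm$ids, d$ids)
  prefixes <- sub(":.*$", "", fm$feature_names)
  expect_equal(rle(prefixes)$values,
               c("kmer", "rckmer", "psednc", "psetnc", "tac", "tcc", "dcc"))
  # column blocks equal the standalone encoder outputs
  cfg <- encoder_config()
  i <- 3
  expect_equal(fm$values[i, 1:16], encode_kmer(d$residues[i], 2))
  expect_equal(fm$values[i, 111:114], encode_tcc(d$residues[i], cfg))
  expect_equal(fm$values[i, 115:174], encode_dcc(d$residues[i], cfg))
})

test_that("a 41-nt homopolymer gives pure AA composition and zero covariance", {
  seqs <- list(rna_sequence("h", strrep("A", 41)))
  fm <- encode_hybrid(seqs)
  expect_equal(unname(fm$values[1, "kmer:AA"]), 1)
  cov_cols <- grepl("^(tac|tcc|dcc):", fm$feature_names)
  expect_true(all(fm$values[1, cov_cols] == 0))
})

test_that("encoder failures propagate with the sequence id attached", {
  seqs <- list(rna_sequence("ok", random_rna(41)),
               rna_sequence("shorty", "ACGU"))
  expect_error(encode_hybrid(seqs), "shorty")
})

test_that("feature CSV round-trips ids, names and values", {
  d <- small_signal_data(n_per_class = 4)
  fm <- encode_hybrid(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back$ids, fm$ids)
  expect_equal(back$feature_names, fm$feature_names)
  expect_equal(back$values, fm$values, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA isolates a single varying column in the rank-1 case", {
  set.seed(71)
  x <- matrix(1, 20, 6)
  x[, 4] <- rnorm(20, sd = 3)
  fm <- feature_matrix(paste0("r", 1:20), paste0("f", 1:6), x)
  model <- fit_pca(fm, 2)
  expect_gt(abs(model$components[1, 4]), 0.999)
  expect_lt(model$explained_variance[2] / model$explained_variance[1], 1e-12)
})

test_that("PCA components are orthonormal with non-increasing variance", {
  set.seed(72)
  d <- small_signal_data(n_per_class = 25)
  fm <- encode_hybrid(d)
  model <- fit_pca(fm, 30)
  gram <- model$components %*% t(model$components)
  expect_equal(gram, diag(30), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(model$explained_variance) <= 1e-12))
  # deterministic sign convention: the dominant loading is positive
  peaks <- apply(model$components, 1, function(r) r[which.max(abs(r))])
  expect_true(all(peaks > 0))
  # refitting gives bit-identical components
  expect_identical(model$components, fit_pca(fm, 30)$components)
  expect_error(fit_pca(fm, 174), "exceeds")
})

test_that("transforming the training matrix reproduces explained variance", {
  d <- small_signal_data(n_per_class = 20)
  fm <- encode_hybrid(d)
  model <- fit_pca(fm, 10)
  scores <- transform_pca(model, fm)
  expect_equal(scores$feature_names, paste0("pc", 1:10))
  pervar <- apply(scores$values, 2, function(v) sum((v - mean(v))^2) /
                    (length(v) - 1))
  expect_equal(pervar, model$explained_variance, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("transform rejects mismatched schemas and maps equal rows together", {
  d <- small_signal_data(n_per_class = 10)
  fm <- encode_hybrid(d)
  model <- fit_pca(fm, 5)
  bad <- feature_matrix(fm$ids, c(fm$feature_names[-1], "rogue"), fm$values)
  expect_error(transform_pca(model, bad), "rogue")
  dup <- feature_matrix(c("a", "b"), fm$feature_names,
                        fm$values[c(1, 1), , drop = FALSE])
  sc <- transform_pca(model, dup)
  expect_equal(sc$values[1, ], sc$values[2, ])
})

test_that("reconstruction error is non-increasing in component count", {
  d <- small_signal_data(n_per_class = 40)
  fm <- encode_hybrid(d)
  errs <- vapply(c(5, 15, 30, 50, 75), function(nc) {
    model <- fit_pca(fm, nc)
    rec <- inverse_pca(model, transform_pca(model, fm))
    sqrt(mean((rec$values - fm$values)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("variance-retention fractions and standardize mode are honoured", {
  d <- small_signal_data(n_per_class = 15)
  fm <- encode_hybrid(d)
  m_frac <- fit_pca(fm, 0.9)
  cum <- cumsum(m_frac$explained_variance)
  full <- fit_pca(fm, min(nrow(fm$values) - 1, 174))
  expect_gte(cum[m_frac$n_components] / sum(full$explained_variance), 0.9)
  m_std <- fit_pca(fm, 5, standardize = TRUE)
  expect_false(isTRUE(all.equal(m_std$components, fit_pca(fm, 5)$components)))
})

test_that("PCA models serialize losslessly to JSON", {
  d <- small_signal_data(n_per_class = 10)
  fm <- encode_hybrid(d)
  model <- fit_pca(fm, 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_equal(back$components, model$components, ignore_attr = TRUE)
  expect_equal(unname(back$mean), unname(model$mean))
  expect_equal(transform_pca(back, fm)$values, transform_pca(model, fm)$values,
               ignore_attr = TRUE)
})

test_that("cross-validation fits PCA inside each fold, not on pooled data", {
  d <- small_signal_data(n_per_class = 15)
  cv <- suppressWarnings(run_cv(d, use_pca = TRUE, n_components = 5,
               model_cfg = fast_dnn(epochs = 3), folds = 3, seed = 2))
  expect_length(cv$pca_models, 3)
  expect_false(isTRUE(all.equal(cv$pca_models[[1]]$components,
                                cv$pca_models[[2]]$components)))
  pooled <- suppressWarnings(run_cv(d, use_pca = TRUE, n_components = 5,
                   model_cfg = fast_dnn(epochs = 3), folds = 3, seed = 2,
                   pca_pooled = TRUE))
  expect_identical(pooled$pca_models[[1]]$components,
                   pooled$pca_models[[2]]$components)
})
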