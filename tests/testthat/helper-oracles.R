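# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately written as naive loops, independent of the
# vectorised implementation paths they check.

# Mean-centred lagged covariance by explicit double loop over positions.
oracle_lagged_cov <- function(residues, table, u1, u2, lag) {
  g <- table$granularity
  n <- nchar(residues) - g + 1L
  p1 <- numeric(n)
  p2 <- numeric(n)
  for (i in seq_len(n)) {
    w <- substr(residues, i, i + g - 1L)
    p1[i] <- table$values[w, u1]
    p2[i] <- table$values[w, u2]
  }
  m1 <- sum(p1) / n
  m2 <- sum(p2) / n
  s <- 0
  for (i in seq_len(n - lag)) {
    s <- s + (p1[i] - m1) * (p2[i + lag] - m2)
  }
  s / (n - lag)
}

# Mann-Whitney pair-counting AUC with ties counted one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Direct arithmetic on a confusion table (the published metric definitions).
oracle_metrics <- function(tp, tn, fp, fn) {
  list(
    acc = (tp + tn) / (tp + fp + fn + tn) * 100,
    sn = tp / (tp + fn) * 100,
    sp = tn / (tn + fp) * 100,
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    recall = tp / (tp + fn)
  )
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Reduced-size network for tests that exercise wiring rather than the
# full training budget.
fast_dnn <- function(epochs = 40L, seed = 1L, ...) {
  dnn_config(hidden_sizes = c(16L, 8L), epochs = epochs, seed = seed, ...)
}

# Small planted-signal dataset for pipeline wiring tests.
small_signal_data <- function(n_per_class = 50L, seed = 7L,
                              motif_prob = 1, shift = 0.1) {
  generate(synthetic_spec(n_pos = n_per_class, n_neg = n_per_class,
                          motif_prob = motif_prob,
                          composition_shift = shift, seed = seed))
}

# Linearly separable two-feature fixture: classes sit in disjoint slabs
# along f1 (margin 0.2), f2 is a distractor.
separable_fixture <- function(n = 200L, seed = 42L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = 2 * y + runif(n, -0.9, 0.9), f2 = rnorm(n))
  list(x = x, y = y)
}
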