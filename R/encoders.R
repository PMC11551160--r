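# The seven sequence-encoding schemes that feed the hybrid feature vector:
# k-mer composition, reverse-complement (canonical) k-mer composition, pseudo
# di-/tri-nucleotide composition, and the three covariance descriptors (TAC,
# TCC, DCC) over physicochemical property profiles. All encoders are pure
# functions with fixed, documented feature-name order.

#' Encoder configuration
#'
#' Holds every tunable of the seven encoders. The defaults reproduce the
#' published per-method dimensions exactly: k-mer 16, RC-k-mer 10, PseDNC 16,
#' PseTNC 64, TAC 4 (2 tri-properties x lag 2), TCC 4 (2 ordered property
#' pairs x lag 2), DCC 60 (30 ordered property pairs x lag 2), 174 in total.
#'
#' @param kmer_k k for the k-mer encoder. Default 2.
#' @param rc_kmer_k k for the canonical reverse-complement k-mer encoder.
#'   Default 2.
#' @param cov_lag maximum lag for the covariance encoders. Default 2.
#' @param di_properties dinucleotide `property_table`
#'   (default [default_di_properties()], 6 properties).
#' @param tri_properties trinucleotide `property_table`
#'   (default [default_tri_properties()], 2 properties).
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(kmer_k = 2L, rc_kmer_k = 2L, cov_lag = 2L,
                           di_properties = default_di_properties(),
                           tri_properties = default_tri_properties()) {
  stopifnot(kmer_k >= 1L, rc_kmer_k >= 1L, cov_lag >= 1L,
            inherits(di_properties, "property_table"),
            di_properties$granularity == 2L,
            inherits(tri_properties, "property_table"),
            tri_properties$granularity == 3L)
  structure(list(
    kmer_k = as.integer(kmer_k),
    rc_kmer_k = as.integer(rc_kmer_k),
    cov_lag = as.integer(cov_lag),
    di_properties = di_properties,
    tri_properties = tri_properties
  ), class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  d <- encoder_dimensions(x)
  cat(sprintf("<encoder_config> kmer_k=%d rc_kmer_k=%d lag=%d | dims: %s (total %d)\n",
              x$kmer_k, x$rc_kmer_k, x$cov_lag,
              paste(sprintf("%s=%d", names(d), d), collapse = " "), sum(d)))
  invisible(x)
}

#' Per-encoder output dimensions
#'
#' @param cfg an `encoder_config`.
#' @return named integer vector of the seven encoder dimensions, in hybrid
#'   concatenation order.
#' @export
encoder_dimensions <- function(cfg = encoder_config()) {
  n_di <- length(cfg$di_properties$property_names)
  n_tri <- length(cfg$tri_properties$property_names)
  c(kmer = 4L^cfg$kmer_k,
    rc_kmer = length(canonical_rc_kmers(cfg$rc_kmer_k)),
    pse_dnc = 16L,
    pse_tnc = 64L,
    tac = n_tri * cfg$cov_lag,
    tcc = n_tri * (n_tri - 1L) * cfg$cov_lag,
    dcc = n_di * (n_di - 1L) * cfg$cov_lag)
}

#' Minimum sequence length an encoder configuration can consume
#'
#' Trinucleotide covariance at lag L needs at least 3 + L residues.
#'
#' @param cfg an `encoder_config`.
#' @return integer minimum length.
#' @export
min_sequence_length <- function(cfg = encoder_config()) {
  max(3L + cfg$cov_lag, 2L + cfg$cov_lag, cfg$kmer_k, cfg$rc_kmer_k, 3L)
}

feature_vector <- function(names, values) {
  stopifnot(length(names) == length(values), !anyDuplicated(names),
            all(is.finite(values)))
  stats::setNames(as.numeric(values), names)
}

#' K-mer composition
#'
#' Sliding-window frequency of every length-k word over \{A,C,G,U\}, in
#' lexicographic word order: `count(word) / (L - k + 1)`. The vector is
#' non-negative and sums to 1.
#'
#' @param seq an [rna_sequence] or residue string.
#' @param k word length (default 2, giving 16 features).
#' @return named numeric vector of length `4^k`.
#' @export
encode_kmer <- function(seq, k = 2L) {
  res <- residues_of(seq)
  if (nchar(res) < k) {
    stop(sprintf("sequence of length %d is shorter than k = %d", nchar(res), k),
         call. = FALSE)
  }
  words <- all_kmers(k)
  counts <- table(factor(sliding_words(res, k), levels = words))
  feature_vector(paste0("kmer:", words),
                 as.numeric(counts) / (nchar(res) - k + 1L))
}

#' Reverse complement of an RNA sequence
#'
#' Reverses the residue order and complements each base (A<->U, C<->G).
#' An involution: applying it twice returns the input.
#'
#' @param seq an [rna_sequence] or residue string.
#' @return same type as the input (`rna_sequence` in, `rna_sequence` out).
#' @export
reverse_complement <- function(seq) {
  res <- residues_of(seq)
  rc <- chartr("ACGU", "UGCA",
               paste(rev(strsplit(res, "", fixed = TRUE)[[1]]), collapse = ""))
  if (inherits(seq, "rna_sequence")) rna_sequence(seq$id, rc) else rc
}

#' Canonical reverse-complement k-mer classes
#'
#' Merges every k-word with its reverse complement and returns the sorted
#' canonical representatives (the lexicographically smaller member of each
#' pair). For k = 2 this yields the 10 canonical dinucleotide classes.
#'
#' @param k word length.
#' @return character vector of canonical k-words, sorted.
#' @export
canonical_rc_kmers <- function(k) {
  stopifnot(k >= 1L)
  words <- all_kmers(k)
  canon <- vapply(words, function(w) min(w, reverse_complement(w)), character(1))
  sort(unique(unname(canon)))
}

#' Canonical reverse-complement k-mer composition
#'
#' Strand-agnostic k-mer composition: each window is counted for the canonical
#' class of its word, so the encoding is invariant under reverse
#' complementation of the whole sequence. One feature per canonical class,
#' summing to 1.
#'
#' @inheritParams encode_kmer
#' @return named numeric vector, one entry per canonical class (10 for k = 2).
#' @export
encode_rc_kmer <- function(seq, k = 2L) {
  res <- residues_of(seq)
  if (nchar(res) < k) {
    stop(sprintf("sequence of length %d is shorter than k = %d", nchar(res), k),
         call. = FALSE)
  }
  classes <- canonical_rc_kmers(k)
  obs <- sliding_words(res, k)
  canon <- vapply(obs, function(w) min(w, reverse_complement(w)), character(1))
  counts <- table(factor(canon, levels = classes))
  feature_vector(paste0("rckmer:", classes),
                 as.numeric(counts) / (nchar(res) - k + 1L))
}

#' Pseudo dinucleotide composition (composition tier)
#'
#' The 16 dinucleotide composition features. In this toolkit the pseudo
#' composition is the pure composition tier (no lambda correlation terms), so
#' the output is numerically identical to `encode_kmer(seq, 2)` apart from the
#' feature-name namespace.
#'
#' @inheritParams encode_kmer
#' @return named numeric vector of length 16.
#' @export
encode_pse_dnc <- function(seq) {
  v <- encode_kmer(seq, 2L)
  stats::setNames(unname(v), sub("^kmer:", "psednc:", names(v)))
}

#' Pseudo trinucleotide composition (composition tier)
#'
#' The 64 trinucleotide composition features; identical to
#' `encode_kmer(seq, 3)` apart from the feature-name namespace.
#'
#' @inheritParams encode_kmer
#' @return named numeric vector of length 64.
#' @export
encode_pse_tnc <- function(seq) {
  v <- encode_kmer(seq, 3L)
  stats::setNames(unname(v), sub("^kmer:", "psetnc:", names(v)))
}

# Mean-centred lagged covariance between two property profiles:
# (1/(N - l)) * sum_{i=1}^{N-l} (p1[i] - mean(p1)) (p2[i+l] - mean(p2)),
# where N is the common profile length. Auto-covariance is p1 == p2.
lagged_covariance <- function(p1, p2, lag) {
  n <- length(p1)
  stopifnot(length(p2) == n, lag >= 1L, n - lag >= 1L)
  c1 <- p1 - mean(p1)
  c2 <- p2 - mean(p2)
  i <- seq_len(n - lag)
  sum(c1[i] * c2[i + lag]) / (n - lag)
}

check_cov_length <- function(res, g, lag, what) {
  need <- g + lag
  if (nchar(res) < need) {
    stop(sprintf("%s with lag %d requires at least %d residues (got %d)",
                 what, lag, need, nchar(res)), call. = FALSE)
  }
}

#' Trinucleotide auto-covariance (TAC)
#'
#' For every trinucleotide property u and every lag l in 1..`cov_lag`, the
#' mean-centred auto-covariance of the property profile of the sequence at
#' lag l. Vanishes on homopolymers (constant profile). Default dimension
#' 2 properties x 2 lags = 4.
#'
#' @param seq an [rna_sequence] or residue string.
#' @param cfg an `encoder_config`.
#' @return named numeric vector of length `n_tri_properties * cov_lag`.
#' @export
encode_tac <- function(seq, cfg = encoder_config()) {
  res <- residues_of(seq)
  check_cov_length(res, 3L, cfg$cov_lag, "trinucleotide auto-covariance")
  props <- cfg$tri_properties$property_names
  out <- numeric(0)
  nms <- character(0)
  for (u in props) {
    p <- property_profile(res, cfg$tri_properties, u)
    for (l in seq_len(cfg$cov_lag)) {
      out <- c(out, lagged_covariance(p, p, l))
      nms <- c(nms, sprintf("tac:%s@lag%d", u, l))
    }
  }
  feature_vector(nms, out)
}

#' Trinucleotide cross-covariance (TCC)
#'
#' For every ordered pair of distinct trinucleotide properties (u1, u2) and
#' every lag l, the mean-centred cross-covariance of their profiles. Default
#' dimension 2 x 1 x 2 = 4.
#'
#' @inheritParams encode_tac
#' @return named numeric vector.
#' @export
encode_tcc <- function(seq, cfg = encoder_config()) {
  res <- residues_of(seq)
  check_cov_length(res, 3L, cfg$cov_lag, "trinucleotide cross-covariance")
  cross_covariance_block(res, cfg$tri_properties, cfg$cov_lag, "tcc")
}

#' Dinucleotide cross-covariance (DCC)
#'
#' Cross-covariance over dinucleotide property profiles, for every ordered
#' pair of distinct dinucleotide properties and every lag. Default dimension
#' 6 x 5 x 2 = 60.
#'
#' @inheritParams encode_tac
#' @return named numeric vector.
#' @export
encode_dcc <- function(seq, cfg = encoder_config()) {
  res <- residues_of(seq)
  check_cov_length(res, 2L, cfg$cov_lag, "dinucleotide cross-covariance")
  cross_covariance_block(res, cfg$di_properties, cfg$cov_lag, "dcc")
}

cross_covariance_block <- function(res, table, cov_lag, prefix) {
  props <- table$property_names
  if (length(props) < 2L) {
    stop("cross-covariance requires at least 2 properties", call. = FALSE)
  }
  profiles <- lapply(props, function(u) property_profile(res, table, u))
  names(profiles) <- props
  out <- numeric(0)
  nms <- character(0)
  for (u1 in props) for (u2 in props) {
    if (u1 == u2) next
    for (l in seq_len(cov_lag)) {
      out <- c(out, lagged_covariance(profiles[[u1]], profiles[[u2]], l))
      nms <- c(nms, sprintf("%s:%s~%s@lag%d", prefix, u1, u2, l))
    }
  }
  feature_vector(nms, out)
}
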