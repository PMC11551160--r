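RNA_ALPHABET <- c("A", "C", "G", "U")

#' Validated RNA sequence
#'
#' Constructs a single validated RNA sequence: an identifier plus a residue
#' string over the alphabet A/C/G/U. Input is normalised before validation:
#' lower-case letters are upper-cased and the DNA letter T is mapped to U, so
#' DNA-alphabet FASTA files (common for public modification-site data) are
#' accepted without changing any downstream arithmetic.
#'
#' @param id single character identifier.
#' @param residues single character string of residues.
#' @return An object of class `rna_sequence`: a list with elements `id` and
#'   `residues` (normalised).
#' @examples
#' rna_sequence("s1", "acgt")$residues  # "ACGU"
#' @export
rna_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  res <- normalize_residues(residues, id = id)
  structure(list(id = id, residues = res), class = "rna_sequence")
}

# Case-fold, map T->U, and reject anything outside {A,C,G,U}. Ambiguity codes
# (N etc.) are rejected rather than skipped: every encoder assumes a complete
# profile and silent skipping would distort the composition statistics.
normalize_residues <- function(residues, id = "<sequence>") {
  res <- chartr("t", "u", toupper(residues))
  res <- chartr("T", "U", res)
  if (!nzchar(res)) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(res, "", fixed = TRUE)[[1]]), RNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s': invalid residue(s) %s (alphabet is A/C/G/U, with T accepted as U)",
      id, paste(sprintf("'%s'", bad), collapse = ", ")
    ), call. = FALSE)
  }
  res
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Labeled RNA dataset
#'
#' A set of RNA sequences with aligned binary 5hmC labels (1 = modified /
#' positive, 0 = unmodified / negative).
#'
#' @param sequences list of [rna_sequence] objects.
#' @param labels integer/numeric vector of 0/1, one per sequence.
#' @return An object of class `labeled_dataset` with elements `ids`,
#'   `residues` (character vectors) and `labels` (integer vector).
#' @export
labeled_dataset <- function(sequences, labels) {
  stopifnot(is.list(sequences))
  labels <- as.integer(labels)
  if (length(labels) != length(sequences)) {
    stop("labels length must equal number of sequences", call. = FALSE)
  }
  if (length(sequences) == 0L) stop("dataset is empty", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  ids <- vapply(sequences, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(
    ids = ids,
    residues = vapply(sequences, `[[`, character(1), "residues"),
    labels = labels
  ), class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$ids)

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- class_counts(x)
  cat(sprintf("<labeled_dataset> %d sequences (%d positive, %d negative)\n",
              length(x), n[["pos"]], n[["neg"]]))
  invisible(x)
}

#' Class counts of a labeled dataset
#'
#' @param data a `labeled_dataset`.
#' @return named integer vector with elements `pos` and `neg`.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  c(pos = sum(data$labels == 1L), neg = sum(data$labels == 0L))
}

# Subset a labeled_dataset by integer indices, preserving order.
subset_dataset <- function(data, idx) {
  structure(list(
    ids = data$ids[idx],
    residues = data$residues[idx],
    labels = data$labels[idx]
  ), class = "labeled_dataset")
}

#' Read RNA sequences from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file, normalises residues
#' (case fold, T mapped to U) and validates the alphabet. Record identifiers
#' are taken from the header up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return list of [rna_sequence], in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  res <- as.character(set)
  lapply(seq_along(set), function(i) rna_sequence(ids[[i]], res[[i]]))
}

#' Write RNA sequences to a FASTA file
#'
#' Companion writer for [read_fasta]; `read_fasta(write_fasta(x, path))`
#' reproduces `x`.
#'
#' @param sequences list of [rna_sequence], or a `labeled_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "labeled_dataset")) {
    set <- Biostrings::BStringSet(stats::setNames(sequences$residues, sequences$ids))
  } else {
    set <- Biostrings::BStringSet(stats::setNames(
      vapply(sequences, `[[`, character(1), "residues"),
      vapply(sequences, `[[`, character(1), "id")
    ))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a labeled dataset from positive/negative FASTA files
#'
#' Builds the benchmark-style dataset H = H+ u H-: records from `pos_path`
#' are labeled 1 (5hmC-modified) and records from `neg_path` 0, positives
#' first. Identifiers must be disjoint across the two files.
#'
#' @param pos_path FASTA of positive (5hmC) sequences.
#' @param neg_path FASTA of negative sequences.
#' @return a `labeled_dataset`.
#' @export
load_labeled <- function(pos_path, neg_path) {
  pos <- read_fasta(pos_path)
  neg <- read_fasta(neg_path)
  pid <- vapply(pos, `[[`, character(1), "id")
  nid <- vapply(neg, `[[`, character(1), "id")
  both <- intersect(pid, nid)
  if (length(both) > 0L) {
    stop(sprintf("id(s) present in both positive and negative files: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  labeled_dataset(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Load a labeled dataset from one FASTA plus a TSV label sidecar
#'
#' Alternative labeling route: a two-column tab-separated file (id, label in
#' \{0,1\}) assigns a label to every record of a single FASTA file.
#'
#' @param fasta_path FASTA file with all sequences.
#' @param tsv_path two-column TSV (no header): id, label.
#' @return a `labeled_dataset`.
#' @export
load_labeled_tsv <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path)
  tab <- utils::read.table(tsv_path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  ids <- vapply(seqs, `[[`, character(1), "id")
  missing <- setdiff(ids, tab$id)
  if (length(missing) > 0L) {
    stop(sprintf("no label for id(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  labeled_dataset(seqs, tab$label[match(ids, tab$id)])
}

#' Stratified train / independent split
#'
#' Holds out `round(fraction * n_class)` sequences per class (seeded,
#' stratified), mirroring the usual 10% independent-set protocol: with a
#' balanced 662/662 dataset and `fraction = 0.1` the independent set has
#' 132 sequences.
#'
#' @param data a `labeled_dataset` containing both classes.
#' @param fraction proportion held out, in (0, 1). Default 0.1.
#' @param seed integer seed. Default 1234.
#' @return An object of class `dataset_split`: list with `train` and
#'   `independent` (`labeled_dataset`s), `fraction`, `seed`.
#' @export
make_split <- function(data, fraction = 0.1, seed = 1234L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes must be present", call. = FALSE)
  held <- integer(0)
  with_local_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- which(data$labels == cls)
      k <- round(fraction * length(idx))
      held <- c(held, sample(idx, k))
    }
  })
  held <- sort(held)
  keep <- setdiff(seq_along(data$ids), held)
  structure(list(
    train = subset_dataset(data, keep),
    independent = subset_dataset(data, held),
    fraction = fraction,
    seed = as.integer(seed)
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / independent %d (fraction %.3g, seed %d)\n",
              length(x$train), length(x$independent), x$fraction, x$seed))
  invisible(x)
}

#' Write / read a JSON split manifest
#'
#' Records where a split's FASTA files live together with the fraction, seed
#' and whether the input had been deduplicated upstream (e.g. by CD-HIT),
#' so a run is reproducible from its manifest.
#'
#' @param split a `dataset_split`.
#' @param dir output directory (created if needed).
#' @param deduplicated logical flag recorded verbatim in the manifest.
#' @return path of the manifest JSON, invisibly.
#' @export
write_split_manifest <- function(split, dir, deduplicated = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    train_pos = file.path(dir, "train_pos.fasta"),
    train_neg = file.path(dir, "train_neg.fasta"),
    independent_pos = file.path(dir, "independent_pos.fasta"),
    independent_neg = file.path(dir, "independent_neg.fasta")
  )
  write_fasta(subset_dataset(split$train, which(split$train$labels == 1L)),
              paths$train_pos)
  write_fasta(subset_dataset(split$train, which(split$train$labels == 0L)),
              paths$train_neg)
  write_fasta(subset_dataset(split$independent, which(split$independent$labels == 1L)),
              paths$independent_pos)
  write_fasta(subset_dataset(split$independent, which(split$independent$labels == 0L)),
              paths$independent_neg)
  manifest <- list(
    files = lapply(paths, basename),
    fraction = split$fraction,
    seed = split$seed,
    deduplicated = deduplicated,
    tool_version = as.character(utils::packageVersion("hmcpred"))
  )
  mpath <- file.path(dir, "split_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_split_manifest
#' @param path path to a manifest JSON written by [write_split_manifest].
#' @export
read_split_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  list(
    train = load_labeled(file.path(dir, m$files$train_pos),
                         file.path(dir, m$files$train_neg)),
    independent = load_labeled(file.path(dir, m$files$independent_pos),
                               file.path(dir, m$files$independent_neg)),
    fraction = m$fraction,
    seed = m$seed,
    deduplicated = m$deduplicated
  )
}

# Run `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so library calls never perturb user code.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
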