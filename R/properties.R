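# Physicochemical property tables used by the covariance encoders (TAC, TCC,
# DCC). A property table maps every k-word of one granularity (16
# dinucleotides or 64 trinucleotides) to a real value per named property.
# Tables are standardized (zero mean, unit variance over the k-words) before
# any profile is computed, as is conventional for auto/cross-covariance
# nucleotide descriptors.

all_kmers <- function(k) {
  stopifnot(k >= 1)
  words <- do.call(expand.grid,
                   c(rep(list(RNA_ALPHABET), k), stringsAsFactors = FALSE))
  sort(apply(as.matrix(words), 1L, paste0, collapse = ""))
}

#' Construct a physicochemical property table
#'
#' @param values numeric matrix: rows = k-words (rownames required, complete
#'   for the granularity), columns = named properties.
#' @param granularity 2 (dinucleotide) or 3 (trinucleotide).
#' @param standardize standardize each property to zero mean and unit
#'   variance over the k-words (population variance). Default `TRUE`.
#' @return object of class `property_table`.
#' @export
property_table <- function(values, granularity, standardize = TRUE) {
  stopifnot(is.matrix(values), granularity %in% c(2L, 3L))
  words <- all_kmers(granularity)
  if (is.null(rownames(values)) || !setequal(rownames(values), words)) {
    stop(sprintf("property table must cover all %d %s-nucleotide words",
                 length(words), if (granularity == 2L) "di" else "tri"),
         call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("property columns must be uniquely named", call. = FALSE)
  }
  values <- values[words, , drop = FALSE]
  if (standardize) {
    values <- apply(values, 2L, function(v) {
      s <- sqrt(mean((v - mean(v))^2))
      if (s == 0) stop("constant property cannot be standardized", call. = FALSE)
      (v - mean(v)) / s
    })
    rownames(values) <- words
  }
  structure(list(
    granularity = as.integer(granularity),
    property_names = colnames(values),
    values = values,
    standardized = standardize
  ), class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d-nucleotide, %d properties: %s%s\n",
              x$granularity, length(x$property_names),
              paste(x$property_names, collapse = ", "),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Load a property table from CSV
#'
#' The CSV has a header row `word,<property>,<property>,...`; comment lines
#' start with `#`. Used both for the shipped default table and for
#' user-supplied overrides.
#'
#' @param path CSV file path.
#' @param granularity 2 or 3; inferred from word length when `NULL`.
#' @inheritParams property_table
#' @return a `property_table`.
#' @export
read_property_table <- function(path, granularity = NULL, standardize = TRUE) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  words <- toupper(chartr("Tt", "Uu", tab[[1]]))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- words
  if (is.null(granularity)) granularity <- nchar(words[[1]])
  property_table(vals, granularity, standardize = standardize)
}

#' Default dinucleotide property table
#'
#' Six RNA dinucleotide helical step parameters (shift, slide, rise, tilt,
#' roll, twist), standardized over the 16 dinucleotides. Shipped as a
#' versioned CSV under `extdata`.
#'
#' @return a `property_table` with granularity 2 and 6 properties.
#' @export
default_di_properties <- function() {
  path <- system.file("extdata", "rna_dinucleotide_properties.csv",
                      package = "hmcpred", mustWork = TRUE)
  read_property_table(path, granularity = 2L)
}

#' Default trinucleotide property table
#'
#' Two trinucleotide properties (roll, twist) lifted from the dinucleotide
#' helical-step table: the value of a trinucleotide is the mean of its two
#' overlapping dinucleotide steps. Standardized over the 64 trinucleotides.
#'
#' @return a `property_table` with granularity 3 and 2 properties.
#' @export
default_tri_properties <- function() {
  di <- read_property_table(
    system.file("extdata", "rna_dinucleotide_properties.csv",
                package = "hmcpred", mustWork = TRUE),
    granularity = 2L, standardize = FALSE
  )
  words <- all_kmers(3L)
  lift <- function(prop) {
    vapply(words, function(w) {
      steps <- c(substr(w, 1L, 2L), substr(w, 2L, 3L))
      mean(di$values[steps, prop])
    }, numeric(1))
  }
  vals <- cbind(roll = lift("roll"), twist = lift("twist"))
  rownames(vals) <- words
  property_table(vals, 3L)
}

#' Positional property profile of a sequence
#'
#' The shared substrate of the covariance encoders: the series of standardized
#' property values of the k-words read at positions 1..(L-g+1) of the
#' sequence, where g is the table granularity.
#'
#' @param seq an [rna_sequence] or a plain residue string.
#' @param table a `property_table`.
#' @param property a property name present in the table.
#' @return numeric vector of length `nchar(seq) - granularity + 1`.
#' @export
property_profile <- function(seq, table, property) {
  stopifnot(inherits(table, "property_table"))
  res <- residues_of(seq)
  g <- table$granularity
  if (nchar(res) < g) {
    stop(sprintf("sequence shorter than granularity %d", g), call. = FALSE)
  }
  if (!property %in% table$property_names) {
    stop(sprintf("unknown property '%s' (available: %s)", property,
                 paste(table$property_names, collapse = ", ")), call. = FALSE)
  }
  words <- sliding_words(res, g)
  unname(table$values[words, property])
}

residues_of <- function(seq) {
  if (inherits(seq, "rna_sequence")) seq$residues
  else normalize_residues(seq)
}

# All overlapping k-words of a residue string, in position order.
sliding_words <- function(res, k) {
  n <- nchar(res)
  substring(res, 1:(n - k + 1L), k:n)
}
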