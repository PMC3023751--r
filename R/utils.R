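DNA_BASES <- c("A", "C", "G", "T")
SBFI_REMNANT <- "TGCAGG"
TAG_LENGTH <- 28L
READ_LENGTH <- 36L
BARCODE_LENGTH <- 4L

#' Hamming distance between equal-length strings
#'
#' Vectorised positional mismatch count between two character vectors of
#' equal-length strings (recycled to common length).
#'
#' @param x,y Character vectors of strings; `x[i]` and `y[i]` must have equal
#'   number of characters.
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' str_hamming("TGCAGGAA", "TGCAGGAT")
str_hamming <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  if (any(nchar(x) != nchar(y))) {
    abort("str_hamming() requires pairs of equal-length strings")
  }
  mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)), x, y,
         USE.NAMES = FALSE)
}

# positions (1-based) at which two equal-length strings differ
str_diff_positions <- function(a, b) {
  which(utf8ToInt(a) != utf8ToInt(b))
}

# random DNA strings of fixed width (vectorised)
random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- sample(DNA_BASES, n * width, replace = TRUE)
  apply(matrix(m, nrow = width), 2, paste, collapse = "")
}

#' Convert long genotype calls to a marker-by-individual matrix
#'
#' The long format (`marker`, `individual`, `call`) is the package's working
#' representation of a genotype matrix; several linear-algebra steps need the
#' wide character matrix instead. Row and column order follow first appearance
#' in the long table.
#'
#' @param calls Tibble with columns `marker`, `individual`, `call`
#'   (values `"A"`, `"B"` or `NA`).
#' @return Character matrix, markers in rows, individuals in columns.
#' @export
geno_matrix <- function(calls) {
  stopifnot(all(c("marker", "individual", "call") %in% names(calls)))
  markers <- unique(calls$marker)
  individuals <- unique(calls$individual)
  m <- matrix(NA_character_, length(markers), length(individuals),
              dimnames = list(markers, individuals))
  m[cbind(match(calls$marker, markers), match(calls$individual, individuals))] <-
    calls$call
  m
}

#' Convert a marker-by-individual matrix to long genotype calls
#'
#' Inverse of [geno_matrix()].
#'
#' @param mat Character matrix with marker rownames and individual colnames.
#' @return Tibble with columns `marker`, `individual`, `call`.
#' @export
geno_tibble <- function(mat) {
  tibble(
    marker = rep(rownames(mat), times = ncol(mat)),
    individual = rep(colnames(mat), each = nrow(mat)),
    call = as.character(mat)
  )
}

# per-marker / per-individual missing summaries of a long call table
#' Missing-data summaries of a genotype call table
#'
#' @param calls Long genotype call tibble (see [geno_matrix()]).
#' @return List with tibbles `by_marker` and `by_individual`, each carrying
#'   `n_missing` and `missing_rate`.
#' @export
missing_rates <- function(calls) {
  by_marker <- calls %>%
    group_by(.data$marker) %>%
    summarise(n = n(), n_missing = sum(is.na(.data$call)),
              missing_rate = .data$n_missing / .data$n, .groups = "drop")
  by_individual <- calls %>%
    group_by(.data$individual) %>%
    summarise(n = n(), n_missing = sum(is.na(.data$call)),
              missing_rate = .data$n_missing / .data$n, .groups = "drop")
  list(by_marker = by_marker, by_individual = by_individual)
}
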