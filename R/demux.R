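#' Read a FASTQ file into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; keeps the first
#' whitespace-delimited token of each description as the read id.
#'
#' @param path FASTQ path, plain or gzipped.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' Read a two-column barcode map
#'
#' @param path TSV with columns `sample_id` and `barcode` (header optional;
#'   detected from the first line).
#' @return Tibble `sample_id`, `barcode`.
#' @export
read_barcode_map <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", first, ignore.case = TRUE)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("sample_id", "barcode"))
  }
  names(df)[1:2] <- c("sample_id", "barcode")
  as_tibble(df[, 1:2])
}

#' Partition reads by inline barcode and restriction remnant
#'
#' A read is assigned to a sample if and only if its first four bases exactly
#' match that sample's multiplex identifier (MID) and bases 5-10 equal the
#' SbfI remnant TGCAGG. Assigned reads contribute bases 5-32 (1-based,
#' inclusive) as their 28-nt tag. No mismatch rescue is attempted: anything
#' else is counted in a discard category (`discarded_barcode`,
#' `discarded_remnant`, or `discarded_short` for reads under 32 nt). Reads
#' containing N in the barcode or remnant necessarily fail the exact match.
#'
#' @param reads Tibble with `read_id` and `sequence`, or a FASTQ path.
#' @param barcode_map Tibble with `sample_id` and `barcode` (distinct 4-mers),
#'   or a TSV path.
#' @return A `rad_demux` list: `reads` (read-level log with `sample_id`,
#'   `tag`, `status`), `tags` (per-sample tag counts: `sample_id`, `tag`,
#'   `count`), `summary` (per-sample assigned counts, including zero-read
#'   samples), `discards` (category counts), `n_input`.
#' @export
demultiplex <- function(reads, barcode_map) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (is.character(barcode_map) && length(barcode_map) == 1) {
    barcode_map <- read_barcode_map(barcode_map)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)),
            all(c("sample_id", "barcode") %in% names(barcode_map)))
  if (anyDuplicated(barcode_map$barcode)) {
    abort("duplicate barcodes in barcode map")
  }
  if (any(grepl("N", barcode_map$barcode, fixed = TRUE))) {
    abort("barcodes must not contain N")
  }
  if (any(nchar(barcode_map$barcode) != BARCODE_LENGTH)) {
    abort("barcodes must be 4 nt")
  }

  seq <- reads$sequence
  len <- nchar(seq)
  bc <- substr(seq, 1L, 4L)
  remnant <- substr(seq, 5L, 10L)
  hit <- match(bc, barcode_map$barcode)

  status <- rep("assigned", length(seq))
  status[len < 32L] <- "discarded_short"
  status[len >= 32L & is.na(hit)] <- "discarded_barcode"
  status[len >= 32L & !is.na(hit) & remnant != SBFI_REMNANT] <- "discarded_remnant"

  assigned <- status == "assigned"
  out <- tibble(
    read_id = reads$read_id,
    sample_id = ifelse(assigned, barcode_map$sample_id[hit], NA_character_),
    tag = ifelse(assigned, substr(seq, 5L, 32L), NA_character_),
    status = status
  )
  tags <- out %>%
    filter(.data$status == "assigned") %>%
    count(.data$sample_id, .data$tag, name = "count")
  summary <- tibble(sample_id = barcode_map$sample_id) %>%
    left_join(count(filter(out, assigned), .data$sample_id, name = "n_assigned"),
              by = "sample_id") %>%
    mutate(n_assigned = ifelse(is.na(.data$n_assigned), 0L, .data$n_assigned))
  discards <- tibble(category = c("discarded_barcode", "discarded_remnant",
                                  "discarded_short", "discarded_ambiguous")) %>%
    left_join(count(filter(out, !assigned), .data$status, name = "n"),
              by = c(category = "status")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(list(reads = out, tags = tags, summary = summary,
                 discards = discards, n_input = length(seq)),
            class = "rad_demux")
}

#' @export
print.rad_demux <- function(x, ...) {
  cat("<rad_demux> ", x$n_input, " reads; ",
      sum(x$summary$n_assigned), " assigned to ",
      nrow(x$summary), " samples; ", sum(x$discards$n), " discarded\n", sep = "")
  invisible(x)
}

#' Trim reads to the analysed 28-nt tag
#'
#' Returns bases 5-32 (1-based, inclusive): the SbfI remnant plus 22 genomic
#' nucleotides, dropping the 4-nt barcode and the trailing filler.
#'
#' @param sequence Character vector of read sequences (>= 32 nt each).
#' @return Character vector of 28-nt tags.
#' @export
trim_tag <- function(sequence) {
  if (any(nchar(sequence) < 32L)) abort("reads must be at least 32 nt to trim")
  substr(sequence, 5L, 32L)
}
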