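#' Genotype one DH individual against the codominant panel
#'
#' For each codominant locus, reads matching each parental allele exactly
#' (Hamming distance 0 over the full 28-nt tag) are counted. The call is A
#' when at least `min_reads` allele-A reads and zero allele-B reads are seen
#' (B symmetrically); any locus with reads of both alleles is a conflict and
#' coded missing, as is any locus below the read floor. Error-tolerant
#' matching is deliberately avoided: it risks allele switching at 1-SNP loci.
#' No depth ceiling applies here - the 8x/500x window is a discovery-phase
#' filter, and DH genotypes are callable at low coverage.
#'
#' @param clusters Cluster tibble for a single sample (`tag`, `depth`).
#' @param panel Marker panel; only its codominant rows are scored.
#' @param min_reads Minimum supporting reads for a call.
#' @return Tibble `marker`, `depth_A`, `depth_B`, `call`.
#' @export
genotype_sample <- function(clusters, panel, min_reads = 2) {
  if ("sample_id" %in% names(clusters) &&
      length(unique(clusters$sample_id)) > 1) {
    abort("genotype_sample() expects clusters from a single sample")
  }
  sub <- filter(panel, .data$marker_class == "codominant")
  da <- clusters$depth[match(sub$allele_A, clusters$tag)]
  db <- clusters$depth[match(sub$allele_B, clusters$tag)]
  da[is.na(da)] <- 0
  db[is.na(db)] <- 0
  call <- rep(NA_character_, nrow(sub))
  call[da >= min_reads & db == 0] <- "A"
  call[db >= min_reads & da == 0] <- "B"
  tibble(marker = sub$locus_id, depth_A = da, depth_B = db, call = call)
}

#' Genotype all samples into a long genotype call table
#'
#' Applies [genotype_sample()] to every individual and assembles the complete
#' markers-by-individuals call set in long form. Individuals with no callable
#' locus are retained but flagged with a message.
#'
#' @param clusters Cluster tibble over samples (`sample_id`, `tag`, `depth`),
#'   e.g. `cluster_tags(demux$tags)`.
#' @param panel Marker panel (codominant rows are scored).
#' @param individuals Individuals to genotype; defaults to all sample ids
#'   present in `clusters`.
#' @param min_reads Minimum supporting reads for a call.
#' @return Long call tibble `marker`, `individual`, `call` covering every
#'   marker for every individual.
#' @export
build_genotype_matrix <- function(clusters, panel, individuals = NULL,
                                  min_reads = 2) {
  if (is.null(individuals)) individuals <- unique(clusters$sample_id)
  by_sample <- split(clusters, clusters$sample_id)
  calls <- bind_rows(lapply(individuals, function(id) {
    cl <- by_sample[[id]]
    if (is.null(cl)) cl <- tibble(tag = character(0), depth = numeric(0))
    g <- genotype_sample(cl, panel, min_reads = min_reads)
    tibble(marker = g$marker, individual = id, call = g$call)
  }))
  empty <- calls %>%
    group_by(.data$individual) %>%
    summarise(all_missing = all(is.na(.data$call)), .groups = "drop") %>%
    filter(.data$all_missing)
  if (nrow(empty)) {
    inform(paste0("individuals with 100% missing calls: ",
                  paste(empty$individual, collapse = ", ")))
  }
  calls
}

#' Write genotype calls in JoinMap 4 .loc format
#'
#' Header lines `name = <population_name>`, `popt = DH`, `nloc`, `nind`, then
#' one line per marker: the marker id followed by whitespace-separated codes
#' `a` (call A), `b` (call B), `-` (missing) in individual order.
#'
#' @param calls Long genotype call tibble.
#' @param path Output path.
#' @param population_name Population name for the header.
#' @return `path`, invisibly.
#' @export
write_joinmap_loc <- function(calls, path, population_name = "POP") {
  mat <- geno_matrix(calls)
  if (any(grepl("\\s", rownames(mat)))) {
    abort("marker ids must not contain whitespace")
  }
  codes <- matrix("-", nrow(mat), ncol(mat))
  codes[mat == "A"] <- "a"
  codes[mat == "B"] <- "b"
  lines <- c(
    paste("name =", population_name),
    "popt = DH",
    paste("nloc =", nrow(mat)),
    paste("nind =", ncol(mat)),
    paste(rownames(mat), apply(codes, 1, paste, collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a JoinMap 4 .loc file written by [write_joinmap_loc()]
#'
#' Exact inverse of the writer up to individual naming: the format carries no
#' individual ids, so `ind_001`... are assigned unless supplied.
#'
#' @param path Input path.
#' @param individuals Optional individual ids (length `nind`).
#' @return Long genotype call tibble; the population name is attached as
#'   attribute `population`.
#' @export
read_joinmap_loc <- function(path, individuals = NULL) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)[1]
    trimws(sub(".*=", "", ln))
  }
  nloc <- as.integer(hdr("nloc"))
  nind <- as.integer(hdr("nind"))
  body <- lines[grep("^nind\\s*=", lines)[1] + seq_len(nloc)]
  parts <- strsplit(trimws(body), "\\s+")
  markers <- vapply(parts, `[`, "", 1)
  codes <- matrix(unlist(lapply(parts, `[`, -1)), nrow = nloc, byrow = TRUE)
  mat <- matrix(NA_character_, nloc, nind)
  mat[codes == "a"] <- "A"
  mat[codes == "b"] <- "B"
  if (is.null(individuals)) individuals <- sprintf("ind_%03d", seq_len(nind))
  dimnames(mat) <- list(markers, individuals)
  out <- geno_tibble(mat)
  attr(out, "population") <- hdr("name")
  out
}

#' Write / read genotype calls as a marker-by-individual CSV
#'
#' Markers are rows, individuals are columns, values `A`/`B` or empty for
#' missing.
#'
#' @param calls Long genotype call tibble.
#' @param path File path.
#' @return `path` (writer) or the long call tibble (reader).
#' @export
write_geno_csv <- function(calls, path) {
  mat <- geno_matrix(calls)
  utils::write.csv(cbind(marker = rownames(mat), as.data.frame(mat)),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_geno_csv
#' @export
read_geno_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$marker
  geno_tibble(mat)
}
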