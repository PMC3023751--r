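#' Collapse tags into per-sample clusters
#'
#' One cluster per distinct 28-nt tag per sample; depth is the read
#' multiplicity, so depths sum to the number of input tag observations.
#'
#' @param tags Tibble with `sample_id` and `tag`, one row per read, or with a
#'   `count` column of pre-aggregated multiplicities.
#' @return Tibble `sample_id`, `tag`, `depth`.
#' @export
cluster_tags <- function(tags) {
  stopifnot(all(c("sample_id", "tag") %in% names(tags)))
  if ("count" %in% names(tags)) {
    tags %>%
      group_by(.data$sample_id, .data$tag) %>%
      summarise(depth = sum(.data$count), .groups = "drop")
  } else {
    count(tags, .data$sample_id, .data$tag, name = "depth")
  }
}

#' Depth-filter tag clusters
#'
#' Retains clusters whose depth lies in `[min_depth, max_depth]`. The floor
#' removes under-sequenced tags (sequencing error artefacts); the ceiling
#' removes putative high-copy repeats. Both bounds are inclusive: depth 8 and
#' depth 500 are retained at the defaults, 7 and 501 are not.
#'
#' @param clusters Tibble with a `depth` column (from [cluster_tags()]).
#' @param min_depth,max_depth Inclusive depth bounds.
#' @return Filtered tibble.
#' @export
filter_clusters <- function(clusters, min_depth = 8, max_depth = 500) {
  if (min_depth <= 0 || max_depth <= 0 || min_depth > max_depth) {
    abort("need 0 < min_depth <= max_depth")
  }
  filter(clusters, .data$depth >= min_depth, .data$depth <= max_depth)
}

# pigeonhole candidate pairs: split tags into (max_mismatch + 1) segments;
# any pair within max_mismatch shares at least one exact segment
segment_candidates <- function(tags_a, tags_b, max_mismatch) {
  nseg <- max_mismatch + 1L
  bounds <- round(seq(0, TAG_LENGTH, length.out = nseg + 1L))
  cand <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    seg_a <- substr(tags_a, bounds[s] + 1L, bounds[s + 1L])
    seg_b <- substr(tags_b, bounds[s] + 1L, bounds[s + 1L])
    common <- intersect(seg_a, seg_b)
    if (!length(common)) next
    ia <- split(seq_along(tags_a), seg_a)[common]
    ib <- split(seq_along(tags_b), seg_b)[common]
    cand[[s]] <- bind_rows(lapply(seq_along(common), function(k) {
      expand.grid(i = ia[[k]], j = ib[[k]], KEEP.OUT.ATTRS = FALSE)
    }))
  }
  distinct(bind_rows(cand))
}

#' Match parental tag clusters into a SNP marker panel
#'
#' Pairs each parent-A tag with parent-B tags at Hamming distance at most
#' `max_mismatch` (default 2), using pigeonhole k-mer seeding (split into
#' `max_mismatch + 1` segments; any qualifying pair shares an exact segment)
#' followed by full Hamming verification, so results equal an all-pairs scan.
#' Uniquely paired tags at distance 0 are monomorphic loci; at distance 1-2,
#' codominant SNP loci with `snp_positions` the 0-based differing offsets.
#' Tags with no partner are dominant (present in one parent only); tags
#' involved in non-unique pairings are ambiguous (paralog/repeat risk) and
#' excluded downstream.
#'
#' @param parent_a,parent_b Depth-filtered cluster tibbles for each parent
#'   (columns `tag`, optionally `depth`); tags must be unique within a parent.
#' @param max_mismatch Maximum Hamming distance considered.
#' @return Panel tibble: `locus_id`, `allele_A`, `allele_B`, `snp_positions`
#'   (list-column, 0-based), `n_snps`, `marker_class`. Locus ids are
#'   `FGX_SIM%05d` in lexicographic tag order.
#' @export
match_parent_clusters <- function(parent_a, parent_b, max_mismatch = 2) {
  tags_a <- parent_a$tag
  tags_b <- parent_b$tag
  if (anyDuplicated(tags_a) || anyDuplicated(tags_b)) {
    abort("clusters must be unique within a parent")
  }
  cand <- segment_candidates(tags_a, tags_b, max_mismatch)
  if (nrow(cand)) {
    d <- str_hamming(tags_a[cand$i], tags_b[cand$j])
    pairs <- cand[d <= max_mismatch, , drop = FALSE]
  } else {
    pairs <- cand
  }

  deg_a <- tabulate(pairs$i, nbins = length(tags_a))
  deg_b <- tabulate(pairs$j, nbins = length(tags_b))
  clean <- deg_a[pairs$i] == 1L & deg_b[pairs$j] == 1L

  rows <- list()
  if (any(clean)) {
    i <- pairs$i[clean]; j <- pairs$j[clean]
    snp <- mapply(function(a, b) str_diff_positions(a, b) - 1L,
                  tags_a[i], tags_b[j], SIMPLIFY = FALSE, USE.NAMES = FALSE)
    nsnp <- lengths(snp)
    rows$paired <- tibble(
      allele_A = tags_a[i], allele_B = tags_b[j],
      snp_positions = snp, n_snps = nsnp,
      marker_class = ifelse(nsnp == 0, "monomorphic", "codominant")
    )
  }
  amb_a <- tags_a[deg_a > 1 | (deg_a == 1 & !seq_along(tags_a) %in% pairs$i[clean])]
  amb_b <- tags_b[deg_b > 1 | (deg_b == 1 & !seq_along(tags_b) %in% pairs$j[clean])]
  if (length(amb_a)) {
    rows$amb_a <- tibble(allele_A = amb_a, allele_B = NA_character_,
                         snp_positions = replicate(length(amb_a), integer(0),
                                                   simplify = FALSE),
                         n_snps = NA_integer_, marker_class = "ambiguous")
  }
  if (length(amb_b)) {
    rows$amb_b <- tibble(allele_A = NA_character_, allele_B = amb_b,
                         snp_positions = replicate(length(amb_b), integer(0),
                                                   simplify = FALSE),
                         n_snps = NA_integer_, marker_class = "ambiguous")
  }
  dom_a <- tags_a[deg_a == 0L]
  dom_b <- tags_b[deg_b == 0L]
  if (length(dom_a)) {
    rows$dom_a <- tibble(allele_A = dom_a, allele_B = NA_character_,
                         snp_positions = replicate(length(dom_a), integer(0),
                                                   simplify = FALSE),
                         n_snps = NA_integer_, marker_class = "dominant_A")
  }
  if (length(dom_b)) {
    rows$dom_b <- tibble(allele_A = NA_character_, allele_B = dom_b,
                         snp_positions = replicate(length(dom_b), integer(0),
                                                   simplify = FALSE),
                         n_snps = NA_integer_, marker_class = "dominant_B")
  }
  panel <- bind_rows(rows)
  if (!nrow(panel)) {
    panel <- tibble(allele_A = character(0), allele_B = character(0),
                    snp_positions = list(), n_snps = integer(0),
                    marker_class = character(0))
  }
  key <- ifelse(is.na(panel$allele_A), panel$allele_B, panel$allele_A)
  panel <- panel[order(key), ]
  panel <- mutate(panel, locus_id = sprintf("FGX_SIM%05d", row_number())) %>%
    select("locus_id", "allele_A", "allele_B", "snp_positions", "n_snps",
           "marker_class")
  panel
}

#' Tally marker classes and extract the codominant subpanel
#'
#' Only codominant loci (both parental alleles observed, 1-2 SNPs apart) feed
#' genotyping and mapping; dominant-style presence/absence tags are excluded
#' for their reduced genotyping quality.
#'
#' @param panel Panel tibble from [match_parent_clusters()].
#' @return List with `class_counts` (tibble `marker_class`, `n`, counts
#'   partitioning the panel) and `codominant` (the subpanel tibble).
#' @export
classify_panel <- function(panel) {
  counts <- count(panel, .data$marker_class, name = "n")
  sub <- filter(panel, .data$marker_class == "codominant")
  if (!nrow(sub)) warn("panel contains no codominant loci")
  list(class_counts = counts, codominant = sub)
}

#' Write / read a marker panel TSV
#'
#' SNP offsets are serialised 0-based, comma-joined.
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path` (writer) or the panel tibble (reader).
#' @export
write_panel <- function(panel, path) {
  out <- panel
  out$snp_positions <- vapply(out$snp_positions, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$snp_positions <- lapply(strsplit(ifelse(is.na(df$snp_positions), "",
                                             df$snp_positions), ","),
                             function(x) as.integer(x[nzchar(x)]))
  as_tibble(df)
}
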