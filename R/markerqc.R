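#' Exclude markers with excessive missing data
#'
#' A marker is excluded when its missing fraction over individuals is greater
#' than or equal to `threshold` (so with 93 individuals and the default 0.15,
#' 14 missing calls excludes a marker and 13 retains it). Idempotent.
#'
#' @param calls Long genotype call tibble.
#' @param threshold Missing-fraction cutoff in (0, 1].
#' @return List with `calls` (retained markers) and `excluded` (tibble
#'   `marker`, `n_missing`, `missing_rate`).
#' @export
filter_missing <- function(calls, threshold = 0.15) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  rates <- missing_rates(calls)$by_marker
  excl <- filter(rates, .data$missing_rate >= threshold)
  list(
    calls = filter(calls, !.data$marker %in% excl$marker),
    excluded = select(excl, "marker", "n_missing", "missing_rate")
  )
}

#' Detect sets of genotypically identical lines
#'
#' Two individuals are duplicates when they conflict at zero markers where
#' both are non-missing and share at least `min_overlap` mutually non-missing
#' markers (guarding against vacuous matches). Duplicate sets are the
#' transitive closures of this relation; one representative (first in input
#' order) is retained per set.
#'
#' @param calls Long genotype call tibble with >= 2 individuals.
#' @param min_overlap Minimum shared non-missing markers.
#' @return List with `sets` (list of character vectors, each a duplicate set),
#'   `duplicates` (tibble `set`, `individual`, `representative`), and `calls`
#'   (reduced table keeping one representative per set).
#' @export
find_duplicate_lines <- function(calls, min_overlap = 50) {
  mat <- geno_matrix(calls)
  if (ncol(mat) < 2) abort("need at least 2 individuals")
  if (min_overlap > nrow(mat)) abort("min_overlap exceeds the marker count")
  A <- (mat == "A") & !is.na(mat)
  B <- (mat == "B") & !is.na(mat)
  M <- !is.na(mat)
  storage.mode(A) <- storage.mode(B) <- storage.mode(M) <- "double"
  conflicts <- crossprod(A, B) + crossprod(B, A)
  overlap <- crossprod(M)
  adj <- conflicts == 0 & overlap >= min_overlap
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sets <- split(colnames(mat), comp$membership)
  sets <- unname(sets[vapply(sets, length, 1L) >= 2])
  # preserve input order within sets, representative first by input order
  sets <- lapply(sets, function(s) colnames(mat)[sort(match(s, colnames(mat)))])
  dup_tbl <- bind_rows(lapply(seq_along(sets), function(k) {
    tibble(set = k, individual = sets[[k]],
           representative = sets[[k]] == sets[[k]][1])
  }))
  drop <- if (nrow(dup_tbl)) dup_tbl$individual[!dup_tbl$representative]
          else character(0)
  list(sets = sets, duplicates = dup_tbl,
       calls = filter(calls, !.data$individual %in% drop))
}

#' Per-marker segregation-distortion profile
#'
#' For each marker, tests the observed allele counts against the DH 1:1
#' expectation with a 1-df chi-square (no continuity correction):
#' chi2 = (nA - nB)^2 / (nA + nB). The signed score -log10(p) * sign(nA - nB)
#' makes direction visible: positive values mean distortion in favour of the
#' parent-A allele. Markers with no callable individuals are flagged
#' uncallable with an undefined score.
#'
#' @param calls Long genotype call tibble.
#' @param alpha Significance level for the distortion flag.
#' @param map Optional genetic map tibble (`marker`, `group`, `pos_cM`) to
#'   join positions for plotting.
#' @return A `rad_distortion` tibble: `marker`, `n_A`, `n_B`, `chi2`, `p`,
#'   `signed_score`, `distorted`, `uncallable` (plus map columns if given).
#' @export
segregation_distortion <- function(calls, alpha = 0.05, map = NULL) {
  if (!nrow(calls)) abort("need at least one marker")
  prof <- calls %>%
    group_by(.data$marker) %>%
    summarise(n_A = sum(.data$call == "A", na.rm = TRUE),
              n_B = sum(.data$call == "B", na.rm = TRUE), .groups = "drop") %>%
    mutate(
      n_called = .data$n_A + .data$n_B,
      uncallable = .data$n_called == 0,
      chi2 = ifelse(.data$uncallable, NA_real_,
                    (.data$n_A - .data$n_B)^2 / pmax(.data$n_called, 1)),
      p = pchisq(.data$chi2, df = 1, lower.tail = FALSE),
      signed_score = -log10(.data$p) * sign(.data$n_A - .data$n_B),
      distorted = !.data$uncallable & .data$p < alpha
    ) %>%
    select(-"n_called")
  if (!is.null(map)) {
    prof <- left_join(prof, select(map, "marker", "group", "pos_cM"),
                      by = "marker")
  }
  structure(prof, class = c("rad_distortion", class(prof)), alpha = alpha)
}

#' Detect and recode singleton genotypes
#'
#' A singleton is a call that differs from the nearest non-missing call on
#' both sides within its linkage group - an apparent double crossover over a
#' short interval, far more likely a genotyping error than two real
#' crossovers. Singletons are recoded to missing only when both flanking
#' distances are below `max_flank_cM`; with wide flanks recombination is
#' plausible and the call is retained. Terminal calls (one flank) are never
#' singletons. Recoding never flips a call to the opposite allele.
#'
#' @param calls Long genotype call tibble.
#' @param map Genetic map tibble (`marker`, `group`, `pos_cM`); markers absent
#'   from the map are skipped with a message.
#' @param max_flank_cM Flank-distance ceiling (cM) below which a singleton is
#'   recoded.
#' @return List with `report` (tibble `marker`, `individual`, `action`,
#'   `left_cM`, `right_cM`) and `calls` (the recoded table).
#' @export
detect_singletons <- function(calls, map, max_flank_cM = 10) {
  off_map <- setdiff(unique(calls$marker), map$marker)
  if (length(off_map)) {
    inform(paste0(length(off_map), " markers not on the map skipped"))
  }
  mat <- geno_matrix(calls)
  report <- list()
  for (grp in unique(map$group)) {
    gm <- map[map$group == grp, ]
    gm <- gm[order(gm$pos_cM), ]
    ids <- gm$marker[gm$marker %in% rownames(mat)]
    if (length(ids) < 3) next
    pos <- gm$pos_cM[match(ids, gm$marker)]
    sub <- mat[ids, , drop = FALSE]
    for (col in seq_len(ncol(sub))) {
      x <- sub[, col]
      obs <- which(!is.na(x))
      if (length(obs) < 3) next
      inner <- 2:(length(obs) - 1)
      v <- x[obs]
      is_singleton <- v[inner] != v[inner - 1] & v[inner] != v[inner + 1]
      for (k in inner[is_singleton]) {
        left <- pos[obs[k]] - pos[obs[k - 1]]
        right <- pos[obs[k + 1]] - pos[obs[k]]
        recode <- left < max_flank_cM && right < max_flank_cM
        report[[length(report) + 1]] <- tibble(
          marker = ids[obs[k]], individual = colnames(sub)[col],
          action = if (recode) "recoded_missing" else "retained",
          left_cM = left, right_cM = right
        )
        if (recode) mat[ids[obs[k]], col] <- NA_character_
      }
    }
  }
  report <- if (length(report)) bind_rows(report) else
    tibble(marker = character(0), individual = character(0),
           action = character(0), left_cM = numeric(0), right_cM = numeric(0))
  recoded <- calls
  if (nrow(report)) {
    rec <- report[report$action == "recoded_missing", ]
    hit <- paste(recoded$marker, recoded$individual) %in%
      paste(rec$marker, rec$individual)
    recoded$call[hit] <- NA_character_
  }
  list(report = report, calls = recoded)
}
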