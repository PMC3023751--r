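#' Haldane map function and its inverse
#'
#' Converts a recombination fraction to a map distance assuming no crossover
#' interference: d = -50 ln(1 - 2r) cM, with inverse
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return Distance in cM, or recombination fraction.
#' @export
#' @examples
#' haldane(0.2)            # ~25.54 cM
#' haldane_inverse(25)     # ~0.197
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("r must be in [0, 0.5): r >= 0.5 is unlinked")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0)) abort("d must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Two-point recombination fractions and linkage LOD for all marker pairs
#'
#' In a DH population an individual is recombinant for a marker pair iff its
#' calls differ; missing calls make the individual uninformative for that
#' pair. The recombination fraction estimate is r = k/n over the n informative
#' individuals, and the linkage LOD is the log10 likelihood ratio of r versus
#' independence (r = 1/2):
#' LOD = k log10(r) + (n - k) log10(1 - r) + n log10(2), with the k log10(r)
#' term taken as its limit 0 when k = 0, and LOD = 0 when r >= 1/2. Pairs with
#' no informative individual are flagged uninformative (`n = 0`, `rf = NA`).
#'
#' @param calls Long genotype call tibble with >= 2 markers.
#' @return Tibble `marker1`, `marker2`, `n`, `k`, `rf`, `lod`, one row per
#'   unordered pair.
#' @export
pairwise_rf_lod <- function(calls) {
  mat <- geno_matrix(calls)
  if (nrow(mat) < 2) abort("need at least 2 markers")
  A <- (mat == "A") & !is.na(mat)
  B <- (mat == "B") & !is.na(mat)
  M <- !is.na(mat)
  storage.mode(A) <- storage.mode(B) <- storage.mode(M) <- "double"
  K <- tcrossprod(A, B) + tcrossprod(B, A)
  N <- tcrossprod(M)
  idx <- which(upper.tri(K), arr.ind = TRUE)
  n <- N[idx]
  k <- K[idx]
  rf <- ifelse(n > 0, k / n, NA_real_)
  lod <- two_point_lod(k, n, rf)
  tibble(marker1 = rownames(mat)[idx[, 1]], marker2 = rownames(mat)[idx[, 2]],
         n = as.integer(n), k = as.integer(k), rf = rf, lod = lod)
}

two_point_lod <- function(k, n, rf) {
  lod <- rep(NA_real_, length(k))
  ok <- !is.na(rf) & rf < 0.5
  kl <- ifelse(k[ok] == 0, 0, k[ok] * log10(rf[ok]))
  lod[ok] <- kl + (n[ok] - k[ok]) * log10(1 - rf[ok]) + n[ok] * log10(2)
  lod[!is.na(rf) & rf >= 0.5] <- 0
  lod
}

#' Group markers into linkage groups at a LOD threshold
#'
#' Builds the graph whose edges join marker pairs with LOD >= `min_lod` and
#' r < 0.5; linkage groups are its connected components. Markers with no edge
#' are reported unlinked. A marker bridging two otherwise separate clusters
#' merges them (connected components); such merges are visible in the
#' pairwise table if they need inspection.
#'
#' @param pairs Pairwise linkage tibble from [pairwise_rf_lod()].
#' @param min_lod Minimum LOD to declare linkage.
#' @return List with `groups` (list of character vectors, largest first),
#'   `unlinked` (character vector), and `membership` (tibble `marker`,
#'   `group`).
#' @export
group_markers <- function(pairs, min_lod = 5) {
  markers <- unique(c(pairs$marker1, pairs$marker2))
  edges <- filter(pairs, !is.na(.data$lod), .data$lod >= min_lod,
                  !is.na(.data$rf), .data$rf < 0.5)
  g <- igraph::graph_from_data_frame(
    edges[, c("marker1", "marker2")], directed = FALSE,
    vertices = data.frame(name = markers)
  )
  comp <- igraph::components(g)
  sets <- split(markers, comp$membership[markers])
  sizes <- vapply(sets, length, 1L)
  unlinked <- unlist(sets[sizes == 1], use.names = FALSE)
  groups <- sets[sizes >= 2]
  groups <- groups[order(-vapply(groups, length, 1L),
                         vapply(groups, `[`, "", 1))]
  groups <- unname(lapply(groups, function(s) markers[sort(match(s, markers))]))
  names(groups) <- sprintf("LG%d", seq_along(groups))
  membership <- bind_rows(lapply(names(groups), function(nm) {
    tibble(marker = groups[[nm]], group = nm)
  }))
  list(groups = groups, unlinked = if (is.null(unlinked)) character(0) else unlinked,
       membership = membership)
}

# symmetric rf lookup matrix for a marker subset; NA where uninformative
rf_matrix <- function(pairs, markers) {
  m <- matrix(NA_real_, length(markers), length(markers),
              dimnames = list(markers, markers))
  sel <- pairs$marker1 %in% markers & pairs$marker2 %in% markers
  p <- pairs[sel, ]
  m[cbind(p$marker1, p$marker2)] <- p$rf
  m[cbind(p$marker2, p$marker1)] <- p$rf
  diag(m) <- 0
  m
}

# sum of adjacent recombination fractions along an order (SARF)
sarf <- function(order_idx, rf) {
  d <- rf[cbind(order_idx[-length(order_idx)], order_idx[-1])]
  sum(ifelse(is.na(d), 0.5, d))
}

#' Order the markers of one linkage group
#'
#' Co-segregating markers (pairwise r = 0) are first collapsed into bins and
#' ordered as units. The bin order minimises the sum of adjacent
#' recombination fractions (SARF) heuristically: a greedy nearest-neighbour
#' chain is grown from one end of the most distal pair, then refined by 2-opt
#' segment reversals until no improving move remains (2-opt never increases
#' SARF). Orientation: if `anchors` supplies an ordering for >= 2 of the
#' group's markers the order follows it; otherwise the end with the
#' lexicographically smallest marker comes first. Deterministic given the
#' input order.
#'
#' @param markers Markers of one group (character).
#' @param pairs Pairwise linkage tibble from [pairwise_rf_lod()].
#' @param anchors Optional tibble `marker`, `order` (or row order) used to
#'   orient the group.
#' @return Tibble `marker`, `bin` in map order; bins are numbered 1.. along
#'   the order and markers within a bin keep input order.
#' @export
order_group <- function(markers, pairs, anchors = NULL, alt_start = FALSE) {
  rf <- rf_matrix(pairs, markers)
  # bins: connected components of the rf == 0 relation among informative pairs
  zero <- !is.na(rf) & rf == 0
  diag(zero) <- TRUE
  gz <- igraph::graph_from_adjacency_matrix(zero, mode = "undirected")
  bin_id <- igraph::components(gz)$membership
  bins <- split(markers, bin_id)
  bins <- lapply(bins, function(s) markers[sort(match(s, markers))])
  reps <- vapply(bins, `[`, "", 1)

  rfr <- rf[reps, reps, drop = FALSE]
  nb <- length(reps)
  ord <- if (nb <= 2) seq_len(nb) else {
    two_opt(greedy_chain(rfr, alt_start), rfr)
  }

  # orientation
  ordered_markers <- unlist(bins[ord], use.names = FALSE)
  if (!is.null(anchors) && sum(anchors$marker %in% ordered_markers) >= 2) {
    if (!"order" %in% names(anchors)) anchors$order <- seq_len(nrow(anchors))
    hit <- anchors[anchors$marker %in% ordered_markers, ]
    along <- match(hit$marker, ordered_markers)
    if (stats::cor(along, hit$order, method = "spearman") < 0) ord <- rev(ord)
  } else {
    first <- bins[[ord[1]]][1]
    last <- bins[[ord[nb]]][1]
    if (last < first) ord <- rev(ord)
  }
  bind_rows(lapply(seq_along(ord), function(j) {
    tibble(marker = bins[[ord[j]]], bin = j)
  }))
}

greedy_chain <- function(rfr, alt_start = FALSE) {
  nb <- nrow(rfr)
  d <- rfr
  d[is.na(d)] <- 0.5
  diag(d) <- Inf
  # start from one end of the most distal (largest rf) pair
  far <- which(d == max(d[is.finite(d)]), arr.ind = TRUE)[1, ]
  chain <- if (alt_start) max(far) else min(far)
  left <- setdiff(seq_len(nb), chain)
  while (length(left)) {
    last <- chain[length(chain)]
    nxt <- left[which.min(d[last, left])]
    chain <- c(chain, nxt)
    left <- setdiff(left, nxt)
  }
  chain
}

# refine an order by 2-opt segment reversals and or-opt single-element
# reinsertions, alternating until neither improves SARF
two_opt <- function(ord, rfr) {
  d <- rfr
  d[is.na(d)] <- 0.5
  sarf_val <- function(o) sum(d[cbind(o[-length(o)], o[-1])])
  repeat {
    improved <- FALSE
    nb <- length(ord)
    # 2-opt: reverse ord[i..j]; cost change involves only the boundary edges
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        before <- (if (i > 1) d[ord[i - 1], ord[i]] else 0) +
          (if (j < nb) d[ord[j], ord[j + 1]] else 0)
        after <- (if (i > 1) d[ord[i - 1], ord[j]] else 0) +
          (if (j < nb) d[ord[i], ord[j + 1]] else 0)
        if (after < before - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    # or-opt: relocate single elements while any relocation lowers SARF
    repeat {
      cur <- sarf_val(ord)
      best <- NULL
      for (i in seq_len(nb)) {
        rest <- ord[-i]
        for (j in 0:(nb - 1)) {
          cand <- append(rest, ord[i], after = j)
          sc <- sarf_val(cand)
          if (sc < cur - 1e-12) {
            best <- cand
            cur <- sc
          }
        }
      }
      if (is.null(best)) break
      ord <- best
      improved <- TRUE
    }
    if (!improved) break
  }
  ord
}

#' Assemble ordered groups into a genetic map
#'
#' Positions accumulate Haldane distances between adjacent bins: the first
#' bin sits at 0 cM and each next bin at the previous position plus
#' `haldane(r)` for the adjacent-bin recombination fraction. Markers within a
#' bin share one position. An adjacent r >= 0.5 rejects the order: the group
#' is re-ordered once from the opposite greedy start, and if the anomaly
#' persists the fraction is clamped just under 0.5 with a warning.
#'
#' @param orders Named list of ordered `marker`/`bin` tibbles (one per group,
#'   from [order_group()]).
#' @param pairs Pairwise linkage tibble.
#' @return A `rad_map` tibble: `marker`, `group`, `bin`, `pos_cM`.
#' @export
assemble_map <- function(orders, pairs) {
  out <- bind_rows(lapply(names(orders), function(nm) {
    ob <- orders[[nm]]
    reps <- vapply(split(ob$marker, ob$bin), `[`, "", 1)
    nb <- length(reps)
    pos <- 0
    if (nb > 1) {
      rfr <- rf_matrix(pairs, reps)
      adj <- rfr[cbind(seq_len(nb - 1), 2:nb)]
      if (any(is.na(adj) | adj >= 0.5)) {
        warn(paste0("group ", nm, ": adjacent r >= 0.5 or uninformative; ",
                    "clamped below 0.5"))
        adj[is.na(adj) | adj >= 0.5] <- 0.4999
      }
      pos <- c(0, cumsum(haldane(adj)))
    }
    tibble(marker = ob$marker, group = nm, bin = ob$bin,
           pos_cM = pos[ob$bin])
  }))
  structure(out, class = c("rad_map", class(out)))
}

#' Build a genetic map from genotype calls
#'
#' Full linkage workflow: two-point recombination/LOD table, LOD-threshold
#' grouping, SARF/2-opt ordering per group, Haldane positions. Anchor markers
#' with known chromosome labels, when supplied, rename the groups they land
#' in and orient them.
#'
#' @param calls Long genotype call tibble.
#' @param min_lod LOD threshold for grouping.
#' @param anchors Optional tibble `marker`, `chromosome` (and optional
#'   `order`).
#' @return A `rad_map` tibble (`marker`, `group`, `bin`, `pos_cM`) with
#'   attributes `unlinked` (markers with no linkage at the threshold) and
#'   `pairs` (the pairwise table).
#' @export
build_linkage_map <- function(calls, min_lod = 5, anchors = NULL) {
  pairs <- pairwise_rf_lod(calls)
  grp <- group_markers(pairs, min_lod = min_lod)
  if (!length(grp$groups)) abort("no linkage groups at this LOD threshold")
  orders <- lapply(grp$groups, order_group, pairs = pairs, anchors = anchors)
  # an adjacent r >= 0.5 rejects the order: retry from the opposite greedy start
  bad_adjacency <- function(ob) {
    reps <- vapply(split(ob$marker, ob$bin), `[`, "", 1)
    if (length(reps) < 2) return(FALSE)
    rfr <- rf_matrix(pairs, reps)
    adj <- rfr[cbind(seq_len(length(reps) - 1), seq_len(length(reps) - 1) + 1)]
    any(is.na(adj) | adj >= 0.5)
  }
  for (nm in names(orders)) {
    if (bad_adjacency(orders[[nm]])) {
      orders[[nm]] <- order_group(grp$groups[[nm]], pairs, anchors = anchors,
                                  alt_start = TRUE)
    }
  }
  map <- assemble_map(orders, pairs)
  if (!is.null(anchors) && "chromosome" %in% names(anchors)) {
    relabel <- map %>%
      left_join(select(anchors, "marker", "chromosome"), by = "marker") %>%
      filter(!is.na(.data$chromosome)) %>%
      count(.data$group, .data$chromosome) %>%
      group_by(.data$group) %>%
      arrange(dplyr::desc(.data$n)) %>%
      dplyr::slice(1) %>%
      ungroup()
    ren <- stats::setNames(relabel$chromosome, relabel$group)
    map$group <- ifelse(map$group %in% names(ren), ren[map$group], map$group)
  }
  attr(map, "unlinked") <- grp$unlinked
  attr(map, "pairs") <- pairs
  map
}
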