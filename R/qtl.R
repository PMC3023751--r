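#' Derive grain yield from its component traits
#'
#' Grain yield per plant is the literal product GY = SN * GN * HGW (spike
#' number x grains per spike x hundred-grain weight), computed on genotype
#' means of the components. HGW enters as hundred-grain weight without
#' division by 100, so GY is on a "per hundred grains" weight scale. An
#' individual missing any component gets a missing GY.
#'
#' @param traits Trait tibble `individual`, `trait`, `replicate`, `value`
#'   containing traits `SN`, `GN` and `HGW`.
#' @return The input with appended `GY` rows (one per individual,
#'   `replicate = 1`).
#' @export
derive_gy <- function(traits) {
  need <- c("SN", "GN", "HGW")
  if (!all(need %in% unique(traits$trait))) {
    abort("traits SN, GN and HGW are required to derive GY")
  }
  means <- traits %>%
    filter(.data$trait %in% need) %>%
    group_by(.data$individual, .data$trait) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  for (tr in need) if (!tr %in% names(means)) means[[tr]] <- NA_real_
  gy <- means %>%
    mutate(trait = "GY", replicate = 1L,
           value = .data$SN * .data$GN * .data$HGW) %>%
    select("individual", "trait", "replicate", "value")
  bind_rows(traits, gy)
}

#' Per-individual line means of a trait table
#'
#' @param traits Trait tibble `individual`, `trait`, `replicate`, `value`.
#' @param trait Trait name to extract.
#' @return Tibble `individual`, `value` (mean over non-missing replicates).
#' @export
line_means <- function(traits, trait) {
  traits %>%
    filter(.data$trait == !!trait) %>%
    group_by(.data$individual) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

# combine the markers of each map bin into one +1/-1/NA call row per bin
bin_call_matrix <- function(calls, map) {
  mat <- geno_matrix(calls)
  groups <- unique(map$group)
  out <- lapply(groups, function(grp) {
    gm <- map[map$group == grp, ]
    gm <- gm[gm$marker %in% rownames(mat), ]
    bins <- split(gm, gm$bin)
    pos <- vapply(bins, function(b) b$pos_cM[1], 0)
    o <- order(pos)
    bins <- bins[o]; pos <- pos[o]
    score <- t(vapply(bins, function(b) {
      sub <- mat[b$marker, , drop = FALSE]
      a <- colSums(sub == "A", na.rm = TRUE)
      b2 <- colSums(sub == "B", na.rm = TRUE)
      ifelse(a > 0 & b2 == 0, 1, ifelse(b2 > 0 & a == 0, -1, NA_real_))
    }, numeric(ncol(mat))))
    list(pos = unname(pos), score = score)
  })
  names(out) <- groups
  list(groups = out, individuals = colnames(mat))
}

#' Expected genotype score on a cM grid
#'
#' Codes DH genotypes +1 (parent A) / -1 (parent B) at markers and, between
#' flanking informative markers, takes the conditional expectation under
#' Haldane no-interference recombination probabilities (Haley-Knott
#' regression scores). With one informative flank at distance d the score is
#' the flank call shrunk by (1 - 2 r(d)); with none, 0 (uninformative,
#' flagged). At an observed marker the score equals the hard call. The grid
#' covers each linkage group from 0 to its length at `step_cM` (the walk
#' speed), always including the terminal position.
#'
#' @param calls Long genotype call tibble.
#' @param map A `rad_map` (or tibble `marker`, `group`, `bin`, `pos_cM`).
#' @param step_cM Grid step (walk speed), cM.
#' @return A `rad_expectation` list: `grid` (tibble `group`, `pos_cM`),
#'   `scores` (matrix positions x individuals), `individuals`,
#'   `uninformative` (tibble of individual x group flags), `step_cM`.
#' @export
genotype_expectation <- function(calls, map, step_cM = 1) {
  bc <- bin_call_matrix(calls, map)
  grid_list <- list()
  score_list <- list()
  uninf <- list()
  for (grp in names(bc$groups)) {
    g <- bc$groups[[grp]]
    pmax_ <- max(g$pos)
    grid <- seq(0, pmax_, by = step_cM)
    if (utils::tail(grid, 1) < pmax_) grid <- c(grid, pmax_)
    sc <- matrix(0, length(grid), length(bc$individuals),
                 dimnames = list(NULL, bc$individuals))
    for (i in seq_along(bc$individuals)) {
      x <- g$score[, i]
      obs <- which(!is.na(x))
      if (!length(obs)) {
        uninf[[length(uninf) + 1]] <- tibble(individual = bc$individuals[i],
                                             group = grp)
        next
      }
      opos <- g$pos[obs]
      oval <- x[obs]
      li <- findInterval(grid, opos)          # last obs position <= grid
      at_marker <- li >= 1 & opos[pmax(li, 1)] == grid
      ri <- ifelse(at_marker, li, li + 1L)    # first obs position >= grid
      has_l <- li >= 1
      has_r <- ri <= length(opos)
      s <- numeric(length(grid))
      # exactly at an observed marker
      s[at_marker] <- oval[li[at_marker]]
      # interior: both flanks observed
      both <- !at_marker & has_l & has_r
      if (any(both)) {
        rl <- haldane_inverse(grid[both] - opos[li[both]])
        rr <- haldane_inverse(opos[ri[both]] - grid[both])
        xl <- oval[li[both]]
        xr <- oval[ri[both]]
        same <- xl == xr
        p_same <- (1 - rl) * (1 - rr) / ((1 - rl) * (1 - rr) + rl * rr)
        p_left <- (1 - rl) * rr / ((1 - rl) * rr + rl * (1 - rr))
        s[both] <- ifelse(same, xl * (2 * p_same - 1), xl * (2 * p_left - 1))
      }
      # one flank only
      lonly <- !at_marker & has_l & !has_r
      s[lonly] <- oval[li[lonly]] *
        (1 - 2 * haldane_inverse(grid[lonly] - opos[li[lonly]]))
      ronly <- !at_marker & !has_l & has_r
      s[ronly] <- oval[ri[ronly]] *
        (1 - 2 * haldane_inverse(opos[ri[ronly]] - grid[ronly]))
      sc[, i] <- s
    }
    grid_list[[grp]] <- tibble(group = grp, pos_cM = grid)
    score_list[[grp]] <- sc
  }
  structure(list(
    grid = bind_rows(grid_list),
    scores = do.call(rbind, score_list),
    individuals = bc$individuals,
    uninformative = if (length(uninf)) bind_rows(uninf) else
      tibble(individual = character(0), group = character(0)),
    step_cM = step_cM
  ), class = "rad_expectation")
}

#' @export
print.rad_expectation <- function(x, ...) {
  cat("<rad_expectation> ", nrow(x$grid), " grid positions x ",
      length(x$individuals), " individuals (step ", x$step_cM, " cM)\n",
      sep = "")
  invisible(x)
}

#' @method tidy rad_expectation
#' @export
tidy.rad_expectation <- function(x, ...) {
  tibble(
    group = rep(x$grid$group, times = length(x$individuals)),
    pos_cM = rep(x$grid$pos_cM, times = length(x$individuals)),
    individual = rep(x$individuals, each = nrow(x$grid)),
    score = as.vector(x$scores)
  )
}

# +1/-1 marker score matrix (individuals x markers), NA -> 0, for cofactors
marker_score_matrix <- function(calls, markers, individuals) {
  mat <- geno_matrix(calls)[markers, individuals, drop = FALSE]
  s <- matrix(0, length(individuals), length(markers),
              dimnames = list(individuals, markers))
  s[t(mat == "A") %in% TRUE] <- 1
  s[t(mat == "B") %in% TRUE] <- -1
  s
}

#' Stepwise cofactor selection for composite interval mapping
#'
#' Forward-selection / backward-elimination regression of the line-mean trait
#' on marker scores (+1/-1, missing coded 0): at each forward step the
#' candidate with the smallest partial-F p-value below `alpha` enters; any
#' selected marker whose p-value rises to `alpha` or above is then dropped;
#' iterated to a fixed point or `max_cofactors`. Only bin-representative
#' markers are eligible (co-segregating markers are collinear).
#'
#' @param calls Long genotype call tibble.
#' @param map A `rad_map`.
#' @param trait Tibble `individual`, `value` (line means), or a vector named
#'   by individual.
#' @param max_cofactors Maximum markers retained (0 reduces CIM to simple
#'   interval mapping).
#' @param alpha Entry/stay significance threshold.
#' @return Character vector of selected marker ids.
#' @export
select_cofactors <- function(calls, map, trait, max_cofactors = 7,
                             alpha = 0.1) {
  trait <- as_trait_vector(trait)
  individuals <- names(trait)
  if (length(individuals) < 10) abort("need trait values for >= 10 individuals")
  reps <- map %>%
    group_by(.data$group, .data$bin) %>%
    summarise(marker = .data$marker[1], .groups = "drop") %>%
    pull(.data$marker)
  C <- marker_score_matrix(calls, reps, individuals)
  y <- unname(trait)
  n <- length(y)
  if (max_cofactors == 0) return(character(0))

  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(selected) < max_cofactors) {
      X0 <- cbind(1, C[, selected, drop = FALSE])
      q <- qr(X0)
      Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
      ry <- y - Q %*% crossprod(Q, y)
      cand <- setdiff(reps, selected)
      RC <- C[, cand, drop = FALSE]
      RC <- RC - Q %*% crossprod(Q, RC)
      ssc <- colSums(RC^2)
      gain <- ifelse(ssc > 1e-10, colSums(RC * as.vector(ry))^2 / ssc, 0)
      rss0 <- sum(ry^2)
      rss1 <- rss0 - gain
      df2 <- n - q$rank - 1
      fstat <- ifelse(rss1 > 1e-12, gain / (rss1 / df2), Inf)
      pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
      best <- which.min(pval)
      if (length(best) && df2 > 0 && pval[best] < alpha) {
        selected <- c(selected, cand[best])
        changed <- TRUE
      }
    }
    # backward step: drop any member whose partial p >= alpha (worst first)
    repeat {
      if (length(selected) < 1) break
      pvals <- vapply(selected, function(m) {
        others <- setdiff(selected, m)
        partial_f_p(y, C[, others, drop = FALSE], C[, m])
      }, 0)
      worst <- which.max(pvals)
      if (pvals[worst] >= alpha) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed || length(selected) >= max_cofactors) break
  }
  selected
}

partial_f_p <- function(y, X_others, x_new) {
  n <- length(y)
  X0 <- cbind(1, X_others)
  q <- qr(X0)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  ry <- y - Q %*% crossprod(Q, y)
  rc <- x_new - Q %*% crossprod(Q, x_new)
  ssc <- sum(rc^2)
  if (ssc <= 1e-10) return(1)
  gain <- sum(rc * ry)^2 / ssc
  rss1 <- sum(ry^2) - gain
  df2 <- n - q$rank - 1
  if (df2 <= 0 || rss1 <= 1e-12) return(0)
  stats::pf(gain / (rss1 / df2), 1, df2, lower.tail = FALSE)
}

as_trait_vector <- function(trait) {
  if (is.data.frame(trait)) {
    stats::setNames(trait$value, trait$individual)
  } else {
    if (is.null(names(trait))) abort("trait vector must be named by individual")
    trait
  }
}

# precomputed regression machinery for fast (permutation) scans:
# per grid position, orthonormal bases of the cofactor-only (X0) and
# cofactor-plus-score (X1) design matrices, with the window exclusion applied
cim_machine <- function(expect, calls, map, cofactors, window_cM) {
  individuals <- expect$individuals
  n <- length(individuals)
  C <- if (length(cofactors)) {
    marker_score_matrix(calls, cofactors, individuals)
  } else matrix(0, n, 0)
  cof_pos <- if (length(cofactors)) {
    map[match(cofactors, map$marker), c("group", "pos_cM")]
  } else tibble(group = character(0), pos_cM = numeric(0))

  np <- nrow(expect$grid)
  incl_key <- character(np)
  incl_list <- vector("list", np)
  for (p in seq_len(np)) {
    excl <- cof_pos$group == expect$grid$group[p] &
      abs(cof_pos$pos_cM - expect$grid$pos_cM[p]) <= window_cM
    incl_list[[p]] <- which(!excl)
    incl_key[p] <- paste(incl_list[[p]], collapse = ",")
  }
  patterns <- unique(incl_key)
  pat_idx <- match(incl_key, patterns)
  Q0s <- lapply(patterns, function(k) {
    idx <- incl_list[[match(k, incl_key)]]
    X0 <- cbind(1, C[, idx, drop = FALSE])
    q <- qr(X0)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  })

  Q1s <- vector("list", np)
  skip <- logical(np)
  for (p in seq_len(np)) {
    X1 <- cbind(1, C[, incl_list[[p]], drop = FALSE], expect$scores[p, ])
    q <- qr(X1)
    if (n - q$rank < 1) { skip[p] <- TRUE; next }
    Q1s[[p]] <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  list(n = n, C = C, incl_list = incl_list, pat_idx = pat_idx,
       Q0s = Q0s, Q1s = Q1s, skip = skip,
       grid = expect$grid, scores = expect$scores)
}

# LOD profiles for a matrix of trait vectors (columns); returns positions x m
cim_lod_matrix <- function(machine, Y) {
  Y <- as.matrix(Y)
  tss <- colSums(Y^2)
  keep <- which(!machine$skip)
  bigQ1 <- do.call(cbind, machine$Q1s[keep])
  id1 <- rep(seq_along(keep), vapply(machine$Q1s[keep], ncol, 0L))
  expl1 <- rowsum((crossprod(bigQ1, Y))^2, id1)
  bigQ0 <- do.call(cbind, machine$Q0s)
  id0 <- rep(seq_along(machine$Q0s), vapply(machine$Q0s, ncol, 0L))
  expl0 <- rowsum((crossprod(bigQ0, Y))^2, id0)
  pat_of <- machine$pat_idx[keep]

  rss1 <- pmax(sweep(-expl1, 2, tss, "+"), 0)
  rss0 <- pmax(sweep(-expl0[pat_of, , drop = FALSE], 2, tss, "+"), 0)
  lr <- machine$n * log(ifelse(rss1 > 1e-12, rss0 / rss1, 1))
  lr[rss0 <= 1e-12] <- 0
  lod <- matrix(NA_real_, nrow(machine$grid), ncol(Y))
  lod[keep, ] <- 0.217 * pmax(lr, 0)
  lod
}

#' Composite interval mapping scan for a DH trait
#'
#' At each grid position the line-mean trait is regressed on the expected
#' genotype score plus the background cofactors, excluding any cofactor
#' mapping within `window_cM` of the scanned position. The likelihood ratio
#' against the cofactor-only model is LR = n ln(RSS0 / RSS1), reported as
#' LOD = 0.217 LR (the QTL-mapping convention; 0.217 is used verbatim rather
#' than 1 / (2 ln 10)). The additive effect is the regression coefficient on
#' the score, i.e. half the fitted contrast between the two genotype classes,
#' and R2 is the share of total trait variance explained by the score term,
#' (RSS0 - RSS1) / TSS. With zero cofactors the scan reduces exactly to
#' simple interval mapping. Positions with fewer residual degrees of freedom
#' than parameters are skipped (LOD `NA`).
#'
#' @param calls Long genotype call tibble.
#' @param map A `rad_map`.
#' @param trait Line-mean trait: tibble `individual`, `value` or named vector.
#' @param cofactors Character vector of cofactor markers (e.g. from
#'   [select_cofactors()]); `NULL` or empty for simple interval mapping.
#' @param window_cM Cofactor exclusion window around the scanned position.
#' @param step_cM Walk speed (grid step), cM.
#' @param threshold Optional genome-wide LOD threshold (from
#'   [permutation_threshold()]) used to declare QTL.
#' @param trait_name Label for the scan.
#' @return A `rad_qtl_scan` list: `scan` (tibble `group`, `pos_cM`, `lod`,
#'   `additive`, `r2`), `trait`, `cofactors`, `threshold`, `qtl` (declared
#'   peaks with 2-LOD support intervals when a threshold is given), plus the
#'   walk/window settings.
#' @export
cim_scan <- function(calls, map, trait, cofactors = NULL, window_cM = 50,
                     step_cM = 1, threshold = NA_real_,
                     trait_name = "trait") {
  trait <- as_trait_vector(trait)
  expect <- genotype_expectation(calls, map, step_cM = step_cM)
  ord <- match(expect$individuals, names(trait))
  if (anyNA(ord)) abort("trait values missing for some genotyped individuals")
  y <- unname(trait[ord])
  machine <- cim_machine(expect, calls, map, cofactors %||% character(0),
                         window_cM)
  lod <- cim_lod_matrix(machine, matrix(y, ncol = 1))[, 1]

  np <- nrow(expect$grid)
  additive <- rep(NA_real_, np)
  r2 <- rep(NA_real_, np)
  tss <- sum((y - mean(y))^2)
  for (p in which(!machine$skip)) {
    X1 <- cbind(1, machine$C[, machine$incl_list[[p]], drop = FALSE],
                machine$scores[p, ])
    fit <- stats::lm.fit(X1, y)
    cf <- fit$coefficients
    additive[p] <- cf[length(cf)]
    Q0 <- machine$Q0s[[machine$pat_idx[p]]]
    rss0 <- sum(y^2) - sum(crossprod(Q0, y)^2)
    rss1 <- sum(fit$residuals^2)
    r2[p] <- if (tss > 0) max(rss0 - rss1, 0) / tss else NA_real_
  }

  scan <- tibble(group = expect$grid$group, pos_cM = expect$grid$pos_cM,
                 lod = lod, additive = additive, r2 = r2)
  obj <- structure(list(
    trait = trait_name, scan = scan, cofactors = cofactors %||% character(0),
    threshold = threshold, window_cM = window_cM, step_cM = step_cM,
    n = machine$n, qtl = NULL
  ), class = "rad_qtl_scan")
  obj$qtl <- declare_qtl(obj, threshold)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Declare QTL from a scan and a threshold
#'
#' For each linkage group whose maximum LOD exceeds the threshold, reports the
#' peak with its 2-LOD support interval.
#'
#' @param scan A `rad_qtl_scan`.
#' @param threshold Genome-wide LOD threshold.
#' @param drop LOD drop defining the support interval.
#' @return Tibble `trait`, `group`, `pos_cM`, `lod`, `additive`, `r2`,
#'   `ci_lo`, `ci_hi`, `threshold` (zero rows if threshold is `NA`).
#' @export
declare_qtl <- function(scan, threshold, drop = 2) {
  empty <- tibble(trait = character(0), group = character(0),
                  pos_cM = numeric(0), lod = numeric(0), additive = numeric(0),
                  r2 = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
                  threshold = numeric(0))
  if (is.na(threshold)) return(empty)
  s <- scan$scan
  out <- list()
  for (grp in unique(s$group)) {
    g <- s[s$group == grp & !is.na(s$lod), ]
    if (!nrow(g)) next
    pk <- which.max(g$lod)
    if (g$lod[pk] <= threshold) next
    ci <- support_interval(scan, peak = list(group = grp, pos_cM = g$pos_cM[pk]),
                           drop = drop)
    out[[length(out) + 1]] <- tibble(
      trait = scan$trait, group = grp, pos_cM = g$pos_cM[pk], lod = g$lod[pk],
      additive = g$additive[pk], r2 = g$r2[pk],
      ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, threshold = threshold
    )
  }
  if (length(out)) bind_rows(out) else empty
}

#' 2-LOD support interval around a scan peak
#'
#' The widest contiguous interval around the peak where LOD stays within
#' `drop` of the peak LOD, truncated at the ends of the linkage group.
#'
#' @param scan A `rad_qtl_scan`.
#' @param peak List/row with `group` and `pos_cM`; defaults to the global
#'   maximum of the scan.
#' @param drop LOD units dropped from the peak.
#' @return One-row tibble `group`, `ci_lo`, `ci_hi`.
#' @export
support_interval <- function(scan, peak = NULL, drop = 2) {
  s <- scan$scan
  if (is.null(peak)) {
    i <- which.max(s$lod)
    peak <- list(group = s$group[i], pos_cM = s$pos_cM[i])
  }
  g <- s[s$group == peak$group, ]
  g <- g[order(g$pos_cM), ]
  pk <- which.min(abs(g$pos_cM - peak$pos_cM))
  keep <- !is.na(g$lod) & g$lod >= g$lod[pk] - drop
  lo <- pk; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < nrow(g) && keep[hi + 1]) hi <- hi + 1
  tibble(group = peak$group, ci_lo = g$pos_cM[lo], ci_hi = g$pos_cM[hi])
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the trait values across individuals (breaking the
#' genotype-phenotype link while keeping the marker structure), re-runs the
#' scan for each permutation, and returns the empirical (1 - alpha) quantile
#' of the genome-wide maximum LOD. Reproducible bit-for-bit for a fixed seed.
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (warns below 100: unstable quantile).
#' @param alpha Genome-wide significance level.
#' @param seed Random seed.
#' @return The LOD threshold (numeric scalar) with the permutation maxima as
#'   attribute `max_lods`.
#' @export
permutation_threshold <- function(calls, map, trait, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, cofactors = NULL,
                                  window_cM = 50, step_cM = 1) {
  if (n_perm < 100) warn("n_perm < 100 gives an unstable quantile")
  trait <- as_trait_vector(trait)
  expect <- genotype_expectation(calls, map, step_cM = step_cM)
  y <- unname(trait[match(expect$individuals, names(trait))])
  machine <- cim_machine(expect, calls, map, cofactors %||% character(0),
                         window_cM)
  if (!is.null(seed)) withr::local_seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
              numeric(length(y)))
  lods <- cim_lod_matrix(machine, Y)
  max_lods <- apply(lods, 2, max, na.rm = TRUE)
  th <- stats::quantile(max_lods, 1 - alpha, names = FALSE, type = 7)
  attr(th, "max_lods") <- max_lods
  th
}

#' Broad-sense heritability from replicated trait data
#'
#' One-way random-effects decomposition over genotypes: the residual variance
#' sigmae2 is the within-genotype mean square, the genetic variance sigmaG2 is
#' (between-MS - within-MS) / r clamped at zero, and
#' H2 = sigmaG2 / (sigmaG2 + sigmae2 / r) with r replicates per genotype.
#' Requires a balanced design with r >= 2.
#'
#' @param traits Trait tibble `individual`, `trait`, `replicate`, `value`.
#' @return Tibble `trait`, `sigma_G2`, `sigma_e2`, `r`, `H2`.
#' @export
estimate_heritability <- function(traits) {
  bind_rows(lapply(unique(traits$trait), function(tr) {
    d <- filter(traits, .data$trait == !!tr, !is.na(.data$value))
    reps <- table(d$individual)
    if (any(reps < 2)) abort(paste0("trait ", tr, ": need >= 2 replicates per genotype"))
    if (length(unique(reps)) != 1) abort(paste0("trait ", tr, ": unbalanced replicates"))
    r <- unname(reps[1])
    an <- stats::anova(lm(value ~ factor(individual), data = d))
    ms_between <- an$`Mean Sq`[1]
    ms_within <- an$`Mean Sq`[2]
    sigma_g2 <- max(0, (ms_between - ms_within) / r)
    h2 <- if (sigma_g2 == 0) 0 else sigma_g2 / (sigma_g2 + ms_within / r)
    tibble(trait = tr, sigma_G2 = sigma_g2, sigma_e2 = ms_within,
           r = as.integer(r), H2 = h2)
  }))
}
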