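# simple deterministic map + calls used across QTL tests
flat_map <- function(markers, spacing = 10, group = "LG1") {
  tibble::tibble(marker = markers, group = group,
                 bin = seq_along(markers),
                 pos_cM = spacing * (seq_along(markers) - 1))
}

test_that("GY is the literal product of its components", {
  traits <- tibble::tibble(
    individual = rep(c("d1", "d2", "d3"), each = 3),
    trait = rep(c("SN", "GN", "HGW"), 3),
    replicate = 1L,
    value = c(2, 30, 5,   0, 10, 4,   3, 20, NA)
  )
  out <- derive_gy(traits)
  gy <- out[out$trait == "GY", ]
  expect_equal(gy$value[gy$individual == "d1"], 300)
  expect_equal(gy$value[gy$individual == "d2"], 0)
  expect_true(is.na(gy$value[gy$individual == "d3"]))
  expect_error(derive_gy(traits[traits$trait != "HGW", ]), "HGW")
})

test_that("expected genotype score interpolates Haldane probabilities", {
  calls <- calls_from_rows(list(L = c("A", "A", "B", NA),
                                R = c("A", "B", "B", "A")),
                           individuals = c("aa", "ab", "bb", "na"))
  map <- flat_map(c("L", "R"), spacing = 20)
  ex <- genotype_expectation(calls, map, step_cM = 10)
  sc <- ex$scores
  mid <- which(ex$grid$pos_cM == 10)
  # at markers the score is the hard call; a missing call there falls back to
  # the other flank shrunk by 1 - 2r over its distance
  expect_equal(unname(sc[1, c("aa", "ab", "bb")]), c(1, 1, -1))
  expect_equal(unname(sc[1, "na"]), 1 * (1 - 2 * haldane_inverse(20)),
               tolerance = 1e-12)
  # enumeration oracle for the A,A midpoint: four flank-interior paths
  r <- haldane_inverse(10)
  p_same <- (1 - r)^2 / ((1 - r)^2 + r^2)
  expect_equal(unname(sc[mid, "aa"]), 2 * p_same - 1, tolerance = 1e-12)
  # opposite flanks at the midpoint cancel by symmetry
  expect_equal(unname(sc[mid, "ab"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc[mid, "bb"]), -(2 * p_same - 1), tolerance = 1e-12)
  # single informative flank decays by 1 - 2r
  expect_equal(unname(sc[mid, "na"]), 1 * (1 - 2 * haldane_inverse(10)),
               tolerance = 1e-12)
  # scores always within [-1, 1] and equal to calls at observed markers
  expect_true(all(sc >= -1 & sc <= 1))
  expect_equal(unname(sc[nrow(sc), c("aa", "ab", "bb")]), c(1, -1, -1))
})

test_that("expectation at an observed marker equals the hard call", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 10, n = 20,
                 miss_rate = 0.1, seed = 160)
  map <- build_linkage_map(s$calls, min_lod = 3)
  ex <- genotype_expectation(s$calls, map, step_cM = 1)
  m <- tidy(map)
  mat <- geno_matrix(s$calls)
  for (k in seq_len(nrow(m))) {
    row <- which(ex$grid$group == m$group[k] &
                   abs(ex$grid$pos_cM - m$pos_cM[k]) < 1e-9)
    if (!length(row)) next
    obs <- mat[m$marker[k], ]
    hard <- ifelse(is.na(obs), NA, ifelse(obs == "A", 1, -1))
    idx <- !is.na(hard)
    expect_true(all(ex$scores[row[1], idx] == hard[idx]))
  }
  # an individual missing a whole group scores 0 everywhere and is flagged
  calls2 <- s$calls
  first <- calls2$individual[1]
  calls2$call[calls2$individual == first] <- NA
  ex2 <- genotype_expectation(calls2, map)
  expect_true(first %in% ex2$uninformative$individual)
  expect_true(all(ex2$scores[, ex2$individuals == first] == 0))
})

test_that("cofactor selection finds a planted QTL and respects the cap", {
  s <- sim_calls(n_chromosomes = 2, loci_per_chromosome = 10, n = 93,
                 seed = 170)
  map <- build_linkage_map(s$calls, min_lod = 5)
  ph <- simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0005",
                                                    effect = 2),
                            h2_target = 0.95, n_reps = 2, seed = 171)
  y <- line_means(ph, "trait1")
  sel <- select_cofactors(s$calls, map, y)
  expect_true("LOC0005" %in% sel)
  expect_lte(length(sel), 7)
  expect_equal(select_cofactors(s$calls, map, y, max_cofactors = 0),
               character(0))
})

test_that("pure-noise traits rarely recruit cofactors", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 10, n = 93,
                 seed = 180)
  map <- build_linkage_map(s$calls, min_lod = 5)
  picked <- 0
  for (i in 1:20) {
    withr::with_seed(1800 + i, {
      y <- tibble::tibble(individual = unique(s$calls$individual),
                          value = rnorm(93))
    })
    picked <- picked + (length(select_cofactors(s$calls, map, y)) > 0)
  }
  # each forward entry tests ~10 markers at alpha = 0.1 with a familywise
  # hit rate well under 1; expect no more than ~2/3 of null runs to recruit
  expect_lte(picked, 14)
})

test_that("CIM reduces to simple interval mapping without cofactors and
           reproduces LOD = 0.217 LR at every grid point", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 8, n = 93,
                 miss_rate = 0.05, seed = 190)
  map <- build_linkage_map(s$calls, min_lod = 5)
  ph <- simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0004",
                                                    effect = 1),
                            h2_target = 0.8, n_reps = 2, seed = 191)
  y <- line_means(ph, "trait1")
  sc <- cim_scan(s$calls, map, y, cofactors = NULL, step_cM = 2)
  ex <- genotype_expectation(s$calls, map, step_cM = 2)
  yy <- y$value[match(ex$individuals, y$individual)]
  for (p in seq_len(nrow(sc$scan))) {
    # independent route: two explicit least-squares fits at this position
    f1 <- lm(yy ~ ex$scores[p, ])
    rss1 <- sum(residuals(f1)^2)
    rss0 <- sum((yy - mean(yy))^2)
    lr <- length(yy) * log(rss0 / rss1)
    expect_equal(sc$scan$lod[p], 0.217 * lr, tolerance = 1e-8)
    expect_equal(sc$scan$additive[p], unname(coef(f1)[2]), tolerance = 1e-8)
  }
})

test_that("LOD is invariant to affine transformation of the trait", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 8, n = 60,
                 seed = 200)
  map <- build_linkage_map(s$calls, min_lod = 5)
  ph <- simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0003",
                                                    effect = 1),
                            h2_target = 0.7, n_reps = 2, seed = 201)
  y <- line_means(ph, "trait1")
  cof <- select_cofactors(s$calls, map, y)
  s1 <- cim_scan(s$calls, map, y, cofactors = cof)
  y2 <- dplyr::mutate(y, value = 3.7 * value - 11)
  s2 <- cim_scan(s$calls, map, y2, cofactors = cof)
  expect_equal(s1$scan$lod, s2$scan$lod, tolerance = 1e-9)
})

test_that("permutation threshold is reproducible, exchangeable and degenerate-safe", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 10, n = 50,
                 seed = 210)
  map <- build_linkage_map(s$calls, min_lod = 5)
  withr::with_seed(211, {
    y <- tibble::tibble(individual = unique(s$calls$individual),
                        value = rnorm(50))
  })
  t1 <- permutation_threshold(s$calls, map, y, n_perm = 200, seed = 5)
  t2 <- permutation_threshold(s$calls, map, y, n_perm = 200, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_identical(attr(t1, "max_lods"), attr(t2, "max_lods"))
  # invariant to permuting individual order in the input
  y3 <- y[rev(seq_len(nrow(y))), ]
  t3 <- permutation_threshold(s$calls, map, y3, n_perm = 200, seed = 5)
  expect_equal(as.numeric(t1), as.numeric(t3), tolerance = 1e-9)
  # constant trait: every LOD is 0
  yc <- dplyr::mutate(y, value = 1)
  tc <- permutation_threshold(s$calls, map, yc, n_perm = 120, seed = 5)
  expect_equal(as.numeric(tc), 0)
  expect_warning(permutation_threshold(s$calls, map, y, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("support intervals bracket the peak and handle flat profiles", {
  fake <- structure(list(
    trait = "t",
    scan = tibble::tibble(group = "LG1", pos_cM = 0:10,
                          lod = c(0, 1, 2, 4, 6, 7, 6, 4, 2, 1, 0),
                          additive = 0, r2 = 0),
    threshold = NA_real_, cofactors = character(0)
  ), class = "rad_qtl_scan")
  ci <- support_interval(fake)
  expect_equal(c(ci$ci_lo, ci$ci_hi), c(4, 6))   # lod >= 5 around the peak
  flat <- fake
  flat$scan$lod <- rep(5, 11)
  cif <- support_interval(flat)
  expect_equal(c(cif$ci_lo, cif$ci_hi), c(0, 10))  # whole group
})

test_that("heritability follows its formula and clamps at zero", {
  # sigmaG2 = 3, sigmae2 = 1, r = 2 -> H2 = 6/7, from constructed data:
  # within-genotype MS = 1 and between-genotype MS = 7 exactly
  g <- 40
  d <- tibble::tibble(
    individual = rep(sprintf("g%02d", 1:g), each = 2),
    trait = "t", replicate = rep(1:2, g),
    value = 0
  )
  withr::with_seed(220, {
    gm <- rnorm(g)
    gm <- (gm - mean(gm)) / sd(gm) * sqrt(7 / 2)   # between-MS = r * var = 7
    dev <- rep(c(-1, 1) / sqrt(2), g)              # within-MS = 1 exactly
  })
  d$value <- rep(gm, each = 2) + dev
  h <- estimate_heritability(d)
  expect_equal(h$sigma_G2, 3, tolerance = 1e-12)
  expect_equal(h$sigma_e2, 1, tolerance = 1e-12)
  expect_equal(h$H2, 6 / 7, tolerance = 1e-12)
  # identical genotype means with pure noise clamps H2 at 0
  d2 <- d
  d2$value <- dev
  h2 <- estimate_heritability(d2)
  expect_equal(h2$sigma_G2, 0)
  expect_equal(h2$H2, 0)
  expect_error(estimate_heritability(d[d$replicate == 1, ]), "replicates")
})

test_that("scan objects expose tidy, glance and declared QTL", {
  s <- sim_calls(n_chromosomes = 2, loci_per_chromosome = 10, n = 93,
                 seed = 230)
  map <- build_linkage_map(s$calls, min_lod = 5)
  ph <- simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0015",
                                                    effect = 1),
                            h2_target = 0.8, n_reps = 2, seed = 231)
  y <- line_means(ph, "trait1")
  th <- permutation_threshold(s$calls, map, y, n_perm = 200, seed = 7)
  sc <- cim_scan(s$calls, map, y, threshold = th, trait_name = "trait1")
  td <- tidy(sc)
  expect_true(all(c("trait", "group", "pos_cM", "lod", "additive", "r2")
                  %in% names(td)))
  gl <- glance(sc)
  expect_equal(gl$trait, "trait1")
  expect_gte(nrow(sc$qtl), 1)
  expect_true(all(sc$qtl$lod > as.numeric(th)))
  # the support interval contains the peak
  expect_true(all(sc$qtl$ci_lo <= sc$qtl$pos_cM &
                    sc$qtl$pos_cM <= sc$qtl$ci_hi))
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(map), "ggplot")
})
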