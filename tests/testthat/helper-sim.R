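# shared test helpers: genotype-level simulations and independent oracles

# long call tibble from a character matrix given as list of rows
calls_from_rows <- function(rows, individuals = NULL) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  colnames(mat) <- individuals %||% sprintf("I%02d", seq_len(ncol(mat)))
  geno_tibble(mat)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype-level DH simulation: returns calls + truth for mapping tests
sim_calls <- function(n_chromosomes = 1, loci_per_chromosome = 20,
                      inter_locus_cM = 5, n = 93, miss_rate = 0,
                      seed = 1) {
  cfg <- sim_config(n_chromosomes = n_chromosomes,
                    loci_per_chromosome = loci_per_chromosome,
                    inter_locus_cM = inter_locus_cM,
                    n_individuals = min(n, 93), seed = seed)
  truth <- simulate_dh_population(simulate_genome(cfg), n = n)
  calls <- geno_tibble(truth$inheritance)
  if (miss_rate > 0) {
    withr::with_seed(seed + 7919, {
      calls$call[runif(nrow(calls)) < miss_rate] <- NA
    })
  }
  list(calls = calls, truth = truth)
}

# independent brute-force oracle: all-pairs Hamming distances between two
# tag sets, written without the package's matcher machinery
oracle_hamming_pairs <- function(tags_a, tags_b, max_mismatch = 2) {
  out <- list()
  for (i in seq_along(tags_a)) {
    ai <- utf8ToInt(tags_a[i])
    for (j in seq_along(tags_b)) {
      d <- sum(ai != utf8ToInt(tags_b[j]))
      if (d <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(i = i, j = j, d = d)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(0), j = integer(0), d = integer(0))
}

# independent oracle classification built on the brute-force pair scan
oracle_panel_classes <- function(tags_a, tags_b, max_mismatch = 2) {
  pr <- oracle_hamming_pairs(tags_a, tags_b, max_mismatch)
  deg_a <- table(factor(pr$i, levels = seq_along(tags_a)))
  deg_b <- table(factor(pr$j, levels = seq_along(tags_b)))
  class_a <- rep("dominant_A", length(tags_a))
  for (i in seq_along(tags_a)) {
    if (deg_a[i] == 0) next
    js <- pr$j[pr$i == i]
    if (deg_a[i] == 1 && deg_b[js] == 1) {
      class_a[i] <- if (pr$d[pr$i == i] == 0) "monomorphic" else "codominant"
    } else {
      class_a[i] <- "ambiguous"
    }
  }
  class_a
}

random_tags <- function(n, seed, width = 22) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste0("TGCAGG", paste(sample(c("A", "C", "G", "T"), width,
                                    replace = TRUE), collapse = ""))
    }, "")
  })
}

# mutate one tag at k random positions after the 6-nt remnant
mutate_tag <- function(tag, k, seed) {
  withr::with_seed(seed, {
    chars <- strsplit(tag, "")[[1]]
    pos <- sample(7:nchar(tag), k)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  })
}
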