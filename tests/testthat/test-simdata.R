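test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_chromosomes = -1), "counts")
  expect_error(sim_config(snp_fraction = 1.2), "snp_fraction")
  expect_error(sim_config(error_rate = 1), "error_rate")
  bad <- tibble::tibble(sample_id = c("a", "b"), barcode = c("ACGT", "ACGT"),
                        role = c("parent_A", "parent_B"))
  expect_error(sim_config(barcodes = bad), "distinct")
  bad2 <- tibble::tibble(sample_id = c("a", "b"), barcode = c("ACGT", "ACGN"),
                         role = c("parent_A", "parent_B"))
  expect_error(sim_config(barcodes = bad2), "4-mers")
})

test_that("simulate_genome controls polymorphism fraction and SNP placement", {
  cfg0 <- sim_config(n_chromosomes = 2, loci_per_chromosome = 10,
                     snp_fraction = 0, seed = 3)
  g0 <- simulate_genome(cfg0)
  expect_true(all(g0$loci$allele_A == g0$loci$allele_B))
  expect_equal(sum(g0$loci$polymorphic), 0)

  cfg1 <- sim_config(n_chromosomes = 5, loci_per_chromosome = 20,
                     snp_fraction = 1, seed = 3)
  g1 <- simulate_genome(cfg1)
  expect_equal(sum(g1$loci$polymorphic), 100)
  expect_true(all(startsWith(g1$loci$allele_A, "TGCAGG")))
  expect_true(all(startsWith(g1$loci$allele_B, "TGCAGG")))
  expect_true(all(nchar(g1$loci$allele_A) == 28))
  snps <- unlist(g1$loci$snp_positions)
  expect_true(all(snps >= 6 & snps <= 27))   # 0-based, after the remnant
  nsnp <- lengths(g1$loci$snp_positions[g1$loci$polymorphic])
  expect_true(all(nsnp %in% 1:2))
  # declared SNP offsets are exactly where the alleles differ
  poly <- g1$loci[g1$loci$polymorphic, ]
  expect_equal(str_hamming(poly$allele_A, poly$allele_B),
               lengths(poly$snp_positions))
})

test_that("simulate_genome warns into zero polymorphic loci and is seed-stable", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10,
                    snp_fraction = 0.01, seed = 5)
  expect_warning(g <- simulate_genome(cfg), "zero polymorphic")
  expect_equal(sum(g$loci$polymorphic), 0)

  cfg2 <- sim_config(seed = 11)
  a <- simulate_genome(cfg2)
  b <- simulate_genome(cfg2)
  expect_identical(a$loci, b$loci)
})

test_that("DH population is homozygous with 1:1 segregation", {
  s <- sim_calls(n_chromosomes = 10, loci_per_chromosome = 100, n = 93,
                 seed = 2)   # 1000 loci
  inh <- s$truth$inheritance
  expect_true(all(inh %in% c("A", "B")))
  freq_a <- rowMeans(inh == "A")
  # mean across 1000 loci within 3 SD of 0.5 (SD of the mean of 1000
  # independent Binomial(93, 1/2) proportions)
  sd_mean <- sqrt(0.25 / 93 / 1000)
  expect_lt(abs(mean(freq_a) - 0.5), 3 * sd_mean)
  expect_error(simulate_dh_population(s$truth, n = 0), "n must be")
})

test_that("recombinant fraction converges to Haldane r(d)", {
  for (d in c(1, 5, 25, 50)) {
    cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 2,
                      inter_locus_cM = d, n_individuals = 10,
                      seed = 17 + d)
    truth <- simulate_dh_population(simulate_genome(cfg), n = 10000)
    inh <- truth$inheritance
    obs <- mean(inh[1, ] != inh[2, ])
    r <- (1 - exp(-2 * d / 100)) / 2
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / 10000))
  }
  # d = 0 gives zero recombinants
  cfg0 <- sim_config(n_chromosomes = 1, loci_per_chromosome = 2,
                     inter_locus_cM = 0, n_individuals = 10, seed = 4)
  t0 <- simulate_dh_population(simulate_genome(cfg0), n = 500)
  expect_equal(sum(t0$inheritance[1, ] != t0$inheritance[2, ]), 0)
})

test_that("read simulation respects layout, depth and error model", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10,
                    n_individuals = 5, mean_depth = 8, parent_mean_depth = 8,
                    depth_dispersion = Inf, error_rate = 0, seed = 6)
  truth <- simulate_dh_population(simulate_genome(cfg))
  reads <- simulate_reads(truth, cfg)
  expect_true(all(nchar(reads$sequence) == 36))
  # with zero error every read's tag equals its source allele
  loci <- truth$loci
  src <- ifelse(reads$source_allele == "A",
                loci$allele_A[match(reads$locus_id, loci$locus_id)],
                loci$allele_B[match(reads$locus_id, loci$locus_id)])
  expect_true(all(substr(reads$sequence, 5, 32) == src))
  # barcode prefix identifies the sample
  bc <- cfg$barcodes$barcode[match(reads$sample_id, cfg$barcodes$sample_id)]
  expect_true(all(substr(reads$sequence, 1, 4) == bc))

  # zero depth -> no reads
  cfg0 <- sim_config(n_chromosomes = 1, loci_per_chromosome = 5,
                     n_individuals = 2, mean_depth = 0, parent_mean_depth = 0,
                     seed = 6)
  t0 <- simulate_dh_population(simulate_genome(cfg0))
  expect_equal(nrow(simulate_reads(t0, cfg0)), 0)
})

test_that("observed base-error rate matches the configured rate", {
  cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 30,
                    n_individuals = 70, mean_depth = 30, parent_mean_depth = 30,
                    error_rate = 0.001, seed = 8)
  truth <- simulate_dh_population(simulate_genome(cfg))
  reads <- simulate_reads(truth, cfg)
  n_bases <- nrow(reads) * 36
  expect_gt(nrow(reads), 1e5)
  obs <- sum(reads$n_errors) / n_bases
  expect_lt(abs(obs - 0.001), 3 * sqrt(0.001 * 0.999 / n_bases))
})

test_that("same seed gives byte-identical FASTQ", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10,
                    n_individuals = 5, seed = 12)
  truth <- simulate_dh_population(simulate_genome(cfg))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(truth, cfg, fastq = f1)
  simulate_reads(truth, cfg, fastq = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("phenotype simulation hits its design points", {
  s <- sim_calls(n_chromosomes = 1, loci_per_chromosome = 5, n = 40, seed = 9)
  # single QTL, no noise: exactly two values, difference 2a
  ph <- simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0003",
                                                    effect = 1.5),
                            h2_target = 1, n_reps = 2)
  vals <- sort(unique(ph$value))
  expect_length(vals, 2)
  expect_equal(diff(vals), 3)
  expect_error(
    simulate_phenotypes(s$truth, tibble::tibble(locus_id = "LOC0001",
                                                effect = 1), h2_target = 0),
    "h2_target")
  expect_error(
    simulate_phenotypes(s$truth, tibble::tibble(locus_id = "NOPE", effect = 1)),
    "exist")
})

test_that("heritability recovery at the simulator's target", {
  s <- sim_calls(n_chromosomes = 2, loci_per_chromosome = 10, n = 200,
                 seed = 10)
  ph <- simulate_phenotypes(s$truth,
                            tibble::tibble(locus_id = c("LOC0004", "LOC0013"),
                                           effect = c(1, 0.5)),
                            h2_target = 0.9, n_reps = 2, seed = 23)
  h2 <- estimate_heritability(ph)
  expect_equal(h2$H2, 0.9, tolerance = 0.05 / 0.9)
})

test_that("high-copy repeat tags inflate depth and trip the cluster ceiling", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10,
                    n_individuals = 0, parent_mean_depth = 10,
                    depth_dispersion = Inf, error_rate = 0,
                    n_repeat_loci = 3, seed = 13)
  truth <- simulate_genome(cfg)
  rep_loci <- truth$loci[truth$loci$copy_number > 1, ]
  expect_equal(nrow(rep_loci), 3)
  expect_true(all(rep_loci$copy_number >= 20 & rep_loci$copy_number <= 100))
  expect_true(all(is.na(rep_loci$chrom)))
  log <- simulate_reads(truth, cfg)
  counts <- table(log$locus_id[log$sample_id == "PARENT_A"])
  # repeat loci emit roughly copy-number-fold reads
  expect_true(all(counts[rep_loci$locus_id] >
                    5 * median(counts[truth$loci$locus_id[
                      truth$loci$copy_number == 1]])))
  # and the 500x ceiling removes the saturated clusters
  dmx <- demultiplex(tibble::tibble(read_id = log$read_id,
                                    sequence = log$sequence),
                     cfg$barcodes[, c("sample_id", "barcode")])
  cl <- cluster_tags(dmx$tags)
  pa <- cl[cl$sample_id == "PARENT_A", ]
  kept <- filter_clusters(pa)
  over <- pa$tag[pa$depth > 500]
  expect_true(length(over) > 0)
  expect_false(any(over %in% kept$tag))
})
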