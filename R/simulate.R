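#' Configuration for a simulated RAD experiment
#'
#' Bundles the knobs of the simulator: the genome of restriction-site tags,
#' the doubled-haploid (DH) population design, the sequencing depth and error
#' model, and the sample barcoding. Defaults describe a desk-scale experiment
#' with the structure of a cereal DH RAD experiment: 7 chromosomes, evenly spaced
#' tag loci, a 93-line DH population genotyped at modest depth, and deeply
#' sequenced parents.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param loci_per_chromosome Restriction-site tag loci per chromosome.
#' @param inter_locus_cM Map distance between adjacent loci, in centimorgans.
#' @param snp_fraction Proportion of loci polymorphic between the two parents.
#' @param n_individuals Number of DH lines.
#' @param mean_depth Mean sequencing depth per locus per DH individual.
#' @param parent_mean_depth Mean depth per locus for each parent (parents are
#'   sequenced more deeply than progeny, as SNP discovery requires).
#' @param depth_dispersion Negative-binomial size parameter for read depth
#'   (variance = mu + mu^2/size); `Inf` gives Poisson depth.
#' @param error_rate Per-base substitution probability.
#' @param n_repeat_loci Number of high-copy repetitive tags (copy number drawn
#'   uniformly in 20..100); these are unplaced and monomorphic.
#' @param barcodes Optional tibble `sample_id`, `barcode` (distinct 4-mers over
#'   ACGT), `role` in `"parent_A"`, `"parent_B"`, `"progeny"`. Generated
#'   deterministically when `NULL`.
#' @param seed Random seed used by [simulate_genome()] and downstream steps
#'   unless overridden.
#' @return A `rad_sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 7, loci_per_chromosome = 20,
                       inter_locus_cM = 5, snp_fraction = 1,
                       n_individuals = 93, mean_depth = 10,
                       parent_mean_depth = 50, depth_dispersion = 10,
                       error_rate = 0.001, n_repeat_loci = 0,
                       barcodes = NULL, seed = 1L) {
  counts <- c(n_chromosomes = n_chromosomes,
              loci_per_chromosome = loci_per_chromosome,
              n_individuals = n_individuals, n_repeat_loci = n_repeat_loci)
  if (any(counts < 0)) abort("all counts must be >= 0")
  if (snp_fraction < 0 || snp_fraction > 1) abort("snp_fraction must be in [0, 1]")
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  if (inter_locus_cM < 0) abort("inter_locus_cM must be >= 0")
  if (mean_depth < 0 || parent_mean_depth < 0) abort("depths must be >= 0")
  if (is.null(barcodes)) barcodes <- default_barcodes(n_individuals)
  validate_barcodes(barcodes)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    inter_locus_cM = inter_locus_cM,
    snp_fraction = snp_fraction,
    n_individuals = as.integer(n_individuals),
    mean_depth = mean_depth,
    parent_mean_depth = parent_mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    n_repeat_loci = as.integer(n_repeat_loci),
    barcodes = barcodes,
    seed = as.integer(seed)
  ), class = "rad_sim_config")
}

default_barcodes <- function(n_individuals) {
  n <- n_individuals + 2L
  if (n > 256L) abort("at most 254 individuals with generated 4-nt barcodes")
  all4 <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES,
                                      stringsAsFactors = FALSE)[, 4:1])
  ids <- c("PARENT_A", "PARENT_B", sprintf("DH_%03d", seq_len(n_individuals)))
  tibble(sample_id = ids, barcode = sort(all4)[seq_len(n)],
         role = c("parent_A", "parent_B", rep("progeny", n_individuals)))
}

validate_barcodes <- function(barcodes) {
  stopifnot(all(c("sample_id", "barcode", "role") %in% names(barcodes)))
  if (anyDuplicated(barcodes$barcode)) abort("barcodes must be distinct")
  if (anyDuplicated(barcodes$sample_id)) abort("sample ids must be distinct")
  ok <- grepl("^[ACGT]{4}$", barcodes$barcode)
  if (!all(ok)) abort("barcodes must be 4-mers over {A,C,G,T}")
  invisible(barcodes)
}

#' Simulate the parental tag genome
#'
#' Draws one 28-nt tag per locus per parent, each beginning with the SbfI
#' remnant TGCAGG. A fraction `snp_fraction` of the placed loci is polymorphic
#' between parents, carrying 1-2 substitutions confined to the 22 genomic
#' positions after the remnant. `n_repeat_loci` additional unplaced
#' monomorphic tags model high-copy repeats (copy number uniform in 20..100).
#'
#' @param config A [sim_config()] object.
#' @return A `rad_truth` list with `loci` (tibble: `locus_id`, `chrom`,
#'   `pos_cM`, `allele_A`, `allele_B`, `snp_positions` list-column of 0-based
#'   offsets, `copy_number`, `polymorphic`) and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "rad_sim_config"))
  withr::local_seed(config$seed)
  n_placed <- config$n_chromosomes * config$loci_per_chromosome
  n_loci <- n_placed + config$n_repeat_loci

  # distinct random tag cores; duplicates re-drawn
  cores <- random_dna(n_loci, TAG_LENGTH - 6L)
  while (anyDuplicated(cores)) {
    dup <- duplicated(cores)
    cores[dup] <- random_dna(sum(dup), TAG_LENGTH - 6L)
  }
  tags <- paste0(SBFI_REMNANT, cores)

  n_poly <- round(config$snp_fraction * n_placed)
  if (config$snp_fraction > 0 && n_poly < 1) {
    warn("snp_fraction * n_loci < 1: zero polymorphic loci simulated")
    n_poly <- 0
  }
  poly_idx <- if (n_poly > 0) sort(sample.int(n_placed, n_poly)) else integer(0)

  allele_b <- tags
  snp_positions <- vector("list", n_loci)
  for (i in seq_len(n_loci)) snp_positions[[i]] <- integer(0)
  for (i in poly_idx) {
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    # SNPs confined to the 22 genomic nt: 1-based 7..28, i.e. 0-based 6..27
    pos <- sort(sample(7:TAG_LENGTH, k))
    chars <- strsplit(tags[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    allele_b[i] <- paste(chars, collapse = "")
    snp_positions[[i]] <- pos - 1L
  }

  chrom <- c(rep(sprintf("chr%d", seq_len(config$n_chromosomes)),
                 each = config$loci_per_chromosome),
             rep(NA_character_, config$n_repeat_loci))
  pos_cM <- c(rep(config$inter_locus_cM * (seq_len(config$loci_per_chromosome) - 1),
                  times = config$n_chromosomes),
              rep(NA_real_, config$n_repeat_loci))
  copy_number <- c(rep(1L, n_placed),
                   if (config$n_repeat_loci > 0)
                     sample(20:100, config$n_repeat_loci, replace = TRUE)
                   else integer(0))

  loci <- tibble(
    locus_id = c(sprintf("LOC%04d", seq_len(n_placed)),
                 if (config$n_repeat_loci > 0)
                   sprintf("REP%04d", seq_len(config$n_repeat_loci))
                 else character(0)),
    chrom = chrom, pos_cM = pos_cM,
    allele_A = tags, allele_B = allele_b,
    snp_positions = snp_positions,
    copy_number = copy_number,
    polymorphic = seq_len(n_loci) %in% poly_idx
  )
  structure(list(loci = loci, config = config,
                 individuals = NULL, inheritance = NULL),
            class = "rad_truth")
}

#' @export
print.rad_truth <- function(x, ...) {
  cat("<rad_truth> ", nrow(x$loci), " loci (",
      sum(x$loci$polymorphic), " polymorphic), ",
      if (is.null(x$individuals)) "no individuals yet"
      else paste0(length(x$individuals), " DH individuals"), "\n", sep = "")
  invisible(x)
}

#' Simulate a doubled-haploid population
#'
#' Each individual's chromosome is a mosaic of the two parental haplotypes
#' from a single meiosis: the source parent at the first locus is Bernoulli(1/2)
#' and a crossover occurs independently in each inter-locus interval with the
#' Haldane probability r = (1 - exp(-2 d / 100)) / 2. DH lines are fully
#' homozygous, so the truth records one source-parent label per locus.
#'
#' @param truth A `rad_truth` from [simulate_genome()].
#' @param n Number of DH individuals (default from the config).
#' @param seed Random seed (default `config$seed + 1`).
#' @return The `rad_truth` with `individuals` (ids) and `inheritance`
#'   (character matrix placed-loci x individuals of `"A"`/`"B"`).
#' @export
simulate_dh_population <- function(truth, n = truth$config$n_individuals,
                                   seed = truth$config$seed + 1L) {
  stopifnot(inherits(truth, "rad_truth"))
  if (n < 1) abort("n must be >= 1")
  withr::local_seed(seed)
  placed <- truth$loci[!is.na(truth$loci$chrom), ]
  individuals <- sprintf("DH_%03d", seq_len(n))
  inh <- matrix(NA_character_, nrow(placed), n,
                dimnames = list(placed$locus_id, individuals))
  for (ch in unique(placed$chrom)) {
    idx <- which(placed$chrom == ch)
    pos <- placed$pos_cM[idx]
    L <- length(idx)
    start <- rbinom(n, 1, 0.5)
    if (L > 1) {
      r <- haldane_inverse(diff(pos))
      xo <- matrix(rbinom((L - 1) * n, 1, rep(r, n)), nrow = L - 1)
      state <- (rbind(start, apply(xo, 2, cumsum) + rep(start, each = L - 1))) %% 2
    } else {
      state <- matrix(start, nrow = 1)
    }
    inh[idx, ] <- ifelse(state == 0, "A", "B")
  }
  truth$individuals <- individuals
  truth$inheritance <- inh
  truth
}

#' Simulate barcoded RAD reads
#'
#' Emits 36-nt reads: 4-nt sample barcode (MID), the 28-nt tag of the
#' individual's allele, and 4 nt of random downstream filler. Per-sample
#' per-locus read counts are negative binomial (parents use
#' `parent_mean_depth`, progeny `mean_depth`); high-copy repeat tags emit
#' copy-number-fold reads. Every base of the read (barcode and remnant
#' included) is substituted independently with probability `error_rate`.
#' Qualities are constant Phred+33 `"I"`.
#'
#' @param truth A `rad_truth` with a simulated population.
#' @param config A [sim_config()]; defaults to the one in `truth`.
#' @param fastq Optional path; when given, reads are written as plain (or
#'   gzipped, if the path ends in `.gz`) 4-line FASTQ.
#' @param seed Random seed (default `config$seed + 2`).
#' @return Tibble truth log, one row per read: `read_id`, `sample_id`,
#'   `locus_id`, `source_allele`, `n_errors`, `sequence`.
#' @export
simulate_reads <- function(truth, config = truth$config, fastq = NULL,
                           seed = config$seed + 2L) {
  stopifnot(inherits(truth, "rad_truth"))
  if (is.null(truth$inheritance) && config$n_individuals > 0) {
    abort("simulate the DH population before reads")
  }
  withr::local_seed(seed)
  bc <- config$barcodes
  loci <- truth$loci
  n_loci <- nrow(loci)

  sample_rows <- list()
  for (s in seq_len(nrow(bc))) {
    role <- bc$role[s]
    mu <- if (role == "progeny") config$mean_depth else config$parent_mean_depth
    if (mu <= 0) next
    depth <- draw_depth(n_loci, mu, config$depth_dispersion) * loci$copy_number
    if (role == "parent_A") {
      allele <- loci$allele_A
    } else if (role == "parent_B") {
      allele <- loci$allele_B
    } else {
      src <- rep("A", n_loci)
      placed_ids <- rownames(truth$inheritance)
      m <- match(loci$locus_id, placed_ids)
      src[!is.na(m)] <- truth$inheritance[m[!is.na(m)], bc$sample_id[s]]
      allele <- ifelse(src == "A", loci$allele_A, loci$allele_B)
    }
    keep <- depth > 0
    if (!any(keep)) next
    sample_rows[[length(sample_rows) + 1]] <- tibble(
      sample_id = bc$sample_id[s],
      barcode = bc$barcode[s],
      locus_id = rep(loci$locus_id[keep], depth[keep]),
      source_allele = rep(if (role == "parent_B") "B" else if (role == "parent_A") "A"
                          else NA_character_, sum(depth[keep])),
      tag = rep(allele[keep], depth[keep])
    )
    if (role == "progeny") {
      src_keep <- rep(ifelse(allele[keep] == loci$allele_A[keep], "A", "B"),
                      depth[keep])
      sample_rows[[length(sample_rows)]]$source_allele <- src_keep
    }
  }
  reads <- if (length(sample_rows)) bind_rows(sample_rows) else
    tibble(sample_id = character(0), barcode = character(0),
           locus_id = character(0), source_allele = character(0),
           tag = character(0))

  n_reads <- nrow(reads)
  seqs <- if (n_reads > 0) {
    paste0(reads$barcode, reads$tag, random_dna(n_reads, 4L))
  } else character(0)
  n_err <- if (n_reads > 0) rbinom(n_reads, READ_LENGTH, config$error_rate)
           else integer(0)
  for (i in which(n_err > 0)) {
    pos <- sample.int(READ_LENGTH, n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }

  log <- tibble(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    sample_id = reads$sample_id,
    locus_id = reads$locus_id,
    source_allele = reads$source_allele,
    n_errors = n_err,
    sequence = seqs
  )
  if (!is.null(fastq)) write_fastq(log$read_id, log$sequence, fastq)
  log
}

draw_depth <- function(n, mu, size) {
  if (n == 0) return(integer(0))
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Write reads as 4-line FASTQ
#'
#' @param ids,sequences Parallel character vectors.
#' @param path Output path; gzipped when it ends in `.gz`.
#' @param quality Quality character repeated over each read (Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, sequences, path, quality = "I") {
  qual <- strrep(quality, nchar(sequences))
  lines <- as.vector(rbind(paste0("@", ids), sequences, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate replicated quantitative traits controlled by additive QTL
#'
#' The genetic value of each DH line is the sum of signed additive effects
#' over the QTL (+a for the parent-A allele, -a for parent-B) plus an optional
#' polygenic line-level deviation. Residual replicate noise is scaled so the
#' realised broad-sense heritability H2 = sigmaG2 / (sigmaG2 + sigmae2 / r)
#' matches `h2_target`.
#'
#' @param truth A `rad_truth` with a simulated population.
#' @param qtl_spec Tibble with `locus_id` and additive `effect` (may have zero
#'   rows for a null trait).
#' @param h2_target Target broad-sense heritability in (0, 1]; 1 means zero
#'   residual noise.
#' @param n_reps Replicates per genotype.
#' @param polygenic_sd SD of the normal line-level deviation added to the QTL
#'   value (0 disables it).
#' @param trait_name Name of the simulated trait.
#' @param seed Random seed (default `config$seed + 3`).
#' @return Tibble `individual`, `trait`, `replicate`, `value`.
#' @export
simulate_phenotypes <- function(truth, qtl_spec, h2_target = 0.8, n_reps = 2,
                                polygenic_sd = 0, trait_name = "trait1",
                                seed = truth$config$seed + 3L) {
  stopifnot(inherits(truth, "rad_truth"))
  if (h2_target <= 0 || h2_target > 1) abort("h2_target must be in (0, 1]")
  if (is.null(truth$individuals)) abort("simulate the DH population first")
  if (nrow(qtl_spec) > 0 &&
      !all(qtl_spec$locus_id %in% rownames(truth$inheritance))) {
    abort("qtl_spec loci must exist among placed loci")
  }
  withr::local_seed(seed)
  n <- length(truth$individuals)
  g <- rep(0, n)
  for (i in seq_len(nrow(qtl_spec))) {
    src <- truth$inheritance[qtl_spec$locus_id[i], ]
    g <- g + qtl_spec$effect[i] * ifelse(src == "A", 1, -1)
  }
  if (polygenic_sd > 0) g <- g + rnorm(n, 0, polygenic_sd)
  sigma_g2 <- stats::var(g)
  sigma_e2 <- if (sigma_g2 > 0 && h2_target < 1) {
    n_reps * sigma_g2 * (1 - h2_target) / h2_target
  } else if (sigma_g2 == 0) 1 else 0
  tibble(
    individual = rep(truth$individuals, each = n_reps),
    trait = trait_name,
    replicate = rep(seq_len(n_reps), n),
    value = rep(g, each = n_reps) + rnorm(n * n_reps, 0, sqrt(sigma_e2))
  )
}

#' Run the full simulator: genome, population, reads, truth tables
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_dh_population()]
#' and [simulate_reads()].
#'
#' @inheritParams simulate_reads
#' @param config A [sim_config()].
#' @return List with `truth` (rad_truth) and `reads` (truth log tibble).
#' @export
simulate_rad_experiment <- function(config, fastq = NULL) {
  truth <- simulate_genome(config)
  truth <- simulate_dh_population(truth)
  reads <- simulate_reads(truth, config, fastq = fastq)
  list(truth = truth, reads = reads)
}

#' Write simulation truth tables as TSV
#'
#' Writes `loci.tsv` (locus, position, alleles, 0-based SNP offsets) and, when
#' the population exists, `inheritance.tsv` (locus x individual source labels).
#'
#' @param truth A `rad_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- truth$loci
  loci$snp_positions <- vapply(loci$snp_positions, paste, "", collapse = ",")
  utils::write.table(loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth$inheritance)) {
    utils::write.table(cbind(locus_id = rownames(truth$inheritance),
                             as.data.frame(truth$inheritance)),
                       file.path(dir, "inheritance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
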