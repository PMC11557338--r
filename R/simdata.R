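#' Simulation configuration for pooled-experiment data
#'
#' Bundles every tunable of the synthetic data generator. Defaults describe a
#' deliberately shallow, desk-scale experiment: a few hundred SNPs at common
#' minor-allele frequencies, sparse coverage (mean 2 reads per cell per
#' locus), a realistic cross-genotype doublet load, and Y-gene expression
#' that separates male from female donors by two orders of magnitude.
#'
#' @param n_loci Number of SNP loci.
#' @param maf_low,maf_high Bounds of the uniform minor-allele-frequency draw.
#' @param cells_per_sample Cells emitted per pooled sample.
#' @param mean_depth Expected reads per cell per locus (Poisson).
#' @param error_rate Sequencing error rate: the alt-read probability at
#'   homozygous-reference loci (and 1 minus it at homozygous-alt loci).
#' @param doublet_rate Fraction of emitted cells that are doublets (two
#'   independently drawn member cells merged in one droplet).
#' @param y_gene_rate_male Expected UMIs per Y gene per male-donor cell.
#' @param y_leak_rate_female Expected UMIs per Y gene per female-donor cell
#'   (ambient/misassignment leakage; must be below `y_gene_rate_male`).
#' @param background_genes Number of autosomal background genes filling the
#'   expression matrix (per-gene rates drawn from Gamma(2, 0.2), mean 10
#'   UMIs per cell per gene).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 300L, maf_low = 0.1, maf_high = 0.5,
                       cells_per_sample = 200L, mean_depth = 2,
                       error_rate = 0.01, doublet_rate = 0.05,
                       y_gene_rate_male = 0.5, y_leak_rate_female = 0.005,
                       background_genes = 100L, seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci), maf_low = maf_low, maf_high = maf_high,
    cells_per_sample = as.integer(cells_per_sample), mean_depth = mean_depth,
    error_rate = error_rate, doublet_rate = doublet_rate,
    y_gene_rate_male = y_gene_rate_male,
    y_leak_rate_female = y_leak_rate_female,
    background_genes = as.integer(background_genes), seed = as.integer(seed)
  )
  if (cfg$n_loci < 1) abort("n_loci must be >= 1")
  if (cfg$maf_low > cfg$maf_high || cfg$maf_low < 0 || cfg$maf_high > 1) {
    abort("need 0 <= maf_low <= maf_high <= 1")
  }
  rates <- c(cfg$mean_depth, cfg$y_gene_rate_male, cfg$y_leak_rate_female)
  if (any(rates < 0)) abort("rates must be non-negative")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 0.5) abort("doublet_rate must be in [0, 0.5)")
  if (cfg$y_leak_rate_female >= cfg$y_gene_rate_male) {
    abort("y_leak_rate_female must be below y_gene_rate_male")
  }
  structure(cfg, class = "sim_config")
}

#' The Y-chromosome gene panel used for donor sex inference
#'
#' Nine Y-linked genes whose summed expression share of a cluster's
#' transcriptome serves as the male-sex proxy.
#'
#' @return Character vector of gene symbols.
#' @export
y_genes <- function() {
  c("ZFY", "RPS4Y1", "EIF1AY", "KDM5D", "NLGN4Y", "TMSB4Y", "UTY", "DDX3Y", "USP9Y")
}

#' Simulate donor SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Per locus, an alt-allele frequency is drawn uniformly in
#' `[maf_low, maf_high]`; each donor's genotype is the sum of two independent
#' allele draws at that frequency (alt copy number 0, 1 or 2).
#'
#' @param roster A roster tibble (see [make_roster()]).
#' @param config A [sim_config()].
#' @return A `donor_genotypes` object: list with `calls` (loci x donors
#'   integer matrix), `loci` (tibble `locus_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`), and `donors`.
#' @export
simulate_donor_genotypes <- function(roster, config = sim_config()) {
  roster <- validate_roster(roster)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  maf <- runif(L, config$maf_low, config$maf_high)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- map_chr(ref, function(b) sample(setdiff(bases, b), 1L))
  loci <- tibble(
    chrom = "1", pos = seq_len(L) * 100L, ref = ref, alt = alt, maf = maf
  ) |> mutate(locus_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"))
  donors <- sort(roster$donor_id)
  calls <- matrix(
    rbinom(L * length(donors), 2L, rep(maf, times = length(donors))),
    nrow = L, ncol = length(donors), dimnames = list(loci$locus_id, donors)
  )
  structure(list(calls = calls, loci = loci, donors = donors),
            class = "donor_genotypes")
}

#' @export
print.donor_genotypes <- function(x, ...) {
  cat(sprintf("<donor_genotypes: %d loci x %d donors>\n", nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

# alt-read probability per genotype: 0 -> error, 1 -> 0.5, 2 -> 1 - error
genotype_alt_prob <- function(g, error_rate) {
  ifelse(g == 0L, error_rate, ifelse(g == 1L, 0.5, 1 - error_rate))
}

# draw (ref, alt) count matrices (loci x n_cells) for cells of given donors
draw_allele_counts <- function(donor_vec, genotypes, config) {
  L <- nrow(genotypes$calls)
  n <- length(donor_vec)
  depth <- matrix(rpois(L * n, config$mean_depth), nrow = L)
  p <- genotype_alt_prob(genotypes$calls[, donor_vec, drop = FALSE], config$error_rate)
  alt <- matrix(rbinom(L * n, as.vector(depth), as.vector(p)), nrow = L)
  list(ref = depth - alt, alt = alt)
}

# draw expression counts (genes x n_cells): background genes + Y panel
draw_expression <- function(sex_vec, bg_rates, config) {
  n <- length(sex_vec)
  bg <- matrix(rpois(length(bg_rates) * n, rep(bg_rates, times = n)),
               nrow = length(bg_rates))
  y_rate <- ifelse(sex_vec == "male", config$y_gene_rate_male, config$y_leak_rate_female)
  ny <- length(y_genes())
  yy <- matrix(rpois(ny * n, rep(y_rate, each = ny)), nrow = ny)
  rbind(bg, yy)
}

#' Simulate one pooled reaction
#'
#' Emits `cells_per_sample x n_members` droplets. A singlet's allele counts
#' follow Poisson(depth) coverage with binomial alt reads at its donor's
#' genotype-specific alt probability; a `doublet_rate` fraction of droplets
#' instead merge two independently drawn member cells (summing both allele
#' and expression counts; cross-genotype when the two donors differ). Y-gene
#' UMIs are Poisson at the male rate for male-donor cells and at the leak
#' rate otherwise. Ground truth is recorded for every barcode.
#'
#' @param design A `pooling_design`.
#' @param reaction_id Which reaction of the design to simulate.
#' @param genotypes A `donor_genotypes` covering all member donors.
#' @param config A [sim_config()]; the reaction seed is derived
#'   deterministically from `config$seed` and the reaction's position in the
#'   design, so simulating reactions in any order gives identical data.
#' @return A `reaction_sim`: list with `ref`/`alt` sparse loci-x-cells
#'   matrices, `expression` (genes x cells sparse), `features`, `barcodes`,
#'   `loci`, and `truth` (tibble `barcode`, `sample_id`, `donor_id`,
#'   `is_doublet`, `second_donor_id`, `sex`).
#' @export
simulate_reaction <- function(design, reaction_id, genotypes, config = sim_config()) {
  stopifnot(inherits(design, "pooling_design"), inherits(genotypes, "donor_genotypes"))
  rxn_ids <- unique(design$reactions$reaction_id)
  idx <- match(reaction_id, rxn_ids)
  if (is.na(idx)) abort(sprintf("reaction '%s' not found in design", reaction_id))
  members <- design$reactions$sample_id[design$reactions$reaction_id == reaction_id]
  smp <- design$samples
  donor_of <- setNames(smp$donor_id, smp$sample_id)
  sex_of <- setNames(smp$sex, smp$donor_id)
  missing_d <- setdiff(donor_of[members], genotypes$donors)
  if (length(missing_d)) {
    abort(paste0("genotypes missing for donor(s): ", paste(missing_d, collapse = ", ")))
  }

  set.seed((config$seed + 7919L * idx) %% .Machine$integer.max)
  m <- length(members)
  total <- config$cells_per_sample * m
  primary <- rep(members, each = config$cells_per_sample)
  is_doublet <- as.logical(rbinom(total, 1L, config$doublet_rate))
  sample1 <- ifelse(is_doublet, sample(members, total, replace = TRUE), primary)
  sample2 <- ifelse(is_doublet, sample(members, total, replace = TRUE), NA_character_)

  bg_rates <- stats::rgamma(config$background_genes, shape = 2, rate = 0.2)

  donor1 <- unname(donor_of[sample1])
  a1 <- draw_allele_counts(donor1, genotypes, config)
  e1 <- draw_expression(unname(sex_of[donor1]), bg_rates, config)
  ref <- a1$ref; alt <- a1$alt; expr <- e1
  if (any(is_doublet)) {
    donor2 <- unname(donor_of[sample2[is_doublet]])
    a2 <- draw_allele_counts(donor2, genotypes, config)
    e2 <- draw_expression(unname(sex_of[donor2]), bg_rates, config)
    ref[, is_doublet] <- ref[, is_doublet, drop = FALSE] + a2$ref
    alt[, is_doublet] <- alt[, is_doublet, drop = FALSE] + a2$alt
    expr[, is_doublet] <- expr[, is_doublet, drop = FALSE] + e2
  }

  barcodes <- sprintf("%s_BC%05d", reaction_id, seq_len(total))
  features <- c(sprintf("BG%04d", seq_len(config$background_genes)), y_genes())
  dimnames(ref) <- dimnames(alt) <- list(genotypes$loci$locus_id, barcodes)
  dimnames(expr) <- list(features, barcodes)

  truth <- tibble(
    barcode = barcodes,
    sample_id = sample1,
    donor_id = donor1,
    is_doublet = is_doublet,
    second_donor_id = ifelse(is_doublet, donor_of[sample2], NA_character_),
    sex = unname(sex_of[donor1])
  )

  structure(
    list(
      reaction_id = reaction_id,
      ref = as(ref, "CsparseMatrix"),
      alt = as(alt, "CsparseMatrix"),
      expression = as(expr, "CsparseMatrix"),
      features = features,
      barcodes = barcodes,
      loci = genotypes$loci,
      truth = truth,
      config = config
    ),
    class = "reaction_sim"
  )
}

#' @export
print.reaction_sim <- function(x, ...) {
  cat(sprintf(
    "<reaction_sim %s: %d cells (%d doublets), %d loci, %d genes>\n",
    x$reaction_id, length(x$barcodes), sum(x$truth$is_doublet),
    nrow(x$ref), nrow(x$expression)
  ))
  invisible(x)
}

#' Write a simulated reaction to disk as plain-text fixtures
#'
#' Writes `ref.mtx`/`alt.mtx` (MatrixMarket allele counts), `matrix.mtx` +
#' `features.tsv` + `barcodes.tsv` (expression), `loci.tsv`, `truth.tsv` and
#' a `manifest.json` echoing the simulation configuration (including the
#' seed). [read_fixture()] reproduces the in-memory object exactly.
#'
#' @param sim A `reaction_sim`.
#' @param out_dir Output directory (created if missing).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "reaction_sim"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(sprintf("output directory '%s' is not empty (use overwrite = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sim$ref, file.path(out_dir, "ref.mtx"))
  Matrix::writeMM(sim$alt, file.path(out_dir, "alt.mtx"))
  Matrix::writeMM(sim$expression, file.path(out_dir, "matrix.mtx"))
  readr::write_tsv(tibble(feature = sim$features), file.path(out_dir, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble(barcode = sim$barcodes), file.path(out_dir, "barcodes.tsv"),
                   col_names = FALSE)
  readr::write_tsv(sim$loci, file.path(out_dir, "loci.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  manifest <- c(list(reaction_id = sim$reaction_id), unclass(sim$config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a simulated-reaction fixture back from disk
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `reaction_sim`.
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg_names <- setdiff(names(manifest), "reaction_id")
  config <- do.call(sim_config, manifest[cfg_names])
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                              col_types = "c")$barcode
  features <- readr::read_tsv(file.path(dir, "features.tsv"), col_names = "feature",
                              col_types = "c")$feature
  loci <- readr::read_tsv(file.path(dir, "loci.tsv"),
                          col_types = readr::cols(chrom = "c", pos = "i", .default = "c")) |>
    mutate(maf = as.numeric(.data$maf))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = readr::cols(is_doublet = "l", .default = "c"))
  load_mtx <- function(name, rn) {
    m <- as(Matrix::readMM(file.path(dir, name)), "CsparseMatrix")
    dimnames(m) <- list(rn, barcodes)
    m
  }
  structure(
    list(
      reaction_id = manifest$reaction_id,
      ref = load_mtx("ref.mtx", loci$locus_id),
      alt = load_mtx("alt.mtx", loci$locus_id),
      expression = load_mtx("matrix.mtx", features),
      features = features,
      barcodes = barcodes,
      loci = loci,
      truth = truth,
      config = config
    ),
    class = "reaction_sim"
  )
}
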