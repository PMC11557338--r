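# Readers and writers for the on-disk interchange formats: demultiplexer
# cluster tables (souporcell dialect), per-cluster genotype VCFs, design
# YAML. Count matrices travel as MatrixMarket via write_fixture()/read_fixture().

#' Write a cluster assignment table in the souporcell dialect
#'
#' Columns: `barcode status assignment log_prob_singleton log_prob_doublet
#' cluster0 ... cluster{K-1}`; doublet assignments are rendered `i/j`.
#'
#' @param assignment Assignment tibble from [call_doublets()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_souporcell_clusters <- function(assignment, path) {
  cols <- c("barcode", "status", "assignment", "log_prob_singleton",
            "log_prob_doublet", grep("^cluster[0-9]+$", names(assignment), value = TRUE))
  readr::write_tsv(assignment[, cols], path)
  invisible(path)
}

#' Read a souporcell-compatible cluster assignment table
#'
#' Accepts tab or whitespace delimiters (field counts vary across producer
#' versions); columns beyond the documented set are preserved as
#' annotations. Statuses must be `singlet`, `doublet` or `unassigned`;
#' doublet assignments `i/j` are parsed into pairs and an identical pair
#' (`0/0`) is rejected.
#'
#' @param path TSV with a header starting `barcode status assignment`.
#' @return An assignment tibble with `barcode`, `status`, `assignment`,
#'   `cluster` (integer for singlets, `NA` otherwise), `doublet_pair`
#'   (list column), and any extra columns.
#' @export
read_souporcell_clusters <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), "[ \t]+")[[1]]
  if (length(header) < 3L || !identical(header[1:3], c("barcode", "status", "assignment"))) {
    abort("expected a header beginning 'barcode status assignment'")
  }
  tbl <- readr::read_table(path, col_types = readr::cols(
    barcode = "c", status = "c", assignment = "c",
    .default = readr::col_guess()
  ))
  bad <- which(!tbl$status %in% c("singlet", "doublet", "unassigned"))
  if (length(bad)) {
    abort(sprintf("unknown status token '%s' at line %d", tbl$status[bad[1]], bad[1] + 1L))
  }
  pairs <- strsplit(tbl$assignment, "/", fixed = TRUE)
  for (i in which(tbl$status == "doublet")) {
    p <- pairs[[i]]
    if (length(p) != 2L || p[1] == p[2]) {
      abort(sprintf("invalid doublet assignment '%s' at line %d (need two distinct clusters)",
                    tbl$assignment[i], i + 1L))
    }
  }
  tbl |> mutate(
    cluster = ifelse(.data$status == "singlet", suppressWarnings(as.integer(.data$assignment)),
                     NA_integer_),
    doublet_pair = map2(.data$status, pairs, function(s, p) {
      if (s == "doublet") as.integer(p) else NULL
    })
  )
}

#' Write consensus cluster genotypes as a VCF
#'
#' One sample column per cluster; calls 0, 0.5, 1 and no-call map to GT
#' `0/0`, `0/1`, `1/1` and `./.`.
#'
#' @param calls Loci x clusters call matrix from [consensus_genotypes()],
#'   rownames keyed `CHROM:POS:REF:ALT`.
#' @param path Output VCF path (plain text).
#' @return `path`, invisibly.
#' @export
write_cluster_genotypes_vcf <- function(calls, path) {
  loci <- do.call(rbind, strsplit(rownames(calls), ":", fixed = TRUE))
  gt <- matrix("./.", nrow(calls), ncol(calls))
  gt[!is.na(calls) & calls == 0] <- "0/0"
  gt[!is.na(calls) & calls == 0.5] <- "0/1"
  gt[!is.na(calls) & calls == 1] <- "1/1"
  samples <- colnames(calls)
  if (is.null(samples)) samples <- as.character(seq_len(ncol(calls)) - 1L)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t"),
    vapply(seq_len(nrow(calls)), function(i) {
      paste(c(loci[i, 1], loci[i, 2], rownames(calls)[i], loci[i, 3], loci[i, 4],
              ".", ".", ".", "GT", gt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read per-cluster genotype calls from a VCF
#'
#' GT values `0/0`, `0/1`, `1/1` and `./.` (phased `|` separators accepted)
#' map to calls 0, 0.5, 1 and `NA`. Loci are keyed `CHROM:POS:REF:ALT`.
#' Multi-allelic records are skipped with a warning.
#'
#' @param path VCF path with one sample column per cluster and a GT field.
#' @return A loci x clusters numeric call matrix.
#' @export
read_cluster_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt)) abort("VCF has no FORMAT/GT field")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipped %d multi-allelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  calls <- matrix(NA_real_, nrow(gt), ncol(gt),
                  dimnames = list(paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                                  colnames(gt)))
  calls[gt == "0/0"] <- 0
  calls[gt %in% c("0/1", "1/0")] <- 0.5
  calls[gt == "1/1"] <- 1
  calls
}

#' Write a pooling design to YAML
#'
#' Keys: `strategy`, `reactions` (list of `{reaction_id, members}`),
#' `samples` (list of `{sample_id, donor_id, tissue, sex}`), `anchors`.
#'
#' @param design A `pooling_design`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "pooling_design"))
  members <- split(design$reactions$sample_id, design$reactions$reaction_id)
  members <- members[unique(design$reactions$reaction_id)]
  obj <- list(
    strategy = design$strategy,
    reactions = unname(imap(members, function(m, rid) {
      list(reaction_id = rid, members = as.list(m))
    })),
    samples = unname(pmap(design$samples, function(sample_id, donor_id, tissue, sex) {
      list(sample_id = sample_id, donor_id = donor_id, tissue = tissue, sex = sex)
    })),
    anchors = unname(pmap(design$anchors, function(donor_id, reaction_a, reaction_b) {
      list(donor_id = donor_id, reaction_a = reaction_a, reaction_b = reaction_b)
    }))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pooling design from YAML
#'
#' @param path YAML path written by [write_design_yaml()].
#' @return A validated `pooling_design`.
#' @export
read_design_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  reactions <- bind_rows(lapply(obj$reactions, function(r) {
    tibble(reaction_id = r$reaction_id, sample_id = unlist(r$members))
  }))
  samples <- bind_rows(lapply(obj$samples, as_tibble))
  anchors <- if (length(obj$anchors)) bind_rows(lapply(obj$anchors, as_tibble)) else
    tibble(donor_id = character(0), reaction_a = character(0), reaction_b = character(0))
  new_pooling_design(obj$strategy, reactions, samples, anchors)
}

#' Read a Y-gene list file
#'
#' One gene symbol per line; blank lines and `#` comments ignored. The
#' package ships its default panel at
#' `system.file("extdata", "ygenes.txt", package = "pairpool")`.
#'
#' @param path Path to the gene list.
#' @return Character vector of gene symbols.
#' @export
read_y_genes <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
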