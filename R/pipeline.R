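# End-to-end orchestration: simulate (or ingest) each reaction, cluster by
# genotype, call doublets, discretize consensus genotypes, match shared
# genotypes across reactions, infer sex, resolve identities, and apply QC.

#' Assemble a pipeline run configuration
#'
#' Every module parameter with its documented default; round-trips through
#' YAML losslessly ([yaml::write_yaml()] on the returned list).
#'
#' @param sim A [sim_config()] for simulated inputs (ignored when
#'   ingesting real demultiplexer outputs).
#' @param doublet_margin Doublet log-likelihood margin in nats.
#' @param n_restarts,max_iter,tol EM settings (see
#'   [fit_genotype_clusters()]).
#' @param hom_threshold,het_band,min_reads Consensus-call settings (see
#'   [consensus_genotypes()]).
#' @param tau_match,min_shared_loci Matching settings (see
#'   [match_shared_clusters()]).
#' @param tau_male Sex-call threshold in percent (see [infer_sex()]).
#' @param y_gene_list Y-gene panel.
#' @param use_sex Use sex calls during identity resolution.
#' @param min_genes_per_cell,max_genes_per_cell,min_cells_per_gene,target_sum
#'   QC thresholds (see [filter_cells_genes()], [normalize_log1p()]). The
#'   defaults are the standard real-data values; simulated matrices are much
#'   smaller than a real transcriptome, so pass thresholds matching the
#'   simulated gene count when running on synthetic data.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), doublet_margin = 2,
                       n_restarts = 5L, max_iter = 100L, tol = 1e-4,
                       hom_threshold = 0.1, het_band = 0.15, min_reads = 3L,
                       tau_match = 0.9, min_shared_loci = 20L,
                       tau_male = 0.02, y_gene_list = y_genes(),
                       use_sex = TRUE,
                       min_genes_per_cell = 200L, max_genes_per_cell = 4000L,
                       min_cells_per_gene = 3L, target_sum = 10000,
                       seed = 1L) {
  structure(
    list(
      sim = sim, doublet_margin = doublet_margin, n_restarts = n_restarts,
      max_iter = max_iter, tol = tol, hom_threshold = hom_threshold,
      het_band = het_band, min_reads = min_reads, tau_match = tau_match,
      min_shared_loci = min_shared_loci, tau_male = tau_male,
      y_gene_list = y_gene_list, use_sex = use_sex,
      min_genes_per_cell = min_genes_per_cell,
      max_genes_per_cell = max_genes_per_cell,
      min_cells_per_gene = min_cells_per_gene, target_sum = target_sum,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full demultiplexing pipeline on a pooling design
#'
#' Stages: per reaction, genotype clustering (K = pool size) and doublet
#' calling, or ingestion of externally produced cluster tables and
#' cluster-genotype VCFs; consensus genotype discretization; cross-reaction
#' matching; Y-gene sex inference; global identity resolution; and QC
#' (cross-genotype doublet removal, detection filters, normalization) of
#' each reaction's expression matrix. When the inputs are simulated the
#' ground truth is carried through and per-cluster label accuracy is
#' reported.
#'
#' @param design A `pooling_design` (or path to its YAML).
#' @param config A [run_config()].
#' @param reactions Optional named list (by reaction id) of pre-loaded
#'   inputs, each a list with `ref`, `alt`, `expression` (and optionally
#'   `truth`), e.g. `reaction_sim` objects or [read_fixture()] results.
#'   When `NULL`, reactions are simulated from `config$sim`.
#' @param out_dir Optional directory for the output files (assignment TSV,
#'   matches TSV, sex-call TSV, evidence JSON, provenance manifest).
#' @return A `pairpool_run`: list with `design`, `fits`, `assignments`,
#'   `consensus`, `match_graph`, `sex_calls`, `identity`, `qc`,
#'   `cluster_truth` and `label_accuracy` (when truth is available), and
#'   `status` (the resolution status).
#' @export
run_pipeline <- function(design, config = run_config(), reactions = NULL,
                         out_dir = NULL) {
  if (is.character(design)) design <- read_design_yaml(design)
  stopifnot(inherits(design, "pooling_design"), inherits(config, "run_config"))
  rxn_ids <- unique(design$reactions$reaction_id)

  simulated <- is.null(reactions)
  genotypes <- NULL
  if (simulated) {
    roster <- design$samples |> distinct(.data$donor_id, .data$sex)
    genotypes <- simulate_donor_genotypes(roster, config$sim)
    reactions <- lapply(rxn_ids, function(rid) {
      simulate_reaction(design, rid, genotypes, config$sim)
    })
    names(reactions) <- rxn_ids
  }
  if (!setequal(names(reactions), rxn_ids)) {
    abort("reactions must be named by the design's reaction ids")
  }

  pool_size <- design$reactions |> count(.data$reaction_id)
  k_of <- setNames(pool_size$n, pool_size$reaction_id)

  fits <- list(); assignments <- list(); consensus <- list()
  sex_calls <- list(); qc_out <- list()
  for (rid in rxn_ids) {
    rx <- reactions[[rid]]
    fit <- fit_genotype_clusters(
      rx$ref, rx$alt, K = k_of[[rid]],
      n_restarts = config$n_restarts, max_iter = config$max_iter,
      tol = config$tol, seed = (config$seed + 104729L * match(rid, rxn_ids)) %%
        .Machine$integer.max
    )
    asg <- call_doublets(fit, margin = config$doublet_margin)
    fits[[rid]] <- fit
    assignments[[rid]] <- asg
    consensus[[rid]] <- consensus_genotypes(
      fit, asg, hom_threshold = config$hom_threshold,
      het_band = config$het_band, min_reads = config$min_reads
    )
    sex_calls[[rid]] <- infer_sex(rx$expression, asg,
                                  y_gene_list = config$y_gene_list,
                                  tau_male = config$tau_male, reaction_id = rid)
    no_dbl <- remove_cross_genotype_doublets(rx$expression, asg)
    qc_out[[rid]] <- filter_cells_genes(
      no_dbl, min_genes_per_cell = config$min_genes_per_cell,
      max_genes_per_cell = config$max_genes_per_cell,
      min_cells_per_gene = config$min_cells_per_gene
    )
    if (ncol(qc_out[[rid]]$matrix) > 0) {
      qc_out[[rid]]$normalized <- normalize_log1p(qc_out[[rid]]$matrix,
                                                  target_sum = config$target_sum)
    }
  }

  mg <- match_shared_clusters(consensus, tau_match = config$tau_match,
                              min_shared_loci = config$min_shared_loci)
  sex_tbl <- bind_rows(sex_calls)
  identity <- resolve_identities(design, mg,
                                 sex_calls = if (config$use_sex) sex_tbl else NULL)

  cluster_truth <- NULL
  label_accuracy <- NA_real_
  if (all(map_lgl(reactions, function(r) !is.null(r$truth)))) {
    cluster_truth <- bind_rows(imap(reactions, function(rx, rid) {
      assignments[[rid]] |>
        filter(.data$status == "singlet") |>
        left_join(rx$truth, by = "barcode") |>
        filter(!.data$is_doublet) |>
        count(.data$cluster, .data$sample_id) |>
        group_by(.data$cluster) |>
        slice_max(.data$n, n = 1, with_ties = FALSE) |>
        ungroup() |>
        transmute(reaction_id = rid, cluster = as.character(.data$cluster),
                  true_sample_id = .data$sample_id)
    }))
    joined <- identity$mapping |>
      left_join(cluster_truth, by = c("reaction_id", "cluster"))
    label_accuracy <- mean(joined$sample_id == joined$true_sample_id)
  }

  run <- structure(
    list(
      design = design, config = config, genotypes = genotypes,
      reactions = reactions, fits = fits, assignments = assignments,
      consensus = consensus, match_graph = mg, sex_calls = sex_tbl,
      identity = identity, qc = qc_out,
      cluster_truth = cluster_truth, label_accuracy = label_accuracy,
      status = identity$status
    ),
    class = "pairpool_run"
  )
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$identity$mapping, file.path(out_dir, "assignment.tsv"))
  readr::write_tsv(run$match_graph$edges, file.path(out_dir, "matches.tsv"))
  readr::write_tsv(run$sex_calls, file.path(out_dir, "sex_calls.tsv"))
  jsonlite::write_json(
    list(status = run$status, n_consistent = run$identity$n_consistent,
         evidence = run$identity$evidence),
    file.path(out_dir, "evidence.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("pairpool")),
    seed = run$config$seed,
    parameters = unclass(run$config)[setdiff(names(run$config), c("sim", "y_gene_list"))],
    sim = unclass(run$config$sim),
    y_gene_list = run$config$y_gene_list,
    strategy = run$design$strategy,
    n_reactions = length(run$fits),
    status = run$status,
    label_accuracy = run$label_accuracy
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pairpool_run <- function(x, ...) {
  cat(sprintf(
    "<pairpool_run: %s design, %d reactions, resolution %s%s>\n",
    x$design$strategy, length(x$fits), x$status,
    if (!is.na(x$label_accuracy)) sprintf(", label accuracy %.1f%%", 100 * x$label_accuracy)
    else ""
  ))
  invisible(x)
}

#' @export
glance.pairpool_run <- function(x, ...) {
  tibble(
    strategy = x$design$strategy,
    n_reactions = length(x$fits),
    n_cells = sum(map_int(x$assignments, nrow)),
    n_doublets_called = sum(map_int(x$assignments, function(a) sum(a$status == "doublet"))),
    status = x$status,
    n_consistent = x$identity$n_consistent,
    label_accuracy = x$label_accuracy
  )
}
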