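# Donor sex per cluster from Y-gene expression share, then global identity
# resolution: every (reaction, cluster) slot is assigned a pooled sample so
# that match-graph components carry one donor each, unmatched clusters carry
# different donors, and sex calls agree - solved exactly by backtracking.

#' Infer donor sex per genotype cluster from Y-gene expression
#'
#' For each cluster, sums UMIs of the Y-gene panel over the cluster's
#' singlet cells and divides by the cells' total UMIs; the percentage
#' `y_pct` is the male-sex proxy. A cluster is called male when
#' `y_pct >= tau_male`. Doublet and unassigned cells are excluded (their
#' mixed origin would blur the signal).
#'
#' @param expression Genes x cells count matrix with gene symbols as
#'   rownames and barcodes as colnames.
#' @param assignment Assignment tibble with columns `barcode`, `status`,
#'   `cluster` (e.g. from [call_doublets()]).
#' @param y_gene_list Y-chromosome gene panel (default [y_genes()]); genes
#'   absent from the matrix are warned about and skipped.
#' @param tau_male Threshold on `y_pct`, in percent (default 0.02).
#' @param reaction_id Optional reaction label copied into the output.
#' @return A `sex_calls` tibble: `reaction_id`, `cluster`, `y_pct`, `call`
#'   (`"male"`/`"female"`, `NA` for a cluster with zero total UMIs),
#'   `n_cells`, `total_umis`.
#' @export
infer_sex <- function(expression, assignment, y_gene_list = y_genes(),
                      tau_male = 0.02, reaction_id = NA_character_) {
  if (length(y_gene_list) == 0) abort("y_gene_list must be non-empty")
  present <- intersect(y_gene_list, rownames(expression))
  if (length(present) == 0) abort("none of the Y genes are present in the feature table")
  missing <- setdiff(y_gene_list, present)
  if (length(missing)) {
    warn(paste0("Y gene(s) absent from features, skipped: ",
                paste(missing, collapse = ", ")))
  }
  sing <- assignment |> filter(.data$status == "singlet", !is.na(.data$cluster))
  out <- sing |>
    group_by(cluster = .data$cluster) |>
    reframe(
      y_pct = {
        cells <- intersect(.data$barcode, colnames(expression))
        tot <- sum(expression[, cells, drop = FALSE])
        yy <- sum(expression[present, cells, drop = FALSE])
        if (tot == 0) NA_real_ else 100 * yy / tot
      },
      n_cells = dplyr::n(),
      total_umis = sum(expression[, intersect(.data$barcode, colnames(expression)), drop = FALSE])
    ) |>
    mutate(
      call = ifelse(is.na(.data$y_pct), NA_character_,
                    ifelse(.data$y_pct >= tau_male, "male", "female")),
      reaction_id = reaction_id
    ) |>
    select("reaction_id", "cluster", "y_pct", "call", "n_cells", "total_umis") |>
    arrange(.data$cluster)
  if (any(is.na(out$call))) {
    warn(paste0("cluster(s) with zero total UMIs get no sex call: ",
                paste(out$cluster[is.na(out$call)], collapse = ", ")))
  }
  out
}

#' Plot per-cluster Y-gene expression percentages
#'
#' Diagnostic for auditing male/female separation before trusting the
#' threshold on real data.
#'
#' @param sex_calls A tibble from [infer_sex()] (rows from several reactions
#'   may be bound together).
#' @param tau_male Threshold line to draw (default 0.02).
#' @return A ggplot of `y_pct` per cluster on a log-ish scale.
#' @export
plot_sex_calls <- function(sex_calls, tau_male = 0.02) {
  ggplot2::ggplot(sex_calls,
                  ggplot2::aes(x = interaction(.data$reaction_id, .data$cluster),
                               y = .data$y_pct + 1e-4, fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = tau_male, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reaction.cluster", y = "% UMIs from Y genes (+1e-4)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Resolve every genotype cluster to a specific sample identity
#'
#' Constraint model: each (reaction, cluster) slot must receive one of the
#' samples pooled in that reaction (injectively within the reaction); all
#' slots of one match-graph component must receive samples of a single
#' donor; slots in different components must receive different donors, but
#' only across reaction pairs whose locus overlap met the matcher's
#' `min_shared_loci` (elsewhere a missing match is missing data, not
#' evidence); and, when sex calls are supplied, the assigned donor's sex
#' must equal the slot's call. Solved exactly by backtracking enumeration.
#' Components containing a conflicted node (one that matched two clusters in
#' a single other reaction) contribute no genotype constraints and a warning
#' is logged.
#'
#' @param design A `pooling_design`.
#' @param match_graph A `match_graph` over every (reaction, cluster) implied
#'   by the design's pool sizes.
#' @param sex_calls Optional tibble with `reaction_id`, `cluster`, `call`
#'   (from [infer_sex()]); required in practice for triplet designs.
#' @param max_store Keep at most this many full assignments when ambiguous
#'   (default 100); beyond that only the count and ambiguous slot groups
#'   are reported.
#' @return An `identity_assignment`: list with `status` (`"unique"`,
#'   `"ambiguous"` or `"inconsistent"`), `n_consistent`, `mapping` (tibble
#'   `reaction_id`, `cluster`, `sample_id`, `donor_id`, `tissue`, `status`),
#'   `assignments` (consistent solutions, up to `max_store`),
#'   `ambiguous_groups`, and `evidence`.
#' @export
resolve_identities <- function(design, match_graph, sex_calls = NULL,
                               max_store = 100L) {
  stopifnot(inherits(design, "pooling_design"), inherits(match_graph, "match_graph"))
  nodes <- match_graph$nodes
  pool <- design$reactions |> count(.data$reaction_id, name = "pool_size")
  got <- nodes |> count(.data$reaction_id, name = "n_clusters")
  chk <- full_join(pool, got, by = "reaction_id")
  if (any(is.na(chk$n_clusters)) || any(is.na(chk$pool_size)) ||
      any(chk$n_clusters != chk$pool_size)) {
    abort("match-graph nodes must cover every (reaction, cluster) implied by the design's pool sizes")
  }

  node_key <- paste(nodes$reaction_id, nodes$cluster, sep = ":")
  conflicted_comp <- unique(nodes$component[node_key %in% match_graph$conflicts])
  if (length(conflicted_comp)) {
    warn(sprintf(
      "%d conflicted node(s): genotype constraints of %d component(s) relaxed to unknown",
      length(match_graph$conflicts), length(conflicted_comp)
    ))
  }
  group <- ifelse(nodes$component %in% conflicted_comp, NA_integer_, nodes$component)

  sex <- rep(NA_character_, nrow(nodes))
  if (!is.null(sex_calls)) {
    key <- paste(sex_calls$reaction_id, sex_calls$cluster, sep = ":")
    sex <- sex_calls$call[match(node_key, key)]
  }

  slots <- tibble(
    reaction_id = nodes$reaction_id,
    cluster = nodes$cluster,
    group = group,
    sex = sex
  )
  members <- split(design$reactions$sample_id, design$reactions$reaction_id)
  res <- solve_slot_assignment(slots, members, design$samples,
                               comparable = match_graph$comparable_pairs,
                               max_store = max_store)

  status <- if (res$n_solutions == 0L) "inconsistent"
            else if (res$n_solutions == 1L) "unique" else "ambiguous"

  smp <- design$samples
  mapping <- res$slots |>
    mutate(
      sample_id = map_chr(res$possible,
                          function(p) if (length(p) == 1L) p else NA_character_),
      slot_status = ifelse(res$n_solutions == 0L, "inconsistent",
                           ifelse(lengths(res$possible) == 1L, "unique", "ambiguous"))
    ) |>
    left_join(smp[, c("sample_id", "donor_id", "tissue")], by = "sample_id") |>
    select("reaction_id", "cluster", "sample_id", "donor_id", "tissue",
           status = "slot_status")

  amb <- tibble(
    reaction_id = res$slots$reaction_id,
    cluster = res$slots$cluster,
    key = map_chr(res$possible, function(p) paste(sort(p), collapse = "|")),
    n_possible = lengths(res$possible)
  ) |> filter(.data$n_possible > 1)
  amb_groups <- if (nrow(amb)) {
    unname(lapply(split(seq_len(nrow(amb)), amb$key),
                  function(i) amb[i, c("reaction_id", "cluster")]))
  } else list()

  evidence <- res$slots |>
    mutate(
      n_pool = map_int(.data$reaction_id, function(r) length(members[[r]])),
      n_consistent = lengths(res$possible),
      sex_constraint = !is.na(res$slots$sex),
      genotype_constraint = !is.na(res$slots$group)
    ) |>
    select("reaction_id", "cluster", "n_pool", "n_consistent",
           "genotype_constraint", "sex_constraint")

  witness <- NULL
  if (status == "inconsistent") {
    # implicate the tightest constraint class whose removal restores a solution
    relax_sex <- solve_slot_assignment(mutate(slots, sex = NA_character_),
                                       members, design$samples,
                                       comparable = match_graph$comparable_pairs,
                                       max_store = 0L)
    if (relax_sex$n_solutions > 0L) {
      witness <- "sex calls contradict the genotype-sharing constraints"
    } else {
      relax_all <- solve_slot_assignment(mutate(slots, group = NA_integer_, sex = NA_character_),
                                         members, design$samples,
                                         comparable = match_graph$comparable_pairs,
                                         max_store = 0L)
      witness <- if (relax_all$n_solutions > 0L) {
        "genotype-sharing constraints are mutually inconsistent with the design"
      } else {
        "no injective slot-to-sample mapping exists"
      }
    }
  }

  structure(
    list(
      status = status,
      n_consistent = res$n_solutions,
      mapping = mapping,
      assignments = res$solutions,
      ambiguous_groups = amb_groups,
      evidence = evidence,
      witness = witness,
      used_sex = !is.null(sex_calls)
    ),
    class = "identity_assignment"
  )
}

#' @export
print.identity_assignment <- function(x, ...) {
  cat(sprintf("<identity_assignment: %s (%d consistent assignment%s)>\n",
              x$status, x$n_consistent, if (x$n_consistent == 1L) "" else "s"))
  if (!is.null(x$witness)) cat("witness:", x$witness, "\n")
  print(x$mapping, n = Inf)
  invisible(x)
}

#' @export
tidy.identity_assignment <- function(x, ...) {
  x$mapping
}

#' @export
glance.identity_assignment <- function(x, ...) {
  tibble(
    status = x$status,
    n_consistent = x$n_consistent,
    n_slots = nrow(x$mapping),
    n_resolved = sum(x$mapping$status == "unique"),
    used_sex = x$used_sex
  )
}
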