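# Cross-reaction genotype matching: the matched skin/PBMC pair placed in two
# different reactions shows up as a pair of clusters with concordant
# consensus genotypes. Matching those clusters links the reactions.

# connected components of the matched-edge graph over (reaction, cluster) nodes
mg_components <- function(nodes, matched_edges) {
  node_key <- paste(nodes$reaction_id, nodes$cluster, sep = ":")
  gr <- igraph::graph_from_data_frame(
    d = tibble(
      from = paste(matched_edges$reaction_a, matched_edges$cluster_a, sep = ":"),
      to = paste(matched_edges$reaction_b, matched_edges$cluster_b, sep = ":")
    ),
    directed = FALSE,
    vertices = tibble(name = node_key)
  )
  unname(igraph::components(gr)$membership[node_key])
}

#' Concordance between two consensus genotype call vectors
#'
#' Over loci where both vectors carry a confident call (0, 0.5 or 1), the
#' score is the fraction of identical calls. When fewer than
#' `min_shared_loci` loci are co-called the comparison is a no-call
#' (`score = NA`), which is distinct from a low score.
#'
#' @param g_a,g_b Numeric call vectors (values 0, 0.5, 1 or `NA`) indexed on
#'   a common locus set.
#' @param min_shared_loci Minimum co-called loci for a valid comparison
#'   (default 20).
#' @return A one-row tibble: `score`, `n_shared`, `callable` (whether the
#'   shared-locus requirement was met).
#' @export
genotype_concordance <- function(g_a, g_b, min_shared_loci = 20L) {
  if (length(g_a) != length(g_b)) abort("call vectors must share a locus set")
  both <- !is.na(g_a) & !is.na(g_b)
  n_shared <- sum(both)
  callable <- n_shared >= min_shared_loci
  score <- if (callable) mean(g_a[both] == g_b[both]) else NA_real_
  tibble(score = score, n_shared = n_shared, callable = callable)
}

#' Match shared genotype clusters across reactions
#'
#' Computes pairwise genotype concordance between every cross-reaction pair
#' of clusters and adds an edge where the score reaches `tau_match`.
#' Connected components of the resulting graph are the putative same-donor
#' equivalence classes. A node matching two or more clusters within one
#' other reaction is a conflict and is surfaced, never silently resolved.
#' Scores within `borderline_margin` below the threshold are flagged
#' `borderline` in the edge table for manual review.
#'
#' @param genotype_sets Named list (by reaction id) of loci x clusters call
#'   matrices as produced by [consensus_genotypes()], all indexed on a
#'   shared locus universe (matched by rowname intersection).
#' @param tau_match Concordance threshold for declaring a shared genotype
#'   (default 0.9).
#' @param min_shared_loci Minimum co-called loci per comparison (default 20).
#' @param borderline_margin Width of the near-threshold flag band
#'   (default 0.05).
#' @return A `match_graph`: list with `nodes` (tibble `reaction_id`,
#'   `cluster`, `component`), `edges` (all scored cross-reaction pairs),
#'   `conflicts`, and `comparable_pairs` (reaction pairs whose locus overlap
#'   met `min_shared_loci`, where absence of a match is informative).
#' @export
match_shared_clusters <- function(genotype_sets, tau_match = 0.9,
                                  min_shared_loci = 20L,
                                  borderline_margin = 0.05) {
  if (length(genotype_sets) < 2L) abort("need consensus genotypes for at least 2 reactions")
  if (is.null(names(genotype_sets))) abort("genotype_sets must be named by reaction id")
  common <- Reduce(intersect, lapply(genotype_sets, rownames))
  if (length(common) == 0L) abort("empty locus intersection across reactions")
  mats <- lapply(genotype_sets, function(m) m[common, , drop = FALSE])

  nodes <- bind_rows(imap(mats, function(m, rid) {
    tibble(reaction_id = rid, cluster = colnames(m))
  }))
  rids <- names(mats)

  edges <- list()
  comparable <- list()
  for (i in seq_along(rids)) {
    for (j in seq_along(rids)) {
      if (j <= i) next
      pair_ok <- FALSE
      for (ka in colnames(mats[[i]])) {
        for (kb in colnames(mats[[j]])) {
          cc <- genotype_concordance(mats[[i]][, ka], mats[[j]][, kb], min_shared_loci)
          pair_ok <- pair_ok || cc$callable
          edges[[length(edges) + 1L]] <- tibble(
            reaction_a = rids[i], cluster_a = ka,
            reaction_b = rids[j], cluster_b = kb,
            score = cc$score, n_shared = cc$n_shared,
            matched = cc$callable && !is.na(cc$score) && cc$score >= tau_match,
            borderline = cc$callable && !is.na(cc$score) &&
              cc$score < tau_match && cc$score >= tau_match - borderline_margin
          )
        }
      }
      if (pair_ok) {
        comparable[[length(comparable) + 1L]] <-
          tibble(reaction_a = rids[i], reaction_b = rids[j])
      }
    }
  }
  edges <- bind_rows(edges)
  comparable <- if (length(comparable)) bind_rows(comparable) else
    tibble(reaction_a = character(0), reaction_b = character(0))

  matched <- edges |> filter(.data$matched)
  nodes$component <- mg_components(nodes, matched)

  conflicts <- bind_rows(
    matched |> transmute(node = paste(.data$reaction_a, .data$cluster_a, sep = ":"),
                         other_reaction = .data$reaction_b),
    matched |> transmute(node = paste(.data$reaction_b, .data$cluster_b, sep = ":"),
                         other_reaction = .data$reaction_a)
  ) |>
    count(.data$node, .data$other_reaction) |>
    filter(.data$n >= 2L)
  conflict_nodes <- unique(conflicts$node)

  structure(
    list(
      nodes = nodes,
      edges = edges,
      conflicts = conflict_nodes,
      comparable_pairs = comparable,
      tau_match = tau_match,
      min_shared_loci = min_shared_loci
    ),
    class = "match_graph"
  )
}

#' @export
print.match_graph <- function(x, ...) {
  cat(sprintf(
    "<match_graph: %d nodes, %d matched edges, %d components, %d conflict(s)>\n",
    nrow(x$nodes), sum(x$edges$matched), dplyr::n_distinct(x$nodes$component),
    length(x$conflicts)
  ))
  invisible(x)
}

#' @export
tidy.match_graph <- function(x, ...) {
  x$edges
}

#' @export
glance.match_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = sum(x$edges$matched),
    n_components = dplyr::n_distinct(x$nodes$component),
    n_conflicts = length(x$conflicts),
    tau_match = x$tau_match
  )
}

#' Plot the cross-reaction concordance score distribution
#'
#' @param object A `match_graph`.
#' @param ... Unused.
#' @return A ggplot histogram of concordance scores with the matching
#'   threshold marked; same-donor pairs should separate cleanly above it.
#' @export
autoplot.match_graph <- function(object, ...) {
  df <- object$edges |> filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$matched)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$tau_match, linetype = "dashed") +
    ggplot2::labs(x = "genotype concordance", y = "cluster pairs") +
    ggplot2::theme_minimal()
}
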