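#' Pooling designs
#'
#' A `pooling_design` records how paired skin/PBMC samples are distributed
#' across pooled 10x reactions so that every genotype cluster can later be
#' traced back to a specific sample. It holds the strategy (`"dual"` for
#' two-sample pools, `"triplet"` for three-sample sex-encoded pools), a long
#' reaction/member table, the sample table, and the anchor bookkeeping (the
#' donors whose matched pair deliberately spans a pair of reactions).
#'
#' @param strategy `"dual"` or `"triplet"`.
#' @param reactions Tibble with columns `reaction_id`, `sample_id` (one row
#'   per pooled sample, slot order preserved).
#' @param samples Tibble with columns `sample_id`, `donor_id`, `tissue`,
#'   `sex`.
#' @param anchors Tibble with columns `donor_id`, `reaction_a`, `reaction_b`.
#' @return A `pooling_design` object.
#' @keywords internal
new_pooling_design <- function(strategy, reactions, samples, anchors) {
  design <- structure(
    list(
      strategy = strategy,
      reactions = as_tibble(reactions),
      samples = as_tibble(samples),
      anchors = as_tibble(anchors)
    ),
    class = "pooling_design"
  )
  validate_pooling_design(design)
}

validate_pooling_design <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  if (!design$strategy %in% c("dual", "triplet")) {
    abort("strategy must be 'dual' or 'triplet'")
  }
  rx <- design$reactions
  smp <- design$samples
  if (anyDuplicated(smp$sample_id)) abort("duplicated sample_id in design")
  if (anyDuplicated(smp[, c("donor_id", "tissue")])) {
    abort("each donor contributes at most one sample per tissue")
  }
  if (!setequal(rx$sample_id, smp$sample_id) || anyDuplicated(rx$sample_id)) {
    abort("every sample must appear in exactly one reaction")
  }
  long <- left_join(rx, smp, by = "sample_id")
  per_rxn <- long |> count(.data$reaction_id, name = "n_members")
  want <- if (design$strategy == "dual") 2L else 3L
  if (!all(per_rxn$n_members == want)) {
    abort(sprintf("every %s reaction must pool exactly %d samples", design$strategy, want))
  }
  dup_donor <- long |> count(.data$reaction_id, .data$donor_id) |> filter(.data$n > 1)
  if (nrow(dup_donor)) {
    abort("no two samples in one reaction may come from the same donor")
  }
  same_rxn_pair <- long |> count(.data$donor_id, .data$reaction_id) |> filter(.data$n > 1)
  if (nrow(same_rxn_pair)) abort("a donor's skin and PBMC must sit in different reactions")
  if (design$strategy == "triplet" && nrow(design$anchors)) {
    anchor_rxns <- c(design$anchors$reaction_a, design$anchors$reaction_b)
    for (k in seq_len(nrow(design$anchors))) {
      a <- design$anchors[k, ]
      for (rid in c(a$reaction_a, a$reaction_b)) {
        fillers <- long |>
          filter(.data$reaction_id == rid, .data$donor_id != a$donor_id)
        if (length(unique(fillers$sex)) != 2L) {
          abort(sprintf(
            "triplet reaction %s: the two non-anchor members must come from donors of different sexes", rid
          ))
        }
      }
    }
  }
  design
}

#' @export
print.pooling_design <- function(x, ...) {
  cost <- glance(x)
  cat(sprintf(
    "<pooling_design: %s strategy, %d reactions, %d samples (%.1fx fewer reactions)>\n",
    x$strategy, cost$n_reactions, cost$n_samples, cost$fold_reduction
  ))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a pooling design into its long reaction/member table
#'
#' @param x A `pooling_design`.
#' @param ... Unused.
#' @return A tibble with one row per pooled sample: `reaction_id`,
#'   `sample_id`, `donor_id`, `tissue`, `sex`, and `is_anchor` (whether the
#'   donor's matched pair spans a designated reaction pair).
#' @export
tidy.pooling_design <- function(x, ...) {
  left_join(x$reactions, x$samples, by = "sample_id") |>
    mutate(is_anchor = .data$donor_id %in% x$anchors$donor_id)
}

#' Summarize a design's pooling economy
#'
#' One reaction per pooled tube versus one reaction per sample: the fold
#' reduction in reactions (and hence in per-reaction reagent cost) is
#' `n_samples / n_reactions`.
#'
#' @param x A `pooling_design`.
#' @param ... Unused.
#' @return A one-row tibble: `strategy`, `n_reactions`, `n_samples`,
#'   `n_donors`, `fold_reduction`.
#' @export
glance.pooling_design <- function(x, ...) {
  design_cost(x)
}

#' @rdname glance.pooling_design
#' @param design A `pooling_design`.
#' @export
design_cost <- function(design) {
  stopifnot(inherits(design, "pooling_design"))
  if (nrow(design$reactions) == 0) abort("empty design")
  tibble(
    strategy = design$strategy,
    n_reactions = dplyr::n_distinct(design$reactions$reaction_id),
    n_samples = nrow(design$samples),
    n_donors = dplyr::n_distinct(design$samples$donor_id),
    fold_reduction = nrow(design$samples) / dplyr::n_distinct(design$reactions$reaction_id)
  )
}

#' Plot the reaction-by-donor layout of a pooling design
#'
#' @param object A `pooling_design`.
#' @param ... Unused.
#' @return A ggplot: donors on the x axis, reactions on the y axis, tiles
#'   labelled by tissue; anchors outlined.
#' @export
autoplot.pooling_design <- function(object, ...) {
  long <- tidy(object)
  rxn_levels <- unique(object$reactions$reaction_id)
  long$reaction_id <- factor(long$reaction_id, levels = rev(rxn_levels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$donor_id, y = .data$reaction_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$tissue), color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$is_anchor, "★", "")), size = 3) +
    ggplot2::labs(
      x = "donor", y = "reaction",
      title = sprintf("%s pooling design (%d reactions, %d samples)",
                      object$strategy, length(rxn_levels), nrow(object$samples)),
      caption = "★ anchor donor (matched pair spans a reaction pair)"
    ) +
    ggplot2::theme_minimal()
}

# ---------------------------------------------------------------------------
# Strategy 1: dual pools. Donors are partitioned into "chains" (length 3 by
# default; the final chain absorbs any remainder, length 3-5). A chain of m
# donors d1..dm produces m-1 two-sample reactions alternating tissue:
#   r1 = {skin d1, skin d2}, r2 = {pbmc d2, pbmc d3}, r3 = {skin d3, skin d4} ...
# so every interior donor's matched pair spans two consecutive reactions
# (these are the anchors). The chain leaves pbmc(d1) and skin/pbmc(dm)
# pending; pending samples from all chains are paired tissue-by-tissue into
# closing reactions, with one mixed-tissue closing reaction when the counts
# are odd. Total reactions = number of donors.
# ---------------------------------------------------------------------------

#' Generate a dual (two-sample) pooling design
#'
#' Splits each donor's matched skin/PBMC pair across two reactions and fills
#' every reaction to two genetically unrelated samples, so that shared
#' genotypes across reactions uniquely decode every cluster's identity
#' without any label and without sex information. Processes N paired samples
#' in N reactions instead of 2N.
#'
#' @param roster A roster tibble (see [make_roster()]); at least 3 donors,
#'   each contributing both tissues.
#' @param verify Run the exhaustive identifiability check on the generated
#'   design (default `TRUE`; cheap at desk scale).
#' @return A `pooling_design` with `strategy = "dual"` and one reaction per
#'   donor.
#' @examples
#' design <- design_strategy1(make_roster(paste0("S", 1:9)))
#' glance(design)
#' @export
design_strategy1 <- function(roster, verify = TRUE) {
  roster <- validate_roster(roster)
  n <- nrow(roster)
  if (n < 3) {
    abort(paste(
      "dual pooling needs at least 3 donors: with 2 donors the only possible",
      "filler is the other donor's paired sample, which is not allowed"
    ))
  }
  donors <- sort(roster$donor_id)
  samples <- roster_samples(roster)

  # chain lengths: all 3s, last chain absorbs the remainder (3, 4 or 5)
  n_chains <- max(1L, n %/% 3L)
  lens <- rep(3L, n_chains)
  lens[n_chains] <- n - 3L * (n_chains - 1L)
  chains <- split(donors, rep(seq_len(n_chains), lens))

  rxn_members <- list()
  anchors <- list()
  pending_skin <- character(0)
  pending_pbmc <- character(0)
  for (chain in chains) {
    m <- length(chain)
    for (j in seq_len(m - 1L)) {
      tissue <- if (j %% 2L == 1L) "skin" else "pbmc"
      rxn_members[[length(rxn_members) + 1L]] <-
        paste0(chain[c(j, j + 1L)], "_", tissue)
    }
    if (m > 2L) {
      for (j in 2:(m - 1L)) {
        anchors[[length(anchors) + 1L]] <-
          tibble(donor_id = chain[j], idx_a = length(rxn_members) - m + j,
                 idx_b = length(rxn_members) - m + j + 1L)
      }
    }
    pending_pbmc <- c(pending_pbmc, paste0(chain[1L], "_pbmc"))
    if (m %% 2L == 1L) {
      pending_skin <- c(pending_skin, paste0(chain[m], "_skin"))
    } else {
      pending_pbmc <- c(pending_pbmc, paste0(chain[m], "_pbmc"))
    }
  }

  # closing reactions: pair pendings tissue by tissue; odd leftovers form one
  # mixed-tissue closing reaction (cf. a dual design's final Skin+PBMC tube)
  pair_up <- function(v) {
    k <- length(v) %/% 2L
    lapply(seq_len(k), function(i) v[c(2L * i - 1L, 2L * i)])
  }
  rxn_members <- c(rxn_members, pair_up(pending_skin), pair_up(pending_pbmc))
  left_skin <- if (length(pending_skin) %% 2L == 1L) pending_skin[length(pending_skin)] else character(0)
  left_pbmc <- if (length(pending_pbmc) %% 2L == 1L) pending_pbmc[length(pending_pbmc)] else character(0)
  if (length(left_skin) + length(left_pbmc) == 2L) {
    rxn_members[[length(rxn_members) + 1L]] <- c(left_pbmc, left_skin)
  } else if (length(left_skin) + length(left_pbmc) == 1L) {
    abort("internal error: unpaired pending sample") # parity guarantees this never fires
  }

  rxn_ids <- sprintf("R%02d", seq_along(rxn_members))
  reactions <- tibble(
    reaction_id = rep(rxn_ids, lengths(rxn_members)),
    sample_id = unlist(rxn_members)
  )
  anchors <- if (length(anchors)) {
    bind_rows(anchors) |>
      mutate(reaction_a = rxn_ids[.data$idx_a], reaction_b = rxn_ids[.data$idx_b]) |>
      select("donor_id", "reaction_a", "reaction_b")
  } else {
    tibble(donor_id = character(0), reaction_a = character(0), reaction_b = character(0))
  }

  design <- new_pooling_design("dual", reactions, samples, anchors)
  if (verify) {
    rep <- check_identifiability(design, use_sex = FALSE)
    if (!rep$identifiable) {
      abort("internal error: generated dual design is not identifiable")
    }
  }
  design
}

# ---------------------------------------------------------------------------
# Strategy 2: triplet pools with sex encoding. N/3 anchor donors each span a
# dual reaction pair (block); each reaction is filled with two samples from
# filler donors of different sexes. Filler k's skin sits in block k and its
# PBMC in block k-1 (cyclically), so no filler pair sits inside one block and
# each dual pair shares exactly one genotype (the anchor's).
# ---------------------------------------------------------------------------

#' Generate a triplet (three-sample, sex-encoded) pooling design
#'
#' Pools three samples per reaction: one member of an anchor donor's matched
#' pair plus two filler samples from donors of different sexes. Shared
#' genotype across the dual reaction pair identifies the anchor; the
#' Y-chromosome expression of the remaining two clusters identifies which
#' filler is which. Processes N paired samples in 2N/3 reactions instead of
#' 2N. Requires all donor sexes known, N >= 6 and N divisible by 3, and a
#' sex composition with between N/3 and 2N/3 donors of each sex.
#'
#' @inheritParams design_strategy1
#' @return A `pooling_design` with `strategy = "triplet"` and 2N/3 reactions.
#' @examples
#' roster <- make_roster(paste0("S", 1:9), rep(c("male", "female", "male"), 3))
#' design <- design_strategy2(roster)
#' glance(design)
#' @export
design_strategy2 <- function(roster, verify = TRUE) {
  roster <- validate_roster(roster)
  n <- nrow(roster)
  if (n < 6 || n %% 3L != 0L) {
    abort("triplet pooling needs at least 6 donors, in multiples of 3")
  }
  if (any(roster$sex == "unknown")) {
    abort("triplet pooling encodes donor sex: all sexes must be known")
  }
  k <- n %/% 3L
  males <- sort(roster$donor_id[roster$sex == "male"])
  females <- sort(roster$donor_id[roster$sex == "female"])
  n_male_anchors <- length(males) - k
  n_female_anchors <- length(females) - k
  if (n_male_anchors < 0) {
    abort(sprintf(
      "infeasible sex composition: need %d male filler donors but only %d males available",
      k, length(males)
    ))
  }
  if (n_female_anchors < 0) {
    abort(sprintf(
      "infeasible sex composition: need %d female filler donors but only %d females available",
      k, length(females)
    ))
  }
  anchors_d <- sort(c(head(males, n_male_anchors), head(females, n_female_anchors)))
  filler_m <- setdiff(males, anchors_d)
  filler_f <- setdiff(females, anchors_d)

  samples <- roster_samples(roster)
  reactions <- list()
  anchor_rows <- list()
  for (b in seq_len(k)) {
    prev <- if (b == 1L) k else b - 1L
    rid_a <- sprintf("R%02d", 2L * b - 1L)
    rid_b <- sprintf("R%02d", 2L * b)
    reactions[[rid_a]] <- c(
      paste0(anchors_d[b], "_pbmc"),
      paste0(filler_m[b], "_skin"),
      paste0(filler_f[b], "_skin")
    )
    reactions[[rid_b]] <- c(
      paste0(anchors_d[b], "_skin"),
      paste0(filler_m[prev], "_pbmc"),
      paste0(filler_f[prev], "_pbmc")
    )
    anchor_rows[[b]] <- tibble(
      donor_id = anchors_d[b], reaction_a = rid_a, reaction_b = rid_b
    )
  }
  reactions_tbl <- tibble(
    reaction_id = rep(names(reactions), lengths(reactions)),
    sample_id = unlist(reactions, use.names = FALSE)
  )
  design <- new_pooling_design("triplet", reactions_tbl, samples, bind_rows(anchor_rows))
  if (verify) {
    rep <- check_identifiability(design, use_sex = TRUE)
    if (!rep$identifiable) {
      abort("internal error: generated triplet design is not identifiable with sex")
    }
  }
  design
}

# ---------------------------------------------------------------------------
# Identifiability checking
# ---------------------------------------------------------------------------

#' Check whether a pooling design is uniquely decodable
#'
#' Constructs the noise-free observables the experiment would yield — the
#' partition of per-reaction genotype clusters into same-donor equivalence
#' classes across reactions, and optionally a sex label per cluster — and
#' counts, by exhaustive enumeration with pruning, every assignment of the
#' pooled samples to clusters that is consistent with those observables. The
#' design is identifiable when exactly one assignment survives.
#'
#' @param design A `pooling_design`.
#' @param use_sex Include per-cluster sex labels among the observables
#'   (requires all donor sexes known).
#' @return An `identifiability_report`: a list with
#'   `n_consistent_assignments`, `identifiable`, `ambiguous_groups` (sets of
#'   interchangeable `(reaction_id, sample_id)` slots), and `used_sex`.
#' @examples
#' design <- design_strategy1(make_roster(paste0("S", 1:3)), verify = FALSE)
#' check_identifiability(design, use_sex = FALSE)
#' @export
check_identifiability <- function(design, use_sex = FALSE) {
  design <- validate_pooling_design(design)
  long <- left_join(design$reactions, design$samples, by = "sample_id")
  if (use_sex && any(long$sex == "unknown")) {
    abort("use_sex = TRUE requires all donor sexes known")
  }
  slots <- tibble(
    reaction_id = long$reaction_id,
    truth = long$sample_id,
    group = long$donor_id,
    sex = if (use_sex) long$sex else NA_character_
  )
  members <- split(design$reactions$sample_id, design$reactions$reaction_id)
  res <- solve_slot_assignment(slots, members, design$samples,
                               comparable = "all", max_store = 0L)
  stopifnot(res$n_solutions >= 1L) # the ground truth itself is always consistent

  amb <- tibble(
    reaction_id = res$slots$reaction_id,
    sample_id = res$slots$truth,
    key = map_chr(res$possible, function(p) paste(sort(p), collapse = "|")),
    n_possible = lengths(res$possible)
  ) |> filter(.data$n_possible > 1)
  groups <- if (nrow(amb)) {
    unname(lapply(split(seq_len(nrow(amb)), amb$key),
                  function(i) amb[i, c("reaction_id", "sample_id")]))
  } else {
    list()
  }

  structure(
    list(
      n_consistent_assignments = res$n_solutions,
      identifiable = res$n_solutions == 1L,
      ambiguous_groups = groups,
      used_sex = use_sex
    ),
    class = "identifiability_report"
  )
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf(
    "<identifiability_report: %s (%d consistent assignment%s, sex %s)>\n",
    if (x$identifiable) "identifiable" else "NOT identifiable",
    x$n_consistent_assignments,
    if (x$n_consistent_assignments == 1L) "" else "s",
    if (x$used_sex) "used" else "not used"
  ))
  if (length(x$ambiguous_groups)) {
    cat("interchangeable slot groups:\n")
    for (g in x$ambiguous_groups) {
      cat("  ", paste(g$reaction_id, g$sample_id, sep = ":", collapse = " <-> "), "\n")
    }
  }
  invisible(x)
}

#' @export
tidy.identifiability_report <- function(x, ...) {
  tibble(
    n_consistent_assignments = x$n_consistent_assignments,
    identifiable = x$identifiable,
    n_ambiguous_groups = length(x$ambiguous_groups),
    used_sex = x$used_sex
  )
}
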