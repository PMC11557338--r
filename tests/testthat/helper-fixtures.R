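# Shared fixtures, all generated in code under fixed seeds.

# nine donors, six male / three female: feasible for both strategies
tt_roster9 <- function() {
  make_roster(paste0("S", 1:9), rep(c("male", "female", "male"), 3))
}

roster_samples_tt <- function(roster) pairpool:::roster_samples(roster)

# one simulated reaction pooling skin samples of `donors`
tt_sim_reaction <- function(donors, sexes = "male", config = sim_config()) {
  roster <- make_roster(donors, sexes)
  samples <- roster_samples_tt(roster)
  rx <- tibble::tibble(reaction_id = "R1", sample_id = paste0(sort(donors), "_skin"))
  keep <- samples$sample_id %in% rx$sample_id
  # reactions of 2 or 3 members only; pad class invariants by hand
  design <- structure(
    list(strategy = if (length(donors) == 2L) "dual" else "triplet",
         reactions = rx, samples = samples[keep, ],
         anchors = tibble::tibble(donor_id = character(0), reaction_a = character(0),
                                  reaction_b = character(0))),
    class = "pooling_design"
  )
  genotypes <- simulate_donor_genotypes(roster, config)
  list(design = design, genotypes = genotypes,
       sim = simulate_reaction(design, "R1", genotypes, config))
}

# cached default two-donor simulation shared across test files
tt_cache <- new.env(parent = emptyenv())
tt_default_2donor <- function() {
  if (is.null(tt_cache$sim2)) {
    tt_cache$sim2 <- tt_sim_reaction(c("A", "B"), c("male", "female"),
                                     sim_config(doublet_rate = 0, seed = 42))
  }
  tt_cache$sim2
}

# noise-free consensus call matrices derived directly from donor genotypes:
# cluster j of each reaction is exactly its j-th pooled sample's donor
tt_noisefree_sets <- function(design, genotypes) {
  rxns <- unique(design$reactions$reaction_id)
  donor_of <- stats::setNames(design$samples$donor_id, design$samples$sample_id)
  sets <- lapply(rxns, function(rid) {
    members <- design$reactions$sample_id[design$reactions$reaction_id == rid]
    m <- genotypes$calls[, donor_of[members], drop = FALSE] / 2
    colnames(m) <- as.character(seq_along(members) - 1L)
    m
  })
  names(sets) <- rxns
  sets
}

# ground-truth (reaction, cluster) -> sample_id implied by tt_noisefree_sets
tt_noisefree_truth <- function(design) {
  design$reactions |>
    dplyr::group_by(reaction_id) |>
    dplyr::mutate(cluster = as.character(dplyr::row_number() - 1L)) |>
    dplyr::ungroup()
}

# complete-data log-likelihood of a hard labeling (independent oracle)
tt_hard_ll <- function(alt, ref, labels, K, eps = 0.01) {
  q <- sapply(seq_len(K), function(k) {
    a <- rowSums(alt[, labels == k, drop = FALSE])
    d <- a + rowSums(ref[, labels == k, drop = FALSE])
    pmin(pmax(ifelse(d > 0, a / d, 0.5), eps), 1 - eps)
  })
  sum(sapply(seq_len(ncol(alt)), function(c) {
    sum(alt[, c] * log(q[, labels[c]]) + ref[, c] * log(1 - q[, labels[c]]))
  }))
}
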