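# Y-gene sex inference and constraint-based identity resolution.

test_that("the default Y panel is the nine-gene list and ships as extdata", {
  expect_equal(y_genes(),
               c("ZFY", "RPS4Y1", "EIF1AY", "KDM5D", "NLGN4Y", "TMSB4Y",
                 "UTY", "DDX3Y", "USP9Y"))
  shipped <- read_y_genes(system.file("extdata", "ygenes.txt", package = "pairpool"))
  expect_equal(shipped, y_genes())
})

test_that("sex calls follow the Y-expression share with correct edge handling", {
  fx <- tt_default_2donor()   # donor A male, donor B female
  fit <- fit_genotype_clusters(fx$sim$ref, fx$sim$alt, K = 2, seed = 7)
  asg <- call_doublets(fit)
  calls <- infer_sex(fx$sim$expression, asg, reaction_id = "R1")
  truth <- fx$sim$truth
  donor_of_cluster <- sapply(0:1, function(k) {
    cells <- asg$barcode[asg$status == "singlet" & asg$cluster == k]
    names(which.max(table(truth$donor_id[truth$barcode %in% cells])))
  })
  expected <- ifelse(donor_of_cluster == "A", "male", "female")
  expect_equal(calls$call, unname(expected[as.integer(calls$cluster) + 1L]))
  # male clusters separate from female leak by far more than 10x
  expect_gt(min(calls$y_pct[calls$call == "male"]),
            10 * max(calls$y_pct[calls$call == "female"]))

  # zero Y counts give y_pct 0 and a female call
  expr0 <- fx$sim$expression
  expr0[y_genes(), ] <- 0
  calls0 <- infer_sex(expr0, asg)
  expect_true(all(calls0$y_pct == 0))
  expect_true(all(calls0$call == "female"))

  # missing panel genes: warn when some, error when all
  expr_some <- fx$sim$expression[setdiff(rownames(fx$sim$expression), "ZFY"), ]
  expect_warning(infer_sex(expr_some, asg), "ZFY")
  expr_none <- fx$sim$expression[1:50, ]
  expect_error(infer_sex(expr_none, asg), "none of the Y genes")
})

test_that("noise-free dual-design observables resolve uniquely without sex", {
  roster <- make_roster(paste0("S", 1:9))
  design <- design_strategy1(roster, verify = FALSE)
  genotypes <- simulate_donor_genotypes(roster, sim_config(n_loci = 150, seed = 4))
  mg <- match_shared_clusters(tt_noisefree_sets(design, genotypes))
  res <- resolve_identities(design, mg)
  expect_equal(res$status, "unique")
  expect_equal(nrow(res$mapping), 18L)
  truth <- tt_noisefree_truth(design)
  joined <- dplyr::left_join(res$mapping, truth, by = c("reaction_id", "cluster"),
                             suffix = c("", "_true"))
  expect_equal(joined$sample_id, joined$sample_id_true)
})

test_that("triplet resolution needs sex, and anchor-edge loss degrades to explicit ambiguity", {
  roster <- tt_roster9()
  design <- design_strategy2(roster, verify = FALSE)
  genotypes <- simulate_donor_genotypes(roster, sim_config(n_loci = 150, seed = 4))
  mg <- match_shared_clusters(tt_noisefree_sets(design, genotypes))
  truth <- tt_noisefree_truth(design) |>
    dplyr::left_join(design$samples, by = "sample_id")
  sex_calls <- truth |>
    dplyr::transmute(reaction_id, cluster, call = sex)

  with_sex <- resolve_identities(design, mg, sex_calls)
  expect_equal(with_sex$status, "unique")
  joined <- dplyr::left_join(with_sex$mapping, truth, by = c("reaction_id", "cluster"),
                             suffix = c("", "_true"))
  expect_equal(joined$sample_id, joined$sample_id_true)

  no_sex <- resolve_identities(design, mg)
  expect_equal(no_sex$status, "ambiguous")
  expect_gt(no_sex$n_consistent, 1L)
  # solution-set monotonicity: sex only ever narrows the consistent set
  expect_lte(with_sex$n_consistent, no_sex$n_consistent)

  # deleting one anchor's match edge leaves its block ambiguous, never guessed
  anchor <- design$anchors[1, ]
  anchor_samples <- design$samples$sample_id[design$samples$donor_id == anchor$donor_id]
  truth_slots <- tt_noisefree_truth(design)
  aslots <- truth_slots[truth_slots$sample_id %in% anchor_samples, ]
  drop <- mg
  hit <- with(drop$edges, matched &
                paste(reaction_a, cluster_a) %in% paste(aslots$reaction_id, aslots$cluster) &
                paste(reaction_b, cluster_b) %in% paste(aslots$reaction_id, aslots$cluster))
  expect_equal(sum(hit), 1L)
  drop$edges$matched[hit] <- FALSE
  drop$nodes$component <- pairpool:::mg_components(drop$nodes,
                                                   drop$edges[drop$edges$matched, ])
  # a missed match means the pair lacked usable shared loci: absence of an
  # edge there is missing data, so the pair is no longer comparable
  pair <- sort(c(anchor$reaction_a, anchor$reaction_b))
  drop$comparable_pairs <- drop$comparable_pairs |>
    dplyr::filter(!(reaction_a == pair[1] & reaction_b == pair[2]))
  # constraint removal can only enlarge the consistent set, never flip to a
  # silent wrong guess; with sex the fillers' own cross-block matches still
  # pin the block by elimination
  dropped <- resolve_identities(design, drop, sex_calls)
  expect_gte(dropped$n_consistent, with_sex$n_consistent)
  still_unique <- dropped$mapping[dropped$mapping$status == "unique", ]
  joined_drop <- dplyr::left_join(still_unique, truth,
                                  by = c("reaction_id", "cluster"),
                                  suffix = c("", "_true"))
  expect_equal(joined_drop$sample_id, joined_drop$sample_id_true)

  # without the sex layer the lost anchor makes the whole block symmetric:
  # the ambiguity grows beyond the filler swaps and is listed, not guessed
  dropped_nosex <- resolve_identities(design, drop)
  expect_equal(dropped_nosex$status, "ambiguous")
  expect_gte(dropped_nosex$n_consistent, no_sex$n_consistent)
  amb_slots <- dplyr::bind_rows(dropped_nosex$ambiguous_groups)
  expect_true(all(c(anchor$reaction_a, anchor$reaction_b) %in% amb_slots$reaction_id))
})

test_that("resolution reproduces ground truth whenever the checker proves identifiability", {
  for (n in c(6L, 9L, 12L)) {
    roster <- make_roster(sprintf("D%02d", 1:n),
                          rep(c("male", "female"), length.out = n))
    genotypes <- simulate_donor_genotypes(roster, sim_config(n_loci = 150, seed = n))
    configs <- list(
      list(design = design_strategy1(roster, verify = FALSE), use_sex = FALSE),
      list(design = design_strategy2(roster, verify = FALSE), use_sex = TRUE)
    )
    for (cfg in configs) {
      design <- cfg$design
      expect_true(check_identifiability(design, use_sex = cfg$use_sex)$identifiable)
      mg <- match_shared_clusters(tt_noisefree_sets(design, genotypes))
      truth <- tt_noisefree_truth(design) |>
        dplyr::left_join(design$samples, by = "sample_id")
      sex_calls <- if (cfg$use_sex) {
        truth |> dplyr::transmute(reaction_id, cluster, call = sex)
      } else NULL
      res <- resolve_identities(design, mg, sex_calls)
      expect_equal(res$status, "unique")
      joined <- dplyr::left_join(res$mapping, truth, by = c("reaction_id", "cluster"),
                                 suffix = c("", "_true"))
      expect_equal(joined$sample_id, joined$sample_id_true)
    }
  }
})

test_that("contradictory sex calls yield an inconsistent status with a witness", {
  roster <- tt_roster9()
  design <- design_strategy2(roster, verify = FALSE)
  genotypes <- simulate_donor_genotypes(roster, sim_config(n_loci = 150, seed = 4))
  mg <- match_shared_clusters(tt_noisefree_sets(design, genotypes))
  truth <- tt_noisefree_truth(design) |>
    dplyr::left_join(design$samples, by = "sample_id")
  flipped <- truth |>
    dplyr::transmute(reaction_id, cluster,
                     call = ifelse(sex == "male", "female", "male"))
  res <- resolve_identities(design, mg, flipped)
  expect_equal(res$status, "inconsistent")
  expect_match(res$witness, "sex")
})

test_that("pool-size mismatches between match graph and design are rejected", {
  roster <- tt_roster9()
  design <- design_strategy2(roster, verify = FALSE)
  genotypes <- simulate_donor_genotypes(roster, sim_config(n_loci = 150, seed = 4))
  mg <- match_shared_clusters(tt_noisefree_sets(design, genotypes))
  mg$nodes <- mg$nodes[-1, ]
  expect_error(resolve_identities(design, mg), "pool sizes")
})
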