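# Pooling-design generators and the exhaustive identifiability checker.

test_that("the nine-donor dual design reproduces the canonical block layout", {
  design <- design_strategy1(make_roster(paste0("S", 1:9)))
  expect_equal(glance(design)$n_reactions, 9L)
  expect_equal(glance(design)$n_samples, 18L)
  members <- split(design$reactions$sample_id, design$reactions$reaction_id)
  # three chains of three donors, then skin-pair, pbmc-pair and mixed closers
  expect_equal(members$R01, c("S1_skin", "S2_skin"))
  expect_equal(members$R02, c("S2_pbmc", "S3_pbmc"))
  expect_equal(members$R03, c("S4_skin", "S5_skin"))
  expect_equal(members$R04, c("S5_pbmc", "S6_pbmc"))
  expect_equal(members$R05, c("S7_skin", "S8_skin"))
  expect_equal(members$R06, c("S8_pbmc", "S9_pbmc"))
  expect_equal(members$R07, c("S3_skin", "S6_skin"))
  expect_equal(members$R08, c("S1_pbmc", "S4_pbmc"))
  expect_setequal(members$R09, c("S7_pbmc", "S9_skin"))
  expect_setequal(design$anchors$donor_id, c("S2", "S5", "S8"))
})

test_that("dual designs exist, are the right size and decodable for all roster sizes", {
  for (n in 3:15) {
    design <- design_strategy1(make_roster(sprintf("D%02d", 1:n)), verify = FALSE)
    long <- tidy(design)
    expect_equal(dplyr::n_distinct(long$reaction_id), n)
    expect_equal(nrow(long), 2L * n)
    expect_true(all(table(long$reaction_id) == 2L))
    expect_equal(sort(long$sample_id), sort(roster_samples_tt(
      make_roster(sprintf("D%02d", 1:n)))$sample_id))
    report <- check_identifiability(design, use_sex = FALSE)
    expect_true(report$identifiable)
  }
})

test_that("a two-donor roster is rejected: the only filler would be the paired sample", {
  expect_error(design_strategy1(make_roster(c("A", "B"))), "at least 3 donors")
})

test_that("triplet designs pool three samples with sex-discordant fillers", {
  for (n in c(6L, 9L, 12L, 15L)) {
    roster <- make_roster(sprintf("D%02d", 1:n),
                          rep(c("male", "female"), length.out = n))
    design <- design_strategy2(roster, verify = FALSE)
    long <- tidy(design)
    expect_equal(dplyr::n_distinct(long$reaction_id), 2L * n / 3L)
    expect_true(all(table(long$reaction_id) == 3L))
    # anchors span their block; fillers never pair up inside one block
    for (k in seq_len(nrow(design$anchors))) {
      a <- design$anchors[k, ]
      spanned <- long$reaction_id[long$donor_id == a$donor_id]
      expect_setequal(spanned, c(a$reaction_a, a$reaction_b))
    }
    fillers <- setdiff(long$donor_id, design$anchors$donor_id)
    block_of <- stats::setNames(rep(seq_len(nrow(design$anchors)), each = 2L),
                                c(rbind(design$anchors$reaction_a, design$anchors$reaction_b)))
    for (f in fillers) {
      rxns <- long$reaction_id[long$donor_id == f]
      expect_length(unique(block_of[rxns]), 2L)
    }
    # each reaction's two fillers differ in sex
    filler_sexes <- long[long$donor_id %in% fillers, ] |>
      dplyr::count(reaction_id, sex)
    expect_true(all(filler_sexes$n == 1L))
    expect_true(check_identifiability(design, use_sex = TRUE)$identifiable)
  }
})

test_that("triplet pooling rejects infeasible rosters with an informative error", {
  expect_error(design_strategy2(make_roster(paste0("S", 1:7), "male")),
               "multiples of 3")
  expect_error(design_strategy2(tt_roster9() |> dplyr::mutate(sex = "unknown")),
               "sexes must be known")
  expect_error(design_strategy2(make_roster(paste0("S", 1:9), "male")), "female")
  expect_error(design_strategy2(make_roster(paste0("S", 1:9), "female")), "male")
})

test_that("pooling economy follows directly from the layout", {
  d1 <- design_strategy1(make_roster(paste0("S", 1:9)), verify = FALSE)
  expect_equal(design_cost(d1)$fold_reduction, 2.0)
  d2 <- design_strategy2(tt_roster9(), verify = FALSE)
  expect_equal(design_cost(d2)$fold_reduction, 3.0)
  # a single two-sample reaction
  roster <- make_roster(c("A", "B"))
  samples <- roster_samples_tt(roster)
  one <- pairpool:::new_pooling_design(
    "dual",
    tibble::tibble(reaction_id = "R1", sample_id = c("A_skin", "B_pbmc")),
    samples[samples$sample_id %in% c("A_skin", "B_pbmc"), ],
    tibble::tibble(donor_id = character(0), reaction_a = character(0),
                   reaction_b = character(0))
  )
  expect_equal(design_cost(one)$fold_reduction, 2.0)
})

test_that("the checker proves the dual layout decodable and the triplet layout sex-dependent", {
  d1 <- design_strategy1(make_roster(paste0("S", 1:9)), verify = FALSE)
  rep1 <- check_identifiability(d1, use_sex = FALSE)
  expect_true(rep1$identifiable)
  expect_equal(rep1$n_consistent_assignments, 1L)

  d2 <- design_strategy2(tt_roster9(), verify = FALSE)
  rep_nosex <- check_identifiability(d2, use_sex = FALSE)
  expect_false(rep_nosex$identifiable)
  expect_gte(rep_nosex$n_consistent_assignments, 2L)
  # each block's two same-tissue fillers are the interchangeable pairs: 2^3
  expect_equal(rep_nosex$n_consistent_assignments, 8L)
  rep_sex <- check_identifiability(d2, use_sex = TRUE)
  expect_true(rep_sex$identifiable)
})

test_that("the forbidden two-donor swap layout is exactly two-fold ambiguous", {
  roster <- make_roster(c("A", "B"))
  samples <- roster_samples_tt(roster)
  bad <- pairpool:::new_pooling_design(
    "dual",
    tibble::tibble(reaction_id = c("R1", "R1", "R2", "R2"),
                   sample_id = c("A_skin", "B_pbmc", "B_skin", "A_pbmc")),
    samples,
    tibble::tibble(donor_id = character(0), reaction_a = character(0),
                   reaction_b = character(0))
  )
  report <- check_identifiability(bad, use_sex = FALSE)
  expect_equal(report$n_consistent_assignments, 2L)
  expect_false(report$identifiable)
  expect_length(report$ambiguous_groups, 2L)
})

test_that("a filler pair placed inside one dual block breaks identifiability", {
  # six donors: anchors X1 (m), X2 (f); naive layout puts filler M1's pair
  # into block 1 (both reactions), so M1 and the male anchor X1 span the same
  # reaction pair and even sex cannot separate them
  roster <- make_roster(c("X1", "X2", "M1", "M2", "F1", "F2"),
                        c("male", "female", "male", "male", "female", "female"))
  samples <- roster_samples_tt(roster)
  rx <- tibble::tibble(
    reaction_id = rep(c("R1", "R2", "R3", "R4"), each = 3L),
    sample_id = c(
      "X1_pbmc", "M1_skin", "F1_skin",
      "X1_skin", "M1_pbmc", "F1_pbmc",   # naive: M1/F1 pairs inside block 1
      "X2_pbmc", "M2_skin", "F2_skin",
      "X2_skin", "M2_pbmc", "F2_pbmc"
    )
  )
  naive <- pairpool:::new_pooling_design(
    "triplet", rx, samples,
    tibble::tibble(donor_id = c("X1", "X2"), reaction_a = c("R1", "R3"),
                   reaction_b = c("R2", "R4"))
  )
  expect_false(check_identifiability(naive, use_sex = TRUE)$identifiable)
  # the generator's layout for the same roster is identifiable
  proper <- design_strategy2(roster, verify = FALSE)
  expect_true(check_identifiability(proper, use_sex = TRUE)$identifiable)
})

test_that("removing the sex observable never shrinks the consistent set", {
  for (n in c(6L, 9L)) {
    roster <- make_roster(sprintf("D%02d", 1:n),
                          rep(c("male", "female"), length.out = n))
    design <- design_strategy2(roster, verify = FALSE)
    with_sex <- check_identifiability(design, use_sex = TRUE)$n_consistent_assignments
    without <- check_identifiability(design, use_sex = FALSE)$n_consistent_assignments
    expect_gte(without, with_sex)
  }
})

test_that("designs round-trip losslessly through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (design in list(design_strategy1(make_roster(paste0("S", 1:5)), verify = FALSE),
                      design_strategy2(tt_roster9(), verify = FALSE))) {
    write_design_yaml(design, path)
    back <- read_design_yaml(path)
    expect_equal(back$strategy, design$strategy)
    expect_equal(back$reactions, design$reactions)
    expect_equal(back$samples, design$samples)
    expect_equal(back$anchors, design$anchors)
  }
})
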