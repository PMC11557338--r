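# Exhaustive constraint solver shared by the identifiability checker and the
# identity resolver. Variables are (reaction, slot) positions; each slot's
# domain is the set of samples pooled in its reaction. Constraints:
#   * injectivity within each reaction;
#   * all slots carrying the same group label map to samples of one donor;
#   * slots in *different* groups map to different donors, but only across
#     reaction pairs listed as comparable (for the noise-free checker that is
#     every pair; for real data only pairs with adequate locus overlap);
#   * a slot with a sex label only accepts samples from donors of that sex.
# Slots with group NA contribute no genotype constraint (conflicted nodes).
#
# Enumeration is exact: backtracking with forward pruning visits every
# consistent assignment. Full assignments are stored up to `max_store`; the
# per-slot sets of feasible samples are accumulated for all solutions.

solve_slot_assignment <- function(slots, reaction_members, samples,
                                  comparable = "all", max_store = 100L) {
  stopifnot(is.data.frame(slots), nrow(slots) >= 1L)
  n <- nrow(slots)
  ord <- order(slots$reaction_id)
  slots <- slots[ord, , drop = FALSE]

  donor_of <- setNames(samples$donor_id, samples$sample_id)
  sex_of_donor <- setNames(samples$sex, samples$donor_id)

  # normalize group labels to integers, NA kept
  grp <- match(slots$group, unique(stats::na.omit(slots$group)))

  # comparable reaction pairs as a lookup "a||b" (unordered)
  all_comparable <- identical(comparable, "all")
  cmp_key <- character(0)
  if (!all_comparable && nrow(comparable) > 0) {
    cmp_key <- unique(c(
      paste(comparable$reaction_a, comparable$reaction_b, sep = "\r"),
      paste(comparable$reaction_b, comparable$reaction_a, sep = "\r")
    ))
  }
  pair_comparable <- function(ra, rb) {
    all_comparable || paste(ra, rb, sep = "\r") %in% cmp_key
  }

  # diff-donor constraints between group labels
  n_grp <- max(grp, 0L, na.rm = TRUE)
  diff_adj <- vector("list", n_grp)
  if (n_grp > 0) {
    for (i in seq_len(n)) {
      gi <- grp[i]
      if (is.na(gi)) next
      for (j in seq_len(n)) {
        gj <- grp[j]
        if (is.na(gj) || gj == gi) next
        if (slots$reaction_id[i] == slots$reaction_id[j]) next
        if (pair_comparable(slots$reaction_id[i], slots$reaction_id[j])) {
          diff_adj[[gi]] <- union(diff_adj[[gi]], gj)
        }
      }
    }
  }

  domains <- lapply(seq_len(n), function(i) reaction_members[[slots$reaction_id[i]]])

  assignment <- character(n)
  group_donor <- rep(NA_character_, max(n_grp, 1L))
  n_solutions <- 0L
  solutions <- list()
  possible <- lapply(seq_len(n), function(i) character(0))

  has_sex <- "sex" %in% names(slots)

  recurse <- function(i) {
    if (i > n) {
      n_solutions <<- n_solutions + 1L
      if (n_solutions <= max_store) solutions[[n_solutions]] <<- assignment
      for (k in seq_len(n)) possible[[k]] <<- union(possible[[k]], assignment[k])
      return(invisible(NULL))
    }
    rid <- slots$reaction_id[i]
    used <- assignment[seq_len(i - 1L)][slots$reaction_id[seq_len(i - 1L)] == rid]
    gi <- grp[i]
    for (cand in setdiff(domains[[i]], used)) {
      d <- donor_of[[cand]]
      if (has_sex && !is.na(slots$sex[i])) {
        if (!identical(sex_of_donor[[d]], slots$sex[i])) next
      }
      if (!is.na(gi)) {
        fixed <- group_donor[gi]
        if (!is.na(fixed)) {
          if (fixed != d) next
        } else {
          neigh <- diff_adj[[gi]]
          if (length(neigh) && any(!is.na(group_donor[neigh]) &
                                     group_donor[neigh] == d)) next
        }
      }
      assignment[i] <<- cand
      prev <- NA_character_
      if (!is.na(gi)) {
        prev <- group_donor[gi]
        group_donor[gi] <<- d
      }
      recurse(i + 1L)
      if (!is.na(gi)) group_donor[gi] <<- prev
    }
    invisible(NULL)
  }
  recurse(1L)

  list(
    n_solutions = n_solutions,
    solutions = solutions,
    possible = possible,
    slots = slots
  )
}
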