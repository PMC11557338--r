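#' Build a donor roster
#'
#' A roster is a tibble with one row per donor, the starting point for every
#' pooling design. Each donor is assumed to contribute one skin and one PBMC
#' sample (the matched pair that will be split across reactions).
#'
#' @param donor_id Character vector of unique donor identifiers.
#' @param sex Donor sexes, `"male"`, `"female"` or `"unknown"`. Recycled if
#'   length 1. Sexes must be known for triplet (sex-encoded) designs.
#' @return A tibble with columns `donor_id` and `sex`.
#' @examples
#' make_roster(paste0("S", 1:9), rep(c("male", "female", "male"), 3))
#' @export
make_roster <- function(donor_id, sex = "unknown") {
  if (length(sex) == 1L) sex <- rep(sex, length(donor_id))
  roster <- tibble(donor_id = as.character(donor_id), sex = as.character(sex))
  validate_roster(roster)
}

#' Read a donor roster from CSV
#'
#' Expects a header `donor_id,sex` with sex in `male`, `female`, `unknown`.
#'
#' @param path Path to the CSV file.
#' @return A roster tibble (see [make_roster()]).
#' @export
read_roster <- function(path) {
  roster <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("donor_id", "sex") %in% names(roster))) {
    abort("roster CSV must have columns 'donor_id' and 'sex'")
  }
  validate_roster(as_tibble(roster[, c("donor_id", "sex")]))
}

validate_roster <- function(roster) {
  if (anyDuplicated(roster$donor_id)) {
    abort(paste0(
      "duplicated donor_id in roster: ",
      paste(unique(roster$donor_id[duplicated(roster$donor_id)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(roster$sex), c("male", "female", "unknown"))
  if (length(bad)) {
    abort(paste0("invalid sex value(s): ", paste(bad, collapse = ", ")))
  }
  roster
}

# Expand a roster into its sample table: one skin + one PBMC sample per donor.
# Sample ids follow the "<donor>_<tissue>" convention used throughout.
roster_samples <- function(roster) {
  tidyr::expand_grid(donor_id = roster$donor_id, tissue = c("skin", "pbmc")) |>
    left_join(roster, by = "donor_id") |>
    mutate(sample_id = paste0(.data$donor_id, "_", .data$tissue)) |>
    select("sample_id", "donor_id", "tissue", "sex") |>
    arrange(.data$donor_id, .data$tissue)
}
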