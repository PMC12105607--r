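#' Construct and validate a group roster
#'
#' A roster records, for every (group, individual) pair, the individual's sex
#' and age class, whether it is the group's dominant female, and whether the
#' group has visual/physical access to another group (which is what makes
#' intergroup conflict possible). Individuals may appear in more than one
#' group — group compositions are rearranged by keepers — but at most once per
#' group.
#'
#' @param x A data frame with columns `group_id`, `individual`,
#'   `dominant_female` (logical), `intergroup_access` (logical, constant
#'   within group), and optionally `sex` (`"F"`/`"M"`) and `age_class`
#'   (`"juvenile"`, `"subadult"`, `"adolescent"`, `"adult"`).
#' @return A validated tibble with class `focal_roster` prepended.
#' @export
as_roster <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("group_id", "individual", "dominant_female", "intergroup_access")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  if (!"age_class" %in% names(x)) x$age_class <- NA_character_
  x$dominant_female <- as.logical(x$dominant_female)
  x$intergroup_access <- as.logical(x$intergroup_access)
  validate_roster(x)
  class(x) <- c("focal_roster", class(x))
  x
}

validate_roster <- function(x) {
  split_groups <- split(x, x$group_id)
  for (g in names(split_groups)) {
    grp <- split_groups[[g]]
    if (anyDuplicated(grp$individual)) {
      stop("group ", g, ": duplicated individual ID", call. = FALSE)
    }
    n <- nrow(grp)
    if (n < 3 || n > 8) {
      stop("group ", g, " has ", n, " members; expected 3-8", call. = FALSE)
    }
    ndf <- sum(grp$dominant_female)
    if (ndf != 1) {
      stop("group ", g, " has ", ndf,
           " dominant females; exactly one required", call. = FALSE)
    }
    if (!isTRUE(grp$sex[grp$dominant_female] %in% c("F", NA_character_))) {
      stop("group ", g, ": dominant female flagged on a male", call. = FALSE)
    }
    if (length(unique(grp$intergroup_access)) != 1) {
      stop("group ", g, ": intergroup_access must be constant within group",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a roster from CSV or YAML
#'
#' CSV files must carry one row per (group, individual) with the columns
#' described in [as_roster()]. YAML files carry one block per group:
#' `members` (named list individual -> list(sex, age_class)), a
#' `dominant_female` ID and an `intergroup_access` flag.
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @return A `focal_roster` tibble.
#' @export
read_roster <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    rows <- purrr::imap(raw, function(blk, g) {
      members <- blk$members
      tibble::tibble(
        group_id = g,
        individual = names(members),
        sex = purrr::map_chr(members, ~ .x$sex %||% NA_character_),
        age_class = purrr::map_chr(members, ~ .x$age_class %||% NA_character_),
        dominant_female = names(members) == blk$dominant_female,
        intergroup_access = isTRUE(blk$intergroup_access)
      )
    })
    as_roster(dplyr::bind_rows(rows))
  } else {
    as_roster(readr::read_csv(path, show_col_types = FALSE))
  }
}

roster_members <- function(roster, group) {
  roster$individual[roster$group_id == group]
}

roster_dominant <- function(roster, group) {
  roster$individual[roster$group_id == group & roster$dominant_female]
}
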