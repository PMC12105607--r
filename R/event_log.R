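#' @keywords internal
#' @importFrom rlang %||%
#' @importFrom stats pchisq pf pnorm rnorm sd aov cor.test lm rlnorm rpois
#'   runif setNames complete.cases
#' @importFrom utils head
"_PACKAGE"

.log_columns <- c("session_id", "group_id", "focal_id", "record_type",
                  "behavior", "actor", "partner", "initiator", "start_iso",
                  "duration_s", "kind", "participants")

new_behavior_log <- function(focals, bouts, points, disruptions) {
  structure(
    list(focals = focals, bouts = bouts, points = points,
         disruptions = disruptions),
    class = "behavior_log"
  )
}

#' @export
print.behavior_log <- function(x, ...) {
  cat("<behavior_log>\n")
  cat("  focal samples   :", nrow(x$focals), "\n")
  cat("  state bouts     :", nrow(x$bouts), "\n")
  cat("  point events    :", nrow(x$points), "\n")
  cat("  disruptions     :", nrow(x$disruptions), "\n")
  invisible(x)
}

#' Read a behavioral event log
#'
#' Parses a long-format CSV of focal-sampling records into a `behavior_log`
#' holding four tables: focal samples (`record_type = "focal"`), social state
#' bouts (`"state"`), point events (`"point"`: sociosexual, aggression,
#' submission counts) and disruption events (`"disruption"`: intragroup or
#' intergroup conflicts and single-individual outbursts). Every referenced
#' individual must exist in the roster for its group; state bouts must have
#' `actor != partner` and a non-negative duration. Validation errors name the
#' offending row of the file.
#'
#' @param path Path to the CSV event log.
#' @param roster A `focal_roster` (see [read_roster()]).
#' @return A `behavior_log` object with bouts sorted by start time.
#' @export
read_event_log <- function(path, roster) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      group_id = readr::col_character(),
      focal_id = readr::col_character(),
      record_type = readr::col_character(),
      behavior = readr::col_character(),
      actor = readr::col_character(),
      partner = readr::col_character(),
      initiator = readr::col_character(),
      start_iso = readr::col_character(),
      duration_s = readr::col_double(),
      kind = readr::col_character(),
      participants = readr::col_character()
    )
  )
  missing_cols <- setdiff(.log_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("event log ", path, " contains a header but no records",
            call. = FALSE)
  }
  raw$.row <- seq_len(nrow(raw)) + 1L  # file line number (header = line 1)
  raw$start <- as.POSIXct(raw$start_iso, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                         "%Y-%m-%d %H:%M:%S"))
  bad_time <- raw$.row[is.na(raw$start) & !is.na(raw$start_iso)]
  if (length(bad_time) > 0) {
    stop("unparseable start_iso at line(s) ",
         paste(head(bad_time, 5), collapse = ", "), call. = FALSE)
  }

  check_ids <- function(ids, groups, rows, field) {
    ok <- mapply(function(id, g) {
      is.na(id) || id %in% roster_members(roster, g)
    }, ids, groups)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("line ", rows[i], ": ", field, " '", ids[i],
           "' is not a member of group ", groups[i], call. = FALSE)
    }
  }

  focals <- raw[raw$record_type == "focal", ]
  check_ids(focals$focal_id, focals$group_id, focals$.row, "focal_id")
  if (any(is.na(focals$duration_s) | focals$duration_s < 0)) {
    i <- which(is.na(focals$duration_s) | focals$duration_s < 0)[1]
    stop("line ", focals$.row[i], ": focal sample with missing or negative ",
         "duration", call. = FALSE)
  }

  bouts <- raw[raw$record_type == "state", ]
  check_ids(bouts$focal_id, bouts$group_id, bouts$.row, "focal_id")
  check_ids(bouts$actor, bouts$group_id, bouts$.row, "actor")
  check_ids(bouts$partner, bouts$group_id, bouts$.row, "partner")
  if (nrow(bouts) > 0) {
    same <- which(bouts$actor == bouts$partner)
    if (length(same) > 0) {
      stop("line ", bouts$.row[same[1]], ": actor equals partner ('",
           bouts$actor[same[1]], "')", call. = FALSE)
    }
    neg <- which(is.na(bouts$duration_s) | bouts$duration_s < 0)
    if (length(neg) > 0) {
      stop("line ", bouts$.row[neg[1]], ": state bout with missing or ",
           "negative duration", call. = FALSE)
    }
    pool_behavior(bouts$behavior)  # errors on unknown ethogram labels
    bad_init <- which(!bouts$initiator %in% c("actor", "partner", "unknown"))
    if (length(bad_init) > 0) {
      stop("line ", bouts$.row[bad_init[1]], ": initiator must be ",
           "actor/partner/unknown", call. = FALSE)
    }
  }

  points <- raw[raw$record_type == "point", ]
  check_ids(points$actor, points$group_id, points$.row, "actor")
  check_ids(points$partner, points$group_id, points$.row, "partner")
  if (nrow(points) > 0) {
    bad_kind <- which(!points$kind %in% c("sociosexual", "aggression",
                                          "submission"))
    if (length(bad_kind) > 0) {
      stop("line ", points$.row[bad_kind[1]], ": unknown point-event kind '",
           points$kind[bad_kind[1]], "'", call. = FALSE)
    }
    ss <- points$kind == "sociosexual"
    if (any(ss & (is.na(points$actor) | is.na(points$partner)))) {
      i <- points$.row[which(ss & (is.na(points$actor) |
                                     is.na(points$partner)))[1]]
      stop("line ", i, ": sociosexual events require two participants",
           call. = FALSE)
    }
  }

  disruptions <- raw[raw$record_type == "disruption", ]
  if (nrow(disruptions) > 0) {
    bad_kind <- which(!disruptions$kind %in% c("outburst", "intragroup",
                                               "intergroup"))
    if (length(bad_kind) > 0) {
      stop("line ", disruptions$.row[bad_kind[1]],
           ": unknown disruption kind '", disruptions$kind[bad_kind[1]], "'",
           call. = FALSE)
    }
    n_part <- vapply(strsplit(disruptions$participants %||%
                                rep(NA_character_, nrow(disruptions)), ";"),
                     function(p) sum(!is.na(p) & nzchar(p)), integer(1))
    ob <- disruptions$kind == "outburst"
    if (any(ob & n_part != 1)) {
      i <- disruptions$.row[which(ob & n_part != 1)[1]]
      stop("line ", i, ": outbursts have exactly one participant",
           call. = FALSE)
    }
    ig <- disruptions$kind == "intergroup"
    if (any(ig)) {
      access <- vapply(disruptions$group_id[ig], function(g) {
        any(roster$intergroup_access[roster$group_id == g])
      }, logical(1))
      if (!all(access)) {
        i <- disruptions$.row[ig][which(!access)[1]]
        stop("line ", i, ": intergroup conflict recorded for a group ",
             "without intergroup access", call. = FALSE)
      }
    }
  }

  keep <- function(d, cols) {
    d <- d[order(d$start), cols, drop = FALSE]
    tibble::as_tibble(d)
  }
  new_behavior_log(
    focals = keep(focals, c("session_id", "group_id", "focal_id", "start",
                            "duration_s")),
    bouts = keep(bouts, c("session_id", "group_id", "focal_id", "actor",
                          "partner", "behavior", "initiator", "start",
                          "duration_s")),
    points = keep(points, c("session_id", "group_id", "kind", "actor",
                            "partner", "start")),
    disruptions = {
      d <- disruptions[order(disruptions$start), ]
      tibble::tibble(group_id = d$group_id, time = d$start, kind = d$kind,
                     participants = d$participants)
    }
  )
}

#' Write a behavior log in the event-log CSV dialect
#'
#' Inverse of [read_event_log()]: serializes the four component tables back
#' into the single long-format CSV.
#'
#' @param log A `behavior_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  empty <- function(n) rep(NA_character_, n)
  f <- log$focals
  b <- log$bouts
  p <- log$points
  d <- log$disruptions
  rows <- dplyr::bind_rows(
    tibble::tibble(session_id = f$session_id, group_id = f$group_id,
                   focal_id = f$focal_id, record_type = "focal",
                   behavior = empty(nrow(f)), actor = empty(nrow(f)),
                   partner = empty(nrow(f)), initiator = empty(nrow(f)),
                   start_iso = iso(f$start), duration_s = f$duration_s,
                   kind = empty(nrow(f)), participants = empty(nrow(f))),
    tibble::tibble(session_id = b$session_id, group_id = b$group_id,
                   focal_id = b$focal_id, record_type = "state",
                   behavior = b$behavior, actor = b$actor,
                   partner = b$partner, initiator = b$initiator,
                   start_iso = iso(b$start), duration_s = b$duration_s,
                   kind = empty(nrow(b)), participants = empty(nrow(b))),
    tibble::tibble(session_id = p$session_id, group_id = p$group_id,
                   focal_id = empty(nrow(p)), record_type = "point",
                   behavior = empty(nrow(p)), actor = p$actor,
                   partner = p$partner, initiator = empty(nrow(p)),
                   start_iso = iso(p$start), duration_s = NA_real_,
                   kind = p$kind, participants = empty(nrow(p))),
    tibble::tibble(session_id = empty(nrow(d)), group_id = d$group_id,
                   focal_id = empty(nrow(d)), record_type = "disruption",
                   behavior = empty(nrow(d)), actor = empty(nrow(d)),
                   partner = empty(nrow(d)), initiator = empty(nrow(d)),
                   start_iso = iso(d$time), duration_s = NA_real_,
                   kind = d$kind, participants = d$participants)
  )
  rows <- rows[order(rows$start_iso, rows$record_type), ]
  readr::write_csv(rows, path, na = "")
  invisible(path)
}
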