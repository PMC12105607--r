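#' Build the per-individual observation-time ledger
#'
#' Assigns every focal sample, as a whole, to the conflict context of its
#' start time (a conflict occurring mid-focal changes the context of later
#' samples only), then tallies observed minutes per (group, individual,
#' context). Minutes are conserved: summing the ledger over contexts gives
#' each individual's total focal minutes in that group. Disruption-event
#' windows are matched within each group's own event stream.
#'
#' Focal samples must not overlap in time: the design assumes a single
#' observer, so two simultaneous focals indicate a corrupt log.
#'
#' @param log A `behavior_log`.
#' @param events Disruption events (defaults to `log$disruptions`).
#' @param window_min Post-event window in minutes (default 60).
#' @return A tibble with columns `group_id`, `individual`, `context`,
#'   `minutes`, complete over all four contexts for every observed
#'   (group, individual), plus the per-sample context assignment as
#'   attribute `"focal_contexts"`.
#' @export
build_ledger <- function(log, events = log$disruptions, window_min = 60) {
  f <- log$focals
  if (nrow(f) > 0) {
    o <- order(as.numeric(f$start))
    st <- as.numeric(f$start)[o]
    en <- st + f$duration_s[o]
    if (any(st[-1] < en[-length(en)] - 1e-9)) {
      i <- which(st[-1] < en[-length(en)] - 1e-9)[1]
      stop("overlapping focal samples (single-observer design): samples ",
           "starting ", format(f$start[o][i]), " and ",
           format(f$start[o][i + 1]), call. = FALSE)
    }
  }
  ctx <- factor(rep("neutral", nrow(f)), levels = context_levels())
  for (g in unique(f$group_id)) {
    sel <- f$group_id == g
    ev <- events[events$group_id == g, , drop = FALSE]
    ctx[sel] <- classify_context(f$start[sel], ev, window_min = window_min)
  }
  focal_ctx <- tibble::tibble(
    session_id = f$session_id, group_id = f$group_id, focal_id = f$focal_id,
    start = f$start, duration_s = f$duration_s, context = ctx
  )
  ledger <- focal_ctx |>
    dplyr::group_by(group_id, individual = focal_id, context) |>
    dplyr::summarise(minutes = sum(duration_s) / 60, .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(group_id, individual),
      context = factor(context_levels(), levels = context_levels()),
      fill = list(minutes = 0)
    ) |>
    dplyr::arrange(group_id, individual, context)
  attr(ledger, "focal_contexts") <- focal_ctx
  class(ledger) <- c("observation_ledger", class(ledger))
  ledger
}

#' Observed minutes for a set of individuals in one (group, context)
#' @keywords internal
ledger_minutes <- function(ledger, group, context, individuals) {
  sub <- ledger[ledger$group_id == group & ledger$context == context, ]
  m <- setNames(sub$minutes, sub$individual)
  out <- m[individuals]
  out[is.na(out)] <- 0
  setNames(as.numeric(out), individuals)
}
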