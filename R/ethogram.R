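#' Conflict-context levels
#'
#' Canonical ordering of the four analysis strata: neutral, the hour after a
#' single-individual outburst, the hour after an intragroup conflict, and the
#' hour after an intergroup conflict. All factors in the package use this
#' ordering, and the a priori contrasts ([context_contrasts()]) are defined
#' over it.
#'
#' @return Character vector of length 4.
#' @export
context_levels <- function() {
  c("neutral", "post_outburst", "post_intragroup", "post_intergroup")
}

# Ethogram: affiliative state behaviors that imply proximity (within 2 m) are
# pooled into a single "proximity" category for network construction. The
# affiliative/proximity subclass split is retained for the pooling-validation
# correlation.
.affiliative_states <- c("groom", "play", "cofeed")
.proximity_states  <- c("contact", "close_proximity", "partial_proximity")
.other_states      <- c("rest", "locomotion", "feed", "self_groom",
                        "vigilance", "out_of_view", "solitary")

#' Pool a state behavior into the proximity category
#'
#' Collapses the six affiliative social state behaviors that require proximity
#' (grooming, play, co-feeding, contact, close proximity, partial proximity)
#' into a single `"proximity"` category; all non-affiliative states map to
#' `"other"`. The affiliative subclass (`"affiliative"` for groom/play/cofeed,
#' `"proximity"` for the three proximity states) is returned alongside, so the
#' pooling decision can be validated by correlating the two subclasses at the
#' dyad level (see [spearman_affiliation()]).
#'
#' @param behavior Character vector of ethogram labels.
#' @return A tibble with columns `behavior`, `category`
#'   (`"proximity"`/`"other"`) and `subclass` (`"affiliative"`, `"proximity"`,
#'   or `NA` for non-affiliative states).
#' @examples
#' pool_behavior(c("groom", "partial_proximity", "rest"))
#' @export
pool_behavior <- function(behavior) {
  stopifnot(is.character(behavior))
  known <- c(.affiliative_states, .proximity_states, .other_states)
  bad <- setdiff(unique(behavior), known)
  if (length(bad) > 0) {
    stop("unknown ethogram label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  category <- ifelse(behavior %in% c(.affiliative_states, .proximity_states),
                     "proximity", "other")
  subclass <- rep(NA_character_, length(behavior))
  subclass[behavior %in% .affiliative_states] <- "affiliative"
  subclass[behavior %in% .proximity_states]   <- "proximity"
  tibble::tibble(behavior = behavior, category = category, subclass = subclass)
}

#' Classify focal-sample start times into conflict contexts
#'
#' A time `t` is post-X when a disruption event of kind X occurred in the
#' half-open window `(t - window_min, t]`: an event exactly `window_min`
#' minutes earlier no longer qualifies, an event at `t` itself does. When
#' several events qualify, conflicts outrank outbursts
#' (intergroup > intragroup > outburst) and, within the same kind, the most
#' recent event wins. With no qualifying event the context is neutral, so the
#' classification is total: every focal sample receives exactly one context.
#'
#' @param t POSIXct vector of focal-sample start times.
#' @param events A data frame of disruption events with columns `time`
#'   (POSIXct) and `kind` (`"outburst"`, `"intragroup"`, `"intergroup"`), or
#'   `NULL`/empty for no events.
#' @param window_min Post-event window length in minutes (default 60).
#' @return Factor with levels [context_levels()].
#' @export
classify_context <- function(t, events, window_min = 60) {
  stopifnot(inherits(t, "POSIXct"))
  lv <- context_levels()
  if (is.null(events) || nrow(events) == 0) {
    return(factor(rep("neutral", length(t)), levels = lv))
  }
  stopifnot(all(c("time", "kind") %in% names(events)),
            all(events$kind %in% c("outburst", "intragroup", "intergroup")))
  et <- as.numeric(events$time)
  # precedence: higher number wins; within kind the most recent event wins
  prec <- c(outburst = 1L, intragroup = 2L, intergroup = 3L)[events$kind]
  tn <- as.numeric(t)
  win <- window_min * 60
  out <- vapply(tn, function(ti) {
    ok <- et > ti - win & et <= ti
    if (!any(ok)) return("neutral")
    p <- prec[ok]
    cand <- which(p == max(p))
    kind <- events$kind[ok][cand[which.max(et[ok][cand])]]
    switch(kind,
           outburst   = "post_outburst",
           intragroup = "post_intragroup",
           intergroup = "post_intergroup")
  }, character(1))
  factor(out, levels = lv)
}
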