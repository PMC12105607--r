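#' Default group structure: five zoo compositions
#'
#' The default simulated population mirrors the observed study system: five
#' alternating group compositions of sizes 6, 7, 4, 4 and 3 drawn from a pool
#' of 18 individuals, one dominant female per group, with two groups (C and
#' D) able to see and hear each other through a mesh barrier and therefore
#' able to engage in intergroup conflict. Session counts are set so
#' per-group focal minutes are of the same magnitude as the observed
#' schedule (10-minute focals, one session = one focal of every member).
#'
#' @return A list of per-group specifications (members, sex, dominant
#'   female, intergroup access, sessions).
#' @export
table2_groups <- function() {
  list(
    list(group_id = "A",
         members = c("F3", "M5", "M8", "M2", "F5", "M7"),
         dominant_female = "F3", intergroup_access = FALSE, sessions = 5),
    list(group_id = "B",
         members = c("F3", "M5", "M8", "M2", "F2", "F7", "F10"),
         dominant_female = "F3", intergroup_access = FALSE, sessions = 19),
    list(group_id = "C",
         members = c("F5", "M7", "M1", "F9"),
         dominant_female = "F5", intergroup_access = TRUE, sessions = 13),
    list(group_id = "D",
         members = c("F4", "M6", "F6", "M3"),
         dominant_female = "F4", intergroup_access = TRUE, sessions = 8),
    list(group_id = "E",
         members = c("F1", "F8", "M4"),
         dominant_female = "F1", intergroup_access = FALSE, sessions = 8)
  )
}

#' Homogeneous group structure for calibration experiments
#'
#' Five groups of five individuals each, one dominant female per group, two
#' groups with intergroup access. With equal group sizes the dominance
#' factor is not confounded with group size (node strength scales with the
#' number of incoming dyads), which makes this the appropriate design for
#' type-I-error and power experiments on the dominance effect.
#'
#' @param sessions Sessions per group (default 10, giving ~2,500 focal
#'   minutes in total, the magnitude of the observed schedule).
#' @return A list of per-group specifications.
#' @export
calibration_groups <- function(sessions = 10) {
  purrr::map(seq_len(5), function(i) {
    g <- LETTERS[i]
    list(group_id = g,
         members = paste0(g, c("F1", "F2", "M1", "M2", "M3")),
         dominant_female = paste0(g, "F1"),
         intergroup_access = i >= 4, sessions = sessions)
  })
}

#' Generator configuration
#'
#' Collects every generative parameter of the synthetic observation model.
#' Bouts arise per directed dyad as a Poisson process at
#' `lambda_dyad * context_mod[context] * alpha_df^(target is DF)` bouts per
#' observation hour while either member is the focal subject; bout durations
#' are log-normal (median 60 s by default), truncated to the focal window.
#' `alpha_df` is the dominance attraction multiplier on initiation rates
#' toward the dominant female — `alpha_df = 1` makes her statistically
#' exchangeable with other members, the null used for type-I calibration.
#' Disruption events (outbursts, intragroup and — where access permits —
#' intergroup conflicts) are Poisson in session time; sociosexual point
#' events occur at per-individual, per-hour rates that depend on context.
#'
#' @param groups Per-group specifications (default [table2_groups()]).
#' @param focal_min Focal-sample length in minutes (default 10).
#' @param lambda_dyad Baseline bout initiation rate per directed dyad,
#'   bouts/observation-hour (default 0.7).
#' @param bout_meanlog,bout_sdlog Log-normal bout-duration parameters
#'   (default `log(60)`, 0.75: median 60 s, right-skewed).
#' @param alpha_df Dominance attraction multiplier (default 2.5: group
#'   members are substantially more likely to initiate proximity toward the
#'   dominant female, the structure seen in the study system; set to 1 for
#'   a null generator in which she is exchangeable).
#' @param context_mod Named multipliers on bout rates per context. Default
#'   `c(neutral = 1, post_outburst = 1.6, post_intragroup = 0.6,
#'   post_intergroup = 0.6)`: proximity is elevated after outbursts and
#'   suppressed after conflicts, the ordering seen in the study system; the
#'   magnitudes are order-of-magnitude choices, not estimates.
#' @param event_rates Named disruption rates per observation hour
#'   (default outburst 0.5, intragroup 0.3, intergroup 0.8).
#' @param socio_rates Named sociosexual event rates per individual per hour
#'   by context (default 0.2 in non-conflict contexts, 4 post-conflict:
#'   sociosexual behavior is markedly elevated after conflicts, with totals
#'   over a full schedule of a few dozen events).
#' @param p_unknown_initiator Probability a bout's initiator goes
#'   unrecorded (default 0).
#' @param seed Integer seed; fully determines the output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(groups = table2_groups(),
                       focal_min = 10,
                       lambda_dyad = 0.7,
                       bout_meanlog = log(60),
                       bout_sdlog = 0.75,
                       alpha_df = 2.5,
                       context_mod = c(neutral = 1, post_outburst = 1.6,
                                       post_intragroup = 0.6,
                                       post_intergroup = 0.6),
                       event_rates = c(outburst = 0.5, intragroup = 0.3,
                                       intergroup = 0.8),
                       socio_rates = c(neutral = 0.2, post_outburst = 0.2,
                                       post_intragroup = 4,
                                       post_intergroup = 4),
                       p_unknown_initiator = 0,
                       seed = 1L) {
  stopifnot(all(context_levels() %in% names(context_mod)),
            all(context_levels() %in% names(socio_rates)),
            all(c("outburst", "intragroup", "intergroup") %in%
                  names(event_rates)),
            alpha_df > 0, lambda_dyad >= 0, focal_min > 0,
            all(context_mod >= 0), all(event_rates >= 0),
            all(socio_rates >= 0),
            p_unknown_initiator >= 0, p_unknown_initiator <= 1)
  structure(list(
    groups = groups, focal_min = focal_min, lambda_dyad = lambda_dyad,
    bout_meanlog = bout_meanlog, bout_sdlog = bout_sdlog,
    alpha_df = alpha_df, context_mod = context_mod,
    event_rates = event_rates, socio_rates = socio_rates,
    p_unknown_initiator = p_unknown_initiator, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_roster <- function(groups) {
  rows <- purrr::map_dfr(groups, function(g) {
    sex <- if (!is.null(g$sex)) g$sex else
      ifelse(grepl("F[0-9]+$", g$members), "F", "M")
    tibble::tibble(
      group_id = g$group_id, individual = g$members, sex = sex,
      age_class = if (!is.null(g$age_class)) g$age_class else "adult",
      dominant_female = g$members == g$dominant_female,
      intergroup_access = isTRUE(g$intergroup_access)
    )
  })
  as_roster(rows)
}

#' Simulate a focal-sampling observation study
#'
#' Draws a full synthetic dataset under the generative model of
#' [sim_config()]: a schedule of sessions (one focal of every group member,
#' in random order, on consecutive days), Poisson disruption events within
#' sessions, per-focal dyadic proximity bouts whose rates depend on context
#' and on whether the initiation targets the dominant female, and
#' context-dependent sociosexual point events. The output parses through the
#' ingestion layer with zero validation errors and is byte-identical for
#' identical seeds.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_output`: `roster` (a `focal_roster`), `log`
#'   (a `behavior_log`), and `truth` (the generative parameters, including
#'   the per-focal true contexts).
#' @export
simulate_observations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$groups) == 0 ||
      sum(purrr::map_dbl(config$groups, ~ .x$sessions %||% 0)) == 0) {
    stop("zero-length schedule: no sessions to simulate", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  roster <- sim_roster(config$groups)
  flen_s <- config$focal_min * 60
  base_day <- as.POSIXct("2023-07-01 00:00:00", tz = "UTC")

  # one session per calendar day (single observer, no overlap)
  sess <- purrr::map_dfr(config$groups, function(g) {
    tibble::tibble(group_id = g$group_id, s = seq_len(g$sessions))
  })
  sess$day <- seq_len(nrow(sess))
  sess$start <- base_day + (sess$day - 1) * 86400 +
    9 * 3600 + floor(runif(nrow(sess), 0, 180)) * 60

  gspec <- setNames(config$groups,
                    purrr::map_chr(config$groups, "group_id"))

  focal_rows <- list()
  disr_rows <- list()
  for (k in seq_len(nrow(sess))) {
    g <- sess$group_id[k]
    members <- gspec[[g]]$members
    ord <- sample(members)
    st <- sess$start[k] + (seq_along(ord) - 1) * flen_s
    focal_rows[[k]] <- tibble::tibble(
      session_id = sprintf("S%03d", k), group_id = g, focal_id = ord,
      start = st, duration_s = flen_s
    )
    dur_h <- length(ord) * flen_s / 3600
    for (kind in c("outburst", "intragroup", "intergroup")) {
      if (kind == "intergroup" && !isTRUE(gspec[[g]]$intergroup_access)) next
      nev <- rpois(1, config$event_rates[[kind]] * dur_h)
      if (nev > 0) {
        et <- sess$start[k] + sort(floor(runif(nev, 0, dur_h * 3600)))
        parts <- if (kind == "outburst") {
          sample(members, nev, replace = TRUE)
        } else if (kind == "intragroup") {
          vapply(seq_len(nev), function(i)
            paste(sample(members, 2), collapse = ";"), character(1))
        } else {
          sample(members, nev, replace = TRUE)  # own-group participant seen
        }
        disr_rows[[length(disr_rows) + 1]] <- tibble::tibble(
          group_id = g, time = et, kind = kind, participants = parts
        )
      }
    }
  }
  focals <- dplyr::bind_rows(focal_rows)
  disruptions <- if (length(disr_rows) > 0) {
    d <- dplyr::bind_rows(disr_rows)
    d[order(d$time), ]
  } else {
    tibble::tibble(group_id = character(0),
                   time = as.POSIXct(character(0), tz = "UTC"),
                   kind = character(0), participants = character(0))
  }

  # context of each focal sample (start-time rule, same as the ledger)
  ctx <- factor(rep("neutral", nrow(focals)), levels = context_levels())
  for (g in unique(focals$group_id)) {
    selg <- focals$group_id == g
    ctx[selg] <- classify_context(
      focals$start[selg], disruptions[disruptions$group_id == g, ])
  }
  focals$context <- ctx

  # dyadic bouts: per focal, both directions with every partner
  pair_tpl <- purrr::map_dfr(config$groups, function(g) {
    tidyr::crossing(group_id = g$group_id, other = g$members,
                    direction = c("out", "in"))
  })
  pr <- dplyr::inner_join(
    dplyr::mutate(focals, .f = dplyr::row_number()),
    pair_tpl, by = "group_id", relationship = "many-to-many"
  )
  pr <- pr[pr$other != pr$focal_id, ]
  df_of <- purrr::map_chr(gspec, "dominant_female")
  target <- ifelse(pr$direction == "out", pr$other, pr$focal_id)
  target_df <- target == df_of[pr$group_id]
  rate_h <- config$lambda_dyad *
    config$context_mod[as.character(pr$context)] *
    ifelse(target_df, config$alpha_df, 1)
  nb <- rpois(nrow(pr), rate_h * config$focal_min / 60)
  idx <- rep(seq_len(nrow(pr)), nb)
  bouts <- if (length(idx) > 0) {
    off <- floor(runif(length(idx), 0, flen_s - 1))
    dur <- rlnorm(length(idx), config$bout_meanlog, config$bout_sdlog)
    dur <- pmin(round(dur), flen_s - off)
    dur <- pmax(dur, 1)
    init <- ifelse(pr$direction[idx] == "out", "actor", "partner")
    if (config$p_unknown_initiator > 0) {
      unk <- runif(length(idx)) < config$p_unknown_initiator
      init[unk] <- "unknown"
    }
    b <- tibble::tibble(
      session_id = pr$session_id[idx], group_id = pr$group_id[idx],
      focal_id = pr$focal_id[idx], actor = pr$focal_id[idx],
      partner = pr$other[idx],
      behavior = sample(c(.affiliative_states, .proximity_states),
                        length(idx), replace = TRUE,
                        prob = c(.15, .1, .1, .25, .25, .15)),
      initiator = init, start = pr$start[idx] + off, duration_s = dur
    )
    b[order(b$start), ]
  } else {
    tibble::tibble(session_id = character(0), group_id = character(0),
                   focal_id = character(0), actor = character(0),
                   partner = character(0), behavior = character(0),
                   initiator = character(0),
                   start = as.POSIXct(character(0), tz = "UTC"),
                   duration_s = numeric(0))
  }

  # sociosexual point events
  ns <- rpois(nrow(focals),
              config$socio_rates[as.character(focals$context)] *
                config$focal_min / 60)
  sidx <- rep(seq_len(nrow(focals)), ns)
  points <- if (length(sidx) > 0) {
    partner <- vapply(sidx, function(i) {
      m <- setdiff(gspec[[focals$group_id[i]]]$members, focals$focal_id[i])
      sample(m, 1)
    }, character(1))
    p <- tibble::tibble(
      session_id = focals$session_id[sidx], group_id = focals$group_id[sidx],
      kind = "sociosexual", actor = focals$focal_id[sidx], partner = partner,
      start = focals$start[sidx] + floor(runif(length(sidx), 0, flen_s))
    )
    p[order(p$start), ]
  } else {
    tibble::tibble(session_id = character(0), group_id = character(0),
                   kind = character(0), actor = character(0),
                   partner = character(0),
                   start = as.POSIXct(character(0), tz = "UTC"))
  }

  log <- new_behavior_log(
    focals = focals[, c("session_id", "group_id", "focal_id", "start",
                        "duration_s")],
    bouts = bouts, points = points, disruptions = disruptions
  )
  structure(list(
    roster = roster, log = log,
    truth = list(alpha_df = config$alpha_df,
                 context_mod = config$context_mod,
                 lambda_dyad = config$lambda_dyad,
                 socio_rates = config$socio_rates,
                 seed = config$seed,
                 focal_contexts = focals[, c("session_id", "focal_id",
                                             "context")])
  ), class = "sim_output")
}

#' Write a simulated dataset to disk
#'
#' Emits the event-log CSV (ingestible by [read_event_log()]), the roster
#' CSV, and the ground-truth generative parameters as JSON.
#'
#' @param sim A `sim_output`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    log = file.path(dir, "event_log.csv"),
    roster = file.path(dir, "roster.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_event_log(sim$log, paths[["log"]])
  readr::write_csv(as.data.frame(sim$roster), paths[["roster"]])
  truth <- sim$truth
  truth$focal_contexts <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Packaged synthetic fixture with the observed study's shape
#'
#' Generates a dataset over the five default group compositions (sizes 6, 7,
#' 4, 4, 3, one dominant female each, intergroup access only in the two
#' mesh-adjacent groups) and optionally writes it to a fixtures directory.
#'
#' @param seed Integer seed (default 20230701).
#' @param dir Optional output directory passed to [write_sim_output()].
#' @return The `sim_output`, invisibly if `dir` is given.
#' @export
make_fixture <- function(seed = 20230701, dir = NULL) {
  sim <- simulate_observations(sim_config(seed = seed))
  if (!is.null(dir)) {
    write_sim_output(sim, dir)
    return(invisible(sim))
  }
  sim
}
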