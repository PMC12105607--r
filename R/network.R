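#' Observation-time-normalized directed dyadic rate
#'
#' The weight of a directed edge A -> B is the total number of seconds A spent
#' initiating proximity with B, divided by the combined focal observation time
#' of the two dyad members in minutes:
#' `weight = seconds / (minutes_A + minutes_B)` (units s/min). Normalizing by
#' the dyad's combined observation time makes weights comparable across
#' individuals and (group, context) networks with unequal focal effort.
#'
#' @param seconds Seconds the directed dyad spent in proximity (>= 0).
#' @param min_a Focal minutes observing the initiator (source).
#' @param min_b Focal minutes observing the recipient (target).
#' @return Numeric weight, seconds per combined minute. Vectorized.
#' @examples
#' dyadic_rate(171, 33, 26)  # 171/59 = 2.898...
#' @export
dyadic_rate <- function(seconds, min_a, min_b) {
  stopifnot(is.numeric(seconds), is.numeric(min_a), is.numeric(min_b))
  if (any(seconds < 0)) stop("seconds must be >= 0", call. = FALSE)
  denom <- min_a + min_b
  if (any(denom <= 0)) {
    stop("undefined dyadic rate: combined observation time is zero",
         call. = FALSE)
  }
  seconds / denom
}

new_proximity_network <- function(group_id, context, nodes, edges) {
  structure(
    list(group_id = group_id, context = context, nodes = nodes, edges = edges,
         centrality_invalid = FALSE, strength_excluded = character(0)),
    class = "proximity_network"
  )
}

#' @export
print.proximity_network <- function(x, ...) {
  cat("<proximity_network> group", x$group_id, "/", as.character(x$context),
      "\n  nodes:", nrow(x$nodes), " edges:", nrow(x$edges),
      if (x$centrality_invalid) " [centrality invalid]" else "", "\n")
  invisible(x)
}

#' Build one proximity network per (group, context)
#'
#' Pools state bouts into the proximity category, attaches each bout to the
#' conflict context of its enclosing focal sample (a bout spanning a context
#' boundary contributes its full duration to the start-time context), sums
#' seconds per directed dyad, and converts them to weights with
#' [dyadic_rate()] using the context-specific observed minutes of the two
#' dyad members. The bout's initiator is the edge source. Bouts with an
#' unknown initiator become undirected edges (`directed = FALSE`): they carry
#' a weight but no direction, and later contribute to total strength only.
#'
#' A network is produced for every (group, context) cell with any observed
#' minutes, including cells with zero proximity bouts (nodes, no edges).
#'
#' @param log A `behavior_log`.
#' @param ledger An `observation_ledger` from [build_ledger()].
#' @param roster A `focal_roster`.
#' @return A list of `proximity_network` objects, named `"group/context"`.
#' @export
build_networks <- function(log, ledger, roster) {
  focal_ctx <- attr(ledger, "focal_contexts")
  if (is.null(focal_ctx)) {
    stop("ledger lacks focal-context attribute; use build_ledger()",
         call. = FALSE)
  }
  b <- log$bouts
  if (nrow(b) > 0) {
    pooled <- pool_behavior(b$behavior)
    b <- b[pooled$category == "proximity", , drop = FALSE]
  }
  if (nrow(b) > 0) {
    b <- dplyr::left_join(
      b,
      focal_ctx[, c("session_id", "focal_id", "context")],
      by = c("session_id", "focal_id")
    )
    if (anyNA(b$context)) {
      stop("state bout without an enclosing focal sample", call. = FALSE)
    }
    src <- ifelse(b$initiator == "actor", b$actor, b$partner)
    tgt <- ifelse(b$initiator == "actor", b$partner, b$actor)
    unk <- b$initiator == "unknown"
    # canonical order for undirected (unknown-initiator) edges
    lo <- pmin(b$actor, b$partner)
    hi <- pmax(b$actor, b$partner)
    src[unk] <- lo[unk]
    tgt[unk] <- hi[unk]
    edges_all <- tibble::tibble(
      group_id = b$group_id, context = b$context,
      source = src, target = tgt, directed = !unk, seconds = b$duration_s
    ) |>
      dplyr::group_by(group_id, context, source, target, directed) |>
      dplyr::summarise(seconds = sum(seconds), .groups = "drop")
  } else {
    edges_all <- tibble::tibble(
      group_id = character(0), context = factor(levels = context_levels()),
      source = character(0), target = character(0), directed = logical(0),
      seconds = numeric(0)
    )
  }

  cells <- ledger |>
    dplyr::group_by(group_id, context) |>
    dplyr::summarise(total_min = sum(minutes), .groups = "drop") |>
    dplyr::filter(total_min > 0)

  nets <- purrr::pmap(
    list(cells$group_id, as.character(cells$context)),
    function(g, ctx) {
      members <- roster_members(roster, g)
      mins <- ledger_minutes(ledger, g, ctx, members)
      nodes <- tibble::tibble(
        individual = members,
        minutes = as.numeric(mins),
        dominant_female = members %in% roster_dominant(roster, g)
      )
      e <- edges_all[edges_all$group_id == g & edges_all$context == ctx, ]
      if (nrow(e) > 0) {
        # one member of a dyad may have zero focal minutes in this context
        # (seen only as a partner); the rate is still defined as long as the
        # combined observation time is positive
        undef <- mins[e$source] + mins[e$target] <= 0
        if (any(undef)) {
          stop("inconsistent ledger: bouts recorded for ", g, "/", ctx,
               " for dyad(s) with zero combined observed minutes: ",
               paste(unique(paste0(e$source[undef], "-", e$target[undef])),
                     collapse = ", "), call. = FALSE)
        }
        weight <- unname(dyadic_rate(e$seconds, mins[e$source],
                                     mins[e$target]))
      } else {
        weight <- numeric(0)
      }
      edges <- tibble::tibble(
        source = e$source, target = e$target, directed = e$directed,
        seconds = e$seconds, weight = weight
      )
      new_proximity_network(g, factor(ctx, levels = context_levels()),
                            nodes, edges)
    }
  )
  names(nets) <- paste(cells$group_id, as.character(cells$context), sep = "/")
  nets
}

#' Apply the small-sample exclusion rules
#'
#' Two rules guard against incomplete networks. (a) If two or more members of
#' a (group, context) network have zero focal minutes, no dyadic interaction
#' between them could ever be observed, so eigenvector centrality is invalid
#' for the whole network, and the strength scores of the unobserved
#' individuals are excluded. (b) If fewer than `min_dyads` distinct
#' (unordered) dyads were observed in proximity, the network is too sparse
#' for a meaningful centrality score, but strengths are kept.
#'
#' @param networks List of `proximity_network` from [build_networks()].
#' @param min_dyads Minimum distinct dyads required for centrality
#'   (default 2).
#' @return A list with `networks` (flags set) and `report`, a tibble with
#'   columns `scope` (`"network"`/`"individual"`), `group_id`, `context`,
#'   `individual` and a machine-readable `reason`.
#' @export
apply_exclusions <- function(networks, min_dyads = 2) {
  report <- list()
  networks <- purrr::map(networks, function(net) {
    zero <- net$nodes$individual[net$nodes$minutes <= 0]
    if (length(zero) >= 2) {
      net$centrality_invalid <- TRUE
      net$strength_excluded <- zero
      report[[length(report) + 1]] <<- tibble::tibble(
        scope = "network", group_id = net$group_id,
        context = as.character(net$context), individual = NA_character_,
        reason = "unobserved_individuals"
      )
      for (id in zero) {
        report[[length(report) + 1]] <<- tibble::tibble(
          scope = "individual", group_id = net$group_id,
          context = as.character(net$context), individual = id,
          reason = "zero_focal_minutes"
        )
      }
    }
    dyads <- unique(paste(pmin(net$edges$source, net$edges$target),
                          pmax(net$edges$source, net$edges$target)))
    if (length(dyads) < min_dyads && !net$centrality_invalid) {
      net$centrality_invalid <- TRUE
      report[[length(report) + 1]] <<- tibble::tibble(
        scope = "network", group_id = net$group_id,
        context = as.character(net$context), individual = NA_character_,
        reason = "too_few_dyads"
      )
    }
    net
  })
  report <- if (length(report) > 0) dplyr::bind_rows(report) else
    tibble::tibble(scope = character(0), group_id = character(0),
                   context = character(0), individual = character(0),
                   reason = character(0))
  list(networks = networks, report = report)
}

#' Write networks as CSV edge lists and GraphML
#'
#' @param networks List of `proximity_network`.
#' @param dir Output directory (created if needed).
#' @param graphml Also write GraphML files for interchange (default TRUE).
#' @return Invisibly, the paths written.
#' @export
write_networks <- function(networks, dir, graphml = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(networks, function(net, nm) {
    stem <- gsub("/", "_", nm)
    p <- file.path(dir, paste0(stem, "_edges.csv"))
    readr::write_csv(net$edges, p)
    if (graphml) {
      g <- as_igraph(net)
      igraph::write_graph(g, file.path(dir, paste0(stem, ".graphml")),
                          format = "graphml")
    }
    p
  })
  invisible(paths)
}

#' Convert a proximity network to an igraph graph
#' @param net A `proximity_network`.
#' @return An igraph directed graph; undirected (unknown-initiator) edges are
#'   stored as a pair of reciprocal half-weight arcs.
#' @export
as_igraph <- function(net) {
  e <- net$edges
  if (any(!e$directed)) {
    u <- e[!e$directed, ]
    e <- dplyr::bind_rows(
      e[e$directed, ],
      tibble::tibble(source = u$source, target = u$target, directed = FALSE,
                     seconds = u$seconds / 2, weight = u$weight / 2),
      tibble::tibble(source = u$target, target = u$source, directed = FALSE,
                     seconds = u$seconds / 2, weight = u$weight / 2)
    )
  }
  igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target, weight = e$weight,
                   seconds = e$seconds),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$individual,
                          minutes = net$nodes$minutes,
                          dominant_female = net$nodes$dominant_female)
  )
}
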