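#' Pipeline configuration
#'
#' Analysis switches for [run_pipeline()], echoed verbatim into every output
#' header. Unknown switches are rejected.
#'
#' @param centrality_mode Matrix mode for [eigenvector_centrality()].
#' @param ss_type Sums-of-squares type for the two-way ANOVAs (3 or 2).
#' @param williams Williams correction for the G-test (default FALSE).
#' @param ranking `"global"` (rank over the full analysis sample, default)
#'   or `"within_category"` (rank within dominance class) for the one-way
#'   context comparison of total strength.
#' @param min_dyads Centrality-validity threshold for [apply_exclusions()].
#' @param ks_seed Seed for the Monte Carlo normality screens.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(centrality_mode = "undirected_total",
                            ss_type = 3, williams = FALSE,
                            ranking = c("global", "within_category"),
                            min_dyads = 2, ks_seed = 42L) {
  ranking <- match.arg(ranking)
  structure(list(centrality_mode = centrality_mode, ss_type = ss_type,
                 williams = williams, ranking = ranking,
                 min_dyads = min_dyads, ks_seed = as.integer(ks_seed)),
            class = "pipeline_config")
}

# ledger -> networks -> exclusions -> metrics, shared by the pipeline and the
# simulation experiments
build_metrics <- function(log, roster, config = pipeline_config()) {
  ledger <- build_ledger(log)
  nets <- build_networks(log, ledger, roster)
  excl <- apply_exclusions(nets, min_dyads = config$min_dyads)
  metrics <- metrics_table(excl$networks, mode = config$centrality_mode)
  list(ledger = ledger, networks = excl$networks, exclusions = excl$report,
       metrics = metrics)
}

#' Run the full analysis pipeline
#'
#' Ingested log + roster in, statistics out: builds the observation-time
#' ledger and per-(group, context) proximity networks, applies the
#' exclusion rules, computes node metrics, and runs the statistical battery:
#'
#' * Spearman validation of the behavior pooling (per-dyad affiliative vs
#'   proximity-subclass seconds, totalled within group across contexts);
#' * Lilliefors normality screens of centrality and strengths by dominance
#'   class;
#' * one-way ANOVA of eigenvector centrality, dominant females vs others;
#' * two-way rank ANOVAs of in- and out-strength
#'   (dominance x conflict context);
#' * one-way rank ANOVAs of total strength across contexts with the a
#'   priori orthogonal contrasts, separately for dominant females and
#'   others;
#' * replicated G-test of sociosexual counts, conflict vs non-conflict
#'   contexts, groups as replicates, observed minutes as exposure.
#'
#' @param log A `behavior_log`.
#' @param roster A `focal_roster`.
#' @param config A `pipeline_config`.
#' @return List of class `pipeline_result`: `ledger`, `networks`,
#'   `exclusions`, `metrics`, `stats` (list of test objects), `stats_table`
#'   (tidy tibble: analysis, effect, statistic, df1, df2, p), `config`.
#' @export
run_pipeline <- function(log, roster, config = pipeline_config()) {
  core <- build_metrics(log, roster, config)
  metrics <- core$metrics
  stats <- list()

  stats$spearman_pooling <- tryCatch(
    do.call(spearman_affiliation, dyad_subclass_totals(log)),
    error = function(e) NULL
  )

  dom <- factor(ifelse(metrics$dominant_female, "DF", "other"),
                levels = c("DF", "other"))
  stats$ks <- list()
  for (v in c("eigenvector", "in_strength", "out_strength")) {
    for (d in levels(dom)) {
      x <- metrics[[v]][dom == d]
      x <- x[!is.na(x)]
      key <- paste(v, d, sep = ".")
      stats$ks[[key]] <- tryCatch(
        ks_normality(x, seed = config$ks_seed),
        error = function(e) NULL
      )
    }
  }

  cent <- metrics[!is.na(metrics$eigenvector), ]
  stats$centrality_anova <- if (nrow(cent) >= 4 &&
                                length(unique(cent$dominant_female)) == 2) {
    fit <- aov(eigenvector ~ dominant_female, data = cent)
    tab <- summary(fit)[[1]]
    tibble::tibble(effect = "dominance", F = tab[1, "F value"],
                   df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
                   p = tab[1, "Pr(>F)"])
  } else NULL

  stats$in_strength_twoway <- with(
    metrics[!is.na(metrics$in_strength), ],
    anova_twoway_ranks(in_strength, dominant_female, context,
                       ss_type = config$ss_type)
  )
  stats$out_strength_twoway <- with(
    metrics[!is.na(metrics$out_strength), ],
    anova_twoway_ranks(out_strength, dominant_female, context,
                       ss_type = config$ss_type)
  )

  stats$total_strength_contrasts <- list()
  for (d in c("DF", "other")) {
    sub <- metrics[dom == d & !is.na(metrics$total_strength), ]
    y <- sub$total_strength
    if (config$ranking == "within_category") y <- midrank(y)
    stats$total_strength_contrasts[[d]] <- tryCatch(
      anova_oneway_contrasts(y, sub$context,
                             rank_response = config$ranking == "global"),
      error = function(e) NULL
    )
  }

  gt <- sociosexual_g_inputs(log, core$ledger)
  stats$sociosexual_g <- if (!is.null(gt)) {
    tryCatch(replicated_g_test(gt$counts, gt$exposure,
                               williams = config$williams),
             error = function(e) NULL)
  } else NULL

  structure(c(core, list(stats = stats,
                         stats_table = tidy_stats(stats),
                         config = config)),
            class = "pipeline_result")
}

# Per-dyad totals of the two behavior subclasses, for the pooling validation.
# Dyads are unordered, totalled within group across contexts.
dyad_subclass_totals <- function(log) {
  b <- log$bouts
  if (nrow(b) == 0) return(list(affiliative = numeric(0),
                                proximity = numeric(0)))
  pooled <- pool_behavior(b$behavior)
  b$subclass <- pooled$subclass
  b <- b[!is.na(b$subclass), ]
  b$dyad <- paste(b$group_id, pmin(b$actor, b$partner),
                  pmax(b$actor, b$partner))
  tot <- b |>
    dplyr::group_by(dyad, subclass) |>
    dplyr::summarise(seconds = sum(duration_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = subclass, values_from = seconds,
                       values_fill = 0)
  if (!"affiliative" %in% names(tot)) tot$affiliative <- 0
  if (!"proximity" %in% names(tot)) tot$proximity <- 0
  list(affiliative = tot$affiliative, proximity = tot$proximity)
}

# Sociosexual counts and exposure minutes per group, conflict vs
# non-conflict contexts. Point events are classified by their own timestamp
# against the group's disruption stream.
sociosexual_g_inputs <- function(log, ledger) {
  p <- log$points[log$points$kind == "sociosexual", , drop = FALSE]
  groups <- sort(unique(ledger$group_id))
  if (length(groups) < 2) return(NULL)
  is_conflict <- function(ctx) {
    as.character(ctx) %in% c("post_intragroup", "post_intergroup")
  }
  counts <- matrix(0, length(groups), 2,
                   dimnames = list(groups, c("nonconflict", "conflict")))
  exposure <- counts
  for (g in groups) {
    sub <- ledger[ledger$group_id == g, ]
    conf <- is_conflict(sub$context)
    exposure[g, "conflict"] <- sum(sub$minutes[conf])
    exposure[g, "nonconflict"] <- sum(sub$minutes[!conf])
    pg <- p[p$group_id == g, ]
    if (nrow(pg) > 0) {
      ctx <- classify_context(
        pg$start, log$disruptions[log$disruptions$group_id == g, ])
      counts[g, "conflict"] <- sum(is_conflict(ctx))
      counts[g, "nonconflict"] <- sum(!is_conflict(ctx))
    }
  }
  list(counts = counts, exposure = exposure)
}

tidy_stats <- function(stats) {
  rows <- list()
  add <- function(analysis, effect, statistic, value, df1 = NA, df2 = NA,
                  p = NA) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analysis = analysis, effect = effect, statistic = statistic,
      value = value, df1 = df1, df2 = df2, p = p)
  }
  if (!is.null(stats$spearman_pooling)) {
    s <- stats$spearman_pooling
    add("spearman_pooling", "affiliative~proximity", "rho", s$rho,
        df1 = s$n, p = s$p)
  }
  for (key in names(stats$ks)) {
    k <- stats$ks[[key]]
    if (!is.null(k)) add("ks_normality", key, "D", k$D, df1 = k$n, p = k$p)
  }
  if (!is.null(stats$centrality_anova)) {
    r <- stats$centrality_anova
    add("centrality_anova", r$effect, "F", r$F, r$df1, r$df2, r$p)
  }
  for (nm in c("in_strength_twoway", "out_strength_twoway")) {
    tb <- stats[[nm]]
    if (!is.null(tb)) {
      for (i in seq_len(nrow(tb))) {
        add(nm, tb$effect[i], "F", tb$F[i], tb$df1[i], tb$df2[i], tb$p[i])
      }
    }
  }
  for (d in names(stats$total_strength_contrasts)) {
    ca <- stats$total_strength_contrasts[[d]]
    if (is.null(ca)) next
    o <- ca$omnibus
    add(paste0("total_strength_contrasts.", d), "context", "F", o$F,
        o$df1, o$df2, o$p)
    for (i in seq_len(nrow(ca$contrasts))) {
      r <- ca$contrasts[i, ]
      add(paste0("total_strength_contrasts.", d), r$contrast, "F", r$F,
          r$df1, r$df2, r$p)
    }
  }
  if (!is.null(stats$sociosexual_g)) {
    g <- stats$sociosexual_g
    add("sociosexual_g", "total", "G", g$total_G, g$df_total, p = g$p_total)
    add("sociosexual_g", "pooled", "G", g$pooled_G, g$df_pooled,
        p = g$p_pooled)
    add("sociosexual_g", "heterogeneity", "G", g$heterogeneity_G, g$df_het,
        p = g$p_het)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(analysis = character(0), effect = character(0),
                          statistic = character(0), value = numeric(0),
                          df1 = numeric(0), df2 = numeric(0),
                          p = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Write a pipeline result bundle to disk
#'
#' Emits the metrics table, network edge lists (+ GraphML), exclusion
#' report, tidy statistics CSV and a human-readable text report with the
#' configuration echoed in its header.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @param graphml Write GraphML network files too (default TRUE).
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(result, dir, graphml = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(result$exclusions, file.path(dir, "exclusions.csv"))
  readr::write_csv(result$stats_table, file.path(dir, "statistics.csv"))
  readr::write_csv(
    tibble::as_tibble(result$ledger)[, c("group_id", "individual", "context",
                                         "minutes")],
    file.path(dir, "ledger.csv"))
  write_networks(result$networks, file.path(dir, "networks"),
                 graphml = graphml)
  con <- file(file.path(dir, "report.txt"), open = "wt")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w("Post-conflict proximity network analysis")
  w("config: centrality_mode=", result$config$centrality_mode,
    " ss_type=", result$config$ss_type,
    " williams=", result$config$williams,
    " ranking=", result$config$ranking,
    " min_dyads=", result$config$min_dyads,
    " ks_seed=", result$config$ks_seed)
  w("")
  w("networks: ", length(result$networks),
    " (centrality-invalid: ",
    sum(purrr::map_lgl(result$networks, "centrality_invalid")), ")")
  w("individual rows in metrics table: ", nrow(result$metrics))
  w("")
  tb <- result$stats_table
  for (i in seq_len(nrow(tb))) {
    w(sprintf("%-34s %-26s %s = %9.4f  df = %s%s  p = %s",
              tb$analysis[i], tb$effect[i], tb$statistic[i], tb$value[i],
              ifelse(is.na(tb$df1[i]), "-", format(tb$df1[i])),
              ifelse(is.na(tb$df2[i]), "",
                     paste0(", ", format(tb$df2[i]))),
              ifelse(is.na(tb$p[i]), "-", formatC(tb$p[i], digits = 4,
                                                  format = "g"))))
  }
  invisible(dir)
}
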