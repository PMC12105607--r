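#' Parameter-recovery and type-I-error experiment for the dominance effect
#'
#' For each value of the dominance attraction multiplier in `alpha_grid`,
#' simulates `n_reps` datasets, runs each through the network and metrics
#' pipeline, and records (a) whether the dominant females' mean eigenvector
#' centrality exceeds the other individuals' mean and (b) whether the
#' dominance main effect of the two-way rank ANOVA on in-strength rejects at
#' the 0.05 level. With `alpha = 1` the dominant female is exchangeable with
#' her groupmates, so (b) estimates the type-I error of the test; with
#' `alpha > 1` it estimates power.
#'
#' Replicate seeds are derived deterministically from `base_seed`.
#'
#' @param config A `sim_config` used as the template (its `alpha_df` is
#'   overridden); [calibration_groups()] with equal-sized groups is the
#'   appropriate design (see the methods vignette).
#' @param n_reps Replicates per grid point (>= 1).
#' @param alpha_grid Numeric vector of multipliers to test.
#' @param base_seed Integer; replicate r at grid point k uses seed
#'   `base_seed + 10000 * k + r`.
#' @param level Nominal significance level (default 0.05).
#' @return Tibble: `alpha`, `n_reps`, `frac_df_centrality_higher`,
#'   `frac_reject` (dominance main effect of the two-way rank ANOVA),
#'   `frac_reject_centrality` (one-way centrality ANOVA), `ci_lo`, `ci_hi`
#'   (95% Wilson interval on `frac_reject`).
#' @export
recovery_experiment <- function(config, n_reps, alpha_grid = c(1, 2, 5),
                                base_seed = 1L, level = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  purrr::map_dfr(seq_along(alpha_grid), function(k) {
    a <- alpha_grid[k]
    hits_cent <- hits_rej <- hits_rej_cent <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$alpha_df <- a
      cfg$seed <- as.integer(base_seed + 10000 * k + r)
      res <- sim_dominance_fit(cfg)
      hits_cent[r] <- isTRUE(res$df_centrality_higher)
      hits_rej[r] <- isTRUE(res$p_dominance < level)
      hits_rej_cent[r] <- isTRUE(res$p_centrality < level)
    }
    ci <- stats::prop.test(sum(hits_rej), n_reps)$conf.int
    tibble::tibble(
      alpha = a, n_reps = n_reps,
      frac_df_centrality_higher = mean(hits_cent),
      frac_reject = mean(hits_rej),
      frac_reject_centrality = mean(hits_rej_cent),
      ci_lo = ci[1], ci_hi = ci[2]
    )
  })
}

# One replicate: simulate, build metrics, extract the two dominance
# diagnostics. Kept lean so 1,000-replicate calibrations stay fast.
sim_dominance_fit <- function(cfg) {
  sim <- simulate_observations(cfg)
  # sparse post-conflict networks routinely split into components or drop
  # thin context cells; those warnings are expected in bulk simulation
  core <- suppressWarnings(build_metrics(sim$log, sim$roster))
  m <- core$metrics
  cent_df <- m$eigenvector[m$dominant_female]
  cent_ot <- m$eigenvector[!m$dominant_female]
  higher <- mean(cent_df, na.rm = TRUE) > mean(cent_ot, na.rm = TRUE)
  tw <- suppressWarnings(
    with(m[!is.na(m$in_strength), ],
         anova_twoway_ranks(in_strength, dominant_female, context)))
  cent <- m[!is.na(m$eigenvector), ]
  p_cent <- if (nrow(cent) >= 4 &&
                length(unique(cent$dominant_female)) == 2) {
    tab <- summary(aov(eigenvector ~ dominant_female, data = cent))[[1]]
    tab[1, "Pr(>F)"]
  } else NA_real_
  list(df_centrality_higher = higher,
       p_dominance = tw$p[tw$effect == "dominance"],
       p_centrality = p_cent)
}

#' Contrast-recovery experiment for the post-outburst signal
#'
#' Holds every generative rate at its neutral value except the post-outburst
#' bout-rate modifier, simulates `n_reps` datasets per modifier value, runs
#' the one-way rank ANOVA of total strength across contexts with the a
#' priori contrasts, and reports each contrast's rejection rate at 0.05.
#' When only the post-outburst rate is elevated, the neutral-vs-outburst
#' contrast carries the full effect while non-conflict-vs-conflict carries
#' half of it, so the neutral-vs-outburst contrast should show the highest
#' rejection rate.
#'
#' @param config Template `sim_config`; its `context_mod` and `alpha_df` are
#'   overridden to the null except for the outburst modifier.
#' @param n_reps Replicates (>= 1).
#' @param m_outburst Post-outburst bout-rate multiplier (default 3).
#' @param base_seed Integer seed root.
#' @param level Nominal significance level (default 0.05).
#' @return Tibble: `contrast`, `n_reps`, `frac_reject`.
#' @export
contrast_recovery_experiment <- function(config, n_reps, m_outburst = 3,
                                         base_seed = 1L, level = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  cnames <- rownames(context_contrasts())
  rej <- matrix(FALSE, n_reps, length(cnames),
                dimnames = list(NULL, cnames))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$alpha_df <- 1
    cfg$context_mod <- c(neutral = 1, post_outburst = m_outburst,
                         post_intragroup = 1, post_intergroup = 1)
    cfg$seed <- as.integer(base_seed + r)
    sim <- simulate_observations(cfg)
    core <- suppressWarnings(build_metrics(sim$log, sim$roster))
    m <- core$metrics[!is.na(core$metrics$total_strength), ]
    ca <- tryCatch(
      anova_oneway_contrasts(m$total_strength, m$context),
      error = function(e) NULL
    )
    if (!is.null(ca)) {
      pr <- setNames(ca$contrasts$p, ca$contrasts$contrast)
      rej[r, names(pr)] <- pr < level
    }
  }
  tibble::tibble(contrast = cnames, n_reps = n_reps,
                 frac_reject = colMeans(rej))
}
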