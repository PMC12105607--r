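#' Replicated goodness-of-fit G-test with exposure-time expectations
#'
#' Log-likelihood-ratio test of whether event counts are distributed across
#' categories in proportion to observation time, replicated over groups and
#' partitioned in the Sokal-Rohlf style. For each replicate (row),
#' `G = 2 * sum(O * ln(O / E))` with expected counts
#' `E = row_total * exposure_share` computed from that replicate's own
#' exposure minutes; zero-count cells contribute 0. The total G is the sum of
#' per-replicate G's (df = R * (C - 1)); the pooled G is computed from summed
#' counts against summed exposures (df = C - 1); the heterogeneity G is their
#' difference (df = (R - 1) * (C - 1)), measuring whether replicates deviate
#' from expectation in consistent directions. Replicates with zero total
#' count carry no information and are dropped from the partition with a
#' warning.
#'
#' Williams' small-sample correction (off by default) divides each component
#' by `q = 1 + (C^2 - 1) / (6 * N * (C - 1))` with `N` the relevant total
#' count; note G additivity then holds only approximately.
#'
#' @param counts Matrix of observed counts, replicates x categories (e.g.,
#'   groups x {non-conflict, conflict}).
#' @param exposure Matrix of observation minutes, same shape, positive
#'   wherever the corresponding count is positive.
#' @param williams Apply Williams' correction (default FALSE).
#' @return List of class `g_test`: `total_G`, `pooled_G`, `heterogeneity_G`,
#'   `df_total`, `df_pooled`, `df_het`, `p_total`, `p_pooled`, `p_het`,
#'   `per_replicate` (tibble: replicate, G, df), `williams`.
#' @export
replicated_g_test <- function(counts, exposure, williams = FALSE) {
  counts <- as.matrix(counts)
  exposure <- as.matrix(exposure)
  stopifnot(all(dim(counts) == dim(exposure)))
  if (any(counts < 0) || any(exposure < 0)) {
    stop("counts and exposures must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  if (any(counts > 0 & exposure <= 0)) {
    stop("positive count in a category with zero exposure", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("rep", seq_len(nrow(counts)))
  }
  C <- ncol(counts)
  if (C < 2) stop("need at least 2 categories", call. = FALSE)

  g_one <- function(O, E) {
    pos <- O > 0
    2 * sum(O[pos] * log(O[pos] / E[pos]))
  }
  row_g <- function(O, expo) {
    E <- sum(O) * expo / sum(expo)
    g_one(O, E)
  }

  totals <- rowSums(counts)
  zero_rep <- totals == 0
  if (any(zero_rep)) {
    warning("replicate(s) with zero total count dropped from the partition: ",
            paste(rownames(counts)[zero_rep], collapse = ", "),
            call. = FALSE)
  }
  use <- !zero_rep
  if (sum(use) < 1) {
    stop("no replicate has any counts", call. = FALSE)
  }
  per_g <- vapply(which(use), function(r) row_g(counts[r, ], exposure[r, ]),
                  numeric(1))
  R <- sum(use)
  total_G <- sum(per_g)
  pooled_G <- row_g(colSums(counts[use, , drop = FALSE]),
                    colSums(exposure[use, , drop = FALSE]))
  het_G <- total_G - pooled_G
  df_pooled <- C - 1L
  df_total <- R * (C - 1L)
  df_het <- df_total - df_pooled

  if (williams) {
    q <- function(N, df) 1 + (C^2 - 1) / (6 * N * df)
    Ntot <- sum(counts[use, ])
    per_g <- per_g / q(totals[use], df_pooled)
    total_G <- sum(per_g)
    pooled_G <- pooled_G / q(Ntot, df_pooled)
    het_G <- total_G - pooled_G
  }

  structure(list(
    total_G = total_G, pooled_G = pooled_G, heterogeneity_G = het_G,
    df_total = df_total, df_pooled = df_pooled, df_het = df_het,
    p_total = pchisq(total_G, df_total, lower.tail = FALSE),
    p_pooled = pchisq(pooled_G, df_pooled, lower.tail = FALSE),
    p_het = if (df_het > 0) {
      pchisq(max(het_G, 0), df_het, lower.tail = FALSE)
    } else NA_real_,
    per_replicate = tibble::tibble(replicate = rownames(counts)[use],
                                   G = per_g, df = df_pooled),
    williams = williams
  ), class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat("Replicated goodness-of-fit G-test",
      if (x$williams) "(Williams-corrected)", "\n")
  cat(sprintf("  Total G         = %8.3f, df = %d, p = %.5g\n",
              x$total_G, x$df_total, x$p_total))
  cat(sprintf("  Pooled G        = %8.3f, df = %d, p = %.5g\n",
              x$pooled_G, x$df_pooled, x$p_pooled))
  cat(sprintf("  Heterogeneity G = %8.3f, df = %d, p = %.5g\n",
              x$heterogeneity_G, x$df_het, x$p_het))
  invisible(x)
}
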