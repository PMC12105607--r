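#' Midrank transform
#'
#' Converts a sample to ranks, assigning tied values the average of the ranks
#' they occupy, so ranks always sum to n(n+1)/2. This is the transform behind
#' all nonparametric ANOVAs in the package.
#'
#' @param x Numeric vector (NAs keep their position as NA).
#' @return Numeric vector of midranks.
#' @examples
#' midrank(c(1.2, 3.4, 3.4, 5.0))  # 1 2.5 2.5 4
#' @export
midrank <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}

#' Lilliefors normality screen with Monte Carlo p-value
#'
#' Kolmogorov-Smirnov test of normality with mean and SD estimated from the
#' sample (the Lilliefors variant): D is the maximum deviation between the
#' empirical CDF and the fitted normal CDF. Because the null distribution of
#' D under estimated parameters has no closed form, the p-value is computed
#' by Monte Carlo (default 10,000 standard-normal samples of the same n,
#' seeded for reproducibility). p-values are reported in the bound style of
#' the classical Lilliefors tables: values above 0.15 as `"> 0.15"`, values
#' below 0.01 as `"< 0.01"`, otherwise the Monte Carlo estimate itself.
#'
#' @param x Numeric sample, n >= 4, non-constant.
#' @param n_mc Monte Carlo replicates (default 10,000).
#' @param seed Optional integer seed for the Monte Carlo draw.
#' @return List of class `ks_normality`: `D`, `p`, `p_bound` (character),
#'   `bound` (one of `"exact"`, `">0.15"`, `"<0.01"`), `n`, `n_mc`.
#' @export
ks_normality <- function(x, n_mc = 10000, seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(x) == 0) stop("constant sample: normality test undefined",
                       call. = FALSE)
  D <- lilliefors_D(x)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  sims <- vapply(seq_len(n_mc), function(i) lilliefors_D(rnorm(n)),
                 numeric(1))
  p <- (1 + sum(sims >= D)) / (n_mc + 1)
  if (p > 0.15) {
    bound <- ">0.15"; p_bound <- "> 0.15"
  } else if (p < 0.01) {
    bound <- "<0.01"; p_bound <- "< 0.01"
  } else {
    bound <- "exact"; p_bound <- formatC(p, digits = 4, format = "f")
  }
  structure(list(D = D, p = p, p_bound = p_bound, bound = bound, n = n,
                 n_mc = n_mc),
            class = "ks_normality")
}

lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  Fe <- pnorm(z)
  max(seq_len(n) / n - Fe, Fe - (seq_len(n) - 1) / n)
}

#' @export
print.ks_normality <- function(x, ...) {
  cat("Lilliefors (Kolmogorov-Smirnov) normality test\n")
  cat(sprintf("  D = %.6f, p %s, n = %d (Monte Carlo, %d reps)\n",
              x$D, x$p_bound, x$n, x$n_mc))
  invisible(x)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The a priori orthogonal contrasts over conflict contexts
#'
#' Three mutually orthogonal 1-df comparisons over the four contexts in the
#' order neutral, post-outburst, post-intragroup, post-intergroup:
#' non-conflict vs conflict `(+1, +1, -1, -1)`, post-intragroup vs
#' post-intergroup `(0, 0, +1, -1)`, and neutral vs post-outburst
#' `(+1, -1, 0, 0)`. Coefficients sum to zero and pairwise dot products are
#' zero, so under a balanced design the three contrast sums of squares
#' partition the between-context sum of squares exactly.
#'
#' @return A 3 x 4 numeric matrix; rows named by comparison, columns by
#'   [context_levels()].
#' @export
context_contrasts <- function() {
  m <- rbind(
    nonconflict_vs_conflict  = c(1, 1, -1, -1),
    intragroup_vs_intergroup = c(0, 0, 1, -1),
    neutral_vs_outburst      = c(1, -1, 0, 0)
  )
  colnames(m) <- context_levels()
  m
}

#' One-way ANOVA on ranks with a priori orthogonal contrasts
#'
#' Rank-transforms the response (midranks over the full sample), fits a
#' one-way ANOVA across conflict contexts, and tests each planned contrast
#' as a 1-df F ratio: `SS_c = (sum c_k * mean_k)^2 / sum(c_k^2 / n_k)`,
#' `F_c = SS_c / MS_within`. Contrasts are evaluated against the within-cell
#' mean square of the omnibus fit.
#'
#' @param y Numeric response (raw scores; ranked internally unless
#'   `rank_response = FALSE`, for callers who have ranked already).
#' @param context Factor (or character) of conflict contexts.
#' @param contrasts Contrast matrix, rows = comparisons, columns named by
#'   context level (default [context_contrasts()]).
#' @param rank_response Rank-transform `y` first (default TRUE).
#' @return List of class `contrast_anova`: `omnibus` (tibble: F, df1, df2,
#'   p) and `contrasts` (tibble: contrast, estimate, ss, F, df1, df2, p).
#' @export
anova_oneway_contrasts <- function(y, context,
                                   contrasts = context_contrasts(),
                                   rank_response = TRUE) {
  keep <- !is.na(y) & !is.na(context)
  y <- y[keep]
  context <- factor(as.character(context)[keep],
                    levels = intersect(context_levels(),
                                       unique(as.character(context)[keep])))
  if (nlevels(context) < 2) {
    stop("need at least 2 contexts with data", call. = FALSE)
  }
  if (rank_response) y <- midrank(y)
  if (stats::var(y) == 0) {
    # degenerate input: no variation anywhere, every F is 0 by convention
    df2 <- length(y) - nlevels(context)
    omnibus <- tibble::tibble(effect = "context", F = 0,
                              df1 = nlevels(context) - 1, df2 = df2, p = 1)
    rows <- tibble::tibble(contrast = rownames(contrasts), estimate = 0,
                           ss = 0, F = 0, df1 = 1, df2 = df2, p = 1)
    return(structure(list(omnibus = omnibus, contrasts = rows,
                          ranked = rank_response),
                     class = "contrast_anova"))
  }
  fit <- aov(y ~ context)
  tab <- summary(fit)[[1]]
  df2 <- tab["Residuals", "Df"]
  ms_within <- tab["Residuals", "Mean Sq"]
  omnibus <- tibble::tibble(
    effect = "context",
    F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = df2,
    p = tab[1, "Pr(>F)"]
  )
  means <- tapply(y, context, mean)
  ns <- tapply(y, context, length)
  rows <- purrr::map_dfr(rownames(contrasts), function(cn) {
    cv <- contrasts[cn, ]
    used <- names(cv)[cv != 0]
    absent <- setdiff(used, levels(context))
    if (length(absent) > 0) {
      stop("contrast '", cn, "' references absent context(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    est <- sum(cv[levels(context)] * means)
    ss <- est^2 / sum(cv[levels(context)]^2 / ns)
    Fc <- ss / ms_within
    tibble::tibble(contrast = cn, estimate = est, ss = ss, F = Fc,
                   df1 = 1, df2 = df2, p = pf(Fc, 1, df2, lower.tail = FALSE))
  })
  structure(list(omnibus = omnibus, contrasts = rows,
                 ranked = rank_response),
            class = "contrast_anova")
}

#' @export
print.contrast_anova <- function(x, ...) {
  cat("One-way ANOVA", if (x$ranked) "on ranks", "across conflict contexts\n")
  cat(sprintf("  omnibus: F = %.3f, df = %d, %d, p = %.4f\n",
              x$omnibus$F, x$omnibus$df1, x$omnibus$df2, x$omnibus$p))
  for (i in seq_len(nrow(x$contrasts))) {
    r <- x$contrasts[i, ]
    cat(sprintf("  %-26s F = %.3f, df = 1, %d, p = %.4f\n",
                r$contrast, r$F, r$df2, r$p))
  }
  invisible(x)
}

#' Two-way ANOVA on ranks: dominance x conflict context
#'
#' Rank-transforms the response over the full analysis sample, then fits
#' `rank ~ dominance * context` and reports the overall model F (full model
#' against the intercept-only null) plus main-effect and interaction F's.
#' The design is a possibly unbalanced 2 x 4, so effect tests default to
#' Type III sums of squares (sum-to-zero contrasts, each term adjusted for
#' all others); Type II is available. Factor levels with no observations are
#' dropped with a warning.
#'
#' @param y Numeric response.
#' @param dominance Two-level factor (e.g., dominant female vs other).
#' @param context Conflict-context factor.
#' @param ss_type 3 (default) or 2.
#' @param rank_response Rank-transform `y` first (default TRUE).
#' @return Tibble with one row per effect (`model`, `dominance`, `context`,
#'   `dominance:context`): `F`, `df1`, `df2`, `p`.
#' @export
anova_twoway_ranks <- function(y, dominance, context, ss_type = 3,
                               rank_response = TRUE) {
  stopifnot(ss_type %in% c(2, 3))
  keep <- !is.na(y) & !is.na(dominance) & !is.na(context)
  y <- y[keep]
  dominance <- droplevels2(factor(dominance)[keep], "dominance")
  context <- droplevels2(
    factor(as.character(context)[keep], levels = context_levels()), "context")
  if (nlevels(dominance) < 2) {
    stop("need both dominance classes", call. = FALSE)
  }
  # a context observed for only one dominance class aliases the interaction;
  # drop it like an empty level
  cell <- table(dominance, context)
  bad_ctx <- colnames(cell)[apply(cell == 0, 2, any)]
  if (length(bad_ctx) > 0) {
    warning("dropping context level(s) with an empty dominance cell: ",
            paste(bad_ctx, collapse = ", "), call. = FALSE)
    keep2 <- !context %in% bad_ctx
    y <- y[keep2]
    dominance <- droplevels(dominance[keep2])
    context <- droplevels(context[keep2])
  }
  if (nlevels(context) < 2) {
    stop("need at least 2 context levels with both dominance classes",
         call. = FALSE)
  }
  if (rank_response) y <- midrank(y)
  if (stats::var(y) == 0) {
    k <- nlevels(dominance) * nlevels(context)
    df2 <- length(y) - k
    return(tibble::tibble(
      effect = c("model", "dominance", "context", "dominance:context"),
      F = 0,
      df1 = c(k - 1, nlevels(dominance) - 1, nlevels(context) - 1,
              (nlevels(dominance) - 1) * (nlevels(context) - 1)),
      df2 = df2, p = 1))
  }
  dat <- data.frame(y = y, dominance = dominance, context = context)
  fit <- lm(y ~ dominance * context, data = dat,
            contrasts = list(dominance = "contr.sum",
                             context = "contr.sum"))
  fs <- summary(fit)$fstatistic
  model_row <- tibble::tibble(
    effect = "model", F = unname(fs[1]), df1 = unname(fs[2]),
    df2 = unname(fs[3]),
    p = pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  )
  a <- car::Anova(fit, type = ss_type)
  a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  df2 <- stats::df.residual(fit)
  eff_rows <- tibble::tibble(
    effect = rownames(a),
    F = a[["F value"]], df1 = a[["Df"]], df2 = df2,
    p = a[["Pr(>F)"]]
  )
  dplyr::bind_rows(model_row, eff_rows)
}

droplevels2 <- function(f, label) {
  empty <- setdiff(levels(f), unique(as.character(f)))
  if (length(empty) > 0) {
    warning("dropping empty ", label, " level(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  droplevels(f)
}

#' Spearman validation of the behavior pooling
#'
#' Checks that the affiliative subclass (grooming, play, co-feeding) and the
#' proximity subclass (contact, close, partial proximity) tell a consistent
#' story at the dyad level: per-dyad total seconds in the two subclasses are
#' correlated by Spearman's rank correlation (two-sided). A substantial
#' positive correlation supports pooling all six behaviors into the single
#' proximity category used for network construction.
#'
#' @param affiliative,proximity Numeric vectors of per-dyad total seconds,
#'   same length, n >= 5.
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_affiliation <- function(affiliative, proximity) {
  stopifnot(length(affiliative) == length(proximity))
  keep <- !is.na(affiliative) & !is.na(proximity)
  a <- affiliative[keep]
  b <- proximity[keep]
  if (length(a) < 5) stop("need at least 5 dyads", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}
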