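#' Node strengths of a proximity network
#'
#' In-strength of an individual is the sum of weights of edges directed at it
#' (rates of receiving initiations); out-strength the sum of weights of edges
#' it initiates. Total strength is in + out, a proxy for overall sociality.
#' Undirected edges (unknown initiator) add their weight to the total
#' strength of both endpoints but to neither in- nor out-strength, so
#' `total = in + out` holds exactly when every bout's initiator was observed.
#'
#' @param net A `proximity_network`.
#' @return Tibble with columns `individual`, `in_strength`, `out_strength`,
#'   `total_strength` (all in s/min).
#' @export
strengths <- function(net) {
  ids <- net$nodes$individual
  z <- setNames(numeric(length(ids)), ids)
  ins <- outs <- und <- z
  e <- net$edges
  if (nrow(e) > 0) {
    d <- e[e$directed, ]
    if (nrow(d) > 0) {
      outs_t <- tapply(d$weight, d$source, sum)
      ins_t <- tapply(d$weight, d$target, sum)
      outs[names(outs_t)] <- outs_t
      ins[names(ins_t)] <- ins_t
    }
    u <- e[!e$directed, ]
    if (nrow(u) > 0) {
      for (k in seq_len(nrow(u))) {
        und[u$source[k]] <- und[u$source[k]] + u$weight[k]
        und[u$target[k]] <- und[u$target[k]] + u$weight[k]
      }
    }
  }
  tibble::tibble(individual = ids, in_strength = as.numeric(ins),
                 out_strength = as.numeric(outs),
                 total_strength = as.numeric(ins + outs + und))
}

# Symmetric (or directed) weight matrix of a network. Undirected edges enter
# symmetrically in every mode.
weight_matrix <- function(net, mode = c("undirected_total", "directed_right",
                                        "directed_left")) {
  mode <- match.arg(mode)
  ids <- net$nodes$individual
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      i <- e$source[k]; j <- e$target[k]
      if (e$directed[k]) {
        W[i, j] <- W[i, j] + e$weight[k]
      } else {
        W[i, j] <- W[i, j] + e$weight[k] / 2
        W[j, i] <- W[j, i] + e$weight[k] / 2
      }
    }
  }
  switch(mode,
         undirected_total = W + t(W),
         directed_right   = W,
         directed_left    = t(W))
}

# Power iteration for the principal eigenvector of a non-negative square
# matrix. A diagonal shift by the maximum absolute row sum makes the dominant
# eigenvalue unique in modulus (a symmetrized star graph, e.g., has paired
# +/- eigenvalues on which unshifted iteration oscillates) without changing
# eigenvectors. Returns the Perron vector (non-negative) and its eigenvalue.
power_iteration <- function(A, tol = 1e-10, max_iter = 10000) {
  n <- nrow(A)
  if (n == 1) return(list(vector = 1, value = A[1, 1]))
  shift <- max(rowSums(abs(A)))
  B <- A + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    w <- B %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(vector = rep(0, n), value = 0))
    w <- as.numeric(w / nw)
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  lambda <- as.numeric(v %*% A %*% v) / sum(v^2)
  v <- abs(v)
  list(vector = v, value = lambda)
}

#' Eigenvector centrality, scaled to a maximum of 1
#'
#' Scores individuals by the principal eigenvector of the network's
#' non-negative weight matrix, computed by power iteration (tolerance 1e-10,
#' at most 10,000 iterations) and rescaled so the most central individual
#' scores exactly 1 — comparable across groups of different sizes. The
#' default mode symmetrizes the directed weights (`W + t(W)`): proximity is
#' physically mutual, and a directed spectrum is ill-defined for nodes that
#' never receive initiations, which is common at this sparsity. Directed
#' variants are exposed for sensitivity analyses (`directed_right`: scores
#' propagate along initiation direction; `directed_left`: against it).
#'
#' If the positive edges span several connected components, the principal
#' vector is computed within each component, each component's scores are
#' scaled in proportion to its dominant eigenvalue relative to the global
#' maximum (components are processed in order of their smallest node ID), and
#' a warning is raised. Isolated nodes score 0.
#'
#' @param net A `proximity_network` (must not be centrality-invalid), or a
#'   non-negative square weight matrix with dimnames.
#' @param mode Matrix construction mode; see Details.
#' @param tol,max_iter Power-iteration controls.
#' @return Named numeric vector of scores in `[0, 1]`, maximum exactly 1.
#' @export
eigenvector_centrality <- function(net,
                                   mode = c("undirected_total",
                                            "directed_right",
                                            "directed_left"),
                                   tol = 1e-10, max_iter = 10000) {
  mode <- match.arg(mode)
  if (inherits(net, "proximity_network")) {
    if (isTRUE(net$centrality_invalid)) {
      stop("network is flagged centrality-invalid; see apply_exclusions()",
           call. = FALSE)
    }
    W <- weight_matrix(net, mode)
  } else {
    W <- as.matrix(net)
    stopifnot(nrow(W) == ncol(W), all(W >= 0))
    if (is.null(rownames(W))) {
      dimnames(W) <- list(seq_len(nrow(W)), seq_len(nrow(W)))
    }
    # a raw matrix is taken as directed weights; apply the mode the same
    # way as for a network object
    W <- switch(mode, undirected_total = W + t(W), directed_right = W,
                directed_left = t(W))
  }
  if (all(W == 0)) {
    stop("all-zero weight matrix: centrality undefined", call. = FALSE)
  }
  ids <- rownames(W)
  n <- length(ids)
  # connected components of the positive support (undirected sense)
  gsupp <- igraph::graph_from_adjacency_matrix((W + t(W)) > 0, "undirected")
  comp <- igraph::components(gsupp)$membership
  # deterministic component order by smallest node index
  comp_ids <- unique(comp[order(seq_len(n))])
  scores <- setNames(numeric(n), ids)
  values <- numeric(0)
  vecs <- list()
  active <- 0L
  for (cid in comp_ids) {
    members <- which(comp == cid)
    if (length(members) == 1 && sum(W[members, ]) + sum(W[, members]) == 0) {
      next  # isolated node, score 0
    }
    active <- active + 1L
    pi <- power_iteration(W[members, members, drop = FALSE], tol, max_iter)
    v <- pi$vector / max(pi$vector)
    vecs[[active]] <- setNames(v, ids[members])
    values[active] <- pi$value
  }
  if (active > 1) {
    warning("positive edges span ", active, " components; centrality ",
            "computed per component and scaled by component eigenvalue",
            call. = FALSE)
  }
  vmax <- max(values)
  for (k in seq_len(active)) {
    sc <- if (vmax > 0) values[k] / vmax else 1
    scores[names(vecs[[k]])] <- vecs[[k]] * sc
  }
  scores
}

#' Long-format table of node metrics across networks
#'
#' One row per (individual, group, context): eigenvector centrality (absent
#' where the network is centrality-invalid), the three strengths (absent for
#' strength-excluded individuals), observed minutes, and the dominant-female
#' flag from the roster.
#'
#' @param networks List of `proximity_network`, typically after
#'   [apply_exclusions()].
#' @param mode Centrality mode, passed to [eigenvector_centrality()].
#' @return Tibble with columns `group_id`, `context`, `individual`,
#'   `dominant_female`, `minutes`, `eigenvector`, `in_strength`,
#'   `out_strength`, `total_strength`.
#' @export
metrics_table <- function(networks, mode = "undirected_total") {
  if (length(networks) == 0) {
    return(tibble::tibble(
      group_id = character(0), context = character(0),
      individual = character(0), dominant_female = logical(0),
      minutes = numeric(0), eigenvector = numeric(0),
      in_strength = numeric(0), out_strength = numeric(0),
      total_strength = numeric(0)
    ))
  }
  purrr::map_dfr(networks, function(net) {
    s <- strengths(net)
    cent <- rep(NA_real_, nrow(s))
    if (!net$centrality_invalid && nrow(net$edges) > 0 &&
        any(net$edges$weight > 0)) {
      ec <- eigenvector_centrality(net, mode = mode)
      cent <- as.numeric(ec[s$individual])
    }
    excl <- s$individual %in% net$strength_excluded
    tibble::tibble(
      group_id = net$group_id,
      context = as.character(net$context),
      individual = s$individual,
      dominant_female = net$nodes$dominant_female,
      minutes = net$nodes$minutes,
      eigenvector = cent,
      in_strength = ifelse(excl, NA_real_, s$in_strength),
      out_strength = ifelse(excl, NA_real_, s$out_strength),
      total_strength = ifelse(excl, NA_real_, s$total_strength)
    )
  })
}
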