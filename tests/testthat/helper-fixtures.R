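# Small in-code fixtures shared across test files.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# A three-member roster in one group.
tiny_roster <- function() {
  as_roster(tibble::tibble(
    group_id = "A",
    individual = c("F3", "F5", "M7"),
    sex = c("F", "F", "M"),
    age_class = "adult",
    dominant_female = c(TRUE, FALSE, FALSE),
    intergroup_access = FALSE
  ))
}

# Build a behavior_log directly from component tibbles, with defaults that
# satisfy the validation contract.
tiny_log <- function(focals = NULL, bouts = NULL, points = NULL,
                     disruptions = NULL) {
  if (is.null(focals)) {
    focals <- tibble::tibble(
      session_id = character(0), group_id = character(0),
      focal_id = character(0), start = ts(character(0)),
      duration_s = numeric(0))
  }
  if (is.null(bouts)) {
    bouts <- tibble::tibble(
      session_id = character(0), group_id = character(0),
      focal_id = character(0), actor = character(0), partner = character(0),
      behavior = character(0), initiator = character(0),
      start = ts(character(0)), duration_s = numeric(0))
  }
  if (is.null(points)) {
    points <- tibble::tibble(
      session_id = character(0), group_id = character(0),
      kind = character(0), actor = character(0), partner = character(0),
      start = ts(character(0)))
  }
  if (is.null(disruptions)) {
    disruptions <- tibble::tibble(
      group_id = character(0), time = ts(character(0)),
      kind = character(0), participants = character(0))
  }
  focalsna:::new_behavior_log(focals, bouts, points, disruptions)
}

# The worked-example cell: F3 observed 33 min, F5 26 min, one 171-s bout of
# proximity initiated by F3, all in the neutral context. M7 gets a focal so
# the roster's third member has observation time too.
worked_example_log <- function() {
  focals <- tibble::tibble(
    session_id = c("S1", "S1", "S1"),
    group_id = "A",
    focal_id = c("F3", "F5", "M7"),
    start = ts(c("2023-07-01 09:00:00", "2023-07-01 09:33:00",
                 "2023-07-01 09:59:00")),
    duration_s = c(33, 26, 10) * 60
  )
  bouts <- tibble::tibble(
    session_id = "S1", group_id = "A", focal_id = "F3",
    actor = "F3", partner = "F5", behavior = "close_proximity",
    initiator = "actor", start = ts("2023-07-01 09:05:00"),
    duration_s = 171
  )
  tiny_log(focals = focals, bouts = bouts)
}

# Write a minimal event-log CSV; rows are given as a list of named lists.
write_log_csv <- function(rows, path) {
  cols <- c("session_id", "group_id", "focal_id", "record_type", "behavior",
            "actor", "partner", "initiator", "start_iso", "duration_s",
            "kind", "participants")
  df <- do.call(rbind, lapply(rows, function(r) {
    out <- setNames(as.list(rep(NA, length(cols))), cols)
    out[names(r)] <- r
    as.data.frame(out, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Random connected symmetric weight matrix on n nodes (for centrality
# oracle comparisons).
random_connected_weights <- function(n, p_edge = 0.6) {
  repeat {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) {
          w <- runif(1, 0.1, 5)
          W[i, j] <- w
          W[j, i] <- w
        }
      }
    }
    g <- igraph::graph_from_adjacency_matrix(W > 0, "undirected")
    if (igraph::is_connected(g) && any(W > 0)) break
  }
  dimnames(W) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  W
}

# Dense-eigendecomposition oracle: principal eigenvector of a symmetric
# non-negative matrix, max-rescaled.
eigen_oracle <- function(W) {
  e <- eigen(W, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  setNames(v / max(v), rownames(W))
}

# Direct G evaluation for one replicate.
g_direct <- function(O, E) {
  pos <- O > 0
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}
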