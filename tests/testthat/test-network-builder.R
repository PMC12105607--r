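test_that("dyadic rate normalizes seconds by combined observation minutes", {
  expect_equal(round(dyadic_rate(171, 33, 26), 3), 2.898)
  expect_equal(dyadic_rate(0, 10, 10), 0)
  expect_equal(dyadic_rate(300, 10, 20), 10)
  expect_error(dyadic_rate(10, 0, 0), "combined observation time is zero")
  expect_error(dyadic_rate(-1, 5, 5), ">= 0")
})

test_that("the worked-example cell produces a single 2.898 edge", {
  log <- worked_example_log()
  led <- build_ledger(log)
  nets <- build_networks(log, led, tiny_roster())
  expect_length(nets, 1)
  net <- nets[["A/neutral"]]
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "F3")
  expect_equal(net$edges$target, "F5")
  expect_equal(round(net$edges$weight, 3), 2.898)
})

test_that("bout seconds add within a directed dyad before weighting", {
  log <- worked_example_log()
  log$bouts <- dplyr::bind_rows(
    log$bouts[0, ],
    dplyr::mutate(log$bouts, duration_s = 100),
    dplyr::mutate(log$bouts, duration_s = 71,
                  start = log$bouts$start + 300)
  )
  led <- build_ledger(log)
  net <- build_networks(log, led, tiny_roster())[["A/neutral"]]
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$seconds, 171)
  expect_equal(round(net$edges$weight, 3), 2.898)
})

test_that("a log with no proximity bouts yields node-only networks", {
  log <- worked_example_log()
  log$bouts <- log$bouts[0, ]
  led <- build_ledger(log)
  net <- build_networks(log, led, tiny_roster())[["A/neutral"]]
  expect_equal(nrow(net$edges), 0)
  expect_equal(sort(net$nodes$individual), c("F3", "F5", "M7"))
})

test_that("network construction is order independent", {
  sim <- simulate_observations(sim_config(seed = 11))
  led <- build_ledger(sim$log)
  nets1 <- build_networks(sim$log, led, sim$roster)
  shuffled <- sim$log
  set.seed(99)
  shuffled$bouts <- shuffled$bouts[sample(nrow(shuffled$bouts)), ]
  nets2 <- build_networks(shuffled, led, sim$roster)
  expect_equal(names(nets1), names(nets2))
  for (nm in names(nets1)) {
    e1 <- dplyr::arrange(nets1[[nm]]$edges, source, target, directed)
    e2 <- dplyr::arrange(nets2[[nm]]$edges, source, target, directed)
    expect_equal(e1, e2)
  }
})

test_that("weights reconstruct total seconds and scale with effort", {
  sim <- simulate_observations(sim_config(seed = 13))
  led <- build_ledger(sim$log)
  nets <- build_networks(sim$log, led, sim$roster)
  pooled <- pool_behavior(sim$log$bouts$behavior)
  for (net in nets) {
    mins <- setNames(net$nodes$minutes, net$nodes$individual)
    e <- net$edges
    # reconstruction identity: weight * (min_src + min_tgt) recovers seconds
    expect_equal(sum(e$weight * (mins[e$source] + mins[e$target])),
                 sum(e$seconds))
    expect_true(all(e$weight >= 0))
    expect_true(all((e$weight == 0) == (e$seconds == 0)))
    n <- nrow(net$nodes)
    expect_lte(nrow(e[e$directed, ]), n * (n - 1))
  }
  # total across networks equals total pooled proximity seconds
  expect_equal(sum(purrr::map_dbl(nets, ~ sum(.x$edges$seconds))),
               sum(sim$log$bouts$duration_s[pooled$category == "proximity"]))

  # doubling observation minutes (holding bout seconds fixed) halves weights
  log1 <- worked_example_log()
  log2 <- worked_example_log()
  log2$focals$start <- ts(c("2023-07-01 09:00:00", "2023-07-01 11:00:00",
                            "2023-07-01 13:00:00"))
  log2$focals$duration_s <- log2$focals$duration_s * 2
  w1 <- build_networks(log1, build_ledger(log1),
                       tiny_roster())[["A/neutral"]]$edges$weight
  w2 <- build_networks(log2, build_ledger(log2),
                       tiny_roster())[["A/neutral"]]$edges$weight
  expect_equal(w2, w1 / 2)
})

test_that("unknown-initiator bouts become undirected edges", {
  log <- worked_example_log()
  log$bouts$initiator <- "unknown"
  led <- build_ledger(log)
  net <- build_networks(log, led, tiny_roster())[["A/neutral"]]
  expect_false(net$edges$directed)
  s <- strengths(net)
  expect_equal(s$in_strength, rep(0, 3))
  expect_equal(s$out_strength, rep(0, 3))
  expect_equal(s$total_strength[s$individual == "F3"], 171 / 59)
  expect_equal(s$total_strength[s$individual == "F5"], 171 / 59)
})

test_that("exclusion rules follow the unobserved-individual and dyad counts", {
  # 2 of 7 members with zero focal minutes: centrality invalid + exclusions
  roster <- as_roster(tibble::tibble(
    group_id = "B", individual = paste0("I", 1:7),
    dominant_female = c(TRUE, rep(FALSE, 6)), intergroup_access = FALSE,
    sex = c("F", rep("M", 6))))
  focals <- tibble::tibble(
    session_id = "S1", group_id = "B", focal_id = paste0("I", 1:5),
    start = ts("2023-07-01 09:00:00") + (0:4) * 600, duration_s = 600)
  bouts <- tibble::tibble(
    session_id = "S1", group_id = "B", focal_id = c("I1", "I2"),
    actor = c("I1", "I2"), partner = c("I2", "I3"),
    behavior = "contact", initiator = "actor",
    start = ts("2023-07-01 09:00:10") + c(0, 600), duration_s = 60)
  log <- tiny_log(focals = focals, bouts = bouts)
  led <- build_ledger(log)
  nets <- build_networks(log, led, roster)
  out <- apply_exclusions(nets)
  net <- out$networks[["B/neutral"]]
  expect_true(net$centrality_invalid)
  expect_setequal(net$strength_excluded, c("I6", "I7"))
  expect_equal(sum(out$report$scope == "individual"), 2)

  # a single observed dyad: centrality invalid, strengths kept
  log1 <- log
  log1$bouts <- log1$bouts[1, ]
  f6 <- tibble::tibble(session_id = "S1", group_id = "B",
                       focal_id = c("I6", "I7"),
                       start = ts("2023-07-01 10:00:00") + c(0, 600),
                       duration_s = 600)
  log1$focals <- dplyr::bind_rows(log1$focals, f6)
  led1 <- build_ledger(log1)
  out1 <- apply_exclusions(build_networks(log1, led1, roster))
  net1 <- out1$networks[["B/neutral"]]
  expect_true(net1$centrality_invalid)
  expect_length(net1$strength_excluded, 0)
  expect_equal(out1$report$reason, "too_few_dyads")

  # fully observed, enough dyads: no action
  log2 <- log
  log2$focals <- dplyr::bind_rows(log2$focals, f6)
  led2 <- build_ledger(log2)
  out2 <- apply_exclusions(build_networks(log2, led2, roster))
  expect_equal(nrow(out2$report), 0)
  expect_false(out2$networks[["B/neutral"]]$centrality_invalid)
})

test_that("metrics are absent where exclusions apply", {
  roster <- as_roster(tibble::tibble(
    group_id = "B", individual = paste0("I", 1:4),
    dominant_female = c(TRUE, FALSE, FALSE, FALSE),
    intergroup_access = FALSE, sex = c("F", "M", "M", "M")))
  focals <- tibble::tibble(
    session_id = "S1", group_id = "B", focal_id = c("I1", "I2"),
    start = ts("2023-07-01 09:00:00") + c(0, 600), duration_s = 600)
  bouts <- tibble::tibble(
    session_id = "S1", group_id = "B", focal_id = "I1", actor = "I1",
    partner = "I2", behavior = "contact", initiator = "actor",
    start = ts("2023-07-01 09:00:10"), duration_s = 60)
  log <- tiny_log(focals = focals, bouts = bouts)
  out <- apply_exclusions(build_networks(log, build_ledger(log), roster))
  m <- metrics_table(out$networks)
  expect_true(all(is.na(m$eigenvector)))
  expect_true(all(is.na(m$in_strength[m$individual %in% c("I3", "I4")])))
  expect_false(anyNA(m$in_strength[m$individual %in% c("I1", "I2")]))
})

test_that("network export writes edge lists and GraphML", {
  log <- worked_example_log()
  nets <- build_networks(log, build_ledger(log), tiny_roster())
  dir <- withr::local_tempdir()
  write_networks(nets, dir)
  expect_true(file.exists(file.path(dir, "A_neutral_edges.csv")))
  expect_true(file.exists(file.path(dir, "A_neutral.graphml")))
  g <- igraph::read_graph(file.path(dir, "A_neutral.graphml"),
                          format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 1)
})
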