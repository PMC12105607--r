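test_that("behavior pooling collapses affiliative states onto proximity", {
  p <- pool_behavior(c("groom", "play", "cofeed", "contact",
                       "close_proximity", "partial_proximity"))
  expect_true(all(p$category == "proximity"))
  expect_equal(p$subclass,
               c("affiliative", "affiliative", "affiliative",
                 "proximity", "proximity", "proximity"))
  expect_equal(pool_behavior("rest")$category, "other")
  expect_equal(pool_behavior("locomotion")$category, "other")
  expect_error(pool_behavior("teleport"), "unknown ethogram label")
})

test_that("pooling is idempotent and surjective onto {proximity, other}", {
  labels <- c("groom", "play", "cofeed", "contact", "close_proximity",
              "partial_proximity", "rest", "locomotion", "feed",
              "self_groom", "vigilance", "out_of_view", "solitary")
  cats <- pool_behavior(labels)$category
  expect_setequal(unique(cats), c("proximity", "other"))
  # pooling twice changes nothing: category depends only on the label
  expect_identical(pool_behavior(labels)$category, cats)
})

test_that("context classification follows the 1-hour half-open window", {
  ev <- tibble::tibble(group_id = "A",
                       time = ts("2023-07-01 10:00:00"),
                       kind = "outburst", participants = "F3")
  expect_equal(
    as.character(classify_context(ts("2023-07-01 10:30:00"), ev)),
    "post_outburst")
  # 90 minutes later: outside the window
  expect_equal(
    as.character(classify_context(ts("2023-07-01 11:30:00"), ev)),
    "neutral")
  # exactly 60 minutes later: window is half-open, event excluded
  expect_equal(
    as.character(classify_context(ts("2023-07-01 11:00:00"), ev)),
    "neutral")
  # event at t itself is included
  expect_equal(
    as.character(classify_context(ts("2023-07-01 10:00:00"), ev)),
    "post_outburst")
  expect_equal(
    as.character(classify_context(ts("2023-07-01 10:30:00"), NULL)),
    "neutral")
})

test_that("conflicts outrank outbursts and intergroup outranks intragroup", {
  ev <- tibble::tibble(
    group_id = "A",
    time = ts(c("2023-07-01 10:00:00", "2023-07-01 10:20:00")),
    kind = c("outburst", "intragroup"), participants = c("F3", "F3;F5"))
  expect_equal(
    as.character(classify_context(ts("2023-07-01 10:30:00"), ev)),
    "post_intragroup")
  ev2 <- tibble::tibble(
    group_id = "C",
    time = ts(c("2023-07-01 10:20:00", "2023-07-01 10:00:00")),
    kind = c("intragroup", "intergroup"), participants = c("F5;M7", "F5"))
  expect_equal(
    as.character(classify_context(ts("2023-07-01 10:30:00"), ev2)),
    "post_intergroup")
})

test_that("context classification is total over random event streams", {
  set.seed(41)
  for (rep in 1:20) {
    ne <- sample(0:6, 1)
    ev <- tibble::tibble(
      group_id = "A",
      time = ts("2023-07-01 08:00:00") + sort(runif(ne, 0, 8 * 3600)),
      kind = sample(c("outburst", "intragroup", "intergroup"), ne,
                    replace = TRUE),
      participants = "F3")
    t <- ts("2023-07-01 08:00:00") + runif(15, 0, 9 * 3600)
    ctx <- classify_context(t, ev)
    expect_false(anyNA(ctx))
    expect_true(all(as.character(ctx) %in% context_levels()))
  }
})

test_that("event-log ingestion validates rows and names offenders", {
  roster <- tiny_roster()
  path <- withr::local_tempfile(fileext = ".csv")
  write_log_csv(list(
    list(session_id = "S1", group_id = "A", focal_id = "F3",
         record_type = "focal", start_iso = "2023-07-01T09:00:00",
         duration_s = 600),
    list(session_id = "S1", group_id = "A", focal_id = "F3",
         record_type = "state", behavior = "groom", actor = "F3",
         partner = "F5", initiator = "actor",
         start_iso = "2023-07-01T09:01:00", duration_s = 120),
    list(session_id = "S1", group_id = "A", record_type = "point",
         kind = "sociosexual", actor = "F3", partner = "M7",
         start_iso = "2023-07-01T09:05:00")
  ), path)
  log <- read_event_log(path, roster)
  expect_s3_class(log, "behavior_log")
  expect_equal(nrow(log$focals), 1)
  expect_equal(nrow(log$bouts), 1)
  expect_equal(nrow(log$points), 1)

  write_log_csv(list(
    list(session_id = "S1", group_id = "A", focal_id = "F3",
         record_type = "state", behavior = "groom", actor = "F3",
         partner = "F9", initiator = "actor",
         start_iso = "2023-07-01T09:01:00", duration_s = 120)
  ), path)
  expect_error(read_event_log(path, roster), "line 2.*F9")

  write_log_csv(list(
    list(session_id = "S1", group_id = "A", focal_id = "F3",
         record_type = "state", behavior = "groom", actor = "F3",
         partner = "F3", initiator = "actor",
         start_iso = "2023-07-01T09:01:00", duration_s = 120)
  ), path)
  expect_error(read_event_log(path, roster), "actor equals partner")

  write_log_csv(list(
    list(session_id = "S1", group_id = "A", focal_id = "F3",
         record_type = "state", behavior = "groom", actor = "F3",
         partner = "F5", initiator = "actor",
         start_iso = "2023-07-01T09:01:00", duration_s = -5)
  ), path)
  expect_error(read_event_log(path, roster), "negative duration")
})

test_that("an empty log with a header ingests to an empty log with warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(focalsna:::.log_columns, collapse = ","), path)
  expect_warning(log <- read_event_log(path, tiny_roster()),
                 "no records")
  expect_equal(nrow(log$focals) + nrow(log$bouts) + nrow(log$points), 0)
})

test_that("roster validation enforces structure", {
  expect_error(as_roster(tibble::tibble(
    group_id = "A", individual = c("F1", "F2"),
    dominant_female = c(TRUE, FALSE), intergroup_access = FALSE
  )), "expected 3-8")
  expect_error(as_roster(tibble::tibble(
    group_id = "A", individual = c("F1", "F2", "M1"),
    dominant_female = c(TRUE, TRUE, FALSE), intergroup_access = FALSE
  )), "dominant females")
  expect_error(as_roster(tibble::tibble(
    group_id = "A", individual = c("F1", "F1", "M1"),
    dominant_female = c(TRUE, FALSE, FALSE), intergroup_access = FALSE
  )), "duplicated")
})

test_that("the ledger assigns whole focal samples to start-time contexts", {
  focals <- tibble::tibble(
    session_id = "S1", group_id = "A", focal_id = "F3",
    start = ts("2023-07-01 09:00:00"), duration_s = 600)
  log <- tiny_log(focals = focals)
  led <- build_ledger(log)
  expect_equal(
    led$minutes[led$individual == "F3" & led$context == "neutral"], 10)
  expect_equal(sum(led$minutes[led$individual == "F3"]), 10)

  # a focal starting 59 min after a conflict is post-conflict for all 10 min
  ev <- tibble::tibble(group_id = "A", time = ts("2023-07-01 08:01:00"),
                       kind = "intragroup", participants = "F3;F5")
  led2 <- build_ledger(tiny_log(focals = focals), events = ev)
  expect_equal(
    led2$minutes[led2$individual == "F3" &
                   led2$context == "post_intragroup"], 10)
  expect_equal(
    led2$minutes[led2$individual == "F3" & led2$context == "neutral"], 0)
})

test_that("ledger minutes are conserved on simulated schedules", {
  sim <- simulate_observations(sim_config(seed = 3))
  led <- build_ledger(sim$log)
  totals <- sim$log$focals |>
    dplyr::group_by(group_id, individual = focal_id) |>
    dplyr::summarise(minutes = sum(duration_s) / 60, .groups = "drop")
  led_tot <- led |>
    dplyr::group_by(group_id, individual) |>
    dplyr::summarise(minutes = sum(minutes), .groups = "drop")
  joined <- dplyr::inner_join(totals, led_tot,
                              by = c("group_id", "individual"))
  expect_equal(nrow(joined), nrow(totals))
  expect_equal(joined$minutes.x, joined$minutes.y)
})

test_that("with no disruption events every minute is neutral", {
  cfg <- sim_config(seed = 5,
                    event_rates = c(outburst = 0, intragroup = 0,
                                    intergroup = 0))
  sim <- simulate_observations(cfg)
  led <- build_ledger(sim$log)
  expect_true(all(led$minutes[led$context != "neutral"] == 0))
  expect_true(all(led$minutes[led$context == "neutral"] > 0))
})

test_that("overlapping focal samples are rejected", {
  focals <- tibble::tibble(
    session_id = c("S1", "S1"), group_id = "A",
    focal_id = c("F3", "F5"),
    start = ts(c("2023-07-01 09:00:00", "2023-07-01 09:05:00")),
    duration_s = 600)
  expect_error(build_ledger(tiny_log(focals = focals)), "overlapping")
})
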