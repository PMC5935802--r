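test_that("a synthetic trial round-trips through its CSV exports", {
  g <- example_graph()
  sim <- simulate_trial(g, trial = 2, seed = 8, accel = FALSE)
  dir <- withr::local_tempdir()
  write_trial(sim, dir)
  back <- read_streams(dir)
  expect_equal(back$rssi$epoch, sim$rssi$epoch)
  expect_equal(back$rssi$beacon_id, sim$rssi$beacon_id)
  expect_equal(back$rssi$rssi, sim$rssi$rssi)
  expect_equal(back$steps$steps, sim$steps$steps)
  expect_equal(back$truth$area_id, sim$truth$area_id)
  expect_equal(back$config$seed, 8)
  # localization is identical on original and round-tripped streams
  f1 <- localize(g, sim$rssi, sim$steps)
  f2 <- localize(g, back$rssi, back$steps)
  expect_identical(f1$trace, f2$trace)
})

test_that("malformed and off-grid timestamps are reported with their line", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rssi.csv")
  writeLines(c("timestamp,receiver_id,beacon_id,rssi_dbm",
               "2020-01-01T00:00:00Z,r1,b1,-60",
               "not-a-time,r1,b1,-61"), p)
  expect_error(read_rssi(p), "line.* 3")
  writeLines(c("timestamp,receiver_id,beacon_id,rssi_dbm",
               "2020-01-01T00:00:00Z,r1,b1,-60",
               "2020-01-01T00:00:07Z,r1,b1,-61"), p)
  expect_error(read_rssi(p), "epoch grid")
  writeLines(c("timestamp,receiver_id,beacon_id,rssi"), p)
  expect_error(read_rssi(p), "rssi_dbm")
})

test_that("an empty stream file reads as an empty stream with a warning", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "steps.csv")
  writeLines("timestamp,receiver_id,steps", p)
  expect_warning(d <- read_steps(p), "empty")
  expect_equal(nrow(d), 0L)
})

test_that("mixed receivers partition cleanly and can be voted", {
  g <- two_room_graph()
  truth <- plan_walk(g, data.frame(area_id = c("R1", "R2"),
                                   dwell_s = c(120, 120)), 1.4)
  set.seed(31)
  streams <- lapply(c("w1", "w2", "w3"), function(r)
    synthesize_rssi(truth, g, receiver_id = r, noise_sd = 3,
                    glitch_prob = 0, dropout_prob = 0))
  rssi <- do.call(rbind, streams)
  fits <- lapply(split(rssi, rssi$receiver_id), function(d)
    localize(g, d, model = motion_model("model1")))
  v <- majority_vote(unname(fits))
  expect_equal(nrow(v), nrow(truth))
  acc <- mean(v$map_smooth == truth$area_id)
  expect_gt(acc, 0.9)
})

test_that("traces serialize with smoothed, raw and wide probability columns", {
  g <- two_room_graph()
  rssi <- data.frame(epoch = 0:5, beacon_id = "R1", rssi = -50)
  fit <- localize(g, rssi, model = motion_model("model1"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(fit, p, wide = TRUE)
  d <- utils::read.csv(p)
  expect_equal(d$map_area_smoothed, rep("R1", 6))
  expect_equal(d$prob_R1 + d$prob_R2, rep(1, 6), tolerance = 1e-12)
})

test_that("lasagna ordering rules match their sort oracles", {
  g <- chain3_graph()
  pred <- rep(c("A", "B", "C"), times = c(30, 6, 12))
  fit <- structure(list(
    trace = data.frame(epoch = seq_along(pred) - 1L, map_raw = pred,
                       map_smooth = pred, exception = ""),
    graph = g, model = motion_model("model1"), config = loc_config()),
    class = "localization")
  lev <- factor(rep(c("low", "middle", "high"), length.out = 48),
                levels = c("low", "middle", "high"), ordered = TRUE)
  act <- data.frame(epoch = 0:47, level = lev)
  M <- lasagna_matrix(fit, act, "absolute")
  expect_equal(rownames(M),
               names(sort(tapply(rep(10, 48), pred, sum),
                          decreasing = TRUE)))
  expect_equal(sum(M), 480)
  # relative ordering keys on the low-level fraction
  act2 <- data.frame(epoch = 0:47,
                     level = factor(c(rep("low", 30), rep("high", 18)),
                                    c("low", "middle", "high"),
                                    ordered = TRUE))
  M2 <- lasagna_matrix(fit, act2, "relative")
  frac <- sapply(rownames(M2), function(a)
    M2[a, "low"] / sum(M2[a, ]))
  expect_true(all(diff(frac) <= 1e-12))
  # route ordering follows first appearance
  M3 <- lasagna_matrix(fit, act, "route")
  expect_equal(rownames(M3), c("A", "B", "C"))
  expect_error(lasagna_matrix(fit, act, "sideways"))
})

test_that("plot functions render without error on real and empty input", {
  g <- example_graph()
  sim <- simulate_trial(g, trial = 3, seed = 14, accel = FALSE)
  fit <- localize(g, sim$rssi, sim$steps)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(fit, sim$truth))
  expect_no_error(plot(confusion(fit, sim$truth)))
  empty <- localize(g, data.frame(epoch = integer(),
                                  beacon_id = character(),
                                  rssi = numeric()))
  expect_no_error(plot(empty))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("the CLI subcommands compose on the packaged map", {
  skip_on_os("windows")
  cli <- system.file("cli", "roomtrack", package = "roomtrack")
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  # child Rscript processes must see the same library paths
  withr::local_envvar(
    R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(...) {
    res <- suppressWarnings(
      system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    expect_true(is.null(status) || status == 0,
                info = paste(res, collapse = "\n"))
  }
  map <- example_map()
  run("simulate", "--map", map, "--trial", "3", "--seed", "2",
      "--out-dir", dir)
  run("localize", "--map", map, "--model", "model3", "--w", "1.0",
      "--rssi", file.path(dir, "rssi.csv"),
      "--steps", file.path(dir, "steps.csv"),
      "--out", file.path(dir, "trace.csv"))
  run("classify-activity", "--accel", file.path(dir, "accel.csv"),
      "--out", file.path(dir, "activity.csv"))
  run("evaluate", "--map", map, "--trace", file.path(dir, "trace.csv"),
      "--truth", file.path(dir, "truth.csv"),
      "--out", file.path(dir, "report.json"))
  run("plot", "--map", map, "--trace", file.path(dir, "trace.csv"),
      "--truth", file.path(dir, "truth.csv"),
      "--out", file.path(dir, "plot.png"))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(rep$errors$e_nt >= 0 && rep$errors$e_nt <= 100)
  expect_true(file.size(file.path(dir, "plot.png")) > 0)
  act <- utils::read.csv(file.path(dir, "activity.csv"))
  expect_true(all(act$level %in% c("low", "middle", "high")))
})
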