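# forge a localization-shaped object so evaluation can be exercised on
# hand-built prediction sequences
forge_fit <- function(pred, g, epoch_s = 10) {
  structure(list(
    trace = data.frame(epoch = seq_along(pred) - 1L, map_raw = pred,
                       map_smooth = pred, exception = "",
                       stringsAsFactors = FALSE),
    posterior = NULL, graph = g, model = motion_model("model1"),
    config = loc_config(epoch_s = epoch_s)),
    class = "localization")
}
truth_df <- function(areas) data.frame(epoch = seq_along(areas) - 1L,
                                       area_id = areas)

test_that("transition masking enumerates the windowed epochs", {
  expect_equal(mark_transitions(truth_df(rep("A", 6))), rep(FALSE, 6))
  tr <- truth_df(c("A", "A", "A", "B", "B", "B"))
  # change first visible at epoch 3 (0-based) -> rows 3:5 (1-based) flagged
  expect_equal(which(mark_transitions(tr, 1)), 3:5)
  expect_equal(which(mark_transitions(tr, 0)), 4L)
  expect_equal(which(mark_transitions(tr, 2)), 2:6)
  # change at the boundary clips the window
  expect_equal(which(mark_transitions(truth_df(c("A", "B", "B")), 1)), 1:3)
})

test_that("the error decomposition reproduces the printed formulas", {
  g <- two_room_graph()
  # 100 s of transition time with 25 s misclassified -> e_t = 25%
  truth <- truth_df(c(rep("R1", 10), rep("R2", 10)))
  pred <- truth$area_id
  mask <- mark_transitions(truth, 1)   # epochs 9:11 (1-based 10:12)
  stopifnot(sum(mask) * 10 == 30)
  # corrupt 1 masked epoch and 1 unmasked epoch
  pred[which(mask)[1]] <- "R2"
  pred[3] <- "R2"
  er <- error_report(forge_fit(pred, g), truth)
  expect_equal(er$T_t, 30); expect_equal(er$T_nt, 170)
  expect_equal(er$e_hat_t, 10); expect_equal(er$e_hat_nt, 10)
  expect_equal(er$e_t, 100 * 10 / 30)
  expect_equal(er$e_nt, 100 * 10 / 170)
  expect_equal(er$e_bar_t, 100 * 10 / 200)
  expect_equal(er$e_total, 100 * 20 / 200)
})

test_that("a perfect prediction scores zero everywhere", {
  g <- two_room_graph()
  truth <- truth_df(c(rep("R1", 12), rep("R2", 12)))
  er <- error_report(forge_fit(truth$area_id, g), truth)
  expect_equal(er$e_t, 0); expect_equal(er$e_nt, 0)
  expect_equal(er$e_total, 0)
})

test_that("zero-duration denominators report as undefined, not zero", {
  g <- two_room_graph()
  truth <- truth_df(rep("R1", 8))        # no transitions at all
  er <- error_report(forge_fit(truth$area_id, g), truth)
  expect_true(is.na(er$e_t))
  expect_equal(er$e_nt, 0)
})

test_that("error quantities are invariant to area relabelling", {
  g <- chain3_graph()
  set.seed(21)
  truth <- truth_df(sample(c("A", "B", "C"), 40, replace = TRUE,
                           prob = c(.5, .3, .2)))
  pred <- truth$area_id
  pred[sample(40, 8)] <- sample(c("A", "B", "C"), 8, replace = TRUE)
  er1 <- error_report(forge_fit(pred, g), truth)
  relab <- c(A = "C", B = "A", C = "B")
  er2 <- error_report(forge_fit(unname(relab[pred]), g),
                      truth_df(unname(relab[truth$area_id])))
  for (f in c("e_t", "e_nt", "e_bar_t", "e_total"))
    expect_equal(er1[[f]], er2[[f]])
})

test_that("dwelling agreement is exact for a perfect trace", {
  g <- chain3_graph()
  truth <- truth_df(rep(c("A", "B", "C", "A", "B", "C"),
                        times = c(18, 12, 24, 9, 15, 21)))
  ag <- dwelling_agreement(forge_fit(truth$area_id, g), truth)
  expect_equal(ag$p1, 1); expect_equal(ag$p2, 0, tolerance = 1e-10)
  expect_equal(ag$icc, 1)
  expect_equal(ag$fit_all$R2, 1)
  expect_equal(ag$fit_all$RMSE, 0)
  expect_equal(ag$fit_all$SSE, 0)
})

test_that("a constant offset keeps the regression perfect but dents the ICC", {
  g <- chain3_graph()
  truth <- truth_df(rep(c("A", "B", "C", "A", "B"),
                        times = c(30, 18, 24, 12, 21)))
  fitp <- forge_fit(truth$area_id, g)
  ag0 <- dwelling_agreement(fitp, truth)
  # shorten every visit by exactly 2 epochs of mismatch at the visit start
  pred <- truth$area_id
  v <- rle(truth$area_id)
  starts <- cumsum(c(1, head(v$lengths, -1)))
  for (s in starts) pred[s:(s + 1)] <- setdiff(c("A", "B", "C"), pred[s])[1]
  ag <- dwelling_agreement(forge_fit(pred, g), truth)
  expect_equal(ag$p1, 1, tolerance = 1e-8)
  expect_equal(ag$p2, -20, tolerance = 1e-6)
  expect_equal(ag$fit_all$R2, 1, tolerance = 1e-8)  # against the fit line
  expect_lt(ag$icc, ag0$icc)                        # absolute agreement
})

test_that("the ICC matches an independent ANOVA computation", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(12, 50, 300)
    y <- x + rnorm(12, 5, 25)
    expect_equal(roomtrack:::icc_a1(y, x), oracle_icc_a1(y, x),
                 tolerance = 1e-10)
  }
  # small hand table
  x <- c(100, 120, 200, 240)
  y <- c(90, 130, 210, 220)
  expect_equal(roomtrack:::icc_a1(y, x), oracle_icc_a1(y, x),
               tolerance = 1e-12)
})

test_that("confusion matrices count time fractions by true area", {
  g <- chain3_graph()
  truth <- truth_df(rep(c("A", "B"), each = 20))
  pred <- truth$area_id
  pred[1:2] <- "B"        # 2 of 20 A-epochs wrong
  cm <- confusion(forge_fit(pred, g), truth, "all")
  expect_equal(cm["A", "A"], 0.9)
  expect_equal(cm["A", "B"], 0.1)
  expect_equal(cm["B", "B"], 1)
  expect_equal(unname(rowSums(cm)[c("A", "B")]), c(1, 1))
  # perfect prediction -> identity on occupied rows
  cmp <- confusion(forge_fit(truth$area_id, g), truth, "all")
  expect_equal(unname(diag(cmp)[1:2]), c(1, 1))
})

test_that("the nontransition variant equals recomputation on the unmasked subset", {
  g <- chain3_graph()
  set.seed(8)
  truth <- truth_df(rep(c("A", "B", "C", "B"), times = c(10, 8, 12, 10)))
  pred <- truth$area_id
  pred[sample(40, 10)] <- sample(c("A", "B", "C"), 10, replace = TRUE)
  cm <- confusion(forge_fit(pred, g), truth, "nontransition")
  keep <- !mark_transitions(truth, 1)
  sub <- table(factor(truth$area_id[keep], c("A", "B", "C")),
               factor(pred[keep], c("A", "B", "C")))
  sub <- sub / pmax(rowSums(sub), 1)
  expect_equal(unclass(cm), unclass(sub), ignore_attr = TRUE)
})

test_that("diagonal mean complements the time-weighted error rate", {
  g <- chain3_graph()
  set.seed(13)
  truth <- truth_df(rep(c("A", "B", "C"), times = c(15, 15, 15)))
  pred <- truth$area_id
  pred[sample(45, 9)] <- sample(c("A", "B", "C"), 9, replace = TRUE)
  cm <- confusion(forge_fit(pred, g), truth, "all")
  occupied <- c("A", "B", "C")
  acc_rows <- diag(cm[occupied, occupied])
  # each row's diagonal is that area's accuracy; time-weighted mean of
  # the rows equals overall accuracy
  w <- table(factor(truth$area_id, occupied)) / length(pred)
  expect_equal(sum(acc_rows * as.numeric(w)), mean(pred == truth$area_id))
})

test_that("longer transition lag never decreases e_t", {
  g <- chain3_graph()
  truth <- truth_df(rep(c("A", "B", "C", "B", "A"), each = 12))
  v <- rle(truth$area_id)
  starts <- cumsum(c(1, head(v$lengths, -1)))[-1]   # change points
  e_prev <- -Inf
  for (burst in 0:2) {
    # the prediction keeps reporting the old area for `burst` epochs
    # after each true change -- a growing transition-tracking lag
    pred <- truth$area_id
    if (burst > 0)
      for (s in starts)
        pred[s:min(s + burst - 1, length(pred))] <- truth$area_id[s - 1]
    er <- error_report(forge_fit(pred, g), truth, window = 2)
    expect_gte(er$e_t + 1e-12, e_prev)
    e_prev <- er$e_t
  }
})
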