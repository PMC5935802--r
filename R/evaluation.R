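#' Flag transition epochs in a ground-truth trace
#'
#' A transition period surrounds every change of the true area.  With the
#' 10-s proximity epoch being the natural atom, the default window flags
#' one epoch on either side of each change: for a change first visible at
#' epoch `k` (truth differs from epoch `k-1`), epochs `k-1 .. k+1` are
#' transition epochs.  Everything else is nontransition (dwelling) time.
#'
#' @param truth data frame with columns `epoch` and `area_id`, epochs
#'   contiguous.
#' @param window epochs flagged on either side of a change (default 1).
#' @return Logical vector along `truth`: `TRUE` for transition epochs.
#' @export
mark_transitions <- function(truth, window = 1L) {
  area <- as.character(truth$area_id)
  n <- length(area)
  mask <- logical(n)
  if (n < 2L) return(mask)
  changes <- which(area[-1] != area[-n]) + 1L
  for (k in changes) {
    lo <- max(1L, k - window)
    hi <- min(n, k + window)
    mask[lo:hi] <- TRUE
  }
  mask
}

align_truth <- function(fit, truth) {
  stopifnot(inherits(fit, "localization"))
  truth <- as.data.frame(truth)
  stopifnot(all(c("epoch", "area_id") %in% names(truth)))
  common <- intersect(fit$trace$epoch, truth$epoch)
  if (!length(common))
    stop("trace and truth share no epochs", call. = FALSE)
  list(pred = fit$trace$map_smooth[match(common, fit$trace$epoch)],
       true = as.character(truth$area_id[match(common, truth$epoch)]),
       epoch = common)
}

#' Transition / nontransition error decomposition
#'
#' Misclassified time is accumulated separately over transition and
#' nontransition epochs of a trial `l` and expressed relative to the
#' matching durations:
#' \deqn{e_{t,l} = 100 \hat e_{t,l} / T_{t,l}, \quad
#'       e_{nt,l} = 100 \hat e_{nt,l} / T_{nt,l},}
#' the transition-attributed share of the whole trial
#' \eqn{\bar e_{l} = 100 \hat e_{t,l} / T_l}, and the overall relative
#' error \eqn{e_l = 100 (\hat e_{t,l} + \hat e_{nt,l}) / T_l}, with
#' \eqn{T_l = T_{t,l} + T_{nt,l}}.  A zero-duration denominator yields
#' `NA` (undefined), never 0.
#'
#' @param fit a [localize()] result (the smoothed reported area is
#'   scored -- it is the algorithm's output).
#' @param truth data frame with columns `epoch`, `area_id`.
#' @param window transition window in epochs (default from the fit's
#'   config).
#' @return Object of class `error_report` with the durations (seconds)
#'   and relative errors (percent).
#' @export
error_report <- function(fit, truth, window = fit$config$transition_window) {
  al <- align_truth(fit, truth)
  es <- fit$config$epoch_s
  mask <- mark_transitions(data.frame(epoch = al$epoch, area_id = al$true),
                           window)
  mis <- al$pred != al$true
  T_t <- sum(mask) * es
  T_nt <- sum(!mask) * es
  e_hat_t <- sum(mis & mask) * es
  e_hat_nt <- sum(mis & !mask) * es
  T_l <- T_t + T_nt
  rel <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    T_t = T_t, T_nt = T_nt, T_total = T_l,
    e_hat_t = e_hat_t, e_hat_nt = e_hat_nt,
    e_t = rel(e_hat_t, T_t),
    e_nt = rel(e_hat_nt, T_nt),
    e_bar_t = rel(e_hat_t, T_l),     # transition-caused error over T_l
    e_total = rel(e_hat_t + e_hat_nt, T_l),
    window = window, epoch_s = es), class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 2, ...) {
  cat(sprintf("Trial of %.0f s: transition %.0f s, nontransition %.0f s\n",
              x$T_total, x$T_t, x$T_nt))
  fmt <- function(v) ifelse(is.na(v), "undefined",
                            formatC(v, digits = digits, format = "f"))
  cat("  e_t  (transition error)          :", fmt(x$e_t), "%\n")
  cat("  e_nt (nontransition error)       :", fmt(x$e_nt), "%\n")
  cat("  e_bar (transition share of trial):", fmt(x$e_bar_t), "%\n")
  cat("  e    (overall relative error)    :", fmt(x$e_total), "%\n")
  invisible(x)
}

#' Average an error decomposition over trials
#'
#' @param reports list of [error_report()] objects.
#' @return Named numeric vector of trial-averaged `e_t`, `e_nt`,
#'   `e_bar_t`, `e_total` (percent; `NA` components are dropped
#'   per quantity).
#' @export
average_errors <- function(reports) {
  stopifnot(all(vapply(reports, inherits, TRUE, "error_report")))
  pick <- function(f) mean(vapply(reports, `[[`, numeric(1), f),
                           na.rm = TRUE)
  c(e_t = pick("e_t"), e_nt = pick("e_nt"),
    e_bar_t = pick("e_bar_t"), e_total = pick("e_total"))
}

# ICC(A,1): single-rater, absolute-agreement, two-way mixed, from the
# two-way ANOVA mean squares (rows = subjects, columns = raters).
icc_a1 <- function(x, y) {
  dat <- cbind(x, y)
  n <- nrow(dat); k <- ncol(dat)
  if (n < 2) return(NA_real_)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k / n * (MSC - MSE)
  if (denom <= 0) return(NA_real_)
  (MSR - MSE) / denom
}

visits <- function(area, epoch_s) {
  r <- rle(as.character(area))
  ends <- cumsum(r$lengths)
  data.frame(area_id = r$values,
             start = c(1L, utils::head(ends, -1) + 1L),
             end = ends,
             dwell_s = r$lengths * epoch_s,
             stringsAsFactors = FALSE)
}

#' Dwelling-time agreement between predicted and criterion traces
#'
#' Dwelling times are paired per visit (continuous occupancy bout of the
#' criterion trace): for each true visit the predicted dwell is the time
#' the reported area matched during that visit's span.  The pairs feed a
#' linear regression `predicted = p1 * truth + p2` with 95% CIs, an
#' intraclass correlation ICC(A,1) (single rater, absolute agreement,
#' two-way mixed), and the regression's goodness of fit: `SSE` (sum of
#' squared residuals), `R^2`, adjusted `R^2`, and `RMSE` (the standard
#' error of the regression, `sqrt(SSE / (n - 2))`).  The regression
#' absorbs systematic offsets -- those are penalized by the ICC, which
#' demands absolute agreement.  Stats are also stratified at a dwelling
#' threshold (default 100 s, about 10 proximity samples): short visits
#' suffer quantization error, long ones are robust.
#'
#' @param fit a [localize()] result.
#' @param truth criterion trace (`epoch`, `area_id`).
#' @param threshold_s stratification threshold in seconds.
#' @return Object of class `dwelling_agreement`: visit table, regression
#'   coefficients `p1`, `p2` with CIs, `icc`, and per-stratum fit stats.
#' @export
dwelling_agreement <- function(fit, truth, threshold_s = 100) {
  al <- align_truth(fit, truth)
  es <- fit$config$epoch_s
  vis <- visits(al$true, es)
  if (nrow(vis) < 3)
    stop("need at least 3 visits to assess agreement", call. = FALSE)
  vis$pred_s <- vapply(seq_len(nrow(vis)), function(i) {
    idx <- vis$start[i]:vis$end[i]
    sum(al$pred[idx] == vis$area_id[i]) * es
  }, numeric(1))

  gof <- function(pred, obs) {
    n <- length(obs)
    if (n < 3 || stats::var(obs) == 0)
      return(list(n = n, SSE = NA_real_, R2 = NA_real_,
                  adj_R2 = NA_real_, RMSE = NA_real_))
    fit <- stats::lm(pred ~ obs)
    SSE <- sum(stats::residuals(fit)^2)
    sm <- suppressWarnings(summary(fit))   # quiet on a perfect fit
    list(n = n, SSE = SSE, R2 = sm$r.squared,
         adj_R2 = sm$adj.r.squared,
         RMSE = sqrt(SSE / (n - 2)))
  }

  lmfit <- stats::lm(pred_s ~ dwell_s, data = vis)
  ci <- tryCatch(suppressWarnings(stats::confint(lmfit)),
                 error = function(e) matrix(NA_real_, 2, 2))
  long <- vis$dwell_s > threshold_s
  structure(list(
    visits = vis,
    p1 = unname(stats::coef(lmfit)[2]), p1_ci = unname(ci[2, ]),
    p2 = unname(stats::coef(lmfit)[1]), p2_ci = unname(ci[1, ]),
    icc = icc_a1(vis$pred_s, vis$dwell_s),
    mean_diff = mean(vis$pred_s - vis$dwell_s),
    fit_all = gof(vis$pred_s, vis$dwell_s),
    fit_over = gof(vis$pred_s[long], vis$dwell_s[long]),
    fit_under = gof(vis$pred_s[!long], vis$dwell_s[!long]),
    threshold_s = threshold_s), class = "dwelling_agreement")
}

#' @export
print.dwelling_agreement <- function(x, ...) {
  cat(sprintf("Dwelling-time agreement over %d visits\n", nrow(x$visits)))
  cat(sprintf("  regression  p1 = %.4f (%.4f-%.4f), p2 = %.3f (%.3f-%.3f) s\n",
              x$p1, x$p1_ci[1], x$p1_ci[2], x$p2, x$p2_ci[1], x$p2_ci[2]))
  cat(sprintf("  ICC(A,1) = %.4f, mean difference = %.2f s\n",
              x$icc, x$mean_diff))
  f <- x$fit_all
  cat(sprintf("  all visits      (n=%3d): SSE=%.0f s^2  R2=%.4f  RMSE=%.2f s\n",
              f$n, f$SSE, f$R2, f$RMSE))
  f <- x$fit_over
  cat(sprintf("  dwell > %3.0f s  (n=%3d): SSE=%.0f s^2  R2=%.4f  RMSE=%.2f s\n",
              x$threshold_s, f$n, f$SSE, f$R2, f$RMSE))
  invisible(x)
}

#' Time-weighted confusion matrix of predicted vs true areas
#'
#' Rows are true areas, columns predicted; entries are fractions of the
#' row's occupancy time.  The `"nontransition"` variant drops transition
#' epochs first, isolating steady-state (dwelling) performance.
#'
#' @param fit a [localize()] result.
#' @param truth criterion trace.
#' @param variant `"all"` or `"nontransition"`.
#' @param window transition window (epochs) for the nontransition
#'   variant.
#' @return Matrix of class `confusion_matrix` (rows with zero truth time
#'   are all-zero); attribute `variant` records the subset used.
#' @export
confusion <- function(fit, truth, variant = c("all", "nontransition"),
                      window = fit$config$transition_window) {
  variant <- match.arg(variant)
  al <- align_truth(fit, truth)
  keep <- rep(TRUE, length(al$true))
  if (variant == "nontransition")
    keep <- !mark_transitions(
      data.frame(epoch = al$epoch, area_id = al$true), window)
  ids <- fit$graph$areas$area_id
  tab <- table(factor(al$true[keep], ids), factor(al$pred[keep], ids))
  m <- unclass(tab / pmax(rowSums(tab), 1L))
  m <- matrix(m, nrow = length(ids), dimnames = list(true = ids, predicted = ids))
  structure(m, class = c("confusion_matrix", "matrix"), variant = variant)
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("Confusion matrix (", attr(x, "variant"),
      " epochs), row-normalized by true-area time\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}
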