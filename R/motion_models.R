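#' A priori motion models
#'
#' Three heuristic rules turn the pathway adjacency matrix `A` into the
#' per-epoch transition-weight matrix `M` used by the predict step:
#'
#' * `model1` -- constant connection weights, `M = A`: moving to an
#'   adjacent area and staying are equally weighted.
#' * `model2` -- the diagonal (staying put) is modulated by the step count
#'   of the last epoch: `m[i,i] = 0.5` when more than `step_threshold`
#'   steps were taken, `m[i,i] = 2.0` otherwise; off-diagonal entries stay
#'   `a[i,j]`.
#' * `model3` -- as `model2` for rooms, social areas and stairs, but
#'   corridor diagonals get a constant weight `w`: step counts carry
#'   little information about leaving a corridor, whose traversal time is
#'   dominated by its length.  `w = 1` treats corridors neutrally;
#'   `w < 1` favours leaving, `w > 1` favours lingering.
#'
#' @param model one of `"model1"`, `"model2"`, `"model3"`.
#' @param w corridor self-transition weight (model 3 only); the study grid
#'   is 0.25 to 1.25 in steps of 0.25, default 1.0.
#' @param step_threshold step count above which an epoch counts as
#'   walking (default 2 steps per 10-s epoch).
#' @param low_weight,high_weight diagonal weights for walking /
#'   stationary epochs (defaults 0.5 and 2.0).
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(model = c("model3", "model1", "model2"),
                         w = 1.0, step_threshold = 2L,
                         low_weight = 0.5, high_weight = 2.0) {
  model <- match.arg(model)
  stopifnot(w > 0, low_weight > 0, high_weight > 0, step_threshold >= 0)
  structure(list(model = model, w = w,
                 step_threshold = as.integer(step_threshold),
                 low_weight = low_weight, high_weight = high_weight),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat("Motion model", sub("model", "", x$model))
  if (x$model == "model3") cat(" (corridor weight w =", x$w, ")")
  cat("\n")
  invisible(x)
}

#' Per-epoch transition-weight matrix
#'
#' @param model a [motion_model()].
#' @param A adjacency matrix from [adjacency()].
#' @param areas the `areas` data frame of the graph (needed by model 3 to
#'   identify corridor rows).
#' @param steps step count of the epoch (nonnegative integer); required
#'   for models 2 and 3.
#' @return Nonnegative `N x N` matrix `M` with zeros exactly where
#'   `A[i,j] == 0` off the diagonal.
#' @examples
#' A <- matrix(1, 2, 2)
#' transition_matrix(motion_model("model1"), A)
#' transition_matrix(motion_model("model2"), A, steps = 5)
#' @export
transition_matrix <- function(model, A, areas = NULL, steps = NULL) {
  stopifnot(inherits(model, "motion_model"), is.matrix(A),
            nrow(A) == ncol(A))
  if (model$model == "model1") return(A)

  if (is.null(steps) || is.na(steps))
    stop(model$model, " requires a step count for the epoch", call. = FALSE)
  if (steps < 0) stop("step count must be nonnegative", call. = FALSE)

  diag_w <- if (steps > model$step_threshold) model$low_weight
            else model$high_weight
  M <- A
  diag(M) <- diag_w
  if (model$model == "model3") {
    if (is.null(areas))
      stop("model3 requires the `areas` table to identify corridors",
           call. = FALSE)
    stopifnot(nrow(areas) == nrow(A))
    corridor <- areas$kind == "corridor"
    diag(M)[corridor] <- model$w
  }
  M
}
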