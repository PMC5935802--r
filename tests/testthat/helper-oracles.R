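# Shared fixtures and independent oracles.  Everything here is written
# from the definitions, deliberately not reusing package internals, so
# the tests compare two separately-coded routes.

# random connected area graph: spanning tree plus optional extra edges
random_graph <- function(N, seed, extra = 0L, kinds = NULL) {
  set.seed(seed)
  ids <- paste0("A", seq_len(N))
  if (is.null(kinds))
    kinds <- sample(c("room", "corridor", "social"), N, replace = TRUE)
  edges <- if (N > 1)
    data.frame(from = ids[vapply(2:N, function(i)
                 sample.int(i - 1L, 1L), 1L)],
               to = ids[2:N], stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character())
  for (e in seq_len(extra)) {
    pair <- sample(ids, 2)
    edges <- rbind(edges, data.frame(from = pair[1], to = pair[2]))
  }
  area_graph(
    areas = data.frame(area_id = ids, kind = kinds, floor = 1L),
    beacons = data.frame(beacon_id = ids, area_id = ids),
    edges = edges)
}

two_room_graph <- function() {
  area_graph(
    areas = data.frame(area_id = c("R1", "R2"), kind = "room", floor = 1L),
    beacons = data.frame(beacon_id = c("R1", "R2"),
                         area_id = c("R1", "R2")),
    edges = data.frame(from = "R1", to = "R2"))
}

chain3_graph <- function() {
  area_graph(
    areas = data.frame(area_id = c("A", "B", "C"), kind = "room",
                       floor = 1L),
    beacons = data.frame(beacon_id = c("A", "B", "C"),
                         area_id = c("A", "B", "C")),
    edges = data.frame(from = c("A", "B"), to = c("B", "C")))
}

# literal-transcription recursion: norm(norm(X * M) (.) Y), all loops
brute_filter <- function(Y, M_list) {
  N <- ncol(Y)
  X <- rep(1 / N, N)
  out <- matrix(NA_real_, nrow(Y), N)
  for (k in seq_len(nrow(Y))) {
    M <- M_list[[k]]
    xp <- numeric(N)
    for (j in seq_len(N))
      for (i in seq_len(N))
        xp[j] <- xp[j] + X[i] * M[i, j]
    xp <- xp / sum(xp)
    xn <- xp * Y[k, ]
    xn <- xn / sum(xn)
    out[k, ] <- xn
    X <- xn
  }
  out
}

# independent restatement of the motion-model rules
oracle_M <- function(model_id, A, kinds, steps, w = 1) {
  if (model_id == "model1") return(A)
  M <- A
  for (i in seq_len(nrow(A)))
    M[i, i] <- if (steps > 2) 0.5 else 2.0
  if (model_id == "model3")
    for (i in seq_len(nrow(A)))
      if (kinds[i] == "corridor") M[i, i] <- w
  M
}

# naive per-window centered moving SD, shrunken at the edges
oracle_moving_sd <- function(x, width = 5) {
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i)
    stats::sd(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

# ICC(A,1) through R's ANOVA machinery (separate route from the
# mean-squares arithmetic in the package)
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- anova(lm(score ~ subj + rater, data = d))[["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + MSE + 2 / n * (MSC - MSE))
}

# A -> B -> A with the excursion lasting exactly one epoch?
has_single_epoch_excursion <- function(v) {
  n <- length(v)
  if (n < 3) return(FALSE)
  any(v[2:(n - 1)] != v[1:(n - 2)] &
        v[2:(n - 1)] != v[3:n] &
        v[1:(n - 2)] == v[3:n])
}

# rssi stream in which every beacon is heard every epoch (no exceptions
# can fire); values stay inside the linear band of the proximity map
dense_rssi_stream <- function(N, T, seed) {
  set.seed(seed)
  data.frame(
    epoch = rep(seq_len(T) - 1L, each = N),
    beacon_id = rep(paste0("A", seq_len(N)), T),
    rssi = stats::runif(N * T, -85, -50),
    stringsAsFactors = FALSE)
}

example_graph <- function() read_beacon_map(example_map())
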