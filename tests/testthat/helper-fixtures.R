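# fixtures are built in code; no binary data ships with the package

tiny_runs <- function() {
  data.frame(
    run_id = c("C1", "C2", "T1", "T2"),
    bait_id = c("EMPTY", "EMPTY", "BAITX", "BAITX"),
    role = c("control", "control", "test", "test"),
    condition = c("cycling", "ciliated", "cycling", "cycling"),
    stringsAsFactors = FALSE)
}

tiny_experiment <- function() {
  sc_experiment(
    counts = data.frame(
      run_id = c("T1", "T1", "T2", "C1"),
      prey_id = c("P1", "P2", "P1", "P2"),
      count = c(5L, 2L, 7L, 1L),
      stringsAsFactors = FALSE),
    runs = tiny_runs())
}

# random small experiment for round-trip / property tests
random_experiment <- function(seed) {
  set.seed(seed)
  n_runs <- sample(3:6, 1)
  n_preys <- sample(3:8, 1)
  runs <- data.frame(
    run_id = sprintf("R%02d", seq_len(n_runs)),
    bait_id = c("EMPTY", sample(c("B1", "B2"), n_runs - 1, replace = TRUE)),
    role = c("control", rep("test", n_runs - 1)),
    condition = sample(c("cycling", "ciliated"), n_runs, replace = TRUE),
    stringsAsFactors = FALSE)
  preys <- sprintf("P%02d", seq_len(n_preys))
  grid <- expand.grid(run_id = runs$run_id, prey_id = preys,
                      stringsAsFactors = FALSE)
  grid$count <- rpois(nrow(grid), 3)
  grid <- grid[grid$count > 0 | runif(nrow(grid)) < 0.3, , drop = FALSE]
  if (!nrow(grid)) grid <- data.frame(run_id = runs$run_id[1],
                                      prey_id = preys[1], count = 1L)
  grid$count <- as.integer(grid$count)
  sc_experiment(grid, runs,
                data.frame(prey_id = preys, gene_symbol = tolower(preys),
                           sequence_length = sample(100:900, n_preys),
                           stringsAsFactors = FALSE))
}

# random scored table covering the dot-plot encoding domain
random_scored <- function(seed, n = 60) {
  set.seed(seed)
  baits <- sample(c("B1", "B2", "B3"), n, replace = TRUE)
  preys <- sprintf("P%02d", sample(1:20, n, replace = TRUE))
  df <- data.frame(bait_id = baits,
                   condition = sample(c("cycling", "ciliated"), n, TRUE),
                   prey_id = preys, stringsAsFactors = FALSE)
  df <- unique(df)
  n <- nrow(df)
  df$replicate_counts <- lapply(seq_len(n), function(i) rpois(2, 20))
  df$replicate_probs <- lapply(seq_len(n), function(i) runif(2))
  df$ctrl_counts <- lapply(seq_len(n), function(i) rpois(4, 2))
  df$avg_spec <- vapply(df$replicate_counts, mean, 0) *
    sample(c(0.1, 1, 4), n, TRUE)
  df$ctrl_avg <- vapply(df$ctrl_counts, mean, 0)
  df$avg_p <- vapply(df$replicate_probs, mean, 0)
  df$bfdr <- runif(n, 0, 0.2)
  df$detected <- df$avg_spec > 0
  df
}

# analytic ring membership used as the independent pixel oracle in tests
analytic_ring <- function(n, centre, radius, width) {
  xs <- matrix(seq_len(n), n, n) - centre[1]
  ys <- matrix(seq_len(n), n, n, byrow = TRUE) - centre[2]
  d <- sqrt(xs^2 + ys^2)
  d > radius & d <= radius + width
}
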