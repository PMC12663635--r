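scored_stub <- function(bfdr, bait = "B1") {
  data.frame(bait_id = bait, condition = "cycling",
             prey_id = sprintf("P%02d", seq_along(bfdr)),
             avg_spec = 10, ctrl_avg = 0, avg_p = 1 - bfdr, bfdr = bfdr,
             detected = TRUE, stringsAsFactors = FALSE)
}

test_that("the BFDR cutoff is inclusive and matches a one-line oracle", {
  s <- scored_stub(c(0.005, 0.01, 0.02))
  expect_equal(nrow(filter_bfdr(s, 0.01)), 2)       # boundary included
  expect_equal(filter_bfdr(s, 0)$prey_id, character(0))
  s0 <- scored_stub(c(0, 0.3, 0))
  expect_equal(nrow(filter_bfdr(s0, 0)), 2)
  set.seed(12)
  for (i in 1:200) {
    b <- round(runif(sample(1:20, 1), 0, 0.05), 3)
    thr <- sample(c(0, 0.01, 0.02, 0.05), 1)
    expect_identical(filter_bfdr(scored_stub(b), thr)$prey_id,
                     scored_stub(b)$prey_id[b <= thr])
  }
})

test_that("partner rescue re-admits only detected preys", {
  got <- rescue_by_partner(c("A", "B"), c("A", "B", "C", "D"), c("C", "X"))
  expect_setequal(as.character(got), c("A", "B", "C"))
  expect_equal(attr(got, "rescued"), "C")            # X never detected
  expect_equal(as.character(rescue_by_partner(c("A", "B"), c("A", "B", "C"),
                                              character())),
               c("A", "B"))                          # empty partner set
  full <- rescue_by_partner(c("A", "C"), c("A", "C"), c("C"))
  expect_equal(as.character(full), c("A", "C"))      # nothing to rescue
  expect_length(attr(full, "rescued"), 0)
  # gene symbols compare case-insensitively
  ci <- rescue_by_partner("A", c("A", "snapin"), "SNAPIN")
  expect_setequal(as.character(ci), c("A", "snapin"))
})

test_that("control-bait exclusion applies the 4x rule with the 0.25 floor", {
  ex <- function(bait, ctrl)
    length(attr(exclude_control_enriched("P", c(P = bait), c(P = ctrl)),
                "excluded")) == 1
  expect_true(ex(2, 8))         # 8 >= 4 * 2
  expect_false(ex(5, 10))       # 10 < 20
  expect_true(ex(0, 1))         # floor: 1 >= 4 * 0.25
  expect_false(ex(0, 0.9))      # just under the floored threshold
  # preys absent from the control-bait map count as zero there
  kept <- exclude_control_enriched(c("P", "Q"), c(P = 2, Q = 2), c(P = 8))
  expect_equal(as.character(kept), "Q")
})

test_that("the full selection removes sticky preys from the filtered bait only", {
  sim <- simulate_experiment(simulation_design(
    n_baits = 3, n_preys = 400, n_true_per_bait = 30, n_sticky = 15,
    seed = 17))
  sc <- score_experiment(sim$experiment)
  plan <- filter_plan(rescue = list(BAIT1 = c("BAIT2", "BAIT3")),
                      exclude = list(BAIT1 = "CTRLBAIT"))
  hc <- build_high_confidence(sc, plan)
  # sticky preys pass BFDR for unfiltered baits but are excluded from BAIT1
  expect_length(intersect(sim$sticky_preys, hc$kept$BAIT1), 0)
  expect_gt(length(intersect(sim$sticky_preys, hc$kept$BAIT2)), 0)
  # planted true interactors survive the manual filters
  b1_truth <- sim$truth$prey_id[sim$truth$bait_id == "BAIT1"]
  expect_gt(mean(b1_truth %in% hc$kept$BAIT1), 0.9)

  # accounting identity on the decision trail
  s <- hc$report$summary
  tr <- hc$report$trail
  for (b in s$bait_id) {
    tb <- tr[tr$bait_id == b, ]
    expect_equal(s$final_n[s$bait_id == b], sum(tb$decision == "keep"))
    expect_equal(sum(tb$decision == "keep"),
                 sum((tb$pass_bfdr | tb$rescued) & !tb$excluded))
    expect_equal(nrow(tb), s$input_n[s$bait_id == b])
  }
  # every detected prey has exactly one terminal decision
  expect_true(all(tr$decision %in% c("keep", "drop")))
  expect_false(anyDuplicated(tr[, c("bait_id", "prey_id")]) > 0)
})

test_that("a plan with no manual filters reduces to the BFDR cutoff", {
  sim <- simulate_experiment(simulation_design(
    n_baits = 2, n_preys = 150, n_true_per_bait = 15, seed = 19))
  sc <- score_experiment(sim$experiment)
  hc <- build_high_confidence(sc, filter_plan())
  for (b in names(hc$kept)) {
    manual <- filter_bfdr(sc[sc$bait_id == b & sc$detected, ], 0.01)
    expect_setequal(hc$kept[[b]], unique(manual$prey_id))
  }
  expect_error(build_high_confidence(sc, filter_plan(
    exclude = list(BAIT1 = "NOSUCH"))), "unknown bait")
})

test_that("the selection is idempotent and its order is rescue then exclude", {
  sim <- simulate_experiment(simulation_design(
    n_baits = 2, n_preys = 200, n_true_per_bait = 20, n_sticky = 10,
    seed = 23))
  sc <- score_experiment(sim$experiment)
  plan <- filter_plan(rescue = list(BAIT1 = "BAIT2"),
                      exclude = list(BAIT1 = "CTRLBAIT"))
  hc1 <- build_high_confidence(sc, plan)
  # rerun on a scored table restricted to the kept pairs: nothing changes
  keep_rows <- sc$bait_id %in% c("CTRLBAIT", "BAIT2") |
    (sc$bait_id == "BAIT1" & sc$prey_id %in% hc1$kept$BAIT1)
  hc2 <- build_high_confidence(sc[keep_rows, ], plan)
  expect_setequal(hc2$kept$BAIT1, hc1$kept$BAIT1)

  # adversarial fixture: a sticky prey that the partner also calls at high
  # confidence is rescued first and must still be excluded afterwards
  sticky_in_partner <- intersect(sim$sticky_preys,
                                 unique(filter_bfdr(
                                   sc[sc$bait_id == "BAIT2", ])$prey_id))
  expect_gt(length(sticky_in_partner), 0)
  expect_length(intersect(sticky_in_partner, hc1$kept$BAIT1), 0)
})

test_that("filter reports export to CSV and JSON", {
  sim <- simulate_experiment(simulation_design(
    n_baits = 1, n_preys = 50, n_true_per_bait = 5, seed = 29))
  hc <- build_high_confidence(score_experiment(sim$experiment))
  prefix <- file.path(withr::local_tempdir(), "report")
  write_filter_report(hc$report, prefix)
  expect_true(file.exists(paste0(prefix, "_summary.csv")))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$summary[[1]]$final_n, hc$report$summary$final_n[1])
})
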