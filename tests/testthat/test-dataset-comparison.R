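test_that("overlap summaries are exact set arithmetic", {
  ov <- overlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ov$intersection_n, 2)
  expect_equal(ov$jaccard_similarity, 0.5)
  expect_equal(ov$jaccard_distance, 0.5)
  expect_equal(ov$pct_a_in_b, 67)
  same <- overlap(c("a", "b"), c("A", "B"))     # case-insensitive symbols
  expect_equal(same$jaccard_distance, 0)
  expect_error(overlap(character(), "A"), "empty")
})

test_that("overlap matches a brute-force double loop on random sets", {
  set.seed(55)
  universe <- sprintf("G%02d", 1:30)
  for (i in 1:200) {
    a <- sample(universe, sample(1:20, 1))
    b <- sample(universe, sample(1:20, 1))
    ov <- overlap(a, b)
    inter <- 0
    for (g in a) for (h in b) if (g == h) inter <- inter + 1
    expect_equal(ov$intersection_n, inter)
    expect_equal(ov$union_n, length(a) + length(b) - inter)
    expect_equal(ov$jaccard_distance,
                 1 - inter / (length(a) + length(b) - inter))
    expect_equal(ov$intersection_n + length(ov$a_only), ov$set_a_n)
    expect_equal(ov$intersection_n + length(ov$b_only), ov$set_b_n)
  }
})

test_that("multi-database tiers cross-tabulate against bait exclusivity", {
  dbs <- list(reference_gene_set("d1", c("G1", "G2", "G3")),
              reference_gene_set("d2", c("G1", "G2", "G4")),
              reference_gene_set("d3", c("G1", "G5")))
  mm <- multi_db_membership(list(a = c("G1", "G2", "G9"),
                                 b = c("G1", "G4")), dbs)
  pp <- mm$per_prey
  expect_equal(pp$n_dbs[pp$gene == "G1"], 3L)
  expect_equal(pp$n_dbs[pp$gene == "G2"], 2L)
  expect_equal(pp$n_dbs[pp$gene == "G9"], 0L)
  expect_equal(mm$tier_table["at_least_two", "both"], 1L)   # G1
  expect_equal(mm$tier_table["at_least_two", "a_only"], 1L) # G2
  expect_equal(mm$tier_table["all_dbs", "both"], 1L)        # G1 only
  expect_error(multi_db_membership(list(a = "G1", b = "G2"), dbs[1]),
               "two databases")

  # brute-force enumeration oracle on random fixtures
  set.seed(77)
  universe <- sprintf("H%02d", 1:15)
  for (i in 1:50) {
    a <- sample(universe, sample(2:10, 1))
    b <- sample(universe, sample(2:10, 1))
    dbs <- lapply(1:3, function(j)
      reference_gene_set(paste0("db", j), sample(universe, sample(2:10, 1))))
    mm <- multi_db_membership(list(a = a, b = b), dbs)
    for (g in union(a, b)) {
      hits <- sum(vapply(dbs, function(d) g %in% d$genes, TRUE))
      expect_equal(mm$per_prey$n_dbs[mm$per_prey$gene == g], hits)
    }
    sel <- mm$per_prey$n_dbs >= 2
    expect_equal(sum(mm$tier_table["at_least_two", ]), sum(sel))
  }
})

test_that("over-representation matches brute-force hypergeometric mass", {
  set.seed(66)
  universe <- sprintf("U%03d", 1:200)
  for (i in 1:60) {
    N <- 200
    ref <- reference_gene_set("ref", sample(universe, sample(5:50, 1)))
    q <- sample(universe, sample(5:40, 1))
    res <- overrepresentation(q, ref, N)
    m <- length(ref$genes); k <- length(q)
    brute <- sum(dhyper(res$overlap_n:min(m, k), m, N - m, k))
    expect_equal(res$p_value, brute, tolerance = 1e-12)
  }
  # landmarks
  ref <- reference_gene_set("r", sprintf("U%03d", 1:20))
  self <- overrepresentation(sprintf("U%03d", 1:20), ref, 1000)
  expect_lt(self$p_value, 1e-20)
  disj <- overrepresentation(sprintf("U%03d", 21:40), ref, 1000)
  expect_equal(disj$p_value, 1)
  expect_error(overrepresentation(sprintf("U%03d", 1:40), ref, 30),
               "universe")
  tab <- overrepresentation_table(sprintf("U%03d", 1:20),
                                  list(ref, reference_gene_set("r2", "ZZZ")),
                                  1000)
  expect_equal(tab$p_adj, p.adjust(tab$p_value, "BH"))
})

test_that("dot-plot encoding is total and respects cap and border bins", {
  for (seed in 1:5) {
    s <- random_scored(seed)
    s$bfdr[1] <- 0.01; s$bfdr[2] <- 0.05; s$bfdr[3] <- 0.2   # bin boundaries
    s$avg_spec[4] <- 75; s$ctrl_avg[4] <- 0                  # cap case
    dp <- dotplot_export(s)
    expect_equal(nrow(dp), nrow(s))                           # total function
    expect_true(all(dp$color_value >= 0 & dp$color_value <= 50))
    expect_true(all(dp$size_value >= 0 & dp$size_value <= 1 + 1e-12))
    expect_equal(dp$color_value[4], 50)
    expect_equal(dp$border_class[1:3], c("black", "blue", "light_blue"))
    expect_identical(dp$border_class,
                     ifelse(s$bfdr <= 0.01, "black",
                            ifelse(s$bfdr <= 0.05, "blue", "light_blue")))
    # a prey seen with a single bait dataset is its own maximum
    lone <- names(which(table(s$prey_id) == 1))
    if (length(lone)) {
      i <- which(s$prey_id == lone[1])
      expect_equal(dp$size_value[i], if (s$avg_spec[i] > 0) 1 else 0)
    }
  }
})

test_that("gene lists load from one-symbol-per-line files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "Snapin", "BLOC1S2", "", "snapin"), path)
  gs <- read_gene_set(path, "markers")
  expect_setequal(gs$genes, c("SNAPIN", "BLOC1S2"))
  bundled <- read_gene_set(system.file("extdata",
                                       "synthetic_lysosomal_db1.txt",
                                       package = "bioidpipe"))
  expect_gt(length(bundled$genes), 5)
})

test_that("both shared-interactome constructions are available", {
  a <- list(c("G1", "G2", "G3"), c("G2", "G3", "G4"))
  b <- list(c("G2", "G5"), c("G2", "G3"))
  expect_setequal(shared_preys(a, b, require_all_conditions = FALSE),
                  c("G2", "G3"))
  expect_setequal(shared_preys(a, b, require_all_conditions = TRUE), "G2")
})
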