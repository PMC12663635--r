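#' Fold change between ciliated and cycling spectral counts
#'
#' Ratio of replicate-mean spectral counts with a symmetric pseudocount so
#' the ratio stays finite for preys absent from one condition:
#' `FC = (mean(ciliated) + pseudocount) / (mean(cycling) + pseudocount)`.
#'
#' @param ciliated_counts,cycling_counts Numeric replicate count vectors
#'   (each length >= 1).
#' @param pseudocount Added to both means, default 0.5.
#' @export
fold_change <- function(ciliated_counts, cycling_counts, pseudocount = 0.5) {
  stopifnot(length(ciliated_counts) >= 1, length(cycling_counts) >= 1)
  (mean(ciliated_counts) + pseudocount) /
    (mean(cycling_counts) + pseudocount)
}

#' Two-sample test for a condition effect on one prey
#'
#' Welch's two-sided t test on `log2(count + 1)`. With fewer than two
#' replicates in either condition no test is possible and `p = 1` is
#' returned by contract. When both sides are constant, `p` is 1 for equal
#' means and 0 otherwise (the data admit no within-group variance estimate).
#'
#' @param ciliated_counts,cycling_counts Numeric replicate count vectors.
#' @return A p-value in `[0, 1]`.
#' @export
enrichment_test <- function(ciliated_counts, cycling_counts) {
  if (length(ciliated_counts) < 2 || length(cycling_counts) < 2) return(1)
  a <- log2(ciliated_counts + 1)
  b <- log2(cycling_counts + 1)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Classify condition-effect results for a volcano plot
#'
#' Adds the volcano class per the study's thresholds: `increased` iff
#' `FC >= fc_threshold` and `p < alpha`; `decreased` iff
#' `FC <= 1/fc_threshold` and `p < alpha`; otherwise `unchanged`. Also adds
#' the volcano coordinates (`log2_fc`, `neg_log10_p`) and a
#' Benjamini-Hochberg adjusted p-value column for users who want one (the
#' classification itself uses the raw p, as on the study's volcano plots).
#'
#' @param results data.frame with columns `fold_change` and `p_value`.
#' @param fc_threshold Fold-change cutoff, default 2.
#' @param alpha Significance cutoff, default 0.05.
#' @export
classify_enrichment <- function(results, fc_threshold = 2, alpha = 0.05) {
  stopifnot(all(c("fold_change", "p_value") %in% names(results)))
  fc <- results$fold_change; p <- results$p_value
  cls <- rep("unchanged", nrow(results))
  cls[fc >= fc_threshold & p < alpha] <- "increased"
  cls[fc <= 1 / fc_threshold & p < alpha] <- "decreased"
  results$class <- cls
  results$log2_fc <- log2(fc)
  results$neg_log10_p <- -log10(pmax(p, .Machine$double.xmin))
  results$p_adj <- stats::p.adjust(p, method = "BH")
  results
}

#' Ciliated-versus-cycling differential enrichment for one bait
#'
#' For every prey, compares the bait's ciliated replicate counts against its
#' cycling replicate counts ([fold_change()], [enrichment_test()]) and
#' classifies the result ([classify_enrichment()]).
#'
#' @param experiment An [sc_experiment()].
#' @param bait Bait id; must have test runs in both conditions.
#' @param pseudocount Passed to [fold_change()].
#' @param fc_threshold,alpha Passed to [classify_enrichment()].
#' @return Volcano-ready data.frame: `bait_id`, `prey_id`, `avg_ciliated`,
#'   `avg_cycling`, `fold_change`, `p_value`, `class`, `log2_fc`,
#'   `neg_log10_p`, `p_adj`.
#' @export
differential_enrichment <- function(experiment, bait, pseudocount = 0.5,
                                    fc_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(experiment, "sc_experiment"))
  runs <- experiment$runs
  cil <- runs$run_id[runs$bait_id == bait & runs$role == "test" &
                     runs$condition == "ciliated"]
  cyc <- runs$run_id[runs$bait_id == bait & runs$role == "test" &
                     runs$condition == "cycling"]
  if (!length(cil) || !length(cyc))
    stop(sprintf("bait %s lacks runs in one of the conditions", bait),
         call. = FALSE)
  mc <- count_matrix(experiment, cil)
  my <- count_matrix(experiment, cyc)
  res <- data.frame(
    bait_id = bait, prey_id = rownames(mc),
    avg_ciliated = rowMeans(mc), avg_cycling = rowMeans(my),
    stringsAsFactors = FALSE)
  res$fold_change <- (res$avg_ciliated + pseudocount) /
    (res$avg_cycling + pseudocount)
  res$p_value <- vapply(seq_len(nrow(mc)),
                        function(i) enrichment_test(mc[i, ], my[i, ]), 0)
  rownames(res) <- NULL
  classify_enrichment(res, fc_threshold, alpha)
}
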