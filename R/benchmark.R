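#' Recompute the published interactome summary counts
#'
#' Applies the pipeline's high-confidence selection to externally supplied
#' scored tables and returns the study-level summary counts: the PC1-bait
#' interactome size after BFDR cutoff, partner rescue and control-bait
#' exclusion; the FB-PC2 interactome size; the FB-PC2 preys also present in
#' PC2-BF; the PC1 preys present in either PC2 dataset; and the two shared-
#' interactome constructions of [shared_preys()].
#'
#' The scored tables are not bundled with the package: they come from the
#' study's supplementary material and must be converted to the
#' [read_scored_table()] layout, one file per bait dataset, in `dir`:
#' `PC1BF.tsv`, `PC1BF_cil.tsv`, `PC2BF.tsv`, `PC2BF_cil.tsv`,
#' `FBPC2.tsv`, `FBPC2_cil.tsv` and `CD16.tsv` (the CD16.7 control bait).
#'
#' @param dir Directory holding the scored tables.
#' @param bfdr_threshold High-confidence BFDR cutoff, default 0.01.
#' @param ratio Control-bait exclusion ratio, default 4.
#' @return Named integer vector: `pc1_n`, `fb_pc2_n`, `fb_pc2_in_pc2bf_n`,
#'   `pc1_in_pc2_n`, `shared_any_n`, `shared_all_n`.
#' @export
published_benchmark <- function(dir, bfdr_threshold = 0.01, ratio = 4) {
  files <- c(PC1BF = "PC1BF.tsv", PC1BF_cil = "PC1BF_cil.tsv",
             PC2BF = "PC2BF.tsv", PC2BF_cil = "PC2BF_cil.tsv",
             FBPC2 = "FBPC2.tsv", FBPC2_cil = "FBPC2_cil.tsv",
             CD16 = "CD16.tsv")
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop("missing scored table(s) in ", dir, ": ",
         paste(missing, collapse = ", "),
         " (supply the study's supplementary SAINT outputs in the",
         " read_scored_table() layout)", call. = FALSE)
  tabs <- lapply(stats::setNames(paths, names(files)), read_scored_table)
  scored <- do.call(rbind, tabs)

  hc <- function(nm) unique(filter_bfdr(tabs[[nm]], bfdr_threshold)$prey_id)
  pc2_union <- Reduce(union, lapply(c("PC2BF", "PC2BF_cil",
                                      "FBPC2", "FBPC2_cil"), hc))
  pc1_detected <- unique(unlist(lapply(c("PC1BF", "PC1BF_cil"), function(nm)
    tabs[[nm]]$prey_id[vapply(tabs[[nm]]$replicate_counts,
                              function(v) any(v > 0), TRUE)])))
  pc1_pass <- union(hc("PC1BF"), hc("PC1BF_cil"))
  pc1 <- rescue_by_partner(pc1_pass, pc1_detected, pc2_union)
  pc1 <- exclude_control_enriched(
    as.character(pc1),
    bait_avg = tapply(scored$avg_spec[scored$bait_id %in%
                                        c("PC1BF", "PC1BF_cil")],
                      scored$prey_id[scored$bait_id %in%
                                       c("PC1BF", "PC1BF_cil")], mean),
    control_bait_avg = tapply(tabs$CD16$avg_spec, tabs$CD16$prey_id, mean),
    ratio = ratio)
  pc1 <- as.character(pc1)

  fb <- union(hc("FBPC2"), hc("FBPC2_cil"))
  pc2bf <- union(hc("PC2BF"), hc("PC2BF_cil"))
  pc1_sets <- list(pc1)
  pc2_sets <- list(pc2bf, fb)
  c(pc1_n = length(pc1),
    fb_pc2_n = length(fb),
    fb_pc2_in_pc2bf_n = length(intersect(fb, pc2bf)),
    pc1_in_pc2_n = length(intersect(toupper(pc1), union(pc2bf, fb))),
    shared_any_n = length(shared_preys(pc1_sets, pc2_sets, FALSE)),
    shared_all_n = length(shared_preys(
      list(hc("PC1BF"), hc("PC1BF_cil")),
      list(hc("PC2BF"), hc("PC2BF_cil"), hc("FBPC2"), hc("FBPC2_cil")),
      TRUE)))
}
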