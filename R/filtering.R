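#' Keep scored interactions at or below a BFDR threshold
#'
#' The high-confidence cutoff is inclusive: `bfdr <= threshold` (a BFDR of
#' exactly 1\% passes at the default threshold).
#'
#' @param scored A scored table from [score_experiment()].
#' @param threshold BFDR cutoff, default 0.01.
#' @return The subset of `scored` rows passing the cutoff.
#' @export
filter_bfdr <- function(scored, threshold = 0.01) {
  stopifnot(!is.null(scored$bfdr))
  scored[scored$bfdr <= threshold, , drop = FALSE]
}

norm_sym <- function(x) toupper(as.character(x))

#' Rescue sub-threshold preys present in a partner dataset
#'
#' Preys detected with the bait (spectral count > 0 in at least one
#' replicate) that fall below the confidence threshold are re-admitted if
#' they belong to the partner bait's high-confidence set. Preys never
#' detected with the bait cannot be rescued. Symbols are compared
#' case-insensitively; the returned ids keep their original case.
#'
#' @param candidate_preys Character vector: the bait's preys passing the
#'   BFDR filter.
#' @param detected_preys Character vector: all preys detected with the bait.
#' @param partner_preys Character vector: the partner dataset's
#'   high-confidence preys (itself BFDR-filtered).
#' @return Character vector `candidate ∪ (detected ∩ partner)`, with
#'   attribute `rescued` naming the re-admitted preys.
#' @export
rescue_by_partner <- function(candidate_preys, detected_preys,
                              partner_preys) {
  rescued <- detected_preys[norm_sym(detected_preys) %in%
                              norm_sym(partner_preys) &
                            !(norm_sym(detected_preys) %in%
                                norm_sym(candidate_preys))]
  out <- c(candidate_preys, rescued)
  attr(out, "rescued") <- rescued
  out
}

#' Drop preys over-represented in a negative-control bait
#'
#' A prey is excluded when its mean spectral count with the control bait is
#' at least `ratio` times its mean count with the bait of interest. The bait
#' average is floored at `floor` (one count spread over four virtual slots)
#' so the ratio is defined when the bait average is zero.
#'
#' @param candidate_preys Character vector of prey ids under consideration.
#' @param bait_avg Named numeric: mean spectral count per prey with the bait.
#' @param control_bait_avg Named numeric: mean spectral count per prey with
#'   the negative-control bait. Preys absent from either map count as 0.
#' @param ratio Exclusion ratio, default 4.
#' @param floor Floor on the bait average, default 0.25.
#' @return The preys kept, with attribute `excluded` naming the dropped ones.
#' @export
exclude_control_enriched <- function(candidate_preys, bait_avg,
                                     control_bait_avg, ratio = 4,
                                     floor = 0.25) {
  get0num <- function(map, keys) {
    v <- map[keys]
    v[is.na(v)] <- 0
    unname(v)
  }
  ba <- pmax(get0num(bait_avg, candidate_preys), floor)
  ca <- get0num(control_bait_avg, candidate_preys)
  drop <- ca >= ratio * ba
  out <- candidate_preys[!drop]
  attr(out, "excluded") <- candidate_preys[drop]
  out
}

#' Filtering plan for [build_high_confidence()]
#'
#' Names, per bait, which manual filters to apply on top of the BFDR cutoff.
#' Baits not mentioned receive the BFDR filter only.
#'
#' @param bfdr_threshold BFDR cutoff applied to every bait.
#' @param rescue Named list: for each bait to be rescued, the character
#'   vector of partner bait ids whose pooled high-confidence preys can
#'   re-admit sub-threshold detections.
#' @param exclude Named list: for each bait, the id of the negative-control
#'   bait used for the enrichment exclusion.
#' @param ratio,floor Passed to [exclude_control_enriched()].
#' @export
filter_plan <- function(bfdr_threshold = 0.01, rescue = list(),
                        exclude = list(), ratio = 4, floor = 0.25) {
  structure(list(bfdr_threshold = bfdr_threshold, rescue = rescue,
                 exclude = exclude, ratio = ratio, floor = floor),
            class = "filter_plan")
}

bait_mean_spec <- function(scored, bait) {
  # overall mean spectral count per prey across the bait's datasets
  s <- scored[scored$bait_id == bait, , drop = FALSE]
  tapply(s$avg_spec, s$prey_id, mean)
}

#' Build per-bait high-confidence interactomes
#'
#' Applies the selection used for the study's datasets, in fixed order:
#' (1) BFDR cutoff for every bait; (2) partner-dataset rescue for baits the
#' plan designates; (3) control-bait enrichment exclusion last, so that
#' control-sticky preys cannot re-enter via rescue. Conditions of one bait
#' are pooled by union after the BFDR cutoff.
#'
#' @param scored A scored table covering all baits ([score_experiment()]).
#' @param plan A [filter_plan()].
#' @return List with `kept` (named list of prey-id vectors per bait) and
#'   `report` (a `filter_report`: per-bait tallies plus a per-prey decision
#'   trail in which every detected prey has exactly one terminal decision).
#' @export
build_high_confidence <- function(scored, plan = filter_plan()) {
  stopifnot(inherits(plan, "filter_plan"))
  baits <- unique(scored$bait_id)
  unknown <- setdiff(c(names(plan$rescue), unlist(plan$rescue),
                       names(plan$exclude), unlist(plan$exclude)), baits)
  if (length(unknown))
    stop("plan references unknown bait(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  pass <- lapply(baits, function(b) {
    s <- filter_bfdr(scored[scored$bait_id == b, , drop = FALSE],
                     plan$bfdr_threshold)
    unique(s$prey_id)
  })
  names(pass) <- baits
  detected <- lapply(baits, function(b) {
    s <- scored[scored$bait_id == b, , drop = FALSE]
    unique(s$prey_id[s$detected])
  })
  names(detected) <- baits

  kept <- list(); trail <- NULL; summary <- NULL
  for (b in baits) {
    cand <- intersect(pass[[b]], detected[[b]])
    res <- character()
    if (!is.null(plan$rescue[[b]])) {
      partner <- unique(unlist(pass[plan$rescue[[b]]]))
      cand <- rescue_by_partner(cand, detected[[b]], partner)
      res <- attr(cand, "rescued")
      cand <- as.character(cand)
    }
    exc <- character()
    if (!is.null(plan$exclude[[b]])) {
      cb <- plan$exclude[[b]]
      cand <- exclude_control_enriched(cand, bait_mean_spec(scored, b),
                                       bait_mean_spec(scored, cb),
                                       plan$ratio, plan$floor)
      exc <- attr(cand, "excluded")
      cand <- as.character(cand)
    }
    kept[[b]] <- sort(cand)
    all_preys <- detected[[b]]
    tr <- data.frame(
      bait_id = b, prey_id = all_preys,
      pass_bfdr = all_preys %in% pass[[b]],
      rescued = all_preys %in% res,
      excluded = all_preys %in% exc,
      stringsAsFactors = FALSE)
    tr$decision <- ifelse(all_preys %in% kept[[b]], "keep", "drop")
    tr$rule_trail <- paste0(
      "bfdr:", ifelse(tr$pass_bfdr, "pass", "fail"),
      ";rescue:", ifelse(tr$rescued, "rescued", "-"),
      ";exclude:", ifelse(tr$excluded, "dropped", "-"))
    trail <- rbind(trail, tr)
    summary <- rbind(summary, data.frame(
      bait_id = b, input_n = length(all_preys),
      pass_bfdr = sum(tr$pass_bfdr), rescued_by_partner = length(res),
      excluded_by_control = length(exc), final_n = length(kept[[b]]),
      stringsAsFactors = FALSE))
  }
  report <- structure(list(summary = summary, trail = trail),
                      class = "filter_report")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("high-confidence filter report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a filter report
#'
#' Writes the per-bait summary and per-prey decision trail as CSV, and the
#' whole report as JSON.
#'
#' @param report A `filter_report` from [build_high_confidence()].
#' @param prefix Path prefix; writes `<prefix>_summary.csv`,
#'   `<prefix>_trail.csv` and `<prefix>.json`.
#' @export
write_filter_report <- function(report, prefix) {
  stopifnot(inherits(report, "filter_report"))
  utils::write.csv(report$summary, paste0(prefix, "_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$trail, paste0(prefix, "_trail.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary, trail = report$trail),
                       paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
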