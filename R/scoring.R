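#' Parameters of the two-component spectral-count mixture
#'
#' The scorer compares each replicate's spectral count against two Poisson
#' (optionally negative-binomial) components with equal prior odds: a
#' background component whose mean is the average of the compressed virtual
#' controls, floored at `eps` so the model is defined for preys never seen in
#' controls, and a true-interaction component whose mean is the larger of the
#' test-count mean across replicates and `min_fold` times the background
#' mean, so the alternative is always strictly elevated.
#'
#' This is a documented SAINT-style model, not a re-derivation of the
#' SAINTexpress likelihood; its contract is the thresholding behaviour
#' (control-like preys fail, strongly enriched preys pass at BFDR <= 0.01).
#'
#' @param eps Floor on the background mean, counts.
#' @param min_fold Minimum fold elevation of the true component over the
#'   background component.
#' @param model_dispersion Negative-binomial size of both components;
#'   `Inf` (default) gives Poisson likelihoods.
#' @export
saint_params <- function(eps = 0.1, min_fold = 2, model_dispersion = Inf) {
  stopifnot(eps > 0, min_fold > 1, model_dispersion > 0)
  structure(list(eps = eps, min_fold = min_fold,
                 model_dispersion = model_dispersion),
            class = "saint_params")
}

dcount <- function(x, mu, size) {
  if (is.infinite(size)) stats::dpois(x, mu)
  else stats::dnbinom(x, mu = mu, size = size)
}

#' Compress negative-control runs into virtual controls
#'
#' For every prey the `k` largest spectral counts across the negative-control
#' runs are retained, in descending order, zero-padded when fewer than `k`
#' control runs exist. Compressing many controls to their top counts makes
#' the background estimate deliberately conservative (stringent).
#'
#' @param experiment An [sc_experiment()] with at least one control run.
#' @param k Number of virtual controls (the study used 4).
#' @param condition Optionally restrict to controls of one condition
#'   (`"cycling"` or `"ciliated"`); default pools all controls.
#' @return Integer matrix, preys x k, with attribute `k`.
#' @export
compress_controls <- function(experiment, k = 4, condition = NULL) {
  stopifnot(inherits(experiment, "sc_experiment"), k >= 1)
  runs <- experiment$runs
  sel <- runs$role == "control"
  if (!is.null(condition)) sel <- sel & runs$condition == condition
  ids <- runs$run_id[sel]
  if (!length(ids)) stop("no control runs", call. = FALSE)
  m <- count_matrix(experiment, ids)
  out <- t(apply(m, 1, function(v) {
    v <- sort(v, decreasing = TRUE)
    length(v) <- k               # pads with NA beyond available controls
    v[is.na(v)] <- 0L
    v
  }))
  if (k == 1L) out <- matrix(out, ncol = 1, dimnames = list(rownames(m), NULL))
  storage.mode(out) <- "integer"
  colnames(out) <- sprintf("VC%d", seq_len(k))
  attr(out, "k") <- as.integer(k)
  out
}

#' Score one bait-prey pair against its virtual controls
#'
#' Returns the per-replicate posterior probability that the observed counts
#' come from the elevated true-interaction component rather than the
#' control-derived background component (see [saint_params()]). The
#' probability is monotone non-decreasing in the test count with controls
#' held fixed, and a count of zero can never favour the interaction.
#'
#' @param test_counts Integer vector of test spectral counts, one per
#'   biological replicate (length >= 1).
#' @param control_counts The prey's compressed virtual-control counts.
#' @param params A [saint_params()].
#' @return List with `replicate_probs`, `avg_p` (their mean), `avg_spec`
#'   (mean test count) and `ctrl_avg` (mean virtual-control count).
#' @export
score_pair <- function(test_counts, control_counts, params = saint_params()) {
  stopifnot(length(test_counts) >= 1, all(test_counts >= 0))
  mu0 <- max(mean(control_counts), params$eps)
  mu1 <- max(mean(test_counts), params$min_fold * mu0)
  l0 <- dcount(test_counts, mu0, params$model_dispersion)
  l1 <- dcount(test_counts, mu1, params$model_dispersion)
  p <- l1 / (l0 + l1)
  list(replicate_probs = p, avg_p = mean(p),
       avg_spec = mean(test_counts), ctrl_avg = mean(control_counts))
}

#' Bayesian false discovery rate from replicate-averaged probabilities
#'
#' Records are ranked by descending `avg_p`; the BFDR at rank r is the
#' cumulative mean of `1 - avg_p` over the top r records. Tied probabilities
#' share the largest (worst) BFDR of their tie block so that thresholding is
#' order-independent.
#'
#' @param avg_p Numeric vector of replicate-averaged interaction
#'   probabilities in `[0, 1]` (non-empty).
#' @return Numeric vector of BFDRs, aligned with the input order.
#' @export
compute_bfdr <- function(avg_p) {
  if (!length(avg_p)) stop("empty probability vector", call. = FALSE)
  stopifnot(all(avg_p >= 0 & avg_p <= 1))
  o <- order(avg_p, decreasing = TRUE)
  sorted <- avg_p[o]
  cum <- cumsum(1 - sorted) / seq_along(sorted)
  # worst-of-block for ties: every member of a tie block takes the block max
  cum <- stats::ave(cum, sorted, FUN = max)
  out <- numeric(length(avg_p))
  out[o] <- cum
  out
}

#' Score a whole experiment against compressed virtual controls
#'
#' Each bait x condition set of replicate runs is scored as one dataset: the
#' per-replicate mixture probabilities are averaged into `AvgP` and converted
#' into a BFDR within the dataset. Negative controls are pooled across
#' conditions before compression by default; `by_condition = TRUE` scores
#' each condition against condition-matched controls instead.
#'
#' @param experiment An [sc_experiment()] with at least one control run.
#' @param k Number of virtual controls.
#' @param by_condition Score against condition-matched controls?
#' @param params A [saint_params()].
#' @return data.frame with one row per bait x condition x prey: list-columns
#'   `replicate_counts`, `replicate_probs`, `ctrl_counts`, numeric `avg_p`,
#'   `avg_spec`, `ctrl_avg`, `bfdr` and logical `detected` (count > 0 in at
#'   least one replicate).
#' @export
score_experiment <- function(experiment, k = 4, by_condition = FALSE,
                             params = saint_params()) {
  stopifnot(inherits(experiment, "sc_experiment"))
  runs <- experiment$runs
  vc_all <- if (by_condition) NULL else compress_controls(experiment, k)
  test_runs <- runs[runs$role == "test", , drop = FALSE]
  datasets <- unique(test_runs[, c("bait_id", "condition")])
  out <- NULL
  for (i in seq_len(nrow(datasets))) {
    b <- datasets$bait_id[i]; cond <- datasets$condition[i]
    ids <- test_runs$run_id[test_runs$bait_id == b &
                            test_runs$condition == cond]
    m <- count_matrix(experiment, ids)
    vc <- if (by_condition) compress_controls(experiment, k, cond) else vc_all
    mu0 <- pmax(rowMeans(vc), params$eps)
    mu1 <- pmax(rowMeans(m), params$min_fold * mu0)
    l0 <- dcount(m, mu0, params$model_dispersion)
    l1 <- dcount(m, mu1, params$model_dispersion)
    probs <- l1 / (l0 + l1)
    avg_p <- rowMeans(probs)
    df <- data.frame(bait_id = b, condition = cond,
                     prey_id = rownames(m), stringsAsFactors = FALSE)
    df$replicate_counts <- lapply(seq_len(nrow(m)),
                                  function(j) as.numeric(m[j, ]))
    df$replicate_probs <- lapply(seq_len(nrow(probs)),
                                 function(j) unname(probs[j, ]))
    df$ctrl_counts <- lapply(seq_len(nrow(vc)),
                             function(j) as.numeric(vc[j, ]))
    df$avg_p <- avg_p
    df$avg_spec <- rowMeans(m)
    df$ctrl_avg <- rowMeans(vc)
    df$bfdr <- compute_bfdr(avg_p)
    df$detected <- rowSums(m) > 0
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  out
}
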