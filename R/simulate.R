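#' Design of a synthetic spectral-count experiment
#'
#' Describes a BioID-style study: a set of test baits profiled in cycling and
#' ciliated conditions with replicate runs, a pool of empty-vector negative
#' controls, and a prey background. Each bait receives `n_true_per_bait`
#' planted true interactors whose counts are inflated by `effect_multiplier`
#' in that bait's runs, and additionally by `condition_effect` in its ciliated
#' runs. Optional "sticky" preys emulate scaffold contaminants: they are
#' elevated in every test bait and `sticky_multiplier`-fold more in a
#' dedicated negative-control bait (`CTRLBAIT`), the situation the
#' control-enrichment exclusion filter is designed to remove.
#'
#' Counts are negative binomial with mean `mu` and variance
#' `mu + mu^2 / dispersion`; `dispersion = Inf` gives the Poisson limit.
#' The defaults emulate the study conditions: 2 biological replicates per
#' condition, 9 negative controls (5 cycling, 4 ciliated), low spectral-count
#' background, and mild overdispersion consistent with the high
#' replicate-to-replicate reproducibility typical of the assay.
#'
#' @param n_baits Number of test baits.
#' @param n_replicates_per_condition Biological replicates per bait per
#'   condition (the study used 2).
#' @param n_controls Number of negative-control runs (the study used 9;
#'   split ceiling/floor between cycling and ciliated).
#' @param n_preys Number of preys in the background.
#' @param n_true_per_bait Planted true interactors per bait.
#' @param background_mean Mean background spectral count.
#' @param effect_multiplier Count inflation for planted true interactors
#'   (must be >= 1; 1 is the no-effect null).
#' @param dispersion Negative-binomial size parameter; `Inf` for Poisson.
#' @param condition_effect Extra multiplier applied to planted interactors in
#'   ciliated runs (1 = no condition effect).
#' @param n_sticky Number of sticky contaminant preys (0 disables the
#'   control bait entirely).
#' @param sticky_multiplier Extra enrichment of sticky preys in the control
#'   bait relative to their level in test baits.
#' @param dropout Per-observation probability that a prey fails detection in
#'   a run (count forced to 0). Default 0 (no zero-inflation).
#' @param seed Integer seed; the same design yields byte-identical output.
#' @return A validated `simulation_design` list.
#' @export
simulation_design <- function(n_baits = 3, n_replicates_per_condition = 2,
                              n_controls = 9, n_preys = 2000,
                              n_true_per_bait = 150, background_mean = 2,
                              effect_multiplier = 8, dispersion = 20,
                              condition_effect = 1, n_sticky = 0,
                              sticky_multiplier = 8, dropout = 0, seed = 1L) {
  d <- list(n_baits = as.integer(n_baits),
            n_replicates_per_condition = as.integer(n_replicates_per_condition),
            n_controls = as.integer(n_controls),
            n_preys = as.integer(n_preys),
            n_true_per_bait = as.integer(n_true_per_bait),
            background_mean = background_mean,
            effect_multiplier = effect_multiplier,
            dispersion = dispersion,
            condition_effect = condition_effect,
            n_sticky = as.integer(n_sticky),
            sticky_multiplier = sticky_multiplier,
            dropout = dropout,
            seed = as.integer(seed))
  stopifnot(d$n_baits >= 1, d$n_replicates_per_condition >= 1,
            d$n_controls >= 1, d$n_preys >= 1,
            d$n_true_per_bait >= 0, d$n_true_per_bait <= d$n_preys,
            d$background_mean > 0, d$effect_multiplier >= 1,
            d$dispersion > 0, d$condition_effect > 0,
            d$n_sticky >= 0, d$n_sticky + d$n_true_per_bait <= d$n_preys,
            d$sticky_multiplier >= 1, d$dropout >= 0, d$dropout < 1)
  class(d) <- "simulation_design"
  d
}

rcounts <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = dispersion)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a spectral-count experiment with planted ground truth
#'
#' @param design A [simulation_design()].
#' @return A list with elements `experiment` (an [sc_experiment()]),
#'   `truth` (data.frame of planted true `(bait_id, prey_id)` pairs) and
#'   `sticky_preys` (character vector of planted contaminant preys).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  with_seed(d$seed, {
    prey_ids <- sprintf("PREY%04d", seq_len(d$n_preys))
    baits <- sprintf("BAIT%d", seq_len(d$n_baits))
    has_ctrlbait <- d$n_sticky > 0L

    # run manifest: negative controls split cycling/ciliated like the study
    n_cyc_ctrl <- ceiling(d$n_controls / 2)
    runs <- data.frame(
      run_id = sprintf("CTRL%02d", seq_len(d$n_controls)),
      bait_id = "EMPTY",
      role = "control",
      condition = rep(c("cycling", "ciliated"),
                      c(n_cyc_ctrl, d$n_controls - n_cyc_ctrl)),
      stringsAsFactors = FALSE)
    all_baits <- c(baits, if (has_ctrlbait) "CTRLBAIT")
    for (b in all_baits) for (cond in c("cycling", "ciliated")) {
      runs <- rbind(runs, data.frame(
        run_id = sprintf("%s_%s_R%d", b, toupper(substr(cond, 1, 3)),
                         seq_len(d$n_replicates_per_condition)),
        bait_id = b, role = "test", condition = cond,
        stringsAsFactors = FALSE))
    }

    # planted truth: disjoint true sets per bait where room allows, plus a
    # shared sticky contaminant block
    pool <- sample(prey_ids, d$n_preys)   # permuted to decorrelate from ids
    sticky <- if (d$n_sticky) pool[seq_len(d$n_sticky)] else character()
    rest <- setdiff(pool, sticky)
    truth <- NULL
    for (i in seq_along(baits)) {
      off <- ((i - 1L) * d$n_true_per_bait) %% max(length(rest), 1L)
      idx <- if (d$n_true_per_bait)
        ((off + seq_len(d$n_true_per_bait) - 1L) %% length(rest)) + 1L
        else integer()
      if (length(idx))
        truth <- rbind(truth, data.frame(bait_id = baits[i],
                                         prey_id = rest[idx],
                                         stringsAsFactors = FALSE))
    }
    if (is.null(truth))
      truth <- data.frame(bait_id = character(), prey_id = character(),
                          stringsAsFactors = FALSE)

    counts <- NULL
    for (r in seq_len(nrow(runs))) {
      mu <- rep(d$background_mean, d$n_preys)
      names(mu) <- prey_ids
      b <- runs$bait_id[r]
      if (runs$role[r] == "test") {
        if (b %in% baits) {
          tp <- truth$prey_id[truth$bait_id == b]
          mu[tp] <- mu[tp] * d$effect_multiplier
          if (runs$condition[r] == "ciliated")
            mu[tp] <- mu[tp] * d$condition_effect
          mu[sticky] <- d$background_mean * d$effect_multiplier
        } else {  # CTRLBAIT: sticky preys are strongly over-represented
          mu[sticky] <- d$background_mean * d$effect_multiplier *
            d$sticky_multiplier
        }
      }
      x <- rcounts(d$n_preys, mu, d$dispersion)
      if (d$dropout > 0)
        x[stats::runif(d$n_preys) < d$dropout] <- 0L
      nz <- x > 0
      if (any(nz))
        counts <- rbind(counts, data.frame(run_id = runs$run_id[r],
                                           prey_id = prey_ids[nz],
                                           count = as.integer(x[nz]),
                                           stringsAsFactors = FALSE))
    }
    preys <- data.frame(prey_id = prey_ids, gene_symbol = prey_ids,
                        sequence_length = NA_integer_,
                        stringsAsFactors = FALSE)
    list(experiment = sc_experiment(counts, runs, preys),
         truth = truth, sticky_preys = sticky)
  })
}

#' Design of a synthetic two-channel cell image
#'
#' One cell per frame: the nuclear channel holds a filled disc at the frame
#' centre; the lysosome channel holds `n_puncta` Gaussian puncta on a
#' constant background, a fraction `perinuclear_fraction` of them centred in
#' the 30-pixel-wide (by default `ring_width`) annulus just outside the
#' nucleus and the remainder placed peripherally. Images are single-plane
#' 16-bit (values clipped to `[0, 65535]` and rounded), emulating
#' deconvolved, projected micrographs.
#'
#' @param image_size Frame side in pixels.
#' @param nucleus_radius Nuclear disc radius, pixels. The nucleus plus the
#'   ring must fit in the frame with margin.
#' @param n_puncta Number of lysosomal puncta.
#' @param perinuclear_fraction Fraction of puncta centred in the ring.
#' @param punctum_intensity Peak amplitude of one punctum (grey levels).
#' @param punctum_sigma Gaussian radius of a punctum, pixels.
#' @param background_level Constant background added to both channels.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param nucleus_intensity Amplitude of the nuclear disc.
#' @param ring_width Width of the perinuclear annulus, pixels.
#' @param seed Integer seed.
#' @export
image_design <- function(image_size = 256, nucleus_radius = 40,
                         n_puncta = 150, perinuclear_fraction = 0.5,
                         punctum_intensity = 2000, punctum_sigma = 2,
                         background_level = 100, noise_sd = 5,
                         nucleus_intensity = 3000, ring_width = 30,
                         seed = 1L) {
  d <- list(image_size = as.integer(image_size),
            nucleus_radius = nucleus_radius, n_puncta = as.integer(n_puncta),
            perinuclear_fraction = perinuclear_fraction,
            punctum_intensity = punctum_intensity,
            punctum_sigma = punctum_sigma,
            background_level = background_level, noise_sd = noise_sd,
            nucleus_intensity = nucleus_intensity,
            ring_width = ring_width, seed = as.integer(seed))
  stopifnot(d$image_size >= 64, d$nucleus_radius > 0, d$n_puncta >= 0,
            d$perinuclear_fraction >= 0, d$perinuclear_fraction <= 1,
            d$punctum_intensity > 0, d$punctum_sigma > 0,
            d$background_level >= 0, d$noise_sd >= 0, d$ring_width > 0)
  margin <- d$image_size / 2 - (d$nucleus_radius + d$ring_width)
  if (margin < 3 * d$punctum_sigma + 2)
    stop("nucleus plus ring does not fit in the frame with enough margin",
         call. = FALSE)
  class(d) <- "image_design"
  d
}

radial_distance <- function(n, centre) {
  xs <- matrix(seq_len(n), n, n) - centre[1]
  ys <- matrix(seq_len(n), n, n, byrow = TRUE) - centre[2]
  sqrt(xs^2 + ys^2)
}

add_punctum <- function(img, cx, cy, amp, sigma) {
  n <- nrow(img)
  w <- ceiling(4 * sigma)
  xr <- max(1, floor(cx - w)):min(n, ceiling(cx + w))
  yr <- max(1, floor(cy - w)):min(n, ceiling(cy + w))
  gx <- exp(-((xr - cx)^2) / (2 * sigma^2))
  gy <- exp(-((yr - cy)^2) / (2 * sigma^2))
  img[xr, yr] <- img[xr, yr] + amp * outer(gx, gy)
  img
}

#' Simulate a two-channel cell image with known perinuclear fraction
#'
#' @param design An [image_design()].
#' @return List with `nuclear` and `lysosome` (numeric matrices, 16-bit
#'   scale), `truth_fraction` (exact fraction of noise-free lysosome
#'   intensity inside the analytic ring; 0 when there are no puncta),
#'   `centre` and `puncta` (data.frame of punctum centres with a
#'   `perinuclear` flag).
#' @export
simulate_cell_image <- function(design) {
  stopifnot(inherits(design, "image_design"))
  d <- design
  with_seed(d$seed, {
    n <- d$image_size
    centre <- c((n + 1) / 2, (n + 1) / 2)
    dist <- radial_distance(n, centre)
    R <- d$nucleus_radius; W <- d$ring_width; s <- d$punctum_sigma

    nuc <- matrix(0, n, n)
    nuc[dist <= R] <- d$nucleus_intensity

    lys <- matrix(0, n, n)
    n_peri <- round(d$perinuclear_fraction * d$n_puncta)
    n_dist <- d$n_puncta - n_peri
    # centres uniform by area within each annulus, inset by one sigma so a
    # punctum's mass stays mostly within its designated compartment
    r_peri <- sqrt(stats::runif(n_peri, (R + s)^2, (R + W - s)^2))
    out_lo <- R + W + s
    out_hi <- n / 2 - 3 * s - 2
    if (n_dist > 0 && out_hi <= out_lo)
      stop("no room to place peripheral puncta", call. = FALSE)
    r_dist <- sqrt(stats::runif(n_dist, out_lo^2, out_hi^2))
    r_all <- c(r_peri, r_dist)
    th <- stats::runif(d$n_puncta, 0, 2 * pi)
    px <- centre[1] + r_all * cos(th)
    py <- centre[2] + r_all * sin(th)
    for (i in seq_len(d$n_puncta))
      lys <- add_punctum(lys, px[i], py[i], d$punctum_intensity, s)

    ring <- dist > R & dist <= R + W
    total <- sum(lys)
    truth <- if (total > 0) sum(lys[ring]) / total else 0

    noisy <- function(img) {
      img <- img + d$background_level
      if (d$noise_sd > 0)
        img <- img + matrix(stats::rnorm(n * n, 0, d$noise_sd), n, n)
      matrix(pmin(pmax(round(img), 0), 65535), n, n)
    }
    list(nuclear = noisy(nuc), lysosome = noisy(lys),
         truth_fraction = truth, centre = centre,
         puncta = data.frame(x = px, y = py,
                             perinuclear = rep(c(TRUE, FALSE),
                                               c(n_peri, n_dist))))
  })
}
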