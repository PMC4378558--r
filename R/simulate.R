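# Ground-truthed synthetic data: centroided spectra with planted averagine
# envelopes, and abstract labeled feature sets for weight-recovery and
# FDR-calibration studies.

#' Simulation configuration
#'
#' Defaults emulate high-charge top-down fragment data: ion masses
#' 1,000-20,000 Da, charges 1-24, log-uniform envelope abundances,
#' multiplicative log-normal intensity noise (sigma 0.2), 5 ppm m/z jitter,
#' 10% peak dropout, and a uniform noise-peak floor of 200 peaks per
#' 2,000 Th whose intensities reach 1/snr of the smallest envelope base
#' intensity.
#'
#' @param n_ions Number of planted ions.
#' @param mass_range Monoisotopic mass range (Da).
#' @param charge_range Charge-state range.
#' @param mz_range Spectrum m/z window (Th); ions are drawn so their base
#'   peak falls inside it.
#' @param base_intensity_range Log-uniform range for the most-abundant-peak
#'   intensity of an envelope (arbitrary units).
#' @param intensity_sigma Log-normal sigma of multiplicative peak-intensity
#'   noise.
#' @param mz_jitter_ppm Gaussian m/z jitter in ppm.
#' @param dropout Peak dropout rate for the weakest envelope peaks.
#'   Dropout emulates censoring at the detection/centroiding limit, which
#'   hits peaks that are weak relative to their own envelope: a peak with
#'   relative theoretical intensity `r` (1 = most abundant) drops with
#'   probability `dropout * exp(-r / 0.15)`. Missing peaks therefore
#'   concentrate at envelope ends, as observed in real centroided data,
#'   and strong mid peaks essentially never vanish.
#' @param snr Signal-to-noise ratio: noise-peak intensities are uniform on
#'   `(0, min(base_intensity_range) / snr)`.
#' @param noise_density Noise peaks per 2,000 Th.
#' @param multi_charge Probability that an ion species is planted at two
#'   adjacent charge states instead of one (fragment ions of intact
#'   proteins commonly show up at several charges, which is what the
#'   supporting-envelope feature keys on). Each envelope draws its own
#'   abundance.
#' @param centroid_width_ppm Centroider resolution: peaks closer than this
#'   (in ppm) are merged into one centroid with summed intensity at the
#'   intensity-weighted mean m/z, as a real centroider does. This is what
#'   lets overlapping envelopes contaminate each other's peak intensities.
#'   The default 15 ppm stays below the isotopomer spacing of the highest
#'   default charge state across the default m/z window.
#' @param prune Theoretical-distribution prune threshold for planted
#'   envelopes.
#' @param avoid_overlap When `TRUE`, redraw ions whose envelope m/z window
#'   (padded by 2 Th) would overlap an already-planted one. Default
#'   `FALSE`: real top-down spectra contain overlapping envelopes.
#' @param seed Random seed fixing all randomness (`NULL` = leave RNG
#'   state alone).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ions = 10L, mass_range = c(1000, 20000),
                       charge_range = c(1L, 24L), mz_range = c(200, 2500),
                       base_intensity_range = c(1e4, 1e5),
                       intensity_sigma = 0.2, mz_jitter_ppm = 5,
                       dropout = 0.1, snr = 20, noise_density = 200,
                       multi_charge = 0.5, centroid_width_ppm = 15,
                       prune = 0.01, avoid_overlap = FALSE, seed = NULL) {
  stopifnot(n_ions >= 0, diff(mass_range) >= 0, diff(mz_range) > 0,
            charge_range[1] >= 1L, dropout >= 0, dropout <= 1,
            intensity_sigma >= 0, snr > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a centroided spectrum with ground truth
#'
#' For each planted ion, draws a mass and a feasible charge, computes the
#' averagine isotopomer distribution, scales it to a drawn abundance,
#' perturbs intensities multiplicatively (log-normal) and m/z by ppm
#' jitter, drops peaks with the dropout probability, and finally adds
#' uniform noise peaks over the m/z window.
#'
#' @param cfg A [sim_config()].
#' @return List with `spectrum` (a `spectrum`) and `truth`: a data frame
#'   with one row per planted envelope (`ion`, `mass`, `charge`,
#'   `base_mz`, `base_intensity`, `n_peaks`, `n_dropped`; one ion species
#'   may contribute envelopes at two charge states) plus attribute
#'   `"peaks"`, a list of per-envelope peak tables (`mz`, `intensity`,
#'   `dropped`).
#' @export
simulate_spectrum <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed))
    set.seed(cfg$seed)
  ions <- list()
  windows <- matrix(numeric(0), ncol = 2)
  zs <- seq(cfg$charge_range[1], cfg$charge_range[2])
  plant <- function(ion, mono, dist1, z) {
    mz <- (mono + dist1$shift * ISOTOPE_SPACING + z * PROTON_MASS) / z
    A <- exp(stats::runif(1, log(cfg$base_intensity_range[1]),
                          log(cfg$base_intensity_range[2])))
    rel <- dist1$prob / max(dist1$prob)
    intensity <- rel * A * exp(stats::rnorm(length(mz), 0,
                                            cfg$intensity_sigma))
    mz_obs <- mz * (1 + stats::rnorm(length(mz), 0,
                                     cfg$mz_jitter_ppm * 1e-6))
    ## censoring at the detection/centroiding limit: drop probability
    ## decays exponentially in the peak's relative intensity
    dropped <- stats::runif(length(mz)) < cfg$dropout * exp(-rel / 0.15)
    list(ion = ion, mass = mono, charge = z,
         base_mz = mz[dist1$most_abundant], base_intensity = A,
         peaks = data.frame(mz = mz_obs, intensity = intensity,
                            dropped = dropped))
  }
  for (i in seq_len(cfg$n_ions)) {
    for (try in seq_len(100L)) {
      mass <- stats::runif(1, cfg$mass_range[1], cfg$mass_range[2])
      comp <- averagine_composition(mass)
      dist1 <- isotope_distribution(comp, z = 1L, prune = cfg$prune)
      mono <- dist1$mono_mass
      base_shift <- dist1$shift[dist1$most_abundant]
      base_mz_at <- (mono + base_shift * ISOTOPE_SPACING + zs * PROTON_MASS) / zs
      span <- (max(dist1$shift) - min(dist1$shift)) * ISOTOPE_SPACING / zs
      win_free <- function(w) !cfg$avoid_overlap || !nrow(windows) ||
        !any(w[1] <= windows[, 2] & w[2] >= windows[, 1])
      ok <- base_mz_at >= cfg$mz_range[1] & base_mz_at <= cfg$mz_range[2]
      if (!any(ok)) next
      z <- if (sum(ok) == 1L) zs[ok] else sample(zs[ok], 1L)
      zi <- match(z, zs)
      win <- c(base_mz_at[zi] - span[zi], base_mz_at[zi] + span[zi]) + c(-2, 2)
      if (!win_free(win)) next
      windows <- rbind(windows, win)
      ions[[length(ions) + 1L]] <- plant(i, mono, dist1, z)
      ## optionally plant the same species at an adjacent charge state
      if (stats::runif(1) < cfg$multi_charge) {
        for (z2 in c(z + 1L, z - 1L)) {
          zi2 <- match(z2, zs)
          if (is.na(zi2) || !ok[zi2]) next
          win2 <- c(base_mz_at[zi2] - span[zi2],
                    base_mz_at[zi2] + span[zi2]) + c(-2, 2)
          if (!win_free(win2)) next
          windows <- rbind(windows, win2)
          ions[[length(ions) + 1L]] <- plant(i, mono, dist1, z2)
          break
        }
      }
      break
    }
  }
  n_noise <- round(cfg$noise_density * diff(cfg$mz_range) / 2000)
  noise_mz <- stats::runif(n_noise, cfg$mz_range[1], cfg$mz_range[2])
  noise_int <- stats::runif(n_noise, 0, cfg$base_intensity_range[1] / cfg$snr)
  mz_all <- c(unlist(lapply(ions, function(x) x$peaks$mz[!x$peaks$dropped])),
              noise_mz)
  int_all <- c(unlist(lapply(ions, function(x)
    x$peaks$intensity[!x$peaks$dropped])), noise_int)
  ## centroider merging: peaks closer than the resolution width collapse
  ## into one centroid (summed intensity, intensity-weighted mean m/z)
  if (length(mz_all) && cfg$centroid_width_ppm > 0) {
    o <- order(mz_all)
    mz_all <- mz_all[o]; int_all <- int_all[o]
    gap <- diff(mz_all) > mz_all[-length(mz_all)] * cfg$centroid_width_ppm * 1e-6
    grp <- cumsum(c(1L, as.integer(gap)))
    int_g <- as.numeric(tapply(int_all, grp, sum))
    mz_g <- as.numeric(tapply(mz_all * int_all, grp, sum)) / int_g
    mz_all <- mz_g; int_all <- int_g
  }
  spec <- new_spectrum(mz_all, int_all, id = "synthetic")
  truth <- data.frame(
    ion = vapply(ions, function(x) as.integer(x$ion), integer(1)),
    mass = vapply(ions, `[[`, numeric(1), "mass"),
    charge = vapply(ions, function(x) as.integer(x$charge), integer(1)),
    base_mz = vapply(ions, `[[`, numeric(1), "base_mz"),
    base_intensity = vapply(ions, `[[`, numeric(1), "base_intensity"),
    n_peaks = vapply(ions, function(x) nrow(x$peaks), integer(1)),
    n_dropped = vapply(ions, function(x) sum(x$peaks$dropped), integer(1)))
  attr(truth, "peaks") <- lapply(ions, `[[`, "peaks")
  list(spectrum = spec, truth = truth)
}

## analytic mean of min(Poisson(lambda), 2)
capped_pois_mean <- function(lambda, cap) {
  if (cap == 0L) return(0)
  x <- 0:cap
  px <- stats::dpois(x, lambda)
  sum(x * px) + cap * (1 - sum(px))
}

#' Simulate a labeled feature set
#'
#' Draws abstract envelope-match feature vectors and Bernoulli labels from
#' a logistic model with the given weights: `P(incorrect | f) =
#' plogis(w . (f - mu))`, where `mu` is the analytic mean of the feature
#' distributions (mean-centering keeps the classes balanced, so all-zero
#' weights give ~50% prevalence). The m/z and intensity distances are
#' half-normal, the three counts small-mean Poisson; the missing-peak count
#' is capped at the largest value the candidate filters admit for the
#' group (0, 1, 2, 2). The default scales were fixed by an a-priori
#' Fisher-information analysis so that n = 10,000 observations identify
#' every weight to roughly +/-0.1; they are statistical-power settings, not
#' spectral realism (use [simulate_spectrum()] for that).
#'
#' @param weights A `weight_set` providing the planted per-group weights.
#' @param n_per_group Observations per group.
#' @param seed Random seed (`NULL` = leave RNG state alone).
#' @param sigma_dx,sigma_dy Half-normal scales of the two distances.
#' @param rate_s,rate_n,rate_m Poisson means of the three counts.
#' @return Feature table with columns `mz_dist`, `int_dist`, `n_support`,
#'   `n_loss`, `n_missing`, `k`, `label` (`TRUE` = correct).
#' @export
simulate_feature_set <- function(weights = default_weights(),
                                 n_per_group = 10000L, seed = NULL,
                                 sigma_dx = 1.2, sigma_dy = 0.9,
                                 rate_s = 0.7, rate_n = 0.5, rate_m = 0.6) {
  stopifnot(inherits(weights, "weight_set"), n_per_group >= 1L)
  if (!is.null(seed))
    set.seed(seed)
  m_cap <- c("2" = 0L, "3" = 1L, "4" = 2L, "5+" = 2L)
  out <- lapply(GROUP_LEVELS, function(g) {
    n <- n_per_group
    k <- switch(g, "2" = rep(2L, n), "3" = rep(3L, n), "4" = rep(4L, n),
                "5+" = 5L + stats::rpois(n, 2))
    f <- cbind(
      mz_dist = abs(stats::rnorm(n, 0, sigma_dx)),
      int_dist = abs(stats::rnorm(n, 0, sigma_dy)),
      n_support = stats::rpois(n, rate_s),
      n_loss = stats::rpois(n, rate_n),
      n_missing = pmin(stats::rpois(n, rate_m), m_cap[[g]]))
    mu <- c(sigma_dx * sqrt(2 / pi), sigma_dy * sqrt(2 / pi),
            rate_s, rate_n, capped_pois_mean(rate_m, m_cap[[g]]))
    w <- weights[[g]]
    feats <- names(w)
    eta <- as.vector(sweep(f[, feats, drop = FALSE], 2,
                           mu[match(feats, FEATURE_NAMES)]) %*% w)
    incorrect <- stats::runif(n) < stats::plogis(eta)
    df <- as.data.frame(f)
    df$k <- k
    df$label <- !incorrect
    df
  })
  do.call(rbind, out)
}
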