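# Candidate envelope enumeration: noise-level estimation, peak matching,
# top-3 intensity scaling with sub-noise pruning, missing-peak filters,
# and supporting / neutral-loss annotation.

#' Estimate the noise intensity level of a spectrum
#'
#' Builds an intensity histogram and returns the upper edge of the most
#' populated bin. Peaks with intensity strictly above this value are
#' "signal peaks". Bins are equal-width between 0 and the median of the
#' top-decile intensities (peaks above that cap are counted in the top
#' bin), which stops a handful of huge peaks from stretching the bins.
#'
#' @param spectrum A `spectrum`.
#' @param n_bins Number of histogram bins (default 100).
#' @return Noise intensity level (scalar).
#' @export
estimate_noise_level <- function(spectrum, n_bins = 100L) {
  stopifnot(inherits(spectrum, "spectrum"))
  y <- spectrum$peaks$intensity
  if (!length(y))
    stop("empty spectrum")
  if (n_bins < 2L)
    stop("n_bins must be >= 2")
  top <- sort(y, decreasing = TRUE)
  cap <- stats::median(top[seq_len(max(1L, ceiling(length(y) / 10)))])
  if (cap <= 0)
    return(0)
  width <- cap / n_bins
  bin <- pmin(pmax(ceiling(y / width), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  which.max(counts) * width
}

## per-peak matching tolerance in Th
mz_tolerance <- function(mz, tol_mz = 0.01, tol_ppm = 15) {
  pmax(tol_mz, mz * tol_ppm * 1e-6)
}

#' Match theoretical peaks to experimental peaks
#'
#' Maps each peak of an (aligned) theoretical distribution to the nearest
#' experimental peak within the matching tolerance
#' `max(tol_mz, tol_ppm * 1e-6 * mz)`; equidistant candidates break toward
#' the higher intensity. Unmatched positions are filled with zero-intensity
#' placeholder peaks at the theoretical m/z.
#'
#' @param dist A `theo_dist`, aligned to a base peak.
#' @param spectrum A `spectrum`.
#' @param tol_mz Absolute tolerance floor in Th (default 0.01).
#' @param tol_ppm Relative tolerance in ppm (default 15).
#' @return List with `mz`, `intensity`, `placeholder` (logical) and
#'   `peak_index` (index into the spectrum peak table, `NA` for
#'   placeholders), all of the theoretical peak count's length.
#' @export
match_peaks <- function(dist, spectrum, tol_mz = 0.01, tol_ppm = 15) {
  stopifnot(inherits(dist, "theo_dist"), inherits(spectrum, "spectrum"))
  smz <- spectrum$peaks$mz
  sint <- spectrum$peaks$intensity
  tmz <- dist$mz
  tol <- mz_tolerance(tmz, tol_mz, tol_ppm)
  idx <- rep(NA_integer_, length(tmz))
  if (length(smz)) {
    ns <- length(smz)
    left <- findInterval(tmz, smz)
    right <- pmin(left + 1L, ns)
    left <- pmax(left, 1L)
    dl <- abs(smz[left] - tmz)
    dr <- abs(smz[right] - tmz)
    best <- ifelse(dl < dr, left,
                   ifelse(dr < dl, right,
                          ifelse(sint[left] >= sint[right], left, right)))
    dist <- pmin(dl, dr)
    idx[dist <= tol] <- best[dist <= tol]
  }
  matched <- !is.na(idx)
  list(mz = ifelse(matched, smz[idx], tmz),
       intensity = ifelse(matched, sint[idx], 0),
       placeholder = !matched,
       peak_index = idx)
}

#' Scale a theoretical distribution against its experimental envelope
#'
#' Multiplies each theoretical probability by
#' `r = sum(experimental intensities at the 3 most probable theoretical
#' positions) / sum(those 3 probabilities)` (all peaks if fewer than 3;
#' placeholders contribute 0), then removes theoretical peaks whose scaled
#' intensity does not exceed the noise level, dropping the corresponding
#' experimental positions in lockstep (the contiguous run around the
#' most abundant peak is kept).
#'
#' @param dist A `theo_dist` aligned to a base peak.
#' @param exp_env Matching result from [match_peaks()].
#' @param noise Noise intensity level.
#' @return An `envelope_match` object, or `NULL` when the envelope is
#'   unmatchable (the top-3 experimental intensities are all zero) or fewer
#'   than 2 peaks survive pruning. Fields: `theo_mz`, `theo_int`, `exp_mz`,
#'   `exp_int`, `placeholder`, `peak_index`, `k`, `z`, `mono_mass`,
#'   `base_mz`, `f_support`, `f_loss`, `label`.
#' @export
scale_theoretical <- function(dist, exp_env, noise = 0) {
  stopifnot(inherits(dist, "theo_dist"),
            length(dist$mz) == length(exp_env$mz))
  top3 <- order(dist$prob, decreasing = TRUE)[seq_len(min(3L, length(dist$prob)))]
  denom <- sum(dist$prob[top3])
  num <- sum(exp_env$intensity[top3])
  if (num <= 0)
    return(NULL)
  r <- num / denom
  scaled <- dist$prob * r
  keep <- scaled > noise
  if (!any(keep))
    return(NULL)
  imax <- which.max(scaled)
  lo <- imax; hi <- imax
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  while (hi < length(scaled) && keep[hi + 1L]) hi <- hi + 1L
  idx <- lo:hi
  if (length(idx) < 2L)
    return(NULL)
  structure(list(
    theo_mz = dist$mz[idx],
    theo_int = scaled[idx],
    exp_mz = exp_env$mz[idx],
    exp_int = exp_env$intensity[idx],
    placeholder = exp_env$placeholder[idx],
    peak_index = exp_env$peak_index[idx],
    k = length(idx),
    z = dist$z,
    mono_mass = dist$mono_mass,
    base_mz = dist$mz[dist$most_abundant],
    f_support = NA_integer_,
    f_loss = NA_integer_,
    label = NA
  ), class = "envelope_match")
}

#' @export
print.envelope_match <- function(x, ...) {
  cat(sprintf(
    "Envelope match: mono mass %.5f Da, z=%d, k=%d, %d missing\n",
    x$mono_mass, x$z, x$k, sum(x$placeholder)))
  invisible(x)
}

## longest run of TRUE in a logical vector
longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Missing-peak candidate filters
#'
#' A candidate envelope match is rejected iff any of: it has 3 or more
#' missing peaks; 3 theoretical peaks and 2 missing peaks; 2 theoretical
#' peaks and 1 missing peak; or it does not contain `k - 3` consecutive
#' matched peaks (`k` = theoretical peak count).
#'
#' @param match An `envelope_match`.
#' @return `TRUE` if the candidate passes all four filters.
#' @export
passes_filters <- function(match) {
  stopifnot(inherits(match, "envelope_match"))
  k <- match$k
  missing <- sum(match$placeholder)
  if (missing >= 3L) return(FALSE)
  if (k == 3L && missing == 2L) return(FALSE)
  if (k == 2L && missing == 1L) return(FALSE)
  if (longest_run(!match$placeholder) < k - 3L) return(FALSE)
  TRUE
}

#' Enumerate candidate envelope matches
#'
#' For every signal peak (intensity above the noise level) taken as a base
#' peak and every charge `z` in `1..max_charge`: estimates the ion mass
#' from the base peak, builds the averagine theoretical distribution with
#' its most abundant peak anchored at the base peak, matches it to the
#' spectrum, scales it (with sub-noise pruning), and keeps the match if it
#' passes the missing-peak filters.
#'
#' @param spectrum A `spectrum`.
#' @param max_charge Largest valid charge state (default 30).
#' @param tol_mz,tol_ppm Matching tolerance, see [match_peaks()].
#' @param prune Theoretical-distribution prune threshold (default 0.01).
#' @param noise Noise level; estimated from the spectrum when `NULL`.
#' @return List of `envelope_match` objects (possibly empty).
#' @export
generate_candidates <- function(spectrum, max_charge = 30L, tol_mz = 0.01,
                                tol_ppm = 15, prune = 0.01, noise = NULL) {
  stopifnot(inherits(spectrum, "spectrum"), max_charge >= 1L)
  if (!nrow(spectrum$peaks))
    return(list())
  if (is.null(noise))
    noise <- estimate_noise_level(spectrum)
  signal <- which(spectrum$peaks$intensity > noise)
  out <- vector("list", 0L)
  ## averagine distributions recur across base peaks and spectra; memoise
  ## them package-wide by (composition, prune)
  comp_cache <- .ldeconv_cache$dist_cache
  if (is.null(comp_cache)) {
    comp_cache <- new.env(parent = emptyenv())
    .ldeconv_cache$dist_cache <- comp_cache
  }
  for (i in signal) {
    base_mz <- spectrum$peaks$mz[i]
    for (z in seq_len(max_charge)) {
      est_mass <- (base_mz - PROTON_MASS) * z
      if (est_mass < 50)
        next
      comp <- averagine_composition(est_mass)
      key <- paste(c(comp, prune), collapse = ",")
      dist <- comp_cache[[key]]
      if (is.null(dist)) {
        dist <- tryCatch(isotope_distribution(comp, z = 1L, prune = prune),
                         error = function(e) NULL)
        if (is.null(dist)) next
        comp_cache[[key]] <- dist
      }
      if (length(dist$mz) < 2L)
        next
      dist <- align_to_base_peak(dist, base_mz, z = z)
      ## re-space peaks for charge z around the anchored base peak
      dist$mz <- base_mz +
        (dist$shift - dist$shift[dist$most_abundant]) * ISOTOPE_SPACING / z
      exp_env <- match_peaks(dist, spectrum, tol_mz, tol_ppm)
      m <- scale_theoretical(dist, exp_env, noise)
      if (is.null(m))
        next
      if (passes_filters(m))
        out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Annotate supporting and neutral-loss envelopes
#'
#' For each candidate, `f_support` counts other candidates with the same
#' monoisotopic mass (within `ppm_tol`, allowing a +/-1.00235 Da isotope
#' error) and a different charge state, and `f_loss` counts candidates
#' whose monoisotopic mass is lower by the mass of NH3 (17.02655 Da) or H2O
#' (18.01056 Da) within `ppm_tol`.
#'
#' @param candidates List of `envelope_match` objects from one spectrum.
#' @param ppm_tol Mass tolerance in ppm (default 15).
#' @return The candidate list with `f_support` and `f_loss` filled in.
#' @export
annotate_support <- function(candidates, ppm_tol = 15) {
  n <- length(candidates)
  if (!n) return(candidates)
  mass <- vapply(candidates, `[[`, numeric(1), "mono_mass")
  z <- vapply(candidates, `[[`, integer(1), "z")
  tol <- ppm_tol * 1e-6 * mass
  for (i in seq_len(n)) {
    dm <- mass[i] - mass
    same <- abs(dm) <= tol[i] | abs(abs(dm) - ISOTOPE_SPACING) <= tol[i]
    candidates[[i]]$f_support <-
      as.integer(sum(same & z != z[i]) )
    loss <- (abs(dm - NH3_MASS) <= tol[i]) | (abs(dm - H2O_MASS) <= tol[i])
    candidates[[i]]$f_loss <- as.integer(sum(loss))
  }
  candidates
}
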