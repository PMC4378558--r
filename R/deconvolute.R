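# End-to-end deconvolution: candidates -> features -> L-score / local FDR
# -> greedy envelope selection -> merged monoisotopic mass list.

#' Estimate the number of envelope matches to report
#'
#' For a tandem spectrum with precursor mass `M`, the target protein length
#' is estimated as `L = ceiling(M / m_avg)` (`m_avg` = average amino-acid
#' residue mass) and the report count as `x = 2 * (L - 1)` (roughly one b
#' and one y fragment per backbone cleavage).
#'
#' @param precursor_mass Precursor mass `M` in Da (> 0).
#' @param m_avg Average residue mass (default [average_residue_mass()]).
#' @return Integer report count `x >= 0`.
#' @export
estimate_report_count <- function(precursor_mass,
                                  m_avg = average_residue_mass()) {
  if (!is.numeric(precursor_mass) || any(!is.finite(precursor_mass)) ||
      any(precursor_mass <= 0))
    stop("precursor mass must be positive")
  as.integer(2 * (ceiling(precursor_mass / m_avg) - 1))
}

## are two monoisotopic masses the same up to ppm tolerance and an optional
## +/- one-isotope error?
same_mass <- function(m1, m2, ppm_tol = 15, isotope_error = ISOTOPE_SPACING) {
  dm <- abs(m1 - m2)
  tol <- ppm_tol * 1e-6 * pmax(m1, m2)
  dm <= tol | abs(dm - isotope_error) <= tol
}

#' Greedy envelope selection
#'
#' Candidates (with `score` and `fdr` fields set) are visited in ascending
#' (local FDR, raw score) order. A candidate is accepted unless it shares
#' at least half of its non-placeholder experimental peaks with an
#' already-accepted candidate of a different monoisotopic mass (same-mass
#' candidates at other charges are kept and merged downstream). Selection
#' stops after `x` acceptances. This greedy overlap rule is a documented
#' simplification standing in for a combinatorial envelope-selection model;
#' the L-score/local-FDR ordering is the ranking criterion.
#'
#' @param candidates List of scored `envelope_match` objects.
#' @param x Maximum number of envelopes to accept (`Inf` for all).
#' @param merge_ppm Mass tolerance (ppm) used to decide "same mass".
#' @return The accepted candidates, in acceptance order.
#' @export
select_envelopes <- function(candidates, x = Inf, merge_ppm = 15) {
  if (!length(candidates) || x <= 0)
    return(list())
  fdr <- vapply(candidates, `[[`, numeric(1), "fdr")
  score <- vapply(candidates, `[[`, numeric(1), "score")
  ord <- order(fdr, score)
  accepted <- list()
  used_peaks <- list()   # per accepted candidate: its peak indices + mass
  for (i in ord) {
    cand <- candidates[[i]]
    peaks <- cand$peak_index[!cand$placeholder]
    block <- FALSE
    for (a in accepted) {
      if (same_mass(cand$mono_mass, a$mono_mass, merge_ppm))
        next
      shared <- sum(peaks %in% a$peak_index[!a$placeholder])
      if (shared >= length(peaks) / 2) {
        block <- TRUE
        break
      }
    }
    if (block) next
    accepted[[length(accepted) + 1L]] <- cand
    if (length(accepted) >= x) break
  }
  accepted
}

#' Deconvolute a centroided spectrum
#'
#' Full pipeline: noise-level estimation, candidate envelope enumeration
#' over all signal peaks and charge states, supporting / neutral-loss
#' annotation, five-feature L-scoring with local-FDR lookup,
#' per-(mass, charge) deduplication, greedy envelope selection, and merging
#' of the same monoisotopic mass across charge states (within
#' `merge_ppm` ppm, allowing a one-isotope error; intensities summed, best
#' FDR kept).
#'
#' @param spectrum A `spectrum`.
#' @param max_charge Largest charge state to consider (default 30).
#' @param tol_mz,tol_ppm Peak-matching tolerance (see [match_peaks()]).
#' @param prune Theoretical-distribution prune threshold.
#' @param t,c Intensity-distance parameters.
#' @param weights A `weight_set` (default the shipped Table of weights).
#' @param fdr_table An `fdr_table` (default the synthetic-trained one).
#' @param report_count Number of envelope matches to report; `NULL` =
#'   estimate from the precursor mass via [estimate_report_count()] when
#'   available, otherwise report all.
#' @param fdr_ceiling Optional local-FDR ceiling; entries above it are
#'   dropped.
#' @param merge_ppm Cross-charge mass-merge tolerance in ppm.
#' @return A `deconv_result`: spectrum/precursor metadata plus an `entries`
#'   data frame (`mass`, `charge`, `intensity`, `score`, `fdr`) ranked by
#'   ascending (fdr, score). `intensity` is the summed non-placeholder
#'   experimental intensity over the merged envelopes.
#' @export
deconvolute <- function(spectrum, max_charge = 30L, tol_mz = 0.01,
                        tol_ppm = 15, prune = 0.01, t = 0.5, c = 2,
                        weights = default_weights(),
                        fdr_table = default_fdr_table(),
                        report_count = NULL, fdr_ceiling = NULL,
                        merge_ppm = 15) {
  stopifnot(inherits(spectrum, "spectrum"))
  empty <- function() structure(list(
    id = spectrum$id, precursor_mz = spectrum$precursor_mz,
    precursor_charge = spectrum$precursor_charge,
    precursor_mass = spectrum$precursor_mass,
    activation = spectrum$activation,
    entries = data.frame(mass = numeric(0), intensity = numeric(0),
                         charge = integer(0), score = numeric(0),
                         fdr = numeric(0))), class = "deconv_result")
  if (!nrow(spectrum$peaks)) {
    warning("empty spectrum: nothing to deconvolute")
    return(empty())
  }
  candidates <- generate_candidates(spectrum, max_charge = max_charge,
                                    tol_mz = tol_mz, tol_ppm = tol_ppm,
                                    prune = prune)
  if (!length(candidates))
    return(empty())
  candidates <- annotate_support(candidates, ppm_tol = tol_ppm)
  feats <- matches_to_table(candidates, t = t, c = c)
  score <- score_feature_table(feats, weights)
  fdr <- local_fdr(score, feats$k, fdr_table)
  for (i in seq_along(candidates)) {
    candidates[[i]]$score <- score[i]
    candidates[[i]]$fdr <- fdr[i]
  }
  ## deduplicate candidates sharing (mass, charge): keep the lowest
  ## (fdr, score) one
  ord <- order(fdr, score)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      if (candidates[[j]]$z == candidates[[i]]$z &&
          abs(candidates[[j]]$mono_mass - candidates[[i]]$mono_mass) <=
            merge_ppm * 1e-6 * candidates[[i]]$mono_mass) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  candidates <- candidates[kept]
  x <- report_count
  if (is.null(x))
    x <- if (!is.na(spectrum$precursor_mass))
      estimate_report_count(spectrum$precursor_mass) else Inf
  selected <- select_envelopes(candidates, x = x, merge_ppm = merge_ppm)
  if (!length(selected))
    return(empty())
  ## merge the same monoisotopic mass across charge states
  entries <- list()
  for (cand in selected) {
    intensity <- sum(cand$exp_int[!cand$placeholder])
    merged <- FALSE
    for (j in seq_along(entries)) {
      if (same_mass(entries[[j]]$mass, cand$mono_mass, merge_ppm)) {
        entries[[j]]$intensity <- entries[[j]]$intensity + intensity
        merged <- TRUE
        break
      }
    }
    if (!merged)
      entries[[length(entries) + 1L]] <- list(
        mass = cand$mono_mass, charge = cand$z, intensity = intensity,
        score = cand$score, fdr = cand$fdr)
  }
  e <- data.frame(
    mass = vapply(entries, `[[`, numeric(1), "mass"),
    intensity = vapply(entries, `[[`, numeric(1), "intensity"),
    charge = vapply(entries, function(x) as.integer(x$charge), integer(1)),
    score = vapply(entries, `[[`, numeric(1), "score"),
    fdr = vapply(entries, `[[`, numeric(1), "fdr"))
  if (!is.null(fdr_ceiling))
    e <- e[e$fdr <= fdr_ceiling, , drop = FALSE]
  e <- e[order(e$fdr, e$score), , drop = FALSE]
  rownames(e) <- NULL
  res <- empty()
  res$entries <- e
  res
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Deconvolution result '%s': %d monoisotopic masses\n",
              x$id, nrow(x$entries)))
  if (nrow(x$entries))
    print(utils::head(x$entries, 10))
  invisible(x)
}
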