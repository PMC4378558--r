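# Training: fragment-ion labeling of envelope matches, per-group logistic
# regression for the L-score weights, and local-FDR table construction.

ION_TYPES <- c("b", "y", "b-H2O", "b-NH3", "y-H2O", "y-NH3")

#' Theoretical fragment masses of a proteoform
#'
#' Monoisotopic neutral masses of prefix (b) and suffix (y) fragments of an
#' unmodified proteoform sequence, optionally with H2O / NH3 neutral
#' losses. `b` fragments are prefix residue-mass sums; `y` fragments are
#' suffix residue-mass sums plus one water.
#'
#' @param sequence Amino-acid sequence over the 20 standard residues.
#' @param ion_types Subset of `c("b", "y", "b-H2O", "b-NH3", "y-H2O",
#'   "y-NH3")`.
#' @return Data frame with columns `mass` (Da, sorted), `ion_type`, `site`
#'   (cleavage site index, 1-based from the respective terminus).
#' @export
#' @examples
#' theoretical_fragments("PEPTIDE", c("b", "y"))
theoretical_fragments <- function(sequence, ion_types = ION_TYPES) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (length(ion_types))
    ion_types <- match.arg(ion_types, ION_TYPES, several.ok = TRUE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(RESIDUE_MONO_MASS))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  n <- length(aa)
  empty <- data.frame(mass = numeric(0), ion_type = character(0),
                      site = integer(0))
  if (!length(ion_types) || n < 2L)
    return(empty)
  res <- RESIDUE_MONO_MASS[aa]
  sites <- seq_len(n - 1L)
  b <- cumsum(res)[sites]
  y <- rev(cumsum(rev(res)))[-1L] + H2O_MASS   # suffix sums, site i = length i
  y <- rev(y)                                   # y_i = C-terminal i residues
  base <- list(b = data.frame(mass = b, ion_type = "b", site = sites),
               y = data.frame(mass = y, ion_type = "y", site = sites))
  out <- lapply(ion_types, function(it) {
    parts <- strsplit(it, "-", fixed = TRUE)[[1]]
    d <- base[[parts[1]]]
    if (length(parts) == 2L) {
      loss <- switch(parts[2], H2O = H2O_MASS, NH3 = NH3_MASS)
      d$mass <- d$mass - loss
      d$ion_type <- it
    }
    d
  })
  out <- do.call(rbind, out)
  out <- out[out$mass > 0, ]
  out <- out[order(out$mass), ]
  rownames(out) <- NULL
  out
}

#' Match monoisotopic masses against reference masses
#'
#' A mass matches a reference iff `|mass - (ref + delta)| <= ppm_tol * 1e-6
#' * ref` for some `delta` in `{-isotope_error, 0, +isotope_error}` (off-
#' by-one-isotope errors are common when reading monoisotopic masses off
#' envelopes).
#'
#' @param masses Numeric vector of query masses (Da).
#' @param reference Numeric vector of reference masses (Da).
#' @param ppm_tol Tolerance in ppm (default 15).
#' @param isotope_error Allowed isotope-error shift in Da (default
#'   1.00235).
#' @return Logical vector along `masses`.
#' @export
match_masses <- function(masses, reference, ppm_tol = 15,
                         isotope_error = ISOTOPE_SPACING) {
  if (!length(reference))
    return(rep(FALSE, length(masses)))
  ref <- sort(reference)
  tol_of <- ppm_tol * 1e-6 * ref
  hit <- rep(FALSE, length(masses))
  for (delta in c(-isotope_error, 0, isotope_error)) {
    q <- masses - delta
    i <- findInterval(q, ref)
    for (side in 0:1) {
      j <- pmin(pmax(i + side, 1L), length(ref))
      hit <- hit | abs(q - ref[j]) <= tol_of[j]
    }
  }
  hit
}

#' Label envelope matches against a fragment set
#'
#' Marks each envelope match `correct` iff its monoisotopic mass maps to a
#' theoretical fragment mass within `ppm_tol` (allowing a +/-1-isotope
#' error), else `incorrect`.
#'
#' @param matches List of `envelope_match` objects.
#' @param frags Fragment table from [theoretical_fragments()], or a plain
#'   numeric vector of reference masses.
#' @param ppm_tol,isotope_error See [match_masses()].
#' @return The match list with `label` set to `TRUE` (correct) or `FALSE`.
#' @export
label_matches <- function(matches, frags, ppm_tol = 15,
                          isotope_error = ISOTOPE_SPACING) {
  ref <- if (is.data.frame(frags)) frags$mass else as.numeric(frags)
  mass <- vapply(matches, `[[`, numeric(1), "mono_mass")
  lab <- match_masses(mass, ref, ppm_tol, isotope_error)
  for (i in seq_along(matches))
    matches[[i]]$label <- lab[i]
  matches
}

#' Tabulate labeled envelope matches
#'
#' Flattens a list of (annotated, labeled) envelope matches into the
#' feature table used by [fit_weights()], [build_fdr_table()] and
#' [compare_scorers()]: one row per match with the five features, `k`, the
#' label, mass and charge. Serializes losslessly to TSV via
#' [utils::write.table()].
#'
#' @param matches List of `envelope_match` objects.
#' @param t,c Intensity-distance parameters.
#' @return Data frame with columns `mz_dist`, `int_dist`, `n_support`,
#'   `n_loss`, `n_missing`, `k`, `label`, `mass`, `charge`.
#' @export
matches_to_table <- function(matches, t = 0.5, c = 2) {
  fv <- t(vapply(matches, compute_features, numeric(5), t = t, c = c))
  df <- as.data.frame(fv)
  df$k <- vapply(matches, `[[`, integer(1), "k")
  df$label <- vapply(matches, `[[`, logical(1), "label")
  df$mass <- vapply(matches, `[[`, numeric(1), "mono_mass")
  df$charge <- vapply(matches, `[[`, integer(1), "z")
  df
}

## ridge-stabilized IRLS logistic regression; responses y in {0,1}.
## lambda is negligible (1e-6) -- it only guarantees convergence on
## separable data; the planted-weight recovery bias it introduces is far
## below 0.01.
logistic_fit <- function(X, y, lambda = 1e-6, max_iter = 100L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)[-1L]
}

#' Fit L-score weights by per-group logistic regression
#'
#' Regresses the label (incorrect = 1) on the five features within each
#' peak-pair-count group; the missing-peak feature is excluded for group 2.
#' The fit is plain logistic regression with a negligible L2 ridge (1e-6)
#' for numerical stability on separable data; it is deterministic. The
#' intercept is fitted but not retained (the L-score carries no intercept).
#'
#' @param labeled Feature table from [matches_to_table()] or
#'   [simulate_feature_set()]; must contain both classes in every group
#'   present.
#' @return A `weight_set` for the groups present in the data (groups with
#'   no data raise no error but are absent; use
#'   [new_weight_set()]-compatible completion if needed). All four groups
#'   must be present for a complete set.
#' @export
fit_weights <- function(labeled) {
  stopifnot(all(FEATURE_NAMES %in% names(labeled)),
            "k" %in% names(labeled), "label" %in% names(labeled))
  g <- group_of(labeled$k)
  groups <- stats::setNames(vector("list", 4L), GROUP_LEVELS)
  for (grp in GROUP_LEVELS) {
    idx <- which(g == grp)
    if (!length(idx)) next
    y <- as.numeric(!labeled$label[idx])   # incorrect = 1
    if (length(unique(y)) < 2L)
      stop("group ", grp, " contains a single class; cannot fit")
    feats <- if (grp == "2") FEATURE_NAMES[1:4] else FEATURE_NAMES
    X <- as.matrix(labeled[idx, feats, drop = FALSE])
    beta <- logistic_fit(X, y)
    groups[[grp]] <- stats::setNames(beta, feats)
  }
  missing_groups <- GROUP_LEVELS[vapply(groups, is.null, logical(1))]
  if (length(missing_groups))
    stop("no envelope matches in group(s): ",
         paste(missing_groups, collapse = ", "))
  new_weight_set(groups)
}

#' Build a local-FDR lookup table
#'
#' Scores the labeled matches with the given weights, bins the raw scores
#' on the fixed 0.02-wide grid, and stores per bin the counts of correct
#' and incorrect matches and the local FDR
#' `incorrect / (correct + incorrect)`.
#'
#' @param labeled Feature table (see [fit_weights()]).
#' @param weights A `weight_set`.
#' @return An `fdr_table`.
#' @export
build_fdr_table <- function(labeled, weights = default_weights()) {
  score <- score_feature_table(labeled, weights)
  bin <- as.integer(floor(score / FDR_BIN_WIDTH))
  g <- group_of(labeled$k)
  out <- stats::setNames(vector("list", 4L), GROUP_LEVELS)
  for (grp in GROUP_LEVELS) {
    idx <- which(g == grp)
    if (!length(idx)) {
      out[[grp]] <- data.frame(bin = integer(0), fdr = numeric(0),
                               n_correct = integer(0),
                               n_incorrect = integer(0))
      next
    }
    b <- bin[idx]
    lab <- labeled$label[idx]
    ub <- sort(unique(b))
    n_cor <- vapply(ub, function(x) sum(lab[b == x]), numeric(1))
    n_tot <- vapply(ub, function(x) sum(b == x), numeric(1))
    out[[grp]] <- data.frame(bin = ub,
                             fdr = (n_tot - n_cor) / n_tot,
                             n_correct = as.integer(n_cor),
                             n_incorrect = as.integer(n_tot - n_cor))
  }
  structure(out, class = "fdr_table")
}
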