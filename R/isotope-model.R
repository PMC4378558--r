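# Averagine composition estimation and centroided theoretical isotopomer
# distributions over the CHNOS element set.

#' Parse a molecular formula
#'
#' Parses a simple Hill-style formula over the CHNOS element set, e.g.
#' `"H2O"`, `"C6H12O6"`, `"C254H377N65O75S6"`.
#'
#' @param formula Character scalar.
#' @return Named integer vector with components `C`, `H`, `N`, `O`, `S`.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  comp <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || paste(pieces, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  for (p in pieces) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(comp))
      stop("unsupported element '", el, "' (CHNOS only)")
    comp[el] <- comp[el] + n
  }
  comp
}

#' Mass of an elemental composition
#'
#' @param comp Named integer vector over `C, H, N, O, S` (see
#'   [parse_formula()], [averagine_composition()]).
#' @param type `"mono"` for the monoisotopic mass, `"average"` for the
#'   abundance-weighted average mass.
#' @return Mass in Da.
#' @export
composition_mass <- function(comp, type = c("mono", "average")) {
  type <- match.arg(type)
  comp <- as_composition(comp)
  w <- if (type == "mono") ELEMENT_MONO_MASS else ELEMENT_AVG_MASS
  sum(comp * w[names(comp)])
}

## normalize a composition vector: named, CHNOS, non-negative integers
as_composition <- function(comp) {
  if (is.null(names(comp)) || !all(names(comp) %in% c("C", "H", "N", "O", "S")))
    stop("composition must be a named vector over C, H, N, O, S")
  full <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  full[names(comp)] <- comp
  if (any(full < 0) || any(full != round(full)))
    stop("element counts must be non-negative integers")
  storage.mode(full) <- "integer"
  full
}

#' Estimate an elemental composition from a mass (averagine model)
#'
#' Scales the averagine unit formula (C4.9384 H7.7583 N1.3577 O1.4773
#' S0.0417, 111.1254 Da per unit) by `mass / 111.1254`, rounds each element
#' count to the nearest integer, and then adjusts the hydrogen count so the
#' average mass of the composition is as close as possible to the input
#' mass. The result always contains at least one atom, and its average mass
#' is within half a hydrogen mass of the target.
#'
#' @param mass Target (average) mass in Da; must be positive.
#' @return Named integer vector over `C, H, N, O, S`.
#' @export
#' @examples
#' averagine_composition(10000)
averagine_composition <- function(mass) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("mass must be a positive number")
  scale <- mass / AVERAGINE_UNIT_MASS
  comp <- round(AVERAGINE_UNIT * scale)
  ## hydrogen adjustment: absorb the rounding error of the other elements
  mass_no_h <- sum(comp[c("C", "N", "O", "S")] *
                     ELEMENT_AVG_MASS[c("C", "N", "O", "S")])
  comp["H"] <- max(0, round((mass - mass_no_h) / ELEMENT_AVG_MASS[["H"]]))
  if (sum(comp) == 0)
    comp["H"] <- 1
  as_composition(comp)
}

## distribution of the total neutron-count shift for `n` atoms of one
## element, as a probability vector indexed by shift 0, 1, 2, ...
## Two-isotope elements are binomial; three-isotope elements use the
## multinomial decomposition n2 ~ Bin(n, p2), n1 | n2 ~ Bin(n - n2,
## p1 / (p0 + p1)); anything else (sulfur, with its shift-4 isotope) falls
## back to the convolution power. `tail` bounds the discarded mass.
element_shift_distribution <- function(element, n, tail = 1e-14) {
  iso <- ELEMENT_ISOTOPES[[element]]
  ab <- iso$abundance / sum(iso$abundance)
  if (nrow(iso) == 2L && iso$shift[2] == 1L)
    return(stats::dbinom(0:stats::qbinom(1 - tail, n, ab[2]), n, ab[2]))
  if (nrow(iso) == 3L && all(iso$shift == c(0L, 1L, 2L))) {
    n2max <- stats::qbinom(1 - tail, n, ab[3])
    smax <- 2L * n2max + stats::qbinom(1 - tail, n, ab[2])
    out <- numeric(smax + 1L)
    q1 <- ab[2] / (ab[1] + ab[2])
    for (n2 in 0:n2max) {
      s <- (2L * n2):smax
      out[s + 1L] <- out[s + 1L] +
        stats::dbinom(n2, n, ab[3]) * stats::dbinom(s - 2L * n2, n - n2, q1)
    }
    return(out)
  }
  p <- numeric(max(iso$shift) + 1L)
  p[iso$shift + 1L] <- ab
  conv_pow(p, n, tail)
}

## p^(*n) by exponentiation-by-squaring on probability vectors
conv_pow <- function(p, n, tail = 1e-15) {
  trim <- function(v) {
    cs <- cumsum(v)
    keep <- which(cs < cs[length(cs)] * (1 - tail))
    k <- if (length(keep)) min(keep[length(keep)] + 1L, length(v)) else 1L
    v[seq_len(k)]
  }
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1)
      result <- trim(convolve_vec(result, base))
    base <- trim(convolve_vec(base, base))
    n <- n %/% 2
  }
  result
}

convolve_vec <- function(a, b) {
  if (identical(a, 1)) return(b)
  if (identical(b, 1)) return(a)
  ## outer-product convolution; vectors stay short (< a few hundred)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Centroided theoretical isotopomer distribution
#'
#' Aggregates isotopologues by total neutron count (one centroided peak per
#' neutron count) via convolution of the per-element isotope distributions.
#' Peak m/z values are `(monoisotopic mass + j * 1.00235 + z * 1.007276) / z`
#' for neutron count `j`, so adjacent peaks are spaced 1.00235/z Th apart.
#' Peaks with probability below `prune` are removed (keeping the contiguous
#' run around the most abundant peak) and the remainder renormalized.
#'
#' @param comp Elemental composition (named vector over CHNOS).
#' @param z Positive integer charge state.
#' @param prune Probability threshold in `[0, 1)`; peaks below it are
#'   dropped. Default 0.01.
#' @return Object of class `theo_dist` with fields `mz`, `prob`, `z`,
#'   `mono_mass`, `most_abundant` (index of the most abundant peak, 1-based).
#' @export
#' @examples
#' isotope_distribution(parse_formula("C6H12O6"), z = 1)
isotope_distribution <- function(comp, z = 1L, prune = 0.01) {
  comp <- as_composition(comp)
  if (sum(comp) == 0)
    stop("empty composition")
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L)
    stop("z must be a positive integer")
  if (!is.numeric(prune) || prune < 0 || prune >= 1)
    stop("prune must be in [0, 1)")
  p <- 1
  for (el in names(comp)) {
    if (comp[[el]] > 0)
      p <- convolve_vec(p, element_shift_distribution(el, comp[[el]]))
  }
  if (identical(p, 1))
    stop("empty composition")
  p <- p / sum(p)
  j <- seq_along(p) - 1L
  keep <- p >= prune
  if (!any(keep))
    stop("all peaks pruned: prune threshold ", prune,
         " exceeds the most abundant isotopomer probability")
  ## isotope distributions are unimodal; keep the contiguous run holding the
  ## maximum so the spacing invariant is preserved
  imax <- which.max(p)
  lo <- imax
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- imax
  while (hi < length(p) && keep[hi + 1L]) hi <- hi + 1L
  idx <- lo:hi
  p <- p[idx] / sum(p[idx])
  j <- j[idx]
  mono <- composition_mass(comp, "mono")
  structure(list(
    mz = (mono + j * ISOTOPE_SPACING + z * PROTON_MASS) / z,
    prob = p,
    shift = j,
    z = z,
    mono_mass = mono,
    most_abundant = which.max(p)
  ), class = "theo_dist")
}

#' Anchor a theoretical distribution at a base peak
#'
#' Rigidly shifts all peak m/z values so the most abundant peak sits exactly
#' at `base_mz`, and recomputes the monoisotopic mass from the anchored
#' position: `mono = (base_mz - j * 1.00235 / z - 1.007276) * z`, where `j`
#' is the neutron-count shift of the most abundant peak. Idempotent;
#' inter-peak spacings are preserved exactly.
#'
#' @param dist A `theo_dist`.
#' @param base_mz Target m/z (Th) for the most abundant peak; positive.
#' @param z Charge state; defaults to the distribution's charge.
#' @return The shifted `theo_dist`.
#' @export
align_to_base_peak <- function(dist, base_mz, z = dist$z) {
  stopifnot(inherits(dist, "theo_dist"), length(dist$mz) >= 1L)
  if (!is.numeric(base_mz) || length(base_mz) != 1L || base_mz <= 0)
    stop("base_mz must be positive")
  z <- as.integer(z)
  i <- dist$most_abundant
  shift <- base_mz - dist$mz[i]
  dist$mz <- dist$mz + shift
  dist$z <- z
  j <- dist$shift[i]
  dist$mono_mass <- (base_mz - j * ISOTOPE_SPACING / z - PROTON_MASS) * z
  dist
}

#' @export
print.theo_dist <- function(x, ...) {
  cat(sprintf(
    "Theoretical isotopomer distribution: z=%d, mono mass %.5f Da, %d peaks\n",
    x$z, x$mono_mass, length(x$mz)))
  print(data.frame(mz = x$mz, prob = x$prob))
  invisible(x)
}
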