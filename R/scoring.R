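# The five envelope-match features, the L-score linear combination, the
# per-group local-FDR lookup tables, and the comparison scorers (dot
# product, Kullback-Leibler divergence).
#
# Score orientation: the weights are oriented toward the "incorrect" class
# (positive weights on the distance features, negative on the support
# counts), so a LOWER L-score means a more likely correct envelope match.

FEATURE_NAMES <- c("mz_dist", "int_dist", "n_support", "n_loss", "n_missing")
GROUP_LEVELS <- c("2", "3", "4", "5+")

## group label from the peak-pair count k
group_of <- function(k) {
  stopifnot(all(k >= 2L))
  ifelse(k >= 5L, "5+", as.character(k))
}

#' m/z distance of an envelope match
#'
#' Root mean square deviation of the m/z values over the matched peak
#' pairs; pairs with zero-intensity placeholder peaks are excluded.
#'
#' @param match An `envelope_match`.
#' @return RMSD in Th.
#' @export
mz_distance <- function(match) {
  real <- !match$placeholder
  if (!any(real))
    stop("no matched peak pairs: m/z distance undefined")
  sqrt(mean((match$theo_mz[real] - match$exp_mz[real])^2))
}

#' Intensity-distribution distance of an envelope match
#'
#' Peak intensities are converted to relative intensities `r(y) = y / y_h`
#' where `y_h` is the highest theoretical peak intensity. For each pair the
#' signed error is `e = r(y') - r(y)`; the per-pair distance is
#' `min(e, t)` when `e >= 0` and `min(c * (-e), c * t)` otherwise (large
#' positive errors, typically overlap with other envelopes, are capped at
#' `t`; negative errors carry the penalty factor `c`). The feature is the
#' root mean square over all `k` pairs, placeholders included (their
#' error is `-r(y)`).
#'
#' @param match An `envelope_match`.
#' @param t Large-error threshold (default 0.5).
#' @param c Penalty factor for negative errors (default 2).
#' @return Non-negative distance (unitless).
#' @export
intensity_distance <- function(match, t = 0.5, c = 2) {
  y_h <- max(match$theo_int)
  if (y_h <= 0)
    stop("theoretical envelope has no positive peak intensity")
  e <- match$exp_int / y_h - match$theo_int / y_h
  d <- ifelse(e >= 0, pmin(e, t), pmin(c * (-e), c * t))
  sqrt(mean(d^2))
}

#' Compute the five-feature vector of an envelope match
#'
#' @param match An `envelope_match`, annotated with supporting and
#'   neutral-loss counts (see [annotate_support()]).
#' @param t,c Intensity-distance parameters (see [intensity_distance()]).
#' @return Named numeric vector `(mz_dist, int_dist, n_support, n_loss,
#'   n_missing)`.
#' @export
compute_features <- function(match, t = 0.5, c = 2) {
  s <- match$f_support
  n <- match$f_loss
  if (is.na(s) || is.na(n))
    stop("match not annotated: run annotate_support() first")
  c(mz_dist = mz_distance(match),
    int_dist = intensity_distance(match, t, c),
    n_support = as.numeric(s),
    n_loss = as.numeric(n),
    n_missing = sum(match$placeholder))
}

#' L-score of a feature vector
#'
#' Linear combination of the five features with per-group weights; the
#' group is `min(k, 5)` mapped to `{2, 3, 4, 5+}`. Group 2 has no
#' missing-peak weight (group-2 envelopes carry no missing peaks). No
#' intercept: within a group, ranking and the empirical local-FDR lookup
#' are invariant to an additive constant. Lower score = more likely
#' correct.
#'
#' @param fv Feature vector from [compute_features()] (a named vector or a
#'   plain numeric vector in the feature order).
#' @param weights A `weight_set` (default [default_weights()]).
#' @param k Peak-pair count (>= 2) used to pick the group.
#' @return Raw score (scalar).
#' @export
l_score <- function(fv, weights = default_weights(), k) {
  if (k < 2L)
    stop("k must be >= 2")
  g <- group_of(k)
  w <- weights[[g]]
  if (is.null(names(fv)))
    names(fv) <- FEATURE_NAMES[seq_along(fv)]
  sum(w * fv[names(w)])
}

## vectorized scoring of a feature data frame (columns FEATURE_NAMES + k)
score_feature_table <- function(df, weights = default_weights()) {
  g <- group_of(df$k)
  score <- numeric(nrow(df))
  for (grp in GROUP_LEVELS) {
    idx <- which(g == grp)
    if (!length(idx)) next
    w <- weights[[grp]]
    score[idx] <- as.matrix(df[idx, names(w), drop = FALSE]) %*% w
  }
  score
}

# ---- weight sets -----------------------------------------------------------

#' Construct a weight set
#'
#' @param groups Named list with components `"2"`, `"3"`, `"4"`, `"5+"`;
#'   each a named numeric vector of feature weights (`mz_dist`, `int_dist`,
#'   `n_support`, `n_loss`, and, except for group 2, `n_missing`).
#' @return Object of class `weight_set`.
#' @export
new_weight_set <- function(groups) {
  stopifnot(setequal(names(groups), GROUP_LEVELS))
  for (g in GROUP_LEVELS) {
    expected <- if (g == "2") FEATURE_NAMES[1:4] else FEATURE_NAMES
    if (!identical(names(groups[[g]]), expected))
      stop("group ", g, " weights must be named ",
           paste(expected, collapse = ", "))
  }
  structure(groups[GROUP_LEVELS], class = "weight_set")
}

#' Shipped default L-score weights
#'
#' The per-group logistic-regression weights shipped with the package
#' (trained on annotated Salmonella typhimurium CID envelope matches),
#' read from the plain-text defaults file under `extdata`.
#'
#' @return A `weight_set`.
#' @export
default_weights <- function() {
  w <- .ldeconv_cache$default_weights
  if (is.null(w)) {
    w <- read_weights(system.file("extdata", "lscore_weights.txt",
                                  package = "ldeconv", mustWork = TRUE))
    .ldeconv_cache$default_weights <- w
  }
  w
}

#' Read / write weight sets
#'
#' Human-readable key-value text: lines `group.feature = value`, `#`
#' comments.
#'
#' @param path File path.
#' @return `read_weights()` returns a `weight_set`; `write_weights()`
#'   returns `path` invisibly.
#' @export
read_weights <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=[:space:]]+")
  groups <- stats::setNames(vector("list", 4L), GROUP_LEVELS)
  for (p in kv) {
    key <- strsplit(p[[1]], ".", fixed = TRUE)[[1]]
    if (length(key) != 2L || !key[1] %in% GROUP_LEVELS ||
        !key[2] %in% FEATURE_NAMES)
      stop("bad weight entry: ", paste(p, collapse = " "))
    groups[[key[1]]][key[2]] <- as.numeric(p[[2]])
  }
  groups <- lapply(groups, function(v) {
    v[intersect(FEATURE_NAMES, names(v))]
  })
  new_weight_set(groups)
}

#' @param weights A `weight_set`.
#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# L-score feature weights, one line per group.feature", con)
  for (g in GROUP_LEVELS)
    for (f in names(weights[[g]]))
      writeLines(sprintf("%s.%s = %.6g", g, f, weights[[g]][[f]]), con)
  invisible(path)
}

#' @export
print.weight_set <- function(x, ...) {
  cat("L-score weight set (lower score = more likely correct):\n")
  for (g in GROUP_LEVELS) {
    cat(sprintf("  k = %-3s ", g))
    cat(paste(sprintf("%s=%.3f", names(x[[g]]), x[[g]]), collapse = "  "),
        "\n")
  }
  invisible(x)
}

# ---- local-FDR tables ------------------------------------------------------

FDR_BIN_WIDTH <- 0.02

#' Look up the local FDR of a raw score
#'
#' The score falls into a fixed grid bin of width 0.02; the table stores,
#' per group, the fraction of training envelope matches in that bin labeled
#' incorrect. Scores outside the trained range (or in an empty bin) take
#' the FDR of the nearest populated bin.
#'
#' @param score Raw L-score (vectorized).
#' @param k Peak-pair count (scalar or vector).
#' @param table An `fdr_table` (see [build_fdr_table()],
#'   [default_fdr_table()]).
#' @return Local FDR in `[0, 1]`.
#' @export
local_fdr <- function(score, k, table = default_fdr_table()) {
  stopifnot(inherits(table, "fdr_table"))
  g <- group_of(k)
  if (length(g) == 1L) g <- rep(g, length(score))
  fdr <- rep(NA_real_, length(score))
  bin <- as.integer(floor(score / FDR_BIN_WIDTH))
  for (grp in GROUP_LEVELS) {
    idx <- which(g == grp)
    if (!length(idx)) next
    tab <- table[[grp]]
    if (is.null(tab) || !nrow(tab)) {
      fdr[idx] <- 1      # untrained group: maximally conservative
      next
    }
    nearest <- vapply(bin[idx], function(b) which.min(abs(tab$bin - b)),
                      integer(1))
    fdr[idx] <- tab$fdr[nearest]
  }
  fdr
}

#' @export
print.fdr_table <- function(x, ...) {
  cat("Local-FDR lookup table (bin width 0.02):\n")
  for (g in GROUP_LEVELS) {
    tab <- x[[g]]
    if (is.null(tab) || !nrow(tab)) {
      cat(sprintf("  k = %-3s <empty>\n", g))
    } else {
      cat(sprintf("  k = %-3s %d bins, scores [%.2f, %.2f], %d matches\n",
                  g, nrow(tab), min(tab$bin) * FDR_BIN_WIDTH,
                  (max(tab$bin) + 1) * FDR_BIN_WIDTH,
                  sum(tab$n_correct + tab$n_incorrect)))
    }
  }
  invisible(x)
}

#' Read / write local-FDR tables
#'
#' Tab-separated text with columns `group`, `bin`, `fdr`, `n_correct`,
#' `n_incorrect`; bin index `b` covers raw scores
#' `[0.02 * b, 0.02 * (b + 1))`.
#'
#' @param path File path.
#' @export
read_fdr_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(group = "character"))
  out <- stats::setNames(vector("list", 4L), GROUP_LEVELS)
  for (g in GROUP_LEVELS) {
    sub <- df[df$group == g, c("bin", "fdr", "n_correct", "n_incorrect")]
    rownames(sub) <- NULL
    out[[g]] <- sub[order(sub$bin), ]
  }
  structure(out, class = "fdr_table")
}

#' @param table An `fdr_table`.
#' @rdname read_fdr_table
#' @export
write_fdr_table <- function(table, path) {
  stopifnot(inherits(table, "fdr_table"))
  rows <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
    tab <- table[[g]]
    if (is.null(tab) || !nrow(tab)) return(NULL)
    cbind(group = g, tab)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default local-FDR table
#'
#' Trained lookup tables are data-set specific, so the shipped default is a
#' SYNTHETIC calibration: candidate envelopes enumerated from simulated
#' spectra with ground-truth labels, scored with the shipped default
#' weights (see `tools/make_default_fdr_table.R` in the package sources;
#' the file name carries `synthetic` as a reminder). Retrain with
#' [build_fdr_table()] on annotated real data where available.
#'
#' @return An `fdr_table`.
#' @export
default_fdr_table <- function() {
  tab <- .ldeconv_cache$default_fdr_table
  if (is.null(tab)) {
    tab <- read_fdr_table(system.file("extdata", "lscore_fdr_synthetic.tsv",
                                      package = "ldeconv", mustWork = TRUE))
    .ldeconv_cache$default_fdr_table <- tab
  }
  tab
}

# ---- comparison scorers ----------------------------------------------------

#' Dot-product (cosine) similarity of an envelope match
#'
#' Cosine of the theoretical and experimental intensity vectors after
#' normalization to unit length; placeholder pairs enter with intensity 0.
#'
#' @param match An `envelope_match`.
#' @return Similarity in `[0, 1]` (0 when the experimental vector is all
#'   zero). Higher = more similar.
#' @export
dot_product_score <- function(match) {
  a <- match$theo_int
  b <- match$exp_int
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(0)
  sum(a * b) / (sqrt(sum(a^2)) * nb)
}

#' Kullback-Leibler divergence of an envelope match
#'
#' Both intensity vectors are converted to probability distributions by
#' dividing by their sums; the divergence of the experimental distribution
#' Q from the theoretical distribution P is `sum(P * log(P / Q))` (natural
#' log). A pseudocount of 1e-6 of the total intensity is added to every
#' component before normalizing, so zero experimental components (e.g.
#' placeholders) stay finite. Lower = more similar.
#'
#' @param match An `envelope_match`.
#' @return Divergence `>= 0`, or `Inf` when all experimental intensities
#'   are zero.
#' @export
kl_divergence <- function(match) {
  p <- match$theo_int
  q <- match$exp_int
  if (sum(q) == 0) return(Inf)
  p <- p + 1e-6 * sum(p)
  q <- q + 1e-6 * sum(q)
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}
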