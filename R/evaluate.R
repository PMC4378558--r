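# ROC/AUC evaluation harness comparing L-score, the five single features,
# and the dot-product / KL-divergence scorers.

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Exact AUC with midrank tie handling: the probability that a randomly
#' chosen positive (correct) item is scored better than a randomly chosen
#' negative one (ties count 1/2).
#'
#' @param score Numeric scores (`Inf` allowed).
#' @param label Logical labels (`TRUE` = positive/correct class).
#' @param higher_is_better If `FALSE`, lower scores mean "better"; the AUC
#'   is computed for the corresponding orientation.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label, higher_is_better = TRUE) {
  stopifnot(length(score) == length(label), is.logical(label))
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(score)     # midranks for ties
  auc <- (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (!higher_is_better) auc <- 1 - auc
  auc
}

## scorer orientations: is a HIGHER value evidence for "correct"?
SCORER_HIGHER_BETTER <- c(
  l_score = FALSE, mz_dist = FALSE, int_dist = FALSE,
  n_support = TRUE, n_loss = TRUE, n_missing = FALSE,
  dot_product = TRUE, kl_divergence = FALSE
)

#' Compare scorers by AUC, per group and pooled
#'
#' Computes, for labeled envelope matches, the AUC of the L-score, of each
#' of the five single features, and of the dot-product and KL-divergence
#' intensity scorers, within each peak-pair-count group and pooled over
#' all matches. Orientations are handled per scorer (e.g. more supporting
#' envelopes = better; lower KL = better). Pooled L-score uses the raw
#' score.
#'
#' @param matches List of annotated, labeled `envelope_match` objects.
#' @param weights A `weight_set`.
#' @param t,c Intensity-distance parameters.
#' @return Data frame with one row per group plus `"pooled"`, columns
#'   `group`, `n`, and one AUC column per scorer (`NA` when a group lacks
#'   one of the classes).
#' @export
compare_scorers <- function(matches, weights = default_weights(),
                            t = 0.5, c = 2) {
  stopifnot(length(matches) > 0)
  df <- matches_to_table(matches, t = t, c = c)
  if (anyNA(df$label))
    stop("matches must be labeled (see label_matches())")
  df$l_score <- score_feature_table(df, weights)
  df$dot_product <- vapply(matches, dot_product_score, numeric(1))
  df$kl_divergence <- vapply(matches, kl_divergence, numeric(1))
  g <- group_of(df$k)
  rows <- lapply(c(GROUP_LEVELS, "pooled"), function(grp) {
    idx <- if (grp == "pooled") seq_len(nrow(df)) else which(g == grp)
    aucs <- vapply(names(SCORER_HIGHER_BETTER), function(sc) {
      if (!length(idx)) return(NA_real_)
      tryCatch(roc_auc(df[[sc]][idx], df$label[idx],
                       SCORER_HIGHER_BETTER[[sc]]),
               error = function(e) NA_real_)
    }, numeric(1))
    cbind(data.frame(group = grp, n = length(idx)), as.data.frame(t(aucs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
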