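# Independent oracles and small constructors shared across tests.

## Brute-force centroided isotopomer distribution: enumerate, per element,
## every partition of its atoms over its isotopes (multinomial
## probabilities), then combine elements by explicit enumeration over the
## cross product, aggregating by total neutron-count shift. Independent of
## the package's binomial/convolution implementation.
brute_force_distribution <- function(comp) {
  iso <- list(
    C = list(shift = c(0, 1), ab = c(0.9893, 0.0107)),
    H = list(shift = c(0, 1), ab = c(0.999885, 0.000115)),
    N = list(shift = c(0, 1), ab = c(0.99636, 0.00364)),
    O = list(shift = c(0, 1, 2), ab = c(0.99757, 0.00038, 0.00205)),
    S = list(shift = c(0, 1, 2, 4), ab = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  partitions <- function(n, k) {
    if (k == 1L) return(matrix(n, ncol = 1))
    out <- NULL
    for (i in 0:n)
      out <- rbind(out, cbind(i, partitions(n - i, k - 1L)))
    out
  }
  element_dist <- function(el, n) {
    z <- iso[[el]]
    if (n == 0) return(c(`0` = 1))
    parts <- partitions(n, length(z$ab))
    shifts <- as.vector(parts %*% z$shift)
    probs <- apply(parts, 1, function(cnt) stats::dmultinom(cnt, prob = z$ab))
    tapply(probs, shifts, sum)
  }
  total <- c(`0` = 1)
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    d <- element_dist(el, comp[[el]])
    new <- numeric(0)
    for (a in names(total)) for (b in names(d)) {
      s <- as.character(as.numeric(a) + as.numeric(b))
      new[s] <- (if (s %in% names(new)) new[[s]] else 0) +
        total[[a]] * d[[b]]
    }
    total <- new
  }
  total <- total[order(as.numeric(names(total)))]
  total / sum(total)
}

## total variation distance between the package distribution (full,
## prune = 0) and the oracle, aligned on neutron-count shift
tv_against_oracle <- function(comp) {
  d <- isotope_distribution(comp, z = 1, prune = 0)
  oracle <- brute_force_distribution(as_comp(comp))
  shifts <- sort(unique(c(d$shift, as.numeric(names(oracle)))))
  p <- q <- numeric(length(shifts))
  p[match(d$shift, shifts)] <- d$prob
  q[match(as.numeric(names(oracle)), shifts)] <- oracle
  sum(abs(p - q)) / 2
}

as_comp <- function(comp) {
  full <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  full[names(comp)] <- comp
  full
}

## hand-made envelope match for scoring tests
make_match <- function(theo_int, exp_int, placeholder = exp_int == 0,
                       theo_mz = NULL, exp_mz = NULL, z = 1L,
                       mono_mass = 1000, f_support = 0L, f_loss = 0L,
                       label = NA, peak_index = NULL) {
  k <- length(theo_int)
  if (is.null(theo_mz)) theo_mz <- 500 + (seq_len(k) - 1) * 1.00235
  if (is.null(exp_mz)) exp_mz <- theo_mz
  if (is.null(peak_index)) peak_index <- ifelse(placeholder, NA_integer_,
                                                seq_len(k))
  structure(list(
    theo_mz = theo_mz, theo_int = theo_int, exp_mz = exp_mz,
    exp_int = exp_int, placeholder = placeholder, peak_index = peak_index,
    k = k, z = as.integer(z), mono_mass = mono_mass, base_mz = theo_mz[1],
    f_support = as.integer(f_support), f_loss = as.integer(f_loss),
    label = label
  ), class = "envelope_match")
}

## brute-force all-pairs AUC (midrank ties), oracle for roc_auc
auc_brute <- function(score, label, higher_is_better = TRUE) {
  if (!higher_is_better) score <- -score
  pos <- score[label]; neg <- score[!label]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}
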