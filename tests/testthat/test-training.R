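# Fragment generation, labeling, logistic-regression training, FDR tables.

test_that("theoretical_fragments computes b/y ladders with neutral losses", {
  fr <- theoretical_fragments("GG", c("b", "y"))
  expect_equal(fr$mass[fr$ion_type == "b"], 57.02146, tolerance = 1e-5)
  expect_equal(fr$mass[fr$ion_type == "y"], 57.02146 + 18.010565,
               tolerance = 1e-4)
  # PEPTIDE: 6 cleavage sites per ion type, masses sorted
  fr2 <- theoretical_fragments("PEPTIDE", c("b", "y", "b-H2O", "y-NH3"))
  expect_equal(nrow(fr2), 4L * 6L)
  expect_true(!is.unsorted(fr2$mass))
  b2 <- fr2$mass[fr2$ion_type == "b" ][fr2$site[fr2$ion_type == "b"] == 2]
  expect_equal(b2, 97.05276 + 129.04259, tolerance = 1e-4)
  loss <- fr2[fr2$ion_type == "b-H2O" & fr2$site == 2, "mass"]
  expect_equal(loss, 97.05276 + 129.04259 - 18.010565, tolerance = 1e-4)
  expect_equal(nrow(theoretical_fragments("PEPTIDE", character(0))), 0L)
  expect_error(theoretical_fragments("PEPZIDE"), "unknown residue")
})

test_that("label_matches applies 15 ppm with a one-isotope allowance", {
  frags <- data.frame(mass = c(1000, 2500, 4000))
  mk <- function(mass) make_match(c(60, 40), c(60, 40), mono_mass = mass)
  matches <- list(mk(1000), mk(1000 + 1.00235), mk(1000.5),
                  mk(2500 * (1 + 10e-6)), mk(4000 + 0.5))
  lab <- vapply(label_matches(matches, frags), `[[`, logical(1), "label")
  expect_identical(lab, c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("fit_weights recovers planted weights and reproduces sign pattern", {
  fs <- simulate_feature_set(default_weights(), n_per_group = 4000,
                             seed = 17)
  w <- fit_weights(fs)
  expect_s3_class(w, "weight_set")
  # sign pattern: positive distances, negative support/loss counts
  for (g in c("2", "3", "4", "5+")) {
    expect_gt(w[[g]][["mz_dist"]], 0)
    expect_gt(w[[g]][["int_dist"]], 0)
    expect_lt(w[[g]][["n_support"]], 0)
    expect_lt(w[[g]][["n_loss"]], 0)
  }
  # coarse recovery at n = 4000 (acceptance tightens this at n = 10000)
  expect_lt(max(abs(w[["5+"]] - default_weights()[["5+"]])), 0.25)
  # single-class group errors out, naming the group
  bad <- fs
  bad$label[ldeconv:::group_of(bad$k) == "3"] <- TRUE
  expect_error(fit_weights(bad), "group 3")
})

test_that("fit_weights converges on a separable toy set", {
  df <- data.frame(
    mz_dist = rep(c(0.01, 1), each = 50),
    int_dist = 0.1, n_support = 0, n_loss = 0, n_missing = 0,
    k = rep(c(2L, 3L, 4L, 6L), 25),
    label = rep(c(TRUE, FALSE), each = 50))
  w <- fit_weights(df)
  expect_true(all(is.finite(unlist(w))))
  expect_gt(w[["5+"]][["mz_dist"]], 0)
})

test_that("build_fdr_table counts correct/incorrect per 0.02 bin", {
  # three matches in one bin: correct, correct, incorrect -> 1/3
  labeled <- data.frame(mz_dist = 0, int_dist = 0, n_support = 0,
                        n_loss = 0, n_missing = 0, k = 5L,
                        label = c(TRUE, TRUE, FALSE))
  tab <- build_fdr_table(labeled, default_weights())
  expect_equal(tab[["5+"]]$fdr, 1 / 3)
  expect_equal(tab[["5+"]]$n_correct, 2L)
  expect_s3_class(tab, "fdr_table")
  # groups with no data give empty tables; all-correct bins give 0
  expect_equal(nrow(tab[["2"]]), 0L)
  lab2 <- labeled; lab2$label <- TRUE
  expect_equal(build_fdr_table(lab2, default_weights())[["5+"]]$fdr, 0)
})

test_that("held-out FDR calibration is consistent for well-filled bins", {
  # a lighter version of acceptance criterion 7: with 0.02-wide bins a
  # 150k-per-group set fills the central bins to ~250 members, where the
  # mean absolute train/test discrepancy should sit well under 0.05
  fs <- simulate_feature_set(default_weights(), n_per_group = 150000,
                             seed = 23)
  odd <- seq(1, nrow(fs), 2)
  tab <- build_fdr_table(fs[odd, ], default_weights())
  test <- fs[-odd, ]
  sc <- ldeconv:::score_feature_table(test, default_weights())
  pred <- local_fdr(sc, test$k, tab)
  bin <- floor(sc / 0.02)
  key <- paste(ldeconv:::group_of(test$k), bin)
  emp <- tapply(!test$label, key, mean)
  n <- tapply(sc, key, length)
  prd <- tapply(pred, key, function(x) x[1])
  big <- n >= 200
  expect_gt(sum(big), 50)
  expect_lt(mean(abs(emp[big] - prd[big])), 0.05)
  expect_lt(max(abs(emp[big] - prd[big])), 0.2)
})

test_that("labeled match tables round-trip through TSV", {
  fs <- simulate_feature_set(default_weights(), n_per_group = 50, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f)
  back$label <- as.logical(back$label)
  expect_equal(back$mz_dist, fs$mz_dist, tolerance = 1e-9)
  expect_identical(back$label, fs$label)
})
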