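# Noise estimation, peak matching, top-3 scaling, candidate filters,
# supporting / neutral-loss annotation.

test_that("estimate_noise_level returns the most populated bin's upper edge", {
  sp <- new_spectrum(mz = seq_len(105), intensity = c(rep(1, 100), rep(100, 5)))
  nl <- estimate_noise_level(sp)
  expect_lt(nl, 100)
  expect_gt(sum(sp$peaks$intensity > nl), 0)       # the 5 tall peaks survive
  expect_true(all(sp$peaks$intensity[sp$peaks$intensity > nl] == 100))
  # all identical intensities: level equals that value, zero signal peaks
  sp2 <- new_spectrum(mz = 1:10, intensity = rep(7, 10))
  expect_equal(estimate_noise_level(sp2), 7)
  expect_equal(sum(sp2$peaks$intensity > estimate_noise_level(sp2)), 0L)
  # single peak
  sp3 <- new_spectrum(500, 123)
  expect_gte(estimate_noise_level(sp3), 123 / 100)
  expect_error(estimate_noise_level(new_spectrum(numeric(0), numeric(0))),
               "empty")
})

test_that("match_peaks takes the nearest peak in tolerance else placeholders", {
  d <- structure(list(mz = c(500, 500.5, 501), prob = c(0.3, 0.5, 0.2),
                      shift = 0:2, z = 2L, mono_mass = 997.5,
                      most_abundant = 2L), class = "theo_dist")
  sp <- new_spectrum(c(500, 500.5, 501), c(30, 50, 20))
  ee <- match_peaks(d, sp)
  expect_false(any(ee$placeholder))
  expect_equal(ee$mz, d$mz)
  expect_equal(ee$peak_index, 1:3)
  # nothing in tolerance: all placeholders at theoretical m/z, intensity 0
  sp2 <- new_spectrum(c(490, 495), c(10, 10))
  ee2 <- match_peaks(d, sp2)
  expect_true(all(ee2$placeholder))
  expect_equal(ee2$mz, d$mz)
  expect_true(all(ee2$intensity == 0))
  # two peaks in tolerance: the nearer wins
  sp3 <- new_spectrum(c(500.496, 500.508), c(10, 99))
  d1 <- structure(list(mz = 500.5, prob = 1, shift = 0L, z = 1L,
                       mono_mass = 499.5, most_abundant = 1L),
                  class = "theo_dist")
  ee3 <- match_peaks(d1, sp3)
  expect_equal(ee3$mz, 500.496)
})

test_that("scale_theoretical applies the top-3 ratio and sub-noise pruning", {
  d <- structure(list(mz = c(500, 501, 502), prob = c(0.5, 0.3, 0.2),
                      shift = 0:2, z = 1L, mono_mass = 499,
                      most_abundant = 1L), class = "theo_dist")
  ee <- list(mz = c(500, 501, 502), intensity = c(50, 30, 20),
             placeholder = rep(FALSE, 3), peak_index = 1:3)
  m <- scale_theoretical(d, ee, noise = 0)
  expect_equal(m$theo_int, c(50, 30, 20))           # ratio = 100 / 1.0
  expect_equal(m$k, 3L)
  # noise 25: scaled peaks at or below 25 are removed in lockstep
  m2 <- scale_theoretical(d, ee, noise = 25)
  expect_equal(m2$k, 2L)
  expect_equal(m2$theo_int, c(50, 30))
  expect_equal(m2$exp_int, c(50, 30))
  # fewer than 3 peaks: ratio over all peaks
  d2 <- structure(list(mz = c(500, 501), prob = c(0.6, 0.4), shift = 0:1,
                       z = 1L, mono_mass = 499, most_abundant = 1L),
                  class = "theo_dist")
  ee2 <- list(mz = c(500, 501), intensity = c(90, 10),
              placeholder = c(FALSE, FALSE), peak_index = 1:2)
  m3 <- scale_theoretical(d2, ee2, noise = 0)
  expect_equal(sum(m3$theo_int), 100)
  # all top-3 counterparts are placeholders: unmatchable
  ee3 <- list(mz = c(500, 501, 502), intensity = c(0, 0, 0),
              placeholder = rep(TRUE, 3), peak_index = rep(NA_integer_, 3))
  expect_null(scale_theoretical(d, ee3, noise = 0))
})

test_that("missing-peak filters implement the four rejection clauses", {
  # 12 toy envelopes: `pattern` marks MATCHED positions; survival computed
  # by hand from the four quoted clauses (missing >= 3; k=3 & missing=2;
  # k=2 & missing=1; longest matched run < k-3)
  tbl <- list(
    list(pattern = c(TRUE, TRUE, FALSE, TRUE, TRUE),  ok = TRUE),  # k5 m1 run2? runs 2,2 -> 2 >= 2
    list(pattern = c(FALSE, FALSE, FALSE, TRUE, TRUE), ok = FALSE), # m3
    list(pattern = c(TRUE, TRUE), ok = TRUE),                       # k2 m0
    list(pattern = c(TRUE, FALSE), ok = FALSE),                     # k2 m1
    list(pattern = c(TRUE, FALSE, FALSE), ok = FALSE),              # k3 m2
    list(pattern = c(TRUE, TRUE, FALSE), ok = TRUE),                # k3 m1
    list(pattern = c(FALSE, TRUE, TRUE, FALSE), ok = TRUE),         # k4 m2 run2>=1
    list(pattern = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE), ok = FALSE), # run2<3
    list(pattern = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE), ok = TRUE),  # run3>=3
    list(pattern = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), ok = TRUE),  # run4>=3
    list(pattern = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), ok = TRUE), # run5>=4
    list(pattern = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE), ok = FALSE) # run4<5
  )
  for (case in tbl) {
    matched <- case$pattern
    m <- make_match(theo_int = rep(100, length(matched)),
                    exp_int = ifelse(matched, 100, 0),
                    placeholder = !matched)
    expect_identical(passes_filters(m), case$ok,
                     label = paste("pattern", paste(as.integer(matched),
                                                    collapse = "")))
  }
})

test_that("generate_candidates finds a clean planted envelope and skips noise", {
  cfg <- sim_config(n_ions = 1, mass_range = c(3000, 3000),
                    charge_range = c(3, 3), intensity_sigma = 0,
                    mz_jitter_ppm = 0, dropout = 0, noise_density = 50,
                    multi_charge = 0, seed = 21)
  sim <- simulate_spectrum(cfg)
  cand <- generate_candidates(sim$spectrum, max_charge = 5)
  expect_gt(length(cand), 0)
  zs <- vapply(cand, `[[`, integer(1), "z")
  masses <- vapply(cand, `[[`, numeric(1), "mono_mass")
  hit <- match_masses(masses, sim$truth$mass)
  expect_true(any(hit & zs == 3L))
  # pure noise below the signal threshold yields nothing
  sp <- new_spectrum(mz = seq(400, 500, length.out = 50),
                     intensity = rep(5, 50))
  expect_length(generate_candidates(sp, max_charge = 5), 0L)
})

test_that("noiseless non-overlapping spectra recover every planted ion", {
  cfg <- sim_config(n_ions = 6, mass_range = c(1000, 12000),
                    charge_range = c(1, 12), intensity_sigma = 0,
                    mz_jitter_ppm = 0, dropout = 0, noise_density = 0,
                    multi_charge = 0, avoid_overlap = TRUE, seed = 31)
  sim <- simulate_spectrum(cfg)
  cand <- generate_candidates(sim$spectrum, max_charge = 12)
  masses <- vapply(cand, `[[`, numeric(1), "mono_mass")
  expect_true(all(match_masses(sim$truth$mass, masses)))
})

test_that("annotate_support counts same-mass other-charge and loss partners", {
  m1 <- make_match(c(60, 40), c(60, 40), z = 2, mono_mass = 2000)
  m2 <- make_match(c(60, 40), c(60, 40), z = 3, mono_mass = 2000)
  ann <- annotate_support(list(m1, m2))
  expect_equal(ann[[1]]$f_support, 1L)
  expect_equal(ann[[2]]$f_support, 1L)
  # symmetric, and a +1-isotope error still counts as the same mass
  m3 <- make_match(c(60, 40), c(60, 40), z = 4, mono_mass = 2000 + 1.00235)
  ann2 <- annotate_support(list(m1, m3))
  expect_equal(ann2[[1]]$f_support, 1L)
  expect_equal(ann2[[2]]$f_support, 1L)
  # water-loss partner
  m4 <- make_match(c(60, 40), c(60, 40), z = 2, mono_mass = 2000 - 18.01056)
  ann3 <- annotate_support(list(m1, m4))
  expect_equal(ann3[[1]]$f_loss, 1L)
  expect_equal(ann3[[2]]$f_loss, 0L)
  # same mass, same charge: no self-support
  ann4 <- annotate_support(list(m1))
  expect_equal(ann4[[1]]$f_support, 0L)
  expect_equal(ann4[[1]]$f_loss, 0L)
})
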