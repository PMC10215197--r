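mk_truth <- function(fmax = 0.9, K = 2.5, hill = 1, basal = 0,
                     firr = 0, n = 1, detect = 1) {
  data.frame(
    site_id = sprintf("T%03d_C1", seq_len(n)),
    protein_id = sprintf("T%03d", seq_len(n)), residue = 1L,
    peptide = "X", fmax_rev = fmax, K = K, hill = hill, basal_ox = basal,
    firr_frac = firr, detect_isotop = detect, detect_oxicat = detect,
    sensitivity_class = NA_character_, stringsAsFactors = FALSE
  )
}

test_that("oxidized_fraction follows the Hill dose response", {
  tr <- mk_truth(fmax = 0.9, K = 2.5, hill = 1, basal = 0)
  expect_equal(oxidized_fraction(tr, 0), 0)
  expect_equal(oxidized_fraction(tr, 2.5), 0.45)  # half-saturation
  expect_equal(oxidized_fraction(tr, 10), 0.9 * 10 / 12.5)  # 0.72
  # basal shifts the curve, monotone non-decreasing
  trb <- mk_truth(fmax = 0.5, K = 1, basal = 0.2)
  cc <- seq(0, 50, by = 0.5)
  f <- oxidized_fraction(trb, cc)
  expect_equal(f[1], 0.2)
  expect_true(all(diff(f) >= 0))
  expect_error(oxidized_fraction(mk_truth(K = 0), 1), "K")
  expect_error(oxidized_fraction(tr, -1), "non-negative")
})

test_that("simulate_isotop emits the closed-form ratio at zero noise", {
  tr <- mk_truth(fmax = 0, basal = 0)
  obs <- simulate_isotop(tr, c(ctrl = 0), n_replicates = 1,
                         noise_cv = 0, dropout_rate = 0, seed = 1)
  expect_equal(obs$ratio_LH, 1)
  tr <- mk_truth(fmax = 0.5, K = 1, hill = 1)
  obs <- simulate_isotop(tr, c(big = 1e9), n_replicates = 1,
                         noise_cv = 0, dropout_rate = 0, seed = 1)
  expect_equal(obs$ratio_LH, 2, tolerance = 1e-6)  # 1/(1-0.5)
  expect_error(simulate_isotop(tr, c(a = 1), n_replicates = 0),
               "n_replicates")
})

test_that("Monte-Carlo mean ratio matches the closed form within 5%", {
  tr <- mk_truth(fmax = 0.9, K = 1e-9, n = 1000)  # f_total ~ 0.9 at 1 mM
  obs <- simulate_isotop(tr, c(x = 1), n_replicates = 1, noise_cv = 0.2,
                         dropout_rate = 0, seed = 42, cap = 1e9)
  expect_equal(mean(obs$ratio_LH), 10, tolerance = 0.05)
})

test_that("full-oxidation censoring removes saturated sites", {
  tr <- mk_truth(fmax = 0.99, K = 1e-9)
  obs <- simulate_isotop(tr, c(x = 1), n_replicates = 2, noise_cv = 0,
                         dropout_rate = 0, seed = 1)
  expect_equal(nrow(obs), 0)
  # just under the threshold the site is kept
  tr$fmax_rev <- 0.97
  obs <- simulate_isotop(tr, c(x = 1), n_replicates = 2, noise_cv = 0,
                         dropout_rate = 0, seed = 1)
  expect_equal(nrow(obs), 2)
})

test_that("isotop round-trip recovers f_total exactly at zero noise", {
  set.seed(5)
  f <- runif(50, 0, 0.95)
  tr <- mk_truth(fmax = 0, K = 1, basal = f, n = 50)
  obs <- simulate_isotop(tr, c(x = 0), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1, cap = 1e9)
  fx <- f[match(obs$site_id, tr$site_id)]
  expect_equal(implied_oxidation(obs$ratio_LH), 100 * fx,
               tolerance = 1e-9)
})

test_that("oxicat channel model reflects reversible share only", {
  # f_rev 0.5, f_irr 0 -> 50%
  tr <- mk_truth(fmax = 0, K = 1, basal = 0.5, firr = 0)
  obs <- simulate_oxicat(tr, c(x = 0), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1)
  expect_equal(percent_oxidation(obs$ratio_LH, "LH"), 50,
               tolerance = 1e-9)
  # f_total 0.7 split 3:4 rev:irr -> 0.3/(0.3+0.3) = 50%
  tr <- mk_truth(fmax = 0, K = 1, basal = 0.7, firr = 4 / 7)
  obs <- simulate_oxicat(tr, c(x = 0), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1)
  expect_equal(percent_oxidation(obs$ratio_LH, "LH"), 50,
               tolerance = 1e-9)
  # fully reduced site: heavy channel empty, ratio capped high -> ~0%
  tr <- mk_truth(fmax = 0, firr = 0)
  obs <- simulate_oxicat(tr, c(x = 0), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1, cap = 1e9)
  expect_lt(percent_oxidation(obs$ratio_LH, "LH"), 1e-6)
})

test_that("oxicat round-trip equals 100*f_rev/(1-f_irr) at zero noise", {
  set.seed(9)
  n <- 40
  f <- runif(n, 0.05, 0.9)
  firr <- runif(n, 0, 0.5)
  tr <- mk_truth(fmax = 0, K = 1, basal = f, firr = firr, n = n)
  obs <- simulate_oxicat(tr, c(x = 0), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1, cap = 1e12)
  i <- match(obs$site_id, tr$site_id)
  f_irr <- firr[i] * f[i]
  f_rev <- f[i] - f_irr
  expect_equal(percent_oxidation(obs$ratio_LH, "LH"),
               100 * f_rev / (1 - f_irr), tolerance = 1e-9)
})

test_that("identical seeds reproduce, different seeds differ", {
  tr <- simulate_truth(50, seed = 3)
  a <- simulate_isotop(tr, c(x = 5), seed = 7)
  b <- simulate_isotop(tr, c(x = 5), seed = 7)
  c <- simulate_isotop(tr, c(x = 5), seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ratio_LH,
                                c$ratio_LH[seq_len(nrow(a))])))
  # truth generation is deterministic too
  expect_identical(tr, simulate_truth(50, seed = 3))
})

test_that("simulate_truth honors its invariants", {
  tr <- simulate_truth(500, seed = 2)
  expect_true(all(tr$basal_ox + tr$fmax_rev <= 1 + 1e-12))
  expect_true(all(tr$K > 0))
  expect_true(all(tr$firr_frac >= 0 & tr$firr_frac <= 1))
  # class is the documented deterministic function of the parameters
  r_top <- 1 / (1 - oxidized_fraction(tr, 10))
  want <- ifelse(r_top >= 5, "high",
                 ifelse(r_top >= 2, "moderate", "resistant"))
  expect_equal(tr$sensitivity_class, want)
})

test_that("chromatogram traces integrate back to the generating areas", {
  tr <- mk_truth(fmax = 0.5, K = 1e-9)
  obs <- simulate_isotop(tr, c(x = 1), n_replicates = 1, noise_cv = 0,
                         dropout_rate = 0, seed = 1)
  ch <- simulate_chromatograms(obs, peak_sigma = 2,
                               sampling_interval = 0.05, seed = 1)
  li <- ch[ch$channel == "LIGHT", ]
  hv <- ch[ch$channel == "HEAVY", ]
  expect_equal(integrate_eic(li$time_s, li$intensity, baseline = FALSE),
               obs$light_area, tolerance = 5e-3)
  expect_equal(integrate_eic(hv$time_s, hv$intensity, baseline = FALSE),
               obs$heavy_area, tolerance = 5e-3)
  # co-elution: both channels share an apex
  expect_equal(li$time_s[which.max(li$intensity)],
               hv$time_s[which.max(hv$intensity)])
  expect_error(simulate_chromatograms(obs, peak_sigma = 1,
                                      sampling_interval = 2),
               "sampling_interval")
})
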