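test_that("switching function matches its closed form and stated values", {
  p <- contact_params()  # r0 = 0.3 nm, n = 6, m = 12
  expect_equal(switching_value(0, p), 1)
  expect_equal(switching_value(0.3, p), 0.5)        # removable singularity limit n/m
  expect_equal(switching_value(0.6, p), 63 / 4095)  # (1-64)/(1-4096)

  set.seed(1)
  r <- runif(1e4, 0, 2)
  expect_lt(max(abs(switching_value(r, p) - 1 / (1 + (r / p$r0)^6))), 1e-12)

  # bounded in (0, 1]; strictly decreasing once (r/r0)^6 is representable
  # (below r ~ 0.02 nm the ratio underflows and c(r) is exactly 1 in doubles)
  v <- switching_value(seq(0, 2, length.out = 1e4), p)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(switching_value(seq(0.05, 2, length.out = 1e4), p)) < 0))

  expect_error(switching_value(-0.1, p), "non-negative")
})

test_that("general exponents use the explicit n/m limit at r0", {
  p <- contact_params(r0 = 0.5, n = 4L, m = 10L)
  expect_equal(switching_value(0.5, p), 4 / 10)
  x <- 0.8 / 0.5
  expect_equal(switching_value(0.8, p), (1 - x^4) / (1 - x^10))
})

test_that("coordination number sums switching values over H-ring pairs", {
  tr <- aromatic_fixture_trajectory()
  fc <- frame_coords(tr, 1)
  params <- contact_params()
  phe <- detect_aromatic_rings(tr, "PHE")
  donors <- infer_ch_donors(tr)

  # place the single donor H exactly 0.3 nm above the Phe ring center
  h <- donors[[1]]$hydrogen_index
  fc[h, ] <- c(1, 0, 0.3)
  expect_equal(coordination_number(fc, phe, donors, params), 0.5)

  # Trp with the H 0.3 nm from both ring centers contributes 0.5 + 0.5
  trp <- detect_aromatic_rings(tr, "TRP")
  c6 <- ring_center(trp[[1]], fc); c5 <- ring_center(trp[[2]], fc)
  mid <- (c6 + c5) / 2
  dvec <- c5 - c6
  half2 <- sum(dvec^2) / 4
  dhat <- dvec / sqrt(sum(dvec^2))
  u <- c(0, 0, 1) - sum(c(0, 0, 1) * dhat) * dhat
  u <- u / sqrt(sum(u^2))            # on the bisector plane of the two centers
  fc[h, ] <- mid + u * sqrt(0.3^2 - half2)
  expect_equal(coordination_number(fc, trp, donors, params), 1.0,
               tolerance = 1e-10)

  # zero donors is an empty sum; zero rings is undefined
  expect_equal(coordination_number(fc, phe, list(), params), 0)
  expect_error(coordination_number(fc, list(), donors, params), "no aromatic ring")
})

test_that("optimized coordination equals a brute-force double loop", {
  tr <- aromatic_fixture_trajectory()
  params <- contact_params()
  rings <- detect_aromatic_rings(tr, "TRP")
  donors <- infer_ch_donors(tr)
  set.seed(7)
  for (k in 1:50) {
    fc <- frame_coords(tr, 1) + matrix(rnorm(nrow(tr$topology) * 3, sd = 0.3),
                                       ncol = 3)
    expect_lt(abs(coordination_number(fc, rings, donors, params) -
                    brute_coordination(fc, rings, donors, params)), 1e-10)
  }
})

test_that("coordination number is additive over donors and rigid-invariant", {
  sim <- generate_two_state_trajectory(n_frames = 1L, seed = 5L,
                                       positional_noise_sd = 0)
  tr <- sim$trajectory
  params <- contact_params()
  rings <- detect_aromatic_rings(tr, "PHE")
  donors <- infer_ch_donors(tr)
  fc <- frame_coords(tr, 1)
  # duplicate the donor: value doubles
  v1 <- coordination_number(fc, rings, donors, params)
  v2 <- coordination_number(fc, rings, c(donors, donors), params)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)

  set.seed(11)
  for (k in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    vR <- coordination_number(apply_rigid(fc, R, t), rings, donors, params)
    expect_equal(vR, v1, tolerance = 1e-10)
  }

  # scale property: doubling r0 and all coordinates changes nothing
  p2 <- contact_params(r0 = 2 * params$r0)
  expect_equal(coordination_number(2 * fc, rings, donors, p2), v1,
               tolerance = 1e-12)
})

test_that("contact time series is deterministic and guards its preconditions", {
  sim <- generate_two_state_trajectory(n_frames = 5L, occupancy = 1,
                                       positional_noise_sd = 0, seed = 2L)
  tr <- sim$trajectory
  s <- contact_timeseries(tr, "A:23")
  expect_length(s$values, 5L)
  expect_true(all(abs(s$values - s$values[1]) < 1e-12))  # identical frames

  expect_error(contact_timeseries(tr, "A:23", donors = list()), "no C-H donors")
  # the glycan residue has no aromatic ring
  expect_error(contact_timeseries(tr, "G:1"), "no aromatic ring")
})

test_that("mean_contacts averages after burn-in", {
  s <- structure(list(residue_key = NULL, values = c(1, 2, 3, 4),
                      time_step_ns = NA_real_), class = "contact_series")
  expect_equal(mean_contacts(s), 2.5)
  expect_equal(mean_contacts(s, burn_in_frames = 2L), 3.5)
  expect_error(mean_contacts(s, burn_in_frames = 4L), "no frames")
})

test_that("contact distributions use half-open bins and round-half-even counts", {
  s <- structure(list(values = rep(0.5, 100), time_step_ns = NA_real_),
                 class = "contact_series")
  d <- contact_distribution(s, bin_width = 0.25)
  # all mass in the [0.5, 0.75) bin
  expect_equal(d$counts[3], 100L)
  expect_equal(sum(d$counts), 100L)

  s2 <- structure(list(values = c(0.4, 0.6, 1.4), time_step_ns = NA_real_),
                  class = "contact_series")
  d2 <- contact_distribution(s2, bin_width = 0.5)
  expect_equal(d2$integer_counts, c("0" = 1L, "1" = 2L))
  expect_equal(sum(d2$integer_counts), 3L)
  # densities integrate to 1
  expect_equal(sum(d2$densities) * 0.5, 1)
})
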