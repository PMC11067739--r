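# Debye sums: closed forms, self/distinct split, histogram acceleration,
# periodic minimum-image convention and the continuation correction.

test_that("closed forms: single atom and homonuclear diatomic", {
  q <- default_q_grid(0.5, 25, 0.05)
  fr1 <- frame("C", matrix(0, 1, 3))
  expect_equal(debye_intensity(fr1, q, mode = "exact")$values,
               atomic_form_factor("C", q)^2, tolerance = 1e-12)
  d <- 1.5
  fr2 <- frame(c("O", "O"), rbind(c(0, 0, 0), c(d, 0, 0)))
  f <- atomic_form_factor("O", q)
  ref <- 2 * f^2 * (1 + sin(q * d) / (q * d))
  for (m in c("exact", "histogram"))
    expect_equal(debye_intensity(fr2, q, mode = m)$values, ref,
                 tolerance = 1e-10)
})

test_that("the Q->0 sinc limit gives the squared total electron count", {
  fr <- frame(c("H", "H", "O"),
              rbind(c(0, 0, 0), c(0.95, 0, 0), c(0.3, 0.9, 0)))
  i0 <- debye_intensity(fr, 1e-9, mode = "exact")$values
  expect_lt(abs(i0 - 100) / 100, 2e-3)  # (1+1+8)^2, IAM table precision
})

test_that("histogram mode matches the brute-force double sum on a cluster", {
  fr <- rand_cluster(50, seed = 7, box = 12)
  q <- default_q_grid(0.5, 25, 0.02)
  ie <- debye_intensity(fr, q, mode = "exact")$values
  ih <- debye_intensity(fr, q, mode = "histogram")$values
  expect_lt(sqrt(sum((ih - ie)^2) / sum(ie^2)), 1e-3)
})

test_that("self + distinct recomposes the full Debye sum", {
  fr <- rand_cluster(20, seed = 2)
  q <- default_q_grid(0.5, 25, 0.1)
  full <- debye_intensity(fr, q, mode = "exact")$values
  parts <- self_scattering(fr, q)$values +
           distinct_intensity(fr, q, mode = "exact")$values
  expect_equal(parts, full, tolerance = 1e-12)
  expect_equal(self_scattering(frame(c("H", "H", "O"), matrix(0, 3, 3) +
                                     diag(3)), 0)$values, 66,
               tolerance = 1e-2)
})

test_that("set-pair intensities are exchange symmetric and additive", {
  set.seed(5)
  n <- 30
  fr <- frame(sample(c("C", "O"), n, TRUE), matrix(runif(3 * n, 0, 8), n, 3),
              cell = c(8, 8, 8),
              labels = sample(c("solute", "solvent"), n, TRUE))
  q <- default_q_grid(0.5, 25, 0.1)
  for (m in c("exact", "histogram")) {
    iuv <- debye_intensity(fr, q, "solute", "solvent", mode = m)$values
    ivu <- debye_intensity(fr, q, "solvent", "solute", mode = m)$values
    expect_equal(iuv, ivu, tolerance = 1e-12)
    # Eq.-(5)-style additivity: machine precision for the exact sums;
    # histogram estimators of the set pairs regroup bin means, so they
    # recompose the all-atom estimate to binning precision
    id_all <- distinct_intensity(fr, q, mode = m)$values
    id_sum <- distinct_intensity(fr, q, "solute", mode = m)$values +
              2 * iuv +
              distinct_intensity(fr, q, "solvent", mode = m)$values
    tol <- if (m == "exact") 1e-12 else 1e-5
    expect_lt(max(abs(id_sum - id_all)) / max(abs(id_all)), tol)
  }
})

test_that("pair histograms follow the stated binning and image conventions", {
  fr <- frame(c("C", "C"), rbind(c(0, 0, 0), c(1.55, 0, 0)))
  ph <- pair_histogram(fr, bin_width = 0.1)
  expect_equal(sum(ph$total_counts), 1)
  bin <- findInterval(1.55, ph$edges)
  expect_equal(ph$total_counts[bin], 1)
  # periodic image: fractional (0.05, 0, 0) vs (0.95, 0, 0) in a 10 A box
  frp <- frame(c("O", "O"), rbind(c(0.5, 0, 0), c(9.5, 0, 0)),
               cell = c(10, 10, 10))
  php <- pair_histogram(frp, bin_width = 0.1)
  expect_equal(which(php$total_counts > 0), 11L)  # bin [1.0, 1.1)
  expect_error(pair_histogram(frp, bin_width = 100), "exceeds")
  # cross-set counts sum to N_A * N_B when everything is in range
  set.seed(1)
  n <- 12
  frc <- frame(rep(c("C", "O"), each = n / 2),
               matrix(runif(3 * n, 0, 3), n, 3),
               labels = rep(c("solute", "solvent"), each = n / 2))
  ph2 <- pair_histogram(frc, "solute", "solvent", bin_width = 0.05)
  expect_equal(sum(ph2$total_counts) + sum(ph2$overlap), 36)
})

test_that("ensemble averaging is the uniform frame mean with standard errors", {
  q <- default_q_grid(0.5, 25, 0.2)
  f1 <- rand_cluster(10, seed = 3)
  f2 <- rand_cluster(10, seed = 4)
  e1 <- ensemble(list(f1, f1), "sample_B", strict = FALSE)
  expect_equal(ensemble_intensity(e1, q)$values,
               debye_intensity(f1, q)$values, tolerance = 1e-12)
  expect_equal(max(ensemble_intensity(e1, q)$se), 0)
  e2 <- ensemble(list(f1, f2), "sample_B", strict = FALSE)
  expect_equal(ensemble_intensity(e2, q)$values,
               (debye_intensity(f1, q)$values +
                debye_intensity(f2, q)$values) / 2, tolerance = 1e-12)
  bad <- ensemble(list(f1, rand_cluster(11, seed = 5)), "sample_B",
                  strict = FALSE)
  bad$strict <- TRUE
  expect_error(ensemble_intensity(bad, q), "inconsistent atom counts")
})

test_that("corrected distinct scattering of an uncorrelated box vanishes statistically", {
  model <- solvent_model(sigma = 0, density = 0.1, max_disp = 1.0)
  ens <- sample_solvent_box(model, 128, 12, equilibration_sweeps = 20,
                            stride = 5, seed = 3)
  q <- default_q_grid(0.5, 25, 0.1)
  ig <- ensemble_intensity(ens, q, distinct = TRUE)
  z <- ig$values / ig$se
  expect_lt(sqrt(mean(z^2)), 2)      # consistent with pure noise
  expect_lt(max(abs(z)), 6)
  # and the magnitude shrinks roughly like 1/sqrt(frames)
  ig4 <- ensemble_intensity(ensemble(ens$frames[1:4], "sample_B"), q,
                            distinct = TRUE)
  expect_lt(sqrt(mean(ig$values^2)), sqrt(mean(ig4$values^2)))
})

test_that("coincident atoms across sets fall back to the analytic sinc limit", {
  fr <- frame(c("C", "O"), rbind(c(1, 1, 1), c(1, 1, 1)),
              labels = c("solute", "solvent"))
  q <- c(1, 5, 20)
  expect_warning(iv <- debye_intensity(fr, q, "solute", "solvent",
                                       mode = "histogram")$values,
                 "coincident")
  expect_equal(iv, atomic_form_factor("C", q) * atomic_form_factor("O", q),
               tolerance = 1e-12)
})
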