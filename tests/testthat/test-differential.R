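# Differential distinct scattering, solute-power normalization and the
# exact component decomposition.

test_that("identical samples give a vanishing differential", {
  ens <- ensemble(list(rand_cluster(15, seed = 1)), "sample_B")
  ens_a <- ensemble(ens$frames, "sample_A")
  q <- default_q_grid(0.5, 25, 0.1)
  d <- differential_distinct(ens_a, ens, q, mode = "exact")
  expect_equal(d$values, rep(0, length(q)), tolerance = 1e-14)
})

test_that("toy differential equals hand-computed Debye sums", {
  # A: C at origin, O at (2,0,0), O at (0,1.2,0); B: two O at distance 1.2
  q <- default_q_grid(0.5, 25, 0.1)
  fa <- frame(c("C", "O", "O"),
              rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.2, 0)),
              labels = c("solute", "solvent", "solvent"))
  fb <- frame(c("O", "O"), rbind(c(0, 0, 0), c(0, 1.2, 0)))
  d <- differential_distinct(ensemble(list(fa), "sample_A"),
                             ensemble(list(fb), "sample_B"), q,
                             mode = "exact")
  fc <- atomic_form_factor("C", q); fo <- atomic_form_factor("O", q)
  snc <- function(r) sin(q * r) / (q * r)
  r23 <- sqrt(4 + 1.44)
  ref <- 2 * (fc * fo * snc(2) + fc * fo * snc(1.2) + fo^2 * snc(r23)) -
         2 * fo^2 * snc(1.2)
  expect_equal(d$values, ref, tolerance = 1e-10)
})

test_that("reduce_to_dF applies the solute-power normalization linearly", {
  q <- default_q_grid(0.5, 25, 0.1)
  zero <- curve_record(q, rep(0, length(q)), "intensity")
  expect_equal(reduce_to_dF(zero, c("C", "O"))$values, rep(0, length(q)))
  cur <- curve_record(q, sin(q), "intensity")
  f1 <- reduce_to_dF(cur, c("Ru", "Cl"))
  f2 <- reduce_to_dF(2 * cur, c("Ru", "Cl"))
  expect_equal(2 * f1$values, f2$values, tolerance = 1e-14)
  expect_error(reduce_to_dF(cur, character(0)), "empty")
  # on an isolated solute the reduction reproduces the standard F(Q)
  d <- 2.0
  fr <- frame(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  idist <- distinct_intensity(fr, q, mode = "exact")
  fq <- reduce_to_dF(idist, fr$elements)
  fC <- atomic_form_factor("C", q)
  expect_equal(fq$values, q * 2 * fC^2 * (sin(q * d) / (q * d)) / (2 * fC^2),
               tolerance = 1e-10)
})

test_that("decomposition closes exactly and partitions dvv by construction", {
  dec <- small_decomposition()
  expect_named(dec$components, c("uu", "uv", "dvv", "x", "restructure"))
  expect_lt(dec$closure_residual, 1e-10)
  expect_lt(dec$closure_dvv, 1e-12)
  # explicit recomputation of both identities
  s <- with(dec$components,
            uu$values + uv$values + dvv$values - dec$total$values)
  expect_lt(max(abs(s)) / max(abs(dec$total$values)), 1e-10)
  s2 <- with(dec$components,
             dvv$values - (restructure$values - x$values))
  expect_lt(max(abs(s2)) / max(abs(dec$total$values)), 1e-12)
})

test_that("without droplet labels dvv is returned undecomposed and flagged", {
  s <- small_system()
  dec <- decompose_dF(s$a, s$b, droplet = NULL,
                      q = default_q_grid(0.5, 25, 0.25))
  expect_true(dec$undecomposed_dvv)
  expect_false("x" %in% names(dec$components))
})

test_that("the zero-volume-fraction limit kills every component exactly", {
  s <- small_system()
  a0 <- build_solution_box(s$b, NULL)   # A is B relabelled
  q <- default_q_grid(0.5, 25, 0.25)
  # droplet labelling against a vanishing solute criterion flags nothing
  tiny <- frame("H", matrix(rep(s$b$frames[[1]]$cell[1] / 2, 3), 1, 3))
  dl <- label_droplet(s$b, tiny, radii = c(H = 1e-6), seed = 2)
  expect_equal(dl$mean_n_x, 0)
  dec <- decompose_dF(a0, s$b, dl, q = q,
                      solute_elements = s$solute$elements)
  for (nm in names(dec$components))
    expect_equal(dec$components[[nm]]$values, rep(0, length(q)),
                 tolerance = 1e-14, info = nm)
  expect_equal(dec$total$values, rep(0, length(q)), tolerance = 1e-14)
})

test_that("the solute-fills-the-box limit has no restructuring and dvv = -x", {
  sol <- solute_fixture("tetrahedral")
  L <- 8
  fa <- frame(sol$elements, sweep(sol$xyz, 2, rep(L / 2, 3), `+`),
              cell = rep(L, 3), labels = rep("solute", 5),
              mol_id = rep(1L, 5))
  set.seed(9)
  fb <- frame(rep("O", 20), matrix(runif(60, 0, L), 20, 3),
              cell = rep(L, 3), labels = rep("solvent", 20), mol_id = 1:20)
  all_droplet <- label_droplet(ensemble(list(fb), "sample_B"), fa,
                               radii = c(C = L, Cl = L, O = 1.5),
                               placement = "center_fixed", seed = 1)
  expect_equal(all_droplet$counts, 20)  # everything excluded
  dec <- decompose_dF(ensemble(list(fa), "sample_A"),
                      ensemble(list(fb), "sample_B"), all_droplet,
                      q = default_q_grid(0.5, 25, 0.1))
  expect_equal(dec$components$restructure$values,
               rep(0, length(dec$q)), tolerance = 1e-14)
  expect_equal(dec$components$dvv$values, -dec$components$x$values,
               tolerance = 1e-14)
})

test_that("the ideal-dilute restructuring term is statistically null", {
  dec <- small_decomposition()
  nt <- restructure_null_test(dec, n_perm = 200, seed = 5)
  expect_identical(nt$variant, "paired sign-flip")
  expect_gt(nt$p_value, 0.05)
  no_frames <- decompose_dF(small_system()$a, small_system()$b,
                            small_system()$droplet,
                            q = default_q_grid(0.5, 25, 0.5),
                            keep_frames = FALSE)
  expect_error(restructure_null_test(no_frames), "per-frame")
})

test_that("scale_and_subtract fits, fixes and rejects degenerate scales", {
  q <- seq(1, 10, by = 0.1)
  b <- curve_record(q, exp(-q / 3) + 0.2 * sin(q), "intensity")
  a <- 2 * b
  d <- scale_and_subtract(a, b)
  expect_equal(d$meta$scale, 2, tolerance = 1e-12)
  expect_equal(d$values, rep(0, length(q)), tolerance = 1e-12)
  plain <- scale_and_subtract(a, b, scale = 1)
  expect_equal(plain$values, a$values - b$values, tolerance = 1e-14)
  # known volume-fraction-style scale recovered from noisy-free synthetic pair
  s_true <- 1 - 0.127
  a2 <- s_true * b
  expect_lt(abs(scale_and_subtract(a2, b)$meta$scale - s_true), 1e-3)
  zero <- curve_record(q, rep(0, length(q)), "intensity")
  expect_error(scale_and_subtract(a, zero), "degenerate")
})
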