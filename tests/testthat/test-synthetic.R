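# The seeded hard-sphere sampler, rigid fixtures and A/B construction.

test_that("solvent sampling is deterministic and respects the hard core", {
  model <- solvent_model()
  e1 <- sample_solvent_box(model, 64, 3, equilibration_sweeps = 30,
                           stride = 10, seed = 17)
  e2 <- sample_solvent_box(model, 64, 3, equilibration_sweeps = 30,
                           stride = 10, seed = 17)
  expect_identical(lapply(e1$frames, `[[`, "xyz"),
                   lapply(e2$frames, `[[`, "xyz"))
  # hard core under minimum image, every frame
  L <- e1$frames[[1]]$cell[1]
  for (fr in e1$frames) {
    ph <- pair_histogram(fr, bin_width = 0.05)
    mid <- ph$edges[-1] - 0.025
    expect_equal(sum(ph$total_counts[mid < model$sigma]), 0)
  }
  # achieved density is exact by construction
  expect_equal(64 / prod(e1$frames[[1]]$cell), model$density,
               tolerance = 1e-12)
})

test_that("infeasible densities fail before any sampling", {
  expect_error(solvent_model(sigma = 3.0, density = 0.1), "infeasible")
  expect_error(sample_solvent_box(solvent_model(sigma = 2.1, density = 0.095),
                                  64, 1), "infeasible")
})

test_that("the rigid 3-site template carries molecules and labels", {
  model <- solvent_model(sigma = 2.5, density = 0.1, atoms_per_molecule = 3)
  ens <- sample_solvent_box(model, 27, 2, equilibration_sweeps = 10,
                            stride = 5, seed = 2)
  fr <- ens$frames[[1]]
  expect_length(fr$elements, 81)
  expect_equal(as.vector(table(fr$elements)), c(54, 27))  # H, O
  expect_equal(length(unique(fr$mol_id)), 27)
  expect_true(all(table(fr$mol_id) == 3))
  # intramolecular geometry is the rigid template
  o <- fr$xyz[fr$elements == "O", ][1, ]
  h <- fr$xyz[fr$mol_id == fr$mol_id[1] & fr$elements == "H", ]
  L <- fr$cell
  dd <- apply(h, 1, function(p) {
    d <- p - o; d <- d - L * round(d / L); sqrt(sum(d^2))
  })
  expect_equal(dd, rep(0.9572, 2), tolerance = 1e-6)
})

test_that("solute fixtures are rigid, labelled and correctly sized", {
  dia <- solute_fixture("diatomic", d = 2.0)
  expect_equal(dist(dia$xyz)[1], 2.0)
  tet <- solute_fixture("tetrahedral")
  expect_length(tet$elements, 5)
  expect_equal(max(abs(dist(tet$xyz[-1, ]) - dist(tet$xyz[-1, ])[1])), 0)
  rub <- solute_fixture("rubpy3cl2")
  expect_length(rub$elements, 63)
  expect_equal(as.vector(table(rub$elements)),
               c(30, 2, 24, 6, 1))  # C, Cl, H, N, Ru
  expect_true(all(rub$labels == "solute"))
  # Ru-N first coordination sphere at the idealized bond length
  dru <- sqrt(rowSums(sweep(rub$xyz[rub$elements == "N", ], 2,
                            rub$xyz[1, ])^2))
  expect_equal(dru, rep(2.06, 6), tolerance = 1e-9)
  # no steric collapse: closest non-bonded approach stays chemical
  expect_gt(min(dist(rub$xyz)), 1.0)
})

test_that("count-matched construction removes exactly the heuristic count", {
  s <- small_system()
  v <- vdw_volume(s$solute, s$radii, "grid", 0.1)
  k <- n_excluded_heuristic(v, 0.1, 1)$molecules
  fr_a <- s$a$frames[[1]]
  expect_equal(sum(fr_a$labels == "solvent"), 128 - k)
  expect_equal(sum(fr_a$labels == "solute"), 5)
  expect_true(all(s$a$metadata$n_deleted == k))
  # the deleted molecules are the nearest ones: every survivor is farther
  # from the solute than the criterion region boundary would require
  expect_identical(s$a$role, "sample_A")
})

test_that("no solute reproduces the reference ensemble exactly", {
  s <- small_system()
  a0 <- build_solution_box(s$b, NULL)
  expect_identical(a0$role, "sample_A")
  expect_identical(lapply(a0$frames, `[[`, "xyz"),
                   lapply(s$b$frames, `[[`, "xyz"))
})

test_that("overlap deletion matches the Poisson expectation on an ideal gas", {
  model <- solvent_model(sigma = 0, density = 0.1, max_disp = 1.0)
  ens <- sample_solvent_box(model, 128, 20, equilibration_sweeps = 20,
                            stride = 5, seed = 4)
  sol <- solute_fixture("tetrahedral")
  radii <- vdw_radii("ff")
  a <- build_solution_box(ens, sol, "overlap", radii = radii, seed = 5)
  v_crit <- vdw_volume(sol, radii, "grid", 0.05)
  lam <- 0.1 * v_crit  # single-site: molecule density = atomic density
  expect_lt(abs(mean(a$metadata$n_deleted) - lam), 4 * sqrt(lam / 20))
  expect_error(build_solution_box(ens, solute_fixture("rubpy3cl2"),
                                  radii = radii), "too small")
})

test_that("the reference fixture wires the whole construction together", {
  run <- reference_run()
  fix <- run$fix
  expect_identical(fix$a$role, "sample_A")
  expect_identical(fix$b$role, "sample_B")
  expect_length(fix$a, 24)
  expect_length(fix$droplet$flags, 24)
  expect_equal(fix$spec$molecules, 65)  # single-site waters-worth of atoms
  expect_equal(sum(fix$a$frames[[1]]$labels == "solute"), 63)
  expect_equal(sum(fix$a$frames[[1]]$labels == "solvent"), 512 - 65)
  expect_true(fix$spec$nu > 0.1 && fix$spec$nu < 0.15)
})

test_that("the excluded term grows with solute volume", {
  model <- solvent_model()
  radii <- vdw_radii("ff")
  b <- sample_solvent_box(model, 512, 6, seed = 21)
  q <- default_q_grid(0.5, 25, 0.1)
  low_q_mag <- function(solute) {
    dl <- label_droplet(b, solute, radii = radii, seed = 22)
    ix <- vapply(seq_along(b$frames), function(k) {
      fr <- b$frames[[k]]; fl <- dl$flags[[k]]
      ixx <- if (sum(fl) > 1)
        distinct_intensity(fr, q, which(fl))$values else rep(0, length(q))
      ixv <- if (sum(fl) > 0 && sum(!fl) > 0)
        distinct_intensity(fr, q, which(fl), which(!fl))$values
        else rep(0, length(q))
      ixx + 2 * ixv
    }, numeric(length(q)))
    mean(abs(rowMeans(ix)[q <= 1.5]))
  }
  m1 <- low_q_mag(solute_fixture("diatomic"))
  m2 <- low_q_mag(solute_fixture("tetrahedral"))
  m3 <- low_q_mag(solute_fixture("rubpy3cl2"))
  expect_lt(m1, m2)
  expect_lt(m2, m3)
})
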