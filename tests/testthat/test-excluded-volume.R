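# Fused-sphere volumes, the excluded-count heuristic and droplet labelling.

test_that("fused-sphere volumes match analytic references", {
  one <- frame("C", matrix(0, 1, 3))
  expect_lt(abs(vdw_volume(one, c(C = 2), "grid", 0.05) - 4 / 3 * pi * 8) /
            (4 / 3 * pi * 8), 5e-3)
  # disjoint spheres are additive
  two <- frame(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_lt(abs(vdw_volume(two, c(C = 1), "grid", 0.05) - 8 * pi / 3) /
            (8 * pi / 3), 5e-3)
  # overlapping unit spheres at d = 1: union from the spherical-lens formula
  ovl <- frame(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
  lens <- pi * (4 * 1 + 1) * (2 * 1 - 1)^2 / 12
  union_ref <- 2 * (4 / 3) * pi - lens
  expect_lt(abs(vdw_volume(ovl, c(C = 1), "grid", 0.02) - union_ref) /
            union_ref, 5e-3)
})

test_that("grid and Monte Carlo volume integrators agree", {
  rub <- solute_fixture("rubpy3cl2")
  vg <- vdw_volume(rub, vdw_radii("ff"), "grid", 0.1)
  vm <- vdw_volume(rub, vdw_radii("ff"), "monte_carlo", n_samples = 1e6,
                   seed = 2)
  expect_lt(abs(vm - vg) / vg, 5e-3)
  expect_true(is.finite(attr(vm, "se")) && attr(vm, "se") > 0)
})

test_that("volumes and flagged counts grow monotonically with radii", {
  sol <- solute_fixture("tetrahedral")
  v1 <- vdw_volume(sol, c(C = 1.7, Cl = 1.75), "grid", 0.1)
  v2 <- vdw_volume(sol, c(C = 1.7, Cl = 2.29), "grid", 0.1)
  expect_gt(v2, v1)
  expect_error(vdw_volume(sol, c(C = 1.7), "grid", 0.1), "Cl")
})

test_that("the excluded-count heuristic is plain bookkeeping", {
  expect_equal(n_excluded_heuristic(0, 0.1)$n_x, 0)
  expect_equal(n_excluded_heuristic(0, 0.1)$molecules, 0L)
  h <- n_excluded_heuristic(100, 0.05, atoms_per_molecule = 1)
  expect_equal(h$n_x, 5)
  expect_equal(h$molecules, 5L)
  expect_error(n_excluded_heuristic(10, -1), "positive")
})

test_that("the 63-atom fixture heuristic reproduces the 22-water construction", {
  rub <- solute_fixture("rubpy3cl2")
  v <- vdw_volume(rub, vdw_radii("ff"), "grid", 0.1)
  expect_equal(n_excluded_heuristic(v, 0.1, 3)$molecules, 22L)
})

test_that("droplet membership follows the criterion radius", {
  L <- 12
  sol <- frame("C", matrix(rep(L / 2, 3), 1, 3))
  # one coincident solvent atom, one far away
  fb <- frame(c("O", "O"), rbind(rep(L / 2, 3), c(0.5, 0.5, 0.5)),
              cell = rep(L, 3), labels = c("solvent", "solvent"),
              mol_id = 1:2)
  fl <- label_droplet_frame(fb, sol, radii = c(C = 1.9, O = 1.5),
                            placement = "center_fixed")
  expect_identical(as.logical(fl), c(TRUE, FALSE))
  # sum-of-radii criterion enlarges the region
  fb2 <- frame("O", matrix(c(L / 2 + 2.4, L / 2, L / 2), 1, 3),
               cell = rep(L, 3), labels = "solvent", mol_id = 1L)
  f_solute <- label_droplet_frame(fb2, sol, radii = c(C = 1.9, O = 1.5),
                                  placement = "center_fixed")
  f_sum <- label_droplet_frame(fb2, sol, radii = c(C = 1.9, O = 1.5),
                               placement = "center_fixed",
                               criterion = "sum_radii")
  expect_false(as.logical(f_solute))
  expect_true(as.logical(f_sum))
  big <- frame(c("C", "C"), rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_error(label_droplet_frame(fb, big, radii = c(C = 1.9, O = 1.5)),
               "does not fit")
})

test_that("flagged counts match a lattice point-in-sphere enumeration", {
  L <- 10
  g <- as.matrix(expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1),
                             z = seq(0.5, 9.5, 1)))
  fb <- frame(rep("O", nrow(g)), g, cell = rep(L, 3),
              labels = rep("solvent", nrow(g)), mol_id = seq_len(nrow(g)))
  sol <- frame("C", matrix(rep(L / 2, 3), 1, 3))
  rad <- 2.7
  fl <- label_droplet_frame(fb, sol, radii = c(C = rad, O = 1),
                            placement = "center_fixed")
  enum <- sum(sqrt(rowSums(sweep(g, 2, rep(L / 2, 3))^2)) <= rad)
  expect_equal(sum(fl), enum)
  # partition: droplet and bulk tile the solvent
  expect_length(fl, nrow(g))
})

test_that("droplet statistics recover the uniform-solvent expectation", {
  model <- solvent_model(sigma = 0, density = 0.1, max_disp = 1.0)
  ens <- sample_solvent_box(model, 128, 20, equilibration_sweeps = 20,
                            stride = 5, seed = 4)
  sol <- solute_fixture("tetrahedral")
  radii <- vdw_radii("ff")
  v_crit <- vdw_volume(sol, radii, "grid", 0.05)
  dl <- label_droplet(ens, sol, radii = radii, seed = 6)
  st <- droplet_statistics(dl, n_x_ref = 0.1 * v_crit)
  # Poisson-placed points: <N_x> = n * V within ~4 sigma of the mean count
  sig <- sqrt(0.1 * v_crit / 20)
  expect_lt(abs(st$mean - 0.1 * v_crit), 4 * sig)
  expect_gt(st$consistency_ratio, 0.8)
  expect_lt(st$consistency_ratio, 1.2)
  # identical frames have zero variance
  same <- ensemble(list(ens$frames[[1]], ens$frames[[1]]), "sample_B")
  dl2 <- label_droplet(same, sol, radii = radii,
                       placement = "center_fixed", seed = 1)
  expect_equal(droplet_statistics(dl2)$var, 0)
})

test_that("the hard-sphere fixture droplet is consistent with the heuristic", {
  s <- small_system()
  v <- vdw_volume(s$solute, s$radii, "grid", 0.1)
  st <- droplet_statistics(s$droplet, n_x_ref = 0.1 * v)
  expect_gt(st$consistency_ratio, 0.8)
  expect_lt(st$consistency_ratio, 1.2)
})

test_that("excluded-volume spec bundles the bookkeeping", {
  sol <- solute_fixture("tetrahedral")
  sp <- excluded_volume_spec(sol, n_b = 0.1, radii = vdw_radii("ff"),
                             box_volume = 1280)
  expect_equal(sp$n_x, 0.1 * sp$v_vdw, tolerance = 1e-12)
  expect_true(sp$nu > 0 && sp$nu < 1)
  expect_equal(sp$nu, sp$v_vdw / 1280, tolerance = 1e-12)
})
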