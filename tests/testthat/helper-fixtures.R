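# Shared fixtures, built in code and cached for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a random cluster frame (no cell) with a fixed seed
rand_cluster <- function(n, seed, box = 15,
                         elements = c("C", "N", "O", "H")) {
  set.seed(seed)
  frame(sample(elements, n, TRUE), matrix(runif(3 * n, 0, box), n, 3))
}

# small end-to-end system: tetrahedral solute in a 128-molecule box
small_system <- function() with_cache("small", {
  model <- solvent_model()
  radii <- vdw_radii("ff")
  solute <- solute_fixture("tetrahedral")
  solv_a <- sample_solvent_box(model, 128, 8, seed = 11)
  b <- sample_solvent_box(model, 128, 8, seed = 511)
  a <- build_solution_box(solv_a, solute, "count_matched", radii = radii,
                          seed = 12)
  droplet <- label_droplet(b, solute, radii = radii, seed = 13)
  list(a = a, b = b, droplet = droplet, solute = solute, model = model,
       radii = radii)
})

small_decomposition <- function() with_cache("small_dec", {
  s <- small_system()
  decompose_dF(s$a, s$b, s$droplet, q = default_q_grid(0.5, 25, 0.05))
})

# the full reference fixture and its decomposition on the default grids,
# shared by the acceptance criteria
reference_run <- function() with_cache("reference", {
  fix <- make_reference_fixture(seed = 1)
  q <- default_q_grid()
  dec_q <- decompose_dF(fix$a, fix$b, fix$droplet, q = q)
  dec_r <- transform_decomposition(dec_q, transform_spec(0.5, 25, 20, 0.01))
  list(fix = fix, dec_q = dec_q, dec_r = dec_r,
       ladder = model_ladder(dec_r))
})
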