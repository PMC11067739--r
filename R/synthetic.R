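# Synthetic study systems: a seeded hard-sphere Metropolis solvent sampler,
# rigid solute fixtures, and matched A/B ensemble construction, so the whole
# differential pipeline runs end to end with no MD engine.
#
# The solvent surrogate is a single-site hard-sphere fluid realizing the
# atomic number density of liquid water (0.1 atoms/A^3) at a packing
# fraction ~0.36 (sigma = 1.9 A): fast, seeded, and analytically checkable.
# It reproduces a liquid's short-range exclusion correlations, not the
# hydrogen-bond network of real water.  A rigid 3-site water-like template
# is available to exercise molecule-granularity logic.

#' Solvent model specification
#'
#' @param sigma hard-core diameter (A) acting between molecular centres
#' @param density target atomic number density (atoms per cubic A)
#' @param atoms_per_molecule 1 (single-site, default) or 3 (rigid
#'   water-like template: one centre plus two satellite sites)
#' @param element element symbol of the centre site
#' @param max_disp maximum Metropolis displacement per move (A)
#' @return object of class \code{solvent_model}
#' @export
solvent_model <- function(sigma = 1.9, density = 0.1,
                          atoms_per_molecule = 1, element = "O",
                          max_disp = 0.35) {
  if (sigma < 0 || density <= 0) stop("need sigma >= 0 and density > 0")
  if (!atoms_per_molecule %in% c(1, 3))
    stop("atoms_per_molecule must be 1 or 3")
  eta <- pi / 6 * sigma^3 * density / atoms_per_molecule
  if (eta > 0.49)
    stop("infeasible density: hard-sphere packing fraction ",
         format(eta, digits = 3), " exceeds the fluid branch (~0.49)")
  structure(list(sigma = sigma, density = density,
                 atoms_per_molecule = atoms_per_molecule,
                 element = element, max_disp = max_disp, eta = eta),
            class = "solvent_model")
}

# attach two H-like satellite sites (rigid water template) with a random
# orientation per molecule
.attach_satellites <- function(centers, L) {
  doh <- 0.9572; half <- (104.52 / 2) * pi / 180
  n <- nrow(centers)
  out <- matrix(NA_real_, 3 * n, 3)
  el <- character(3 * n)
  mol <- integer(3 * n)
  for (i in seq_len(n)) {
    R <- .random_rotation()
    h1 <- c(doh * sin(half), 0, doh * cos(half)) %*% t(R)
    h2 <- c(-doh * sin(half), 0, doh * cos(half)) %*% t(R)
    k <- 3 * (i - 1)
    out[k + 1, ] <- centers[i, ]
    out[k + 2, ] <- (centers[i, ] + h1) %% L
    out[k + 3, ] <- (centers[i, ] + h2) %% L
    el[k + 1:3] <- c("O", "H", "H")
    mol[k + 1:3] <- i
  }
  list(xyz = out, elements = el, mol_id = mol)
}

#' Sample a pure-solvent box (sample B)
#'
#' Seeded Metropolis hard-core sampling of a cubic periodic box at the
#' model's target atomic number density (realized exactly by construction:
#' the box edge is chosen as \eqn{L = (N_{atoms}/n_B)^{1/3}}).  Particles
#' start on a simple cubic lattice, equilibrate for
#' \code{equilibration_sweeps}, and frames are recorded every \code{stride}
#' sweeps.  The same seed always yields the identical ensemble.
#'
#' @param model a [solvent_model()]
#' @param n_molecules number of solvent molecules
#' @param n_frames number of recorded frames
#' @param equilibration_sweeps Metropolis sweeps before recording
#' @param stride sweeps between recorded frames
#' @param seed RNG seed
#' @return a periodic [ensemble()] with role \code{sample_B}
#' @export
sample_solvent_box <- function(model, n_molecules = 512, n_frames = 20,
                               equilibration_sweeps = 500, stride = 100,
                               seed = 1L) {
  stopifnot(inherits(model, "solvent_model"))
  if (equilibration_sweeps < 1 || stride < 1 || n_frames < 1)
    stop("sweep counts must be positive")
  n_atoms_tot <- n_molecules * model$atoms_per_molecule
  L <- (n_atoms_tot / model$density)^(1 / 3)
  # fcc lattice start: nearest-neighbour spacing a/sqrt(2) must clear sigma
  n_cells <- ceiling((n_molecules / 4)^(1 / 3))
  a <- L / n_cells
  if (a / sqrt(2) <= model$sigma)
    stop("infeasible density: fcc start spacing ",
         format(a / sqrt(2), digits = 3), " A <= sigma")
  base <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
  g <- as.matrix(expand.grid(x = 0:(n_cells - 1), y = 0:(n_cells - 1),
                             z = 0:(n_cells - 1)))
  sites <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    sweep(base, 2, g[i, ], `+`)))
  start <- (sites[seq_len(n_molecules), , drop = FALSE] + 0.25) * a
  set.seed(seed)
  res <- cpp_mc_hs(start, L, model$sigma, model$max_disp,
                   equilibration_sweeps)
  frames <- vector("list", n_frames)
  acc <- res$acceptance
  for (k in seq_len(n_frames)) {
    res <- cpp_mc_hs(res$coords, L, model$sigma, model$max_disp, stride)
    acc <- c(acc, res$acceptance)
    if (model$atoms_per_molecule == 1) {
      frames[[k]] <- frame(rep(model$element, n_molecules), res$coords,
                           cell = rep(L, 3),
                           labels = rep("solvent", n_molecules),
                           mol_id = seq_len(n_molecules))
    } else {
      w <- .attach_satellites(res$coords, L)
      frames[[k]] <- frame(w$elements, w$xyz, cell = rep(L, 3),
                           labels = rep("solvent", 3 * n_molecules),
                           mol_id = w$mol_id)
    }
  }
  ensemble(frames, role = "sample_B",
           metadata = list(seed = seed, sigma = model$sigma,
                           density = model$density, box = L,
                           n_molecules = n_molecules,
                           atoms_per_molecule = model$atoms_per_molecule,
                           equilibration_sweeps = equilibration_sweeps,
                           stride = stride,
                           acceptance = mean(acc),
                           source = "solvscat hard-sphere sampler"))
}

# ---- rigid solute fixtures -------------------------------------------------

# idealized tris-bidentate geometry: three planar aromatic chelates spanning
# octahedron edges (D3 arrangement), plus two outer-sphere chloride ions.
.build_rubpy <- function(bite_deg = 78.7, ru_n = 2.06, ring = 1.39,
                         ch = 1.08, cl_dist = 5.2) {
  delta <- (bite_deg / 2) * pi / 180
  edges <- list(list(c(1, 0, 0), c(0, 1, 0)),
                list(c(0, 0, 1), c(-1, 0, 0)),
                list(c(0, -1, 0), c(0, 0, -1)))
  els <- "Ru"; xyz <- matrix(0, 1, 3); mol <- 1L
  for (ed in edges) {
    ei <- ed[[1]]; ej <- ed[[2]]
    u <- (ei + ej) / sqrt(sum((ei + ej)^2))
    v <- (ei - ej) / sqrt(sum((ei - ej)^2))
    for (sgn in c(1, -1)) {
      n2 <- ru_n * c(cos(delta), sgn * sin(delta))
      out <- n2 / sqrt(sum(n2^2))
      cen <- n2 + ring * out
      phi0 <- atan2(-out[2], -out[1])
      verts <- lapply(0:5, function(k)
        cen + ring * c(cos(phi0 + k * pi / 3), sin(phi0 + k * pi / 3)))
      ord <- if ((verts[[2]][2] - cen[2]) * sgn <
                 (verts[[6]][2] - cen[2]) * sgn) 1:6 else c(1, 6, 5, 4, 3, 2)
      rv <- verts[ord]
      to3 <- function(p2) u * p2[1] + v * p2[2]
      els <- c(els, "N"); xyz <- rbind(xyz, to3(rv[[1]])); mol <- c(mol, 1L)
      for (k in 2:6) {
        els <- c(els, "C"); xyz <- rbind(xyz, to3(rv[[k]])); mol <- c(mol, 1L)
      }
      for (k in 3:6) {  # H on the four CH ring positions
        dirv <- (rv[[k]] - cen) / sqrt(sum((rv[[k]] - cen)^2))
        h2 <- cen + (ring + ch) * dirv
        els <- c(els, "H"); xyz <- rbind(xyz, to3(h2)); mol <- c(mol, 1L)
      }
    }
  }
  ax <- c(1, 1, -1) / sqrt(3)
  for (s in c(1, -1)) {
    els <- c(els, "Cl"); xyz <- rbind(xyz, s * cl_dist * ax)
    mol <- c(mol, max(mol) + 1L)
  }
  frame(els, xyz, labels = rep("solute", length(els)), mol_id = mol)
}

#' Rigid solute fixtures
#'
#' Packaged rigid (frame-invariant) solute structures:
#' \itemize{
#'   \item \code{"diatomic"}: two carbon atoms at a fixed separation
#'     (default 2.0 A), the analytic toy for transform tests;
#'   \item \code{"tetrahedral"}: a 5-atom CCl4-like tetrahedron;
#'   \item \code{"rubpy3cl2"}: a 63-atom tris(bipyridine)ruthenium(II)
#'     dichloride surrogate (RuC30H24N6 + 2 Cl) built from idealized
#'     standard bond lengths (Ru-N 2.06 A, aromatic ring bonds 1.39 A,
#'     C-H 1.08 A) with D3-arranged planar chelates.  This is a synthetic
#'     idealized geometry, not a quantum-chemically optimized structure.
#' }
#' Counterions belong to the solute set: the differential experiment
#' removes the whole electroneutral solute unit.
#'
#' @param name fixture name
#' @param d bond length override for \code{"diatomic"} (A)
#' @return a cluster [frame()] with all atoms labelled \code{"solute"}
#' @export
solute_fixture <- function(name = c("rubpy3cl2", "diatomic", "tetrahedral"),
                           d = 2.0) {
  name <- match.arg(name)
  switch(name,
    diatomic = frame(c("C", "C"),
                     rbind(c(0, 0, 0), c(d, 0, 0)),
                     labels = c("solute", "solute"), mol_id = c(1L, 1L)),
    tetrahedral = {
      b <- 1.77
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                    c(-1, -1, 1)) / sqrt(3)
      frame(c("C", rep("Cl", 4)), rbind(c(0, 0, 0), b * dirs),
            labels = rep("solute", 5), mol_id = rep(1L, 5))
    },
    rubpy3cl2 = .build_rubpy())
}

#' Build a matched solution box (sample A)
#'
#' Constructs the solution ensemble from a pure-solvent reference by
#' inserting the rigid solute into the centre of each frame (seeded uniform
#' random rotation) and deleting solvent molecules, following the
#' ideal-dilute construction: the surviving solvent configuration is
#' untouched, so solvent-solvent correlations are unperturbed by design.
#'
#' Deletion rules: \code{"count_matched"} removes exactly
#' \code{n_delete} molecules nearest to the solute (the excluded-count
#' heuristic value by default), giving every A frame the same composition;
#' \code{"overlap"} removes every molecule with an atom inside the solute's
#' van der Waals region, so the count fluctuates frame to frame.
#'
#' @param solvent_ens a sample-B [ensemble()]
#' @param solute rigid solute [frame()], or \code{NULL} for no solute
#'   (the zero-volume-fraction limit: A is B relabelled)
#' @param deletion_rule \code{"count_matched"} or \code{"overlap"}
#' @param radii named radii vector (vdW criterion and the heuristic)
#' @param n_delete molecules to delete under \code{"count_matched"};
#'   default: the excluded-count heuristic from the solute volume and the
#'   ensemble's density
#' @param seed RNG seed for the per-frame solute orientations
#' @return an [ensemble()] with role \code{sample_A}
#' @export
build_solution_box <- function(solvent_ens, solute,
                               deletion_rule = c("count_matched", "overlap"),
                               radii = vdw_radii("ff"), n_delete = NULL,
                               seed = 1L) {
  deletion_rule <- match.arg(deletion_rule)
  stopifnot(inherits(solvent_ens, "scat_ensemble"))
  if (is.null(solute)) {
    return(ensemble(solvent_ens$frames, role = "sample_A",
                    metadata = c(solvent_ens$metadata,
                                 list(construction = "no solute"))))
  }
  fr1 <- solvent_ens$frames[[1]]
  if (is.null(fr1$cell)) stop("solvent frames must be periodic")
  r_u <- .radii_for(solute$elements, radii)
  ext <- if (nrow(solute$xyz) > 1) max(dist(solute$xyz)) else 0
  if (ext + 2 * max(r_u) > min(fr1$cell))
    stop("box too small for the solute")
  apm <- if (!is.null(solvent_ens$metadata$atoms_per_molecule))
    solvent_ens$metadata$atoms_per_molecule else 1
  if (deletion_rule == "count_matched" && is.null(n_delete)) {
    v <- vdw_volume(solute, radii, "grid", resolution = 0.1)
    n_b <- n_atoms(fr1) / prod(fr1$cell)
    n_delete <- n_excluded_heuristic(v, n_b, apm)$molecules
  }
  set.seed(seed)
  frames <- vector("list", length(solvent_ens$frames))
  deleted <- integer(length(frames))
  for (k in seq_along(frames)) {
    fr <- solvent_ens$frames[[k]]
    emb <- .embed_structure(solute, fr$cell / 2, rotate = TRUE)
    res <- .min_dist_to_solute(fr$xyz, emb$xyz, fr$cell, r_u)
    mol <- if (!is.null(fr$mol_id)) fr$mol_id else seq_len(n_atoms(fr))
    if (deletion_rule == "count_matched") {
      mol_min <- tapply(res$min_dist, mol, min)
      kill <- as.integer(names(sort(mol_min)[seq_len(n_delete)]))
    } else {
      kill <- unique(mol[res$within_radius])
    }
    keep <- !(mol %in% kill)
    deleted[k] <- length(kill)
    n_u <- n_atoms(solute)
    frames[[k]] <- frame(c(solute$elements, fr$elements[keep]),
                         rbind(emb$xyz, fr$xyz[keep, , drop = FALSE]),
                         cell = fr$cell,
                         labels = c(rep("solute", n_u),
                                    rep("solvent", sum(keep))),
                         mol_id = c(rep(0L, n_u), mol[keep]))
  }
  ensemble(frames, role = "sample_A",
           metadata = list(seed = seed, deletion_rule = deletion_rule,
                           n_deleted = deleted,
                           solvent_seed = solvent_ens$metadata$seed),
           strict = deletion_rule == "count_matched")
}

#' Matched reference A/B fixture
#'
#' A desk-scale synthetic realization of the differential experiment: a
#' hard-sphere solvent box at the atomic number density of water, the
#' 63-atom metal-complex fixture inserted by the ideal-dilute
#' (count-matched) construction, and droplet labels applied to the
#' reference, so the full decomposition pipeline can run in minutes.
#'
#' @param seed master RNG seed (solvent sampling, insertion orientations
#'   and droplet embeddings draw dependent seeds from it)
#' @param n_molecules solvent molecules in the reference box
#' @param n_frames frames per ensemble
#' @param solute_name fixture passed to [solute_fixture()]
#' @param radii named radii vector
#' @return list with \code{a}, \code{b} (ensembles), \code{droplet}
#'   ([label_droplet()] result), \code{spec}
#'   ([excluded_volume_spec()]) and the parameters used
#' @details The solution and reference ensembles are sampled independently
#'   (different seeds for the two solvent runs), mirroring the experiment,
#'   where samples A and B are thermally independent: the solution ensemble
#'   is built by inserting the solute into one solvent run, the reference
#'   is a second, untouched run of the same box.
#' @export
make_reference_fixture <- function(seed = 1L, n_molecules = 512,
                                   n_frames = 24,
                                   solute_name = "rubpy3cl2",
                                   radii = vdw_radii("ff")) {
  model <- solvent_model()
  solv_a <- sample_solvent_box(model, n_molecules = n_molecules,
                               n_frames = n_frames, seed = seed)
  b <- sample_solvent_box(model, n_molecules = n_molecules,
                          n_frames = n_frames, seed = seed + 5000L)
  solute <- solute_fixture(solute_name)
  spec <- excluded_volume_spec(solute, n_b = model$density, radii = radii,
                               atoms_per_molecule = model$atoms_per_molecule,
                               box_volume = prod(b$frames[[1]]$cell))
  a <- build_solution_box(solv_a, solute, "count_matched", radii = radii,
                          n_delete = spec$molecules, seed = seed + 1000L)
  droplet <- label_droplet(b, solute, radii = radii, seed = seed + 2000L)
  list(a = a, b = b, droplet = droplet, spec = spec, solute = solute,
       seed = seed, model = model)
}
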