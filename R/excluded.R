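# Solute van der Waals volume, the excluded-atom-count heuristic, and the
# per-frame excluded-solvent droplet labelling of the pure-solvent reference.

#' Fused-sphere van der Waals volume
#'
#' Volume of the union of atomic spheres of a (rigid) structure, by grid
#' integration (counting grid-cell centres inside any sphere) or Monte Carlo
#' sampling of the bounding box.  This volume bounds the solvent excluded
#' volume of the solute and drives the excluded-atom-count heuristic.
#'
#' @param structure a [frame()] (cluster; typically the rigid solute)
#' @param radii named radii vector from [vdw_radii()] (default: the
#'   force-field flavoured set)
#' @param method \code{"grid"} or \code{"monte_carlo"}
#' @param resolution grid spacing (A), for \code{"grid"}
#' @param n_samples number of sample points, for \code{"monte_carlo"}
#' @param seed RNG seed for \code{"monte_carlo"}
#' @return volume in cubic Angstroms; Monte Carlo results carry a
#'   \code{"se"} attribute (standard error)
#' @export
vdw_volume <- function(structure, radii = vdw_radii("ff"),
                       method = c("grid", "monte_carlo"),
                       resolution = 0.1, n_samples = 1e6, seed = NULL) {
  method <- match.arg(method)
  r <- .radii_for(structure$elements, radii)
  xyz <- structure$xyz
  if (method == "grid") {
    if (resolution <= 0) stop("resolution must be positive")
    return(cpp_grid_volume(xyz, r, resolution))
  }
  if (n_samples < 1) stop("n_samples must be positive")
  if (!is.null(seed)) set.seed(seed)
  lo <- apply(xyz - r, 2, min) - 1e-9
  hi <- apply(xyz + r, 2, max) + 1e-9
  vbox <- prod(hi - lo)
  n_in <- 0
  remaining <- n_samples
  while (remaining > 0) {
    m <- min(remaining, 200000L)
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                 runif(m, lo[3], hi[3]))
    inside <- rep(FALSE, m)
    for (i in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
            (pts[, 3] - xyz[i, 3])^2
      inside <- inside | d2 <= r[i]^2
    }
    n_in <- n_in + sum(inside)
    remaining <- remaining - m
  }
  p <- n_in / n_samples
  v <- p * vbox
  attr(v, "se") <- vbox * sqrt(p * (1 - p) / n_samples)
  v
}

#' Excluded-solvent count heuristic
#'
#' Estimates the number of solvent atoms displaced by a solute of fused-
#' sphere volume \code{v_vdw} in a solvent of atomic number density
#' \code{n_b}: \eqn{N_x = n_B V_{vdW}}.  The atom count is kept fractional;
#' the molecule count is rounded half-up at the reporting boundary.
#'
#' @param v_vdw solute van der Waals volume (cubic A)
#' @param n_b solvent atomic number density (atoms per cubic A); liquid
#'   water has \eqn{n_B = 0.1}
#' @param atoms_per_molecule atoms per solvent molecule (3 for water)
#' @return list with \code{n_x} (atoms, fractional) and \code{molecules}
#'   (whole solvent molecules)
#' @export
n_excluded_heuristic <- function(v_vdw, n_b, atoms_per_molecule = 3) {
  if (v_vdw < 0 || n_b <= 0 || atoms_per_molecule <= 0)
    stop("inputs must be positive (v_vdw may be zero)")
  n_x <- n_b * v_vdw
  list(n_x = n_x,
       molecules = as.integer(floor(n_x / atoms_per_molecule + 0.5)))
}

#' Water atomic number density
#'
#' The atomic number density of a molecular liquid from its mass density,
#' molar mass and atoms per molecule; defaults reproduce liquid water at
#' ambient conditions (0.997 g/cm3, 18.015 g/mol, 3 atoms) giving
#' approximately 0.1 atoms per cubic Angstrom.
#'
#' @param mass_density g/cm3
#' @param molar_mass g/mol
#' @param atoms_per_molecule atoms per molecule
#' @return atomic number density in atoms per cubic Angstrom
#' @export
atomic_number_density <- function(mass_density = 0.997,
                                  molar_mass = 18.015,
                                  atoms_per_molecule = 3) {
  avogadro <- 6.02214076e23
  mass_density / molar_mass * avogadro * atoms_per_molecule * 1e-24
}

# uniform random rotation matrix (Arvo/Shoemake via quaternion), consuming
# three uniforms from the active RNG stream
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# embed a rigid structure: centroid to `center`, optional random rotation
.embed_structure <- function(structure, center, rotate = TRUE) {
  xyz <- structure$xyz
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2, cen)
  R <- if (rotate) .random_rotation() else diag(3)
  list(xyz = sweep(rel %*% t(R), 2, center, `+`), rotation = R)
}

# minimum-image distances from each solvent atom to the nearest solute atom
.min_dist_to_solute <- function(solv_xyz, solute_xyz, cell,
                                per_atom_radii = NULL) {
  n <- nrow(solv_xyz)
  best <- rep(Inf, n)
  hit <- rep(FALSE, n)
  for (i in seq_len(nrow(solute_xyz))) {
    dx <- solv_xyz[, 1] - solute_xyz[i, 1]
    dy <- solv_xyz[, 2] - solute_xyz[i, 2]
    dz <- solv_xyz[, 3] - solute_xyz[i, 3]
    if (!is.null(cell)) {
      dx <- dx - cell[1] * round(dx / cell[1])
      dy <- dy - cell[2] * round(dy / cell[2])
      dz <- dz - cell[3] * round(dz / cell[3])
    }
    d <- sqrt(dx^2 + dy^2 + dz^2)
    best <- pmin(best, d)
    if (!is.null(per_atom_radii)) hit <- hit | d <= per_atom_radii[i]
  }
  list(min_dist = best, within_radius = hit)
}

#' Label the excluded-solvent droplet of a pure-solvent frame
#'
#' Embeds a rigid solute structure into a pure-solvent frame (centroid at
#' the box centre, optionally with a seeded uniform random rotation) and
#' flags every solvent atom lying within the criterion radius of any solute
#' atom as belonging to the excluded-solvent droplet.  The default
#' criterion follows the algorithm of the framework: an atom is flagged when
#' its distance to some solute atom is at most that solute atom's van der
#' Waals radius (so the droplet region is exactly the fused-sphere volume);
#' \code{criterion = "sum_radii"} instead uses the sum of the solute- and
#' solvent-atom radii.
#'
#' @param frame_b periodic pure-solvent [frame()]
#' @param solute rigid solute structure (cluster [frame()])
#' @param radii named radii vector
#' @param placement \code{"center_random_rotation"} or \code{"center_fixed"}
#' @param granularity \code{"atom"} flags atoms individually;
#'   \code{"molecule"} flags whole molecules when any member atom qualifies
#' @param criterion \code{"solute_radius"} or \code{"sum_radii"}
#' @param solvent_radius single solvent-atom radius used by
#'   \code{"sum_radii"} (default: radius of the first solvent element)
#' @return logical vector, one flag per atom of \code{frame_b}, with the
#'   embedding transform in attributes
#' @export
label_droplet_frame <- function(frame_b, solute, radii = vdw_radii("ff"),
                                placement = c("center_random_rotation",
                                              "center_fixed"),
                                granularity = c("atom", "molecule"),
                                criterion = c("solute_radius", "sum_radii"),
                                solvent_radius = NULL) {
  placement <- match.arg(placement)
  granularity <- match.arg(granularity)
  criterion <- match.arg(criterion)
  if (is.null(frame_b$cell)) stop("frame_b must be periodic")
  r_u <- .radii_for(solute$elements, radii)
  ext <- if (nrow(solute$xyz) > 1) max(dist(solute$xyz)) else 0
  if (ext > min(frame_b$cell))
    stop("solute (extent ", format(ext, digits = 4),
         " A) does not fit in the box")
  crit <- r_u
  if (criterion == "sum_radii") {
    if (is.null(solvent_radius))
      solvent_radius <- .radii_for(frame_b$elements[1], radii)
    crit <- r_u + solvent_radius
  }
  emb <- .embed_structure(solute, frame_b$cell / 2,
                          rotate = placement == "center_random_rotation")
  res <- .min_dist_to_solute(frame_b$xyz, emb$xyz, frame_b$cell, crit)
  flag <- res$within_radius
  if (granularity == "molecule" && !is.null(frame_b$mol_id)) {
    hit_mol <- unique(frame_b$mol_id[flag])
    flag <- frame_b$mol_id %in% hit_mol
  }
  attr(flag, "rotation") <- emb$rotation
  attr(flag, "center") <- frame_b$cell / 2
  flag
}

#' Droplet labels over a pure-solvent ensemble
#'
#' Applies [label_droplet_frame()] to every frame of a sample-B ensemble
#' under one RNG seed, returning the per-frame membership flags and counts.
#'
#' @param ens_b pure-solvent [ensemble()] (periodic frames)
#' @param solute rigid solute structure
#' @param seed RNG seed controlling the per-frame embedding rotations
#' @inheritParams label_droplet_frame
#' @return object of class \code{droplet_labels}: per-frame flags, counts,
#'   ensemble mean, and the parameters used
#' @export
label_droplet <- function(ens_b, solute, radii = vdw_radii("ff"),
                          placement = c("center_random_rotation",
                                        "center_fixed"),
                          granularity = c("atom", "molecule"),
                          criterion = c("solute_radius", "sum_radii"),
                          seed = 1L) {
  placement <- match.arg(placement)
  granularity <- match.arg(granularity)
  criterion <- match.arg(criterion)
  stopifnot(inherits(ens_b, "scat_ensemble"))
  set.seed(seed)
  flags <- lapply(ens_b$frames, function(fr)
    label_droplet_frame(fr, solute, radii, placement, granularity,
                        criterion))
  counts <- vapply(flags, sum, numeric(1))
  structure(list(flags = flags, counts = counts,
                 mean_n_x = mean(counts),
                 placement = placement, granularity = granularity,
                 criterion = criterion, seed = seed,
                 radii_set = attr(radii, "set")),
            class = "droplet_labels")
}

#' @export
print.droplet_labels <- function(x, ...) {
  cat("<droplet_labels>", length(x$flags), "frame(s); <N_x> =",
      format(x$mean_n_x, digits = 5), "atoms (", x$criterion, ",",
      x$granularity, "granularity )\n")
  invisible(x)
}

#' Droplet statistics and heuristic consistency
#'
#' Summarizes droplet sizes over the ensemble and, when a heuristic
#' excluded-atom count is supplied, reports the consistency ratio
#' \eqn{\langle N_x \rangle / (n_B V_{vdW})}.
#'
#' @param labels a [label_droplet()] result
#' @param n_x_ref heuristic excluded-atom count \eqn{n_B V_{vdW}}
#'   (optional)
#' @return list with mean, variance, quartiles, per-frame counts and
#'   (optionally) the consistency ratio
#' @export
droplet_statistics <- function(labels, n_x_ref = NULL) {
  stopifnot(inherits(labels, "droplet_labels"))
  out <- list(mean = mean(labels$counts),
              var = if (length(labels$counts) > 1) var(labels$counts) else 0,
              quartiles = stats::quantile(labels$counts, c(.25, .5, .75)),
              counts = labels$counts)
  if (!is.null(n_x_ref)) out$consistency_ratio <- out$mean / n_x_ref
  out
}

#' Excluded-volume bookkeeping for a solute/solvent pairing
#'
#' Bundles the radii set, fused-sphere solute volume, solvent density, the
#' heuristic excluded-atom count and (when the box volume is known) the
#' solute volume fraction.
#'
#' @param solute rigid solute [frame()]
#' @param n_b solvent atomic number density (atoms per cubic A)
#' @param radii named radii vector
#' @param atoms_per_molecule atoms per solvent molecule
#' @param box_volume liquid-cell volume (cubic A), for the volume fraction
#' @param resolution grid resolution for the volume integral
#' @return object of class \code{excluded_volume_spec}
#' @export
excluded_volume_spec <- function(solute, n_b, radii = vdw_radii("ff"),
                                 atoms_per_molecule = 1,
                                 box_volume = NULL, resolution = 0.1) {
  v <- vdw_volume(solute, radii, "grid", resolution = resolution)
  h <- n_excluded_heuristic(v, n_b, atoms_per_molecule)
  nu <- if (!is.null(box_volume)) v / box_volume else NA_real_
  structure(list(radii_set = attr(radii, "set"), radii = radii,
                 v_vdw = v, n_b = n_b, n_x = h$n_x,
                 molecules = h$molecules, nu = nu,
                 atoms_per_molecule = atoms_per_molecule),
            class = "excluded_volume_spec")
}

#' @export
print.excluded_volume_spec <- function(x, ...) {
  cat("<excluded_volume_spec> V_vdW =", format(x$v_vdw, digits = 6),
      "A^3 (", x$radii_set, "radii ); n_B =", x$n_b,
      "atoms/A^3; N_x =", format(x$n_x, digits = 5), "atoms (",
      x$molecules, "molecules )\n")
  if (is.finite(x$nu)) cat("  volume fraction nu =", format(x$nu, digits = 4), "\n")
  invisible(x)
}
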