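# Synthetic inverted-repeat helical bundles with recorded ground truth.
#
# The generator emulates the structural assumptions of an elevator-type
# transporter: two alpha-helical domains (static scaffold, mobile
# transport), an internal two-fold inverted repeat in which repeat 2 is
# repeat 1 rotated 180 degrees about a membrane-parallel axis, a known
# rigid transform (spin about the membrane normal plus a membrane-normal
# lift) applied to the transport domain, optional isotropic Gaussian
# coordinate noise, and an optional substrate atom cluster in the binding
# site.  Every bundle ships with the annotation config and the ground-truth
# record the analysis modules are expected to recover.

#' Ideal alpha-helix C-alpha trace
#'
#' @param n_res Number of residues.
#' @param rise Rise per residue along the axis, Angstrom (default 1.5).
#' @param radius Helix radius, Angstrom (default 2.3).
#' @param twist Twist per residue, degrees (default 100).
#' @param phase Angular phase of the first residue, degrees.
#' @return `n_res x 3` CA coordinates winding along +z, centered on z = 0.
#' @export
ideal_helix <- function(n_res, rise = 1.5, radius = 2.3, twist = 100,
                        phase = 0) {
  i <- seq_len(n_res)
  th <- (phase + (i - 1) * twist) * pi / 180
  cbind(radius * cos(th), radius * sin(th),
        (i - (n_res + 1) / 2) * rise)
}

# rigid per-residue backbone placement around a CA trace; CA-C is exactly
# CA_C_LENGTH by construction, which makes the bond-length statistic
# analytically checkable
CA_C_LENGTH <- 1.52
N_CA_LENGTH <- 1.458
C_O_LENGTH <- 1.23

backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  u <- matrix(0, n, 3)
  if (n >= 2L) {
    d <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    u[-n, ] <- d
    u[n, ] <- d[n - 1, ]
  } else {
    u[1, ] <- c(0, 0, 1)
  }
  # a perpendicular direction for the carbonyl oxygen
  ref <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  par <- abs(rowSums(u * ref)) > 0.99
  ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), ncol = 3, byrow = TRUE)
  v <- cbind(u[, 2] * ref[, 3] - u[, 3] * ref[, 2],
             u[, 3] * ref[, 1] - u[, 1] * ref[, 3],
             u[, 1] * ref[, 2] - u[, 2] * ref[, 1])
  v <- v / sqrt(rowSums(v^2))
  list(N = ca - N_CA_LENGTH * u,
       CA = ca,
       C = ca + CA_C_LENGTH * u,
       O = ca + CA_C_LENGTH * u + C_O_LENGTH * v)
}

#' Specify a synthetic inverted-repeat bundle
#'
#' Defaults reflect ideal alpha-helix geometry and, for the applied
#' transport-domain transform, the elevator motion amplitude typical of a
#' DASS transporter outward-to-inward transition (a 37.4-degree spin with a
#' 13.0 Angstrom membrane-normal lift).
#'
#' @param helices_per_domain Helices per domain (even, half per repeat).
#' @param residues_per_helix Residues per helix (>= 4).
#' @param rise,radius,twist Ideal helix parameters (1.5 A, 2.3 A,
#'   100 deg/residue).
#' @param scaffold_ring_radius,transport_ring_radius Radii of the circles
#'   on which helix axes are placed, Angstrom.
#' @param transport_spin_deg Ground-truth spin of the transport domain
#'   about the membrane normal, degrees.
#' @param transport_lift Ground-truth membrane-normal displacement of the
#'   transport domain, Angstrom.
#' @param in_plane_axis Membrane-parallel axis relating the two repeats.
#' @param noise_sd Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed RNG seed recorded in the output.
#' @param ligand_atoms Number of substrate atoms (0 for none).
#' @param ligand_offset Offset of the substrate cluster from the transport
#'   domain centroid, Angstrom.
#' @param res_name Residue type used for every residue.
#' @param protomers 1 (monomer) or 2 (dimer relating chains A and B by an
#'   in-plane translation).
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(helices_per_domain = 4L, residues_per_helix = 12L,
                        rise = 1.5, radius = 2.3, twist = 100,
                        scaffold_ring_radius = 16,
                        transport_ring_radius = 7,
                        transport_spin_deg = 37.4, transport_lift = 13.0,
                        in_plane_axis = c(1, 0, 0), noise_sd = 0,
                        seed = 1L, ligand_atoms = 0L,
                        ligand_offset = c(0, 0, 2), res_name = "GLY",
                        protomers = 1L) {
  stopifnot(helices_per_domain >= 2L, helices_per_domain %% 2L == 0L,
            residues_per_helix >= 4L, noise_sd >= 0, protomers %in% 1:2,
            ligand_atoms >= 0L)
  structure(list(helices_per_domain = as.integer(helices_per_domain),
                 residues_per_helix = as.integer(residues_per_helix),
                 rise = rise, radius = radius, twist = twist,
                 scaffold_ring_radius = scaffold_ring_radius,
                 transport_ring_radius = transport_ring_radius,
                 transport_spin_deg = transport_spin_deg,
                 transport_lift = transport_lift,
                 in_plane_axis = in_plane_axis, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 ligand_atoms = as.integer(ligand_atoms),
                 ligand_offset = ligand_offset, res_name = res_name,
                 protomers = as.integer(protomers)),
            class = "bundle_spec")
}

# layout of one protomer's core (exactly repeat-swap symmetric): returns a
# per-helix list with CA coordinates and bookkeeping labels
core_layout <- function(spec, x_offset = 0) {
  nh2 <- spec$helices_per_domain %/% 2L
  helices <- list()
  for (domain in c("scaffold", "transport")) {
    ring <- if (domain == "scaffold") spec$scaffold_ring_radius
            else spec$transport_ring_radius
    base <- if (domain == "scaffold") 15 else 60
    for (k in seq_len(nh2)) {
      phi <- (base + (k - 1) * 360 / spec$helices_per_domain) * pi / 180
      ca <- ideal_helix(spec$residues_per_helix, spec$rise, spec$radius,
                        spec$twist, phase = (k - 1) * 37)
      ca <- sweep(ca, 2, c(ring * cos(phi) + x_offset, ring * sin(phi), 0),
                  "+")
      helices[[length(helices) + 1L]] <-
        list(domain = domain, rep = 1L, idx = k, ca = ca)
    }
  }
  # repeat 2 = repeat 1 rotated 180 degrees about the in-plane axis through
  # the protomer center (x_offset, 0, 0)
  a <- spec$in_plane_axis / sqrt(sum(spec$in_plane_axis^2))
  M <- 2 * tcrossprod(a) - diag(3)
  n1 <- length(helices)
  for (h in seq_len(n1)) {
    p <- sweep(helices[[h]]$ca, 2, c(x_offset, 0, 0))
    ca2 <- sweep(p %*% M, 2, c(x_offset, 0, 0), "+")
    helices[[n1 + h]] <- list(domain = helices[[h]]$domain, rep = 2L,
                              idx = helices[[h]]$idx, ca = ca2)
  }
  # residue ordering: scaffold r1, transport r1, scaffold r2, transport r2
  ord <- order(vapply(helices, `[[`, 1L, "rep"),
               match(vapply(helices, `[[`, "", "domain"),
                     c("scaffold", "transport")),
               vapply(helices, `[[`, 1L, "idx"))
  helices[ord]
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# fixed substrate cluster geometry (tetrahedral-ish offsets, Angstrom)
ligand_offsets <- matrix(c(0, 0, 0,  0.8, 0.8, 0.8,  -0.8, -0.8, 0.8,
                           0.8, -0.8, -0.8,  -0.8, 0.8, -0.8,
                           1.6, 0, 0,  0, 1.6, 0,  0, 0, 1.6),
                         ncol = 3, byrow = TRUE)

# assemble a full structure for one choice of applied transport transform
build_bundle_structure <- function(spec, spin_deg, lift, noise_sd) {
  chains <- if (spec$protomers == 1L) "A" else c("A", "B")
  offs <- if (spec$protomers == 1L) 0 else c(-30, 30)
  all_atoms <- list(); all_xyz <- list()
  serial <- 0L
  ann_prot <- list()
  gt_centroids <- list()
  for (ci in seq_along(chains)) {
    hel <- core_layout(spec, offs[ci])
    # first pass: core backbone coordinates per helix
    res_seq <- 0L
    helix_meta <- list(); helix_xyz <- list()
    for (h in hel) {
      bb <- backbone_from_ca(h$ca)
      nres <- nrow(h$ca)
      xyz <- matrix(NA_real_, nres * 4L, 3)
      nm <- character(nres * 4L); rs <- integer(nres * 4L)
      for (i in seq_len(nres)) {
        r4 <- (i - 1L) * 4L
        xyz[r4 + 1L, ] <- bb$N[i, ]
        xyz[r4 + 2L, ] <- bb$CA[i, ]
        xyz[r4 + 3L, ] <- bb$C[i, ]
        xyz[r4 + 4L, ] <- bb$O[i, ]
        nm[r4 + 1:4] <- c("N", "CA", "C", "O")
        rs[r4 + 1:4] <- res_seq + i
      }
      start <- res_seq + 1L; end <- res_seq + nres
      res_seq <- end
      helix_meta[[length(helix_meta) + 1L]] <-
        list(domain = h$domain, rep = h$rep, idx = h$idx,
             start = start, end = end, names = nm, res_seq = rs)
      helix_xyz[[length(helix_xyz) + 1L]] <- xyz
    }
    # spin axis passes through the core transport-domain atom centroid
    tr_rows <- vapply(helix_meta, function(h) h$domain == "transport",
                      TRUE)
    cen <- colMeans(do.call(rbind, helix_xyz[tr_rows]))
    Rz <- rot_z(spin_deg)
    for (j in seq_along(helix_xyz)) {
      if (helix_meta[[j]]$domain == "transport") {
        xyz <- helix_xyz[[j]]
        xyz <- sweep(sweep(xyz, 2, cen) %*% t(Rz), 2, cen, "+")
        helix_xyz[[j]] <- sweep(xyz, 2, c(0, 0, lift), "+")
      }
      h <- helix_meta[[j]]
      nres <- h$end - h$start + 1L
      all_atoms[[length(all_atoms) + 1L]] <- data.frame(
        serial = serial + seq_len(nres * 4L),
        name = h$names, elem = substr(h$names, 1, 1),
        res_name = spec$res_name, chain = chains[ci], res_seq = h$res_seq,
        ins = "", alt = "", occ = 1, het = FALSE, stringsAsFactors = FALSE)
      serial <- serial + nres * 4L
      all_xyz[[length(all_xyz) + 1L]] <- helix_xyz[[j]]
    }
    gt_centroids[[chains[ci]]] <- cen
    if (spec$ligand_atoms > 0L) {
      k <- min(spec$ligand_atoms, nrow(ligand_offsets))
      site <- cen + c(0, 0, lift) + spec$ligand_offset
      lx <- sweep(ligand_offsets[seq_len(k), , drop = FALSE], 2, site, "+")
      all_atoms[[length(all_atoms) + 1L]] <- data.frame(
        serial = serial + seq_len(k),
        name = paste0("C", seq_len(k)), elem = "C", res_name = "SUB",
        chain = chains[ci], res_seq = 999L, ins = "", alt = "",
        occ = 1, het = TRUE, stringsAsFactors = FALSE)
      serial <- serial + k
      all_xyz[[length(all_xyz) + 1L]] <- lx
    }
    # annotation for this protomer
    dom_ranges <- function(dn) {
      hm <- Filter(function(h) h$domain == dn, helix_meta)
      do.call(rbind, lapply(hm, function(h)
        ranges_df(chains[ci], h$start, h$end)))
    }
    hm1 <- Filter(function(h) h$rep == 1L, helix_meta)
    hm2 <- Filter(function(h) h$rep == 2L, helix_meta)
    pairs <- lapply(seq_along(hm1), function(j) {
      m2 <- Filter(function(h) h$domain == hm1[[j]]$domain &
                     h$idx == hm1[[j]]$idx, hm2)[[1]]
      list(ranges_df(chains[ci], hm1[[j]]$start, hm1[[j]]$end),
           ranges_df(chains[ci], m2$start, m2$end))
    })
    helices <- list()
    for (h in helix_meta) {
      nmh <- sprintf("%s_r%d_h%d", substr(h$domain, 1, 2), h$rep, h$idx)
      helices[[nmh]] <- ranges_df(chains[ci], h$start, h$end)
    }
    ann_prot[[ci]] <- protomer_annotation(
      name = chains[ci], chains = chains[ci],
      scaffold = dom_ranges("scaffold"),
      transport = dom_ranges("transport"),
      repeats = repeat_mapping(pairs),
      helices = helices,
      binding_site = NULL)
  }
  atoms <- do.call(rbind, all_atoms)
  rownames(atoms) <- NULL
  xyz <- do.call(rbind, all_xyz)
  if (noise_sd > 0) xyz <- xyz + rnorm(length(xyz), sd = noise_sd)
  list(structure = structure3d(atoms, xyz,
                               metadata = list(method = "SYNTHETIC")),
       annotation = topology_annotation(
         ann_prot, substrate = if (spec$ligand_atoms > 0L) "SUB"),
       transport_centroids = gt_centroids)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic inverted-repeat bundle
#'
#' Builds the repeat-swap-symmetric core, applies the spec's transport
#' transform (spin about the membrane normal through the transport-domain
#' centroid, then a membrane-normal lift), optionally adds a substrate
#' cluster and Gaussian noise, and returns the structure together with a
#' ready-to-use annotation, membrane frame and ground-truth record.
#'
#' @param spec A `bundle_spec`.
#' @return An object of class `synthetic_bundle`: `structure`,
#'   `annotation`, `frame`, and `ground_truth` (applied spin/lift, spin
#'   axis, the transition-plan deltas implied by the repeat-swap
#'   construction, and the seed).
#' @export
make_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  built <- with_seed(spec$seed,
    build_bundle_structure(spec, spec$transport_spin_deg,
                           spec$transport_lift, spec$noise_sd))
  gt <- list(
    transport_spin_deg = spec$transport_spin_deg,
    transport_lift = spec$transport_lift,
    spin_axis = c(0, 0, 1),
    distance_z = spec$transport_lift,
    plan_spin_delta_deg = abs(wrap_angle(-2 * spec$transport_spin_deg)),
    plan_distance_z_delta = -2 * spec$transport_lift,
    transport_centroids = built$transport_centroids,
    seed = spec$seed)
  structure(list(structure = built$structure,
                 annotation = built$annotation,
                 frame = membrane_frame(origin = c(0, 0, 0),
                                        z_axis = c(0, 0, 1),
                                        x_axis = spec$in_plane_axis),
                 ground_truth = gt, spec = spec),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic bundle: %d atoms, spin %.1f deg, lift %.1f A, noise %.2f A\n",
    n_atoms(x$structure), x$spec$transport_spin_deg,
    x$spec$transport_lift, x$spec$noise_sd))
  invisible(x)
}

#' Generate a synthetic transition trajectory
#'
#' Frames move the transport domain from the untransformed core to the
#' spec's full transform.  With `motion = "slerp_rigid"` the rotation is
#' interpolated geodesically so the per-frame spin is exactly linear in the
#' frame index; `motion = "linear_cartesian"` interpolates coordinates
#' between the two endpoint structures instead.
#'
#' @param spec A `bundle_spec`.
#' @param n_frames Number of frames, >= 2.
#' @param motion `"slerp_rigid"` or `"linear_cartesian"`.
#' @return List with `trajectory` (a `trajectory3d`), `ground_truth`
#'   (per-frame spin and lift), `annotation`, `frame`, and `reference`
#'   (the frame-1 structure).
#' @export
make_transition_trajectory <- function(spec, n_frames,
                                       motion = c("slerp_rigid",
                                                  "linear_cartesian")) {
  motion <- match.arg(motion)
  stopifnot(n_frames >= 2L)
  fracs <- (seq_len(n_frames) - 1) / (n_frames - 1)
  gt <- data.frame(frame = seq_len(n_frames),
                   spin_deg = fracs * spec$transport_spin_deg,
                   lift = fracs * spec$transport_lift)
  builds <- with_seed(spec$seed, {
    if (motion == "slerp_rigid") {
      lapply(seq_len(n_frames), function(k)
        build_bundle_structure(spec, gt$spin_deg[k], gt$lift[k],
                               spec$noise_sd))
    } else {
      list(build_bundle_structure(spec, 0, 0, spec$noise_sd),
           build_bundle_structure(spec, spec$transport_spin_deg,
                                  spec$transport_lift, spec$noise_sd))
    }
  })
  if (motion == "slerp_rigid") {
    topo <- builds[[1]]$structure
    coords <- array(NA_real_, dim = c(n_atoms(topo), 3, n_frames))
    for (k in seq_len(n_frames))
      coords[, , k] <- model_coords(builds[[k]]$structure)
    traj <- trajectory3d(topo, coords)
  } else {
    traj <- interpolate_states(builds[[1]]$structure,
                               builds[[2]]$structure, n_frames)
  }
  structure(list(trajectory = traj, ground_truth = gt,
                 annotation = builds[[1]]$annotation,
                 frame = membrane_frame(origin = c(0, 0, 0),
                                        z_axis = c(0, 0, 1),
                                        x_axis = spec$in_plane_axis),
                 reference = builds[[1]]$structure),
            class = "synthetic_trajectory")
}
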