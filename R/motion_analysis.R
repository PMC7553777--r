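# Quantification of elevator motion between conformational states, hinge
# and elbow angle dynamics, binding-site RMSD time series, and
# translational trajectory alignment.

#' Quantify the elevator motion between two states
#'
#' The scaffold of `state_b` is superposed onto that of `state_a` (backbone
#' atoms), the transform is applied to all of `state_b`, and the remaining
#' rigid-body motion of the transport domain (helix C-alpha atoms) is
#' decomposed into a rotation angle/axis and a translation split into its
#' membrane-normal and in-plane components.
#'
#' @param state_a,state_b `structure3d` objects (model 1 used).
#' @param annotation_a A `topology_annotation` (or single
#'   `protomer_annotation`) resolving on `state_a`.
#' @param annotation_b Annotation resolving on `state_b`; defaults to
#'   `annotation_a`.  Both must list domains as equal-length ordered
#'   residue ranges, which is how a cross-homolog residue-equivalence map
#'   is supplied.
#' @param frame A `membrane_frame` for `state_a`.
#' @param protomer Protomer name to analyse (default: first).
#' @return An object of class `elevator_motion`: `rotation_deg`,
#'   `rotation_axis`, `translation_z` (signed, along the membrane normal),
#'   `translation_inplane`, `scaffold_rmsd`, `transport_rmsd`, `n_scaffold`,
#'   `n_transport`.
#' @export
quantify_elevator_motion <- function(state_a, state_b, annotation_a,
                                     annotation_b = annotation_a,
                                     frame = membrane_frame(),
                                     protomer = NULL) {
  pa <- pick_protomer(annotation_a, protomer)
  pb <- pick_protomer(annotation_b, protomer)
  sc_a <- resolve_selection(state_a, domain_selection(pa, "scaffold",
                                                      "backbone"))
  sc_b <- resolve_selection(state_b, domain_selection(pb, "scaffold",
                                                      "backbone"))
  if (sc_a$n != sc_b$n)
    stop("unresolved equivalence map: scaffold selections give ", sc_a$n,
         " vs ", sc_b$n, " atoms")
  sup_sc <- superpose(sc_b$coords, sc_a$coords)
  b_aligned <- apply_transform(sup_sc$transform, model_coords(state_b))
  tr_a <- resolve_selection(state_a, domain_selection(pa, "transport",
                                                      "calpha"))
  tr_b <- resolve_selection(state_b, domain_selection(pb, "transport",
                                                      "calpha"))
  if (tr_a$n != tr_b$n)
    stop("unresolved equivalence map: transport selections give ", tr_a$n,
         " vs ", tr_b$n, " atoms")
  tr_b_coords <- b_aligned[tr_b$indices, , drop = FALSE]
  sup_tr <- superpose(tr_a$coords, tr_b_coords)
  d <- colMeans(tr_b_coords) - colMeans(tr_a$coords)
  tz <- sum(d * frame$z_axis)
  inplane <- d - tz * frame$z_axis
  structure(list(rotation_deg = sup_tr$rotation_angle,
                 rotation_axis = sup_tr$rotation_axis,
                 translation_z = tz,
                 translation_inplane = sqrt(sum(inplane^2)),
                 scaffold_rmsd = sup_sc$rmsd,
                 transport_rmsd = sup_tr$rmsd,
                 n_scaffold = sc_a$n, n_transport = tr_a$n),
            class = "elevator_motion")
}

pick_protomer <- function(annotation, protomer = NULL) {
  if (inherits(annotation, "protomer_annotation")) return(annotation)
  stopifnot(inherits(annotation, "topology_annotation"))
  if (is.null(protomer)) annotation$protomers[[1]]
  else annotation$protomers[[protomer]]
}

#' @export
print.elevator_motion <- function(x, ...) {
  cat(sprintf(
    paste0("elevator motion: %.2f deg rotation, %+.2f A along the ",
           "membrane normal (%.2f A in plane)\n",
           "  scaffold rmsd %.3f A (%d atoms), transport fit rmsd %.3f A",
           " (%d atoms)\n"),
    x$rotation_deg, x$translation_z, x$translation_inplane,
    x$scaffold_rmsd, x$n_scaffold, x$transport_rmsd, x$n_transport))
  invisible(x)
}

#' Serialise an elevator-motion result to JSON
#' @param motion An `elevator_motion`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_elevator_motion <- function(motion, path) {
  jsonlite::write_json(unclass(motion), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Inter-helix angle time series
#'
#' For each frame, fits both helix axes (principal component of the
#' C-alpha coordinates, N-to-C sign) and reports the angle between them.
#' Used for hinge (flexible) and elbow (rigid) regions.
#'
#' @param trajectory A `trajectory3d`.
#' @param helix_pairs Named list; each element is a list of two
#'   `selection`s (C-alpha filters) defining a helix pair.
#' @return Data frame: `frame` plus one angle column (degrees) per pair.
#' @export
hinge_angle_series <- function(trajectory, helix_pairs) {
  topo <- trajectory$topology
  idx <- lapply(helix_pairs, function(pr)
    list(resolve_selection(topo, pr[[1]])$indices,
         resolve_selection(topo, pr[[2]])$indices))
  out <- data.frame(frame = seq_len(trajectory$n_frames))
  for (nm in names(helix_pairs)) {
    i1 <- idx[[nm]][[1]]; i2 <- idx[[nm]][[2]]
    out[[nm]] <- vapply(seq_len(trajectory$n_frames), function(k) {
      xyz <- frame_coords(trajectory, k)
      interhelix_angle(fit_helix_axis(xyz[i1, , drop = FALSE]),
                       fit_helix_axis(xyz[i2, , drop = FALSE]))
    }, numeric(1))
  }
  out
}

#' Binding-site RMSD time series after transport-domain overlay
#'
#' Per frame, the frame's overlay atoms (transport-domain helices) are
#' superposed onto the reference's, the resulting transform is applied to
#' the whole frame, and the RMSD over the binding-site atoms (no
#' re-fitting) is reported -- separately for the substrate heavy atoms
#' when a ligand selection is given.
#'
#' @param trajectory A `trajectory3d` congruent with `reference`.
#' @param reference Reference `structure3d` (e.g. a crystal structure).
#' @param site Binding-site `selection` (typically C-alpha plus heavy
#'   side-chain atoms: `atoms = "site"`).
#' @param overlay Overlay `selection` (transport-domain helices).
#' @param ligand Optional substrate `selection` (heavy atoms).
#' @return Data frame: `frame`, `site_rmsd`, and `ligand_rmsd` when
#'   requested (Angstrom).
#' @export
binding_site_rmsd_series <- function(trajectory, reference, site, overlay,
                                     ligand = NULL) {
  stopifnot(n_atoms(trajectory$topology) == n_atoms(reference))
  ov <- resolve_selection(reference, overlay)
  st <- resolve_selection(reference, site)
  lg <- if (!is.null(ligand)) resolve_selection(reference, ligand)
  ref_xyz <- model_coords(reference)
  rms <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
  out <- data.frame(frame = seq_len(trajectory$n_frames))
  out$site_rmsd <- NA_real_
  if (!is.null(lg)) out$ligand_rmsd <- NA_real_
  for (k in seq_len(trajectory$n_frames)) {
    xyz <- frame_coords(trajectory, k)
    sup <- superpose(xyz[ov$indices, , drop = FALSE],
                     ref_xyz[ov$indices, , drop = FALSE])
    moved <- apply_transform(sup$transform, xyz)
    out$site_rmsd[k] <- rms(moved[st$indices, , drop = FALSE],
                            ref_xyz[st$indices, , drop = FALSE])
    if (!is.null(lg))
      out$ligand_rmsd[k] <- rms(moved[lg$indices, , drop = FALSE],
                                ref_xyz[lg$indices, , drop = FALSE])
  }
  out
}

#' Translationally align a trajectory on scaffold and transport centers
#'
#' Per frame, a pure translation is applied so the scaffold's
#' (mass-weighted) center of mass matches the reference frame's along the
#' membrane normal while the transport domain's center of mass matches in
#' the membrane plane.  No rotation is applied; this removes drift while
#' leaving the elevator motion visible.
#'
#' @param trajectory A `trajectory3d`.
#' @param scaffold,transport `selection`s for the two domains.
#' @param frame_def A `membrane_frame`.
#' @param reference_frame Index of the frame used as the reference
#'   (default 1).
#' @param mass_weighted Use atomic masses for the centers (default TRUE).
#' @return The aligned `trajectory3d`.
#' @export
align_trajectory <- function(trajectory, scaffold, transport,
                             frame_def = membrane_frame(),
                             reference_frame = 1L, mass_weighted = TRUE) {
  topo <- trajectory$topology
  sc <- resolve_selection(topo, scaffold)
  tr <- resolve_selection(topo, transport)
  w_sc <- if (mass_weighted) atom_masses(sc$atoms) else NULL
  w_tr <- if (mass_weighted) atom_masses(tr$atoms) else NULL
  ref <- frame_coords(trajectory, reference_frame)
  ref_sc <- weighted_centroid(ref[sc$indices, , drop = FALSE], w_sc)
  ref_tr <- weighted_centroid(ref[tr$indices, , drop = FALSE], w_tr)
  B <- rbind(frame_def$x_axis, frame_def$y_axis, frame_def$z_axis)
  coords <- trajectory$coords
  for (k in seq_len(trajectory$n_frames)) {
    xyz <- coords[, , k, drop = TRUE]
    d_sc <- ref_sc - weighted_centroid(xyz[sc$indices, , drop = FALSE],
                                       w_sc)
    d_tr <- ref_tr - weighted_centroid(xyz[tr$indices, , drop = FALSE],
                                       w_tr)
    # z component from the scaffold, in-plane components from the transport
    shift <- sum(d_tr * B[1, ]) * B[1, ] + sum(d_tr * B[2, ]) * B[2, ] +
      sum(d_sc * B[3, ]) * B[3, ]
    coords[, , k] <- sweep(xyz, 2, shift, "+")
  }
  trajectory3d(topo, coords, trajectory$labels)
}
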