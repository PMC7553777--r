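# Repeat-swap target generation and transition planning.
#
# In a transporter with internal two-fold inverted-repeat topology, an
# approximate model of the opposite-facing conformation is obtained by
# rotating the structure 180 degrees about any membrane-parallel axis and
# aligning it back with the repeats exchanged.  The rigid-body motion of
# the transport domain implied by that swapped alignment parameterises the
# conformational transition.

#' Generate the repeat-swap target model
#'
#' Rotates every atom 180 degrees about a membrane-parallel axis through
#' the frame origin.  The operation is an involution, flips the sign of the
#' transport domain's membrane-normal displacement while preserving its
#' magnitude, and leaves the atom identity list untouched.
#'
#' @param structure A `structure3d`.
#' @param frame A `membrane_frame`; the rotation axis passes through its
#'   origin.
#' @param in_plane_axis Optional rotation axis; must be orthogonal to the
#'   membrane normal (within 1e-6).  Defaults to `frame$x_axis`.
#' @return The rotated `structure3d`, with the axis used recorded in
#'   `metadata$swap_axis`.
#' @export
generate_swap_target <- function(structure, frame, in_plane_axis = NULL) {
  a <- if (is.null(in_plane_axis)) frame$x_axis else as.numeric(in_plane_axis)
  a <- a / sqrt(sum(a^2))
  if (abs(sum(a * frame$z_axis)) > 1e-6)
    stop("in_plane_axis is not in the membrane plane")
  M <- 2 * tcrossprod(a) - diag(3)   # 180-degree rotation, exact involution
  coords <- structure$coords
  for (m in seq_len(structure$n_models)) {
    p <- sweep(coords[, , m, drop = TRUE], 2, frame$origin)
    coords[, , m] <- sweep(p %*% M, 2, frame$origin, "+")
  }
  md <- structure$metadata
  md$swap_axis <- a
  structure3d(structure$atoms, coords, md)
}

# resolve a repeat mapping into the swapped atom-index pairing
# state repeat1 <-> target repeat2 and state repeat2 <-> target repeat1
swapped_pairing <- function(state, target, mapping, domain = NULL) {
  idx_state <- integer(0)
  idx_target <- integer(0)
  for (i in seq_along(mapping$pairs)) {
    p <- mapping$pairs[[i]]
    r1s <- resolve_selection(state,
                             selection(ranges = p[[1]],
                                       atoms = mapping$atoms))$indices
    r2s <- resolve_selection(state,
                             selection(ranges = p[[2]],
                                       atoms = mapping$atoms))$indices
    r1t <- resolve_selection(target,
                             selection(ranges = p[[1]],
                                       atoms = mapping$atoms))$indices
    r2t <- resolve_selection(target,
                             selection(ranges = p[[2]],
                                       atoms = mapping$atoms))$indices
    if (length(r1s) != length(r2t) || length(r2s) != length(r1t))
      stop("repeat pair ", i, " resolves to mismatched atom counts ",
           "after permutation (", length(r1s), " vs ", length(r2t), "; ",
           length(r2s), " vs ", length(r1t), ")")
    idx_state <- c(idx_state, r1s, r2s)
    idx_target <- c(idx_target, r2t, r1t)
  }
  if (!is.null(domain)) {
    d <- resolve_selection(state, domain)$indices
    keep <- idx_state %in% d & idx_target %in% d
    idx_state <- idx_state[keep]
    idx_target <- idx_target[keep]
  }
  if (length(idx_state) < 3L)
    stop("swapped pairing resolves to fewer than 3 atoms")
  list(state = idx_state, target = idx_target)
}

#' Superpose a structure onto its repeat-swapped target
#'
#' Builds the repeat-permuted correspondence (repeat 1 of the state against
#' repeat 2 of the target and vice versa), optionally restricted to a
#' domain, and performs a least-squares rigid fit of the state onto the
#' target under that pairing.
#'
#' @param state The original-state `structure3d`.
#' @param target The swap target (e.g. from [generate_swap_target()]).
#' @param mapping A `repeat_mapping`.
#' @param domain Optional `selection` restricting the fit (e.g. the
#'   transport domain).
#' @return A `superposition` (transform maps state onto target).
#' @export
swapped_repeat_superpose <- function(state, target, mapping,
                                     domain = NULL) {
  pr <- swapped_pairing(state, target, mapping, domain)
  superpose(model_coords(state)[pr$state, , drop = FALSE],
            model_coords(target)[pr$target, , drop = FALSE])
}

#' Plan the conformational transition toward the swap target
#'
#' Generates the repeat-swap target, removes the scaffold-frame alignment
#' (the target is re-posed so its swapped scaffold matches the state's
#' scaffold), then extracts per protomer the spin axis and spin delta from
#' the swapped transport-domain superposition and the change in the
#' transport-vs-scaffold membrane-normal displacement.  Because the swap
#' construction flips the sign of that displacement without changing its
#' magnitude, the planned displacement delta is minus twice the initial
#' value.
#'
#' @param state A `structure3d` of the starting conformation.
#' @param annotation A `topology_annotation`.
#' @param frame A `membrane_frame`.
#' @param in_plane_axis Optional membrane-parallel rotation axis for the
#'   target generation.
#' @return An object of class `transition_plan`: one entry per protomer
#'   with `spin_axis`, `spin_delta_deg`, `transport_fit_rmsd`,
#'   `scaffold_align_rmsd`, `distance_z_state`, `distance_z_target`,
#'   `distance_z_delta`; plus the axis used and the reference label.
#' @export
plan_transition <- function(state, annotation, frame,
                            in_plane_axis = NULL) {
  target <- generate_swap_target(state, frame, in_plane_axis)
  plans <- lapply(annotation$protomers, function(p) {
    sc_sel <- domain_selection(p, "scaffold", atoms = "calpha")
    tr_sel <- domain_selection(p, "transport", atoms = "calpha")
    # remove the scaffold-frame alignment: pose the target so its swapped
    # scaffold coincides with the state's scaffold
    pr_sc <- swapped_pairing(state, target, p$repeats, sc_sel)
    sup_sc <- superpose(model_coords(target)[pr_sc$target, , drop = FALSE],
                        model_coords(state)[pr_sc$state, , drop = FALSE])
    target_aligned <- set_coords(
      target, apply_transform(sup_sc$transform, model_coords(target)))
    sup_tr <- swapped_repeat_superpose(state, target_aligned, p$repeats,
                                       domain = tr_sel)
    sc_state <- resolve_selection(state, sc_sel)$coords
    tr_state <- resolve_selection(state, tr_sel)$coords
    sc_tgt <- resolve_selection(target_aligned, sc_sel)$coords
    tr_tgt <- resolve_selection(target_aligned, tr_sel)$coords
    dz_state <- distance_z(tr_state, sc_state, frame)
    dz_target <- distance_z(tr_tgt, sc_tgt, frame)
    list(name = p$name,
         spin_axis = sup_tr$rotation_axis,
         spin_delta_deg = sup_tr$rotation_angle,
         transport_fit_rmsd = sup_tr$rmsd,
         scaffold_align_rmsd = sup_sc$rmsd,
         distance_z_state = dz_state,
         distance_z_target = dz_target,
         distance_z_delta = dz_target - dz_state)
  })
  axis_used <- target$metadata$swap_axis
  structure(list(protomers = plans, in_plane_axis = axis_used,
                 reference = "state"), class = "transition_plan")
}

#' @export
print.transition_plan <- function(x, ...) {
  cat("transition plan (repeat-swap target):\n")
  for (p in x$protomers) {
    cat(sprintf(
      "  protomer %s: spin %.2f deg, distance_z %+.2f -> %+.2f A (delta %+.2f)\n",
      p$name, p$spin_delta_deg, p$distance_z_state, p$distance_z_target,
      p$distance_z_delta))
  }
  invisible(x)
}

#' Serialise a transition plan to JSON
#' @param plan A `transition_plan`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_transition_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
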