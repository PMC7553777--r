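# Collective variables for the biased transition, their evaluation on
# structures and trajectories, and emission of a Colvars-dialect restraint
# configuration.
#
# Four variable kinds describe the elevator transition: the spin of the
# transport domain about its rotation axis (degrees), its position along
# the membrane normal relative to the scaffold (Angstrom), the overall
# orientation of the scaffold (a best-fit quaternion, restrained to keep
# the protein from rotating as a whole), and the distance of the substrate
# from its binding site.

#' Define a collective variable
#'
#' @param name Variable name (used in emitted configs).
#' @param kind One of `"spin_angle"`, `"distance_z"`, `"orientation"`,
#'   `"site_distance"`.
#' @param group Main atom `selection` (spin_angle, distance_z,
#'   orientation).
#' @param ref_group Reference-group `selection` (distance_z: the scaffold).
#' @param axis Length-3 axis (spin_angle: the spin axis; distance_z
#'   defaults to the membrane normal).
#' @param site Binding-site `selection` (site_distance; C-alpha atoms).
#' @param ligand_res Residue name of the substrate (site_distance; its
#'   non-hydrogen atoms form the ligand group).
#' @return An object of class `colvar_spec`.
#' @export
colvar_spec <- function(name, kind = c("spin_angle", "distance_z",
                                       "orientation", "site_distance"),
                        group = NULL, ref_group = NULL, axis = NULL,
                        site = NULL, ligand_res = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
    spin_angle = !is.null(group) && !is.null(axis),
    distance_z = !is.null(group) && !is.null(ref_group),
    orientation = !is.null(group),
    site_distance = !is.null(site) && !is.null(ligand_res))
  if (!need) stop("colvar_spec '", name, "': required fields missing for ",
                  kind)
  structure(list(name = name, kind = kind, group = group,
                 ref_group = ref_group, axis = axis, site = site,
                 ligand_res = ligand_res), class = "colvar_spec")
}

#' Evaluate a collective variable on a set of coordinates
#'
#' @param spec A `colvar_spec`.
#' @param current A congruent `structure3d`, or an `n x 3` coordinate
#'   matrix congruent with `reference`.
#' @param reference The reference `structure3d` on which selections are
#'   resolved and relative to which spin/orientation are measured.
#' @param frame A `membrane_frame`.
#' @return Scalar (degrees for spin_angle, Angstrom for distance_z and
#'   site_distance) or a unit quaternion for orientation.
#' @export
evaluate_colvar <- function(spec, current, reference, frame) {
  cur <- if (inherits(current, "structure3d")) model_coords(current)
         else as.matrix(current)
  if (nrow(cur) != n_atoms(reference))
    stop("colvar '", spec$name, "': coordinates not congruent with the ",
         "reference")
  switch(spec$kind,
    spin_angle = {
      g <- resolve_selection(reference, spec$group)
      axis <- if (is.null(spec$axis)) frame$z_axis else spec$axis
      spin_angle(cur[g$indices, , drop = FALSE], g$coords, axis)
    },
    distance_z = {
      g <- resolve_selection(reference, spec$group)
      r <- resolve_selection(reference, spec$ref_group)
      distance_z(cur[g$indices, , drop = FALSE],
                 cur[r$indices, , drop = FALSE], frame)
    },
    orientation = {
      g <- resolve_selection(reference, spec$group)
      gc <- sweep(cur[g$indices, , drop = FALSE], 2,
                  colMeans(cur[g$indices, , drop = FALSE]))
      rc <- sweep(g$coords, 2, colMeans(g$coords))
      horn_quaternion(rc, gc)
    },
    site_distance = {
      s <- resolve_selection(reference, spec$site)
      l <- resolve_selection(reference,
                             selection(res_name = spec$ligand_res,
                                       atoms = "heavy"))
      sqrt(sum((colMeans(cur[l$indices, , drop = FALSE]) -
                  colMeans(cur[s$indices, , drop = FALSE]))^2))
    })
}

#' Evaluate collective variables along a trajectory
#'
#' One row per frame, one column per variable.  Orientation variables are
#' reported as their rotation angle from the reference, in degrees.
#'
#' @param trajectory A `trajectory3d` congruent with `reference`.
#' @param specs List of `colvar_spec`.
#' @param reference Reference `structure3d`.
#' @param frame A `membrane_frame`.
#' @return Data frame: `frame` column plus one column per colvar.
#' @export
colvar_timeseries <- function(trajectory, specs, reference, frame) {
  stopifnot(n_atoms(trajectory$topology) == n_atoms(reference))
  out <- data.frame(frame = seq_len(trajectory$n_frames))
  for (sp in specs) {
    vals <- vapply(seq_len(trajectory$n_frames), function(k) {
      v <- evaluate_colvar(sp, frame_coords(trajectory, k), reference,
                           frame)
      if (sp$kind == "orientation") rotation_angle_axis(v)$angle_deg
      else v
    }, numeric(1))
    out[[sp$name]] <- vals
  }
  out
}

#' Write a time-series table as TSV
#' @param series Data frame (e.g. from [colvar_timeseries()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_timeseries <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Define a restraint schedule for a collective variable
#'
#' The staged protocol applies a moving harmonic restraint through four
#' phases: a short transition to a common reference state, a hold, the
#' main transition to the target, and a final hold.
#'
#' @param colvar Name of the restrained collective variable.
#' @param style `"harmonic"` or `"half_harmonic_upper"` (an upper wall).
#' @param force_constant Positive force constant.
#' @param unit Unit string for the force constant (documentation only).
#' @param center Initial restraint center (wall position for walls).
#' @param target_center Final center of the moving restraint (harmonic
#'   only).
#' @param stages_ns Named numeric vector of phase durations in ns:
#'   `ref_transition`, `hold1`, `main_transition`, `hold2`.
#' @return An object of class `restraint_schedule`.
#' @export
restraint_schedule <- function(colvar,
                               style = c("harmonic",
                                         "half_harmonic_upper"),
                               force_constant, unit = "", center = 0,
                               target_center = NULL,
                               stages_ns = c(ref_transition = 10,
                                             hold1 = 10,
                                             main_transition = 100,
                                             hold2 = 50)) {
  style <- match.arg(style)
  stopifnot(force_constant > 0, all(stages_ns > 0))
  structure(list(colvar = colvar, style = style,
                 force_constant = force_constant, unit = unit,
                 center = center, target_center = target_center,
                 stages_ns = stages_ns), class = "restraint_schedule")
}

#' Standard restraint set for the biased transition
#'
#' Builds one schedule per collective variable with the force constants of
#' the staged elevator-transition protocol: 8 kcal/mol/deg^2 on the spin
#' angle, 80 kcal/mol/A^2 on the membrane-normal distance, 100,000
#' kcal/mol on the scaffold orientation, and for the substrate a
#' half-harmonic upper wall at 2.0 A with 1.0 kcal/mol/A^2.
#'
#' @param specs List of `colvar_spec`.
#' @param plan Optional `transition_plan` supplying target centers for the
#'   spin and distance variables (first protomer entries are matched by
#'   spec order within each kind).
#' @param targets Optional named list `colvar name -> target center`,
#'   overriding `plan`.
#' @return List of `restraint_schedule`.
#' @export
default_restraints <- function(specs, plan = NULL, targets = NULL) {
  plan_of <- function(nm, field) {
    if (!is.null(targets) && !is.null(targets[[nm]])) return(targets[[nm]])
    NULL
  }
  lapply(specs, function(sp) {
    switch(sp$kind,
      spin_angle = restraint_schedule(
        sp$name, "harmonic", 8, "kcal/mol/deg^2", center = 0,
        target_center = plan_of(sp$name, "spin")),
      distance_z = restraint_schedule(
        sp$name, "harmonic", 80, "kcal/mol/A^2", center = 0,
        target_center = plan_of(sp$name, "dz")),
      orientation = restraint_schedule(
        sp$name, "harmonic", 100000, "kcal/mol",
        center = "(1.0, 0.0, 0.0, 0.0)"),
      site_distance = restraint_schedule(
        sp$name, "half_harmonic_upper", 1.0, "kcal/mol/A^2",
        center = 2.0))
  })
}

fmt_num <- function(x) {
  if (is.character(x)) return(x)
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

emit_atom_numbers <- function(structure, sel, indent) {
  g <- resolve_selection(structure, sel)
  nums <- sort(structure$atoms$serial[g$indices])
  paste0(indent, "atomNumbers { ", paste(nums, collapse = " "), " }")
}

#' Emit a Colvars-dialect configuration
#'
#' Writes the collective-variable definitions (with 1-based,
#' ascending-sorted atom-number lists resolved against `structure`) and
#' the restraint blocks.  Harmonic schedules become `harmonic` blocks with
#' `forceConstant`/`centers`/`targetCenters`/`targetNumSteps` (the main
#' transition phase, at the given timestep); walls become `harmonicWalls`
#' blocks.  Output is byte-stable for identical inputs.
#'
#' @param specs List of `colvar_spec`.
#' @param schedules List of `restraint_schedule`; every schedule must
#'   reference a defined spec.
#' @param path Output path.
#' @param structure The `structure3d` used to resolve atom numbers.
#' @param timestep_fs Integration timestep used to convert ns to steps
#'   (default 2 fs).
#' @param ref_positions_file Optional PDB filename recorded for
#'   orientation references.
#' @return Invisibly, the path.
#' @export
emit_colvars_config <- function(specs, schedules, path, structure,
                                timestep_fs = 2,
                                ref_positions_file = NULL) {
  spec_names <- vapply(specs, `[[`, "", "name")
  for (sch in schedules) {
    if (!(sch$colvar %in% spec_names))
      stop("schedule references undefined colvar '", sch$colvar, "'")
  }
  L <- character(0)
  add <- function(...) L <<- c(L, ...)
  add("# collective variables and staged restraints for a biased",
      "# elevator-transition simulation")
  for (sp in specs) {
    add("", "colvar {", paste0("    name ", sp$name))
    if (sp$kind == "spin_angle") {
      add("    spinAngle {", "        atoms {",
          emit_atom_numbers(structure, sp$group, "            "),
          "        }",
          sprintf("        axis ( %s, %s, %s )", fmt_num(sp$axis[1]),
                  fmt_num(sp$axis[2]), fmt_num(sp$axis[3])),
          "    }")
    } else if (sp$kind == "distance_z") {
      ax <- if (is.null(sp$axis)) c(0, 0, 1) else sp$axis
      add("    distanceZ {", "        main {",
          emit_atom_numbers(structure, sp$group, "            "),
          "        }", "        ref {",
          emit_atom_numbers(structure, sp$ref_group, "            "),
          "        }",
          sprintf("        axis ( %s, %s, %s )", fmt_num(ax[1]),
                  fmt_num(ax[2]), fmt_num(ax[3])),
          "    }")
    } else if (sp$kind == "orientation") {
      add("    orientation {", "        atoms {",
          emit_atom_numbers(structure, sp$group, "            "),
          "        }")
      if (!is.null(ref_positions_file))
        add(paste0("        refPositionsFile ", ref_positions_file))
      add("    }")
    } else if (sp$kind == "site_distance") {
      add("    distance {", "        group1 {",
          emit_atom_numbers(structure,
                            selection(res_name = sp$ligand_res,
                                      atoms = "heavy"), "            "),
          "        }", "        group2 {",
          emit_atom_numbers(structure, sp$site, "            "),
          "        }", "    }")
    }
    add("}")
  }
  steps_per_ns <- 1e6 / timestep_fs
  for (sch in schedules) {
    st <- sch$stages_ns
    add("", sprintf("# schedule for %s: phases %s ns at %s fs/step",
                    sch$colvar,
                    paste(fmt_num(unname(st)), collapse = "/"),
                    fmt_num(timestep_fs)))
    if (sch$style == "harmonic") {
      add("harmonic {", paste0("    colvars ", sch$colvar),
          paste0("    forceConstant ", fmt_num(sch$force_constant)),
          paste0("    centers ", fmt_num(sch$center)))
      if (!is.null(sch$target_center))
        add(paste0("    targetCenters ", fmt_num(sch$target_center)))
      add(paste0("    targetNumSteps ",
                 fmt_num(st[["main_transition"]] * steps_per_ns)),
          "}")
    } else {
      add("harmonicWalls {", paste0("    colvars ", sch$colvar),
          paste0("    upperWalls ", fmt_num(sch$center)),
          paste0("    upperWallConstant ", fmt_num(sch$force_constant)),
          "}")
    }
  }
  writeLines(L, path)
  invisible(path)
}

#' Parse an emitted Colvars-dialect configuration
#'
#' A round-trip reader for the dialect written by [emit_colvars_config()]:
#' nested `key { ... }` blocks with `key value` assignments, `#` comments,
#' parenthesised vectors and braced atom-number lists.  Repeated block
#' keys (e.g. multiple `colvar` blocks) accumulate into unnamed lists.
#'
#' @param path Config file path.
#' @return Nested list; numeric scalars/vectors are converted.
#' @export
parse_colvars_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  txt <- paste(raw, collapse = "\n")
  txt <- gsub("\\{", " { ", txt)
  txt <- gsub("\\}", " } ", txt)
  txt <- gsub("\\(", " ( ", txt)
  txt <- gsub("\\)", " ) ", txt)
  txt <- gsub(",", " ", txt)
  lines <- strsplit(txt, "\n")[[1]]
  toks <- unlist(strsplit(trimws(lines), "[ \t]+"))
  toks <- toks[toks != ""]
  pos <- 1L
  parse_block <- function() {
    out <- list()
    while (pos <= length(toks)) {
      tk <- toks[pos]
      if (tk == "}") { pos <<- pos + 1L; return(out) }
      key <- tk; pos <<- pos + 1L
      if (key == "atomNumbers" && pos <= length(toks) &&
          toks[pos] == "{") {
        pos <<- pos + 1L
        vals <- character(0)
        while (toks[pos] != "}") { vals <- c(vals, toks[pos])
          pos <<- pos + 1L }
        pos <<- pos + 1L
        out[[key]] <- as.numeric(vals)
        next
      }
      if (pos <= length(toks) && toks[pos] == "{") {
        pos <<- pos + 1L
        val <- parse_block()
      } else {
        vals <- character(0)
        if (pos <= length(toks) && toks[pos] == "(") {
          pos <<- pos + 1L
          while (toks[pos] != ")") { vals <- c(vals, toks[pos]);
            pos <<- pos + 1L }
          pos <<- pos + 1L
        } else {
          # one value token (the dialect writes one assignment per key,
          # except atomNumbers which uses braces)
          vals <- toks[pos]; pos <<- pos + 1L
        }
        num <- suppressWarnings(as.numeric(vals))
        val <- if (!anyNA(num)) num else paste(vals, collapse = " ")
      }
      if (key %in% names(out) || key %in% c("colvar", "harmonic",
                                            "harmonicWalls")) {
        if (is.null(out[[key]]) || !is.list(out[[key]]) ||
            !isTRUE(attr(out[[key]], "multi"))) {
          prev <- out[[key]]
          out[[key]] <- if (is.null(prev)) list(val) else list(prev, val)
          attr(out[[key]], "multi") <- TRUE
        } else {
          out[[key]] <- c(out[[key]], list(val))
          attr(out[[key]], "multi") <- TRUE
        }
      } else {
        out[[key]] <- val
      }
    }
    out
  }
  parse_block()
}
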