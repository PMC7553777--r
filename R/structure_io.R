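# Structure container, PDB reading/writing and residue-range selections.
# Parsing is delegated to bio3d; records are written directly in the fixed
# PDB column layout so HETATM typing and MODEL blocks survive round trips.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Construct a structure object
#'
#' The in-memory representation of a (possibly multi-model) structure: an
#' atom table plus an `n_atoms x 3 x n_models` coordinate array.  All models
#' share the atom identity list.
#'
#' @param atoms Data frame with columns `serial`, `name`, `elem`,
#'   `res_name`, `chain`, `res_seq`, `ins`, `alt`, `occ`, `het`.
#' @param coords Numeric `n x 3` matrix or `n x 3 x m` array, Angstrom.
#' @param metadata Optional list (`method`, `resolution`).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, coords, metadata = list()) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3L)
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  need <- c("serial", "name", "elem", "res_name", "chain", "res_seq",
            "ins", "alt", "occ", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  structure(list(atoms = atoms, coords = coords,
                 n_models = dim(coords)[3], metadata = metadata),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d model(s), chains %s\n",
              nrow(x$atoms), x$n_models,
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `structure3d`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of one model
#' @param structure A `structure3d`.
#' @param model 1-based model index.
#' @return `n x 3` coordinate matrix.
#' @export
model_coords <- function(structure, model = 1L) {
  stopifnot(model >= 1L, model <= structure$n_models)
  structure$coords[, , model, drop = TRUE]
}

#' Replace the coordinates of a structure
#' @param structure A `structure3d`.
#' @param coords `n x 3` matrix or `n x 3 x m` array.
#' @return The modified structure.
#' @export
set_coords <- function(structure, coords) {
  structure3d(structure$atoms, coords, structure$metadata)
}

# per-atom identity strings; the congruence key for models and trajectories
atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$name, sep = "|")
}

# approximate atomic masses for mass-weighted centroids
atom_masses <- function(atoms) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, FE = 55.845, ZN = 65.38, NA_ = 22.99, MG = 24.305)
  el <- toupper(atoms$elem)
  el[el == "NA"] <- "NA_"
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}

# light line-level validation so parse failures name the offending line
validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("PDB parse error in ", path, " at line ", i,
           ": unreadable coordinates")
  }
  invisible(idx)
}

#' Read a structure from a PDB file
#'
#' Atoms are kept in file order.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order).  HETATM records
#' are retained and flagged in the `het` column.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"first"` keeps model 1 only; `"all"` keeps every
#'   MODEL block.
#' @return A `structure3d`.
#' @export
read_structure <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- validate_pdb_lines(lines, path)
  if (length(idx) == 0L) stop("empty structure: no atoms in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    elem = ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety),
                  at$elesy),
    res_name = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    res_seq = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (model_policy == "first") xyz <- xyz[1, , drop = FALSE]
  # alt-loc resolution: within each (chain, res_seq, ins, name) group keep
  # the highest-occupancy record, ties broken by file order
  key <- atom_identity(atoms)
  keep <- !logical(nrow(atoms))
  dup_groups <- unique(key[duplicated(key)])
  for (k in dup_groups) {
    rows <- which(key == k)
    best <- rows[which.max(atoms$occ[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  ci <- bio3d::atom2xyz(which(keep))
  xyz <- xyz[, ci, drop = FALSE]
  nm <- nrow(xyz); na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(na, 3, nm))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  structure3d(atoms, coords, metadata = read_pdb_metadata(lines))
}

guess_element <- function(name) {
  el <- sub("^[0-9]*", "", name)
  substr(el, 1, 1)
}

read_pdb_metadata <- function(lines) {
  md <- list()
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) md$method <- trimws(substr(ex[1], 11, 80))
  res <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res)) {
    v <- suppressWarnings(as.numeric(regmatches(
      res[1], regexpr("[0-9]+\\.?[0-9]*", substr(res[1], 23, 80)))))
    if (length(v) && !is.na(v)) md$resolution <- v
  }
  md
}

fmt_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         sprintf("%-4s", paste0(" ", name)))
}

#' Write a structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks; coordinates
#' use the standard three-decimal fixed columns.
#'
#' @param structure A `structure3d`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_structure <- function(structure, path) {
  if (!inherits(structure, "structure3d") || nrow(structure$atoms) == 0L)
    stop("empty structure: nothing to write")
  at <- structure$atoms
  out <- character(0)
  md <- structure$metadata
  if (!is.null(md$method))
    out <- c(out, sprintf("EXPDTA    %s", md$method))
  if (!is.null(md$resolution))
    out <- c(out, sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", md$resolution))
  multi <- structure$n_models > 1L
  for (m in seq_len(structure$n_models)) {
    xyz <- structure$coords[, , m, drop = TRUE]
    if (any(xyz >= 1e4 | xyz <= -1e3))
      stop("coordinate overflows fixed PDB columns (|x| too large)")
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    rec <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(at$het, "HETATM", "ATOM"),
                   at$serial %% 100000L,
                   fmt_atom_name(at$name),
                   ifelse(at$alt == "", " ", at$alt),
                   at$res_name, at$chain, at$res_seq %% 10000L,
                   ifelse(at$ins == "", " ", at$ins),
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   at$occ, 0, at$elem)
    out <- c(out, rec)
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Define an atom selection
#'
#' Selections name residue ranges (inclusive on both ends, author
#' numbering) on chains, plus an atom filter.  HETATM records are excluded
#' unless the selection names a residue explicitly through `res_name`.
#'
#' @param chain,start,end Parallel vectors defining ranges
#'   `(chain, start..end)`; alternatively supply `ranges`.
#' @param atoms Atom filter: `"calpha"`, `"backbone"` (N, CA, C, O),
#'   `"heavy"` (non-hydrogen), `"all"`, `"site"` (CA plus heavy side-chain
#'   atoms), or an explicit character vector of atom names.
#' @param res_name Optional residue name; selects matching residues
#'   (including HETATM, e.g. a bound substrate) instead of requiring
#'   protein records.
#' @param ranges Optional data frame with columns `chain`, `start`, `end`.
#' @return An object of class `selection`.
#' @export
selection <- function(chain = NULL, start = NULL, end = NULL,
                      atoms = "calpha", res_name = NULL, ranges = NULL) {
  if (is.null(ranges)) {
    if (!is.null(chain)) {
      ranges <- data.frame(chain = as.character(chain),
                           start = as.integer(start),
                           end = as.integer(end),
                           stringsAsFactors = FALSE)
    }
  } else {
    ranges <- data.frame(chain = as.character(ranges$chain),
                         start = as.integer(ranges$start),
                         end = as.integer(ranges$end),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(ranges)) {
    if (nrow(ranges) == 0L) stop("selection has no ranges")
    if (any(ranges$start > ranges$end))
      stop("selection range with start > end")
  }
  if (is.null(ranges) && is.null(res_name))
    stop("selection needs residue ranges or a res_name")
  known <- c("calpha", "backbone", "heavy", "all", "site")
  named <- length(atoms) > 1L || !(atoms[1] %in% known)
  structure(list(ranges = ranges, atoms = atoms, named = named,
                 res_name = res_name), class = "selection")
}

selection_filter_mask <- function(atoms_df, sel) {
  if (sel$named) return(atoms_df$name %in% sel$atoms)
  switch(sel$atoms,
    calpha = atoms_df$name == "CA",
    backbone = atoms_df$name %in% c("N", "CA", "C", "O"),
    heavy = toupper(atoms_df$elem) != "H",
    site = toupper(atoms_df$elem) != "H" &
      !(atoms_df$name %in% c("N", "C", "O")),
    all = rep(TRUE, nrow(atoms_df))
  )
}

#' Resolve a selection on a structure
#'
#' Atoms are returned in structure (file) order regardless of the order of
#' the selection's ranges.
#'
#' @param structure A `structure3d`.
#' @param sel A `selection`.
#' @param model Model whose coordinates are attached.
#' @return An object of class `atom_group`: `indices` (row indices into the
#'   atom table), `atoms`, `coords` (n x 3), `n`.
#' @export
resolve_selection <- function(structure, sel, model = 1L) {
  at <- structure$atoms
  if (!is.null(sel$res_name)) {
    in_range <- at$res_name %in% sel$res_name
  } else {
    in_range <- logical(nrow(at))
  }
  fmask <- selection_filter_mask(at, sel)
  if (!is.null(sel$ranges)) {
    rmask <- logical(nrow(at))
    for (r in seq_len(nrow(sel$ranges))) {
      hit <- at$chain == sel$ranges$chain[r] &
        at$res_seq >= sel$ranges$start[r] &
        at$res_seq <= sel$ranges$end[r]
      if (is.null(sel$res_name)) hit <- hit & !at$het & !sel_is_nonstd(at)
      hit <- hit & fmask
      if (!any(hit))
        stop(sprintf("empty selection: range %s %d-%d matches no atoms",
                     sel$ranges$chain[r], sel$ranges$start[r],
                     sel$ranges$end[r]))
      rmask <- rmask | hit
    }
    in_range <- if (is.null(sel$res_name)) rmask else (in_range & rmask)
  } else {
    in_range <- in_range & fmask
  }
  idx <- which(in_range)
  if (length(idx) == 0L) stop("empty selection: no atoms matched")
  structure(list(indices = idx, atoms = at[idx, , drop = FALSE],
                 coords = structure$coords[idx, , model, drop = TRUE],
                 n = length(idx)), class = "atom_group")
}

# non-standard residues are excluded from protein selections
sel_is_nonstd <- function(atoms_df) !(atoms_df$res_name %in% STANDARD_AA)

#' Construct a coordinate trajectory
#'
#' @param topology A single-model `structure3d` used as the reference atom
#'   list (a multi-model structure contributes its models as frames).
#' @param coords Optional `n x 3 x F` array of frame coordinates; defaults
#'   to the topology's own models.
#' @param labels Optional frame labels.
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, coords = NULL, labels = NULL) {
  if (is.null(coords)) coords <- topology$coords
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(dim(coords)[1] == n_atoms(topology), dim(coords)[2] == 3L)
  topo <- structure3d(topology$atoms,
                      topology$coords[, , 1, drop = FALSE],
                      topology$metadata)
  if (is.null(labels)) labels <- seq_len(dim(coords)[3])
  structure(list(topology = topo, coords = coords,
                 n_frames = dim(coords)[3], labels = labels),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d frames x %d atoms\n", x$n_frames,
              n_atoms(x$topology)))
  invisible(x)
}

#' Coordinates of one trajectory frame
#' @param traj A `trajectory3d`.
#' @param frame 1-based frame index.
#' @return `n x 3` matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= traj$n_frames)
  traj$coords[, , frame, drop = TRUE]
}

#' Read an ordered set of PDB files as a trajectory
#'
#' Multi-model files contribute one frame per model; all frames must be
#' congruent (same ordered chain/residue/atom-name identity list) with the
#' first file.
#'
#' @param paths Character vector of PDB paths, in frame order.
#' @return A `trajectory3d`.
#' @export
read_trajectory <- function(paths) {
  stopifnot(length(paths) >= 1L)
  frames <- list()
  topo <- NULL
  ref_id <- NULL
  fi <- 0L
  for (p in paths) {
    s <- read_structure(p, model_policy = "all")
    id <- atom_identity(s$atoms)
    if (is.null(topo)) {
      topo <- s
      ref_id <- id
    } else if (length(id) != length(ref_id) || any(id != ref_id)) {
      stop("trajectory congruence error at frame ", fi + 1L,
           " (", p, "): atom identity differs from first frame")
    }
    for (m in seq_len(s$n_models)) {
      fi <- fi + 1L
      frames[[fi]] <- s$coords[, , m, drop = TRUE]
    }
  }
  coords <- array(NA_real_, dim = c(n_atoms(topo), 3, fi))
  for (k in seq_len(fi)) coords[, , k] <- frames[[k]]
  trajectory3d(topo, coords)
}

#' Linear coordinate interpolation between two states
#'
#' Frame `k` (0-based) has coordinates `a + k/(n-1) * (b - a)`, so the first
#' and last frames are exactly the two input states.
#'
#' @param state_a,state_b Congruent `structure3d` objects (model 1 used).
#' @param n_frames Number of frames, >= 2.
#' @return A `trajectory3d`.
#' @export
interpolate_states <- function(state_a, state_b, n_frames) {
  stopifnot(n_frames >= 2L)
  ida <- atom_identity(state_a$atoms)
  idb <- atom_identity(state_b$atoms)
  if (length(ida) != length(idb) || any(ida != idb))
    stop("congruence error: atom identity lists differ between states")
  a <- model_coords(state_a, 1L)
  b <- model_coords(state_b, 1L)
  coords <- array(NA_real_, dim = c(nrow(a), 3, n_frames))
  for (k in seq_len(n_frames)) {
    f <- (k - 1) / (n_frames - 1)
    coords[, , k] <- a + f * (b - a)
  }
  trajectory3d(state_a, coords)
}
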