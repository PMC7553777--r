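# Topology annotations: which residues form the scaffold and transport
# domains, the inverted-repeat pairing, helix segments and the binding
# site.  Supplied by the user as YAML for real structures, or generated
# alongside synthetic bundles.

ranges_df <- function(chain, start, end) {
  data.frame(chain = as.character(chain), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

n_res_in_ranges <- function(r) sum(r$end - r$start + 1L)

#' Pair the two halves of an inverted repeat
#'
#' Each pair maps a residue range of repeat 1 to the equivalent range of
#' repeat 2 (equal residue counts, matched in order), defining the
#' atom-order permutation used when an inverted-repeat structure is aligned
#' to its repeat-swapped image.
#'
#' @param pairs List of two-element lists; each element is a range data
#'   frame (`chain`, `start`, `end`) for repeat 1 and repeat 2.
#' @param atoms Atom filter used when the mapping is resolved (default
#'   C-alpha).
#' @return An object of class `repeat_mapping`.
#' @export
repeat_mapping <- function(pairs, atoms = "calpha") {
  stopifnot(length(pairs) >= 1L)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stopifnot(length(p) == 2L)
    if (n_res_in_ranges(p[[1]]) != n_res_in_ranges(p[[2]]))
      stop("repeat pair ", i, " has unequal residue counts (",
           n_res_in_ranges(p[[1]]), " vs ", n_res_in_ranges(p[[2]]), ")")
  }
  for (side in 1:2) {
    segs <- do.call(rbind, lapply(pairs, `[[`, side))
    segs <- segs[order(segs$chain, segs$start), , drop = FALSE]
    if (nrow(segs) > 1L) {
      same <- segs$chain[-1] == segs$chain[-nrow(segs)]
      if (any(same & segs$start[-1] <= segs$end[-nrow(segs)]))
        stop("overlapping ranges within repeat ", side)
    }
  }
  structure(list(pairs = pairs, atoms = atoms), class = "repeat_mapping")
}

#' Describe one protomer's topology
#'
#' @param name Protomer label (e.g. `"A"`).
#' @param chains Chain identifiers belonging to the protomer.
#' @param scaffold,transport Range data frames (`chain`, `start`, `end`)
#'   for the static scaffold and mobile transport domain.
#' @param repeats A `repeat_mapping` for the protomer's inverted repeat.
#' @param helices Named list of range data frames, one per helix segment.
#' @param binding_site Optional range data frame for the substrate-binding
#'   residues.
#' @return An object of class `protomer_annotation`.
#' @export
protomer_annotation <- function(name, chains, scaffold, transport, repeats,
                                helices = list(), binding_site = NULL) {
  stopifnot(inherits(repeats, "repeat_mapping"))
  ov <- merge(scaffold, transport, by = "chain")
  if (nrow(ov) && any(ov$start.x <= ov$end.y & ov$start.y <= ov$end.x))
    stop("scaffold and transport domains overlap in protomer ", name)
  structure(list(name = name, chains = chains, scaffold = scaffold,
                 transport = transport, repeats = repeats,
                 helices = helices, binding_site = binding_site),
            class = "protomer_annotation")
}

#' Full topology annotation
#'
#' @param protomers List of `protomer_annotation` objects.
#' @param substrate Optional residue name of the bound substrate (selected
#'   as HETATM heavy atoms).
#' @return An object of class `topology_annotation`.
#' @export
topology_annotation <- function(protomers, substrate = NULL) {
  stopifnot(length(protomers) >= 1L,
            all(vapply(protomers, inherits, TRUE, "protomer_annotation")))
  names(protomers) <- vapply(protomers, `[[`, "", "name")
  structure(list(protomers = protomers, substrate = substrate),
            class = "topology_annotation")
}

#' @export
print.topology_annotation <- function(x, ...) {
  cat(sprintf("topology annotation: %d protomer(s)%s\n",
              length(x$protomers),
              if (is.null(x$substrate)) ""
              else paste0(", substrate ", x$substrate)))
  invisible(x)
}

yaml_ranges <- function(r) {
  lapply(seq_len(nrow(r)), function(i)
    list(chain = r$chain[i], start = r$start[i], end = r$end[i]))
}

parse_ranges <- function(lst) {
  do.call(rbind, lapply(lst, function(e)
    ranges_df(e$chain, e$start, e$end)))
}

#' Read a topology annotation from YAML
#'
#' The schema mirrors [topology_annotation()]: a `substrate` residue name
#' and a `protomers` list, each with `name`, `chains`, `scaffold`,
#' `transport`, `repeats` (list of `{repeat1: [...], repeat2: [...]}`),
#' `helices` (named map) and optional `binding_site`; all ranges are
#' `{chain, start, end}` with inclusive author numbering.
#'
#' @param path YAML file path.
#' @return A `topology_annotation`.
#' @export
read_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  prot <- lapply(y$protomers, function(p) {
    reps <- repeat_mapping(lapply(p$repeats, function(rp)
      list(parse_ranges(rp$repeat1), parse_ranges(rp$repeat2))))
    hel <- lapply(p$helices, parse_ranges)
    bs <- if (!is.null(p$binding_site)) parse_ranges(p$binding_site)
    protomer_annotation(p$name, unlist(p$chains), parse_ranges(p$scaffold),
                        parse_ranges(p$transport), reps, hel, bs)
  })
  topology_annotation(prot, substrate = y$substrate)
}

#' Write a topology annotation to YAML
#'
#' @param annotation A `topology_annotation`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation <- function(annotation, path) {
  y <- list(
    substrate = annotation$substrate,
    protomers = lapply(annotation$protomers, function(p) {
      list(name = p$name, chains = as.list(p$chains),
           scaffold = yaml_ranges(p$scaffold),
           transport = yaml_ranges(p$transport),
           repeats = lapply(p$repeats$pairs, function(rp)
             list(repeat1 = yaml_ranges(rp[[1]]),
                  repeat2 = yaml_ranges(rp[[2]]))),
           helices = lapply(p$helices, yaml_ranges),
           binding_site = if (!is.null(p$binding_site))
             yaml_ranges(p$binding_site))
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# selection over a protomer's domain ranges with a chosen atom filter
domain_selection <- function(protomer, domain = c("transport", "scaffold"),
                             atoms = "calpha") {
  domain <- match.arg(domain)
  selection(ranges = protomer[[domain]], atoms = atoms)
}
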