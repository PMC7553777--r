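# Model-geometry quality: per-residue C-alpha to carbonyl-carbon bond
# lengths, a simple internal benchmark of coordinate accuracy, and their
# aggregation across structure sets.

#' Per-residue C-alpha to carbonyl-carbon distances
#'
#' For every standard amino-acid residue carrying both a CA and a C atom
#' (after alternate-location resolution at read time), the intra-residue
#' CA-C Euclidean distance is computed; residues missing either atom are
#' counted as excluded.
#'
#' @param structure A `structure3d` (model 1 used).
#' @param model Model index.
#' @return An object of class `bond_length_stats`: `distances` (data frame
#'   with `chain`, `res_seq`, `ins`, `res_name`, `distance`), `median`,
#'   `n_residues`, `n_excluded`, `method`, `resolution`.
#' @export
ca_c_distances <- function(structure, model = 1L) {
  at <- structure$atoms
  xyz <- structure$coords[, , model, drop = TRUE]
  prot <- !at$het & at$res_name %in% STANDARD_AA &
    at$name %in% c("CA", "C")
  if (!any(prot)) stop("no standard protein residues in structure")
  sub <- at[prot, , drop = FALSE]
  sxyz <- xyz[prot, , drop = FALSE]
  key <- paste(sub$chain, sub$res_seq, sub$ins, sep = "|")
  ukeys <- unique(key)
  rows <- list(); n_excl <- 0L
  for (k in ukeys) {
    i <- which(key == k)
    ca <- i[sub$name[i] == "CA"][1]
    cc <- i[sub$name[i] == "C"][1]
    if (is.na(ca) || is.na(cc)) { n_excl <- n_excl + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = sub$chain[ca], res_seq = sub$res_seq[ca],
      ins = sub$ins[ca], res_name = sub$res_name[ca],
      distance = sqrt(sum((sxyz[ca, ] - sxyz[cc, ])^2)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no residues with both CA and C atoms")
  d <- do.call(rbind, rows)
  structure(list(distances = d, median = stats::median(d$distance),
                 n_residues = nrow(d), n_excluded = n_excl,
                 method = structure$metadata$method,
                 resolution = structure$metadata$resolution),
            class = "bond_length_stats")
}

#' @export
print.bond_length_stats <- function(x, ...) {
  cat(sprintf(
    "CA-C bond lengths: median %.4f A over %d residues (%d excluded)\n",
    x$median, x$n_residues, x$n_excluded))
  invisible(x)
}

#' Aggregate bond-length statistics across structures
#'
#' Filters per-structure statistics (experimental method, maximum
#' resolution) and summarises the per-structure medians by method group.
#'
#' @param stats_list List of `bond_length_stats`.
#' @param methods Optional character vector of method strings to keep.
#' @param max_resolution Optional resolution cutoff in Angstrom
#'   (structures resolved worse than, i.e. numerically above, the cutoff
#'   are excluded).
#' @return List with `structures` (per-structure table with an `included`
#'   flag and exclusion `reason`) and `summary` (per-method group: `n`,
#'   `median_of_medians`, `q25`, `q75`).
#' @export
aggregate_bond_stats <- function(stats_list, methods = NULL,
                                 max_resolution = NULL) {
  if (length(stats_list) == 0L)
    return(list(structures = data.frame(), summary = data.frame()))
  per <- do.call(rbind, lapply(seq_along(stats_list), function(i) {
    s <- stats_list[[i]]
    data.frame(id = i,
               method = if (is.null(s$method)) NA_character_ else s$method,
               resolution = if (is.null(s$resolution)) NA_real_
                            else s$resolution,
               median = s$median, n_residues = s$n_residues,
               stringsAsFactors = FALSE)
  }))
  per$included <- TRUE
  per$reason <- ""
  if (!is.null(methods)) {
    bad <- !(per$method %in% methods)
    per$included[bad] <- FALSE
    per$reason[bad] <- "method"
  }
  if (!is.null(max_resolution)) {
    bad <- !is.na(per$resolution) & per$resolution > max_resolution
    per$included[bad] <- FALSE
    per$reason[bad] <- trimws(paste(per$reason[bad], "resolution"))
  }
  inc <- per[per$included, , drop = FALSE]
  if (nrow(inc) == 0L) {
    warning("no structures left after filtering")
    return(list(structures = per, summary = data.frame()))
  }
  groups <- split(inc, inc$method)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    m <- groups[[g]]$median
    data.frame(method = g, n = length(m),
               median_of_medians = stats::median(m),
               q25 = unname(stats::quantile(m, 0.25)),
               q75 = unname(stats::quantile(m, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(structures = per, summary = summ)
}

#' Write per-residue bond-length distances as CSV
#' @param stats A `bond_length_stats`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bond_stats <- function(stats, path) {
  utils::write.csv(stats$distances, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
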