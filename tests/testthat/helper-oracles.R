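# Independent oracles used to pin the semantics of the geometric core.

# Kabsch SVD superposition, independent of the quaternion implementation.
# Returns the minimal RMSD and the rotation applied to centered mobile.
kabsch_oracle <- function(mobile, reference, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else weights
  cm <- colSums(mobile * w) / sum(w)
  cr <- colSums(reference * w) / sum(w)
  Xc <- sweep(mobile, 2, cm)
  Yc <- sweep(reference, 2, cr)
  sv <- svd(t(Xc * w) %*% Yc)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- Xc %*% t(R)
  list(rmsd = sqrt(sum(w * rowSums((moved - Yc)^2)) / sum(w)), R = R)
}

# brute-force spin oracle: scan rotations about the axis (through the
# centroids) at 0.01-degree resolution, minimising the RMSD between the
# rotated reference and the group; coarse pass then local refinement
spin_grid_oracle <- function(group, reference, axis, fine = 0.01) {
  a <- axis / sqrt(sum(axis^2))
  gc <- sweep(group, 2, colMeans(group))
  rc <- sweep(reference, 2, colMeans(reference))
  rot_about <- function(theta_deg) {
    th <- theta_deg * pi / 180
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  score <- function(theta) {
    moved <- rc %*% t(rot_about(theta))
    sum((moved - gc)^2)
  }
  coarse <- seq(-179.5, 180, by = 0.5)
  s1 <- vapply(coarse, score, numeric(1))
  best <- coarse[which.min(s1)]
  finegrid <- seq(best - 0.75, best + 0.75, by = fine)
  s2 <- vapply(finegrid, score, numeric(1))
  th <- finegrid[which.min(s2)]
  th <- th %% 360
  if (th > 180) th <- th - 360
  th
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

random_points <- function(n, spread = 10) {
  matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
}

# tiny hand-written PDB fixtures
write_altloc_fixture <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.400   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

write_two_atom_fixture <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.234   5.678   9.012  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.345   6.789   0.123  1.00  0.00           C",
    "END"), path)
  path
}

# glycine-only chain (N, CA, C, O per residue) along x
write_gly_chain_fixture <- function(path, n_res = 5) {
  lines <- character(0)
  k <- 0
  for (i in seq_len(n_res)) {
    x <- (i - 1) * 3.8
    for (nm in c("N", "CA", "C", "O")) {
      k <- k + 1
      dx <- switch(nm, N = -1.3, CA = 0, C = 1.4, O = 1.6)
      dy <- switch(nm, N = 0, CA = 0, C = 0, O = 1.1)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        k, nm, i, x + dx, dy, 0, substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# locations where deposited experimental structures may be supplied by the
# user for the real-structure reproduction checks
deposited_path <- function(file) {
  base <- system.file("extdata", package = "repswap")
  file.path(base, "deposited", file)
}

make_res_atoms <- function(n, names_per_res = c("N", "CA", "C", "O")) {
  k <- n * length(names_per_res)
  data.frame(serial = seq_len(k),
             name = rep(names_per_res, n), elem = "C",
             res_name = "ALA", chain = "A",
             res_seq = rep(seq_len(n), each = length(names_per_res)),
             ins = "", alt = "", occ = 1, het = FALSE,
             stringsAsFactors = FALSE)
}

# place CA at the residue origin and C at a chosen distance along +x
structure_with_distances <- function(d) {
  n <- length(d)
  atoms <- make_res_atoms(n, c("CA", "C"))
  xyz <- matrix(0, 2 * n, 3)
  for (i in seq_len(n)) {
    base <- c(0, 10 * i, 0)
    xyz[2 * i - 1, ] <- base
    xyz[2 * i, ] <- base + c(d[i], 0, 0)
  }
  structure3d(atoms, xyz)
}
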