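test_that("superpose recovers exact rigid transforms", {
  set.seed(11)
  X <- random_points(40)
  s0 <- superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation_angle, 0, tolerance = 1e-9)
  expect_false(s0$axis_defined)
  R <- quat_to_mat(axis_angle_quat(37.4, c(0, 0, 1)))
  Y <- sweep(X %*% t(R), 2, c(0, 0, 8.3), "+")
  s <- superpose(X, Y)
  expect_equal(s$rotation_angle, 37.4, tolerance = 1e-6)
  expect_equal(s$transform$t, c(0, 0, 8.3), tolerance = 1e-6)
  expect_lt(s$rmsd, 1e-9)
})

test_that("superpose rejects degenerate geometry", {
  expect_error(superpose(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(1:12, 4, 3), matrix(1:9, 3, 3)),
               "differ in atom count")
})

test_that("quaternion fit matches the independent SVD oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    X <- random_points(n)
    q <- random_unit_quat()
    Y <- X %*% t(quat_to_mat(q)) + matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    expect_equal(superpose(X, Y)$rmsd, kabsch_oracle(X, Y)$rmsd,
                 tolerance = 1e-9)
  }
  # weighted fits agree too
  X <- random_points(30); Y <- X + matrix(rnorm(90, sd = 0.2), ncol = 3)
  w <- runif(30, 0.5, 2)
  expect_equal(superpose(X, Y, weights = w)$rmsd,
               kabsch_oracle(X, Y, weights = w)$rmsd, tolerance = 1e-9)
})

test_that("rotation angle/axis decomposition matches the closed form", {
  id <- rotation_angle_axis(rigid_transform())
  expect_equal(id$angle_deg, 0)
  expect_false(id$defined)
  half <- rotation_angle_axis(rigid_transform(c(0, 1, 0, 0)))
  expect_equal(half$angle_deg, 180, tolerance = 1e-9)
  expect_equal(half$axis, c(1, 0, 0))
  set.seed(31)
  for (i in 1:50) {
    q <- random_unit_quat()
    aa <- rotation_angle_axis(rigid_transform(q))
    expect_equal(aa$angle_deg, 2 * acos(abs(q[1])) * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("transform algebra composes and inverts exactly", {
  set.seed(41)
  for (i in 1:20) {
    tr <- rigid_transform(random_unit_quat(), rnorm(3, sd = 5))
    comp <- compose_transforms(invert_transform(tr), tr)
    expect_equal(comp$q, c(1, 0, 0, 0), tolerance = 1e-9)
    expect_equal(comp$t, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("superpose RMSD is invariant under a common rigid transform", {
  set.seed(51)
  X <- random_points(30)
  Y <- X + matrix(rnorm(90, sd = 0.5), ncol = 3)
  base <- superpose(X, Y)$rmsd
  for (i in 1:10) {
    g <- rigid_transform(random_unit_quat(), rnorm(3, sd = 10))
    expect_equal(superpose(apply_transform(g, X), apply_transform(g, Y))$rmsd,
                 base, tolerance = 1e-9)
  }
  # forward and backward fits are mutually inverse
  fw <- superpose(X, Y)$transform
  bw <- superpose(Y, X)$transform
  comp <- compose_transforms(bw, fw)
  expect_equal(comp$q, c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(comp$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("spin angle reproduces imposed rotations and is additive", {
  set.seed(61)
  X <- random_points(25)
  axis <- c(0, 0, 1)
  expect_equal(spin_angle(X, X, axis), 0, tolerance = 1e-9)
  rot <- function(deg) X %*% t(quat_to_mat(axis_angle_quat(deg, axis)))
  expect_equal(spin_angle(rot(37.4), X, axis), 37.4, tolerance = 1e-6)
  expect_equal(spin_angle(rot(-100), X, axis), -100, tolerance = 1e-6)
  # additivity modulo 360 for successive rotations about the same axis
  for (pair in list(c(30, 40), c(100, 120), c(170, 40))) {
    a <- spin_angle(rot(pair[1]), X, axis)
    b <- spin_angle(rot(pair[1] + pair[2]), rot(pair[1]), axis)
    tot <- spin_angle(rot(pair[1] + pair[2]), X, axis)
    d <- (a + b - tot) %% 360
    expect_lt(min(d, 360 - d), 1e-6)
  }
})

test_that("spin angle agrees with the brute-force grid oracle", {
  set.seed(71)
  X <- random_points(20, spread = 8)
  axis <- c(0, 0, 1)
  for (deg in c(-150, -37.4, 12, 90)) {
    g <- X %*% t(quat_to_mat(axis_angle_quat(deg, axis))) +
      matrix(rnorm(nrow(X) * 3, sd = 0.05), ncol = 3)
    expect_equal(spin_angle(g, X, axis),
                 spin_grid_oracle(g, X, axis), tolerance = 0.02)
  }
})

test_that("distance_z projects centroid separation onto the normal", {
  fr <- membrane_frame()
  a <- random_points(10)
  expect_equal(distance_z(a, a, fr), 0)
  b <- sweep(a, 2, c(1, -2, 8.3), "+")
  expect_equal(distance_z(b, a, fr), 8.3, tolerance = 1e-12)
  expect_identical(distance_z(a, b, fr) + distance_z(b, a, fr), 0)
  expect_error(distance_z(a[0, , drop = FALSE], a, fr), "empty")
  # tilted frame: only the z-axis projection counts
  fr2 <- membrane_frame(z_axis = c(1, 1, 0), x_axis = c(0, 0, 1))
  expect_equal(distance_z(b, a, fr2), sum(c(1, -2, 8.3) * fr2$z_axis),
               tolerance = 1e-12)
})

test_that("helix axis fits recover the generating axis and sign", {
  # short fragments carry a phase-imbalance bias of a couple of degrees
  # that decays rapidly with helix length
  ca <- ideal_helix(12)
  h <- fit_helix_axis(ca)
  expect_lt(interhelix_angle(h, c(0, 0, 1)), 3)
  expect_lt(interhelix_angle(fit_helix_axis(ideal_helix(30)),
                             c(0, 0, 1)), 0.5)
  expect_lt(interhelix_angle(fit_helix_axis(ideal_helix(100)),
                             c(0, 0, 1)), 0.1)
  h_rev <- fit_helix_axis(ca[nrow(ca):1, ])
  expect_lt(interhelix_angle(h_rev, c(0, 0, -1)), 3)
  straight <- cbind(seq(0, 15, length.out = 6), 0, 0)
  expect_equal(fit_helix_axis(straight)$axis, c(1, 0, 0),
               tolerance = 1e-9)
  expect_error(fit_helix_axis(ca[1:3, ]), "at least 4")
  expect_error(fit_helix_axis(matrix(1, 5, 3)), "coincident")
})

test_that("interhelix angles use signed axes and are symmetric", {
  expect_equal(interhelix_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(interhelix_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(interhelix_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  h1 <- fit_helix_axis(ideal_helix(10))
  ca2 <- ideal_helix(10) %*% t(quat_to_mat(axis_angle_quat(63, c(1, 0, 0))))
  h2 <- fit_helix_axis(ca2)
  expect_equal(interhelix_angle(h1, h2), interhelix_angle(h2, h1))
})

test_that("linear interpolation hits endpoints, midpoints and stays collinear", {
  b <- make_bundle(bundle_spec())
  a <- b$structure
  bb <- set_coords(a, model_coords(a) +
                     matrix(rnorm(n_atoms(a) * 3), ncol = 3))
  t2 <- interpolate_states(a, bb, 2)
  expect_identical(frame_coords(t2, 1), model_coords(a))
  expect_identical(frame_coords(t2, 2), model_coords(bb))
  t3 <- interpolate_states(a, bb, 3)
  expect_equal(frame_coords(t3, 2),
               (model_coords(a) + model_coords(bb)) / 2)
  # every atom path lies on the a-b segment
  t5 <- interpolate_states(a, bb, 5)
  d <- model_coords(bb) - model_coords(a)
  for (k in 2:4) {
    dev <- frame_coords(t5, k) - model_coords(a) - (k - 1) / 4 * d
    expect_lt(max(abs(dev)), 1e-12)
  }
  bad <- structure3d(a$atoms[-1, ], a$coords[-1, , , drop = FALSE])
  expect_error(interpolate_states(a, bad, 3), "congruence")
})
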