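make_cv_fixture <- function(...) {
  tj <- make_transition_trajectory(bundle_spec(transport_spin_deg = 30,
                                               transport_lift = 6,
                                               ligand_atoms = 4L, ...),
                                   n_frames = 3)
  p <- tj$annotation$protomers[[1]]
  list(tj = tj, p = p,
       spin = colvar_spec("spin_A", "spin_angle",
                          group = selection(ranges = p$transport,
                                            atoms = "calpha"),
                          axis = c(0, 0, 1)),
       dz = colvar_spec("dz_A", "distance_z",
                        group = selection(ranges = p$transport,
                                          atoms = "calpha"),
                        ref_group = selection(ranges = p$scaffold,
                                              atoms = "calpha")),
       ori = colvar_spec("ori_A", "orientation",
                         group = selection(ranges = p$scaffold,
                                           atoms = "calpha")),
       site = colvar_spec("site_A", "site_distance",
                          site = selection(ranges = p$transport[1, ],
                                           atoms = "calpha"),
                          ligand_res = "SUB"))
}

test_that("colvars evaluate to their defining quantities", {
  fx <- make_cv_fixture()
  ref <- fx$tj$reference; fr <- fx$tj$frame
  expect_equal(evaluate_colvar(fx$spin, ref, ref, fr), 0,
               tolerance = 1e-9)
  expect_equal(evaluate_colvar(fx$ori, ref, ref, fr), c(1, 0, 0, 0),
               tolerance = 1e-9)
  # rigidly spinning the whole system +25 degrees about the axis
  R <- quat_to_mat(axis_angle_quat(25, c(0, 0, 1)))
  spun <- model_coords(ref) %*% t(R)
  expect_equal(evaluate_colvar(fx$spin, spun, ref, fr), 25,
               tolerance = 1e-6)
  # spin colvar agrees exactly with the geometry-level spin angle
  g <- resolve_selection(ref, fx$spin$group)
  expect_identical(evaluate_colvar(fx$spin, spun, ref, fr),
                   spin_angle(spun[g$indices, ], g$coords, c(0, 0, 1)))
  # ligand moved onto the site centroid gives distance zero
  st <- resolve_selection(ref, fx$site$site)
  lg <- resolve_selection(ref, selection(res_name = "SUB",
                                         atoms = "heavy"))
  xyz <- model_coords(ref)
  shift <- colMeans(xyz[st$indices, , drop = FALSE]) -
    colMeans(xyz[lg$indices, , drop = FALSE])
  xyz[lg$indices, ] <- sweep(xyz[lg$indices, , drop = FALSE], 2, shift,
                             "+")
  expect_equal(evaluate_colvar(fx$site, xyz, ref, fr), 0,
               tolerance = 1e-9)
})

test_that("colvar time series track the transition and its reversal", {
  fx <- make_cv_fixture()
  ts <- colvar_timeseries(fx$tj$trajectory, list(fx$spin, fx$dz),
                          fx$tj$reference, fx$tj$frame)
  expect_equal(ts$spin_A, c(0, 15, 30), tolerance = 1e-6)
  expect_equal(ts$dz_A, c(0, 3, 6), tolerance = 1e-6)
  # linear Cartesian interpolation: midpoint spin is close to, but not
  # exactly, half the angle; the grid oracle pins the evaluated value
  tj_lin <- make_transition_trajectory(
    bundle_spec(transport_spin_deg = 30, transport_lift = 0),
    n_frames = 3, motion = "linear_cartesian")
  ts_lin <- colvar_timeseries(tj_lin$trajectory, list(fx$spin),
                              tj_lin$reference, tj_lin$frame)
  expect_equal(ts_lin$spin_A[c(1, 3)], c(0, 30), tolerance = 1e-6)
  expect_equal(ts_lin$spin_A[2], 15, tolerance = 0.5)
  g <- resolve_selection(tj_lin$reference, fx$spin$group)
  mid <- frame_coords(tj_lin$trajectory, 2)[g$indices, ]
  expect_equal(ts_lin$spin_A[2],
               spin_grid_oracle(mid, g$coords, c(0, 0, 1)),
               tolerance = 0.02)
  # constant and reversed trajectories
  const <- trajectory3d(fx$tj$reference,
                        array(rep(model_coords(fx$tj$reference), 3),
                              dim = c(n_atoms(fx$tj$reference), 3, 3)))
  ts_c <- colvar_timeseries(const, list(fx$spin), fx$tj$reference,
                            fx$tj$frame)
  expect_true(all(ts_c$spin_A == ts_c$spin_A[1]))
  rev_traj <- trajectory3d(fx$tj$trajectory$topology,
                           fx$tj$trajectory$coords[, , 3:1])
  ts_r <- colvar_timeseries(rev_traj, list(fx$spin), fx$tj$reference,
                            fx$tj$frame)
  expect_equal(ts_r$spin_A, rev(ts$spin_A), tolerance = 1e-9)
})

test_that("emitted configurations carry the restraint set faithfully", {
  fx <- make_cv_fixture()
  specs <- list(fx$spin, fx$dz, fx$ori, fx$site)
  sch <- default_restraints(specs, targets = list(spin_A = -60,
                                                  dz_A = -12))
  ref <- fx$tj$reference
  f1 <- tempfile(fileext = ".colvars")
  emit_colvars_config(specs, sch, f1, ref)
  parsed <- parse_colvars_config(f1)
  # force constants recovered exactly
  harm <- parsed$harmonic
  fc <- vapply(harm, function(h) h$forceConstant, numeric(1))
  nm <- vapply(harm, function(h) h$colvars, character(1))
  expect_equal(fc[nm == "spin_A"], 8)
  expect_equal(fc[nm == "dz_A"], 80)
  expect_equal(fc[nm == "ori_A"], 100000)
  walls <- parsed$harmonicWalls
  if (isTRUE(attr(walls, "multi"))) walls <- walls[[1]]
  expect_equal(walls$upperWalls, 2)
  expect_equal(walls$upperWallConstant, 1)
  # centers and moving targets round-trip
  expect_equal(harm[[which(nm == "spin_A")]]$targetCenters, -60)
  expect_equal(harm[[which(nm == "dz_A")]]$targetCenters, -12)
  # atom numbers are 1-based, sorted ascending, and match the selection
  cvs <- parsed$colvar
  spin_block <- cvs[[which(vapply(cvs, function(cv) cv$name,
                                  "") == "spin_A")]]
  nums <- spin_block$spinAngle$atoms$atomNumbers
  expect_true(all(diff(nums) > 0) && min(nums) >= 1)
  g <- resolve_selection(ref, fx$spin$group)
  expect_equal(nums, sort(ref$atoms$serial[g$indices]))
  # deterministic emission
  f2 <- tempfile(fileext = ".colvars")
  emit_colvars_config(specs, sch, f2, ref)
  expect_identical(readLines(f1), readLines(f2))
  # schedule-free emission defines the variables only
  f3 <- tempfile(fileext = ".colvars")
  emit_colvars_config(specs, list(), f3, ref)
  txt <- readLines(f3)
  expect_false(any(grepl("^harmonic", txt)))
  expect_equal(sum(grepl("^colvar \\{", txt)), 4L)
  # dangling schedule reference errors
  expect_error(
    emit_colvars_config(specs[1],
                        list(restraint_schedule("nope", "harmonic", 1)),
                        tempfile(), ref),
    "undefined colvar")
})

test_that("restraint schedules validate their parameters", {
  expect_error(restraint_schedule("x", "harmonic", force_constant = 0),
               "force_constant")
  expect_error(restraint_schedule("x", "harmonic", 1,
                                  stages_ns = c(a = -1)))
  s <- restraint_schedule("x", "half_harmonic_upper", 1, center = 2)
  expect_equal(s$style, "half_harmonic_upper")
})
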