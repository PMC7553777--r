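test_that("the swap target is an involution that flips z displacements", {
  b <- make_bundle(bundle_spec(transport_spin_deg = 20,
                               transport_lift = 5))
  s <- b$structure; fr <- b$frame
  tgt <- generate_swap_target(s, fr)
  back <- generate_swap_target(tgt, fr)
  expect_identical(back$coords, s$coords)   # exact involution
  p <- b$annotation$protomers[[1]]
  tr_sel <- selection(ranges = p$transport, atoms = "calpha")
  sc_sel <- selection(ranges = p$scaffold, atoms = "calpha")
  dz_s <- distance_z(resolve_selection(s, tr_sel)$coords,
                     resolve_selection(s, sc_sel)$coords, fr)
  dz_t <- distance_z(resolve_selection(tgt, tr_sel)$coords,
                     resolve_selection(tgt, sc_sel)$coords, fr)
  expect_equal(dz_t, -dz_s, tolerance = 1e-9)
  # a single point above the origin lands below it
  one <- s
  pt_target <- generate_swap_target(
    set_coords(s, matrix(rep(c(0, 0, 7), n_atoms(s)), ncol = 3,
                         byrow = TRUE)), fr)
  expect_equal(model_coords(pt_target)[1, ], c(0, 0, -7))
  expect_error(generate_swap_target(s, fr, in_plane_axis = c(0, 0, 1)),
               "not in the membrane plane")
})

test_that("swapped-repeat alignment is exact for the symmetric core", {
  b0 <- make_bundle(bundle_spec(transport_spin_deg = 0,
                                transport_lift = 0))
  tgt <- generate_swap_target(b0$structure, b0$frame)
  p <- b0$annotation$protomers[[1]]
  sup <- swapped_repeat_superpose(b0$structure, tgt, p$repeats)
  expect_lt(sup$rmsd, 1e-9)
  # the permutation is what brings the inverted repeats into register:
  # compared in place (no refit), the swapped pairing already coincides
  # while the identity pairing leaves atoms on opposite membrane sides
  all_sel <- selection(ranges = rbind(p$scaffold, p$transport),
                       atoms = "calpha")
  ga <- resolve_selection(b0$structure, all_sel)
  gb <- resolve_selection(tgt, all_sel)
  in_place <- sqrt(mean(rowSums((ga$coords - gb$coords)^2)))
  expect_gt(in_place, 1)
  pr <- repswap:::swapped_pairing(b0$structure, tgt, p$repeats)
  swapped_in_place <- sqrt(mean(rowSums(
    (model_coords(b0$structure)[pr$state, ] -
       model_coords(tgt)[pr$target, ])^2)))
  expect_lt(swapped_in_place, 1e-9)
})

test_that("swapped-fit rmsd under noise sits on the Monte-Carlo noise floor", {
  sigma <- 0.2
  b <- make_bundle(bundle_spec(transport_spin_deg = 0, transport_lift = 0,
                               noise_sd = sigma, seed = 7))
  tgt <- generate_swap_target(b$structure, b$frame)
  p <- b$annotation$protomers[[1]]
  sup <- swapped_repeat_superpose(b$structure, tgt, p$repeats)
  # oracle: fitted rmsd between two independently noised copies of the
  # same base coordinates, via the independent SVD fit
  b0 <- make_bundle(bundle_spec(transport_spin_deg = 0,
                                transport_lift = 0))
  base <- resolve_selection(
    b0$structure, selection(ranges = rbind(p$scaffold, p$transport),
                            atoms = "calpha"))$coords
  set.seed(99)
  reps <- replicate(1000, {
    n1 <- base + matrix(rnorm(length(base), sd = sigma), ncol = 3)
    n2 <- base + matrix(rnorm(length(base), sd = sigma), ncol = 3)
    kabsch_oracle(n1, n2)$rmsd
  })
  n <- nrow(base)
  expect_lt(abs(sup$rmsd - mean(reps)), 3 * sigma * sqrt(2 / n))
})

test_that("transition plans recover the constructed spin and lift deltas", {
  # +5 A lift -> planned displacement delta of -10 A
  b5 <- make_bundle(bundle_spec(transport_spin_deg = 0,
                                transport_lift = 5))
  pl5 <- plan_transition(b5$structure, b5$annotation, b5$frame)
  expect_equal(pl5$protomers[[1]]$distance_z_delta, -10, tolerance = 1e-9)
  # a 20-degree applied spin makes the swapped fit a 40-degree spin
  b20 <- make_bundle(bundle_spec(transport_spin_deg = 20,
                                 transport_lift = 5))
  pl20 <- plan_transition(b20$structure, b20$annotation, b20$frame)
  expect_equal(pl20$protomers[[1]]$spin_delta_deg, 40, tolerance = 0.1)
  axis_dev <- interhelix_angle(pl20$protomers[[1]]$spin_axis, c(0, 0, -1))
  expect_lt(min(axis_dev, 180 - axis_dev), 1)
  # the symmetric core is a fixed point of the construction
  b0 <- make_bundle(bundle_spec(transport_spin_deg = 0,
                                transport_lift = 0))
  pl0 <- plan_transition(b0$structure, b0$annotation, b0$frame)
  expect_equal(pl0$protomers[[1]]$spin_delta_deg, 0, tolerance = 1e-6)
  expect_equal(pl0$protomers[[1]]$distance_z_delta, 0, tolerance = 1e-9)
})

test_that("displacement magnitude is preserved for any in-plane axis", {
  set.seed(17)
  for (i in 1:5) {
    spin <- runif(1, 0, 80); lift <- runif(1, -8, 8)
    b <- make_bundle(bundle_spec(transport_spin_deg = spin,
                                 transport_lift = lift))
    phi <- runif(1, 0, 2 * pi)
    ax <- c(cos(phi), sin(phi), 0)
    pl <- plan_transition(b$structure, b$annotation, b$frame,
                          in_plane_axis = ax)
    pp <- pl$protomers[[1]]
    expect_equal(abs(pp$distance_z_target), abs(pp$distance_z_state),
                 tolerance = 1e-9)
    expect_equal(pp$distance_z_delta, -2 * lift, tolerance = 1e-6)
  }
})

test_that("repeat mappings validate counts and overlaps", {
  r1 <- ranges_df("A", 1, 10); r2 <- ranges_df("A", 21, 30)
  expect_s3_class(repeat_mapping(list(list(r1, r2))), "repeat_mapping")
  expect_error(repeat_mapping(list(list(r1, ranges_df("A", 21, 29)))),
               "unequal residue counts")
  expect_error(repeat_mapping(list(list(r1, r2),
                                   list(ranges_df("A", 5, 14),
                                        ranges_df("A", 31, 40)))),
               "overlapping")
  # plans serialise to JSON
  b <- make_bundle(bundle_spec())
  pl <- plan_transition(b$structure, b$annotation, b$frame)
  f <- tempfile(fileext = ".json")
  write_transition_plan(pl, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$protomers[[1]]$name, "A")
})
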