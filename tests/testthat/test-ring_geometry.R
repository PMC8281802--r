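# Helix vectors, tilt angles, delta-phi, Kabsch, diameters.

test_that("helix vector and angle conventions on a vertical segment", {
  beads <- data.frame(chain_id = "A", residue_number = 1:8,
                      x = 0, y = 0, z = seq(0, 21, length.out = 8))
  gp <- geometry_params(alpha5_com_a = c(1, 4), alpha5_com_b = c(5, 8))
  v <- helix_vector(bead_model(beads), gp)
  expect_equal(v, c(0, 0, 1), tolerance = 1e-9)
  # translation invariance
  shifted <- beads
  shifted[, c("x", "y", "z")] <- shifted[, c("x", "y", "z")] +
    matrix(c(10, -4, 2), 8, 3, byrow = TRUE)
  expect_equal(helix_vector(bead_model(shifted), gp), v, tolerance = 1e-12)
  # missing anchor residues are an undefined-helix error
  expect_error(helix_vector(bead_model(beads[-2, ]), gp), "undefined helix")
})

test_that("a constructed 40-degree arm is measured at 40 degrees exactly", {
  spec <- small_ring_spec(tilt_schedule = rep(40, 5))
  d <- decomposed_ring(spec)
  ang <- rung_alpha5_angle(d$decomp, d$beads, 3, params = d$geom)
  expect_equal(ang$mean_to_horizontal, 40, tolerance = 1e-6)
  expect_equal(ang$mean_to_axis, 50, tolerance = 1e-6)
  expect_lt(ang$sd, 1e-6)        # Cn symmetry: all subunits identical
})

test_that("delta-phi vanishes on a cylindrical stack and telescopes", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  dp <- delta_phi(d$decomp, d$beads, params = d$geom)
  expect_lt(max(abs(dp$delta_phi_i)), 1e-6)
  # telescoping over randomized monotone-free schedules
  set.seed(9)
  for (k in 1:5) {
    sched <- runif(5, 40, 70)
    dk <- decomposed_ring(small_ring_spec(tilt_schedule = sched))
    dpk <- delta_phi(dk$decomp, dk$beads, params = dk$geom)
    expect_equal(sum(dpk$delta_phi_i), dpk$delta_phi, tolerance = 1e-6)
    expect_equal(dpk$delta_phi,
                 dpk$per_rung_horizontal[1] - dpk$per_rung_horizontal[5],
                 tolerance = 1e-6)
  }
})

test_that("an imposed tilt schedule is recovered interface by interface", {
  sched <- c(56, 51, 48, 45, 40)  # interface rotations 5, 3, 3, 5
  d <- decomposed_ring(small_ring_spec(tilt_schedule = sched))
  dp <- delta_phi(d$decomp, d$beads, params = d$geom)
  expect_equal(dp$delta_phi_i, c(5, 3, 3, 5), tolerance = 1e-3)
  expect_equal(dp$delta_phi, 16, tolerance = 1e-3)
})

test_that("tilt recovery tolerates 0.2 A coordinate noise within a degree", {
  sched <- seq(65, 45, length.out = 5)
  d <- decomposed_ring(small_ring_spec(tilt_schedule = sched,
                                       noise_sd = 0.2, seed = 17))
  dp <- delta_phi(d$decomp, d$beads, params = d$geom)
  expect_lt(max(abs(dp$per_rung_horizontal - sched)), 1)
})

test_that("angles are invariant under a rigid transform of model and frame", {
  spec <- small_ring_spec()
  d <- decomposed_ring(spec)
  dp0 <- delta_phi(d$decomp, d$beads, params = d$geom)
  R <- random_rotation(23)
  t <- c(12, -7, 30)
  moved <- transform_beads(d$beads, R, t)
  frame2 <- ring_frame(drop(d$frame$center %*% t(R)) + t, R %*% d$frame$axis)
  d2 <- assign_rungs(moved, frame2, spec$n_sym)
  dp2 <- delta_phi(d2, moved, frame2, params = d$geom)
  expect_equal(dp2$per_rung_horizontal, dp0$per_rung_horizontal,
               tolerance = 1e-6)
})

test_that("Kabsch recovers applied transforms and rejects degenerate input", {
  spec <- small_ring_spec(n_rungs = 2)
  d <- decomposed_ring(spec)
  sub <- bead_model(d$beads$beads[d$beads$beads$chain_id == "A", ])
  R <- random_rotation(5)
  moved <- transform_beads(sub, R, c(3, 4, 5))
  fit <- kabsch_superpose(moved, sub)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation %*% t(fit$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # transform_beads applied xyz %*% t(R); the fit undoes it on the right
  expect_lt(max(abs(fit$rotation - R)), 1e-6)
  two <- bead_model(data.frame(chain_id = "A", residue_number = 1:2,
                               x = c(0, 1), y = 0, z = 0))
  expect_error(kabsch_superpose(two, two), "3 paired")
  line <- bead_model(data.frame(chain_id = "A", residue_number = 1:5,
                                x = 1:5, y = 0, z = 0))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD equals the quaternion closed form on random pairs", {
  set.seed(31)
  for (k in 1:200) {
    P <- matrix(rnorm(150, sd = 10), 50, 3)
    Q <- P %*% random_rotation(k) + matrix(rnorm(150, sd = 1), 50, 3)
    a <- bead_model(data.frame(chain_id = "A", residue_number = 1:50,
                               x = P[, 1], y = P[, 2], z = P[, 3]))
    b <- bead_model(data.frame(chain_id = "A", residue_number = 1:50,
                               x = Q[, 1], y = Q[, 2], z = Q[, 3]))
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("per-rung diameters report the constructed radius", {
  # untilted ring: the anchor residue sits exactly one helix-decoration
  # radius outside the placement circle
  spec <- small_ring_spec(tilt_schedule = rep(0, 5))
  d <- decomposed_ring(spec)
  prof <- diameter_profile(d$decomp, d$beads, params = d$geom,
                           convention = "alpha1_nterm")
  expect_equal(nrow(prof), 5)
  expect_lt(max(abs(prof$internal_diameter_nm - 2 * spec$radius / 10)), 0.6)
})

test_that("a constructed dome is widest at the equator", {
  # short, gently tilted subunits keep each rung within its own axial
  # slab, so the slab diameters cleanly reflect the imposed radii
  spec <- synthetic_ring_spec(n_sym = 8, n_rungs = 5, radius = 40, rise = 10,
                              tilt_schedule = rep(20, 5),
                              residues_per_subunit = 20,
                              alpha5_like_range = c(13, 20),
                              hairpin_like_range = c(1, 10),
                              radius_schedule = c(30, 36, 40, 36, 30))
  d <- decomposed_ring(spec)
  prof <- diameter_profile(d$decomp, d$beads, params = d$geom,
                           convention = "lumen_percentile")
  eq <- grep("equator", prof$label)
  expect_equal(which.max(prof$internal_diameter_nm), eq)
  # internal diameter decreases monotonically from equator to either end
  inner <- prof$internal_diameter_nm
  expect_true(all(diff(inner[seq_len(eq)]) >= -1e-9))
  expect_true(all(diff(inner[eq:length(inner)]) <= 1e-9))
})

test_that("geometry reports combine both angle conventions", {
  spec <- small_ring_spec()
  d <- decomposed_ring(spec)
  rep_ <- geometry_report(d$decomp, d$beads, params = d$geom)
  expect_equal(rep_$per_rung$mean_angle_to_axis +
               rep_$per_rung$mean_angle_to_horizontal,
               rep(90, spec$n_rungs), tolerance = 1e-9)
  expect_equal(sum(rep_$delta_phi_i), rep_$delta_phi, tolerance = 1e-6)
  json <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_report(rep_, json, tsv, header = "test")
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "")))
})

test_that("rungs without defined helices are skipped, not fatal", {
  spec <- small_ring_spec()
  d <- decomposed_ring(spec)
  beads2 <- d$beads
  # delete the arm from every chain of rung 1 (terminal rungs of the
  # experimental maps lack these helices too)
  gone <- beads2$beads$chain_id %in% d$decomp$rungs[[1]] &
    beads2$beads$residue_number >= spec$alpha5_like_range[1]
  beads2$beads <- beads2$beads[!gone, ]
  dp <- delta_phi(d$decomp, beads2, params = d$geom)
  expect_true(is.na(dp$per_rung_horizontal[1]))
  expect_length(dp$delta_phi_i, 3)
  expect_error(rung_alpha5_angle(d$decomp, beads2, 1, params = d$geom),
               "no subunit")
})
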