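# Harmonic energy, gradients, relaxation.

test_that("energy is the closed-form sum over springs", {
  sys <- toy_system(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
                    data.frame(i = 1, j = 2, d0 = 1), stiffness = 2)
  expect_equal(stack_energy(sys), 1.0)           # (2/2) * (2-1)^2
  relaxed <- toy_system(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                        data.frame(i = 1, j = 2, d0 = 1), stiffness = 2)
  expect_equal(stack_energy(relaxed), 0)
  expect_gt(stack_energy(sys), 0)
})

test_that("R and compiled energies and gradients agree", {
  sys <- random_spring_network()
  expect_equal(stack_energy(sys),
               ringenm:::.enm_energy_cpp(sys$coords, sys$springs$i,
                                         sys$springs$j, sys$springs$d0,
                                         sys$stiffness),
               tolerance = 1e-12)
  expect_equal(stack_gradient(sys),
               ringenm:::.enm_gradient_cpp(sys$coords, sys$springs$i,
                                           sys$springs$j, sys$springs$d0,
                                           sys$stiffness),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  sys <- random_spring_network(n = 100)
  g <- stack_gradient(sys)
  h <- 1e-5
  set.seed(2)
  for (k in sample(300, 30)) {
    i <- (k - 1) %% 100 + 1
    dim_ <- (k - 1) %/% 100 + 1
    cp <- sys$coords; cp[i, dim_] <- cp[i, dim_] + h
    cm <- sys$coords; cm[i, dim_] <- cm[i, dim_] - h
    fd <- (stack_energy(sys, cp) - stack_energy(sys, cm)) / (2 * h)
    expect_equal(g[i, dim_], fd, tolerance = 1e-6)
  }
})

test_that("an equilibrium is a fixed point of noiseless relaxation", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 4), n_rungs = 4)
  d <- decomposed_ring(spec)
  intra <- build_intra_map(d$decomp, d$beads, 1:4)
  inter <- build_inter_map(d$decomp, d$beads, 3, 2)
  sys <- stack_from_rungs(lapply(1:4, function(r) get_rung(d$decomp, d$beads, r)),
                          intra, inter, rise = d$decomp$rise)
  fit <- minimize(sys, minimizer_params(temperature_factor = 0, md_steps = 50))
  expect_lt(max(abs(fit$system$coords - sys$coords)), 1e-9)
  expect_true(fit$trajectory$converged)
})

test_that("two beads on one spring converge to the natural length", {
  sys <- toy_system(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE),
                    data.frame(i = 1, j = 2, d0 = 3))
  fit <- minimize(sys, minimizer_params(temperature_factor = 0, md_steps = 0,
                                        force_tolerance = 1e-9))
  sep <- sqrt(sum((fit$system$coords[1, ] - fit$system$coords[2, ])^2))
  expect_equal(sep, 3, tolerance = 1e-6)
})

test_that("descent-phase energies are monotone non-increasing", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  st <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 2,
                       spec$rise)
  fit <- minimize(st, minimizer_params(seed = 4, max_descent_steps = 2000))
  e <- fit$trajectory$energies
  expect_true(all(diff(e) <= 1e-12))
  expect_lte(stack_energy(fit$system), stack_energy(st))
})

test_that("equilibria are independent of the uniform stiffness", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  p <- minimizer_params(temperature_factor = 0, md_steps = 0,
                        force_tolerance = 1e-6, max_descent_steps = 50000)
  st1 <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 2,
                        spec$rise, stiffness = 1)
  st10 <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 2,
                         spec$rise, stiffness = 10)
  p10 <- p
  p10$force_tolerance <- p$force_tolerance * 10  # force scales with k
  f1 <- minimize(st1, p)
  f10 <- minimize(st10, p10)
  a <- stack_to_bead_model(f1$system)
  b <- stack_to_bead_model(f10$system)
  expect_lt(kabsch_superpose(a, b)$rmsd, 1e-3)
})

test_that("relaxation is equivariant under rigid motions", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  st <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 2,
                       spec$rise)
  p <- minimizer_params(temperature_factor = 0, md_steps = 0,
                        force_tolerance = 1e-6, max_descent_steps = 50000)
  f0 <- minimize(st, p)
  R <- random_rotation(13)
  st2 <- st
  st2$coords <- st$coords %*% t(R)
  f2 <- minimize(st2, p)
  a <- stack_to_bead_model(f0$system)
  b <- stack_to_bead_model(f2$system)
  expect_lt(kabsch_superpose(b, a)$rmsd, 1e-3)
})

test_that("Cn symmetry of the start is preserved at equilibrium", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  st <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 3,
                       spec$rise)
  fit <- minimize(st, minimizer_params(temperature_factor = 0, md_steps = 0))
  x <- fit$system$coords
  # average over the Cn images and compare
  n_sym <- st$n_sym
  th <- 2 * pi / n_sym
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  idx <- fit$system$index
  perm <- order(idx$rung, (idx$slot + 1) %% n_sym, idx$residue)
  acc <- matrix(0, nrow(x), 3)
  cur <- x
  for (k in seq_len(n_sym)) {
    acc <- acc + cur
    cur <- (cur %*% t(Rz))[perm, ]
  }
  sym_avg <- acc / n_sym
  dev <- sqrt(mean(rowSums((x - sym_avg)^2)))
  expect_lt(dev, 0.1)
})

test_that("a zero-drive series stays cylindrical across sizes", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  intra <- build_intra_map(d$decomp, d$beads, 1:5)
  inter <- build_inter_map(d$decomp, d$beads, 4, 3)
  avg <- get_rung(d$decomp, d$beads, 3)
  series <- run_stack_series(avg, intra, inter, n_rungs_list = c(2, 3),
                             params = minimizer_params(seed = 2,
                                                       md_steps = 500),
                             rise = spec$rise, geom = d$geom)
  expect_true(all(series$converged))
  expect_true(all(abs(series$delta_phi) < 0.5))
  path_t <- withr::local_tempfile(fileext = ".tsv")
  path_j <- withr::local_tempfile(fileext = ".json")
  write_series(series, path_t, path_j, header = "seed: 2")
  expect_true(file.exists(path_t) && file.exists(path_j))
})

test_that("failed rows do not abort a series", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  bad_inter <- sys$inter_map
  bad_inter$slot_offset <- bad_inter$slot_offset + spec$n_sym  # invalid
  warns <- capture_warnings(
    series <- run_stack_series(sys$average_rung, sys$intra_map, bad_inter,
                               n_rungs_list = c(2, 3),
                               params = minimizer_params(),
                               rise = spec$rise,
                               geom = geometry_params_for(spec)))
  expect_length(warns, 2)          # one per failed stack size
  expect_true(all(grepl("failed", warns)))
  expect_true(all(is.na(series$delta_phi)))
  expect_equal(series$n_rungs, c(2, 3))
})
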