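# Consensus contact maps, average rung, stack assembly.

test_that("pairwise contact listing honours the cutoff boundary", {
  two <- function(d) bead_model(data.frame(chain_id = "A",
                                           residue_number = 1:2,
                                           x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(contact_map_single(two(9.9), cutoff = 10)), 1)
  expect_equal(nrow(contact_map_single(two(10.1), cutoff = 10)), 0)
})

test_that("contact listing equals the all-pairs brute-force oracle", {
  set.seed(3)
  n <- 500
  df <- data.frame(chain_id = "A", residue_number = seq_len(n),
                   x = runif(n, 0, 50), y = runif(n, 0, 50),
                   z = runif(n, 0, 50))
  bm <- bead_model(df)
  got <- contact_map_single(bm, cutoff = 8)
  # brute force O(n^2) loop
  want <- 0L
  xyz <- as.matrix(df[, c("x", "y", "z")])
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(n - 1)) {
    d2 <- rowSums((xyz[(i + 1):n, , drop = FALSE] -
                   matrix(xyz[i, ], n - i, 3, byrow = TRUE))^2)
    js <- which(d2 <= 64) + i
    if (length(js) > 0) pairs <- rbind(pairs, cbind(i, js))
  }
  expect_equal(nrow(got), nrow(pairs))
  got_key <- paste(got$residue_a, got$residue_b)
  want_key <- paste(pairs[, 1], pairs[, 2])
  expect_setequal(got_key, want_key)
})

test_that("noise-free congruent rings give support exactly one", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  map <- build_intra_map(d$decomp, d$beads, 1:5)
  expect_true(all(map$support == 1))
  # the consensus map matches the contact set of any single environment
  r1 <- get_rung(d$decomp, d$beads, 1)
  chains <- unique(r1$beads$chain_id)
  sub <- function(k) {
    b <- r1$beads[r1$beads$chain_id == chains[(k %% length(chains)) + 1], ]
    bead_model(b)
  }
  env_self <- contact_map_single(sub(-1), cutoff = 10)
  expect_equal(sum(map$slot_offset == 0), nrow(env_self))
})

test_that("the consensus boundary is strict", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  # every support is exactly 1, so a threshold of 1 must exclude all
  empty <- build_intra_map(d$decomp, d$beads, 1:5, consensus = 1)
  expect_equal(nrow(empty), 0)
  # perturbing one of two compared rungs drops support to exactly 0.5
  beads2 <- d$beads
  move <- beads2$beads$chain_id %in% d$decomp$rungs[[2]] &
    beads2$beads$residue_number >= 28
  beads2$beads$z[move] <- beads2$beads$z[move] + 200
  # contacts bridging moved and unmoved residues now exist in exactly
  # half the environments -> excluded by the strict boundary
  mixed <- function(m) xor(m$residue_a >= 28, m$residue_b >= 28)
  map_half <- build_intra_map(d$decomp, beads2, 1:2)
  expect_false(any(mixed(map_half)))
  # ... and they are reported in the removed-contact listing
  rem <- attr(map_half, "removed")
  expect_gt(nrow(rem), 0)
  expect_true(all(xor(rem$residue_a >= 28, rem$residue_b >= 28)))
  # ... but a majority of intact rungs keeps them (support 0.8 > 0.5)
  map_most <- build_intra_map(d$decomp, beads2, 1:5)
  expect_true(any(mixed(map_most)))
  lost <- map_most$support < 1
  expect_true(all(mixed(map_most)[lost]))
})

test_that("raising the consensus threshold never adds contacts", {
  spec <- small_ring_spec(noise_sd = 0.4, seed = 5,
                          tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  key <- function(m) paste(m$residue_a, m$residue_b, m$slot_offset)
  lo <- build_intra_map(d$decomp, d$beads, 1:5, consensus = 0.25)
  hi <- build_intra_map(d$decomp, d$beads, 1:5, consensus = 0.75)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("unequal residue coverage across monomers is an error", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  beads2 <- d$beads
  drop_chain <- d$decomp$rungs[[1]][1]
  beads2$beads <- beads2$beads[!(beads2$beads$chain_id == drop_chain &
                                 beads2$beads$residue_number == 10), ]
  expect_error(build_intra_map(d$decomp, beads2, 1:5), "coverage")
})

test_that("inter map needs complete rungs and warns when rungs are apart", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  decomp2 <- d$decomp
  decomp2$rungs[[4]] <- decomp2$rungs[[4]][-1]
  expect_error(build_inter_map(decomp2, d$beads, 4, 3), "incomplete")
  spread <- small_ring_spec(tilt_schedule = rep(55, 5))
  spread$rise <- 120
  ds <- decomposed_ring(spread)
  expect_warning(empty <- build_inter_map(ds$decomp, ds$beads, 4, 3),
                 "no inter-rung contacts")
  expect_equal(nrow(empty), 0)
})

test_that("a noise-free ring is an exact zero of its own derived network", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  intra <- build_intra_map(d$decomp, d$beads, 1:5)
  inter <- build_inter_map(d$decomp, d$beads, 4, 3)
  rungs <- lapply(1:5, function(r) get_rung(d$decomp, d$beads, r))
  sys <- stack_from_rungs(rungs, intra, inter, rise = d$decomp$rise)
  expect_lt(stack_energy(sys), 1e-9)
})

test_that("the spring graph of one rung is a single connected component", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  intra <- build_intra_map(d$decomp, d$beads, 1:5)
  sys <- stack_from_rungs(list(get_rung(d$decomp, d$beads, 3)), intra,
                          NULL, rise = d$decomp$rise)
  expect_equal(n_components(nrow(sys$coords), sys$springs$i, sys$springs$j), 1)
})

test_that("the average rung of a congruent ring equals the input rung", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  intra <- build_intra_map(d$decomp, d$beads, 1:5)
  avg <- make_average_rung(d$decomp, d$beads, intra, init_rung = 3)
  expect_lt(rmsd_paired(avg, get_rung(d$decomp, d$beads, 3)), 1e-3)
  expect_true(attr(avg, "trajectory")$converged)
})

test_that("stack assembly instantiates the closed-form spring count", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  n_sym <- spec$n_sym
  for (nr in c(1, 4, 8)) {
    st <- suppressWarnings(assemble_stack(sys$average_rung, sys$intra_map,
                                          sys$inter_map, nr, spec$rise))
    want <- nr * n_sym * nrow(sys$intra_map) +
      (nr - 1) * n_sym * nrow(sys$inter_map)
    expect_equal(nrow(st$springs), want)
    if (nr == 1) {
      # no inter springs: all springs live within the single rung
      expect_equal(nrow(st$springs), n_sym * nrow(sys$intra_map))
    }
  }
})

test_that("a tilt-encoding inter map strains the cylindrical stack", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  st <- assemble_stack(sys$average_rung, sys$intra_map, sys$inter_map, 4,
                       spec$rise)
  expect_gt(stack_energy(st), 1)
  # without the inter map the cylindrical stack is already at equilibrium
  st0 <- assemble_stack(sys$average_rung, sys$intra_map, NULL, 4, spec$rise)
  expect_lt(stack_energy(st0), 1e-9)
})

test_that("inter contacts referencing impossible slots are rejected", {
  spec <- small_ring_spec()
  sys <- make_tilt_encoding_system(spec)
  bad <- sys$inter_map
  bad$slot_offset[1] <- spec$n_sym + 2
  expect_error(assemble_stack(sys$average_rung, sys$intra_map, bad, 3,
                              spec$rise), "slot offset")
})

test_that("contact maps serialize with deterministic ordering", {
  spec <- small_ring_spec(tilt_schedule = rep(55, 5))
  d <- decomposed_ring(spec)
  map <- build_intra_map(d$decomp, d$beads, 1:5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(map, path, header = "unit test")
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), nrow(map))
  ord <- order(tab$rung_offset, tab$slot_offset, tab$residue_a, tab$residue_b)
  expect_equal(ord, seq_len(nrow(tab)))
})
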