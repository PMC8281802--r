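# Shared fixtures: reduced-size synthetic rings that keep every
# geometric feature of the default study system (contacts between
# symmetry neighbours and adjacent rungs, rigid helical beams) while
# minimizing relaxation cost.

small_ring_spec <- function(n_rungs = 5,
                            tilt_schedule = seq(65, 45, length.out = n_rungs),
                            n_sym = 8, noise_sd = 0, seed = 1, ...) {
  synthetic_ring_spec(n_sym = n_sym, n_rungs = n_rungs, radius = 40,
                      rise = 10, tilt_schedule = tilt_schedule,
                      residues_per_subunit = 32,
                      alpha5_like_range = c(21, 32),
                      hairpin_like_range = c(1, 20),
                      noise_sd = noise_sd, seed = seed, ...)
}

decomposed_ring <- function(spec) {
  ring <- make_ring(spec)
  beads <- extract_calpha(ring$model)
  frame <- detect_frame(beads, "z_axis")
  decomp <- assign_rungs(beads, frame, spec$n_sym)
  list(ring = ring, beads = beads, frame = frame, decomp = decomp,
       geom = geometry_params_for(spec))
}

# minimal hand-built stack system (exercises energy/gradient/minimize
# without the map machinery)
toy_system <- function(coords, springs, stiffness = 1) {
  ringenm:::new_stack_system(coords, springs, stiffness,
                             n_rungs = 1, n_sym = 1,
                             residues = seq_len(nrow(coords)), rise = 1)
}

random_spring_network <- function(n = 100, seed = 7, box = 50, cutoff = 15,
                                  strain = 0.9) {
  set.seed(seed)
  coords <- matrix(stats::runif(3 * n, 0, box), n, 3)
  d <- as.matrix(stats::dist(coords))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  springs <- data.frame(i = hit[, 1], j = hit[, 2],
                        d0 = d[hit] * strain)
  toy_system(coords, springs, stiffness = 2)
}

# quaternion (Horn) closed-form superposition: independent oracle for
# the SVD-based Kabsch implementation
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P0, Q0)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_beads <- function(model, R, t = c(0, 0, 0)) {
  out <- model
  xyz <- as.matrix(model$beads[, c("x", "y", "z")])
  out$beads[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, "+")
  out
}

# single connected component check via union-find
n_components <- function(n, edges_i, edges_j) {
  edges_i <- as.integer(edges_i)
  edges_j <- as.integer(edges_j)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (k in seq_along(edges_i)) {
    ra <- find(edges_i[k]); rb <- find(edges_j[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# deposited coordinate models are too large to ship as text fixtures;
# the accession-based checks run when the user places them here
deposited_path <- function(accession) {
  candidates <- c(
    system.file("extdata", "deposited", paste0(accession, ".pdb"),
                package = "ringenm"),
    file.path("..", "..", "inst", "extdata", "deposited",
              paste0(accession, ".pdb")))
  candidates <- candidates[nzchar(candidates)]
  hits <- candidates[file.exists(candidates)]
  if (length(hits) > 0) hits[1] else NA_character_
}
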