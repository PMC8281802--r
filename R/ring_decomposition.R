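# Decomposition of a Cn-symmetric stacked-ring model into rungs and
# azimuthal slots, plus ring composition arithmetic.

#' Construct a ring frame
#'
#' @param center 3-vector, Angstrom.
#' @param axis 3-vector; normalised internally, must be non-zero.
#' @return Object of class `ring_frame` with fields `center` and unit `axis`.
#' @export
ring_frame <- function(center, axis) {
  stopifnot(length(center) == 3, length(axis) == 3)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("ring axis must be non-zero")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / n),
            class = "ring_frame")
}

#' Detect the ring frame of a bead model
#'
#' In `z_axis` mode (the convention for the deposited ring structures,
#' which are refined about z) the axis is (0,0,1) and the center is the
#' bead centroid. In `inertia` mode the axis is recovered from the bead
#' covariance: under Cn symmetry two eigenvalues are degenerate and the
#' symmetry axis is the eigenvector whose eigenvalue is isolated from the
#' other two; the sign is chosen so that axis . (0,0,1) >= 0.
#'
#' @param model a [bead_model] with at least 3 chains.
#' @param mode `"z_axis"` or `"inertia"`.
#' @return A [ring_frame].
#' @export
detect_frame <- function(model, mode = c("z_axis", "inertia")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bead_model"))
  if (length(unique(model$beads$chain_id)) < 3) {
    stop("frame detection needs at least 3 chains")
  }
  xyz <- as.matrix(model$beads[, c("x", "y", "z")])
  center <- colMeans(xyz)
  if (mode == "z_axis") return(ring_frame(center, c(0, 0, 1)))
  cov <- crossprod(sweep(xyz, 2, center)) / nrow(xyz)
  eg <- eigen(cov, symmetric = TRUE)
  if (eg$values[2] < 1e-9 * max(eg$values[1], 1)) {
    stop("degenerate (collinear) bead cloud; cannot infer ring axis")
  }
  # eigenvalues sorted decreasing; pick the one isolated from the
  # degenerate in-plane pair
  gaps <- c(eg$values[1] - eg$values[2], eg$values[2] - eg$values[3])
  axis <- if (gaps[1] > gaps[2]) eg$vectors[, 1] else eg$vectors[, 3]
  if (axis[3] < 0) axis <- -axis
  ring_frame(center, axis)
}

# axial coordinate and azimuth (radians, right-handed about axis) of points
frame_cylindrical <- function(xyz, frame) {
  rel <- sweep(xyz, 2, frame$center)
  t_ax <- drop(rel %*% frame$axis)
  # orthonormal in-plane basis
  ref <- if (abs(frame$axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * frame$axis) * frame$axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(frame$axis[2] * e1[3] - frame$axis[3] * e1[2],
          frame$axis[3] * e1[1] - frame$axis[1] * e1[3],
          frame$axis[1] * e1[2] - frame$axis[2] * e1[1])
  u <- drop(rel %*% e1)
  v <- drop(rel %*% e2)
  list(axial = t_ax, azimuth = atan2(v, u), radial = sqrt(u^2 + v^2))
}

#' Assign chains of a ring model to rungs and azimuthal slots
#'
#' Chain centroids are clustered on their axial coordinate (1-D gap
#' clustering: with m = ceiling(n_chains / n_sym) expected rungs, the
#' m - 1 largest axial gaps split the sorted centroids; the split is
#' rejected unless the smallest split gap clearly exceeds the largest
#' within-rung gap). Rung 1 is the top of the ring: the more-constricted
#' end when end diameters differ, otherwise the end with the larger axial
#' coordinate. Within a rung, chains are ordered by azimuth about the
#' axis (slot 0 = smallest azimuth).
#'
#' @param model a [bead_model].
#' @param frame a [ring_frame].
#' @param n_sym the Cn symmetry order (chains per complete rung).
#' @return Object of class `ring_decomposition` with fields `frame`,
#'   `n_sym`, `rungs` (list of chain-id vectors, top to bottom),
#'   `rung_axial_positions` (Angstrom) and `rise` (mean spacing).
#' @export
assign_rungs <- function(model, frame, n_sym) {
  stopifnot(inherits(model, "bead_model"), inherits(frame, "ring_frame"),
            n_sym >= 2)
  beads <- model$beads
  chains <- unique(beads$chain_id)
  cent <- t(vapply(chains, function(ch) {
    colMeans(as.matrix(beads[beads$chain_id == ch, c("x", "y", "z")]))
  }, numeric(3)))
  cyl <- frame_cylindrical(cent, frame)
  m <- ceiling(length(chains) / n_sym)
  ord <- order(cyl$axial)
  t_sorted <- cyl$axial[ord]
  if (m == 1) {
    groups <- list(seq_along(chains))
  } else {
    gaps <- diff(t_sorted)
    split_at <- sort(order(gaps, decreasing = TRUE)[seq_len(m - 1)])
    within <- if (length(gaps) > (m - 1)) max(gaps[-order(gaps, decreasing = TRUE)[seq_len(m - 1)]]) else 0
    if (min(gaps[split_at]) <= 2 * within) {
      stop("axial clustering is ambiguous: split gaps ",
           paste(signif(sort(gaps[split_at]), 3), collapse = ", "),
           " vs largest within-rung gap ", signif(within, 3))
    }
    bounds <- c(0, split_at, length(t_sorted))
    groups <- lapply(seq_len(m), function(k) {
      ord[(bounds[k] + 1):bounds[k + 1]]
    })
  }
  sizes <- lengths(groups)
  if (any(sizes > n_sym)) {
    stop("rung decomposition inconsistent with n_sym = ", n_sym,
         ": cluster sizes ", paste(sizes, collapse = ", "))
  }
  # groups are ordered bottom (smallest axial) to top; decide which end is
  # "top" (rung 1): the more-constricted opening, by mean bead radius of
  # the two terminal rungs; fall back to larger axial coordinate
  rung_chains <- lapply(groups, function(g) chains[g])
  mean_radius <- function(chs) {
    sel <- beads$chain_id %in% chs
    mean(frame_cylindrical(as.matrix(beads[sel, c("x", "y", "z")]), frame)$radial)
  }
  r_low <- mean_radius(rung_chains[[1]])
  r_high <- mean_radius(rung_chains[[length(rung_chains)]])
  top_is_high <- TRUE
  if (length(rung_chains) > 1 && abs(r_low - r_high) > 0.02 * max(r_low, r_high)) {
    top_is_high <- r_high < r_low
  }
  ord_rungs <- if (top_is_high) rev(seq_along(groups)) else seq_along(groups)
  rung_chains <- rung_chains[ord_rungs]
  axial_pos <- vapply(groups, function(g) mean(cyl$axial[g]), numeric(1))[ord_rungs]
  # azimuthal ordering within each rung
  rung_chains <- lapply(rung_chains, function(chs) {
    az <- cyl$azimuth[match(chs, chains)]
    chs[order(az)]
  })
  structure(list(frame = frame, n_sym = as.integer(n_sym),
                 rungs = rung_chains,
                 rung_axial_positions = axial_pos,
                 rise = if (length(axial_pos) > 1) mean(abs(diff(axial_pos))) else NA_real_,
                 top_is_high_axial = top_is_high),
            class = "ring_decomposition")
}

#' @export
print.ring_decomposition <- function(x, ...) {
  cat(sprintf("<ring_decomposition: C%d, %d rungs (%s chains), rise %.2f A>\n",
              x$n_sym, length(x$rungs),
              paste(lengths(x$rungs), collapse = "+"),
              x$rise))
  invisible(x)
}

#' Ring composition and mass
#'
#' @param n_sym rotational symmetry order (subunits per rung).
#' @param n_rungs number of stacked rungs.
#' @param monomer_mass monomer mass in kDa (full-length Vipp1: 28.7 kDa).
#' @return Object of class `ring_composition` with `n_sym`, `n_rungs`,
#'   `n_subunits` and `total_mass` (MDa, one decimal).
#' @export
ring_composition <- function(n_sym, n_rungs, monomer_mass = 28.7) {
  stopifnot(n_sym >= 1, n_rungs >= 1, monomer_mass > 0,
            n_sym == round(n_sym), n_rungs == round(n_rungs))
  n_sub <- as.integer(n_sym) * as.integer(n_rungs)
  structure(list(n_sym = as.integer(n_sym), n_rungs = as.integer(n_rungs),
                 n_subunits = n_sub,
                 total_mass = round(n_sub * monomer_mass / 1000, 1)),
            class = "ring_composition")
}

#' @export
print.ring_composition <- function(x, ...) {
  cat(sprintf("C%d x %d rungs = %d subunits, %.1f MDa\n",
              x$n_sym, x$n_rungs, x$n_subunits, x$total_mass))
  invisible(x)
}

#' Extract one rung of a decomposed ring as a bead model
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it was computed from.
#' @param rung_index 1-based rung index (1 = top).
#' @return A [bead_model] with the rung's chains in azimuthal slot order.
#' @export
get_rung <- function(decomp, model, rung_index) {
  stopifnot(inherits(decomp, "ring_decomposition"), inherits(model, "bead_model"))
  if (rung_index < 1 || rung_index > length(decomp$rungs)) {
    stop("rung index ", rung_index, " out of range 1..", length(decomp$rungs))
  }
  chs <- decomp$rungs[[rung_index]]
  beads <- model$beads[model$beads$chain_id %in% chs, , drop = FALSE]
  beads <- beads[order(match(beads$chain_id, chs), beads$residue_number), ]
  rownames(beads) <- NULL
  bead_model(beads, source_model_id = paste0(model$source_model_id,
                                             "_rung", rung_index))
}

#' Serialize a ring decomposition as TSV
#'
#' Columns: chain_id, rung, slot, axial_position, azimuth_deg.
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it was computed from.
#' @param path output path.
#' @param header optional comment lines (prefixed `#`).
#' @return Invisibly, the table written.
#' @export
write_decomposition <- function(decomp, model, path, header = NULL) {
  beads <- model$beads
  rows <- do.call(rbind, lapply(seq_along(decomp$rungs), function(r) {
    chs <- decomp$rungs[[r]]
    cent <- t(vapply(chs, function(ch) {
      colMeans(as.matrix(beads[beads$chain_id == ch, c("x", "y", "z")]))
    }, numeric(3)))
    cyl <- frame_cylindrical(cent, decomp$frame)
    data.frame(chain_id = chs, rung = r, slot = seq_along(chs) - 1L,
               axial_position = round(cyl$axial, 4),
               azimuth_deg = round(cyl$azimuth * 180 / pi, 4),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
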