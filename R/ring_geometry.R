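# Ring geometry: helix direction vectors and tilt angles, per-interface
# rotations (delta-phi_i) and their cumulative sum, diameter profiles,
# and Kabsch superposition RMSDs.
#
# Angle conventions: the helix direction is sign-ambiguous, so angles to
# the ring axis are folded into [0, 90] degrees (acute convention); the
# horizontal-referenced angle is its complement. A per-interface rotation
# is positive when the upper rung's helix is the more vertical one, so
# the experimental bottom-to-top 40 -> 80 degree progression is positive.

#' Geometry measurement parameters
#'
#' Defaults are the helix alpha-5 anchor intervals of the Vipp1 models
#' (centers of mass of residues 194-202 and 211-219), the hairpin motif
#' interval 24-142, and the N-terminal helix alpha-0 interval 1-22.
#'
#' @param alpha5_com_a,alpha5_com_b inclusive residue intervals whose
#'   centers of mass define the helix direction (a precedes b).
#' @param hairpin_range inclusive hairpin interval (for RMSD pairing).
#' @param alpha0_range inclusive alpha-0 interval.
#' @param alpha1_nterm_residue residue whose beads define the per-rung
#'   constriction diameter.
#' @param slab_half_width axial half-width of diameter slabs, Angstrom.
#' @return Object of class `geometry_params`.
#' @export
geometry_params <- function(alpha5_com_a = c(194, 202),
                            alpha5_com_b = c(211, 219),
                            hairpin_range = c(24, 142),
                            alpha0_range = c(1, 22),
                            alpha1_nterm_residue = 24,
                            slab_half_width = 10) {
  ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(ok(alpha5_com_a), ok(alpha5_com_b), ok(hairpin_range),
            ok(alpha0_range), slab_half_width > 0)
  if (alpha5_com_a[2] >= alpha5_com_b[1]) {
    stop("alpha5 anchor interval a must precede interval b in sequence")
  }
  structure(list(alpha5_com_a = as.integer(alpha5_com_a),
                 alpha5_com_b = as.integer(alpha5_com_b),
                 hairpin_range = as.integer(hairpin_range),
                 alpha0_range = as.integer(alpha0_range),
                 alpha1_nterm_residue = as.integer(alpha1_nterm_residue),
                 slab_half_width = slab_half_width),
            class = "geometry_params")
}

interval_com <- function(xyz, residues, interval) {
  sel <- residues >= interval[1] & residues <= interval[2]
  want <- seq(interval[1], interval[2])
  if (!all(want %in% residues)) {
    stop("undefined helix: residues ",
         paste(setdiff(want, residues), collapse = ","), " missing")
  }
  colMeans(xyz[sel, , drop = FALSE])
}

#' Helix direction vector of one subunit
#'
#' Unit vector from the center of mass of the first anchor interval to
#' that of the second; invariant to translation of the subunit. Errors
#' if either interval is incompletely present ("undefined helix", e.g.
#' terminal rungs built without helices alpha-4/5/6).
#'
#' @param subunit a [bead_model] (or a bare data frame of beads) holding
#'   one chain.
#' @param params a [geometry_params].
#' @return Unit 3-vector.
#' @export
helix_vector <- function(subunit, params = geometry_params()) {
  beads <- if (inherits(subunit, "bead_model")) subunit$beads else subunit
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  a <- interval_com(xyz, beads$residue_number, params$alpha5_com_a)
  b <- interval_com(xyz, beads$residue_number, params$alpha5_com_b)
  v <- unname(b - a)
  v / sqrt(sum(v^2))
}

# acute angle (degrees) between a direction and the axis
angle_to_axis_deg <- function(v, axis) {
  c_ang <- abs(sum(v * axis)) / sqrt(sum(v^2))
  acos(pmin(1, c_ang)) * 180 / pi
}

subunit_angles <- function(bead_list, axis, params) {
  vapply(bead_list, function(b) {
    v <- tryCatch(helix_vector(b, params), error = function(e) NULL)
    if (is.null(v)) NA_real_ else angle_to_axis_deg(v, axis)
  }, numeric(1))
}

#' Mean helix angle of one rung
#'
#' Per-subunit acute angle between the helix direction and the ring
#' axis, averaged over the rung; the horizontal-referenced angle is the
#' complement (90 - axis angle). Subunits with an undefined helix are
#' skipped; a rung with none defined errors.
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it indexes.
#' @param rung rung index.
#' @param frame a [ring_frame] (defaults to the decomposition's).
#' @param params a [geometry_params].
#' @return List: `mean_to_axis`, `mean_to_horizontal`, `sd` (degrees,
#'   sd over subunits), `n_defined`.
#' @export
rung_alpha5_angle <- function(decomp, model, rung, frame = decomp$frame,
                              params = geometry_params()) {
  rg <- get_rung(decomp, model, rung)
  chains <- unique(rg$beads$chain_id)
  per <- subunit_angles(lapply(chains, function(ch) {
    rg$beads[rg$beads$chain_id == ch, , drop = FALSE]
  }), frame$axis, params)
  per <- per[!is.na(per)]
  if (length(per) == 0) stop("rung ", rung, ": no subunit has a defined helix")
  list(mean_to_axis = mean(per), mean_to_horizontal = 90 - mean(per),
       sd = if (length(per) > 1) stats::sd(per) else 0,
       n_defined = length(per))
}

# per-rung mean horizontal angles for a decomposition+model or a stack
rung_horizontal_angles <- function(x, model = NULL, frame = NULL,
                                   params = geometry_params()) {
  if (inherits(x, "stack_system")) {
    axis <- x$axis
    vapply(seq_len(x$n_rungs), function(r) {
      per <- vapply(seq_len(x$n_sym) - 1L, function(s) {
        sel <- x$index$rung == r & x$index$slot == s
        b <- data.frame(residue_number = x$index$residue[sel],
                        x = x$coords[sel, 1], y = x$coords[sel, 2],
                        z = x$coords[sel, 3])
        v <- tryCatch(helix_vector(b, params), error = function(e) NULL)
        if (is.null(v)) NA_real_ else angle_to_axis_deg(v, axis)
      }, numeric(1))
      per <- per[!is.na(per)]
      if (length(per) == 0) NA_real_ else 90 - mean(per)
    }, numeric(1))
  } else {
    if (is.null(frame)) frame <- x$frame
    vapply(seq_along(x$rungs), function(r) {
      ang <- tryCatch(rung_alpha5_angle(x, model, r, frame, params),
                      error = function(e) NULL)
      if (is.null(ang)) NA_real_ else ang$mean_to_horizontal
    }, numeric(1))
  }
}

#' Per-interface and cumulative helix rotations
#'
#' delta_phi_i for interface i is the mean horizontal helix angle of the
#' upper rung minus that of the rung below it (signed; positive when the
#' upper rung is the more vertical). delta_phi is the signed sum over
#' consecutive defined interfaces, which telescopes to top-rung mean
#' minus bottom-rung mean. Rungs with no defined helix (e.g. partially
#' built terminal rungs) are dropped before differencing.
#'
#' @param x a `ring_decomposition` (from [assign_rungs()]) or a `stack_system`.
#' @param model the [bead_model] (when `x` is a decomposition).
#' @param frame optional [ring_frame] override.
#' @param params a [geometry_params].
#' @return List: `per_rung_horizontal` (all rungs, NA where undefined),
#'   `delta_phi_i` (degrees, top interface first), `delta_phi` (degrees).
#' @export
delta_phi <- function(x, model = NULL, frame = NULL,
                      params = geometry_params()) {
  ang <- rung_horizontal_angles(x, model, frame, params)
  defined <- which(!is.na(ang))
  if (length(defined) < 2) {
    stop("fewer than 2 rungs with a defined helix; cannot measure rotations")
  }
  a <- ang[defined]
  dpi <- a[-length(a)] - a[-1]
  list(per_rung_horizontal = ang, delta_phi_i = dpi, delta_phi = sum(dpi))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Pairs beads by residue-number intersection (chains are paired in
#' order of appearance when both models have the same number of chains;
#' otherwise all beads are pooled and paired by residue number), then
#' computes the proper rotation (det = +1) and translation minimizing
#' the RMSD.
#'
#' @param mobile,reference [bead_model]s.
#' @return List: `rotation` (3 x 3, applied on the right of centered
#'   row-vector coordinates), `translation`, `rmsd` (Angstrom),
#'   `n_paired`, and `transformed` (the mobile model after fitting).
#' @export
kabsch_superpose <- function(mobile, reference) {
  pair <- pair_beads(mobile, reference)
  P <- pair$mobile
  Q <- pair$reference
  if (nrow(P) < 3) stop("fewer than 3 paired beads")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  if (svd(Q0)$d[2] < 1e-9) stop("degenerate (collinear) reference")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  out <- mobile
  all_xyz <- as.matrix(mobile$beads[, c("x", "y", "z")])
  out$beads[, c("x", "y", "z")] <- sweep(sweep(all_xyz, 2, cp) %*% R, 2, cq, "+")
  list(rotation = R, translation = cq - drop(cp %*% R), rmsd = rmsd,
       n_paired = nrow(P), transformed = out)
}

pair_beads <- function(mobile, reference) {
  mb <- mobile$beads
  rb <- reference$beads
  mchains <- unique(mb$chain_id)
  rchains <- unique(rb$chain_id)
  pairs_for <- function(m, r) {
    common <- intersect(m$residue_number, r$residue_number)
    list(mobile = as.matrix(m[match(common, m$residue_number),
                              c("x", "y", "z")]),
         reference = as.matrix(r[match(common, r$residue_number),
                                 c("x", "y", "z")]))
  }
  if (length(mchains) == length(rchains)) {
    got <- lapply(seq_along(mchains), function(k) {
      pairs_for(mb[mb$chain_id == mchains[k], , drop = FALSE],
                rb[rb$chain_id == rchains[k], , drop = FALSE])
    })
    list(mobile = do.call(rbind, lapply(got, `[[`, "mobile")),
         reference = do.call(rbind, lapply(got, `[[`, "reference")))
  } else {
    pairs_for(mb, rb)
  }
}

#' Root-mean-square deviation without fitting
#'
#' @param a,b [bead_model]s paired as in [kabsch_superpose()].
#' @return RMSD in Angstrom.
#' @export
rmsd_paired <- function(a, b) {
  pair <- pair_beads(a, b)
  sqrt(mean(rowSums((pair$mobile - pair$reference)^2)))
}

#' Diameter profile of a decomposed ring
#'
#' `lumen_percentile`: per axial slab (one per inter-rung boundary, the
#' central one being the equator), the internal diameter is twice the
#' 5th-percentile radial bead distance and the external twice the 95th.
#' `alpha1_nterm`: per rung, twice the mean radial distance of the
#' designated residue's bead, highlighting hairpin constriction.
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it indexes.
#' @param frame a [ring_frame] (defaults to the decomposition's).
#' @param params a [geometry_params].
#' @param convention `"lumen_percentile"` or `"alpha1_nterm"`.
#' @return data frame: `label`, `axial_position` (Angstrom),
#'   `internal_diameter_nm`, `external_diameter_nm` (the latter NA for
#'   the per-rung convention).
#' @export
diameter_profile <- function(decomp, model, frame = decomp$frame,
                             params = geometry_params(),
                             convention = c("lumen_percentile", "alpha1_nterm")) {
  convention <- match.arg(convention)
  beads <- model$beads
  cyl <- frame_cylindrical(as.matrix(beads[, c("x", "y", "z")]), frame)
  if (convention == "alpha1_nterm") {
    rows <- lapply(seq_along(decomp$rungs), function(r) {
      sel <- beads$chain_id %in% decomp$rungs[[r]] &
        beads$residue_number == params$alpha1_nterm_residue
      if (!any(sel)) return(NULL)
      data.frame(label = sprintf("rung%d", r),
                 axial_position = decomp$rung_axial_positions[r],
                 internal_diameter_nm = 2 * mean(cyl$radial[sel]) / 10,
                 external_diameter_nm = NA_real_)
    })
  } else {
    pos <- decomp$rung_axial_positions
    if (length(pos) < 2) stop("need >= 2 rungs for slab diameters")
    mids <- (pos[-1] + pos[-length(pos)]) / 2
    labels <- sprintf("boundary_%d_%d", seq_along(mids), seq_along(mids) + 1)
    eq <- ceiling(length(mids) / 2)
    labels[eq] <- paste0(labels[eq], "_equator")
    rows <- lapply(seq_along(mids), function(k) {
      sel <- abs(cyl$axial - mids[k]) <= params$slab_half_width
      if (!any(sel)) {
        warning("empty axial slab at ", signif(mids[k], 4), " Angstrom; skipped")
        return(NULL)
      }
      data.frame(label = labels[k], axial_position = mids[k],
                 internal_diameter_nm =
                   2 * stats::quantile(cyl$radial[sel], 0.05, names = FALSE) / 10,
                 external_diameter_nm =
                   2 * stats::quantile(cyl$radial[sel], 0.95, names = FALSE) / 10)
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no diameter entries could be measured")
  rownames(out) <- NULL
  out
}

#' Full geometry report for a decomposed ring
#'
#' Per-rung helix angles in both the axis-referenced and the
#' horizontal-referenced convention (complements), signed per-interface
#' rotations with their cumulative sum, and both diameter profiles.
#'
#' @inheritParams diameter_profile
#' @return Object of class `geometry_report`.
#' @export
geometry_report <- function(decomp, model, frame = decomp$frame,
                            params = geometry_params()) {
  per_rung <- lapply(seq_along(decomp$rungs), function(r) {
    ang <- tryCatch(rung_alpha5_angle(decomp, model, r, frame, params),
                    error = function(e) NULL)
    data.frame(rung = r,
               mean_angle_to_axis = if (is.null(ang)) NA_real_ else ang$mean_to_axis,
               mean_angle_to_horizontal = if (is.null(ang)) NA_real_ else ang$mean_to_horizontal,
               sd_over_subunits = if (is.null(ang)) NA_real_ else ang$sd)
  })
  per_rung <- do.call(rbind, per_rung)
  dp <- tryCatch(delta_phi(decomp, model, frame, params), error = function(e) NULL)
  diam <- tryCatch(diameter_profile(decomp, model, frame, params,
                                    "lumen_percentile"),
                   error = function(e) NULL)
  diam_rung <- tryCatch(diameter_profile(decomp, model, frame, params,
                                         "alpha1_nterm"),
                        error = function(e) NULL)
  structure(list(per_rung = per_rung,
                 delta_phi_i = if (is.null(dp)) NULL else dp$delta_phi_i,
                 delta_phi = if (is.null(dp)) NA_real_ else dp$delta_phi,
                 diameters = diam, rung_diameters = diam_rung),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Geometry report\n")
  print(round(x$per_rung, 2))
  if (!is.null(x$delta_phi_i)) {
    cat("delta_phi_i (deg):", paste(round(x$delta_phi_i, 2), collapse = ", "),
        "\ndelta_phi (deg):", round(x$delta_phi, 2), "\n")
  }
  invisible(x)
}

#' Serialize a geometry report
#'
#' Angles in degrees, diameters in nm (internal Angstrom values are
#' converted at serialization).
#'
#' @param report a `geometry_report`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @param header optional provenance string embedded in the outputs.
#' @return Invisibly, `report`.
#' @export
write_geometry_report <- function(report, json_path = NULL, tsv_path = NULL,
                                  header = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(header = if (is.null(header)) "" else header,
                              per_rung = report$per_rung,
                              delta_phi_i = report$delta_phi_i,
                              delta_phi = report$delta_phi,
                              diameters = report$diameters,
                              rung_diameters = report$rung_diameters),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(report$per_rung, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(report)
}
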