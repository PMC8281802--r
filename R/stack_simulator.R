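# Harmonic energy, analytic gradient, and relaxation of stack systems to
# their elastic equilibrium: a short overdamped low-temperature dynamics
# phase for basin exploration, followed by steepest descent with
# backtracking. Only the minimum matters for the ring geometry, so the
# dynamics is first-order (no inertia, no thermostat bookkeeping).

#' Minimizer parameters
#'
#' @param temperature_factor thermal noise amplitude of the dynamics
#'   phase, in units of k * Angstrom^2 (0 = pure descent).
#' @param md_steps number of overdamped dynamics steps.
#' @param step_size descent trial step, Angstrom per unit force.
#' @param damping mobility factor applied per dynamics step.
#' @param force_tolerance convergence threshold on the gradient max-norm,
#'   energy / Angstrom.
#' @param max_descent_steps step budget for the descent phase.
#' @param seed integer seed; a fixed seed makes the trajectory
#'   bitwise-reproducible.
#' @return Object of class `minimizer_params`.
#' @export
minimizer_params <- function(temperature_factor = 1e-3, md_steps = 5000,
                             step_size = 0.02, damping = 1,
                             force_tolerance = 1e-4,
                             max_descent_steps = 50000, seed = 1) {
  stopifnot(temperature_factor >= 0, md_steps >= 0, step_size > 0,
            damping > 0, force_tolerance > 0, max_descent_steps > 0)
  structure(list(temperature_factor = temperature_factor,
                 md_steps = as.integer(md_steps), step_size = step_size,
                 damping = damping, force_tolerance = force_tolerance,
                 max_descent_steps = as.integer(max_descent_steps),
                 seed = as.integer(seed)),
            class = "minimizer_params")
}

spring_lengths <- function(coords, springs) {
  d <- coords[springs$i, , drop = FALSE] - coords[springs$j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Elastic energy of a stack system
#'
#' E = sum over springs of (k/2) (|ri - rj| - d0)^2; non-negative, zero
#' exactly when every spring sits at its natural length.
#'
#' @param system a `stack_system`.
#' @param coords optional coordinate matrix overriding `system$coords`.
#' @return Scalar energy (units of k * Angstrom^2).
#' @export
stack_energy <- function(system, coords = system$coords) {
  len <- spring_lengths(coords, system$springs)
  0.5 * system$stiffness * sum((len - system$springs$d0)^2)
}

#' Analytic gradient of the elastic energy
#'
#' Coincident beads sharing a spring (zero separation with d0 > 0) get a
#' deterministic unit direction derived from the bead indices so the
#' gradient stays finite; such events are reported.
#'
#' @inheritParams stack_energy
#' @return Matrix (n beads x 3) of dE/dr.
#' @export
stack_gradient <- function(system, coords = system$coords) {
  sp <- system$springs
  d <- coords[sp$i, , drop = FALSE] - coords[sp$j, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  zero <- len < 1e-12
  if (any(zero)) {
    message(sum(zero), " coincident bead pair(s) on a spring; using a deterministic direction")
    ang <- (sp$i[zero] * 2654435761 + sp$j[zero]) %% 360
    d[zero, ] <- cbind(cos(ang), sin(ang), 0.5)
    len[zero] <- sqrt(rowSums(d[zero, , drop = FALSE]^2))
  }
  f <- system$stiffness * (len - sp$d0) / len
  g <- f * d
  grad <- matrix(0, nrow(coords), 3)
  add_i <- rowsum(g, sp$i)
  grad[as.integer(rownames(add_i)), ] <- grad[as.integer(rownames(add_i)), ] + add_i
  add_j <- rowsum(g, sp$j)
  grad[as.integer(rownames(add_j)), ] <- grad[as.integer(rownames(add_j)), ] - add_j
  grad
}

#' Relax a stack system to its elastic equilibrium
#'
#' Three phases, all in compiled code. Phase 1: `md_steps` overdamped
#' Langevin-style steps (a force step plus Gaussian noise of amplitude
#' set by `temperature_factor`, drawn from R's RNG so a fixed seed makes
#' the trajectory reproducible). Phase 2: monotone limited-memory
#' quasi-Newton descent (only energy decreases are accepted), which
#' carries the stack through its soft collective bending modes far
#' faster than first-order steps. Phase 3: steepest descent with backtracking
#' (the step is halved whenever the trial energy increases) until the
#' gradient max-norm drops below `force_tolerance` or the step budget is
#' exhausted; its monotone energy series is reported in the trajectory.
#' Energy at return never exceeds the initial energy; the convergence
#' flag is set truthfully.
#'
#' @param system a `stack_system`.
#' @param params a [minimizer_params].
#' @return List with `system` (coordinates replaced by the equilibrium)
#'   and `trajectory` (energies of accepted descent steps, convergence
#'   flag, final gradient max-norm, initial/final frames).
#' @export
minimize <- function(system, params = minimizer_params()) {
  stopifnot(inherits(system, "stack_system"), inherits(params, "minimizer_params"))
  x0 <- system$coords
  e0 <- stack_energy(system, x0)
  set.seed(params$seed)
  res <- .enm_relax_cpp(x0, system$springs$i, system$springs$j,
                        system$springs$d0, system$stiffness,
                        params$temperature_factor, params$md_steps,
                        params$step_size, params$damping,
                        params$force_tolerance,
                        params$max_descent_steps, params$max_descent_steps)
  x <- res$coords
  if (!all(is.finite(x))) {
    stop("relaxation diverged; initial energy ", signif(e0, 6))
  }
  converged <- res$converged
  grad_norm <- res$final_grad_norm
  energies <- res$energies
  # guard: dynamics noise could in principle leave us above the start
  if (stack_energy(system, x) > e0) {
    x <- x0
    grad_norm <- max(abs(stack_gradient(system, x)))
    converged <- grad_norm < params$force_tolerance
    energies <- e0
  }
  out <- system
  out$coords <- x
  list(system = out,
       trajectory = structure(list(energies = energies,
                                   converged = converged,
                                   final_grad_norm = grad_norm,
                                   initial = x0, final = x),
                              class = "enm_trajectory"))
}

#' Minimize a series of stack sizes and measure their curvature
#'
#' Assembles and relaxes one stack per requested size and reports the
#' per-interface helix rotations and their cumulative sum, reproducing
#' the rung-number titration of the ring-stacking experiment.
#'
#' @param average_rung a [bead_model] (see [make_average_rung()]).
#' @param intra_map,inter_map contact maps.
#' @param n_rungs_list stack sizes (default 2:10).
#' @param params a [minimizer_params].
#' @param rise axial spacing, Angstrom.
#' @param geom a [geometry_params] naming the helix anchor intervals.
#' @param stiffness uniform spring stiffness.
#' @return data frame with one row per size: n_rungs, delta_phi
#'   (degrees), final_energy, converged, and a `delta_phi_i` list column
#'   of per-interface rotations. Rows whose minimization fails carry NA
#'   and the series continues.
#' @export
run_stack_series <- function(average_rung, intra_map, inter_map,
                             n_rungs_list = 2:10, params = minimizer_params(),
                             rise, geom, stiffness = 1) {
  stopifnot(all(n_rungs_list >= 2))
  rows <- lapply(n_rungs_list, function(nr) {
    res <- tryCatch({
      system <- assemble_stack(average_rung, intra_map, inter_map, nr, rise,
                               stiffness = stiffness)
      fit <- minimize(system, params)
      dp <- delta_phi(fit$system, params = geom)
      list(delta_phi = dp$delta_phi, delta_phi_i = dp$delta_phi_i,
           energy = stack_energy(fit$system),
           converged = fit$trajectory$converged)
    }, error = function(e) {
      warning("stack of ", nr, " rungs failed: ", conditionMessage(e))
      list(delta_phi = NA_real_, delta_phi_i = NA_real_,
           energy = NA_real_, converged = FALSE)
    })
    data.frame(n_rungs = nr, delta_phi = res$delta_phi,
               final_energy = res$energy, converged = res$converged,
               delta_phi_i = I(list(res$delta_phi_i)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a stack series table as TSV and/or JSON
#'
#' @param series result of [run_stack_series()].
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @param header optional comment lines for the TSV (prefixed `#`).
#' @return Invisibly, `series`.
#' @export
write_series <- function(series, tsv_path = NULL, json_path = NULL,
                         header = NULL) {
  flat <- series
  flat$delta_phi_i <- vapply(series$delta_phi_i, function(v) {
    paste(signif(v, 6), collapse = ",")
  }, character(1))
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(header = if (is.null(header)) "" else header,
           rows = lapply(seq_len(nrow(series)), function(i) {
             list(n_rungs = series$n_rungs[i],
                  delta_phi = series$delta_phi[i],
                  delta_phi_i = series$delta_phi_i[[i]],
                  final_energy = series$final_energy[i],
                  converged = series$converged[i])
           })),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(series)
}
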