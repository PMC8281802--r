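# Consensus elastic-network construction: canonical intra-rung and
# inter-rung contact maps, the average rung, and stack assembly.
#
# Canonical coordinates for a contact are (residue_a, residue_b,
# slot_offset, rung_offset): slot_offset is the azimuthal subunit offset
# (0 = same subunit), rung_offset 0 for intra-rung and +1 for contacts to
# the rung above. One "monomer environment" is one subunit together with
# its same-rung neighbours at slot offsets 1..max_slot_offset; a
# consensus spring is kept when strictly more than the consensus fraction
# of environments contain the contact, and its natural length is the
# average of the pair distance over the environments.

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' All bead pairs within a distance cutoff
#'
#' Plain (non-canonical) contact listing between two bead models, or
#' within one when `beads_b` is omitted (self-pairs excluded, unordered
#' pairs counted once).
#'
#' @param beads_a,beads_b [bead_model] objects.
#' @param cutoff distance cutoff, Angstrom.
#' @return data frame: chain_a, residue_a, chain_b, residue_b, distance.
#' @export
contact_map_single <- function(beads_a, beads_b = NULL, cutoff) {
  stopifnot(cutoff > 0, inherits(beads_a, "bead_model"))
  a <- beads_a$beads
  same <- is.null(beads_b)
  b <- if (same) a else beads_b$beads
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (same) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  data.frame(chain_a = a$chain_id[hit[, 1]],
             residue_a = a$residue_number[hit[, 1]],
             chain_b = b$chain_id[hit[, 2]],
             residue_b = b$residue_number[hit[, 2]],
             distance = d[hit],
             stringsAsFactors = FALSE)
}

# coordinates of every subunit in the given rungs as [[rung]][[slot]]
# n_res x 3 matrices, after checking that residue coverage is identical
rung_coord_arrays <- function(decomp, model, rungs) {
  beads <- model$beads
  residues <- NULL
  bad <- character(0)
  coords <- list()
  for (r in rungs) {
    chs <- decomp$rungs[[r]]
    coords[[as.character(r)]] <- lapply(chs, function(ch) {
      b <- beads[beads$chain_id == ch, , drop = FALSE]
      b <- b[order(b$residue_number), , drop = FALSE]
      if (is.null(residues)) residues <<- b$residue_number
      if (!identical(b$residue_number, residues)) bad <<- c(bad, ch)
      as.matrix(b[, c("x", "y", "z")])
    })
  }
  if (length(bad) > 0) {
    stop("unequal residue coverage across monomers; offending chain(s): ",
         paste(unique(bad), collapse = ", "))
  }
  list(residues = residues, coords = coords)
}

new_contact_map <- function(df, cutoff, consensus_threshold, n_sym, residues,
                            residues_b = residues, source = "") {
  df <- df[order(df$rung_offset, df$slot_offset, df$residue_a, df$residue_b), ]
  rownames(df) <- NULL
  structure(df, class = c("contact_map", "data.frame"),
            cutoff = cutoff, consensus_threshold = consensus_threshold,
            n_sym = n_sym, residues = residues, residues_b = residues_b,
            source = source)
}

#' Build the consensus intra-rung contact map
#'
#' Compares the contact map of every monomer environment in the given
#' rungs (e.g. the 11 x 4 monomers of the complete rungs 2-5 of the C11
#' ring) and keeps a canonical contact when it exists in strictly more
#' than `consensus` of the environments; the spring's natural length is
#' the average of its distances over all environments (switch to the
#' supporting environments only with `length_mode = "supporting"`).
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it indexes.
#' @param rung_range integer vector of complete rungs to compare.
#' @param cutoff contact cutoff, Angstrom (default 10).
#' @param consensus consensus fraction; strictly-greater boundary
#'   (default 0.5).
#' @param max_slot_offset largest same-rung neighbour offset included in
#'   a monomer environment (default 5; subunit j contacts j+1 and j+3).
#' @param length_mode `"all"` (unconditional average) or `"supporting"`.
#' @return A `contact_map`: data frame with residue_a, residue_b,
#'   slot_offset, rung_offset (= 0), natural_length, support. The
#'   attribute `"removed"` lists contacts that were observed in at
#'   least one environment but failed the consensus rule (in the
#'   deposited rings these localize to the monomer's hinge regions).
#' @export
build_intra_map <- function(decomp, model, rung_range, cutoff = 10,
                            consensus = 0.5, max_slot_offset = 5,
                            length_mode = c("all", "supporting")) {
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(decomp, "ring_decomposition"), cutoff > 0)
  if (any(lengths(decomp$rungs[rung_range]) != decomp$n_sym)) {
    stop("rung_range contains incomplete rungs: sizes ",
         paste(lengths(decomp$rungs[rung_range]), collapse = ", "))
  }
  ca <- rung_coord_arrays(decomp, model, rung_range)
  res <- ca$residues
  n_res <- length(res)
  n_sym <- decomp$n_sym
  n_env <- length(rung_range) * n_sym
  out <- list()
  removed <- list()
  for (delta in 0:min(max_slot_offset, n_sym - 1)) {
    d_sum <- matrix(0, n_res, n_res)
    d_sup <- matrix(0, n_res, n_res)
    cnt <- matrix(0L, n_res, n_res)
    for (r in as.character(rung_range)) {
      for (s in seq_len(n_sym)) {
        a <- ca$coords[[r]][[s]]
        b <- ca$coords[[r]][[(s - 1 + delta) %% n_sym + 1]]
        d <- cross_dist(a, b)
        inside <- d <= cutoff
        d_sum <- d_sum + d
        d_sup <- d_sup + d * inside
        cnt <- cnt + inside
      }
    }
    support <- cnt / n_env
    keep <- support > consensus
    seen <- support > 0
    if (delta == 0) {
      keep <- keep & upper.tri(keep)
      seen <- seen & upper.tri(seen)
    }
    dropped <- seen & !keep
    if (any(dropped)) {
      di <- which(dropped, arr.ind = TRUE)
      removed[[length(removed) + 1]] <- data.frame(residue_a = res[di[, 1]],
                                                   residue_b = res[di[, 2]],
                                                   slot_offset = delta,
                                                   support = support[dropped])
    }
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    nat <- if (length_mode == "all") d_sum[keep] / n_env else d_sup[keep] / cnt[keep]
    out[[length(out) + 1]] <- data.frame(residue_a = res[idx[, 1]],
                                         residue_b = res[idx[, 2]],
                                         slot_offset = delta,
                                         rung_offset = 0L,
                                         natural_length = nat,
                                         support = support[keep])
  }
  df <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(residue_a = integer(0), residue_b = integer(0),
               slot_offset = integer(0), rung_offset = integer(0),
               natural_length = numeric(0), support = numeric(0))
  map <- new_contact_map(df, cutoff = cutoff, consensus_threshold = consensus,
                         n_sym = n_sym, residues = res,
                         source = sprintf("intra-rung consensus, rungs %s",
                                          paste(rung_range, collapse = ",")))
  # contacts observed somewhere but failing the consensus rule (they
  # concentrate at the flexible hinge regions); reported, never asserted
  attr(map, "removed") <- if (length(removed) > 0) do.call(rbind, removed) else
    data.frame(residue_a = integer(0), residue_b = integer(0),
               slot_offset = integer(0), support = numeric(0))
  map
}

#' Build the inter-rung contact map from one rung pair
#'
#' Contacts between the beads of a lower rung and the rung directly above
#' it (by default the equatorial pair, rungs 4 and 3, the interface used
#' for the ring model because the bottom rung is incompletely built).
#' Each canonical contact (residue in lower, residue in upper, slot
#' offset, rung_offset +1) has its natural length averaged over the
#' n_sym symmetry-related copies.
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it indexes.
#' @param lower_rung,upper_rung rung indices (upper = lower - 1 normally).
#' @param cutoff contact cutoff, Angstrom (default 10).
#' @return A `contact_map` with `rung_offset = 1` rows.
#' @export
build_inter_map <- function(decomp, model, lower_rung = 4, upper_rung = 3,
                            cutoff = 10) {
  stopifnot(inherits(decomp, "ring_decomposition"), cutoff > 0)
  n_sym <- decomp$n_sym
  for (r in c(lower_rung, upper_rung)) {
    if (length(decomp$rungs[[r]]) != n_sym) {
      stop("rung ", r, " is incomplete (", length(decomp$rungs[[r]]),
           " of ", n_sym, " chains); inter-rung map needs complete rungs")
    }
  }
  lo <- rung_coord_arrays(decomp, model, lower_rung)
  up <- rung_coord_arrays(decomp, model, upper_rung)
  res_lo <- lo$residues
  res_up <- up$residues
  lo_c <- lo$coords[[as.character(lower_rung)]]
  up_c <- up$coords[[as.character(upper_rung)]]
  out <- list()
  for (delta in 0:(n_sym - 1)) {
    d_sum <- matrix(0, length(res_lo), length(res_up))
    cnt <- matrix(0L, length(res_lo), length(res_up))
    for (s in seq_len(n_sym)) {
      d <- cross_dist(lo_c[[s]], up_c[[(s - 1 + delta) %% n_sym + 1]])
      d_sum <- d_sum + d
      cnt <- cnt + (d <= cutoff)
    }
    keep <- cnt > 0
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    delta_signed <- if (delta > n_sym / 2) delta - n_sym else delta
    out[[length(out) + 1]] <- data.frame(residue_a = res_lo[idx[, 1]],
                                         residue_b = res_up[idx[, 2]],
                                         slot_offset = delta_signed,
                                         rung_offset = 1L,
                                         natural_length = d_sum[keep] / n_sym,
                                         support = cnt[keep] / n_sym)
  }
  if (length(out) == 0) {
    warning("no inter-rung contacts within ", cutoff, " Angstrom")
    df <- data.frame(residue_a = integer(0), residue_b = integer(0),
                     slot_offset = integer(0), rung_offset = integer(0),
                     natural_length = numeric(0), support = numeric(0))
  } else {
    df <- do.call(rbind, out)
  }
  new_contact_map(df, cutoff = cutoff, consensus_threshold = 0,
                  n_sym = n_sym, residues = res_lo, residues_b = res_up,
                  source = sprintf("inter-rung, rungs %d-%d",
                                   lower_rung, upper_rung))
}

#' Relax one rung to the intra-map equilibrium ("average rung")
#'
#' Starts from the coordinates of `init_rung` (by default rung 3, the
#' best-resolved rung) and minimizes the intra-rung elastic network so
#' the result carries the consensus (average) geometry.
#'
#' @param decomp a `ring_decomposition` (from [assign_rungs()]).
#' @param model the [bead_model] it indexes.
#' @param intra_map consensus map from [build_intra_map()].
#' @param init_rung rung whose coordinates seed the relaxation.
#' @param params a [minimizer_params]; pure descent by default.
#' @return A [bead_model] of n_sym chains with attribute `"trajectory"`.
#' @export
make_average_rung <- function(decomp, model, intra_map, init_rung = 3,
                              params = minimizer_params(temperature_factor = 0,
                                                        md_steps = 0,
                                                        force_tolerance = 1e-6)) {
  rung <- get_rung(decomp, model, init_rung)
  system <- stack_from_rungs(list(rung), intra_map, inter_map = NULL,
                             rise = decomp$rise)
  fit <- minimize(system, params)
  if (!fit$trajectory$converged) {
    stop(sprintf("average-rung relaxation did not converge (final gradient max-norm %.3g)",
                 fit$trajectory$final_grad_norm))
  }
  out <- rung
  out$beads[, c("x", "y", "z")] <- fit$system$coords
  out$source_model_id <- paste0(model$source_model_id, "_average_rung")
  attr(out, "trajectory") <- fit$trajectory
  out
}

# map residue numbers to indices of the canonical residue vector,
# erroring on springs that reference residues absent from the beads
residue_index <- function(wanted, residues, what) {
  idx <- match(wanted, residues)
  if (anyNA(idx)) {
    stop(what, " references residue(s) absent from the rung: ",
         paste(unique(wanted[is.na(idx)]), collapse = ", "))
  }
  idx
}

# spring list for an n_rungs x n_sym x n_res bead lattice; bead index of
# (rung r, slot s0 (0-based), residue index i) is ((r-1)*n_sym + s0)*n_res + i
stack_springs <- function(intra_map, inter_map, n_rungs, n_sym, residues) {
  n_res <- length(residues)
  bead_at <- function(r, s0, i) ((r - 1) * n_sym + (s0 %% n_sym)) * n_res + i
  springs <- list()
  if (nrow(intra_map) > 0) {
    ia <- residue_index(intra_map$residue_a, residues, "intra map")
    ib <- residue_index(intra_map$residue_b, residues, "intra map")
    for (r in seq_len(n_rungs)) {
      for (s0 in seq_len(n_sym) - 1L) {
        springs[[length(springs) + 1]] <-
          data.frame(i = bead_at(r, s0, ia),
                     j = bead_at(r, s0 + intra_map$slot_offset, ib),
                     d0 = intra_map$natural_length)
      }
    }
  }
  if (!is.null(inter_map) && nrow(inter_map) > 0) {
    if (any(abs(inter_map$slot_offset) >= n_sym)) {
      stop("inter-rung contact references slot offset >= n_sym")
    }
    ia <- residue_index(inter_map$residue_a, residues, "inter map")
    ib <- residue_index(inter_map$residue_b, residues, "inter map")
    for (r in seq_len(n_rungs)[-1]) {      # r = lower rung, r - 1 above it
      for (s0 in seq_len(n_sym) - 1L) {
        springs[[length(springs) + 1]] <-
          data.frame(i = bead_at(r, s0, ia),
                     j = bead_at(r - 1, s0 + inter_map$slot_offset, ib),
                     d0 = inter_map$natural_length)
      }
    }
  }
  sp <- do.call(rbind, springs)
  # canonical i < j ordering; guards against double counting at the
  # antipodal slot offset of even-order rings
  swap <- sp$i > sp$j
  tmp <- sp$i[swap]; sp$i[swap] <- sp$j[swap]; sp$j[swap] <- tmp
  sp <- sp[!duplicated(sp[, c("i", "j")]), ]
  rownames(sp) <- NULL
  sp
}

new_stack_system <- function(coords, springs, stiffness, n_rungs, n_sym,
                             residues, rise, axis = c(0, 0, 1)) {
  stopifnot(nrow(coords) == n_rungs * n_sym * length(residues))
  if (any(springs$i < 1 | springs$j > nrow(coords))) {
    stop("spring references a bead outside the stack")
  }
  if (any(springs$d0 <= 0)) stop("springs must have positive natural length")
  index <- data.frame(rung = rep(seq_len(n_rungs), each = n_sym * length(residues)),
                      slot = rep(rep(seq_len(n_sym) - 1L, each = length(residues)),
                                 times = n_rungs),
                      residue = rep(residues, times = n_rungs * n_sym))
  structure(list(coords = coords, springs = springs, stiffness = stiffness,
                 n_rungs = as.integer(n_rungs), n_sym = as.integer(n_sym),
                 residues = residues, rise = rise, axis = axis / sqrt(sum(axis^2)),
                 index = index),
            class = "stack_system")
}

#' @export
print.stack_system <- function(x, ...) {
  cat(sprintf("<stack_system: %d rungs x C%d x %d residues = %d beads, %d springs, k = %g>\n",
              x$n_rungs, x$n_sym, length(x$residues), nrow(x$coords),
              nrow(x$springs), x$stiffness))
  invisible(x)
}

#' Assemble a cylindrical stack of average rungs
#'
#' Places `n_rungs` translated copies of the average rung along the axis
#' at the given rise (rung 1 on top) and instantiates the consensus
#' springs inside every rung plus the inter-rung springs across every
#' adjacent pair, using one slot-offset registry throughout.
#'
#' @param average_rung a [bead_model] of n_sym chains in slot order.
#' @param intra_map,inter_map contact maps; `inter_map = NULL` builds an
#'   uncoupled stack.
#' @param n_rungs number of rungs (2-10 is the modeled regime; a warning
#'   is issued outside it).
#' @param rise axial spacing, Angstrom.
#' @param stiffness uniform spring stiffness k (energy / Angstrom^2).
#' @param axis stacking axis (default z).
#' @return A `stack_system`.
#' @export
assemble_stack <- function(average_rung, intra_map, inter_map, n_rungs, rise,
                           stiffness = 1, axis = c(0, 0, 1)) {
  stopifnot(inherits(average_rung, "bead_model"), rise > 0, stiffness > 0)
  if (n_rungs < 1) stop("n_rungs must be >= 1")
  if (n_rungs < 2 || n_rungs > 10) {
    warning("n_rungs = ", n_rungs, " is outside the modeled 2-10 rung regime")
  }
  chains <- unique(average_rung$beads$chain_id)
  n_sym <- length(chains)
  residues <- attr(intra_map, "residues")
  per_chain <- lapply(chains, function(ch) {
    b <- average_rung$beads[average_rung$beads$chain_id == ch, , drop = FALSE]
    if (!identical(b$residue_number, residues)) {
      stop("average rung chain ", ch, " does not match the map's residue set")
    }
    as.matrix(b[, c("x", "y", "z")])
  })
  rung_xyz <- do.call(rbind, per_chain)
  axis <- axis / sqrt(sum(axis^2))
  coords <- do.call(rbind, lapply(seq_len(n_rungs), function(r) {
    sweep(rung_xyz, 2, (r - 1) * rise * axis)
  }))
  springs <- stack_springs(intra_map, inter_map, n_rungs, n_sym, residues)
  new_stack_system(coords, springs, stiffness, n_rungs, n_sym, residues,
                   rise, axis)
}

#' Stack system from explicitly given rung coordinates
#'
#' Builds the same spring topology as [assemble_stack()] but keeps the
#' supplied per-rung coordinates (no translation), e.g. to evaluate the
#' elastic energy of an experimental or generated structure under its
#' own maps.
#'
#' @param rungs list of [bead_model]s, top rung first, congruent residue
#'   coverage matching `intra_map`.
#' @param intra_map,inter_map contact maps (`inter_map = NULL` allowed).
#' @param rise nominal rise, Angstrom (metadata only here).
#' @param stiffness uniform spring stiffness.
#' @return A `stack_system`.
#' @export
stack_from_rungs <- function(rungs, intra_map, inter_map = NULL, rise = NA,
                             stiffness = 1) {
  residues <- attr(intra_map, "residues")
  n_sym <- length(unique(rungs[[1]]$beads$chain_id))
  coords <- do.call(rbind, lapply(rungs, function(rg) {
    chains <- unique(rg$beads$chain_id)
    if (length(chains) != n_sym) stop("rungs differ in chain count")
    do.call(rbind, lapply(chains, function(ch) {
      b <- rg$beads[rg$beads$chain_id == ch, , drop = FALSE]
      if (!identical(b$residue_number, residues)) {
        stop("chain ", ch, " does not match the map's residue set")
      }
      as.matrix(b[, c("x", "y", "z")])
    }))
  }))
  springs <- stack_springs(intra_map, inter_map, length(rungs), n_sym, residues)
  new_stack_system(coords, springs, stiffness, length(rungs), n_sym,
                   residues, rise)
}

#' Express a stack system as a bead model
#'
#' Chains are lettered rung-major in slot order, matching the synthetic
#' generator's convention.
#'
#' @param system a `stack_system`.
#' @return A [bead_model].
#' @export
stack_to_bead_model <- function(system, model_id = "stack") {
  ids <- chain_id_alphabet(system$n_rungs * system$n_sym)
  chain <- ids[(system$index$rung - 1) * system$n_sym + system$index$slot + 1]
  bead_model(data.frame(chain_id = chain,
                        residue_number = system$index$residue,
                        x = system$coords[, 1], y = system$coords[, 2],
                        z = system$coords[, 3], stringsAsFactors = FALSE),
             source_model_id = model_id)
}

#' Serialize a contact map as TSV
#'
#' Deterministic sort order (rung_offset, slot_offset, residue_a,
#' residue_b); lengths in Angstrom.
#'
#' @param map a `contact_map`.
#' @param path output path.
#' @param header optional comment lines (prefixed `#`).
#' @return Invisibly, `path`.
#' @export
write_contact_map <- function(map, path, header = NULL) {
  df <- as.data.frame(map)
  names(df)[names(df) == "natural_length"] <- "natural_length_A"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff_A: %g", attr(map, "cutoff")), con)
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
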