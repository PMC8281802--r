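# Coordinate model input/output and reduction to C-alpha bead models.
# Parsing and writing of PDB/mmCIF go through bio3d; this layer normalises
# the parsed records into plain data frames and enforces the conventions
# needed downstream (model 1 only, alt-loc selection, author numbering).

#' Construct an atom model
#'
#' An atom model is the package's parsed representation of a coordinate
#' file: one row per atom with chain, residue and position, plus an
#' identifier for provenance.
#'
#' @param atoms data frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param model_id character scalar naming the model (file stem or label).
#' @return An object of class `atom_model`.
#' @export
atom_model <- function(atoms, model_id = "model") {
  required <- c("chain_id", "residue_number", "residue_name", "atom_name",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms[required], stringsAsFactors = FALSE)
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) records: e.g. ",
         key[which(duplicated(key))[1]])
  }
  structure(list(atoms = atoms, model_id = as.character(model_id)),
            class = "atom_model")
}

#' Construct a bead model
#'
#' A bead model carries exactly one bead per residue, positioned at the
#' C-alpha atom; residue numbers are strictly increasing within a chain.
#'
#' @param beads data frame with columns `chain_id`, `residue_number`,
#'   `x`, `y`, `z`.
#' @param source_model_id identifier of the originating atom model.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(beads, source_model_id = "model") {
  required <- c("chain_id", "residue_number", "x", "y", "z")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0) {
    stop("bead table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  beads <- as.data.frame(beads[required], stringsAsFactors = FALSE)
  beads$chain_id <- as.character(beads$chain_id)
  beads$residue_number <- as.integer(beads$residue_number)
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")])))) {
    stop("non-finite bead coordinates")
  }
  for (ch in unique(beads$chain_id)) {
    rn <- beads$residue_number[beads$chain_id == ch]
    if (anyDuplicated(rn)) stop("chain ", ch, ": more than one bead per residue")
    if (is.unsorted(rn, strictly = TRUE)) {
      stop("chain ", ch, ": residue numbers not strictly increasing")
    }
  }
  structure(list(beads = beads, source_model_id = as.character(source_model_id)),
            class = "bead_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model '%s': %d atoms, %d chains>\n", x$model_id,
              nrow(x$atoms), length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model '%s': %d beads, %d chains>\n", x$source_model_id,
              nrow(x$beads), length(unique(x$beads$chain_id))))
  invisible(x)
}

# Resolve alternate locations: highest occupancy wins, ties broken by
# altloc letter. Insertion codes are rejected (absent from the target
# ring depositions; supporting them would silently corrupt residue keys).
resolve_altloc <- function(atom) {
  if (!is.null(atom$insert) && any(!is.na(atom$insert) & atom$insert != "")) {
    stop("insertion codes present; not supported")
  }
  alt <- atom$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(atom))
  alt[is.na(alt)] <- ""
  occ <- atom$o
  if (is.null(occ)) occ <- rep(1, nrow(atom))
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$elety)
  ord <- order(key, -occ, alt)
  keep <- ord[!duplicated(key[ord])]
  atom[sort(keep), , drop = FALSE]   # selection in original file order
}

#' Read a coordinate model from PDB or mmCIF
#'
#' Loads all ATOM/HETATM coordinate records of the first model in the
#' file. Alternate locations are resolved to the highest-occupancy copy
#' (ties broken by altloc letter); files with insertion codes are
#' rejected. Residue numbering is taken verbatim (author numbering).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return An [atom_model].
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  atom <- parsed$atom
  if (is.null(atom) || nrow(atom) == 0) stop("empty model: ", path)
  atom <- resolve_altloc(atom)
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(chain_id = chain,
                      residue_number = atom$resno,
                      residue_name = atom$resid,
                      atom_name = atom$elety,
                      x = atom$x, y = atom$y, z = atom$z,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  atom_model(atoms, model_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a model as a PDB file
#'
#' Atom models are written record-for-record; bead models are written as
#' C-alpha-only ATOM records (atom name `CA`). Coordinates that overflow
#' the fixed-width PDB coordinate field raise an error rather than being
#' silently truncated.
#'
#' @param model an [atom_model] or [bead_model].
#' @param path output file path.
#' @param header optional character vector written as leading REMARK lines.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, header = NULL) {
  if (inherits(model, "bead_model")) {
    df <- model$beads
    df$residue_name <- "ALA"
    df$atom_name <- "CA"
  } else if (inherits(model, "atom_model")) {
    df <- model$atoms
  } else {
    stop("model must be an atom_model or bead_model")
  }
  if (nrow(df) == 0) stop("refusing to write an empty model")
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (any(abs(xyz) >= 1e4)) {
    stop("coordinate overflows fixed-width PDB field (|x| >= 10^4 Angstrom)")
  }
  if (any(nchar(df$chain_id) > 1)) {
    stop("chain identifiers longer than one character cannot be written to PDB")
  }
  lines <- character(0)
  if (!is.null(header)) lines <- paste("REMARK   ", header)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = df$residue_number,
                   resid = df$residue_name,
                   eleno = seq_len(nrow(df)),
                   elety = df$atom_name,
                   chain = df$chain_id)
  if (length(lines) > 0) {
    body <- readLines(path)
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Write a multi-frame trajectory as a multi-model PDB
#'
#' @param frames list of [bead_model] objects sharing one topology.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(frames, path) {
  if (length(frames) == 0) stop("no frames to write")
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_along(frames)) {
    write_model(frames[[i]], tmp)
    body <- readLines(tmp)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Reduce an atom model to one bead per residue at the C-alpha position
#'
#' Residues lacking a C-alpha atom are skipped and counted in a warning.
#'
#' @param model an [atom_model].
#' @param residue_range optional inclusive `c(lo, hi)` interval of author
#'   residue numbers to retain.
#' @return A [bead_model].
#' @export
extract_calpha <- function(model, residue_range = NULL) {
  stopifnot(inherits(model, "atom_model"))
  atoms <- model$atoms
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2, residue_range[1] <= residue_range[2])
    atoms <- atoms[atoms$residue_number >= residue_range[1] &
                   atoms$residue_number <= residue_range[2], , drop = FALSE]
  }
  n_res <- nrow(unique(atoms[, c("chain_id", "residue_number")]))
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("empty selection: no C-alpha beads in range")
  skipped <- n_res - nrow(ca)
  if (skipped > 0) {
    warning(skipped, " residue(s) lacking a C-alpha atom were skipped")
  }
  ca <- ca[order(match(ca$chain_id, unique(ca$chain_id)), ca$residue_number), ]
  rownames(ca) <- NULL
  bead_model(ca[, c("chain_id", "residue_number", "x", "y", "z")],
             source_model_id = model$model_id)
}

#' Re-express a bead model as an atom model of C-alpha atoms
#'
#' @param model a [bead_model].
#' @param residue_name residue name stamped on every record.
#' @return An [atom_model].
#' @export
as_atom_model <- function(model, residue_name = "ALA") {
  stopifnot(inherits(model, "bead_model"))
  df <- model$beads
  df$residue_name <- residue_name
  df$atom_name <- "CA"
  atom_model(df, model_id = model$source_model_id)
}

# beads of one chain as an n x 3 coordinate matrix (ordered by residue)
chain_coords <- function(beads, chain) {
  b <- beads$beads[beads$beads$chain_id == chain, , drop = FALSE]
  as.matrix(b[, c("x", "y", "z")])
}
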