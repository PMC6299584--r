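# PDB coordinate I/O and structure/trajectory containers.
#
# Atom records are held as a data.frame (one row per atom); a multi-model
# file is an ordered list of models with identical atom ordering (a
# trajectory). Alternate locations collapse to the highest-occupancy
# conformer (first wins on ties); insertion codes are preserved.

.atom_cols <- c("serial", "atom_name", "alt_loc", "residue_name", "chain_id",
                "residue_seq", "insertion", "x", "y", "z", "occupancy",
                "b_factor", "element")

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with (at least) columns `atom_name`,
#'   `residue_name`, `chain_id`, `residue_seq`, `x`, `y`, `z`; missing
#'   bookkeeping columns are filled with defaults.
#' @param model_index 1-based model number.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_index = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- ""
  if (is.null(atoms$insertion)) atoms$insertion <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0
  if (is.null(atoms$element))
    atoms$element <- substr(trimws(atoms$atom_name), 1, 1)
  atoms <- atoms[, .atom_cols]
  if (n && any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  structure(list(model_index = as.integer(model_index), atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain_id)
  cat(sprintf("Structure model %d: %d atoms in %d chain(s) [%s]\n",
              x$model_index, nrow(x$atoms), length(ch),
              paste(sprintf("%s:%d", names(ch), ch), collapse = ", ")))
  invisible(x)
}

.atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_seq, atoms$insertion, atoms$atom_name,
        sep = "|")
}

#' Bundle structure models into a trajectory
#'
#' @param models List of `structure_model` objects sharing atom ordering.
#' @param frame_interval Time per frame in ps (must be positive).
#' @return Object of class `ab_trajectory`.
#' @export
as_trajectory <- function(models, frame_interval = 10) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (!length(models)) stop("empty trajectory", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  key0 <- .atom_key(models[[1]]$atoms)
  for (i in seq_along(models)) {
    if (!identical(.atom_key(models[[i]]$atoms), key0))
      stop(sprintf("trajectory integrity error: model %d atom ordering differs from model 1", i),
           call. = FALSE)
  }
  structure(list(models = models, frame_interval = frame_interval),
            class = "ab_trajectory")
}

#' @export
print.ab_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.0f ps/frame\n",
              length(x$models), nrow(x$models[[1]]$atoms), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `ab_trajectory`.
#' @export
n_frames <- function(traj) length(traj$models)

.parse_atom_line <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  if (nchar(line) < 54) line <- pad(line, 80)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(trimws(substr(line, from, to))))
    if (is.na(v))
      stop(sprintf("malformed ATOM record at line %d: bad %s field", lineno, what),
           call. = FALSE)
    v
  }
  list(
    serial = as.integer(num(7, 11, "serial")),
    atom_name = trimws(substr(line, 13, 16)),
    alt_loc = trimws(substr(line, 17, 17)),
    residue_name = trimws(substr(line, 18, 20)),
    chain_id = substr(line, 22, 22),
    residue_seq = as.integer(num(23, 26, "residue number")),
    insertion = trimws(substr(line, 27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = if (nchar(trimws(substr(line, 55, 60)))) num(55, 60, "occupancy") else 1,
    b_factor = if (nchar(trimws(substr(line, 61, 66)))) num(61, 66, "b-factor") else 0,
    element = trimws(substr(line, 77, 78))
  )
}

#' Read a (possibly multi-model) PDB file
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL blocks delimit trajectory frames
#' (a file without MODEL records yields a single model). Alternate locations
#' are collapsed to the highest-occupancy conformer (first on ties). Models
#' must share atom count and ordering.
#'
#' @param path Path to a PDB file, or a character vector of lines.
#' @return List of `structure_model` objects.
#' @export
read_pdb <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  idx <- 1L
  in_model <- FALSE
  flush <- function(cur, idx, models) {
    if (!length(cur)) return(models)
    atoms <- do.call(rbind, lapply(cur, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)))
    # alternate locations: keep highest occupancy, first on tie
    key <- paste(atoms$chain_id, atoms$residue_seq, atoms$insertion,
                 atoms$atom_name, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, levels = unique(key))),
                          function(i) i[which.max(atoms$occupancy[i])]))
    atoms <- atoms[sort(keep), , drop = FALSE]
    atoms$alt_loc <- ""
    rownames(atoms) <- NULL
    c(models, list(structure_model(atoms, model_index = idx)))
  }
  for (k in seq_along(lines)) {
    r <- rec[k]
    if (r == "MODEL ") {
      in_model <- TRUE
    } else if (r == "ENDMDL") {
      models <- flush(cur, idx, models)
      cur <- list()
      idx <- idx + 1L
      in_model <- FALSE
    } else if (r %in% c("ATOM  ", "HETATM")) {
      cur <- c(cur, list(.parse_atom_line(lines[k], k)))
    }
  }
  models <- flush(cur, idx, models)
  if (!length(models))
    return(list())
  key0 <- .atom_key(models[[1]]$atoms)
  for (i in seq_along(models)) {
    ki <- .atom_key(models[[i]]$atoms)
    if (length(ki) != length(key0) || !identical(ki, key0))
      stop(sprintf("trajectory integrity error: model %d has inconsistent atoms", i),
           call. = FALSE)
  }
  models
}

.format_atom_line <- function(a) {
  name <- a$atom_name
  name_field <- if (nchar(name) >= 4L) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial, name_field, ifelse(nzchar(a$alt_loc), a$alt_loc, " "),
          a$residue_name, a$chain_id, a$residue_seq,
          ifelse(nzchar(a$insertion), a$insertion, " "),
          a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
}

#' Write structure models as PDB text
#'
#' Multi-model input is wrapped in MODEL/ENDMDL blocks; coordinates are
#' written to 3 decimals. `read_pdb(write_pdb(x))` round-trips all atom
#' record fields (coordinates to 1e-3 Å).
#'
#' @param models A `structure_model`, list thereof, or `ab_trajectory`.
#' @param path Optional output file; if `NULL`, lines are returned.
#' @return Character vector of PDB lines (invisibly if written to file).
#' @export
write_pdb <- function(models, path = NULL) {
  if (inherits(models, "ab_trajectory")) models <- models$models
  if (inherits(models, "structure_model")) models <- list(models)
  multi <- length(models) > 1L
  out <- "REMARK   generated by ablineage"
  for (i in seq_along(models)) {
    atoms <- models[[i]]$atoms
    if (multi) out <- c(out, sprintf("MODEL %8d", i))
    if (nrow(atoms))
      out <- c(out, vapply(seq_len(nrow(atoms)),
                           function(r) .format_atom_line(atoms[r, ]), character(1)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Coordinate matrix of selected atoms
#'
#' @param model A `structure_model`.
#' @param selection Atom selection (see [atom_selection()]); `NULL` selects
#'   all atoms.
#' @return N x 3 numeric matrix of coordinates (Å).
#' @export
coords <- function(model, selection = NULL) {
  atoms <- model$atoms
  idx <- if (is.null(selection)) seq_len(nrow(atoms)) else
    resolve_selection(model, selection)
  as.matrix(atoms[idx, c("x", "y", "z")])
}

#' Describe an atom selection
#'
#' @param chains Optional chain ids to keep.
#' @param atom_names Optional atom names (e.g. `"CA"`, or
#'   `c("N","CA","C","O")` for backbone).
#' @param residues Optional residue numbers to keep.
#' @param exclude_residues Optional residue numbers to drop (the flexible
#'   far-from-pocket residues excluded from RMSD calculations).
#' @return Object of class `atom_selection`.
#' @export
atom_selection <- function(chains = NULL, atom_names = "CA", residues = NULL,
                           exclude_residues = NULL) {
  structure(list(chains = chains, atom_names = atom_names,
                 residues = residues, exclude_residues = exclude_residues),
            class = "atom_selection")
}

#' Resolve an atom selection to row indices in a model
#' @param model A `structure_model`.
#' @param selection An `atom_selection`.
#' @return Integer vector of atom row indices.
#' @export
resolve_selection <- function(model, selection) {
  atoms <- model$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selection$chains)) keep <- keep & atoms$chain_id %in% selection$chains
  if (!is.null(selection$atom_names)) keep <- keep & atoms$atom_name %in% selection$atom_names
  if (!is.null(selection$residues)) keep <- keep & atoms$residue_seq %in% selection$residues
  if (!is.null(selection$exclude_residues))
    keep <- keep & !(atoms$residue_seq %in% selection$exclude_residues)
  idx <- which(keep)
  if (!length(idx)) stop("atom selection matches no atoms", call. = FALSE)
  idx
}
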