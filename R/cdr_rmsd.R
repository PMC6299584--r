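# Fv extraction, antigen stripping, and CDR-level RMSD statistics.

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
ONE_TO_THREE <- stats::setNames(names(THREE_TO_ONE), THREE_TO_ONE)

# residue table of one chain, in order of appearance
.chain_residues <- function(model, chain_id) {
  atoms <- model$atoms[model$atoms$chain_id == chain_id, , drop = FALSE]
  key <- paste(atoms$residue_seq, atoms$insertion, sep = "|")
  first <- !duplicated(key)
  data.frame(residue_seq = atoms$residue_seq[first],
             insertion = atoms$insertion[first],
             residue_name = atoms$residue_name[first],
             stringsAsFactors = FALSE)
}

.chain_seq_one <- function(model, chain_id) {
  res <- .chain_residues(model, chain_id)
  aa <- THREE_TO_ONE[res$residue_name]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Map a numbered chain onto a structure chain: returns for each numbered
# residue the structure residue_seq (author numbering). The numbered sequence
# must occur as a substring of the chain's residue sequence.
.map_numbering <- function(model, chain_id, numbered) {
  seq_struct <- .chain_seq_one(model, chain_id)
  seq_num <- chain_sequence(numbered)
  at <- regexpr(seq_num, seq_struct, fixed = TRUE)[1]
  if (at < 0) {
    # tolerate point substitutions (e.g. mutated or rewritten residues) when
    # the chain has exactly the numbered length: map 1:1 by residue order
    if (nchar(seq_struct) == nchar(seq_num)) at <- 1L
    else stop(sprintf("numbered sequence not found in structure chain %s", chain_id),
              call. = FALSE)
  }
  res <- .chain_residues(model, chain_id)
  idx <- at:(at + nchar(seq_num) - 1L)
  data.frame(label = numbered$residues$label,
             region = numbered$residues$region,
             cdr = .cdr_label(numbered, seq_len(nrow(numbered$residues))),
             residue_seq = res$residue_seq[idx],
             insertion = res$insertion[idx],
             stringsAsFactors = FALSE)
}

#' Truncate antibody chains to the variable (Fv) domain
#'
#' Antibody chains are cut down to the residues covered by their Kabat
#' numbering (FW1 through FW4); antigen chains are left untouched. Applying
#' the function to an already-Fv model is the identity.
#'
#' @param model A `structure_model`.
#' @param chain_roles Named character vector mapping chain id to role
#'   (`"heavy"`, `"light"`, `"antigen"`).
#' @param numbering Named list of `numbered_chain` objects keyed by antibody
#'   chain id.
#' @return A `structure_model` containing only Fv antibody atoms plus all
#'   antigen atoms.
#' @export
extract_fv <- function(model, chain_roles, numbering) {
  ab_chains <- names(chain_roles)[chain_roles %in% c("heavy", "light")]
  if (!length(ab_chains)) stop("no heavy/light chain roles assigned", call. = FALSE)
  keep <- rep(TRUE, nrow(model$atoms))
  for (ch in ab_chains) {
    map <- .map_numbering(model, ch, numbering[[ch]])
    in_chain <- model$atoms$chain_id == ch
    rkey <- paste(model$atoms$residue_seq, model$atoms$insertion, sep = "|")
    fv_keys <- paste(map$residue_seq, map$insertion, sep = "|")
    keep[in_chain & !(rkey %in% fv_keys)] <- FALSE
  }
  structure_model(model$atoms[keep, , drop = FALSE], model$model_index)
}

#' Remove antigen chains from a complex
#'
#' Generates the free-form antibody from a bound complex; antibody atoms are
#' untouched. Idempotent.
#'
#' @inheritParams extract_fv
#' @return A `structure_model` without antigen-role chains.
#' @export
strip_antigen <- function(model, chain_roles) {
  ag <- names(chain_roles)[chain_roles == "antigen"]
  keep <- !(model$atoms$chain_id %in% ag)
  structure_model(model$atoms[keep, , drop = FALSE], model$model_index)
}

.selection_atom_names <- function(atom_selection = c("CA", "backbone", "all-heavy")) {
  atom_selection <- match.arg(atom_selection)
  switch(atom_selection,
         "CA" = "CA",
         "backbone" = c("N", "CA", "C", "O"),
         "all-heavy" = NULL)
}

#' Per-CDR RMSD between two Kabat-numbered antibodies
#'
#' The two structures are first superposed on their shared framework Cα atoms
#' (match), then the RMSD of each CDR is measured in that common frame
#' without per-loop re-fitting (a per-loop re-fit mode is available). CDR-H3
#' is skipped when its length differs between the two antibodies, since
#' junctional diversity changes both its sequence and length within a
#' lineage.
#'
#' @param ref_model,target_model `structure_model` objects.
#' @param ref_numbering,target_numbering Named lists of `numbered_chain`
#'   objects keyed by chain id (heavy and/or light chains).
#' @param atom_selection `"CA"` (default), `"backbone"` or `"all-heavy"`.
#' @param refit_per_loop If `TRUE`, each CDR is independently superposed
#'   before its RMSD is taken.
#' @param antibody_id,reference_id Identifiers carried into the records.
#' @return data.frame of class `cdr_rmsd`: columns `antibody_id`, `region`
#'   (H1..L3), `rmsd` (Å), `reference_id`.
#' @export
per_cdr_rmsd <- function(ref_model, ref_numbering, target_model, target_numbering,
                         atom_selection = "CA", refit_per_loop = FALSE,
                         antibody_id = "target", reference_id = "reference") {
  atom_names <- .selection_atom_names(atom_selection)
  chains <- intersect(names(ref_numbering), names(target_numbering))
  if (!length(chains)) stop("no shared antibody chains", call. = FALSE)

  maps_r <- lapply(chains, function(ch) .map_numbering(ref_model, ch, ref_numbering[[ch]]))
  maps_t <- lapply(chains, function(ch) .map_numbering(target_model, ch, target_numbering[[ch]]))
  names(maps_r) <- names(maps_t) <- chains

  fw_r <- NULL; fw_t <- NULL
  cdr_pairs <- list()
  for (ch in chains) {
    mr <- maps_r[[ch]]; mt <- maps_t[[ch]]
    shared <- intersect(mr$label[mr$cdr == "FW"], mt$label[mt$cdr == "FW"])
    ir <- mr[match(shared, mr$label), ]
    it <- mt[match(shared, mt$label), ]
    fw_r <- rbind(fw_r, .res_xyz(ref_model, ch, ir, atom_names))
    fw_t <- rbind(fw_t, .res_xyz(target_model, ch, it, atom_names))
    for (cdr in unique(mr$cdr[mr$cdr != "FW"])) {
      lr <- mr$label[mr$cdr == cdr]
      lt <- mt$label[mt$cdr == cdr]
      if (cdr == "H3" && length(lr) != length(lt)) next
      shared_c <- intersect(lr, lt)
      if (!length(shared_c)) next
      cdr_pairs[[cdr]] <- list(
        ref = .res_xyz(ref_model, ch, mr[match(shared_c, mr$label), ], atom_names),
        tgt = .res_xyz(target_model, ch, mt[match(shared_c, mt$label), ], atom_names))
    }
  }
  if (is.null(fw_r) || nrow(fw_r) < 3L)
    stop("no shared framework positions for superposition", call. = FALSE)

  sp <- kabsch_superpose(fw_r, fw_t)
  records <- lapply(names(cdr_pairs), function(cdr) {
    pr <- cdr_pairs[[cdr]]
    if (nrow(pr$ref) != nrow(pr$tgt) || !nrow(pr$ref)) return(NULL)
    r <- if (refit_per_loop) coord_rmsd(pr$ref, pr$tgt, superpose = TRUE)
         else .rmsd_raw(pr$ref, apply_superposition(sp, pr$tgt))
    data.frame(antibody_id = antibody_id, region = cdr, rmsd = r,
               reference_id = reference_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(antibody_id = character(0), region = character(0),
                      rmsd = numeric(0), reference_id = character(0))
  class(out) <- c("cdr_rmsd", class(out))
  out
}

# coordinates for mapped residues (map rows carry residue_seq + insertion)
.res_xyz <- function(model, chain_id, map_rows, atom_names) {
  atoms <- model$atoms[model$atoms$chain_id == chain_id, , drop = FALSE]
  if (!is.null(atom_names))
    atoms <- atoms[atoms$atom_name %in% atom_names, , drop = FALSE]
  rkey <- paste(atoms$residue_seq, atoms$insertion, sep = "|")
  want <- unlist(lapply(paste(map_rows$residue_seq, map_rows$insertion, sep = "|"),
                        function(k) which(rkey == k)))
  as.matrix(atoms[want, c("x", "y", "z")])
}

#' Fraction of CDR RMSD records exceeding a threshold
#'
#' Summarises structural divergence among lineage siblings as the percentage
#' of records per CDR with RMSD above a threshold (1 Å by default).
#'
#' @param records data.frame of CDR RMSD records ([per_cdr_rmsd()] output,
#'   possibly row-bound across many antibodies).
#' @param threshold Positive RMSD threshold in Å.
#' @return Named numeric vector: percent of records above the threshold per
#'   region (regions with no records are omitted).
#' @export
rmsd_exceed_fraction <- function(records, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (!nrow(records)) return(stats::setNames(numeric(0), character(0)))
  sp <- split(records$rmsd, records$region)
  vapply(sp, function(v) 100 * sum(v > threshold) / length(v), numeric(1))
}

#' Pairwise superposed RMSD matrix over named conformers
#'
#' Each entry comes from an independent pairwise superposition on the shared
#' atom selection; the matrix is symmetric with a zero diagonal and is the
#' input for conformer heatmaps.
#'
#' @param conformers Named list of `structure_model` objects sharing the atom
#'   selection.
#' @param selection An [atom_selection()] (default: all Cα atoms).
#' @return Symmetric numeric matrix (Å) with conformer names as dimnames.
#' @export
pairwise_rmsd_matrix <- function(conformers, selection = atom_selection()) {
  n <- length(conformers)
  if (is.null(names(conformers))) names(conformers) <- paste0("conf", seq_len(n))
  xyz <- lapply(conformers, coords, selection = selection)
  sizes <- vapply(xyz, nrow, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("atom selection resolves to different sizes across conformers", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(names(conformers), names(conformers)))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- .rmsd_superposed(xyz[[i]], xyz[[j]])
    m[i, j] <- r; m[j, i] <- r
  }
  m
}

#' Write a labelled matrix to CSV
#' @param m Matrix with dimnames.
#' @param path Output CSV (labels in header row and first column).
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
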