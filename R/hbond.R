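# Hydrogen-bond detection at the antibody-antigen interface.
#
# Geometric criterion: heavy-atom donor-acceptor distance <= cutoff (3.5 Å
# by default), no angle term. Donor/acceptor chemistry comes from a built-in
# per-residue table for the 20 amino acids, nucleic-acid residues and water;
# backbone N (donor) and O (acceptor) are included by default because
# backbone-mediated interface bonds (e.g. through Gly) occur in real
# complexes, and can be switched off.

.hbond_chemistry <- function() {
  aa_don <- list(
    SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
    ASN = "ND2", GLN = "NE2", LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1"
  )
  aa_acc <- list(
    SER = "OG", THR = "OG1", TYR = "OH",
    ASN = "OD1", GLN = "OE1",
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    HIS = c("ND1", "NE2"), MET = "SD"
  )
  na_common_acc <- c("OP1", "OP2", "O1P", "O2P", "O3'", "O5'", "O4'", "O2'")
  na_don <- list(
    DA = "N6", DC = "N4", DG = c("N1", "N2"), DT = "N3",
    A = c("N6", "O2'"), C = c("N4", "O2'"), G = c("N1", "N2", "O2'"),
    U = c("N3", "O2'")
  )
  na_acc <- list(
    DA = c("N1", "N3", "N7", na_common_acc),
    DC = c("O2", "N3", na_common_acc),
    DG = c("O6", "N3", "N7", na_common_acc),
    DT = c("O2", "O4", na_common_acc),
    A = c("N1", "N3", "N7", na_common_acc),
    C = c("O2", "N3", na_common_acc),
    G = c("O6", "N3", "N7", na_common_acc),
    U = c("O2", "O4", na_common_acc)
  )
  wat <- list(HOH = "O", WAT = "O")
  list(donors = c(aa_don, na_don, wat), acceptors = c(aa_acc, na_acc, wat))
}

.aa3 <- names(THREE_TO_ONE)
.nuc3 <- c("DA", "DC", "DG", "DT", "A", "C", "G", "U")
.wat3 <- c("HOH", "WAT")

# flag donor/acceptor atoms in an atom table
.flag_da <- function(atoms, include_backbone = TRUE) {
  chem <- .hbond_chemistry()
  known <- c(.aa3, .nuc3, .wat3)
  unknown <- setdiff(unique(atoms$residue_name), known)
  if (length(unknown))
    warning(sprintf("unknown residue type(s) skipped in H-bond chemistry: %s",
                    paste(unknown, collapse = ", ")))
  is_don <- mapply(function(rn, an) an %in% (chem$donors[[rn]] %||% character(0)),
                   atoms$residue_name, atoms$atom_name, USE.NAMES = FALSE)
  is_acc <- mapply(function(rn, an) an %in% (chem$acceptors[[rn]] %||% character(0)),
                   atoms$residue_name, atoms$atom_name, USE.NAMES = FALSE)
  if (include_backbone) {
    bb_ok <- atoms$residue_name %in% .aa3
    is_don <- is_don | (bb_ok & atoms$atom_name == "N" & atoms$residue_name != "PRO")
    is_acc <- is_acc | (bb_ok & atoms$atom_name == "O")
  }
  list(donor = is_don, acceptor = is_acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.atom_label <- function(atoms, idx) {
  paste0(atoms$chain_id[idx], ":", atoms$residue_name[idx],
         atoms$residue_seq[idx], atoms$insertion[idx], ":", atoms$atom_name[idx])
}

#' Detect antibody-antigen hydrogen bonds in one structure
#'
#' All cross-molecule donor-acceptor heavy-atom pairs within the distance
#' cutoff are reported. When Kabat numbering is supplied, the antibody-side
#' residue of each bond is annotated with its CDR (H1..L3) or FW region.
#'
#' @param model A `structure_model` of the complex.
#' @param chain_roles Named character vector chain id -> role (`"heavy"`,
#'   `"light"`, `"antigen"`).
#' @param cutoff Donor-acceptor distance cutoff in Å (default 3.5).
#' @param numbering Optional named list of `numbered_chain` objects keyed by
#'   antibody chain id, used for CDR annotation.
#' @param include_backbone Include backbone N (donor) / O (acceptor).
#' @return data.frame of class `hbond_list`: columns `donor`, `acceptor`
#'   (atom labels `chain:RESn:atom`), `distance`, `donor_side`, `cdr_region`.
#' @export
detect_hbonds <- function(model, chain_roles, cutoff = 3.5, numbering = NULL,
                          include_backbone = TRUE) {
  atoms <- model$atoms
  ab_chains <- names(chain_roles)[chain_roles %in% c("heavy", "light")]
  ag_chains <- names(chain_roles)[chain_roles == "antigen"]
  side <- ifelse(atoms$chain_id %in% ab_chains, "antibody",
                 ifelse(atoms$chain_id %in% ag_chains, "antigen", NA))
  da <- .flag_da(atoms, include_backbone)

  maps <- list()
  if (!is.null(numbering)) {
    for (ch in intersect(ab_chains, names(numbering)))
      maps[[ch]] <- tryCatch(.map_numbering(model, ch, numbering[[ch]]),
                             error = function(e) NULL)
  }
  region_of <- function(idx) {
    map <- maps[[atoms$chain_id[idx]]]
    if (is.null(map)) return(NA_character_)
    hit <- which(map$residue_seq == atoms$residue_seq[idx] &
                   map$insertion == atoms$insertion[idx])
    if (!length(hit)) return("FW")
    map$cdr[hit[1]]
  }

  pairs <- list()
  cross <- function(di, ai, donor_side) {
    if (!length(di) || !length(ai)) return(NULL)
    D <- as.matrix(atoms[di, c("x", "y", "z")])
    A <- as.matrix(atoms[ai, c("x", "y", "z")])
    d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
      outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(
      donor = .atom_label(atoms, di[hit[, 1]]),
      acceptor = .atom_label(atoms, ai[hit[, 2]]),
      distance = sqrt(pmax(d2[hit], 0)),
      donor_side = donor_side,
      ab_atom = if (donor_side == "antibody") di[hit[, 1]] else ai[hit[, 2]],
      stringsAsFactors = FALSE
    )
  }
  ab_d <- which(side == "antibody" & da$donor)
  ab_a <- which(side == "antibody" & da$acceptor)
  ag_d <- which(side == "antigen" & da$donor)
  ag_a <- which(side == "antigen" & da$acceptor)
  out <- rbind(cross(ab_d, ag_a, "antibody"), cross(ag_d, ab_a, "antigen"))
  if (is.null(out))
    out <- data.frame(donor = character(0), acceptor = character(0),
                      distance = numeric(0), donor_side = character(0),
                      ab_atom = integer(0), stringsAsFactors = FALSE)
  out$cdr_region <- if (nrow(out))
    vapply(out$ab_atom, region_of, character(1)) else character(0)
  out$ab_atom <- NULL
  rownames(out) <- NULL
  class(out) <- c("hbond_list", class(out))
  out
}

#' Hydrogen-bond occupancy across trajectory frames
#'
#' For every unique donor/acceptor pair observed in any frame, the occupancy
#' is the fraction of frames in which the bond is present. Bonds below
#' `min_occupancy` are excluded from the primary (`records`) table; the full
#' table is always returned.
#'
#' @param traj An `ab_trajectory` of the complex.
#' @param chain_roles As in [detect_hbonds()].
#' @param cutoff Distance cutoff in Å.
#' @param min_occupancy Occupancy threshold for the primary report
#'   (default 0.30).
#' @param stride Use every `stride`-th frame.
#' @param ... Passed to [detect_hbonds()].
#' @return List of class `hbond_occupancy` with elements `records` (filtered)
#'   and `full`; both data.frames with columns `donor`, `acceptor`,
#'   `occupancy`, `n_frames_present`, `n_frames_total`.
#' @export
hbond_occupancy <- function(traj, chain_roles, cutoff = 3.5,
                            min_occupancy = 0.30, stride = 1L, ...) {
  stopifnot(inherits(traj, "ab_trajectory"))
  frames <- traj$models[seq(1L, n_frames(traj), by = stride)]
  if (!length(frames)) stop("empty trajectory", call. = FALSE)
  counts <- new.env(parent = emptyenv())
  for (m in frames) {
    hb <- detect_hbonds(m, chain_roles, cutoff = cutoff, ...)
    keys <- unique(paste(hb$donor, hb$acceptor, sep = " -> "))
    for (k in keys) assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  keys <- sort(ls(counts))
  n_tot <- length(frames)
  full <- data.frame(
    donor = sub(" -> .*$", "", keys),
    acceptor = sub("^.* -> ", "", keys),
    occupancy = vapply(keys, function(k) counts[[k]] / n_tot, numeric(1)),
    n_frames_present = vapply(keys, function(k) counts[[k]], numeric(1)),
    n_frames_total = rep(n_tot, length(keys)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  full <- full[order(-full$occupancy, full$donor), , drop = FALSE]
  rownames(full) <- NULL
  out <- list(records = full[full$occupancy >= min_occupancy, , drop = FALSE],
              full = full, min_occupancy = min_occupancy)
  class(out) <- "hbond_occupancy"
  out
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("H-bond occupancy: %d bond(s) at >= %.0f%% of %d frames (%d total)\n",
              nrow(x$records), 100 * x$min_occupancy,
              if (nrow(x$full)) x$full$n_frames_total[1] else 0, nrow(x$full)))
  if (nrow(x$records)) print.data.frame(x$records, digits = 3)
  invisible(x)
}

#' Per-CDR contact profile from an interface bond list
#'
#' @param bonds `hbond_list` from [detect_hbonds()] (CDR-annotated).
#' @param antibody_id Identifier carried into the profile.
#' @return Object of class `contact_profile`: named integer vector over
#'   H1, H2, H3, L1, L2, L3, FW whose sum equals `nrow(bonds)`.
#' @export
cdr_contact_profile <- function(bonds, antibody_id = "antibody") {
  regions <- c("H1", "H2", "H3", "L1", "L2", "L3", "FW")
  counts <- stats::setNames(integer(length(regions)), regions)
  if (nrow(bonds)) {
    r <- bonds$cdr_region
    r[is.na(r) | !(r %in% regions)] <- "FW"
    tab <- table(factor(r, levels = regions))
    counts[] <- as.integer(tab)
  }
  structure(counts, antibody_id = antibody_id, class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("Contact profile for %s (%d H-bonds):\n",
              attr(x, "antibody_id"), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Chain-engagement statistics over contact profiles
#'
#' Summarises, across complexes, how often the heavy chain dominates the
#' interface: the percentage of entries with more H- than L-chain bonds, with
#' no L-chain bonds at all, and with no CDR-H3 bonds.
#'
#' @param profiles List of `contact_profile` objects.
#' @return List with `n`, `pct_h_gt_l`, `pct_l_absent`, `pct_h3_absent`.
#' @export
chain_engagement_stats <- function(profiles) {
  if (!length(profiles)) stop("no contact profiles supplied", call. = FALSE)
  hsum <- vapply(profiles, function(p) sum(p[c("H1", "H2", "H3")]), numeric(1))
  lsum <- vapply(profiles, function(p) sum(p[c("L1", "L2", "L3")]), numeric(1))
  h3 <- vapply(profiles, function(p) p[["H3"]], numeric(1))
  n <- length(profiles)
  list(n = n,
       pct_h_gt_l = 100 * sum(hsum > lsum) / n,
       pct_l_absent = 100 * sum(lsum == 0) / n,
       pct_h3_absent = 100 * sum(h3 == 0) / n)
}
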