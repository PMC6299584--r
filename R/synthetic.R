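# Synthetic-data generators with serialized ground truth.
#
# These generators replace MD trajectories and PDB downloads in all testing:
# germline repertoires, mutated lineages with CDR-biased substitutions, toy
# Fv scaffolds (geometric plausibility only, no physics), bound/free
# conformer ensembles, and interface trajectories with scheduled hydrogen-
# bond occupancies. All are pure functions of their arguments and seed.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.mutate_seq <- function(chars, positions, rng_draw = TRUE) {
  for (p in positions) {
    alt <- setdiff(AA_ALPHABET20, chars[p])
    chars[p] <- sample(alt, 1L)
  }
  chars
}

#' Generate a synthetic germline V-gene repertoire
#'
#' Genes are derived from the built-in chain-type template by random
#' substitutions, so every gene remains Kabat-numberable, and are mutually
#' divergent: all pairwise identities are at most
#' `100 * (1 - min_pairwise_divergence)` (checked with [percent_identity()],
#' with bounded retries at increasing mutation load).
#'
#' @param n_genes Number of genes (>= 1).
#' @param chain_type `"H"` or `"L"`.
#' @param min_pairwise_divergence Required pairwise divergence fraction.
#' @param seed Integer seed; same seed gives identical output.
#' @param length Optional truncation length (genes are template prefixes of
#'   this length before mutation), emulating germline V regions that end
#'   before the mature CDR3/FW4.
#' @return List of `germline_gene` objects named `gene*allele`.
#' @export
make_germline_repertoire <- function(n_genes, chain_type = "H",
                                     min_pairwise_divergence = 0.4,
                                     seed = 1, length = NULL) {
  stopifnot(n_genes >= 1)
  base <- kabat_template(chain_type)
  if (!is.null(length)) {
    if (length < 30 || length > nchar(base))
      stop("infeasible template length", call. = FALSE)
    base <- substr(base, 1, length)
  }
  L <- nchar(base)
  base_chars <- strsplit(base, "")[[1]]
  .with_seed(seed, {
    f <- max(0.05, 1 - sqrt(1 - min_pairwise_divergence))
    for (try in 1:20) {
      genes <- lapply(seq_len(n_genes), function(i) {
        k <- max(1L, round(f * L))
        chars <- .mutate_seq(base_chars, sample.int(L, k))
        germline_gene(sprintf("%d-%02d", 1 + (i - 1) %/% 26, i), "01",
                      paste(chars, collapse = ""))
      })
      ok <- TRUE
      if (n_genes > 1) {
        seqs <- vapply(genes, `[[`, character(1), "v_region_sequence")
        for (i in seq_len(n_genes - 1)) for (j in (i + 1):n_genes) {
          pid <- percent_identity(global_align(seqs[i], seqs[j]))
          if (pid > 100 * (1 - min_pairwise_divergence)) ok <- FALSE
        }
      }
      if (ok) {
        names(genes) <- vapply(genes, germline_id, character(1))
        return(genes)
      }
      f <- min(0.95, f * 1.3)
    }
    stop("could not achieve requested pairwise divergence", call. = FALSE)
  })
}

#' Generate a mature antibody lineage with planted mutations
#'
#' Every member carries exactly `mutations_per_member` substitutions at
#' distinct positions of the germline; the number falling inside CDR spans is
#' binomial with success probability `cdr_bias` (so the expected CDR share of
#' mutations equals `cdr_bias`, emulating the CDR-focused mutational load of
#' affinity maturation). The full substitution list is returned as ground
#' truth.
#'
#' @param germline A `germline_gene` (or amino-acid string).
#' @param n_members Number of lineage members.
#' @param mutations_per_member Substitutions per member.
#' @param cdr_bias Probability that a substitution is placed in a CDR.
#' @param seed Integer seed.
#' @param chain_type Chain type for Kabat numbering of the germline.
#' @return List with `sequences` (named character vector), `ground_truth`
#'   (data.frame: `member`, `position`, `kabat_position`, `region`,
#'   `germline_aa`, `mature_aa`), `germline`, `numbering` (the germline's
#'   `numbered_chain`).
#' @export
make_lineage <- function(germline, n_members = 3, mutations_per_member = 5,
                         cdr_bias = 0.6, seed = 1, chain_type = "H") {
  gseq <- if (inherits(germline, "germline_gene")) germline$v_region_sequence
          else germline
  stopifnot(cdr_bias >= 0, cdr_bias <= 1)
  nc <- kabat_number(gseq, chain_type)
  L <- nchar(gseq)
  if (mutations_per_member > L)
    stop("mutations_per_member exceeds sequence length", call. = FALSE)
  in_cdr <- grepl("^CDR", nc$residues$region)
  cdr_pos <- which(in_cdr)
  fw_pos <- which(!in_cdr)
  gchars <- strsplit(gseq, "")[[1]]
  .with_seed(seed, {
    gt <- list(); seqs <- character(n_members)
    for (m in seq_len(n_members)) {
      n_cdr <- stats::rbinom(1L, mutations_per_member, cdr_bias)
      n_cdr <- min(n_cdr, length(cdr_pos))
      n_fw <- min(mutations_per_member - n_cdr, length(fw_pos))
      pos <- c(sample(cdr_pos, n_cdr), sample(fw_pos, n_fw))
      pos <- sort(pos)
      chars <- .mutate_seq(gchars, pos)
      seqs[m] <- paste(chars, collapse = "")
      gt[[m]] <- data.frame(
        member = rep(sprintf("mab%02d", m), length(pos)),
        position = pos,
        kabat_position = nc$residues$label[pos],
        region = .cdr_label(nc, pos),
        germline_aa = gchars[pos],
        mature_aa = chars[pos],
        stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("mab%02d", seq_len(n_members))
    list(sequences = seqs, ground_truth = do.call(rbind, gt),
         germline = germline, numbering = nc)
  })
}

# persistent self-avoiding random walk, 3.8 Å step
.walk_chain <- function(n, seed_dir = c(1, 0, 0), min_sep = 2.5, max_try = 50) {
  for (attempt in seq_len(max_try)) {
    pts <- matrix(0, n, 3)
    d <- seed_dir / sqrt(sum(seed_dir^2))
    ok <- TRUE
    for (i in 2:n) {
      d <- d + 0.25 * stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      pts[i, ] <- pts[i - 1, ] + 3.8 * d
      if (i > 2) {
        prev <- pts[1:(i - 2), , drop = FALSE]
        dd <- sqrt(rowSums(sweep(prev, 2, pts[i, ])^2))
        if (min(dd) < min_sep) { ok <- FALSE; break }
      }
    }
    if (ok) return(pts)
  }
  stop("scaffold packing failure: could not build self-avoiding chain",
       call. = FALSE)
}

.chain_atoms <- function(xyz, chain_id, aa_chars) {
  n <- nrow(xyz)
  data.frame(
    atom_name = "CA",
    residue_name = unname(ONE_TO_THREE[aa_chars] %||na% "GLY"),
    chain_id = chain_id,
    residue_seq = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = "C",
    stringsAsFactors = FALSE)
}

`%||na%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Build a toy Fv scaffold for two numbered chains
#'
#' Cα-only coordinates on a smooth self-avoiding chain per antibody chain
#' (consecutive Cα spacing 3.8 Å); the light chain is translated so that no
#' inter-chain atom pair comes below 2.5 Å. Geometric plausibility only —
#' this is not a folded immunoglobulin domain.
#'
#' @param heavy,light `numbered_chain` objects (chain ids `H` and `L`).
#' @param seed Integer seed; identical seeds give bit-identical coordinates.
#' @return A `structure_model` with chains `H` and `L`.
#' @export
make_fv_scaffold <- function(heavy, light, seed = 1) {
  .with_seed(seed, {
    xh <- .walk_chain(nrow(heavy$residues), c(1, 0, 0))
    xl <- .walk_chain(nrow(light$residues), c(-1, 0, 0))
    # pack without steric overlap: shift light past the heavy bounding box
    shift <- max(xh[, 1]) - min(xl[, 1]) + 10
    xl[, 1] <- xl[, 1] + shift
    atoms <- rbind(.chain_atoms(xh, "H", heavy$residues$aa),
                   .chain_atoms(xl, "L", light$residues$aa))
    structure_model(atoms)
  })
}

#' Add a toy antigen chain to an antibody scaffold
#'
#' @param scaffold Antibody `structure_model` (from [make_fv_scaffold()]).
#' @param antigen_length Number of antigen residues.
#' @param chain_id Antigen chain id.
#' @param offset Distance (Å) of the antigen chain start from the antibody's
#'   maximal-z face.
#' @param seed Integer seed.
#' @return A `structure_model` of the complex.
#' @export
make_complex_scaffold <- function(scaffold, antigen_length = 30, chain_id = "G",
                                  offset = 10, seed = 1) {
  .with_seed(seed, {
    xg <- .walk_chain(antigen_length, c(0, 1, 0))
    xg[, 3] <- xg[, 3] + max(scaffold$atoms$z) + offset
    aa <- sample(AA_ALPHABET20, antigen_length, replace = TRUE)
    structure_model(rbind(scaffold$atoms[, setdiff(.atom_cols, c("serial", "alt_loc", "insertion", "occupancy", "b_factor"))],
                          .chain_atoms(xg, chain_id, aa)))
  })
}

# largest-remainder apportionment of n frames over population fractions
.apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate bound/free conformer ensembles with known cluster structure
#'
#' K reference conformers are built by rigidly displacing a subset of
#' scaffold atoms (the CDR loops) along well-separated directions; the
#' displacement magnitude is auto-scaled so that the minimal pairwise
#' superposed RMSD between conformers over `measure_selection` matches
#' `separation`. Each frame draws a conformer per the source's population
#' fractions (exact largest-remainder counts, seeded shuffle) and adds
#' isotropic Gaussian noise to every atom.
#'
#' @param scaffold A `structure_model` (antibody, typically Fv).
#' @param displace_idx Atom row indices displaced between conformers
#'   (e.g. CDR Cα atoms).
#' @param populations List with numeric vectors `bound` and `free`, each of
#'   length K summing to 1 (zeros allowed; a conformer with free population 0
#'   but bound population > 0 creates an induced-fit scenario).
#' @param separation Target minimal pairwise superposed RMSD (Å) between
#'   conformers over `measure_selection`.
#' @param noise_sigma Per-coordinate Gaussian noise (Å).
#' @param n_frames Frames per source.
#' @param frame_interval Time per frame (ps).
#' @param measure_selection [atom_selection()] over which separation is
#'   measured (default all Cα).
#' @param seed Integer seed.
#' @return List with `bound`, `free` (`ab_trajectory` objects) and
#'   `ground_truth`: per-frame conformer labels per source, realized
#'   pairwise conformer RMSD matrix, populations, `separation_ok` flag
#'   (false when the conformers are too close relative to the noise for
#'   recovery to be guaranteed), and the seed.
#' @export
make_conformer_ensemble <- function(scaffold, displace_idx,
                                    populations = list(bound = c(1, 0),
                                                       free = c(0.5, 0.5)),
                                    separation = 6, noise_sigma = 0.3,
                                    n_frames = 500, frame_interval = 1000,
                                    measure_selection = atom_selection(),
                                    seed = 1) {
  K <- length(populations$bound)
  stopifnot(length(populations$free) == K, K >= 1)
  stopifnot(abs(sum(populations$bound) - 1) < 1e-9,
            abs(sum(populations$free) - 1) < 1e-9)
  base_xyz <- as.matrix(scaffold$atoms[, c("x", "y", "z")])
  midx <- resolve_selection(scaffold, measure_selection)

  # well-separated unit directions: +/- coordinate axes, then random
  dirs <- rbind(diag(3), -diag(3))
  if (K > 1 && K - 1 > nrow(dirs)) {
    extra <- matrix(stats::rnorm(3 * (K - 1 - nrow(dirs))), ncol = 3)
    dirs <- rbind(dirs, extra / sqrt(rowSums(extra^2)))
  }
  conformer_xyz <- function(mag) {
    lapply(seq_len(K), function(k) {
      xyz <- base_xyz
      if (k > 1) xyz[displace_idx, ] <-
          sweep(xyz[displace_idx, , drop = FALSE], 2, mag * dirs[k - 1, ], `+`)
      xyz
    })
  }
  realized <- function(confs) {
    m <- matrix(0, K, K)
    if (K > 1) for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      r <- .rmsd_superposed(confs[[i]][midx, ], confs[[j]][midx, ])
      m[i, j] <- r; m[j, i] <- r
    }
    m
  }
  .with_seed(seed, {
    mag <- separation
    confs <- conformer_xyz(mag)
    if (K > 1) {
      for (it in 1:8) {
        sep_now <- min(realized(confs)[upper.tri(matrix(0, K, K))])
        if (abs(sep_now - separation) < 0.02 * separation) break
        mag <- mag * separation / sep_now
        confs <- conformer_xyz(mag)
      }
    }
    sep_mat <- realized(confs)
    min_sep <- if (K > 1) min(sep_mat[upper.tri(sep_mat)]) else Inf

    make_source <- function(fr) {
      counts <- .apportion(fr, n_frames)
      labels <- sample(rep.int(seq_len(K), counts))
      models <- lapply(seq_len(n_frames), function(f) {
        xyz <- confs[[labels[f]]] +
          matrix(stats::rnorm(length(base_xyz), sd = noise_sigma),
                 ncol = 3)
        atoms <- scaffold$atoms
        atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
        structure_model(atoms, model_index = f)
      })
      list(traj = as_trajectory(models, frame_interval), labels = labels)
    }
    b <- make_source(populations$bound)
    f <- make_source(populations$free)
    list(bound = b$traj, free = f$traj,
         ground_truth = list(
           labels = list(bound = b$labels, free = f$labels),
           conformer_rmsd = sep_mat,
           populations = populations,
           noise_sigma = noise_sigma,
           separation_ok = min_sep > 6 * noise_sigma,
           seed = seed))
  })
}

#' Generate an interface trajectory with scheduled H-bond occupancies
#'
#' For each scheduled bond the donor residue is rewritten as serine (side
#' chain OG donor) and the acceptor residue as aspartate (OD1 acceptor);
#' in exactly `round(occupancy * n_frames)` seeded frames the acceptor atom
#' is placed 2.9 Å from the donor, otherwise 5.0 Å. Each donor/acceptor atom
#' pair occupies a spatially isolated slot (20 Å or more from the scaffold
#' and from other slots) so that scheduled bonds never interfere; all other
#' atoms are static.
#'
#' @param complex A `structure_model` of the antibody-antigen complex
#'   ([make_complex_scaffold()]).
#' @param schedule data.frame with columns `donor_chain`, `donor_res`,
#'   `acceptor_chain`, `acceptor_res`, `occupancy` (fractions in `[0, 1]`).
#' @param n_frames Number of frames.
#' @param frame_interval Time per frame (ps).
#' @param seed Integer seed.
#' @return List with `trajectory` (`ab_trajectory`) and `ground_truth`
#'   (schedule with `realized_occupancy`, `frames` list of per-bond frame
#'   indices, `seed`).
#' @export
make_interface_trajectory <- function(complex, schedule, n_frames = 100,
                                      frame_interval = 100, seed = 1) {
  stopifnot(all(schedule$occupancy >= 0 & schedule$occupancy <= 1))
  acc_key <- paste(schedule$acceptor_chain, schedule$acceptor_res)
  if (anyDuplicated(acc_key))
    stop("conflicting placements: an acceptor atom is scheduled in two bonds",
         call. = FALSE)
  atoms <- complex$atoms
  find_ca <- function(ch, res) {
    i <- which(atoms$chain_id == ch & atoms$residue_seq == res &
                 atoms$atom_name == "CA")
    if (!length(i)) stop(sprintf("residue %s/%d not in scaffold", ch, res),
                         call. = FALSE)
    i[1]
  }
  extra <- list()
  don_xyz <- matrix(0, nrow(schedule), 3)
  dir_vec <- matrix(0, nrow(schedule), 3)
  # each bond gets a spatially isolated slot (>= 20 Å from the scaffold and
  # from every other slot) so scheduled occupancies cannot cross-talk
  slot_base <- c(max(atoms$x) + 20, max(atoms$y) + 20, max(atoms$z) + 20)
  for (b in seq_len(nrow(schedule))) {
    di <- find_ca(schedule$donor_chain[b], schedule$donor_res[b])
    ai <- find_ca(schedule$acceptor_chain[b], schedule$acceptor_res[b])
    atoms$residue_name[atoms$chain_id == schedule$donor_chain[b] &
                         atoms$residue_seq == schedule$donor_res[b]] <- "SER"
    atoms$residue_name[atoms$chain_id == schedule$acceptor_chain[b] &
                         atoms$residue_seq == schedule$acceptor_res[b]] <- "ASP"
    u <- c(1, 0, 0)
    og <- slot_base + c(0, 0, 20 * b)
    don_xyz[b, ] <- og
    dir_vec[b, ] <- u
    extra[[length(extra) + 1L]] <- data.frame(
      atom_name = "OG", residue_name = "SER",
      chain_id = schedule$donor_chain[b], residue_seq = schedule$donor_res[b],
      x = og[1], y = og[2], z = og[3], element = "O",
      stringsAsFactors = FALSE)
    extra[[length(extra) + 1L]] <- data.frame(
      atom_name = "OD1", residue_name = "ASP",
      chain_id = schedule$acceptor_chain[b], residue_seq = schedule$acceptor_res[b],
      x = og[1] + 5 * u[1], y = og[2] + 5 * u[2], z = og[3] + 5 * u[3],
      element = "O", stringsAsFactors = FALSE)
  }
  keep_cols <- c("atom_name", "residue_name", "chain_id", "residue_seq",
                 "x", "y", "z", "element")
  base_atoms <- rbind(atoms[, keep_cols], do.call(rbind, extra))
  acc_rows <- nrow(atoms) + 2L * seq_len(nrow(schedule))
  .with_seed(seed, {
    frames_on <- lapply(schedule$occupancy, function(p) {
      k <- round(p * n_frames)
      if (k == 0) integer(0) else sort(sample.int(n_frames, k))
    })
    models <- lapply(seq_len(n_frames), function(f) {
      a <- base_atoms
      for (b in seq_len(nrow(schedule))) {
        d <- if (f %in% frames_on[[b]]) 2.9 else 5.0
        pos <- don_xyz[b, ] + d * dir_vec[b, ]
        a$x[acc_rows[b]] <- pos[1]
        a$y[acc_rows[b]] <- pos[2]
        a$z[acc_rows[b]] <- pos[3]
      }
      structure_model(a, model_index = f)
    })
    gt <- schedule
    gt$realized_occupancy <- vapply(frames_on, length, integer(1)) / n_frames
    list(trajectory = as_trajectory(models, frame_interval),
         ground_truth = list(schedule = gt, frames = frames_on, seed = seed))
  })
}
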