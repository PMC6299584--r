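# Independent brute-force oracles and fixture builders.

# --- exhaustive global-alignment oracle --------------------------------------
# Maximum score over all global alignments; a gap run of length L costs
# gap_open + L * gap_extend (affine, same convention as the implementation).
# Recursion enumerates alignment columns; practical for lengths <= 6.
brute_force_align_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  # state: (i, j, gstate) gstate 0 = none, 1 = gap in b open, 2 = gap in a open
  rec <- function(i, j, gstate) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    }
    if (i <= length(av)) {  # av[i] against gap
      open <- if (gstate == 1L) 0 else gap_open
      best <- max(best, -open - gap_extend + rec(i + 1, j, 1L))
    }
    if (j <= length(bv)) {
      open <- if (gstate == 2L) 0 else gap_open
      best <- max(best, -open - gap_extend + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# --- rotation-grid Kabsch oracle ---------------------------------------------
# Brute-force minimal RMSD over rotations: nested Euler-angle grid refined
# around the best cell; independent of the SVD route.
grid_kabsch_rmsd <- function(ref, mov, levels = 9, coarse_n = 13) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mov, 2, colMeans(mov))
  rotmat <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  eval_r <- function(ang) {
    R <- rotmat(ang[1], ang[2], ang[3])
    sqrt(sum((B %*% t(R) - A)^2) / nrow(A))
  }
  # global coarse scan, then local refinement from the best few starts
  # (the RMSD landscape over SO(3) has several basins)
  gr <- seq(-pi, pi, length.out = coarse_n)
  cand <- list()
  for (a in gr) for (b in gr) for (c in gr)
    cand[[length(cand) + 1L]] <- c(eval_r(c(a, b, c)), a, b, c)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  starts <- cand[seq_len(min(10, nrow(cand))), , drop = FALSE]
  best_r <- starts[1, 1]
  for (s in seq_len(nrow(starts))) {
    centre <- starts[s, 2:4]
    local_r <- starts[s, 1]
    width <- 2 * pi / (coarse_n - 1)
    for (lev in seq_len(levels)) {
      loc <- seq(-width, width, length.out = 7)
      best_local <- centre
      for (a in centre[1] + loc) for (b in centre[2] + loc) for (c in centre[3] + loc) {
        r <- eval_r(c(a, b, c))
        if (r < local_r) { local_r <- r; best_local <- c(a, b, c) }
      }
      centre <- best_local
      width <- width / 3
    }
    if (local_r < best_r) best_r <- local_r
  }
  best_r
}

# --- all-pairs H-bond oracle -------------------------------------------------
# Explicit double loop over every atom pair with the package's chemistry
# table, independent of the vectorised implementation path.
brute_force_hbonds <- function(model, chain_roles, cutoff,
                               include_backbone = TRUE) {
  atoms <- model$atoms
  ab <- names(chain_roles)[chain_roles %in% c("heavy", "light")]
  ag <- names(chain_roles)[chain_roles == "antigen"]
  da <- ablineage:::.flag_da(atoms, include_backbone)
  lab <- function(i) paste0(atoms$chain_id[i], ":", atoms$residue_name[i],
                            atoms$residue_seq[i], atoms$insertion[i], ":",
                            atoms$atom_name[i])
  out <- character(0)
  for (i in seq_len(nrow(atoms))) for (j in seq_len(nrow(atoms))) {
    ci <- atoms$chain_id[i]; cj <- atoms$chain_id[j]
    opposite <- (ci %in% ab && cj %in% ag) || (ci %in% ag && cj %in% ab)
    if (!opposite || !da$donor[i] || !da$acceptor[j]) next
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    if (d <= cutoff + 1e-12) out <- c(out, paste(lab(i), lab(j), sep = " -> "))
  }
  sort(out)
}

# random mixed-chemistry fixture for the H-bond oracle
random_hbond_fixture <- function(n_atoms = 50, box = 12) {
  res_pool <- data.frame(
    residue_name = c("SER", "THR", "TYR", "ASN", "GLN", "ASP", "GLU", "LYS",
                     "ARG", "HIS", "GLY", "ALA", "DA", "DT", "HOH"),
    atom_name = c("OG", "OG1", "OH", "ND2", "OE1", "OD1", "OE2", "NZ",
                  "NH1", "NE2", "N", "O", "N6", "O4", "O"),
    stringsAsFactors = FALSE)
  pick <- sample.int(nrow(res_pool), n_atoms, replace = TRUE)
  atoms <- data.frame(
    atom_name = res_pool$atom_name[pick],
    residue_name = res_pool$residue_name[pick],
    chain_id = sample(c("H", "L", "G"), n_atoms, replace = TRUE),
    residue_seq = seq_len(n_atoms),
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    element = substr(res_pool$atom_name[pick], 1, 1),
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

# --- shared fixtures ---------------------------------------------------------
fixture_numbering <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- list(H = kabat_number(kabat_template("H"), "H"),
                     L = kabat_number(kabat_template("L"), "L"))
    cache
  }
})

fixture_scaffold <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      nb <- fixture_numbering()
      cache <<- make_fv_scaffold(nb$H, nb$L, seed = 42)
    }
    cache
  }
})

# atom indices of the heavy-chain CDR Cα atoms of the fixture scaffold
fixture_cdr_idx <- function(scaffold = fixture_scaffold()) {
  nb <- fixture_numbering()
  map <- ablineage:::.map_numbering(scaffold, "H", nb$H)
  which(scaffold$atoms$chain_id == "H" &
          scaffold$atoms$residue_seq %in% map$residue_seq[map$cdr != "FW"])
}

random_structure_model <- function(n_atoms = 20) {
  aa <- c("ALA", "GLY", "SER", "TYR", "LYS", "ASP")
  structure_model(data.frame(
    serial = seq_len(n_atoms),
    atom_name = sample(c("CA", "CB", "OG", "N", "O"), n_atoms, replace = TRUE),
    residue_name = sample(aa, n_atoms, replace = TRUE),
    chain_id = sample(c("A", "B"), n_atoms, replace = TRUE),
    residue_seq = seq_len(n_atoms),
    insertion = sample(c("", "A"), n_atoms, replace = TRUE, prob = c(0.9, 0.1)),
    x = round(runif(n_atoms, -99, 99), 3),
    y = round(runif(n_atoms, -99, 99), 3),
    z = round(runif(n_atoms, -99, 99), 3),
    occupancy = 1, b_factor = 0,
    element = "C",
    stringsAsFactors = FALSE))
}

rigid_transform <- function(xyz, angles = runif(3, -pi, pi), shift = runif(3, -20, 20)) {
  a <- angles
  Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])), 3, 3, byrow = TRUE)
  sweep(xyz %*% (Rz %*% Ry %*% Rx), 2, shift, `+`)
}
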