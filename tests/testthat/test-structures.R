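test_that("PDB write/read round-trips atom records", {
  set.seed(31)
  for (case in 1:100) {
    m <- random_structure_model(sample(5:40, 1))
    m2 <- read_pdb(write_pdb(m))
    expect_length(m2, 1)
    a <- m$atoms; b <- m2[[1]]$atoms
    expect_equal(b$atom_name, a$atom_name)
    expect_equal(b$residue_name, a$residue_name)
    expect_equal(b$chain_id, a$chain_id)
    expect_equal(b$residue_seq, a$residue_seq)
    expect_equal(b$insertion, a$insertion)
    expect_equal(b$element, a$element)
    expect_equal(b$x, a$x, tolerance = 1e-9)  # fixture coords have 3 decimals
    expect_equal(b$y, a$y, tolerance = 1e-9)
    expect_equal(b$z, a$z, tolerance = 1e-9)
  }
})

test_that("multi-model files round-trip as trajectories", {
  set.seed(32)
  m1 <- random_structure_model(10)
  m2 <- m1
  m2$atoms$x <- m2$atoms$x + 1
  txt <- write_pdb(list(m1, m2))
  models <- read_pdb(txt)
  expect_length(models, 2)
  expect_identical(ablineage:::.atom_key(models[[1]]$atoms),
                   ablineage:::.atom_key(models[[2]]$atoms))
  expect_equal(models[[2]]$atoms$x, round(m1$atoms$x + 1, 3))
  # empty model list produces header-only text
  expect_match(write_pdb(list())[1], "REMARK")
})

test_that("insertion codes and alternate locations are handled", {
  lines <- c(
    "ATOM      1  CA  ALA H 100      1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY H 100A     4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      3  CB ASER H 101      0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      4  CB BSER H 101      9.000   9.000   9.000  0.70  0.00           C")
  m <- read_pdb(lines)[[1]]
  expect_equal(m$atoms$insertion, c("", "A", ""))
  # altloc: highest occupancy retained
  expect_equal(m$atoms$x[3], 9.0)
  expect_error(read_pdb("ATOM      1  CA  ALA H  xx       1.0     2.0     3.0"),
               "line 1")
})

test_that("inconsistent atom counts across models are rejected", {
  set.seed(33)
  m1 <- random_structure_model(8)
  m2 <- structure_model(m1$atoms[1:7, ])
  txt <- c("MODEL        1", write_pdb(m1)[-1][1:8], "ENDMDL",
           "MODEL        2", write_pdb(m2)[-1][1:7], "ENDMDL")
  expect_error(read_pdb(txt), "integrity")
  expect_error(as_trajectory(list(m1, m2)), "integrity")
})

test_that("Kabsch recovers identity and rigid copies", {
  set.seed(34)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  sp0 <- kabsch_superpose(A, A)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)

  B <- rigid_transform(A)
  sp <- kabsch_superpose(A, B)
  expect_lt(sp$rmsd, 1e-6)
  # returned transform maps B onto A
  expect_equal(apply_superposition(sp, B), A, tolerance = 1e-6)
  # proper rotation
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(A, B[1:9, ]), "identical dimensions")
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("superposed RMSD is invariant under rigid pre-transforms", {
  set.seed(35)
  for (case in 1:10) {
    A <- matrix(rnorm(24, sd = 4), 8, 3)
    B <- A + matrix(rnorm(24, sd = 0.5), 8, 3)
    r0 <- kabsch_superpose(A, B)$rmsd
    r1 <- kabsch_superpose(rigid_transform(A), B)$rmsd
    r2 <- kabsch_superpose(A, rigid_transform(B))$rmsd
    expect_equal(r1, r0, tolerance = 1e-6)
    expect_equal(r2, r0, tolerance = 1e-6)
  }
})

test_that("degenerate geometry triggers a conditioning warning", {
  line <- cbind(1:5, 0, 0) * 1.0
  expect_warning(kabsch_superpose(line, line + 0.0), "degenerate")
})

test_that("Fv extraction truncates constant regions and keeps antigens", {
  nb <- fixture_numbering()
  sc <- fixture_scaffold()
  cx <- make_complex_scaffold(sc, antigen_length = 20, seed = 7)
  roles <- c(H = "heavy", L = "light", G = "antigen")
  # append a fake constant domain to chain H
  nH <- sum(cx$atoms$chain_id == "H")
  const <- data.frame(
    atom_name = "CA", residue_name = "GLY", chain_id = "H",
    residue_seq = nH + 1:25,
    x = 500 + 3.8 * (1:25), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE)
  fab <- structure_model(rbind(cx$atoms[, names(const)], const))
  fv <- extract_fv(fab, roles, list(H = nb$H, L = nb$L))
  expect_equal(sum(fv$atoms$chain_id == "H"), nH)
  expect_equal(sum(fv$atoms$chain_id == "G"), 20)
  # idempotent on already-Fv input
  fv2 <- extract_fv(fv, roles, list(H = nb$H, L = nb$L))
  expect_equal(fv2$atoms, fv$atoms)
})

test_that("antigen stripping removes antigen chains and nothing else", {
  sc <- fixture_scaffold()
  cx <- make_complex_scaffold(sc, antigen_length = 15, seed = 8)
  roles <- c(H = "heavy", L = "light", G = "antigen")
  free <- strip_antigen(cx, roles)
  expect_equal(sum(free$atoms$chain_id == "G"), 0)
  ab <- cx$atoms[cx$atoms$chain_id %in% c("H", "L"), c("x", "y", "z")]
  expect_equal(free$atoms[, c("x", "y", "z")], ab, ignore_attr = TRUE)
  # idempotent
  expect_equal(strip_antigen(free, roles)$atoms, free$atoms)
})

test_that("per-CDR RMSD is zero against itself and isolates displaced loops", {
  nb <- fixture_numbering()
  sc <- fixture_scaffold()
  num <- list(H = nb$H, L = nb$L)
  self <- per_cdr_rmsd(sc, num, sc, num)
  expect_setequal(self$region, c("H1", "H2", "H3", "L1", "L2", "L3"))
  expect_true(all(self$rmsd < 1e-9))

  # sibling with CDR-L1 rigidly displaced by 2 Å
  tgt <- sc
  map <- ablineage:::.map_numbering(sc, "L", nb$L)
  l1 <- map$residue_seq[map$cdr == "L1"]
  idx <- tgt$atoms$chain_id == "L" & tgt$atoms$residue_seq %in% l1
  tgt$atoms$z[idx] <- tgt$atoms$z[idx] + 2
  rec <- per_cdr_rmsd(sc, num, tgt, num)
  expect_equal(rec$rmsd[rec$region == "L1"], 2, tolerance = 0.05)
  expect_true(all(rec$rmsd[rec$region != "L1"] < 0.05))
})

test_that("CDR-H3 is skipped when lengths differ", {
  nb <- fixture_numbering()
  sc <- fixture_scaffold()
  h <- kabat_template("H")
  pre <- 30 + 5 + 14 + 16 + 32
  seq_ins <- paste0(substr(h, 1, pre + 6), "AG", substr(h, pre + 7, nchar(h)))
  nc_ins <- kabat_number(seq_ins, "H")
  sc_ins <- make_fv_scaffold(nc_ins, nb$L, seed = 44)
  rec <- per_cdr_rmsd(sc, list(H = nb$H, L = nb$L),
                      sc_ins, list(H = nc_ins, L = nb$L))
  expect_false("H3" %in% rec$region)
  expect_true(all(c("H1", "H2", "L1") %in% rec$region))
})

test_that("RMSD exceedance fractions count correctly and are monotone", {
  rec <- data.frame(
    antibody_id = "x", region = rep(c("L1", "H1"), c(4, 2)),
    rmsd = c(1.5, 2.0, 0.5, 1.2, 0.2, 0.3), reference_id = "r")
  out <- rmsd_exceed_fraction(rec, 1.0)
  expect_equal(unname(out["L1"]), 75)
  expect_equal(unname(out["H1"]), 0)
  expect_error(rmsd_exceed_fraction(rec, 0), "positive")
  # monotone non-increasing in the threshold, values within [0, 100]
  ths <- c(0.1, 0.5, 1, 1.5, 3)
  vals <- vapply(ths, function(t) unname(rmsd_exceed_fraction(rec, t)["L1"]),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 100))
  # all-zero records: 0% everywhere
  rec0 <- data.frame(antibody_id = "x", region = "L2", rmsd = 0,
                     reference_id = "r")
  expect_equal(unname(rmsd_exceed_fraction(rec0, 1)["L2"]), 0)
})

test_that("planted exceedance rates are recovered at n = 200", {
  set.seed(36)
  n <- 200
  rmsd <- ifelse(runif(n) < 0.6, runif(n, 1.2, 3), runif(n, 0, 0.8))
  rec <- data.frame(antibody_id = "x", region = "L1", rmsd = rmsd,
                    reference_id = "r")
  got <- unname(rmsd_exceed_fraction(rec, 1)["L1"])
  expect_equal(got, 100 * mean(rmsd > 1))
  expect_lt(abs(got - 60), 12)  # ~3 binomial SDs
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal, and exact on planted shifts", {
  sc <- fixture_scaffold()
  cdr <- fixture_cdr_idx(sc)
  shift <- function(d) {
    m <- sc
    m$atoms$x[cdr] <- m$atoms$x[cdr] + d
    m
  }
  confs <- list(a = sc, b = shift(10), dup = sc)
  sel <- atom_selection(chains = "H")
  m <- pairwise_rmsd_matrix(confs, sel)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m["a", "dup"], 0, tolerance = 1e-9)
  expect_gt(m["a", "b"], 1)
  # planted displacement reproduced: same generator arithmetic both ways
  direct <- coord_rmsd(coords(sc, sel), coords(shift(10), sel))
  expect_equal(m["a", "b"], direct, tolerance = 1e-9)
})

test_that("bio3d agrees with the internal reader on a single-model file", {
  skip_if_not_installed("bio3d")
  set.seed(37)
  m <- random_structure_model(15)
  tf <- tempfile(fileext = ".pdb")
  write_pdb(m, tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ref$atom), 15)
  expect_equal(ref$atom$x, read_pdb(tf)[[1]]$atoms$x)
  expect_equal(trimws(ref$atom$elety), read_pdb(tf)[[1]]$atoms$atom_name)
})
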