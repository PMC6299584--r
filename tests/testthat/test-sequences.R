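test_that("global alignment handles identity, substitution and gap cases", {
  aln <- global_align("ACDE", "ACDE")
  expect_equal(aln$aligned_a, "ACDE")
  expect_equal(aln$aligned_b, "ACDE")
  expect_equal(percent_identity(aln), 100)

  aln2 <- global_align("ACDE", "ACE")
  expect_equal(sum(strsplit(aln2$aligned_b, "")[[1]] == "-"), 1)

  aln3 <- global_align("ACDEFGHIK", "ACDEFGHIR")
  a <- strsplit(aln3$aligned_a, "")[[1]]
  b <- strsplit(aln3$aligned_b, "")[[1]]
  expect_equal(sum(a == b), 8)
  expect_equal(length(a), 9)
})

test_that("alignment rejects empty input and names invalid symbols", {
  expect_error(global_align("", "ACDE"), "non-empty")
  expect_error(global_align("AC1E", "ACDE"), "'1'")
  expect_error(global_align("ACDE", "ACZE"), "'Z'")
})

test_that("alignment score equals exhaustive enumeration for short sequences", {
  mat <- blosum62_matrix()
  set.seed(11)
  alphabet <- c("A", "C", "D", "W", "K")
  for (case in 1:30) {
    a <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 brute_force_align_score(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("percent identity counts residue-residue columns only", {
  # 17 substitutions on a 98-residue gap-free pair: 100 * 81 / 98
  set.seed(3)
  base <- paste(sample(c("A", "C", "D", "E", "F", "G"), 98, replace = TRUE),
                collapse = "")
  chars <- strsplit(base, "")[[1]]
  pos <- sample(98, 17)
  for (p in pos) chars[p] <- setdiff(c("K", "R", "H"), chars[p])[1]
  mut <- paste(chars, collapse = "")
  aln <- list(aligned_a = base, aligned_b = mut, score = 0)
  class(aln) <- "ab_alignment"
  expect_equal(percent_identity(aln), 100 * 81 / 98)

  gap_only <- structure(list(aligned_a = "A-", aligned_b = "-A", score = 0),
                        class = "ab_alignment")
  expect_error(percent_identity(gap_only), "undefined")
})

test_that("identity matrix is symmetric with unit diagonal", {
  rep3 <- make_germline_repertoire(3, "H", 0.3, seed = 5)
  seqs <- vapply(rep3, `[[`, character(1), "v_region_sequence")
  m <- build_identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_error(build_identity_matrix(seqs[1]), "at least 2")

  two <- c(a = "ACDEFGHIK", b = "ACDEFGHIK")
  expect_equal(unname(build_identity_matrix(two)["a", "b"]), 100)
})

test_that("Kabat numbering is idempotent on templates with adopted CDR spans", {
  for (ct in c("H", "L")) {
    nc <- kabat_number(kabat_template(ct), ct)
    expect_equal(chain_sequence(nc), kabat_template(ct))
    expect_equal(nrow(nc$residues), nchar(kabat_template(ct)))
    expect_false(any(duplicated(nc$residues$label)))
    # renumbering its own output sequence reproduces the same labels
    nc2 <- kabat_number(chain_sequence(nc), ct)
    expect_equal(nc2$residues$label, nc$residues$label)
  }
  ncH <- kabat_number(kabat_template("H"), "H")
  expect_equal(unname(ncH$cdr_spans$CDR2), c("50", "65"))
  expect_equal(unname(ncH$cdr_spans$CDR1[1]), "31")
  expect_equal(unname(ncH$cdr_spans$CDR3), c("95", "102"))
  ncL <- kabat_number(kabat_template("L"), "L")
  expect_equal(unname(ncL$cdr_spans$CDR2), c("50", "56"))
  expect_equal(unname(ncL$cdr_spans$CDR3), c("89", "97"))
})

test_that("CDR-H3 insertions are lettered at position 100", {
  h <- kabat_template("H")
  # insert two residues into CDR-H3 of the template (8 -> 10 residues)
  base_cdr3_at <- 30 + 5 + 14 + 16 + 32  # residues before CDR3
  seq_ins <- paste0(substr(h, 1, base_cdr3_at + 6), "AG",
                    substr(h, base_cdr3_at + 7, nchar(h)))
  nc <- kabat_number(seq_ins, "H")
  cdr3 <- nc$residues$label[nc$residues$region == "CDR3"]
  expect_true(all(c("100A", "100B") %in% cdr3))
  expect_equal(length(cdr3), 10)
  # a 2-residue-shorter CDR-H3 omits positions backwards from 100
  seq_del <- paste0(substr(h, 1, base_cdr3_at + 3),
                    substr(h, base_cdr3_at + 6, nchar(h)))
  ncd <- kabat_number(seq_del, "H")
  cdr3d <- ncd$residues$label[ncd$residues$region == "CDR3"]
  expect_equal(length(cdr3d), 6)
  expect_false(any(c("99", "100") %in% cdr3d))
})

test_that("numbering fails cleanly on non-antibody sequences", {
  expect_error(kabat_number("PPPPGGGG", "H"), "numbering failure")
})

test_that("every residue receives exactly one strictly increasing position", {
  set.seed(21)
  rep2 <- make_germline_repertoire(2, "H", 0.35, seed = 9)
  for (g in rep2) {
    nc <- kabat_number(g$v_region_sequence, "H")
    expect_equal(nrow(nc$residues), nchar(g$v_region_sequence))
    key <- ablineage:::.kabat_order_key(nc$residues$label)
    expect_true(all(diff(key) > 0))
    expect_true(all(nc$residues$region %in%
                      c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4")))
  }
})

test_that("germline assignment picks the true source gene and obeys tie-breaks", {
  rep2 <- make_germline_repertoire(2, "H", 0.4, seed = 13)
  # mature = exact copy of gene 2
  ex <- assign_germline(rep2[[2]]$v_region_sequence, rep2, antibody_id = "x")
  expect_equal(ex$best_gene$gene_name, rep2[[2]]$gene_name)
  expect_equal(ex$percent_identity, 100)

  # mature built by mutating gene 1 at 10 positions
  lin <- make_lineage(rep2[[1]], n_members = 1, mutations_per_member = 10, seed = 2)
  as1 <- assign_germline(lin$sequences[[1]], rep2)
  expect_equal(as1$best_gene$gene_name, rep2[[1]]$gene_name)

  # equal-score tie resolved by lineage context, then allele name
  twin_a <- germline_gene("9-01", "01", rep2[[1]]$v_region_sequence)
  twin_b <- germline_gene("2-02", "01", rep2[[1]]$v_region_sequence)
  tie <- assign_germline(lin$sequences[[1]], list(twin_a, twin_b),
                         lineage_context = "9-01")
  expect_equal(tie$best_gene$gene_name, "9-01")
  tie2 <- assign_germline(lin$sequences[[1]], list(twin_a, twin_b))
  expect_equal(tie2$best_gene$gene_name, "2-02")  # lexicographic

  expect_error(assign_germline("ACDE", list()), "empty")
})

test_that("mutation mapping recovers planted substitutions exactly", {
  rep1 <- make_germline_repertoire(1, "H", seed = 17)
  for (s in 1:10) {
    lin <- make_lineage(rep1[[1]], n_members = 2, mutations_per_member = 7,
                        cdr_bias = 0.6, seed = s)
    for (m in seq_along(lin$sequences)) {
      rec <- map_mutations(kabat_number(lin$sequences[[m]], "H"), lin$numbering)
      gt <- lin$ground_truth[lin$ground_truth$member == names(lin$sequences)[m], ]
      expect_equal(rec$kabat_position, gt$kabat_position)
      expect_equal(rec$germline_aa, gt$germline_aa)
      expect_equal(rec$mature_aa, gt$mature_aa)
      expect_equal(rec$region, gt$region)
    }
  }
  # identical chains give an empty list
  nc <- kabat_number(rep1[[1]]$v_region_sequence, "H")
  expect_equal(nrow(map_mutations(nc, nc)), 0)
  # chain-type mismatch errors
  ncL <- kabat_number(kabat_template("L"), "L")
  expect_error(map_mutations(nc, ncL), "mismatch")
})

test_that("germline clustering partitions antibodies and flags singletons", {
  rep2 <- make_germline_repertoire(2, "H", 0.4, seed = 23)
  mk <- function(id, gene) {
    a <- assign_germline(gene$v_region_sequence, rep2, antibody_id = id)
    a
  }
  as3 <- list(mk("ab1", rep2[[1]]), mk("ab2", rep2[[1]]), mk("ab3", rep2[[1]]))
  g <- cluster_by_germline(as3)
  expect_equal(length(g), 1)
  expect_equal(sort(g[[1]]), c("ab1", "ab2", "ab3"))
  expect_equal(length(attr(g, "singletons")), 0)

  as_mixed <- list(mk("ab1", rep2[[1]]), mk("ab2", rep2[[2]]))
  g2 <- cluster_by_germline(as_mixed)
  expect_equal(length(g2), 2)
  expect_equal(sort(attr(g2, "singletons")), sort(names(g2)))

  expect_equal(length(cluster_by_germline(list())), 0)
})

test_that("germline recovery holds across divergent repertoires and seeds", {
  # true source gene recovered whenever repertoire genes are <= 80% mutually
  # identical and at most 15 mutations are planted
  for (s in 1:50) {
    rep2 <- make_germline_repertoire(2, "H", min_pairwise_divergence = 0.2,
                                     seed = 300 + s)
    k <- (s %% 15) + 1
    lin <- make_lineage(rep2[[(s %% 2) + 1]], n_members = 1,
                        mutations_per_member = k, seed = s)
    got <- assign_germline(lin$sequences[[1]], rep2)
    expect_equal(got$best_gene$gene_name, rep2[[(s %% 2) + 1]]$gene_name,
                 label = sprintf("seed %d (k=%d)", s, k))
  }
})
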