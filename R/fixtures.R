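# Serialization of generator ground truth and a one-call fixture bundle.

#' Write generator ground truth as a plain-text sidecar
#'
#' Format: scalar entries as `key: value` lines; vectors comma-separated;
#' data.frames as tab-separated blocks introduced by a `[name]` section
#' header with a column-header line. Nested lists flatten with `.`-joined
#' keys.
#'
#' @param ground_truth The `ground_truth` element returned by a generator.
#' @param path Output file.
#' @export
write_ground_truth <- function(ground_truth, path) {
  lines <- character(0)
  emit <- function(x, key) {
    if (is.data.frame(x)) {
      lines <<- c(lines, sprintf("[%s]", key),
                  paste(names(x), collapse = "\t"),
                  do.call(paste, c(lapply(x, as.character), sep = "\t")))
    } else if (is.matrix(x)) {
      lines <<- c(lines, sprintf("[%s]", key),
                  apply(x, 1, paste, collapse = "\t"))
    } else if (is.list(x)) {
      for (nm in names(x)) emit(x[[nm]], paste(key, nm, sep = "."))
    } else {
      lines <<- c(lines, sprintf("%s: %s", key, paste(x, collapse = ",")))
    }
  }
  for (nm in names(ground_truth)) emit(ground_truth[[nm]], nm)
  writeLines(lines, path)
  invisible(path)
}

#' Materialize the default synthetic test-fixture bundle
#'
#' Writes, under `dir`: a 3-gene germline repertoire (FASTA), a mutated
#' lineage (FASTA + ground-truth sidecar), an Fv scaffold (PDB), a
#' two-conformer bound/free ensemble (multi-model PDBs + sidecar), and an
#' interface trajectory with scheduled occupancies (multi-model PDB +
#' sidecar). Deterministic per seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_frames Frames per ensemble source and interface trajectory.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture_bundle <- function(dir, seed = 1, n_frames = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- list()

  rep3 <- make_germline_repertoire(3, "H", 0.3, seed = seed)
  paths$repertoire <- write_fasta(rep3, p("germline_repertoire.fasta"))

  lin <- make_lineage(rep3[[1]], n_members = 3, mutations_per_member = 5,
                      cdr_bias = 0.6, seed = seed)
  paths$lineage <- write_fasta(lin$sequences, p("lineage.fasta"))
  paths$lineage_gt <- write_ground_truth(
    list(germline = germline_id(rep3[[1]]), mutations = lin$ground_truth,
         seed = seed), p("lineage.groundtruth.txt"))

  nbH <- kabat_number(kabat_template("H"), "H")
  nbL <- kabat_number(kabat_template("L"), "L")
  scaffold <- make_fv_scaffold(nbH, nbL, seed = seed)
  paths$scaffold <- p("fv_scaffold.pdb")
  write_pdb(scaffold, paths$scaffold)

  cdr_idx <- which(scaffold$atoms$chain_id == "H")[grepl("^CDR", nbH$residues$region)]
  ens <- make_conformer_ensemble(
    scaffold, cdr_idx,
    populations = list(bound = c(1, 0), free = c(0.6, 0.4)),
    n_frames = n_frames, seed = seed,
    measure_selection = atom_selection(chains = "H"))
  paths$bound <- p("ensemble_bound.pdb"); write_pdb(ens$bound, paths$bound)
  paths$free <- p("ensemble_free.pdb"); write_pdb(ens$free, paths$free)
  paths$ensemble_gt <- write_ground_truth(ens$ground_truth,
                                          p("ensemble.groundtruth.txt"))

  cx <- make_complex_scaffold(scaffold, antigen_length = 20, seed = seed)
  sched <- data.frame(donor_chain = "H", donor_res = c(12, 45, 80),
                      acceptor_chain = "G", acceptor_res = c(4, 9, 14),
                      occupancy = c(1.0, 0.4, 0.2))
  it <- make_interface_trajectory(cx, sched, n_frames = n_frames, seed = seed)
  paths$interface <- p("interface_trajectory.pdb")
  write_pdb(it$trajectory, paths$interface)
  paths$interface_gt <- write_ground_truth(
    list(schedule = it$ground_truth$schedule, seed = seed),
    p("interface.groundtruth.txt"))

  invisible(paths)
}
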