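# Dataset curation and end-to-end report orchestration.

#' Pipeline configuration
#'
#' Holds the analysis constants: X-ray resolution cutoff 3.25 Å for dataset
#' curation, 1 Å threshold for CDR RMSD exceedance statistics, 1.5 Å
#' fixed-radius cluster radius, 3.5 Å hydrogen-bond donor-acceptor cutoff,
#' and the 30% occupancy floor for the primary H-bond report.
#'
#' @param resolution_cutoff Maximum X-ray resolution retained (Å).
#' @param rmsd_threshold CDR RMSD exceedance threshold (Å).
#' @param cluster_radius Fixed-radius clustering radius (Å).
#' @param hbond_cutoff H-bond distance cutoff (Å).
#' @param occupancy_min Occupancy floor for the primary H-bond report.
#' @param cluster_stride,occupancy_stride Frame strides for clustering and
#'   occupancy analysis.
#' @param atom_selection Default observable: `"CA"`, `"backbone"` or
#'   `"all-heavy"`.
#' @param excluded_residues Residue numbers excluded from RMSD calculations
#'   (flexible residues far from the binding pocket; always explicit, never
#'   inferred).
#' @param reference_policy Reference antibody choice within a lineage:
#'   `"lexicographic"` (deterministic) or `"seeded_random"`.
#' @param seed Integer seed for any randomized option.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(resolution_cutoff = 3.25, rmsd_threshold = 1.0,
                            cluster_radius = 1.5, hbond_cutoff = 3.5,
                            occupancy_min = 0.30, cluster_stride = 1L,
                            occupancy_stride = 1L, atom_selection = "CA",
                            excluded_residues = integer(0),
                            reference_policy = c("lexicographic", "seeded_random"),
                            seed = 1L) {
  stopifnot(resolution_cutoff > 0, rmsd_threshold > 0, cluster_radius > 0,
            hbond_cutoff > 0, occupancy_min > 0, occupancy_min <= 1)
  structure(list(resolution_cutoff = resolution_cutoff,
                 rmsd_threshold = rmsd_threshold,
                 cluster_radius = cluster_radius,
                 hbond_cutoff = hbond_cutoff,
                 occupancy_min = occupancy_min,
                 cluster_stride = as.integer(cluster_stride),
                 occupancy_stride = as.integer(occupancy_stride),
                 atom_selection = atom_selection,
                 excluded_residues = excluded_residues,
                 reference_policy = match.arg(reference_policy),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Curate a candidate dataset of antibody structures
#'
#' Retains a record iff its method is X-ray, its resolution is at (or better
#' than) the cutoff, it is not humanized or chimeric, and it is the
#' representative of its redundancy group (`representative_of` empty/NA or
#' equal to its own id). Records with missing required metadata are excluded
#' with reason `"incomplete-metadata"`. Order-independent.
#'
#' @param records data.frame with columns `pdb_id`, `organism`, `resolution`,
#'   `method`, `humanized_or_chimeric`, `representative_of`.
#' @param config A [pipeline_config()].
#' @return List of class `curation_result`: `retained` (data.frame) and
#'   `exclusions` (data.frame with `pdb_id`, `reason`).
#' @export
curate_dataset <- function(records, config = pipeline_config()) {
  needed <- c("pdb_id", "resolution", "method", "humanized_or_chimeric")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop(sprintf("metadata table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (is.null(records$representative_of)) records$representative_of <- NA_character_
  reasons <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$pdb_id) || is.na(r$method) || is.na(r$humanized_or_chimeric) ||
        (toupper(r$method) %in% c("X-RAY", "XRAY", "X-RAY DIFFRACTION") && is.na(r$resolution))) {
      reasons[i] <- "incomplete-metadata"
    } else if (!(toupper(r$method) %in% c("X-RAY", "XRAY", "X-RAY DIFFRACTION"))) {
      reasons[i] <- "not-xray"
    } else if (r$resolution > config$resolution_cutoff) {
      reasons[i] <- sprintf("resolution-above-%.2f", config$resolution_cutoff)
    } else if (isTRUE(as.logical(r$humanized_or_chimeric))) {
      reasons[i] <- "humanized-or-chimeric"
    } else if (!is.na(r$representative_of) && nzchar(r$representative_of) &&
               r$representative_of != r$pdb_id) {
      reasons[i] <- "redundant-non-representative"
    }
  }
  keep <- !nzchar(reasons)
  out <- list(retained = records[keep, , drop = FALSE],
              exclusions = data.frame(pdb_id = records$pdb_id[!keep],
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE))
  class(out) <- "curation_result"
  out
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("Curation: %d retained, %d excluded\n",
              nrow(x$retained), nrow(x$exclusions)))
  if (nrow(x$exclusions)) print(table(x$exclusions$reason))
  invisible(x)
}

.pick_reference <- function(ids, config) {
  ids <- sort(ids)
  if (config$reference_policy == "lexicographic") return(ids[1])
  .with_seed(config$seed, sample(ids, 1))
}

#' Lineage-level sequence and structure report
#'
#' Orchestrates the lineage analysis end to end: germline assignment and
#' clustering by common germline VH origin, per-lineage identity matrices and
#' somatic-mutation tables, per-CDR RMSD of every lineage member against a
#' reference antibody, RMSD exceedance fractions, and (when complexes are
#' supplied) interface contact profiles with chain-engagement statistics.
#' All outputs are written as CSV plus a plain-text summary; reruns with the
#' same inputs are byte-identical.
#'
#' @param sequences Named character vector of mature VH sequences.
#' @param repertoire List of `germline_gene` objects (or a FASTA path).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param structures Optional named list (per antibody id) of lists with
#'   elements `model` (`structure_model`), `numbering` (named list of
#'   `numbered_chain` per chain id), and optionally `chain_roles` for
#'   complexes.
#' @param chain_type Chain type of `sequences`.
#' @return Invisibly, the report bundle (list of all computed tables).
#' @export
run_lineage_report <- function(sequences, repertoire, out_dir,
                               config = pipeline_config(), structures = NULL,
                               chain_type = "H") {
  if (is.character(repertoire) && length(repertoire) == 1L &&
      file.exists(repertoire))
    repertoire <- read_germline_fasta(repertoire)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)

  assignments <- lapply(names(sequences), function(id)
    assign_germline(sequences[[id]], repertoire, antibody_id = id))
  lineages <- cluster_by_germline(assignments)
  memb <- data.frame(
    antibody = vapply(assignments, `[[`, character(1), "antibody_id"),
    germline = vapply(assignments, function(a) germline_id(a$best_gene), character(1)),
    score = vapply(assignments, `[[`, numeric(1), "score"),
    percent_identity = vapply(assignments, `[[`, numeric(1), "percent_identity"),
    stringsAsFactors = FALSE)
  utils::write.csv(memb, file.path(out_dir, "lineage_membership.csv"),
                   row.names = FALSE)

  idm <- if (length(sequences) >= 2) build_identity_matrix(sequences) else NULL
  if (!is.null(idm))
    write_matrix_csv(idm, file.path(out_dir, "identity_matrix.csv"))

  gl_by_id <- stats::setNames(lapply(assignments, `[[`, "best_gene"),
                              vapply(assignments, `[[`, character(1), "antibody_id"))
  mutations <- lapply(names(sequences), function(id) {
    map_mutations(kabat_number(sequences[[id]], chain_type),
                  kabat_number(gl_by_id[[id]]$v_region_sequence, chain_type))
  })
  names(mutations) <- names(sequences)
  write_mutation_csv(mutations, file.path(out_dir, "mutations.csv"))

  rmsd_records <- NULL
  profiles <- list()
  if (!is.null(structures)) {
    for (gene in names(lineages)) {
      ids <- intersect(lineages[[gene]], names(structures))
      if (length(ids) < 2L) {
        notes <- c(notes, sprintf(
          "lineage %s: fewer than 2 structures; RMSD stage skipped", gene))
        next
      }
      ref_id <- .pick_reference(ids, config)
      for (id in setdiff(ids, ref_id)) {
        rec <- per_cdr_rmsd(structures[[ref_id]]$model, structures[[ref_id]]$numbering,
                            structures[[id]]$model, structures[[id]]$numbering,
                            atom_selection = config$atom_selection,
                            antibody_id = id, reference_id = ref_id)
        rmsd_records <- rbind(rmsd_records, rec)
      }
    }
    for (id in names(structures)) {
      st <- structures[[id]]
      if (is.null(st$chain_roles) || !any(st$chain_roles == "antigen")) next
      hb <- detect_hbonds(st$model, st$chain_roles, cutoff = config$hbond_cutoff,
                          numbering = st$numbering)
      profiles[[id]] <- cdr_contact_profile(hb, antibody_id = id)
    }
  }
  if (!is.null(rmsd_records)) {
    utils::write.csv(rmsd_records, file.path(out_dir, "cdr_rmsd.csv"),
                     row.names = FALSE)
    exceed <- rmsd_exceed_fraction(rmsd_records, config$rmsd_threshold)
    utils::write.csv(data.frame(region = names(exceed), percent_above = exceed),
                     file.path(out_dir, "rmsd_exceedance.csv"), row.names = FALSE)
  } else exceed <- NULL
  engagement <- if (length(profiles)) chain_engagement_stats(profiles) else NULL
  if (length(profiles)) {
    ptab <- do.call(rbind, lapply(names(profiles), function(id)
      cbind(data.frame(antibody = id), as.data.frame(t(unclass(profiles[[id]]))))))
    utils::write.csv(ptab, file.path(out_dir, "contact_profiles.csv"),
                     row.names = FALSE)
  }

  summary_lines <- c(
    sprintf("antibodies: %d", length(sequences)),
    sprintf("lineages: %d", length(lineages)),
    sprintf("singleton lineages: %d", length(attr(lineages, "singletons"))),
    if (!is.null(exceed))
      sprintf("RMSD > %.1f A: %s", config$rmsd_threshold,
              paste(sprintf("%s=%.1f%%", names(exceed), exceed), collapse = " ")),
    if (!is.null(engagement))
      sprintf("H>L engagement: %.1f%%; L absent: %.1f%%; H3 absent: %.1f%%",
              engagement$pct_h_gt_l, engagement$pct_l_absent,
              engagement$pct_h3_absent),
    notes)
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(assignments = assignments, lineages = lineages,
                 membership = memb, identity_matrix = idm,
                 mutations = mutations, cdr_rmsd = rmsd_records,
                 exceedance = exceed, profiles = profiles,
                 engagement = engagement, notes = notes))
}

#' Conformational-landscape report for one antibody
#'
#' Joint fixed-radius clustering of the bound and free ensembles, per-source
#' population table, conformational-selection vs induced-fit call,
#' RMSD-versus-time series, representative frames (written as single-model
#' PDB), a conformer heatmap matrix, H-bond occupancy tables for the bound
#' complex (when roles include an antigen), and an optional binding-energy
#' series.
#'
#' @param bound,free `ab_trajectory` objects of the antibody (bound form with
#'   antigen stripped for clustering); `free = NULL` skips the
#'   population/mechanism stages.
#' @param reference `structure_model` used for the RMSD time series.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param selection [atom_selection()] for clustering and RMSD.
#' @param complex_traj Optional `ab_trajectory` of the intact complex for
#'   occupancy analysis.
#' @param chain_roles Roles for `complex_traj`.
#' @param scorer Optional per-model energy scorer for
#'   [binding_energy_series()].
#' @return Invisibly, the report bundle.
#' @export
run_landscape_report <- function(bound, free, reference, out_dir,
                                 config = pipeline_config(),
                                 selection = atom_selection(),
                                 complex_traj = NULL, chain_roles = NULL,
                                 scorer = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  stride <- config$cluster_stride
  take <- function(traj) {
    if (is.null(traj) || stride == 1L) return(traj)
    as_trajectory(traj$models[seq(1L, n_frames(traj), by = stride)],
                  traj$frame_interval * stride)
  }
  bound <- take(bound)
  free <- take(free)

  if (is.null(free)) {
    clusters <- fixed_radius_kcluster(bound, selection, config$cluster_radius,
                                      source = "bound")
    populations <- population_fractions(clusters)
    mechanism <- NULL
    notes <- c(notes, "free trajectory absent; mechanism stage skipped")
  } else {
    clusters <- joint_cluster_landscape(bound, free, selection,
                                        config$cluster_radius)
    populations <- population_fractions(clusters)
    mechanism <- classify_binding_mechanism(populations)
  }
  assign_df <- data.frame(
    frame = seq_along(clusters$assignments),
    source = clusters$sources,
    cluster = clusters$assignments)
  utils::write.csv(assign_df, file.path(out_dir, "cluster_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(populations),
                   file.path(out_dir, "populations.csv"), row.names = FALSE)
  if (!is.null(mechanism))
    writeLines(c(sprintf("verdict: %s", mechanism$verdict),
                 sprintf("bound_dominant_cluster: %d", mechanism$bound_dominant_cluster),
                 sprintf("bound_population: %.4f", mechanism$bound_population),
                 sprintf("free_population_of_bound_dominant: %.4f",
                         mechanism$free_population_of_bound_dominant)),
               file.path(out_dir, "mechanism.txt"))

  series <- rmsd_time_series(bound, reference, selection, clusters)
  utils::write.csv(series, file.path(out_dir, "rmsd_series_bound.csv"),
                   row.names = FALSE)

  n_bound <- n_frames(bound)
  reps <- list()
  for (k in seq_along(clusters$centroids)) {
    f <- representative_frame(clusters, k)
    model <- if (f <= n_bound) bound$models[[f]] else free$models[[f - n_bound]]
    src <- clusters$sources[f]
    write_pdb(model, file.path(out_dir, sprintf("representative_c%d_%s.pdb", k, src)))
    reps[[k]] <- list(cluster = k, frame = f, source = src, model = model)
  }
  rep_models <- stats::setNames(
    lapply(reps, `[[`, "model"),
    vapply(reps, function(r) sprintf("c%d_%s", r$cluster, r$source), character(1)))
  heat <- pairwise_rmsd_matrix(rep_models, selection)
  write_matrix_csv(heat, file.path(out_dir, "conformer_heatmap.csv"))

  occupancy <- NULL
  if (!is.null(complex_traj) && !is.null(chain_roles)) {
    occ_traj <- if (config$occupancy_stride > 1L)
      as_trajectory(complex_traj$models[seq(1L, n_frames(complex_traj),
                                            by = config$occupancy_stride)],
                    complex_traj$frame_interval * config$occupancy_stride)
      else complex_traj
    occupancy <- hbond_occupancy(occ_traj, chain_roles,
                                 cutoff = config$hbond_cutoff,
                                 min_occupancy = config$occupancy_min)
    utils::write.csv(occupancy$full, file.path(out_dir, "hbond_occupancy_full.csv"),
                     row.names = FALSE)
    utils::write.csv(occupancy$records,
                     file.path(out_dir, "hbond_occupancy_filtered.csv"),
                     row.names = FALSE)
  }
  energy <- NULL
  if (!is.null(scorer) && !is.null(complex_traj) && !is.null(chain_roles)) {
    energy <- binding_energy_series(complex_traj, chain_roles, scorer)
    utils::write.csv(as.data.frame(energy), file.path(out_dir, "energy_series.csv"),
                     row.names = FALSE)
  }
  if (length(notes)) writeLines(notes, file.path(out_dir, "notes.txt"))
  invisible(list(clusters = clusters, populations = populations,
                 mechanism = mechanism, rmsd_series = series,
                 representatives = reps, heatmap = heat,
                 occupancy = occupancy, energy = energy, notes = notes))
}
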