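# Fixed-radius (kclust-style) clustering of conformational ensembles and
# conformational-selection vs induced-fit classification.
#
# Plain k-means takes k; the fixed-radius variant used for MD conformer
# analysis takes a radius instead and spawns clusters on overflow: frames
# farther than the radius from every current centroid seed a new cluster.
# The procedure here is normative for this package: seed at the first frame,
# sequentially assign frames to the nearest centroid by superposed Cα RMSD
# (spawning when the nearest distance exceeds the radius), recompute
# centroids as member means after superposing members onto the current
# centroid, and iterate to a fixed point. Deterministic given frame order.

# extract centred coordinate stack (list of N x 3) for a trajectory
.frame_stack <- function(traj, selection) {
  idx <- resolve_selection(traj$models[[1]], selection)
  lapply(traj$models, function(m) {
    xyz <- as.matrix(m$atoms[idx, c("x", "y", "z")])
    sweep(xyz, 2, colMeans(xyz))
  })
}

.cluster_engine <- function(stack, radius, superpose = TRUE, max_iter = 100L) {
  nf <- length(stack)
  dist_fn <- if (superpose)
    function(A, B) .rmsd_superposed(A, B, centered = TRUE)
  else .rmsd_raw
  centroids <- list(stack[[1]])
  assign_vec <- integer(nf)
  converged <- FALSE
  iter <- 0L
  dists <- numeric(nf)
  repeat {
    iter <- iter + 1L
    new_assign <- integer(nf)
    for (f in seq_len(nf)) {
      d <- vapply(centroids, dist_fn, numeric(1), B = stack[[f]])
      j <- which.min(d)
      if (d[j] > radius) {
        centroids <- c(centroids, list(stack[[f]]))
        j <- length(centroids)
        d <- c(d, 0)
      }
      new_assign[f] <- j
      dists[f] <- d[j]
    }
    # recompute centroids as member means after superposition onto centroid
    new_centroids <- lapply(seq_along(centroids), function(j) {
      members <- which(new_assign == j)
      if (!length(members)) return(NULL)
      acc <- 0
      for (f in members) {
        B <- stack[[f]]
        if (superpose) {
          sv <- svd(crossprod(B, centroids[[j]]))
          s3 <- sign(det(sv$v %*% t(sv$u)))
          R <- sv$u %*% diag(c(1, 1, s3)) %*% t(sv$v)
          B <- B %*% R
        }
        acc <- acc + B
      }
      m <- acc / length(members)
      sweep(m, 2, colMeans(m))
    })
    drop <- vapply(new_centroids, is.null, logical(1))
    if (any(drop)) {
      remap <- cumsum(!drop)
      new_assign <- remap[new_assign]
      new_centroids <- new_centroids[!drop]
    }
    if (identical(new_assign, assign_vec) && length(new_centroids) == length(centroids)) {
      centroids <- new_centroids
      converged <- TRUE
      break
    }
    assign_vec <- new_assign
    centroids <- new_centroids
    if (iter >= max_iter) break
  }
  list(assignments = assign_vec, centroids = centroids, dists = dists,
       converged = converged, n_iter = iter)
}

.order_clusters <- function(eng) {
  sizes <- tabulate(eng$assignments, nbins = length(eng$centroids))
  first <- vapply(seq_along(eng$centroids),
                  function(j) min(which(eng$assignments == j)), integer(1))
  ord <- order(-sizes, first)
  remap <- match(seq_along(ord), ord)
  eng$assignments <- remap[eng$assignments]
  eng$centroids <- eng$centroids[ord]
  eng
}

.new_cluster_set <- function(eng, sources, radius, selection, superpose) {
  eng <- .order_clusters(eng)
  structure(list(
    radius = radius,
    centroids = eng$centroids,
    assignments = eng$assignments,
    sources = sources,
    selection = selection,
    centroid_dists = eng$dists,
    converged = eng$converged,
    n_iter = eng$n_iter,
    superpose = superpose
  ), class = "cluster_set")
}

#' Fixed-radius clustering of a trajectory
#'
#' @param traj An `ab_trajectory`.
#' @param selection An [atom_selection()] resolvable in every frame
#'   (default: all Cα atoms).
#' @param radius Cluster radius in Å (default 1.5): a frame farther than this
#'   from every centroid spawns a new cluster.
#' @param superpose Superpose each frame onto the centroid before measuring
#'   RMSD (default `TRUE`); `FALSE` uses raw RMSD, faster but
#'   orientation-sensitive.
#' @param max_iter Iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @param source Source label attached to every frame.
#' @return Object of class `cluster_set`: per-frame `assignments` (cluster
#'   indices ordered by descending membership, ties by first frame),
#'   `centroids` (centred mean coordinates), `sources`, `centroid_dists`,
#'   `converged`, `n_iter`.
#' @export
fixed_radius_kcluster <- function(traj, selection = atom_selection(),
                                  radius = 1.5, superpose = TRUE,
                                  max_iter = 100L, source = "traj") {
  stopifnot(inherits(traj, "ab_trajectory"))
  stack <- .frame_stack(traj, selection)
  eng <- .cluster_engine(stack, radius, superpose, max_iter)
  .new_cluster_set(eng, rep(source, length(stack)), radius, selection, superpose)
}

#' Joint clustering of bound and free ensembles
#'
#' Bound and free frames are pooled (bound first) with source labels and
#' clustered together, so that cluster indices are directly comparable across
#' the two forms — the same cluster index in both sources is the same
#' conformation.
#'
#' @param bound,free `ab_trajectory` objects of the antibody (antigen
#'   stripped) sharing the atom selection.
#' @inheritParams fixed_radius_kcluster
#' @return A `cluster_set` with `sources` in `{"bound", "free"}`.
#' @export
joint_cluster_landscape <- function(bound, free, selection = atom_selection(),
                                    radius = 1.5, superpose = TRUE,
                                    max_iter = 100L) {
  sb <- .frame_stack(bound, selection)
  sf <- .frame_stack(free, selection)
  if (nrow(sb[[1]]) != nrow(sf[[1]]))
    stop("atom selection resolves to different sizes in bound and free trajectories",
         call. = FALSE)
  eng <- .cluster_engine(c(sb, sf), radius, superpose, max_iter)
  .new_cluster_set(eng, c(rep("bound", length(sb)), rep("free", length(sf))),
                   radius, selection, superpose)
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- length(x$centroids)
  cat(sprintf("Fixed-radius cluster set: %d frames, %d cluster(s), radius %.2f Å (%s, %d iter)\n",
              length(x$assignments), k, x$radius,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(table(source = x$sources, cluster = x$assignments))
  invisible(x)
}

#' Per-source cluster population percentages
#'
#' The number of frames of each source falling in each cluster is expressed
#' as a percentage of that source's frames; the cluster with the highest
#' percentage is the source's dominant conformation (ties go to the smallest
#' cluster index).
#'
#' @param clusters A `cluster_set`.
#' @return Object of class `population_table`: data.frame with columns
#'   `source`, `cluster`, `n`, `percent`; attribute `dominant` is a named
#'   integer vector of the dominant cluster per source.
#' @export
population_fractions <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  k <- length(clusters$centroids)
  srcs <- unique(clusters$sources)
  rows <- do.call(rbind, lapply(srcs, function(s) {
    in_s <- clusters$sources == s
    n <- tabulate(clusters$assignments[in_s], nbins = k)
    data.frame(source = s, cluster = seq_len(k), n = n,
               percent = 100 * n / sum(in_s), stringsAsFactors = FALSE)
  }))
  dominant <- vapply(srcs, function(s) {
    p <- rows$percent[rows$source == s]
    which.max(p)  # ties -> smallest index
  }, integer(1))
  structure(rows, dominant = dominant, class = c("population_table", "data.frame"))
}

#' @export
print.population_table <- function(x, ...) {
  cat("Cluster populations (% of source frames):\n")
  print.data.frame(x[x$n > 0, ], digits = 4, row.names = FALSE)
  dom <- attr(x, "dominant")
  cat("Dominant cluster per source:",
      paste(sprintf("%s=%d", names(dom), dom), collapse = ", "), "\n")
  invisible(x)
}

#' Classify the binding mechanism from a joint population table
#'
#' An antibody binds by conformational selection when its bound-state
#' dominant conformation is also sampled by the free-state ensemble; if the
#' free form never visits the bound-dominant cluster (zero free frames), the
#' bound conformation must arise upon antigen contact: induced fit.
#'
#' @param populations A `population_table` from a joint (bound + free)
#'   `cluster_set`.
#' @return Object of class `mechanism_call`: list with `verdict`
#'   (`"conformational_selection"` or `"induced_fit"`),
#'   `bound_dominant_cluster`, `free_population_of_bound_dominant` and
#'   `bound_population` (both percent).
#' @export
classify_binding_mechanism <- function(populations) {
  stopifnot(inherits(populations, "population_table"))
  srcs <- unique(populations$source)
  if (!all(c("bound", "free") %in% srcs))
    stop("population table must contain both 'bound' and 'free' sources",
         call. = FALSE)
  dom <- attr(populations, "dominant")[["bound"]]
  bp <- populations$percent[populations$source == "bound" & populations$cluster == dom]
  fp <- populations$percent[populations$source == "free" & populations$cluster == dom]
  fn <- populations$n[populations$source == "free" & populations$cluster == dom]
  verdict <- if (fn == 0) "induced_fit" else "conformational_selection"
  structure(list(verdict = verdict,
                 bound_dominant_cluster = dom,
                 free_population_of_bound_dominant = fp,
                 bound_population = bp),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Binding mechanism: %s\n", x$verdict))
  cat(sprintf("  bound-dominant cluster %d: %.1f%% of bound frames, %.1f%% of free frames\n",
              x$bound_dominant_cluster, x$bound_population,
              x$free_population_of_bound_dominant))
  invisible(x)
}

#' RMSD-versus-time series with cluster labels
#'
#' @param traj An `ab_trajectory`.
#' @param reference A `structure_model` resolvable to the selection.
#' @param selection An [atom_selection()].
#' @param clusters Optional `cluster_set` whose first `n_frames(traj)`
#'   assignments label the frames.
#' @param superpose Superpose before measuring RMSD.
#' @return data.frame with columns `time_ns`, `rmsd`, `cluster`.
#' @export
rmsd_time_series <- function(traj, reference, selection = atom_selection(),
                             clusters = NULL, superpose = TRUE) {
  stack <- .frame_stack(traj, selection)
  ridx <- resolve_selection(reference, selection)
  ref <- as.matrix(reference$atoms[ridx, c("x", "y", "z")])
  ref <- sweep(ref, 2, colMeans(ref))
  r <- vapply(stack, function(B) {
    if (superpose) .rmsd_superposed(ref, B, centered = TRUE) else .rmsd_raw(ref, B)
  }, numeric(1))
  data.frame(
    time_ns = seq_along(stack) * traj$frame_interval / 1000,
    rmsd = r,
    cluster = if (is.null(clusters)) NA_integer_
              else clusters$assignments[seq_along(stack)]
  )
}

#' Representative frame of a cluster
#'
#' The member frame with the smallest (superposed) RMSD to the cluster
#' centroid; ties resolve to the smallest frame index.
#'
#' @param clusters A `cluster_set`.
#' @param cluster_index Cluster to summarise.
#' @return Frame index into the clustered trajectory.
#' @export
representative_frame <- function(clusters, cluster_index) {
  members <- which(clusters$assignments == cluster_index)
  if (!length(members)) stop("empty cluster", call. = FALSE)
  members[which.min(clusters$centroid_dists[members])]
}

#' Pairwise conformer heatmap matrix
#'
#' Builds the pairwise superposed backbone RMSD matrix over trajectory
#' conformers plus crystal-structure references, optionally rendered with
#' pheatmap.
#'
#' @param conformers Named list of `structure_model` conformers (names
#'   typically suffixed with their cluster index).
#' @param crystal_refs Optional named list of crystal `structure_model`s
#'   appended to the comparison.
#' @param selection Shared [atom_selection()] (default backbone N, CA, C, O).
#' @param image Optional path for a heatmap image (requires pheatmap).
#' @return The labelled symmetric RMSD matrix (Å).
#' @export
conformer_heatmap <- function(conformers, crystal_refs = NULL,
                              selection = atom_selection(atom_names = c("N", "CA", "C", "O")),
                              image = NULL) {
  all_models <- c(conformers, crystal_refs)
  m <- pairwise_rmsd_matrix(all_models, selection)
  if (!is.null(image)) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      warning("pheatmap not installed; skipping image rendering")
    else
      pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                         filename = image, silent = TRUE)
  }
  m
}

#' Per-frame binding-energy series under a pluggable scorer
#'
#' Applies a per-model energy scorer to the full complex, the antibody alone
#' (receptor) and the antigen alone (ligand) in each frame, and combines them
#' as `dG_bind = dG_complex - dG_receptor - dG_ligand`. A trailing-window
#' mean of `dG_bind` summarises the equilibrated tail of the trajectory.
#' Frames where the scorer fails are flagged and excluded from the window
#' mean.
#'
#' @param traj An `ab_trajectory` of the complex.
#' @param chain_roles Named character vector chain id -> role.
#' @param scorer Function taking a `structure_model` and returning a numeric
#'   energy (kcal/mol for physical scorers); see [contact_count_scorer()].
#' @param window Number of trailing frames averaged for `window_mean`.
#' @return Object of class `binding_energy_series`: data.frame with columns
#'   `frame`, `dG_complex`, `dG_receptor`, `dG_ligand`, `dG_bind`, `ok`;
#'   attribute `window_mean`.
#' @export
binding_energy_series <- function(traj, chain_roles, scorer,
                                  window = min(100L, n_frames(traj))) {
  stopifnot(inherits(traj, "ab_trajectory"))
  if (window > n_frames(traj)) stop("window exceeds trajectory length", call. = FALSE)
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    m <- traj$models[[f]]
    rec <- strip_antigen(m, chain_roles)
    ag <- names(chain_roles)[chain_roles == "antigen"]
    lig <- structure_model(m$atoms[m$atoms$chain_id %in% ag, , drop = FALSE],
                           m$model_index)
    vals <- tryCatch(
      c(scorer(m), scorer(rec), scorer(lig)),
      error = function(e) {
        warning(sprintf("scorer failed on frame %d: %s", f, conditionMessage(e)))
        rep(NA_real_, 3)
      })
    data.frame(frame = f, dG_complex = vals[1], dG_receptor = vals[2],
               dG_ligand = vals[3], dG_bind = vals[1] - vals[2] - vals[3],
               ok = all(is.finite(vals)))
  })
  out <- do.call(rbind, rows)
  tail_idx <- out$frame > n_frames(traj) - window
  wm <- mean(out$dG_bind[tail_idx & out$ok])
  structure(out, window_mean = wm, window = window,
            class = c("binding_energy_series", "data.frame"))
}

#' @export
print.binding_energy_series <- function(x, ...) {
  cat(sprintf("Binding-energy series over %d frames; trailing-%d-frame mean dG_bind = %.3f\n",
              nrow(x), attr(x, "window"), attr(x, "window_mean")))
  invisible(x)
}

#' Interface contact-count scorer
#'
#' A simple built-in scorer for the binding-energy pipeline: minus the number
#' of cross-chain heavy-atom pairs within `cutoff` Å. More interface contacts
#' give a lower (more favourable) score; single-chain subsets score by their
#' own inter-chain contacts (zero for one chain). Dimensionless — a stand-in
#' scoring function for exercising the combination rule, not a physical
#' energy.
#'
#' @param cutoff Contact distance cutoff in Å (default 4.5).
#' @return A scorer function suitable for [binding_energy_series()].
#' @export
contact_count_scorer <- function(cutoff = 4.5) {
  force(cutoff)
  function(model) {
    atoms <- model$atoms
    n <- nrow(atoms)
    if (n < 2L) return(0)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    ch <- atoms$chain_id
    total <- 0L
    chains <- unique(ch)
    k <- length(chains)
    if (k < 2L) return(0)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      A <- xyz[ch == chains[i], , drop = FALSE]
      B <- xyz[ch == chains[j], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
      total <- total + sum(d2 <= cutoff^2)
    }
    -as.numeric(total)
  }
}
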