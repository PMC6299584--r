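sel_H <- atom_selection(chains = "H")

toy_ensemble <- function(populations, seed, n_frames = 150, noise = 0.3,
                         separation = 6) {
  sc <- fixture_scaffold()
  make_conformer_ensemble(sc, fixture_cdr_idx(sc), populations = populations,
                          separation = separation, noise_sigma = noise,
                          n_frames = n_frames, seed = seed,
                          measure_selection = sel_H)
}

test_that("degenerate trajectories cluster trivially", {
  sc <- fixture_scaffold()
  one <- as_trajectory(list(sc), 10)
  cs1 <- fixed_radius_kcluster(one, sel_H)
  expect_equal(length(cs1$centroids), 1)
  expect_equal(cs1$assignments, 1L)
  # all frames identical -> one cluster
  same <- as_trajectory(rep(list(sc), 5), 10)
  cs <- fixed_radius_kcluster(same, sel_H, radius = 1.5)
  expect_equal(length(cs$centroids), 1)
  expect_true(all(cs$assignments == 1L))
  expect_true(cs$converged)
})

test_that("two displaced conformers are recovered exactly", {
  ens <- toy_ensemble(list(bound = c(1, 0), free = c(0.5, 0.5)), seed = 51,
                      n_frames = 200)
  cs <- joint_cluster_landscape(ens$bound, ens$free, sel_H, 1.5)
  expect_equal(length(cs$centroids), 2)
  # assignments match planted labels up to relabelling
  free_assign <- cs$assignments[cs$sources == "free"]
  tab <- table(free_assign, ens$ground_truth$labels$free)
  expect_equal(sum(apply(tab, 1, max)), length(free_assign))
  # frames sit within the radius of their centroid
  expect_gte(mean(cs$centroid_dists <= cs$radius), 0.95)
})

test_that("per-source populations sum to 100 and recover planted fractions", {
  ens <- toy_ensemble(list(bound = c(1, 0, 0), free = c(0.5, 0.3, 0.2)),
                      seed = 52, n_frames = 500)
  cs <- joint_cluster_landscape(ens$bound, ens$free, sel_H, 1.5)
  pop <- population_fractions(cs)
  for (s in c("bound", "free"))
    expect_equal(sum(pop$percent[pop$source == s]), 100, tolerance = 1e-6)
  free_pct <- sort(pop$percent[pop$source == "free" & pop$n > 0], decreasing = TRUE)
  expect_equal(free_pct, c(50, 30, 20), tolerance = 3 / 50)  # within ±3 points
  expect_equal(attr(pop, "dominant")[["bound"]], 1)
})

test_that("bound-within-free gives conformational selection, disjoint bound induced fit", {
  cs_ens <- toy_ensemble(list(bound = c(1, 0, 0), free = c(0.5, 0.3, 0.2)),
                         seed = 53)
  cs1 <- joint_cluster_landscape(cs_ens$bound, cs_ens$free, sel_H, 1.5)
  call1 <- classify_binding_mechanism(population_fractions(cs1))
  expect_equal(call1$verdict, "conformational_selection")
  expect_gt(call1$free_population_of_bound_dominant, 0)

  if_ens <- toy_ensemble(list(bound = c(0, 0, 1), free = c(0.6, 0.4, 0)),
                         seed = 54)
  cs2 <- joint_cluster_landscape(if_ens$bound, if_ens$free, sel_H, 1.5)
  call2 <- classify_binding_mechanism(population_fractions(cs2))
  expect_equal(call2$verdict, "induced_fit")
  expect_equal(call2$free_population_of_bound_dominant, 0)

  # identical bound and free -> conformational selection with equal populations
  same <- toy_ensemble(list(bound = c(1, 0), free = c(1, 0)), seed = 55,
                       n_frames = 60)
  cs3 <- joint_cluster_landscape(same$bound, same$free, sel_H, 1.5)
  call3 <- classify_binding_mechanism(population_fractions(cs3))
  expect_equal(call3$verdict, "conformational_selection")
  expect_equal(call3$free_population_of_bound_dominant, call3$bound_population)
})

test_that("mechanism call is invariant to frame order and cluster relabelling", {
  ens <- toy_ensemble(list(bound = c(1, 0), free = c(0.3, 0.7)), seed = 56,
                      n_frames = 100)
  cs <- joint_cluster_landscape(ens$bound, ens$free, sel_H, 1.5)
  v1 <- classify_binding_mechanism(population_fractions(cs))$verdict
  # reverse both trajectories
  rev_traj <- function(t) as_trajectory(rev(t$models), t$frame_interval)
  cs_r <- joint_cluster_landscape(rev_traj(ens$bound), rev_traj(ens$free),
                                  sel_H, 1.5)
  v2 <- classify_binding_mechanism(population_fractions(cs_r))$verdict
  expect_equal(v1, v2)
})

test_that("missing source is an error", {
  ens <- toy_ensemble(list(bound = c(1, 0), free = c(0.5, 0.5)), seed = 57,
                      n_frames = 40)
  cs <- fixed_radius_kcluster(ens$bound, sel_H, source = "bound")
  expect_error(classify_binding_mechanism(population_fractions(cs)),
               "both 'bound' and 'free'")
})

test_that("RMSD time series starts at zero for its own reference and tracks switches", {
  ens <- toy_ensemble(list(bound = c(1, 0), free = c(0.5, 0.5)), seed = 58,
                      n_frames = 60)
  ref <- ens$bound$models[[1]]
  ser <- rmsd_time_series(ens$bound, ref, sel_H)
  expect_equal(ser$rmsd[1], 0, tolerance = 1e-5)
  expect_true(all(diff(ser$time_ns) > 0))
  # two-state free trajectory: frames of the non-reference conformer are far
  lab <- ens$ground_truth$labels$free
  serf <- rmsd_time_series(ens$free, ens$free$models[[which(lab == 1)[1]]], sel_H)
  expect_gt(min(serf$rmsd[lab == 2]), 3)
  expect_lt(max(serf$rmsd[lab == 1]), 1.5)
})

test_that("representative frame equals the exhaustive member-to-centroid argmin", {
  ens <- toy_ensemble(list(bound = c(1, 0), free = c(0.5, 0.5)), seed = 59,
                      n_frames = 80)
  cs <- joint_cluster_landscape(ens$bound, ens$free, sel_H, 1.5)
  stack <- c(ablineage:::.frame_stack(ens$bound, sel_H),
             ablineage:::.frame_stack(ens$free, sel_H))
  for (k in seq_along(cs$centroids)) {
    members <- which(cs$assignments == k)
    d <- vapply(members, function(f)
      ablineage:::.rmsd_superposed(cs$centroids[[k]], stack[[f]], centered = TRUE),
      numeric(1))
    expect_equal(representative_frame(cs, k), members[which.min(d)])
  }
  expect_error(representative_frame(cs, 99), "empty cluster")
})

test_that("conformer heatmap shows within- vs between-scaffold block structure", {
  sc <- fixture_scaffold()
  cdr <- fixture_cdr_idx(sc)
  shift <- function(d, noise_seed) {
    m <- sc
    set.seed(noise_seed)
    m$atoms$x[cdr] <- m$atoms$x[cdr] + d
    m$atoms$x <- m$atoms$x + rnorm(nrow(m$atoms), sd = 0.1)
    m
  }
  confs <- list(a1 = shift(0, 1), a2 = shift(0, 2),
                b1 = shift(12, 3), b2 = shift(12, 4))
  m <- conformer_heatmap(confs, selection = atom_selection(chains = "H"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  within <- c(m["a1", "a2"], m["b1", "b2"])
  between <- c(m["a1", "b1"], m["a2", "b2"])
  expect_true(all(within < min(between)))
})

test_that("binding-energy combination identity holds for any scorer", {
  nb <- fixture_numbering()
  sc <- fixture_scaffold()
  cx <- make_complex_scaffold(sc, antigen_length = 15, seed = 13)
  traj <- as_trajectory(list(cx, cx, cx), 100)
  roles <- c(H = "heavy", L = "light", G = "antigen")

  fixed <- function(vals) function(model) {
    nch <- length(unique(model$atoms$chain_id))
    if (nch == 3) vals[1] else if (nch == 2) vals[2] else vals[3]
  }
  es <- binding_energy_series(traj, roles, fixed(c(-100, -30, -20)))
  expect_true(all(es$dG_bind == -50))
  expect_equal(attr(es, "window_mean"), -50)
  expect_true(all(es$dG_complex - es$dG_receptor - es$dG_ligand == es$dG_bind))

  zero <- binding_energy_series(traj, roles, function(m) 0)
  expect_true(all(unlist(zero[, c("dG_complex", "dG_receptor", "dG_ligand", "dG_bind")]) == 0))

  # scorer failure flags the frame and drops it from the window mean
  flaky_env <- new.env(); flaky_env$n <- 0
  flaky <- function(model) {
    flaky_env$n <- flaky_env$n + 1
    if (flaky_env$n == 1) stop("boom")
    -1
  }
  expect_warning(ef <- binding_energy_series(traj, roles, flaky), "failed on frame")
  expect_false(ef$ok[1])
  expect_true(all(ef$ok[-1]))
})

test_that("contact-count scorer makes dG_bind decrease with interface growth", {
  nb <- fixture_numbering()
  sc <- fixture_scaffold()
  roles <- c(H = "heavy", L = "light", G = "antigen")
  # antigen chain approaching the antibody over frames -> more contacts
  mk_frame <- function(gap) {
    g <- data.frame(atom_name = "CA", residue_name = "GLY", chain_id = "G",
                    residue_seq = 1:10,
                    x = sc$atoms$x[1:10], y = sc$atoms$y[1:10],
                    z = sc$atoms$z[1:10] + gap, element = "C",
                    stringsAsFactors = FALSE)
    structure_model(rbind(sc$atoms[, names(g)], g))
  }
  traj <- as_trajectory(lapply(c(20, 6, 4, 3), mk_frame), 100)
  es <- binding_energy_series(traj, roles, contact_count_scorer(4.5), window = 2)
  expect_true(all(diff(es$dG_bind) <= 0))
  expect_equal(es$dG_bind[1], 0)  # far apart: no interface contacts
  expect_lt(es$dG_bind[4], 0)
})
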