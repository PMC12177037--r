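# Quench-distance geometry: centres of mass, distance series, quench
# fractions and apo/bound contrasts.

test_that("center_of_mass matches identity, symmetry and direct-sum oracle", {
  one <- structure_model(data.frame(
    atom = "C1", element = "C", resid = "X", resno = 1, chain = "A",
    x = 3, y = 4, z = 0))
  expect_equal(center_of_mass(one), c(3, 4, 0))

  two <- structure_model(data.frame(
    atom = c("C1", "C2"), element = "C", resid = "X", resno = 1, chain = "A",
    x = c(0, 2), y = 0, z = 0))
  expect_equal(center_of_mass(two), c(1, 0, 0))

  set.seed(101)
  masses <- c(12, 14, 16, 1, 1)
  xyz <- matrix(rnorm(15, sd = 5), 5, 3)
  five <- structure_model(data.frame(
    atom = paste0("A", 1:5), element = "C", mass = masses, resid = "X",
    resno = 1, chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  oracle <- colSums(masses * xyz) / sum(masses)  # direct sum
  expect_equal(center_of_mass(five), oracle, tolerance = 1e-12)

  expect_error(center_of_mass(five, "B:9"), "B:9")
})

test_that("quencher_distances reproduces constructed and brute-force distances", {
  # 1-frame toy: Trp COM placed exactly 5 A from dye COM
  traj <- toy_trajectory(list(rbind(c(0, 0, 0), c(0, 5, 0))))
  ds <- quencher_distances(traj, quenchers = quencher_set("A:101"))
  expect_equal(unname(ds$distances[[1]][1, 1]), 5, tolerance = 1e-12)

  # 100 random frames, 3 quenchers: brute-force per-frame recomputation
  set.seed(7)
  frames <- lapply(1:100, function(f) matrix(rnorm(12, sd = 8), 4, 3))
  traj <- toy_trajectory(frames)
  ds <- quencher_distances(traj, quenchers = quencher_set(paste0("A:", 101:103)))
  oracle <- brute_distances(traj, q_resnos = 101:103)
  expect_equal(unname(ds$distances[[1]]), oracle[[1]], tolerance = 1e-10)
  # min-series <= every per-quencher series frame-wise
  expect_true(all(ds$min[[1]] <= ds$distances[[1]] + 1e-12))

  expect_error(quencher_distances(traj, quenchers = quencher_set("A:999")),
               "A:999")
})

test_that("distances are invariant under rigid motions", {
  set.seed(11)
  frames <- lapply(1:25, function(f) matrix(rnorm(9, sd = 6), 3, 3))
  traj <- toy_trajectory(frames)
  q <- quencher_set(paste0("A:", 101:102))
  d0 <- quencher_distances(traj, quenchers = q)

  # pure translation
  shifted <- apply_rigid(traj, list(R = diag(3), t = c(10, 10, 10)))
  d1 <- quencher_distances(shifted, quenchers = q)
  expect_equal(d1$distances, d0$distances, tolerance = 1e-10)

  # random proper rotations + translations
  for (k in 1:5) {
    dk <- quencher_distances(apply_rigid(traj, random_rigid()), quenchers = q)
    expect_equal(dk$distances, d0$distances, tolerance = 1e-8)
  }
})

test_that("quench_fraction counts frames and aggregates replicates correctly", {
  # all frames at 5 A -> fraction 1; alternating 5/15 -> 0.5
  all5 <- toy_trajectory(rep(list(rbind(c(0, 0, 0), c(5, 0, 0))), 6))
  qp <- quench_fraction(quencher_distances(all5, quenchers = quencher_set("A:101")))
  expect_equal(qp$fractions$mean, c(1, 1))

  alt <- toy_trajectory(lapply(1:10, function(f) {
    rbind(c(0, 0, 0), c(if (f %% 2) 5 else 15, 0, 0))
  }))
  qp <- quench_fraction(quencher_distances(alt, quenchers = quencher_set("A:101")))
  expect_equal(qp$fractions$mean, c(0.5, 0.5))

  # 3-replicate synthetic series vs hand-computed counts
  set.seed(23)
  mk_rep <- function() {
    frames <- lapply(1:40, function(f) matrix(rnorm(9, sd = 7), 3, 3))
    toy_trajectory(frames)$replicates[[1]]
  }
  model <- toy_topology(2)
  reps <- list(mk_rep(), mk_rep(), mk_rep())
  model[, c("x", "y", "z")] <- reps[[1]][, , 1]
  traj <- trajectory_ensemble(structure_model(as.data.frame(model)), reps, "apo")
  ds <- quencher_distances(traj, quenchers = quencher_set(paste0("A:", 101:102)))
  qp <- quench_fraction(ds, cutoff = 10)
  oracle <- brute_distances(traj, q_resnos = 101:102)
  frac_by_rep <- t(sapply(oracle, function(d) {
    c(mean(d[, 1] <= 10), mean(d[, 2] <= 10), mean(apply(d, 1, min) <= 10))
  }))
  expect_equal(unname(qp$per_replicate), unname(frac_by_rep), tolerance = 1e-12)
  expect_equal(qp$fractions$mean, unname(colMeans(frac_by_rep)), tolerance = 1e-12)
  expect_equal(qp$fractions$sd, unname(apply(frac_by_rep, 2, sd)), tolerance = 1e-12)

  # any-quencher fraction >= each per-quencher fraction, per replicate
  expect_true(all(qp$per_replicate[, "any"] >= qp$per_replicate[, 1] - 1e-12))
  expect_true(all(qp$per_replicate[, "any"] >= qp$per_replicate[, 2] - 1e-12))
})

test_that("histograms are count-normalised and consistent with fractions", {
  set.seed(31)
  frames <- lapply(1:200, function(f) matrix(rnorm(6, sd = 7), 2, 3))
  traj <- toy_trajectory(frames)
  ds <- quencher_distances(traj, quenchers = quencher_set("A:101"))
  qp <- quench_fraction(ds, cutoff = 10, bin_width = 0.5)
  expect_equal(unname(colSums(qp$histogram$prob)), c(1, 1), tolerance = 1e-9)
  # cutoff falls on a bin edge: histogram mass below it equals the raw
  # fraction to within one bin's mass
  below <- qp$histogram$breaks[-1] <= 10 + 1e-9
  hist_frac <- sum(qp$histogram$prob[below, "any"])
  raw_frac <- qp$fractions$mean[qp$fractions$quencher == "any"]
  max_bin <- max(qp$histogram$prob[, "any"])
  expect_lt(abs(hist_frac - raw_frac), max_bin + 1e-12)
})

test_that("compare_states reports apo-minus-bound deltas", {
  traj_a <- toy_trajectory(rep(list(rbind(c(0, 0, 0), c(5, 0, 0))), 10))
  traj_b <- toy_trajectory(lapply(1:10, function(f) {
    rbind(c(0, 0, 0), c(if (f <= 3) 5 else 15, 0, 0))
  }), state = "bound")
  q <- quencher_set("A:101")
  qa <- quench_fraction(quencher_distances(traj_a, quenchers = q))
  qb <- quench_fraction(quencher_distances(traj_b, quenchers = q))

  same <- compare_states(qa, qa)
  expect_equal(same$delta$delta, c(0, 0))

  cs <- compare_states(qa, qb)
  expect_equal(cs$delta$delta, c(0.7, 0.7), tolerance = 1e-12)
  expect_equal(cs$design_score, 0.7, tolerance = 1e-12)

  # mismatched quencher sets refuse to compare
  traj_c <- toy_trajectory(rep(list(rbind(c(0, 0, 0), c(5, 0, 0), c(9, 0, 0))), 4))
  qc <- quench_fraction(quencher_distances(
    traj_c, quenchers = quencher_set(paste0("A:", 101:102))))
  expect_error(compare_states(qa, qc), "quencher sets")
})

test_that("states simulated with known occlusion match the analytic contrast", {
  m <- tether_model()
  apo <- simulate_trajectory(m, "apo", frames = 4000, seed = 5)
  bnd <- simulate_trajectory(m, "bound", frames = 4000, seed = 6)
  q <- apo$quencher_selections
  qa <- quench_fraction(quencher_distances(apo$traj, quenchers = quencher_set(q)))
  qb <- quench_fraction(quencher_distances(bnd$traj, quenchers = quencher_set(q)))
  cs <- compare_states(qa, qb)
  expected_delta <- apo$expected$any - bnd$expected$any
  se <- sqrt(apo$expected$any * (1 - apo$expected$any) / 4000 +
               bnd$expected$any * (1 - bnd$expected$any) / 4000)
  expect_lt(abs(cs$design_score - expected_delta), 4 * se)
  expect_gt(cs$design_score, 0)
})

test_that("PDB and XYZ trajectory round-trips preserve distances", {
  set.seed(41)
  frames <- lapply(1:8, function(f) matrix(rnorm(6, sd = 6), 2, 3))
  traj <- toy_trajectory(frames)
  q <- quencher_set("A:101")
  d0 <- quencher_distances(traj, quenchers = q)

  pdb <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(traj, pdb)
  back <- read_pdb_trajectory(pdb)
  d1 <- quencher_distances(back, quenchers = q)
  expect_equal(d1$distances[[1]], d0$distances[[1]], tolerance = 1e-3)

  # XYZ: write by hand, read back with the topology
  xyz <- tempfile(fileext = ".xyz")
  con <- file(xyz, "w")
  for (f in seq_along(frames)) {
    a <- traj$replicates[[1]][, , f]
    writeLines(c(nrow(traj$model), paste("frame", f),
                 paste(traj$model$element, a[, 1], a[, 2], a[, 3])), con)
  }
  close(con)
  back2 <- read_xyz_trajectory(xyz, model = traj$model)
  d2 <- quencher_distances(back2, quenchers = q)
  expect_equal(d2$distances[[1]], d0$distances[[1]], tolerance = 1e-10)
})
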