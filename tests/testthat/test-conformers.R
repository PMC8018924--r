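toy4 <- function() {
  matrix(c(0, 0, 0,
           1.5, 0, 0,
           0, 1.2, 0,
           0, 0, 1.1), ncol = 3, byrow = TRUE)
}

test_that("kabsch RMSD is zero under rigid motion and symmetric", {
  a <- toy4()
  expect_equal(kabsch_rmsd(a, a), 0)
  moved <- sweep(a %*% rot3(0, 0, pi / 2), 2, c(-1, -2, -3))
  expect_lt(kabsch_rmsd(a, moved), 1e-8)
  set.seed(4)
  b <- a + matrix(rnorm(12, 0, 0.3), ncol = 3)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-12)
  expect_gte(kabsch_rmsd(a, b), 0)
  expect_error(kabsch_rmsd(a, a[1:3, ]), "mismatch")
})

test_that("kabsch RMSD matches numerical minimization over rotations", {
  a <- toy4()
  displaced <- a
  displaced[2, ] <- displaced[2, ] + c(0.4, -0.2, 0.3)
  expect_equal(kabsch_rmsd(a, displaced), rmsd_rotmin_oracle(a, displaced),
               tolerance = 1e-6)
  set.seed(5)
  for (rep in 1:5) {
    b <- a + matrix(rnorm(12, 0, 0.25), ncol = 3)
    b <- sweep(b %*% rot3(runif(1), runif(1), runif(1)), 2, rnorm(3))
    expect_equal(kabsch_rmsd(a, b), rmsd_rotmin_oracle(a, b), tolerance = 1e-6)
  }
})

test_that("kabsch RMSD agrees with an independent superposition routine", {
  set.seed(6)
  a <- matrix(rnorm(30), ncol = 3)
  b <- a + matrix(rnorm(30, 0, 0.4), ncol = 3)
  ours <- kabsch_rmsd(a, b)
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # reference routine prints 3 decimals
})

test_that("triangle inequality holds empirically on random triples", {
  set.seed(7)
  base <- matrix(rnorm(24), ncol = 3)
  for (rep in 1:20) {
    b <- base + matrix(rnorm(24, 0, 0.5), ncol = 3)
    c_ <- base + matrix(rnorm(24, 0, 0.5), ncol = 3)
    expect_lte(kabsch_rmsd(base, c_),
               kabsch_rmsd(base, b) + kabsch_rmsd(b, c_) + 1e-6)
  }
})

test_that("hydrogens are excluded from the RMSD by default", {
  atoms <- c("C", "C", "O", "H")
  a <- toy4()
  b <- a
  b[4, ] <- b[4, ] + c(2, 2, 2)  # move only the hydrogen
  expect_lt(kabsch_rmsd(a, b, atoms = atoms), 1e-8)
  expect_gt(kabsch_rmsd(a, b, atoms = atoms, include_hydrogens = TRUE), 0.5)
})

test_that("energy window retains strictly-below-threshold conformers", {
  cs <- conformer_set(rep(list(toy4()), 4), c(0, 4.9, 5.0, 6.2), rep("C", 4))
  kept <- energy_window_filter(cs)
  expect_equal(kept$energy, c(0, 4.9))
  expect_equal(attr(kept, "discarded"), c("conf_3", "conf_4"))

  one <- conformer_set(list(toy4()), 3.3, rep("C", 4))
  expect_equal(length(energy_window_filter(one)), 1L)
  flat <- conformer_set(rep(list(toy4()), 3), rep(1.5, 3), rep("C", 4))
  expect_equal(length(energy_window_filter(flat)), 3L)
  expect_error(energy_window_filter(cs[integer(0)]), "non-empty")
})

test_that("greedy clustering follows the energy-ordered first-fit rule", {
  a <- toy4()
  one <- greedy_rmsd_cluster(conformer_set(list(a), 0, rep("C", 4)))
  expect_equal(length(one$representatives), 1L)

  twin <- conformer_set(list(a, a), c(1, 0), rep("C", 4), ids = c("hi", "lo"))
  cl <- greedy_rmsd_cluster(twin)
  expect_equal(length(cl$representatives), 1L)
  expect_equal(cl$representatives$ids, "lo")  # lowest-energy member represents

  gen <- generate_conformers(n_clusters = 1, members = 1, n_atoms = 6, seed = 2)
  base <- gen$set$coords[[1]]
  near <- scale_to_rmsd_test(base, 0.3, seed = 21)
  far <- scale_to_rmsd_test(base, 0.8, seed = 22)
  expect_equal(kabsch_rmsd(base, near), 0.3, tolerance = 1e-6)
  trio <- conformer_set(list(base, near, far), c(0, 1, 2), rep("C", 6))
  cl3 <- greedy_rmsd_cluster(trio)
  expect_equal(unname(cl3$assignments), c(1L, 1L, 2L))
  # representatives provably >= cutoff apart
  reps <- cl3$representatives
  expect_gte(conformer_rmsd(reps, 1, 2), 0.5)
})

test_that("clustering the representatives again is idempotent", {
  gen <- generate_conformers(n_clusters = 4, members = 3, n_atoms = 8, seed = 9)
  cl <- greedy_rmsd_cluster(gen$set)
  again <- greedy_rmsd_cluster(cl$representatives)
  expect_equal(again$representatives$ids, cl$representatives$ids)
  # partition property: every conformer assigned, count bounded
  expect_equal(sort(names(cl$assignments)), sort(gen$set$ids))
  expect_lte(length(cl$representatives), length(gen$set))
})

test_that("lowest-energy selection sorts, truncates and keeps ties stable", {
  cs <- conformer_set(rep(list(toy4()), 6), c(2, 1, 3, 0, 5, 4), rep("C", 4))
  sel <- select_lowest(cs, 5)
  expect_equal(sel$energy, c(0, 1, 2, 3, 4))
  expect_equal(length(select_lowest(cs[1:3], 5)), 3L)  # "up to five"
  expect_equal(select_lowest(cs, 1)$energy, 0)         # global optimum only
  expect_error(select_lowest(cs, 0), "at least 1")
})

test_that("the reduction pipeline composes window, clustering and selection", {
  gen <- generate_conformers(n_clusters = 3, members = 4, n_atoms = 8,
                             energy_spread = 1, seed = 13)
  set <- gen$set
  set$energy[gen$truth == 3] <- set$energy[gen$truth == 3] + 10  # push outside window
  red <- reduce_conformers(set, window = 5, rmsd_cut = 0.5, k = 5)
  expect_equal(length(red$representatives), 2L)
  expect_equal(sort(red$discarded), sort(set$ids[gen$truth == 3]))
  tab <- cluster_table(red)
  expect_equal(nrow(tab), length(set))
  expect_equal(sum(tab$discarded), 4L)
})

test_that("multi-structure XYZ files round-trip coordinates and energies", {
  gen <- generate_conformers(n_clusters = 2, members = 2, n_atoms = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(gen$set, path)
  back <- read_xyz(path)
  expect_equal(back$energy, gen$set$energy, tolerance = 1e-10)
  expect_equal(back$atoms, gen$set$atoms)
  for (i in seq_along(back$coords)) {
    expect_equal(back$coords[[i]], gen$set$coords[[i]], tolerance = 1e-10)
  }
  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(read_xyz(empty), "empty XYZ file")
})
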