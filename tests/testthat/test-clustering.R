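# Kabsch RMSD and single-linkage clustering.

test_that("kabsch_rmsd is zero under rigid motion and matches bio3d", {
  set.seed(42)
  a <- matrix(rnorm(33), 11, 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)

  R <- pistack:::rotation_matrix(c(0.3, -1, 2), 113)
  b <- sweep(a %*% t(R), 2, -c(7, -3, 1))
  expect_lt(kabsch_rmsd(a, b), 1e-9)

  # independent oracle: bio3d's superposition RMSD on random pairs
  for (i in 1:20) {
    x <- matrix(rnorm(24), 8, 3)
    y <- x + matrix(rnorm(24, sd = 0.7), 8, 3)
    ref <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)),
                       fit = TRUE)                 # prints 3 decimals
    expect_lt(abs(kabsch_rmsd(x, y) - ref), 6e-4)
  }
  expect_error(kabsch_rmsd(matrix(0, 3, 3), matrix(0, 4, 3)), "identical")
})

test_that("optimal fit beats direct superposition and a rotation grid", {
  # 4-atom toy: square vs the same square puckered by +/-1 A out of plane;
  # coarse rotation-grid search can only approach the Kabsch optimum
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  pk <- sq + rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 1), c(0, 0, -1))
  opt <- kabsch_rmsd(sq, pk)
  grid_best <- Inf
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))) {
    for (ang in seq(0, 355, by = 5)) {
      R <- pistack:::rotation_matrix(ax, ang)
      m <- sq %*% t(R)
      m <- sweep(m, 2, colMeans(m) - colMeans(pk))
      grid_best <- min(grid_best, sqrt(mean(rowSums((m - pk)^2))))
    }
  }
  expect_lte(opt, grid_best + 1e-9)
  expect_lt(abs(opt - grid_best), 1e-3)
  # closed form for this symmetric pucker: the optimal rotation is the
  # identity, leaving each atom 1 A out of plane
  expect_equal(opt, 1, tolerance = 1e-9)
})

test_that("single linkage finds bundles, chains and singletons", {
  set.seed(8)
  ref1 <- matrix(rnorm(15, sd = 3), 5, 3)
  ref2 <- matrix(rnorm(15, sd = 3), 5, 3)   # genuinely different shape
  expect_gt(kabsch_rmsd(ref1, ref2), 3)
  bundle <- c(lapply(1:4, function(i) ref1 + matrix(rnorm(15, sd = 0.05), 5, 3)),
              lapply(1:3, function(i) ref2 + matrix(rnorm(15, sd = 0.05), 5, 3)))
  cl <- single_linkage_cluster(bundle, cutoff = 2)
  expect_equal(length(cl$clusters), 2L)
  expect_equal(lengths(cl$clusters), c(4L, 3L))

  # chaining: consecutive frames ~1.5 A apart link into one cluster even
  # though the ends are far apart (per-atom alternating displacements so
  # the optimal fit cannot undo them as a translation)
  chain <- lapply(0:4, function(i) ref1 + i * 1.5 *
                    matrix(rep_len(c(1, -1), 15), 5, 3) / sqrt(3))
  d01 <- kabsch_rmsd(chain[[1]], chain[[2]])
  dend <- kabsch_rmsd(chain[[1]], chain[[5]])
  expect_lt(d01, 2)
  expect_gt(dend, 2)
  cl2 <- single_linkage_cluster(chain, cutoff = 2)
  expect_equal(length(cl2$clusters), 1L)

  cl3 <- single_linkage_cluster(list(ref1), cutoff = 2)
  expect_equal(length(cl3$clusters), 1L)
  expect_equal(cl3$representatives, 1L)
})

test_that("clusters equal brute-force components and survive reordering", {
  set.seed(99)
  centers <- list(matrix(rnorm(12), 4, 3),
                  matrix(rnorm(12), 4, 3) + 8,
                  matrix(rnorm(12), 4, 3) - 8)
  frames <- lapply(1:60, function(i)
    centers[[sample(3, 1)]] + matrix(rnorm(12, sd = 0.4), 4, 3))
  cl <- single_linkage_cluster(frames, cutoff = 2)

  # oracle: thresholded RMSD matrix (bio3d) + union-find components
  n <- length(frames)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- bio3d::rmsd(as.vector(t(frames[[i]])), as.vector(t(frames[[j]])),
                     fit = TRUE)
    adj[i, j] <- adj[j, i] <- r < 2
  }
  comp <- uf_components(adj)
  # same partition up to labels
  expect_equal(length(unique(comp)), length(cl$clusters))
  for (k in seq_along(cl$clusters)) {
    members <- cl$clusters[[k]]
    expect_equal(length(unique(comp[members])), 1L)
    expect_equal(sum(comp == comp[members[1]]), length(members))
  }

  # reordering frames permutes the partition but not its shape
  perm <- sample(n)
  cl_p <- single_linkage_cluster(frames[perm], cutoff = 2)
  expect_equal(sort(lengths(cl_p$clusters)), sort(lengths(cl$clusters)))
  remapped <- lapply(cl_p$clusters, function(m) sort(perm[m]))
  expect_setequal(vapply(remapped, paste, character(1), collapse = ","),
                  vapply(lapply(cl$clusters, sort), paste, character(1),
                         collapse = ","))
})

test_that("representatives are medoids of the largest clusters", {
  set.seed(61)
  base <- matrix(rnorm(15), 5, 3)
  # cluster of 3 in which frame 2 sits between frames 1 and 3 (distinct
  # single-atom distortions), plus a singleton of a different shape
  f1 <- base; f1[1, ] <- f1[1, ] + c(1.5, 0, 0)
  f3 <- base; f3[2, ] <- f3[2, ] + c(0, 1.5, 0)
  lone <- matrix(rnorm(15, sd = 5), 5, 3)
  frames <- list(f1, base, f3, lone)
  expect_gt(min(sapply(frames[1:3], kabsch_rmsd, b = lone)), 2)
  d12 <- kabsch_rmsd(f1, base); d23 <- kabsch_rmsd(base, f3)
  d13 <- kabsch_rmsd(f1, f3)
  expect_true(d13 > d12 && d13 > d23 && d13 < 2)  # frame 2 is the medoid
  cl <- single_linkage_cluster(frames, cutoff = 2)
  expect_equal(lengths(cl$clusters), c(3L, 1L))
  expect_equal(cl$representatives, c(2L, 4L))
})
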