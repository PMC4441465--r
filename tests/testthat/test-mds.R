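named_dist <- function(pts) {
  D <- as.matrix(dist(pts))
  ids <- sprintf("p%02d", seq_len(nrow(pts)))
  dimnames(D) <- list(ids, ids)
  D
}

test_that("an all-zero distance matrix collapses to the origin with stress 0", {
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cfg <- suppressWarnings(classical_mds(D, q = 2))
  expect_equal(unname(cfg$coords), matrix(0, 3, 2))
  st <- suppressWarnings(stress1(D, cfg))
  expect_equal(st$stress1, 0)
})

test_that("unit-square corners are recovered exactly in two dimensions", {
  pts <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  D <- named_dist(pts)
  cfg <- classical_mds(D, q = 2)
  expect_lt(max(abs(as.matrix(dist(cfg$coords)) - D)), 1e-9)
  st <- stress1(D, cfg)
  expect_lte(st$stress1, 1e-6)
  # independent cross-check against stats::cmdscale
  ref <- cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(cfg$coords)), as.matrix(dist(ref)),
               tolerance = 1e-9)
})

test_that("Euclidean matrices of rank <= q are reproduced to 1e-9", {
  set.seed(4)
  pts <- matrix(runif(30), 10, 3)
  D <- named_dist(pts)
  cfg <- classical_mds(D, q = 3)
  expect_lt(max(abs(as.matrix(dist(cfg$coords)) - D)), 1e-9)
  # eigenvalues beyond the intrinsic rank are ~0
  expect_lt(max(abs(cfg$eigenvalues[4:10])), 1e-9)
  # rank-2 truncation matches the cmdscale rank-2 solution
  cfg2 <- classical_mds(D, q = 2)
  ref2 <- cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(cfg2$coords)), as.matrix(dist(ref2)),
               tolerance = 1e-9)
})

test_that("double centering zeroes row and column sums", {
  set.seed(6)
  D <- named_dist(matrix(runif(40), 10, 4))
  n <- nrow(D)
  D2 <- D * D
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  expect_lt(max(abs(rowSums(B))), 1e-9)
  expect_lt(max(abs(colSums(B))), 1e-9)
  # implementation's eigenvalues are those of B
  cfg <- classical_mds(D, q = 2)
  expect_equal(cfg$eigenvalues, eigen(B, symmetric = TRUE)$values,
               tolerance = 1e-9)
})

test_that("the eigenvector sign convention makes maps reproducible", {
  set.seed(10)
  D <- named_dist(matrix(runif(24), 8, 3))
  cfg <- classical_mds(D, q = 3)
  for (j in seq_len(3)) {
    expect_gt(cfg$coords[which.max(abs(cfg$coords[, j])), j], 0)
  }
  expect_identical(classical_mds(D, q = 3)$coords, cfg$coords)
})

test_that("a perfect configuration has stress 0 with f the identity", {
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  pts <- pts / max(dist(pts)) # keep distances inside the DSSIM range [0, 2]
  D <- named_dist(pts)
  cfg <- structure(list(ids = rownames(D), coords = pts, q = 2,
                        eigenvalues = numeric(8), scaled = FALSE),
                   class = "map_configuration")
  st <- stress1(D, cfg)
  expect_equal(st$stress1, 0, tolerance = 1e-12)
  expect_equal(st$a, 1, tolerance = 1e-9)
  expect_equal(st$b, 0, tolerance = 1e-9)
})

test_that("Stress-1 is non-increasing in the embedding dimension", {
  set.seed(19)
  for (rep in 1:3) {
    # non-Euclidean in 2D: distances from a 6-D cloud
    D <- named_dist(matrix(runif(60), 10, 6))
    st <- vapply(1:3, function(q) {
      stress1(D, classical_mds(D, q = q))$stress1
    }, numeric(1))
    expect_true(all(diff(st) <= 1e-12))
  }
})

test_that("Stress-1 is invariant under rigid motions of the configuration", {
  set.seed(25)
  D <- named_dist(matrix(runif(50), 10, 5))
  cfg <- classical_mds(D, q = 2)
  base <- stress1(D, cfg)$stress1
  qr_q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  rotated <- cfg
  rotated$coords <- sweep(cfg$coords %*% qr_q, 2, c(3, -1), `+`)
  expect_equal(stress1(D, rotated)$stress1, base, tolerance = 1e-9)
})

test_that("degenerate regressions fall back to a = 0 with a warning", {
  D <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  cfg <- classical_mds(D, q = 2)
  expect_warning(st <- stress1(D, cfg), "regression undefined")
  expect_equal(st$a, 0)
  expect_equal(st$b, mean(dist(cfg$coords)))
})

test_that("scale_map sends each axis onto [-1, 1]", {
  cfg <- structure(list(ids = c("a", "b", "c"),
                        coords = cbind(dim1 = c(2, 3, 4), dim2 = c(0, 1, 5)),
                        q = 2, eigenvalues = numeric(3), scaled = FALSE),
                   class = "map_configuration")
  scaled <- scale_map(cfg)
  expect_equal(unname(scaled$coords[, 1]), c(-1, 0, 1))
  expect_equal(range(scaled$coords[, 2]), c(-1, 1))
  expect_equal(unname(scaled$scaling_record[, "dim1"]), c(2, 4))
  # a scaled configuration is a fixed point
  expect_equal(scale_map(scaled)$coords, scaled$coords)
  # postcondition on arbitrary configurations
  set.seed(30)
  cfg$coords <- matrix(rnorm(6, sd = 10), 3, 2,
                       dimnames = list(NULL, c("dim1", "dim2")))
  out <- scale_map(cfg)$coords
  expect_equal(unname(apply(out, 2, range)), matrix(c(-1, 1, -1, 1), 2))
})

test_that("degenerate axes scale to zero with a warning", {
  cfg <- structure(list(ids = c("a", "b", "c"),
                        coords = cbind(dim1 = c(1, 2, 3), dim2 = c(7, 7, 7)),
                        q = 2, eigenvalues = numeric(3), scaled = FALSE),
                   class = "map_configuration")
  expect_warning(scaled <- scale_map(cfg), "degenerate")
  expect_equal(unname(scaled$coords[, 2]), c(0, 0, 0))
})

test_that("dimension bounds and deficient spectra are handled", {
  D <- named_dist(matrix(runif(12), 4, 3))
  expect_error(classical_mds(D, q = 0), "between 1 and")
  expect_error(classical_mds(D, q = 4), "between 1 and")
  # 3 collinear points have rank-1 spectrum: q = 2 warns and zero-fills
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  D <- named_dist(pts)
  expect_warning(cfg <- classical_mds(D, q = 2), "positive eigenvalue")
  expect_equal(unname(cfg$coords[, 2]), rep(0, 3))
  expect_lt(max(abs(as.matrix(dist(cfg$coords)) - D)), 1e-9)
})
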