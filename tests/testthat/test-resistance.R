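test_that("resistance surface modes encode the standard hypotheses", {
  v <- matrix(c(1, 0, 1, 0), 2, 2)
  r <- raster_grid(v, cellsize = 1, xll = 0, yll = 0)
  hab <- build_resistance_surface(r, "habitat")
  expect_setequal(unique(as.vector(hab$values)), c(0.1, 0.9))
  nul <- build_resistance_surface(r, "null")
  expect_true(all(nul$values == 0.5))
  raw <- build_resistance_surface(r, "raw")
  expect_true(all(raw$values[v == 0] == 0.001))  # zero replacement
  inv <- build_resistance_surface(raster_grid(matrix(1:4, 2, 2), 1, 0, 0),
                                  "invert")
  expect_equal(sort(unique(as.vector(inv$values))), c(0.001, 1, 2, 3))
  expect_error(build_resistance_surface(raster_grid(matrix(c(-1, 1), 1, 2),
                                                    1, 0, 0), "raw"),
               "negative")
})

test_that("cropping keeps a one-degree buffer around the sample extent", {
  v <- matrix(1, 40, 40)
  r <- raster_grid(v, cellsize = 0.25, xll = 0, yll = 0)
  pts <- data.frame(lon = c(4, 5), lat = c(4, 6))
  s <- build_resistance_surface(r, "raw", points = pts, buffer = 1)
  cc <- raster_cell_centers(s)
  expect_true(min(cc$x) >= 3 - 0.25 && max(cc$x) <= 6 + 0.25)
  expect_true(min(cc$y) >= 3 - 0.25 && max(cc$y) <= 7 + 0.25)
})

test_that("ESRI ASCII grids round-trip", {
  set.seed(2)
  v <- matrix(runif(35), 5, 7)
  v[2, 3] <- NA
  r <- raster_grid(v, cellsize = 0.5, xll = -40, yll = -10)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
  expect_equal(r2$cellsize, 0.5)
  expect_equal(r2$xll, -40)
  expect_equal(r2$yll, -10)
})

test_that("chain rasters obey the series-resistor law", {
  for (k in c(3, 6, 11)) {
    r <- raster_grid(matrix(2, 1, k), cellsize = 1, xll = 0, yll = 0)
    s <- build_resistance_surface(r, "raw")
    pts <- data.frame(lon = c(0.5, k - 0.5), lat = c(0.5, 0.5))
    R <- pairwise_circuit_resistance(s, pts, neighbors = 4)
    expect_equal(R[1, 2], 2 * (k - 1), tolerance = 1e-10)
  }
})

test_that("2x2 uniform grid matches the parallel/series reduction", {
  r <- raster_grid(matrix(1, 2, 2), cellsize = 1, xll = 0, yll = 0)
  s <- build_resistance_surface(r, "raw")
  pts <- data.frame(lon = c(0.5, 1.5), lat = c(1.5, 0.5))  # opposite corners
  R <- pairwise_circuit_resistance(s, pts, neighbors = 4)
  # unit square of unit resistors, opposite corners: R = 1 (two 2-ohm paths
  # in parallel)
  expect_equal(R[1, 2], 1, tolerance = 1e-10)
  pts2 <- data.frame(lon = c(0.5, 1.5), lat = c(1.5, 1.5))  # adjacent corners
  R2 <- pairwise_circuit_resistance(s, pts2, neighbors = 4)
  # adjacent corners of the square: 1 || 3 = 3/4
  expect_equal(R2[1, 2], 3 / 4, tolerance = 1e-10)
})

test_that("sparse solver matches the dense Laplacian pseudoinverse", {
  for (seed in 1:6) {
    set.seed(seed)
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    v <- matrix(exp(rnorm(nr * nc, 0, 0.8)), nr, nc)
    s <- build_resistance_surface(raster_grid(v, 1, 0, 0), "raw")
    np <- 5
    pts <- data.frame(lon = runif(np, 0, nc), lat = runif(np, 0, nr))
    R <- pairwise_circuit_resistance(s, pts)
    gl <- nmlpe:::grid_laplacian(s, 8, "conductance")
    Lp <- MASS::ginv(as.matrix(gl$L))
    cells <- t(vapply(seq_len(np), function(i)
      raster_cell_at(s, pts$lon[i], pts$lat[i]), integer(2)))
    f <- gl$node[cells]
    Rd <- outer(diag(Lp)[f], diag(Lp)[f], "+") - 2 * Lp[f, f]
    diag(Rd) <- 0
    expect_lt(max(abs(R - Rd)) / max(Rd), 1e-8)
  }
})

test_that("effective resistance is linear, metric, and monotone in cell resistance", {
  set.seed(4)
  v <- matrix(exp(rnorm(64, 0, 0.5)), 8, 8)
  s <- build_resistance_surface(raster_grid(v, 1, 0, 0), "raw")
  pts <- data.frame(lon = runif(5, 0, 8), lat = runif(5, 0, 8))
  R <- pairwise_circuit_resistance(s, pts)
  # linearity under global scaling
  s2 <- build_resistance_surface(raster_grid(2 * v, 1, 0, 0), "raw")
  expect_equal(pairwise_circuit_resistance(s2, pts), 2 * R, tolerance = 1e-10)
  # triangle inequality
  for (a in 1:5) for (b in 1:5) for (cc in 1:5)
    expect_lte(R[a, b], R[a, cc] + R[cc, b] + 1e-10)
  # Rayleigh monotonicity: raising one cell's resistance never lowers any
  # pairwise effective resistance
  for (k in 1:20) {
    v2 <- v
    cell <- c(sample(8, 1), sample(8, 1))
    v2[cell[1], cell[2]] <- v2[cell[1], cell[2]] * (1 + runif(1, 0.5, 3))
    sp <- build_resistance_surface(raster_grid(v2, 1, 0, 0), "raw")
    Rp <- pairwise_circuit_resistance(sp, pts)
    expect_true(all(Rp - R >= -1e-10))
  }
})

test_that("nodata handling: point errors, disconnection yields Inf", {
  v <- matrix(1, 5, 5)
  v[, 3] <- NA  # vertical barrier splits the grid
  r <- raster_grid(v, cellsize = 1, xll = 0, yll = 0)
  r$values[, 3] <- NA
  s <- build_resistance_surface(r, "raw")
  s$values[, 3] <- NA
  expect_error(pairwise_circuit_resistance(s, data.frame(lon = 2.5, lat = 2.5)),
               "nodata")
  pts <- data.frame(lon = c(0.5, 4.5), lat = c(2.5, 2.5))
  expect_warning(R <- pairwise_circuit_resistance(s, pts), "disconnected")
  expect_true(is.infinite(R[1, 2]))
})

test_that("null-surface resistance is monotone in straight-line distance", {
  r <- raster_grid(matrix(1, 30, 30), cellsize = 1, xll = 0, yll = 0)
  s <- build_resistance_surface(r, "null")
  set.seed(9)
  # keep points away from edges where boundary effects distort the field
  pts <- data.frame(lon = runif(8, 8, 22), lat = runif(8, 8, 22))
  R <- pairwise_circuit_resistance(s, pts)
  D <- as.matrix(dist(pts))
  ut <- upper.tri(R)
  expect_gt(cor(R[ut], D[ut], method = "spearman"), 0.9)
})
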