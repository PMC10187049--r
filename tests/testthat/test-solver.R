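test_that("zero reaction relaxes to the bulk concentration everywhere", {
  g <- tinyGrid()
  f <- soluteField("glucose", g, bulk = 2, init = 0)
  out <- solveSteady(f, g, settings = solverSettings(tol = 1e-8))
  expect_equal(max(abs(out@conc - 2)), 0, tolerance = 1e-7)
})

test_that("1D column with uniform sink matches the closed-form parabola", {
  # single-column domain: periodic lateral faces make the problem 1D in z
  g <- domainGrid(side = c(8, 8, 136), voxelSize = 8, boundaryLayer = 8)
  D <- 2.1e4; Sb <- 2; q <- 2  # consumption g/L/h
  f <- soluteField("glucose", g, bulk = Sb, diffusivity = D, init = Sb)
  d <- gridDims(g)
  mask <- array(FALSE, dim = d); mask[, , d[3]] <- TRUE
  out <- solveSteady(f, g, constRate = array(-q, dim = d), bulkMask = mask,
                     settings = solverSettings(tol = 1e-10))
  zc <- (seq_len(d[3]) - 0.5) * g@voxelSize
  zb <- zc[d[3]]                     # Dirichlet node
  exact <- Sb - q / (2 * D) * (zb^2 - zc^2)
  expect_equal(as.numeric(out@conc[1, 1, ]), exact, tolerance = 1e-4)
  expect_equal(as.numeric(out@conc[1, 1, ]), exact, tolerance = 1e-6)
})

test_that("overwhelming constant sink floors concentrations at zero", {
  g <- tinyGrid()
  d <- gridDims(g)
  f <- soluteField("oxygen", g, bulk = 0.0064, init = 0.0064)
  sink <- array(0, dim = d); sink[, , 1:2] <- -1e3
  out <- solveSteady(f, g, constRate = sink,
                     settings = solverSettings(tol = 1e-6))
  expect_true(all(out@conc >= 0))
  expect_equal(min(out@conc), 0)
})

test_that("steady solution is independent of initialization", {
  g <- tinyGrid()
  d <- gridDims(g)
  vm <- array(-0.5, dim = d)  # Monod sink everywhere
  grp <- list(list(vmax = vm, K = 0.5))
  s <- solverSettings(tol = 1e-8)
  fromZero <- solveSteady(soluteField("glucose", g, bulk = 2, init = 0),
                          g, grp, settings = s)
  fromBulk <- solveSteady(soluteField("glucose", g, bulk = 2, init = 2),
                          g, grp, settings = s)
  expect_equal(fromZero@conc, fromBulk@conc, tolerance = 1e-6)
  expect_true(all(fromZero@conc >= 0 & fromZero@conc <= 2))
})

test_that("transient step conserves mass exactly under zero-flux boundaries", {
  g <- tinyGrid()
  d <- gridDims(g)
  f <- soluteField("surfactant", g)
  # uniform field is a diffusion fixed point
  fu <- f; fu@conc <- array(0.3, dim = d)
  out <- stepTransient(fu, g, NULL, dt = 0.05)
  expect_equal(out@conc, fu@conc, tolerance = 1e-14)
  # a single source voxel adds exactly rate * voxel volume * dt
  src <- array(0, dim = d); src[5, 5, 2] <- 7.5
  out2 <- stepTransient(f, g, src, dt = 0.05)
  gained <- sum(out2@conc) * voxelVolume(g)
  expect_equal(gained, 7.5 * voxelVolume(g) * 0.05, tolerance = 1e-12)
  expect_true(all(out2@conc >= 0))
  # and the total is conserved by further pure diffusion
  out3 <- stepTransient(out2, g, NULL, dt = 0.5)
  expect_equal(sum(out3@conc), sum(out2@conc), tolerance = 1e-12)
})

test_that("mirrored sources give a mirror-symmetric field", {
  g <- tinyGrid()
  d <- gridDims(g)
  f <- soluteField("inhibitor", g)
  src <- array(0, dim = d)
  src[2, 4, 3] <- 1; src[d[1] - 1, 4, 3] <- 1  # mirror pair about x-center
  out <- stepTransient(f, g, src, dt = 0.2)
  mirrored <- out@conc[rev(seq_len(d[1])), , ]
  expect_equal(out@conc, mirrored, tolerance = 1e-12)
})

test_that("halving the voxel size leaves the 16-h biovolume nearly unchanged", {
  cfg8 <- runConfig("COMPETITION", seed = 5)
  cfg4 <- runConfig("COMPETITION", seed = 5, grid = domainGrid(voxelSize = 4))
  b8 <- biovolume(finalState(runSimulation(cfg8, seed = 5)))
  b4 <- biovolume(finalState(runSimulation(cfg4, seed = 5)))
  expect_lt(abs(b4 - b8) / b8, 0.10)
})
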