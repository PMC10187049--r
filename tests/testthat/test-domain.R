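test_that("grid geometry and invariants", {
  g <- domainGrid()
  expect_equal(gridDims(g), c(17L, 17L, 17L))
  expect_equal(substratumArea(g), 18496)
  expect_equal(voxelVolume(g), 512)
  expect_error(domainGrid(side = 100, voxelSize = 8), "multiple")
  expect_error(domainGrid(voxelSize = -1))
  expect_error(domainGrid(boundaryLayer = 200), "boundaryLayer")
})

test_that("localConcentration uses the containing voxel", {
  g <- tinyGrid()
  f <- soluteField("glucose", g, bulk = 2)
  # uniform field: any interior position reads the bulk value
  expect_equal(localConcentration(f, g, c(1, 1, 1)), 2)
  expect_equal(localConcentration(f, g, c(63, 63, 63)), 2)
  f0 <- soluteField("inhibitor", g)
  expect_equal(localConcentration(f0, g, c(30, 30, 30)), 0)
  # voxel convention: half-open [i*h, (i+1)*h)
  f@conc[2, 1, 1] <- 5
  expect_equal(localConcentration(f, g, c(8, 0, 0)), 5)
  expect_equal(localConcentration(f, g, c(7.999, 0, 0)), 2)
  # periodic wrap in x
  expect_equal(localConcentration(f, g, c(8 + 64, 0, 0)), 5)
  # out of domain in z errors
  expect_error(localConcentration(f, g, c(1, 1, 65)), "outside")
  expect_error(localConcentration(f, g, c(1, 1, -1)), "outside")
})

test_that("periphery contains exposed cells and excludes enclosed ones", {
  g <- tinyGrid()
  # a single cell alone on the substratum is periphery
  st <- stateWith(agentRow(1), g)
  expect_equal(peripheryAgents(st), 1L)
  # a cell whose full 26-neighborhood is occupied is excluded
  h <- g@voxelSize
  rows <- list()
  id <- 1L
  for (dk in 0:2) for (dj in -1:1) for (di in -1:1) {
    rows[[length(rows) + 1]] <- agentRow(id, x = 20 + di * h, y = 20 + dj * h,
                                         z = 4 + dk * h)
    id <- id + 1L
  }
  ag <- do.call(rbind, rows)
  st <- stateWith(ag, g)
  per <- peripheryAgents(st)
  center <- ag$id[ag$x == 20 & ag$y == 20 & abs(ag$z - 12) < 1e-9]
  expect_false(center %in% per)       # enclosed on all 26 sides
  # the cell below the center is also enclosed: the substratum wall below
  # it counts as occupied, everything else around it is biomass
  bottomCenter <- ag$id[ag$x == 20 & ag$y == 20 & abs(ag$z - 4) < 1e-9]
  expect_false(bottomCenter %in% per)
  expect_true(all(setdiff(ag$id, c(center, bottomCenter)) %in% per))
  # planktonic agents are never periphery
  ag2 <- agentRow(99, state = "PLANKTONIC", z = 40)
  st2 <- stateWith(rbind(agentRow(1), ag2), g)
  expect_equal(peripheryAgents(st2), 1L)
  # no biofilm agents -> empty set
  st3 <- stateWith(agentRow(1, state = "PLANKTONIC", z = 40), g)
  expect_length(peripheryAgents(st3), 0)
})

test_that("periphery can only grow when agents are removed", {
  set.seed(11)
  g <- tinyGrid()
  h <- g@voxelSize
  n <- 60
  ag <- do.call(rbind, lapply(seq_len(n), function(i)
    agentRow(i, x = runif(1, 16, 48), y = runif(1, 16, 48),
             z = runif(1, 1, 20))))
  st <- stateWith(ag, g)
  before <- peripheryAgents(st)
  for (drop in sample(n, 5)) {
    st2 <- stateWith(ag[ag$id != drop, ], g)
    after <- peripheryAgents(st2)
    expect_true(all(setdiff(before, drop) %in% after))
  }
})

test_that("translating all agents by one lateral period is equivalent", {
  set.seed(3)
  g <- tinyGrid()
  ag <- do.call(rbind, lapply(1:12, function(i)
    agentRow(i, x = runif(1, 0, 64), y = runif(1, 0, 64), z = runif(1, 1, 10))))
  st <- stateWith(ag, g)
  agT <- ag
  agT$x <- agT$x + g@sideX
  stT <- stateWith(agT, g)
  expect_equal(biovolume(stT), biovolume(st))
  expect_equal(sort(peripheryAgents(stT)), sort(peripheryAgents(st)))
  expect_equal(biofilmThickness(stT), biofilmThickness(st))
})

test_that("stored radii stay consistent with masses through engine steps", {
  cfg <- tinyConfig(duration = 0.5)
  tr <- runSimulation(cfg)
  ag <- agents(finalState(tr))
  for (s in names(cfg@species)) {
    p <- cfg@species[[s]]
    sel <- ag$species == s
    expect_equal(ag$radius_um[sel],
                 agentRadius(ag$biomass_fg[sel], ag$capsule_fg[sel],
                             p@rhoBiomass, p@rhoCapsule),
                 tolerance = 1e-9)
  }
})
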