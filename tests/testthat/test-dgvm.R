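test_that("co-limitation equals the quadratic's smaller root and is gradual", {
  # oracle: solve theta c^2 - (x + y) c + x y = 0 numerically
  quadRoot <- function(x, y, theta) {
    r <- polyroot(c(x * y, -(x + y), theta))
    min(Re(r[abs(Im(r)) < 1e-9]))
  }
  expect_equal(colimit(0.6, 0.9, theta = 0.8), quadRoot(0.6, 0.9, 0.8),
               tolerance = 1e-12)
  for (x in c(0.1, 0.5, 0.95)) for (y in c(0.2, 0.8)) {
    c2 <- colimit(x, y, theta = 0.8)
    expect_equal(c2, quadRoot(x, y, 0.8), tolerance = 1e-10)
    expect_lte(c2, min(x, y) + 1e-12)    # never exceeds the hard minimum
    expect_gt(c2, 0)
  }
  # three factors: pairwise left-to-right
  expect_equal(colimit(0.6, 0.9, 0.5, theta = 0.8),
               quadRoot(quadRoot(0.6, 0.9, 0.8), 0.5, 0.8), tolerance = 1e-10)
})

test_that("photosynthesis saturates to amax and vanishes in the dark", {
  p <- defaultPFTParams()["broadleaf", ]
  # all limitation factors driven to 1, dense canopy
  p$whalf <- 1e-12; p$chalf <- 1e-9
  gpp <- photosynthesis(p$topt, 1, 1e5, 1e6, 1e4, p, theta = 0.999999)
  expect_equal(gpp, p$amax, tolerance = 5e-3)
  expect_equal(photosynthesis(10, 0.5, 0, 380, 3, defaultPFTParams()["crop", ]), 0)
  expect_error(photosynthesis(10, 0.5, 100, 380, -1, p), "LAI")
  expect_error(photosynthesis(10, 0.5, -5, 380, 1, p), "PAR")
})

test_that("NPP allocation conserves carbon pool by pool", {
  p <- grassParams(resp_frac = 0.5)
  r0 <- nppAllocate(0, c(1, 1, 0, 0, 0), p)
  expect_equal(r0$pools, c(1, 1, 0, 0, 0))
  expect_equal(r0$npp, 0)

  r <- nppAllocate(1.0, c(0, 0, 0, 0, 0), p)
  expect_equal(r$ra, 0.5)
  expect_equal(unname(r$pools[1:2]), c(0.25, 0.25))

  set.seed(7)
  for (i in 1:20) {
    pools <- runif(5)
    gpp <- runif(1, 0, 3)
    pp <- defaultPFTParams()[sample(5, 1), ]
    rr <- nppAllocate(gpp, pools, pp, dt = 0.25)
    expect_equal(sum(rr$pools - pools), rr$npp * 0.25, tolerance = 1e-12)
    expect_equal(rr$npp + rr$ra, gpp, tolerance = 1e-14)
  }
})

test_that("turnover routes losses to the right litter pool and balances", {
  p <- defaultPFTParams()["coldgrass", ]  # woody taus are Inf
  r <- turnoverStep(c(0, 0, 1, 1, 1), p, dt = 1)
  expect_equal(r$structural, 0)  # infinite turnover time: no transfer
  p2 <- defaultPFTParams()["broadleaf", ]
  p2$tau_leaf <- 2
  r2 <- turnoverStep(c(1, 0, 0, 0, 0), p2, dt = 1)
  expect_equal(r2$metabolic, 0.5)

  set.seed(8)
  pools <- matrix(runif(50), 10, 5)
  r3 <- turnoverStep(pools, defaultPFTParams()["needleleaf", ], dt = 1 / 12)
  lost <- rowSums(pools - r3$pools)
  expect_equal(lost, r3$metabolic + r3$structural, tolerance = 1e-12)
})

test_that("one decomposition step matches an explicit transfer-matrix oracle", {
  params <- defaultModelParams()
  n <- 4L
  set.seed(9)
  litter <- matrix(runif(2 * n, 0.1, 2), n, 2)
  dec <- runif(n, 0.01, 0.5)
  soil <- matrix(runif(3 * n, 0.5, 8), n, 3)
  temp <- runif(n, 0, 25); wet <- runif(n, 0.2, 0.9)
  got <- decomposeStep(litter, dec, soil, temp, wet, params, dt = 1 / 12)

  # oracle: per cell, build the 6x6 linear one-step matrix and multiply
  for (i in seq_len(n)) {
    x <- c(litter[i, ], dec[i], soil[i, ])
    env <- params$q10^((temp[i] - params$tref) / 10) * wet[i] / (wet[i] + params$wdecHalf)
    f <- pmin(params$kBase * env / 12, params$fluxLimit)
    rf <- params$respFrac
    A <- diag(1 - f)
    A[3, 1] <- (1 - rf[["metabolic"]]) * f[["metabolic"]]
    A[3, 2] <- (1 - rf[["structural"]]) * f[["structural"]]
    A[4, 3] <- (1 - rf[["decomposer"]]) * f[["decomposer"]]
    A[5, 4] <- (1 - rf[["fast"]]) * f[["fast"]]
    A[6, 5] <- (1 - rf[["intermediate"]]) * f[["intermediate"]]
    xNew <- as.vector(A %*% x)
    expect_equal(c(got$litter[i, ], got$decomposer[i], got$soil[i, ]), xNew,
                 tolerance = 1e-12)
    expect_equal(got$rh[i], sum(rf * f * x), tolerance = 1e-12)
    # balance: pool change + Rh = 0 inside the cascade
    expect_equal(sum(xNew) - sum(x) + got$rh[i], 0, tolerance = 1e-12)
  }

  frozen <- defaultModelParams()
  frozen$kBase[] <- 0
  g0 <- decomposeStep(litter, dec, soil, temp, wet, frozen, dt = 1 / 12)
  expect_equal(g0$rh, rep(0, n))
  expect_identical(g0$soil, soil)
})

test_that("cascade pools reach the closed-form steady state under constant input", {
  params <- defaultModelParams()
  tC <- 12; wet <- 0.6; dt <- 1 / 12
  input <- 0.35 / 12  # constant metabolic litter input per month
  litter <- matrix(0, 1, 2); dec <- 0; soil <- matrix(0, 1, 3)
  for (i in seq_len(12 * 6000)) {
    st <- decomposeStep(litter, dec, soil, tC, wet, params, dt)
    litter <- st$litter; dec <- st$decomposer; soil <- st$soil
    litter[1, 1] <- litter[1, 1] + input  # P <- P(1-f) + I, fixed point I/f
  }
  # oracle: closed-form steady state of the discrete linear chain,
  # pool* = monthly input / monthly decay fraction, cascading the
  # non-respired outflow downstream
  env <- params$q10^((tC - params$tref) / 10) * wet / (wet + params$wdecHalf)
  f <- pmin(params$kBase * env * dt, params$fluxLimit)
  rf <- params$respFrac
  inMet <- input
  expMet <- inMet / f[["metabolic"]]
  inDec <- (1 - rf[["metabolic"]]) * inMet
  expDec <- inDec / f[["decomposer"]]
  inFast <- (1 - rf[["decomposer"]]) * inDec
  expFast <- inFast / f[["fast"]]
  inInt <- (1 - rf[["fast"]]) * inFast
  expInt <- inInt / f[["intermediate"]]
  inSlow <- (1 - rf[["intermediate"]]) * inInt
  expSlow <- inSlow / f[["slow"]]
  expect_equal(litter[1, 1], expMet, tolerance = 1e-3)
  expect_equal(dec, expDec, tolerance = 1e-3)
  expect_equal(soil[1, 1], expFast, tolerance = 1e-3)
  expect_equal(soil[1, 2], expInt, tolerance = 1e-3)
  expect_equal(soil[1, 3], expSlow, tolerance = 1e-3)
})

test_that("the land-use operator moves biomass to litter and conserves carbon", {
  w <- smallWorld()
  st <- initialState(w$grid, w$crop@fraction[, , 1], w$clim)
  land <- as.vector(landMask(w$grid))
  areaV <- as.vector(cellArea(w$grid))

  # identity when the prescribed fraction is unchanged
  r0 <- applyLandUse(st, st@cover[, 5], w$clim)
  expect_equal(cellTrackedC(r0$state), cellTrackedC(st), tolerance = 1e-14)
  expect_equal(max(abs(r0$transfer)), 0)

  # abandon 0.1 of a cell whose crop biomass density is 0.4
  cell <- which(land & st@cover[, 5] > 0.2)[1]
  st2 <- st
  st2@veg[cell, 5, ] <- c(0.25, 0.15, 0, 0, 0)  # 0.4 kgC m-2 total
  newCrop <- st2@cover[, 5]
  newCrop[cell] <- newCrop[cell] - 0.1
  r <- applyLandUse(st2, newCrop, w$clim)
  expect_equal(r$transfer[cell], 0.04, tolerance = 1e-12)
  expect_equal(sum(r$state@litter[cell, ]) - sum(st2@litter[cell, ]), 0.04,
               tolerance = 1e-12)
  expect_equal(cellVegC(r$state)[cell] - cellVegC(st2)[cell], -0.04,
               tolerance = 1e-12)

  # random expansion/abandonment sequence: total carbon invariant
  set.seed(10)
  state <- st2
  tot0 <- sum(cellTrackedC(state) * areaV)
  for (k in 1:12) {
    tgt <- pmin(pmax(state@cover[, 5] +
                       runif(length(land), -0.15, 0.12), 0), 0.8)
    tgt[!land] <- 0
    state <- applyLandUse(state, tgt, w$clim)$state
  }
  expect_equal(sum(cellTrackedC(state) * areaV), tot0, tolerance = 1e-9)
  expect_true(validObject(state))
})

test_that("succession converts abandoned grass exponentially on suitable cells", {
  w <- smallWorld()
  params <- defaultModelParams()
  params$grassLag <- 0
  st <- initialState(w$grid, rep(0, nCells(w$grid)), w$clim, params)
  cell <- which(w$clim$suitableForest & as.vector(landMask(w$grid)))[1]
  # force the cell to 100% abandoned grass
  st@cover[cell, ] <- c(0, 0, 1, 0, 0)
  st@bare[cell] <- 0
  st@abnGrass[cell, ] <- c(1, 0)
  st@abnTree[cell] <- 0
  grass <- numeric(15)
  s <- st
  for (t in 1:15) {
    s <- vegetationDynamics(s, w$clim, params)
    grass[t] <- s@cover[cell, 3]
  }
  expect_equal(grass, exp(-(1:15) / 15), tolerance = 1e-12)
  expect_equal(grass[15], exp(-1), tolerance = 1e-12)
  expect_equal(s@abnTree[cell] + s@abnGrass[cell, 1], 1, tolerance = 1e-12)

  # unsuitable climate: abandoned area stays grass indefinitely
  dry <- w$clim
  dry$suitableForest[] <- FALSE
  s2 <- st
  for (t in 1:25) s2 <- vegetationDynamics(s2, dry, params)
  expect_equal(s2@cover[cell, 3], 1)
  expect_equal(s2@abnTree[cell], 0)

  # no abandonment, stable climate: cover is a fixed point
  st3 <- initialState(w$grid, w$crop@fraction[, , 1], w$clim, params)
  s3 <- vegetationDynamics(st3, w$clim, params)
  expect_identical(s3@cover, st3@cover)
})

test_that("annual stepping closes the carbon budget and is deterministic", {
  w <- smallWorld()
  sp <- smallSpinup()$spinup
  areaV <- as.vector(cellArea(w$grid))

  run <- function() {
    state <- sp$state
    npp <- rh <- 0
    for (t in 1:10) {
      r <- stepYear(state, w$forcing, as.vector(w$crop@fraction[, , t]),
                    w$clim, t = t)
      state <- r$state
      npp <- npp + sum(r$diag$npp * areaV)
      rh <- rh + sum(r$diag$rh * areaV)
    }
    list(state = state, npp = npp, rh = rh)
  }
  a <- run(); b <- run()
  tot0 <- sum(cellTrackedC(sp$state) * areaV)
  tot1 <- sum(cellTrackedC(a$state) * areaV)
  expect_lt(abs(tot1 - tot0 - (a$npp - a$rh)) / tot1, 1e-9)
  # bit-identical repetition
  expect_identical(a$state@soil, b$state@soil)
  expect_identical(a$state@veg, b$state@veg)

  # with photosynthesis shut off, total carbon only decreases (Rh outflow)
  dark <- defaultModelParams()
  dark$pft$amax[] <- 0
  state <- sp$state
  tots <- numeric(5)
  for (t in 1:5) {
    state <- stepYear(state, w$forcing, as.vector(w$crop@fraction[, , t]),
                      w$clim, dark, t = t)$state
    tots[t] <- sum(cellTrackedC(state) * areaV)
  }
  expect_true(all(diff(c(tot0, tots)) < 0))
})

test_that("spin-up converges, restarts instantly and matches the cascade oracle", {
  fx <- smallSpinup()
  sp <- fx$spinup; w <- fx$world
  expect_true(sp$converged)
  expect_lt(abs(sp$nbpFinal), 1e-3 * sp$nppFinal)
  # an equilibrated state converges immediately
  sp2 <- spinUp(w$grid, w$crop@fraction[, , 1], w$clima, state = sp$state,
                maxIters = 10L)
  expect_true(sp2$converged)
  expect_lte(sp2$iters, 2L)
  # |NBP| is eventually decreasing
  tail5 <- abs(tail(sp$nbp, 5))
  expect_lt(tail5[5], max(abs(sp$nbp)) / 10)

  # slow soil pool within 1% of the analytic compartment-chain value under
  # the equilibrated litter input
  params <- defaultModelParams()
  st <- sp$state
  clim <- w$clim
  land <- which(as.vector(landMask(w$grid)))
  cell <- land[which.max(st@soil[land, 3])]
  r <- stepYear(st, w$clima, st@cover[, 5], clim, params, record = TRUE, t = 1L)
  f <- rep(0, 6); names(f) <- names(params$kBase)
  tempM <- matrix(w$clima@temp[, , , 1], nCells(w$grid), 12)
  for (m in 1:12) {
    env <- params$q10^((tempM[cell, m] - params$tref) / 10) *
      r$diag$wetness[cell, m] / (r$diag$wetness[cell, m] + params$wdecHalf)
    f <- f + pmin(params$kBase * env / 12, params$fluxLimit)
  }
  rf <- params$respFrac
  inMet <- r$diag$litterInMet[cell]; inStr <- r$diag$litterInStr[cell]
  inDec <- (1 - rf[["metabolic"]]) * inMet + (1 - rf[["structural"]]) * inStr
  inFast <- (1 - rf[["decomposer"]]) * inDec
  inInt <- (1 - rf[["fast"]]) * inFast
  inSlow <- (1 - rf[["intermediate"]]) * inInt
  expect_equal(unname(st@soil[cell, 3]), inSlow / f[["slow"]], tolerance = 0.01)
})
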