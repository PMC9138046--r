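# Flux operators of the reduced vegetation/carbon model. All functions are
# vectorised over cells; carbon units are kgC m-2 and fluxes kgC m-2 yr-1
# unless noted.

#' Collatz-style pairwise co-limitation
#'
#' Smaller root of `theta c^2 - (x + y) c + x y = 0`, applied pairwise and
#' left-to-right over the supplied limitation factors. The result is
#' `<= min(x, y)` and approaches the hard minimum as `theta -> 1`, giving a
#' more gradual response to any single factor than a Liebig minimum.
#'
#' @param ... limitation factors in `[0, 1]` (vectors recycle).
#' @param theta curvature in (0, 1].
#' @return Co-limited factor in `[0, 1]`.
#' @export
colimit <- function(..., theta = 0.8) {
  fs <- list(...)
  stopifnot(length(fs) >= 1, theta > 0, theta <= 1)
  out <- fs[[1]]
  for (f in fs[-1]) {
    s <- out + f
    disc <- pmax(s^2 - 4 * theta * out * f, 0)
    out <- (s - sqrt(disc)) / (2 * theta)
  }
  out
}

#' Jarvis-type co-limited photosynthesis
#'
#' Gross primary production per unit PFT area:
#' `GPP = amax * colimit(fT, fW, fC) * fL`, with a Gaussian temperature
#' response, Michaelis-type soil-moisture and CO2 responses, and a light
#' response `fL = 1 - exp(-kext * (par/par0) * (lai + lai0))` that saturates
#' with both radiation and leaf area. All limitation factors lie in `[0, 1]`.
#'
#' @param temp air temperature, degC.
#' @param wetness soil wetness in `[0, 1]`.
#' @param par photosynthetically active radiation, W m-2 (>= 0).
#' @param co2 atmospheric CO2, ppm.
#' @param lai leaf area index (>= 0).
#' @param pftPar one row of [defaultPFTParams()] (data.frame or list).
#' @param theta co-limitation curvature.
#' @param par0 PAR normalisation, W m-2.
#' @param lai0 establishment LAI floor added to `lai`.
#' @return GPP in kgC m-2 yr-1.
#' @examples
#' p <- defaultPFTParams()["broadleaf", ]
#' photosynthesis(18, 0.8, 120, 380, 4, p)
#' @export
photosynthesis <- function(temp, wetness, par, co2, lai, pftPar,
                           theta = 0.8, par0 = 100, lai0 = 0) {
  if (any(lai < 0)) stop("negative LAI")
  if (any(par < 0)) stop("negative PAR")
  fT <- exp(-((temp - pftPar$topt) / pftPar$twidth)^2)
  fW <- wetness / (wetness + pftPar$whalf)
  fC <- co2 / (co2 + pftPar$chalf)
  fL <- 1 - exp(-pftPar$kext * (par / par0) * (lai + lai0))
  pftPar$amax * colimit(fT, fW, fC, theta = theta) * fL
}

#' Autotrophic respiration and NPP allocation
#'
#' `Ra = resp_frac * GPP`, `NPP = GPP - Ra`; each vegetation pool gains
#' `NPP * dt` times its allocation fraction, so the pool increments sum to
#' the NPP increment exactly.
#'
#' @param gpp GPP per unit PFT area, kgC m-2 yr-1 (vector over cells).
#' @param pools vegetation pools: numeric length 5 or matrix `[n, 5]`
#'   (leaf, fine root, coarse root, sapwood, heartwood).
#' @param pftPar one PFT parameter row.
#' @param dt time step in years (default 1).
#' @return list with `pools` (updated), `npp`, `ra` (fluxes, kgC m-2 yr-1).
#' @export
nppAllocate <- function(gpp, pools, pftPar, dt = 1) {
  if (any(gpp < 0)) stop("GPP must be >= 0")
  alloc <- unname(unlist(pftPar[paste0("a_", c("leaf", "froot", "croot", "sap", "heart"))]))
  if (abs(sum(alloc) - 1) > 1e-12) stop("allocation fractions must sum to 1")
  ra <- pftPar$resp_frac * gpp
  npp <- gpp - ra
  if (is.matrix(pools)) {
    pools <- pools + outer(npp * dt, alloc)
  } else {
    pools <- pools + npp * dt * alloc
  }
  list(pools = pools, npp = npp, ra = ra)
}

#' First-order vegetation turnover into litter
#'
#' Each pool loses `pool * dt / tau`; leaf and fine-root losses enter
#' metabolic litter, coarse-root, sapwood and heartwood losses enter
#' structural litter. Total vegetation loss equals total litter gain.
#'
#' @param pools numeric length 5 or matrix `[n, 5]`, kgC m-2 of PFT area.
#' @param pftPar one PFT parameter row (uses `tau_*`, yr).
#' @param dt time step, yr (> 0); fractional loss is capped below 1.
#' @return list with `pools` (updated), `metabolic`, `structural` (litter
#'   inputs per unit PFT area, kgC m-2 per step).
#' @export
turnoverStep <- function(pools, pftPar, dt) {
  stopifnot(dt > 0)
  taus <- unlist(pftPar[paste0("tau_", c("leaf", "froot", "croot", "sap", "heart"))])
  fr <- pmin(dt / taus, 0.999)
  fr[!is.finite(taus)] <- 0
  if (is.matrix(pools)) {
    loss <- sweep(pools, 2, fr, `*`)
    met <- rowSums(loss[, 1:2, drop = FALSE])
    str <- rowSums(loss[, 3:5, drop = FALSE])
  } else {
    loss <- pools * fr
    met <- sum(loss[1:2]); str <- sum(loss[3:5])
  }
  list(pools = pools - loss, metabolic = met, structural = str)
}

# Effective monthly decay fractions of the six soil-side donors.
decayFractions <- function(temp, wetness, params, dt) {
  tfac <- params$q10^((temp - params$tref) / 10)
  wfac <- wetness / (wetness + params$wdecHalf)
  env <- tfac * wfac
  lapply(params$kBase, function(k) pmin(k * env * dt, params$fluxLimit))
}

#' One step of the litter-decomposer-soil decomposition cascade
#'
#' Six donor pools (metabolic and structural litter, decomposer, fast,
#' intermediate, slow soil) decay first-order at
#' `kBase * Q10^((T - Tref)/10) * w/(w + 0.3)`. Each donor's outflow is
#' partly respired (heterotrophic respiration) and partly transferred along
#' the fixed cascade litter -> decomposer -> fast -> intermediate -> slow;
#' the slow pool respires fully. The carbon balance
#' `delta(litter + decomposer + soil) = -Rh` holds exactly (no external
#' inputs inside this operator).
#'
#' @param litter matrix `[n, 2]` metabolic, structural (kgC m-2).
#' @param decomposer numeric `[n]`.
#' @param soil matrix `[n, 3]` fast, intermediate, slow.
#' @param temp,wetness per-cell temperature (degC) and wetness `[0, 1]`.
#' @param params model parameter list.
#' @param dt time step, yr.
#' @return list with updated `litter`, `decomposer`, `soil` and `rh`
#'   (kgC m-2 released this step, per cell).
#' @export
decomposeStep <- function(litter, decomposer, soil, temp, wetness, params, dt) {
  stopifnot(dt > 0)
  rf <- params$respFrac
  if (any(rf < 0 | rf > 1)) stop("respired fractions must lie in [0, 1]")
  f <- decayFractions(temp, wetness, params, dt)
  outMet <- litter[, 1] * f$metabolic
  outStr <- litter[, 2] * f$structural
  outDec <- decomposer * f$decomposer
  outFast <- soil[, 1] * f$fast
  outInt <- soil[, 2] * f$intermediate
  outSlow <- soil[, 3] * f$slow
  rh <- rf[["metabolic"]] * outMet + rf[["structural"]] * outStr +
    rf[["decomposer"]] * outDec + rf[["fast"]] * outFast +
    rf[["intermediate"]] * outInt + rf[["slow"]] * outSlow
  litter[, 1] <- litter[, 1] - outMet
  litter[, 2] <- litter[, 2] - outStr
  decomposer <- decomposer - outDec +
    (1 - rf[["metabolic"]]) * outMet + (1 - rf[["structural"]]) * outStr
  soil[, 1] <- soil[, 1] - outFast + (1 - rf[["decomposer"]]) * outDec
  soil[, 2] <- soil[, 2] - outInt + (1 - rf[["fast"]]) * outFast
  soil[, 3] <- soil[, 3] - outSlow + (1 - rf[["intermediate"]]) * outInt
  list(litter = litter, decomposer = decomposer, soil = soil, rh = rh)
}

# One-bucket monthly soil-water balance; returns new storage and wetness.
soilWaterStep <- function(water, precip, temp, params) {
  w <- water + precip
  pet <- params$petCoef * pmax(temp, 0)  # mm/month demand
  et <- pmin(w, pet * w / params$wcap)
  w <- pmin(pmax(w - et, 0), params$wcap)
  list(water = w, wetness = w / params$wcap)
}

#' Per-cell carbon totals
#'
#' `cellVegC()` sums the five live pools over PFTs weighted by cover;
#' `cellSoilC()` sums litter, decomposer and the three soil pools (the
#' "soil-side" grouping used in reporting); `cellTotalC()` is their sum
#' (biosphere carbon); `cellTrackedC()` additionally includes the harvested
#' product pool and is the quantity conserved by the model's bookkeeping.
#'
#' @param state a [CarbonState-class].
#' @return numeric per-cell carbon density, kgC m-2.
#' @export
cellVegC <- function(state) {
  dens <- apply(state@veg, c(1, 2), sum)      # [n, pft]
  rowSums(dens * state@cover)
}

#' @rdname cellVegC
#' @export
cellSoilC <- function(state)
  rowSums(state@litter) + state@decomposer + rowSums(state@soil)

#' @rdname cellVegC
#' @export
cellTotalC <- function(state) cellVegC(state) + cellSoilC(state)

#' @rdname cellVegC
#' @export
cellTrackedC <- function(state) cellTotalC(state) + state@product
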