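#' Default plant-functional-type parameters
#'
#' Five PFTs: broadleaf tree, needleleaf tree, cold (C3) grass, warm (C4)
#' grass and cropland. Columns: photosynthetic pathway, maximum assimilation
#' rate `amax` (kgC m-2 yr-1), Gaussian temperature response (`topt`,
#' `twidth`, degC), soil-moisture half-saturation `whalf` (-), light
#' extinction `kext` (-), CO2 half-saturation `chalf` (ppm), specific leaf
#' area `sla` (m2 kgC-1), allocation fractions to the five vegetation pools
#' (sum to 1; grasses and crops allocate nothing to wood), per-pool turnover
#' times `tau_*` (yr, `Inf` for absent pools), `woody` flag and autotrophic
#' respiration fraction `resp_frac` of GPP.
#'
#' @return data.frame with one row per PFT, rownames
#'   `broadleaf, needleleaf, coldgrass, warmgrass, crop`.
#' @export
defaultPFTParams <- function() {
  p <- data.frame(
    pft = PFT_IDS,
    pathway = c("C3", "C3", "C3", "C4", "C3"),
    amax    = c(6.0, 5.5, 5.0, 5.5, 6.5),
    topt    = c(18, 14, 13, 26, 19),
    twidth  = c(10, 11, 9, 8, 10),
    whalf   = c(0.25, 0.25, 0.22, 0.18, 0.22),
    kext    = c(0.50, 0.45, 0.55, 0.55, 0.55),
    chalf   = c(300, 300, 300, 150, 300),
    sla     = c(12, 8, 18, 16, 16),
    a_leaf  = c(0.25, 0.22, 0.55, 0.55, 0.60),
    a_froot = c(0.25, 0.25, 0.45, 0.45, 0.40),
    a_croot = c(0.10, 0.10, 0, 0, 0),
    a_sap   = c(0.25, 0.25, 0, 0, 0),
    a_heart = c(0.15, 0.18, 0, 0, 0),
    tau_leaf  = c(1.0, 3.0, 1.0, 0.8, 1.0),
    tau_froot = c(1.0, 1.5, 1.2, 1.0, 1.0),
    tau_croot = c(30, 30, Inf, Inf, Inf),
    tau_sap   = c(10, 12, Inf, Inf, Inf),
    tau_heart = c(50, 60, Inf, Inf, Inf),
    woody = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    resp_frac = c(0.45, 0.45, 0.40, 0.40, 0.40),
    row.names = PFT_IDS, stringsAsFactors = FALSE
  )
  stopifnot(all(abs(rowSums(p[, paste0("a_", c("leaf", "froot", "croot", "sap", "heart"))]) - 1) < 1e-12))
  p
}

#' Default model parameter set
#'
#' All tunable constants of the reduced vegetation/carbon model, grouped in
#' a named list:
#' \describe{
#'   \item{pft}{PFT table, see [defaultPFTParams()].}
#'   \item{theta}{co-limitation curvature of the pairwise Collatz quadratic
#'     (0.8; 1 would be a hard minimum, 0 a product).}
#'   \item{par0}{PAR normalisation (100 W m-2) for the light response.}
#'   \item{lai0}{establishment LAI floor (0.3) so vegetation can colonise
#'     area with zero standing biomass.}
#'   \item{q10, tref}{decomposition temperature sensitivity (Q10 = 2,
#'     reference 15 degC).}
#'   \item{wdecHalf}{moisture half-saturation of decomposition, g(w) =
#'     w/(w + 0.3).}
#'   \item{kBase}{base decomposition rates (yr-1) of the six soil-side
#'     donors: metabolic litter, structural litter, decomposer, fast,
#'     intermediate, slow soil.}
#'   \item{respFrac}{respired fraction of each donor's outflow; the
#'     remainder cascades to the next pool (slow soil respires fully).}
#'   \item{wcap, petCoef}{soil-water bucket capacity (150 mm) and potential
#'     evapotranspiration coefficient (4 mm per degC per month).}
#'   \item{harvestExport}{fraction of the annual crop harvest exported from
#'     the ecosystem (0.5); the rest enters metabolic litter.}
#'   \item{tauSucc, grassLag}{grass-to-forest succession e-folding time
#'     (15 yr) and the pure-grassland establishment lag (3 yr).}
#'   \item{forestPrecipMin, forestTempMin}{forest climatic suitability:
#'     annual precipitation >= 400 mm and mean annual T >= 0 degC.}
#'   \item{warmGrassTemp}{mean annual T (12 degC) above which abandoned land
#'     regrows as warm (C4) rather than cold grass.}
#'   \item{broadleafTemp}{mean annual T (8 degC) above which succession
#'     forest is broadleaf rather than needleleaf.}
#'   \item{initForest, initGrassSuit, initBareSuit, initGrassUnsuit}{initial
#'     natural-cover partition of non-crop land.}
#'   \item{burnFrac}{fraction of land-use-cleared biomass released at
#'     conversion (default 0: all biomass enters litter).}
#'   \item{fluxLimit}{cap on a pool's fractional loss per monthly step.}
#' }
#' @return named list of parameters.
#' @export
defaultModelParams <- function() {
  list(
    pft = defaultPFTParams(),
    theta = 0.8,
    par0 = 100,
    lai0 = 0.3,
    q10 = 2,
    tref = 15,
    wdecHalf = 0.3,
    kBase = c(metabolic = 3.0, structural = 0.5, decomposer = 8.0,
              fast = 0.3, intermediate = 0.04, slow = 0.0025),
    respFrac = c(metabolic = 0.55, structural = 0.55, decomposer = 0.60,
                 fast = 0.55, intermediate = 0.55, slow = 1.0),
    wcap = 150,
    petCoef = 4,
    harvestExport = 0.5,
    tauSucc = 15,
    grassLag = 3,
    forestPrecipMin = 400,
    forestTempMin = 0,
    warmGrassTemp = 12,
    broadleafTemp = 8,
    initForest = 0.75,
    initGrassSuit = 0.20,
    initBareSuit = 0.05,
    initGrassUnsuit = 0.80,
    burnFrac = 0,
    fluxLimit = 0.95
  )
}

checkModelParams <- function(params) {
  stopifnot(is.list(params), is.data.frame(params$pft))
  alloc <- rowSums(params$pft[, paste0("a_", c("leaf", "froot", "croot", "sap", "heart"))])
  if (any(abs(alloc - 1) > 1e-12))
    stop("PFT allocation fractions must sum to 1")
  if (any(params$pft[!params$pft$woody, c("a_sap", "a_heart")] != 0))
    stop("non-woody PFTs must allocate 0 to sapwood/heartwood")
  if (any(params$respFrac < 0 | params$respFrac > 1))
    stop("respired fractions must lie in [0, 1]")
  if (any(params$kBase < 0)) stop("decomposition base rates must be >= 0")
  if (params$theta <= 0 || params$theta > 1) stop("theta must be in (0, 1]")
  invisible(TRUE)
}

#' Read / write model parameters as YAML
#'
#' `readModelParams()` loads a YAML file and merges it over
#' [defaultModelParams()] (the `pft` table may be given as a list of columns).
#' `writeModelParams()` serialises a parameter list to YAML.
#'
#' @param path file path.
#' @param params parameter list.
#' @return `readModelParams()` returns the merged, validated parameter list.
#' @export
readModelParams <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- defaultModelParams()
  for (nm in names(raw)) {
    if (nm == "pft") {
      tab <- as.data.frame(raw$pft, stringsAsFactors = FALSE)
      rownames(tab) <- tab$pft
      params$pft <- tab[PFT_IDS, ]
    } else if (nm %in% c("kBase", "respFrac")) {
      v <- unlist(raw[[nm]])
      params[[nm]][names(v)] <- v
    } else {
      params[[nm]] <- raw[[nm]]
    }
  }
  # absent pools use Inf turnover; accept string forms from YAML
  for (cl in grep("^tau_", names(params$pft), value = TRUE))
    params$pft[[cl]] <- suppressWarnings(ifelse(
      params$pft[[cl]] %in% c(".inf", "Inf"), Inf, as.numeric(params$pft[[cl]])))
  checkModelParams(params)
  params
}

#' @rdname readModelParams
#' @export
writeModelParams <- function(params, path) {
  out <- params
  out$pft <- as.list(params$pft)
  yaml::write_yaml(out, path)
  invisible(path)
}
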