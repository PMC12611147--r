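#' Construct a Cellular-Potts parameter set
#'
#' Returns a [CPMParams-class] object.  All arguments default to the
#' vasculogenesis parameter set (see the class documentation); any subset can
#' be overridden.
#'
#' @param lambdaVolume,VTarget volume constraint strength and target volume.
#' @param lambdaSurface,STarget surface constraint strength and target
#'   boundary length.
#' @param JCellMedium,JCellCell contact energies per boundary face.
#' @param lambdaChemotaxis,chemotaxisSaturation saturated chemotaxis strength
#'   and saturation constant.
#' @param decayRate field decay constant k (1/MCS).
#' @param diffusionConstant field diffusion constant D (sites^2/MCS).
#' @param secretionRate concentration added per MCS at cell-occupied sites.
#' @param temperature Boltzmann temperature of the acceptance rule.
#' @param latticeSize periodic lattice side length (sites).
#' @param nCellsInitial number of cells placed at initialization.
#' @param seedBlockSide side length of the square block each cell starts as.
#' @param contactNeighborOrder 1 (von Neumann) or 2 (Moore) contact
#'   neighborhood for the contact-energy term.
#' @param surfaceMeasure `"perimeter"` (default; the surface entering the
#'   energy is the in-plane 4-neighbor boundary length `P`) or `"voxel"`
#'   (`2 V + P`, all exposed faces of the unit-thickness voxel
#'   representation used by 3-D frameworks running 2-D simulations).
#' @param chemotaxisMode `"advance"` (default): the chemotaxis term applies
#'   only when a cell copies into the destination site; `"both"`: the
#'   antisymmetric variant also penalizing retraction from high
#'   concentration.
#' @param pdeSubsteps explicit-Euler substeps of the field solver per MCS
#'   (stability requires `(4 diffusionConstant + decayRate)/pdeSubsteps <= 1`).
#' @return a validated [CPMParams-class] object.
#' @examples
#' cpmParams()
#' cpmParams(latticeSize = 64L, nCellsInitial = 60L)
#' @export
cpmParams <- function(lambdaVolume = 5, VTarget = 50,
                      lambdaSurface = 1, STarget = 16.8,
                      JCellMedium = 8.2, JCellCell = 6,
                      lambdaChemotaxis = 2000, chemotaxisSaturation = 0.5,
                      decayRate = 0.6, diffusionConstant = 2,
                      secretionRate = 0.05, temperature = 8,
                      latticeSize = 256L, nCellsInitial = 1000L,
                      seedBlockSide = 5L, contactNeighborOrder = 2L,
                      surfaceMeasure = c("perimeter", "voxel"),
                      chemotaxisMode = c("advance", "both"),
                      pdeSubsteps = 10L) {
  surfaceMeasure <- match.arg(surfaceMeasure)
  chemotaxisMode <- match.arg(chemotaxisMode)
  new("CPMParams",
      lambdaVolume = lambdaVolume, VTarget = VTarget,
      lambdaSurface = lambdaSurface, STarget = STarget,
      JCellMedium = JCellMedium, JCellCell = JCellCell,
      lambdaChemotaxis = lambdaChemotaxis,
      chemotaxisSaturation = chemotaxisSaturation,
      decayRate = decayRate, diffusionConstant = diffusionConstant,
      secretionRate = secretionRate, temperature = temperature,
      latticeSize = as.integer(latticeSize),
      nCellsInitial = as.integer(nCellsInitial),
      seedBlockSide = as.integer(seedBlockSide),
      contactNeighborOrder = as.integer(contactNeighborOrder),
      surfaceMeasure = surfaceMeasure,
      chemotaxisMode = chemotaxisMode,
      pdeSubsteps = as.integer(pdeSubsteps))
}

#' Assemble a lattice state from raw matrices
#'
#' Builds a [LatticeState-class] from a cell-id lattice and (optionally) a
#' field, recounting the per-cell statistics.  Mostly useful for tests and
#' for constructing hand-made configurations.
#'
#' @param cellLattice integer matrix of ids (0 = medium).
#' @param field numeric matrix of concentrations; defaults to all zero.
#' @param mcs clock value of the state.
#' @return a validated [LatticeState-class].
#' @examples
#' lat <- matrix(0L, 8, 8); lat[3:4, 3:4] <- 1L
#' latticeState(lat)
#' @export
latticeState <- function(cellLattice, field = NULL, mcs = 0) {
  storage.mode(cellLattice) <- "integer"
  if (is.null(field)) field <- matrix(0, nrow(cellLattice), ncol(cellLattice))
  maxId <- max(0L, max(cellLattice))
  rec <- cpp_recount(cellLattice, maxId)
  new("LatticeState", cellLattice = cellLattice, field = field,
      volumes = rec$volumes, surfaces = rec$surfaces, mcs = as.numeric(mcs))
}

#' Total effective energy of a lattice state
#'
#' Brute-force evaluation of the static effective energy: the contact term
#' summed once over every unordered neighbor pair (neighborhood order set by
#' `contactNeighborOrder`), plus the volume and surface constraint terms of
#' every live cell.  The chemotaxis term involves a copy source and
#' destination and is therefore intrinsically per-attempt; it contributes
#' nothing to the static total and appears only in [deltaEnergy()].
#'
#' This is the reference implementation used to validate the incremental
#' energy changes of the Monte-Carlo engine; it is O(sites) per call.
#'
#' @param state a [LatticeState-class].
#' @param params a [CPMParams-class].
#' @return the energy (a single number).
#' @examples
#' p <- cpmParams(latticeSize = 16L)
#' totalEnergy(latticeState(matrix(0L, 16, 16)), p)  # empty lattice: 0
#' @export
totalEnergy <- function(state, params) {
  stopifnot(is(state, "LatticeState"), is(params, "CPMParams"))
  validObject(state)
  cpp_total_energy(state@cellLattice,
                   params@lambdaVolume, params@VTarget,
                   params@lambdaSurface, params@STarget,
                   params@JCellMedium, params@JCellCell,
                   params@contactNeighborOrder,
                   match(params@surfaceMeasure, c("perimeter", "voxel")) - 1L)
}

#' Incremental energy change of a pixel-copy attempt
#'
#' Energy change of copying the id at `source` onto the neighboring site
#' `dest`, computed incrementally (local contact change, volume and surface
#' change of the growing and shrinking cell, and the saturated chemotaxis
#' term).  Attempts between two sites of the same id are no-ops and are
#' rejected here with an error; the engine skips them without scoring.
#'
#' @param state a [LatticeState-class].
#' @param params a [CPMParams-class].
#' @param source,dest integer `(row, col)` positions (1-based); `dest` must
#'   be a 4-neighbor of `source` under periodic wraparound.
#' @return the energy change (a single number).
#' @export
deltaEnergy <- function(state, params, source, dest) {
  stopifnot(is(state, "LatticeState"), is(params, "CPMParams"),
            length(source) == 2L, length(dest) == 2L)
  d <- dim(state@cellLattice)
  dr <- (source[1] - dest[1]) %% d[1]
  dc <- (source[2] - dest[2]) %% d[2]
  adj <- (dr %in% c(1L, d[1] - 1L) && dc == 0L) ||
         (dc %in% c(1L, d[2] - 1L) && dr == 0L)
  if (!adj) stop("source and dest must be 4-neighbors modulo the lattice")
  a <- state@cellLattice[source[1], source[2]]
  b <- state@cellLattice[dest[1], dest[2]]
  if (a == b) stop("source and dest hold the same id; attempt is a no-op and is never scored")
  cpp_delta_energy(state@cellLattice, state@field,
                   state@volumes, state@surfaces,
                   params@lambdaVolume, params@VTarget,
                   params@lambdaSurface, params@STarget,
                   params@JCellMedium, params@JCellCell,
                   params@lambdaChemotaxis, params@chemotaxisSaturation,
                   params@contactNeighborOrder,
                   match(params@surfaceMeasure, c("perimeter", "voxel")) - 1L,
                   match(params@chemotaxisMode, c("advance", "both")) - 1L,
                   source[1] - 1L, source[2] - 1L, dest[1] - 1L, dest[2] - 1L)
}

#' Boltzmann acceptance probability
#'
#' The acceptance rule of the modified Metropolis algorithm:
#' `exp(-max(0, deltaH / temperature))`.  Energy-lowering moves are always
#' accepted; energy-raising moves are accepted with Boltzmann probability.
#'
#' @param deltaH energy change(s) of the attempt (vectorized).
#' @param temperature Boltzmann temperature H' (> 0).
#' @return probabilities in `[0, 1]`.
#' @examples
#' acceptanceProbability(-3, 8)   # 1
#' acceptanceProbability(8, 8)    # exp(-1)
#' @export
acceptanceProbability <- function(deltaH, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number")
  exp(-pmax(0, deltaH / temperature))
}

#' Advance a lattice state by Monte-Carlo steps
#'
#' Runs `nMCS` Monte-Carlo steps.  One MCS is `latticeSize^2` copy attempts,
#' each picking a uniform random site and a uniform random 4-neighbor as the
#' copy source, scoring the move with the incremental energy change and
#' accepting it with the Boltzmann rule; after the attempt sweep the
#' chemoattractant field is advanced one MCS (diffusion, decay, and secretion
#' at cell-occupied sites).  Consumes the R random number stream, so results
#' are reproducible under [set.seed()].
#'
#' @param state a [LatticeState-class].
#' @param params a [CPMParams-class].
#' @param nMCS number of Monte-Carlo steps (>= 0).
#' @return the advanced [LatticeState-class]; the fraction of scored attempts
#'   that were accepted is attached as `attr(, "acceptanceRate")`.
#' @examples
#' p <- cpmParams(latticeSize = 32L, nCellsInitial = 8L)
#' st <- initState(p, seed = 1)
#' st2 <- runMCS(st, p, 5)
#' mcsClock(st2)
#' @export
runMCS <- function(state, params, nMCS) {
  stopifnot(is(state, "LatticeState"), is(params, "CPMParams"), nMCS >= 0)
  if (nMCS == 0) return(state)
  res <- cpp_run_mcs(state@cellLattice, state@field,
                     state@volumes, state@surfaces,
                     params@lambdaVolume, params@VTarget,
                     params@lambdaSurface, params@STarget,
                     params@JCellMedium, params@JCellCell,
                     params@lambdaChemotaxis, params@chemotaxisSaturation,
                     params@temperature, params@contactNeighborOrder,
                     match(params@surfaceMeasure, c("perimeter", "voxel")) - 1L,
                     match(params@chemotaxisMode, c("advance", "both")) - 1L,
                     params@diffusionConstant, params@decayRate,
                     params@secretionRate, params@pdeSubsteps,
                     as.integer(nMCS))
  out <- new("LatticeState", cellLattice = res$cell_lattice, field = res$field,
             volumes = res$volumes, surfaces = res$surfaces,
             mcs = state@mcs + nMCS)
  attr(out, "acceptanceRate") <-
    if (res$n_scored > 0) res$n_accepted / res$n_scored else NA_real_
  out
}
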