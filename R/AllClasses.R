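#' Cellular-Potts model parameters
#'
#' Holds every symbol of the effective-energy functional, the Boltzmann
#' acceptance rule and the secretion-diffusion-decay field equation, plus
#' lattice and initialization settings.  Defaults are the published parameter
#' set for the vasculogenesis model (volume constraint 5 with target 50 sites,
#' surface constraint 1 with target 16.8 faces, cell-medium contact energy
#' 8.2, cell-cell contact energy 6, chemotaxis strength 2000 with saturation
#' 0.5, field decay 0.6 per MCS, simulation temperature 8).  The diffusion
#' constant and secretion rate of the chemoattractant are not part of the
#' published table; the shipped defaults were calibrated so that simulations
#' form a connected vascular network with enclosed lacunae (see the package
#' vignette and [calibrateFieldParams()]).
#'
#' @slot lambdaVolume influence of the volume constraint (energy per site^2).
#' @slot VTarget target cell volume (lattice sites).
#' @slot lambdaSurface influence of the surface constraint (energy per face^2).
#' @slot STarget target cell boundary length (4-neighbor faces).
#' @slot JCellMedium contact energy per cell-medium face.
#' @slot JCellCell contact energy per cell-cell face.
#' @slot lambdaChemotaxis influence of saturated chemotaxis (energy).
#' @slot chemotaxisSaturation saturation constant s (1/concentration).
#' @slot decayRate field decay constant k (1/MCS).
#' @slot diffusionConstant field diffusion constant D (sites^2/MCS).
#' @slot secretionRate concentration added per MCS at each cell-occupied site.
#' @slot temperature Boltzmann temperature H' of the acceptance rule (energy).
#' @slot latticeSize lattice side length (sites); the lattice is periodic.
#' @slot nCellsInitial number of cells placed at initialization.
#' @slot seedBlockSide side of the square block each cell is seeded as (sites).
#' @slot contactNeighborOrder neighborhood order for the contact energy
#'   (1 = von Neumann/4-connected, 2 = Moore/8-connected).
#' @slot surfaceMeasure which surface measure enters the surface-constraint
#'   energy term: `"perimeter"` (default) uses the in-plane 4-neighbor
#'   boundary length `P`; `"voxel"` counts all exposed faces of the
#'   unit-thickness voxel representation of a 2-D cell, i.e. `2 V + P` (the
#'   convention of 3-D CPM frameworks running 2-D simulations).  Cached
#'   per-cell statistics always store `P`.
#' @slot chemotaxisMode `"advance"` applies the chemotaxis term only when a
#'   cell copies into the destination site (medium does not chemotax); this
#'   convention of the major CPM frameworks breaks detailed balance and
#'   sustains the active network remodeling of the model.  `"both"` is the
#'   conservative antisymmetric variant that also penalizes retraction from
#'   high concentration.
#' @slot pdeSubsteps explicit-Euler substeps of the field solver per MCS.
#'
#' @seealso [cpmParams()]
#' @exportClass CPMParams
setClass("CPMParams",
  representation(
    lambdaVolume = "numeric", VTarget = "numeric",
    lambdaSurface = "numeric", STarget = "numeric",
    JCellMedium = "numeric", JCellCell = "numeric",
    lambdaChemotaxis = "numeric", chemotaxisSaturation = "numeric",
    decayRate = "numeric", diffusionConstant = "numeric",
    secretionRate = "numeric", temperature = "numeric",
    latticeSize = "integer", nCellsInitial = "integer",
    seedBlockSide = "integer", contactNeighborOrder = "integer",
    surfaceMeasure = "character", chemotaxisMode = "character",
    pdeSubsteps = "integer"
  )
)

setValidity("CPMParams", function(object) {
  msg <- character()
  nonneg <- c(
    lambdaVolume = object@lambdaVolume, lambdaSurface = object@lambdaSurface,
    lambdaChemotaxis = object@lambdaChemotaxis,
    chemotaxisSaturation = object@chemotaxisSaturation,
    decayRate = object@decayRate, diffusionConstant = object@diffusionConstant,
    secretionRate = object@secretionRate
  )
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad)) msg <- c(msg, paste("must be finite and >= 0:", paste(bad, collapse = ", ")))
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@VTarget <= 0 || object@STarget <= 0) msg <- c(msg, "VTarget and STarget must be > 0")
  if (object@latticeSize < 8L) msg <- c(msg, "latticeSize must be >= 8")
  if (!object@contactNeighborOrder %in% c(1L, 2L)) msg <- c(msg, "contactNeighborOrder must be 1 or 2")
  if (!object@surfaceMeasure %in% c("voxel", "perimeter"))
    msg <- c(msg, "surfaceMeasure must be 'voxel' or 'perimeter'")
  if (!object@chemotaxisMode %in% c("advance", "both"))
    msg <- c(msg, "chemotaxisMode must be 'advance' or 'both'")
  if (object@pdeSubsteps < 1L) msg <- c(msg, "pdeSubsteps must be >= 1")
  if ((4 * object@diffusionConstant + object@decayRate) / object@pdeSubsteps > 1 + 1e-12)
    msg <- c(msg, "explicit field update unstable/non-positive: (4D+k)/pdeSubsteps must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Cellular-Potts lattice state
#'
#' The full mechanistic simulation state: the cell-id lattice (0 = medium,
#' positive integers = cell ids), the chemoattractant field, cached per-cell
#' volumes and boundary lengths, and the Monte-Carlo-step clock.  Validity
#' recounts the cached statistics from the lattice, so a valid object is
#' guaranteed internally consistent.
#'
#' @slot cellLattice integer matrix of cell ids.
#' @slot field numeric matrix of non-negative field concentrations.
#' @slot volumes integer vector; `volumes[i]` is the site count of cell `i`.
#' @slot surfaces integer vector; `surfaces[i]` is the number of 4-neighbor
#'   faces between cell `i` and any other id (periodic wraparound).
#' @slot mcs the Monte-Carlo-step clock.
#'
#' @seealso [initState()], [runMCS()]
#' @exportClass LatticeState
setClass("LatticeState",
  representation(
    cellLattice = "matrix", field = "matrix",
    volumes = "integer", surfaces = "integer", mcs = "numeric"
  )
)

setValidity("LatticeState", function(object) {
  msg <- character()
  lat <- object@cellLattice
  if (!is.integer(lat)) msg <- c(msg, "cellLattice must be an integer matrix")
  if (!identical(dim(lat), dim(object@field)))
    msg <- c(msg, "cellLattice and field must share a shape")
  if (any(!is.finite(object@field)) || any(object@field < 0))
    msg <- c(msg, "field values must be finite and >= 0")
  if (length(msg)) return(msg)
  if (any(lat < 0L) || any(lat > length(object@volumes)))
    return("lattice ids must lie in 0..length(volumes)")
  rec <- cpp_recount(lat, length(object@volumes))
  if (!identical(rec$volumes, object@volumes))
    msg <- c(msg, "cached volumes disagree with the lattice recount")
  if (!identical(rec$surfaces, object@surfaces))
    msg <- c(msg, "cached surfaces disagree with the lattice recount")
  if (length(object@mcs) != 1L || object@mcs < 0) msg <- c(msg, "mcs must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' A saved simulation trajectory
#'
#' Snapshot series emitted by [simulateVasculogenesis()]: the parameter set,
#' the RNG seed (recorded for exact replay), and an ordered list of
#' [LatticeState-class] snapshots at strictly increasing MCS values.
#'
#' @slot params the [CPMParams-class] used.
#' @slot seed integer RNG seed of the run.
#' @slot snapshots list of [LatticeState-class] objects.
#' @slot snapshotMCS numeric vector of the saved MCS values.
#' @slot metadata list of provenance fields (package version, timestamp).
#'
#' @exportClass SimulationRun
setClass("SimulationRun",
  representation(
    params = "CPMParams", seed = "integer",
    snapshots = "list", snapshotMCS = "numeric", metadata = "list"
  )
)

setValidity("SimulationRun", function(object) {
  msg <- character()
  if (length(object@snapshots) != length(object@snapshotMCS))
    msg <- c(msg, "snapshots and snapshotMCS lengths differ")
  if (length(object@snapshotMCS) > 1 && any(diff(object@snapshotMCS) <= 0))
    msg <- c(msg, "snapshot MCS values must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Two-channel rendered frame
#'
#' The surrogate's I/O unit: a binary vessel mask (1 = cell-occupied site)
#' and the chemoattractant field normalized by a recorded constant, at a
#' given MCS of a given simulation.
#'
#' @slot mask numeric matrix, strictly 0/1 for rendered ground truth; in
#'   (0, 1) for surrogate predictions (occupancy probabilities).
#' @slot field numeric matrix of normalized concentrations (>= 0).
#' @slot mcs MCS stamp of the frame (nominal for predicted frames).
#' @slot simId identifier of the source simulation.
#' @slot normalization the constant the raw field was divided by.
#'
#' @seealso [renderFrame()], [predictFrame()]
#' @exportClass TwoChannelFrame
setClass("TwoChannelFrame",
  representation(
    mask = "matrix", field = "matrix", mcs = "numeric",
    simId = "character", normalization = "numeric"
  )
)

setValidity("TwoChannelFrame", function(object) {
  msg <- character()
  if (!identical(dim(object@mask), dim(object@field)))
    msg <- c(msg, "mask and field must share a shape")
  if (any(object@mask < 0) || any(object@mask > 1))
    msg <- c(msg, "mask values must lie in [0, 1]")
  if (any(!is.finite(object@field)) || any(object@field < 0))
    msg <- c(msg, "field values must be finite and >= 0")
  if (object@normalization <= 0) msg <- c(msg, "normalization must be > 0")
  if (length(msg)) msg else TRUE
})

#' Paired training dataset
#'
#' Frames rendered from one or more simulations together with the index
#' pairs (input frame, frame one horizon later) and a seeded train/test
#' split over pairs.
#'
#' @slot frames list of [TwoChannelFrame-class] objects.
#' @slot pairs two-column integer matrix of (input, target) indices into
#'   `frames`.
#' @slot horizon prediction horizon in MCS.
#' @slot normalization field normalization constant shared by all frames.
#' @slot trainIdx,testIdx integer row indices of `pairs` in each split.
#'
#' @seealso [makeDataset()], [buildPairs()], [splitPairs()]
#' @exportClass PairDataset
setClass("PairDataset",
  representation(
    frames = "list", pairs = "matrix", horizon = "numeric",
    normalization = "numeric", trainIdx = "integer", testIdx = "integer"
  )
)

setValidity("PairDataset", function(object) {
  msg <- character()
  p <- object@pairs
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) && (min(p) < 1L || max(p) > length(object@frames)))
    msg <- c(msg, "pair indices out of range")
  if (length(intersect(object@trainIdx, object@testIdx)))
    msg <- c(msg, "train and test splits overlap")
  if (nrow(p)) {
    dm <- vapply(seq_len(nrow(p)), function(i)
      object@frames[[p[i, 2]]]@mcs - object@frames[[p[i, 1]]]@mcs, numeric(1))
    if (any(dm != object@horizon))
      msg <- c(msg, "every pair must span exactly one horizon")
  }
  if (length(msg)) msg else TRUE
})

#' Periodic U-Net surrogate model
#'
#' A convolutional encoder-decoder with skip connections, circular padding in
#' every convolution (so the network lives on the same torus as the lattice)
#' and PReLU activations.  The mask head emits occupancy logits (mapped
#' through a sigmoid at prediction time); the field head is linear.
#'
#' @slot config list of architecture and training settings
#'   (see [buildSurrogate()]).
#' @slot weights named list of parameter arrays.
#' @slot history data.frame of per-epoch losses (empty until trained).
#'
#' @seealso [buildSurrogate()], [trainSurrogate()], [predictFrame()]
#' @exportClass UNetSurrogate
setClass("UNetSurrogate",
  representation(config = "list", weights = "list", history = "data.frame")
)
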