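#' @name accessors
#' @title Accessors for simulation and dataset objects
#'
#' @description Slot accessors for the core classes.  `cellLattice()` and
#' `chemField()` return the id lattice and concentration field of a
#' [LatticeState-class]; `cellVolumes()` / `cellSurfaces()` the cached
#' per-cell statistics (named by cell id, zero-volume cells dropped);
#' `mcsClock()` the Monte-Carlo clock; `nCells()` the number of live cells.
#' `snapshotMCS()` and `getSnapshot()` index into a [SimulationRun-class];
#' `frameMask()` / `frameField()` access a [TwoChannelFrame-class].
#'
#' @param x the object.
#' @param mcs MCS value of the snapshot to fetch.
#' @return the corresponding slot value (see Description).
#' @examples
#' p <- cpmParams(latticeSize = 16L, nCellsInitial = 2L)
#' st <- initState(p, seed = 1)
#' nCells(st)
#' dim(cellLattice(st))
NULL

#' @rdname accessors
#' @export
setGeneric("cellLattice", function(x) standardGeneric("cellLattice"))
#' @rdname accessors
#' @export
setGeneric("chemField", function(x) standardGeneric("chemField"))
#' @rdname accessors
#' @export
setGeneric("cellVolumes", function(x) standardGeneric("cellVolumes"))
#' @rdname accessors
#' @export
setGeneric("cellSurfaces", function(x) standardGeneric("cellSurfaces"))
#' @rdname accessors
#' @export
setGeneric("mcsClock", function(x) standardGeneric("mcsClock"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("snapshotMCS", function(x) standardGeneric("snapshotMCS"))
#' @rdname accessors
#' @export
setGeneric("getSnapshot", function(x, mcs) standardGeneric("getSnapshot"))
#' @rdname accessors
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))
#' @rdname accessors
#' @export
setGeneric("frameField", function(x) standardGeneric("frameField"))

#' @rdname accessors
setMethod("cellLattice", "LatticeState", function(x) x@cellLattice)
#' @rdname accessors
setMethod("chemField", "LatticeState", function(x) x@field)
#' @rdname accessors
setMethod("cellVolumes", "LatticeState", function(x) {
  v <- x@volumes
  names(v) <- seq_along(v)
  v[v > 0L]
})
#' @rdname accessors
setMethod("cellSurfaces", "LatticeState", function(x) {
  s <- x@surfaces
  names(s) <- seq_along(s)
  s[x@volumes > 0L]
})
#' @rdname accessors
setMethod("mcsClock", "LatticeState", function(x) x@mcs)
#' @rdname accessors
setMethod("nCells", "LatticeState", function(x) sum(x@volumes > 0L))
#' @rdname accessors
setMethod("snapshotMCS", "SimulationRun", function(x) x@snapshotMCS)
#' @rdname accessors
setMethod("getSnapshot", "SimulationRun", function(x, mcs) {
  i <- match(mcs, x@snapshotMCS)
  if (is.na(i)) stop("no snapshot at MCS ", mcs)
  x@snapshots[[i]]
})
#' @rdname accessors
setMethod("frameMask", "TwoChannelFrame", function(x) x@mask)
#' @rdname accessors
setMethod("frameField", "TwoChannelFrame", function(x) x@field)

setMethod("show", "CPMParams", function(object) {
  cat("CPMParams:", object@latticeSize, "x", object@latticeSize,
      "periodic lattice,", object@nCellsInitial, "cells\n")
  cat(sprintf("  volume %g (target %g) | surface %g (target %g)\n",
              object@lambdaVolume, object@VTarget,
              object@lambdaSurface, object@STarget))
  cat(sprintf("  J cell-medium %g | J cell-cell %g | T %g\n",
              object@JCellMedium, object@JCellCell, object@temperature))
  cat(sprintf("  chemotaxis %g (saturation %g) | field D %g, k %g, secretion %g (%d substeps)\n",
              object@lambdaChemotaxis, object@chemotaxisSaturation,
              object@diffusionConstant, object@decayRate,
              object@secretionRate, object@pdeSubsteps))
})

setMethod("show", "LatticeState", function(object) {
  d <- dim(object@cellLattice)
  cat(sprintf("LatticeState %dx%d at MCS %g: %d cells, vessel area %d sites, field total %.4g\n",
              d[1], d[2], object@mcs, sum(object@volumes > 0L),
              sum(object@volumes), sum(object@field)))
})

setMethod("show", "SimulationRun", function(object) {
  n <- length(object@snapshotMCS)
  cat(sprintf("SimulationRun (seed %d): %d snapshots", object@seed, n))
  if (n) cat(sprintf(" at MCS %g..%g", min(object@snapshotMCS), max(object@snapshotMCS)))
  cat("\n")
  show(object@params)
})

setMethod("show", "TwoChannelFrame", function(object) {
  d <- dim(object@mask)
  cat(sprintf("TwoChannelFrame %dx%d (sim %s, MCS %g): mask sum %.1f, field mean %.4g\n",
              d[1], d[2], object@simId, object@mcs,
              sum(object@mask), mean(object@field)))
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf("PairDataset: %d frames, %d pairs (horizon %g MCS), %d train / %d test\n",
              length(object@frames), nrow(object@pairs), object@horizon,
              length(object@trainIdx), length(object@testIdx)))
})

setMethod("show", "UNetSurrogate", function(object) {
  np <- sum(vapply(object@weights, length, numeric(1)))
  cat(sprintf("UNetSurrogate: depth %d, base channels %d, %s parameters%s\n",
              object@config$depth, object@config$baseChannels,
              format(np, big.mark = ","),
              if (nrow(object@history)) sprintf(", trained %d epochs", nrow(object@history)) else " (untrained)"))
})
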