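#' Initialize a vasculogenesis lattice
#'
#' Places `nCellsInitial` non-overlapping cells uniformly at random on the
#' periodic lattice, each seeded as a `seedBlockSide` x `seedBlockSide`
#' square block (default 5x5, i.e. initial volume 25, below the target
#' volume of 50 so cells grow during the early simulation).  The field
#' starts at zero.
#'
#' @param params a [CPMParams-class].
#' @param seed optional integer seed; when supplied the R RNG is seeded
#'   before placement.
#' @param maxRetries placement retries per cell before giving up.
#' @return a [LatticeState-class] at MCS 0.
#' @examples
#' st <- initState(cpmParams(latticeSize = 64L, nCellsInitial = 20L), seed = 1)
#' nCells(st)
#' @export
initState <- function(params, seed = NULL, maxRetries = 500L) {
  stopifnot(is(params, "CPMParams"))
  if (!is.null(seed)) set.seed(seed)
  L <- params@latticeSize
  side <- params@seedBlockSide
  n <- params@nCellsInitial
  if (n * side^2 > L^2)
    stop("initial cell footprints exceed the lattice capacity")
  lat <- matrix(0L, L, L)
  occupied <- matrix(FALSE, L, L)
  for (id in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      r0 <- sample.int(L, 1L) - 1L
      c0 <- sample.int(L, 1L) - 1L
      rows <- (r0 + seq_len(side) - 1L) %% L + 1L
      cols <- (c0 + seq_len(side) - 1L) %% L + 1L
      if (any(occupied[rows, cols])) next
      occupied[rows, cols] <- TRUE
      lat[rows, cols] <- id
      placed <- TRUE
      break
    }
    if (!placed)
      stop("failed to place cell ", id, " after ", maxRetries,
           " retries; lower nCellsInitial or enlarge the lattice")
  }
  latticeState(lat)
}

#' Run a vasculogenesis simulation and save snapshots
#'
#' Initializes the lattice, runs an unsaved burn-in up to `mcsStartSave`
#' (during which randomly placed cells settle into vascular-like
#' structures), then advances in `saveEvery`-MCS increments, saving a
#' snapshot at every saved MCS through `mcsEnd`.  The whole trajectory is a
#' deterministic function of `(params, seed)`.
#'
#' @param params a [CPMParams-class].
#' @param seed integer RNG seed (mandatory; recorded in the result).
#' @param mcsStartSave first saved MCS (the burn-in length), default 200.
#' @param mcsEnd last simulated and saved MCS.
#' @param saveEvery snapshot cadence in MCS (>= 1).
#' @param verbose print progress every saved snapshot.
#' @return a [SimulationRun-class].
#' @examples
#' p <- cpmParams(latticeSize = 32L, nCellsInitial = 8L)
#' run <- simulateVasculogenesis(p, seed = 1, mcsStartSave = 10,
#'                               mcsEnd = 30, saveEvery = 10)
#' snapshotMCS(run)
#' @export
simulateVasculogenesis <- function(params, seed, mcsStartSave = 200,
                                   mcsEnd = 20000, saveEvery = 1,
                                   verbose = FALSE) {
  stopifnot(is(params, "CPMParams"), mcsStartSave <= mcsEnd, saveEvery >= 1)
  seed <- as.integer(seed)
  set.seed(seed)
  state <- initState(params)
  if (mcsStartSave > 0) state <- runMCS(state, params, mcsStartSave)
  saveMCS <- seq(mcsStartSave, mcsEnd, by = saveEvery)
  snapshots <- vector("list", length(saveMCS))
  snapshots[[1]] <- state
  for (i in seq_along(saveMCS)[-1]) {
    state <- runMCS(state, params, saveMCS[i] - saveMCS[i - 1])
    snapshots[[i]] <- state
    if (verbose && (i %% 50L == 0L || i == length(saveMCS)))
      message(sprintf("  MCS %g (acceptance %.3f)", saveMCS[i],
                      attr(state, "acceptanceRate")))
  }
  new("SimulationRun", params = params, seed = seed,
      snapshots = snapshots, snapshotMCS = as.numeric(saveMCS),
      metadata = list(package = "cpmunet",
                      version = as.character(utils::packageVersion("cpmunet")),
                      timestamp = format(Sys.time(), tz = "UTC")))
}

#' Calibrate the unconstrained field parameters
#'
#' The diffusion constant and secretion rate of the chemoattractant are not
#' fixed by the published parameter table; this reporting tool runs short
#' simulations over a small grid of candidate `(D, secretionRate)` values
#' and summarizes the resulting morphology, so defaults can be chosen that
#' reproduce a connected vascular network with enclosed lacunae (rather than
#' one compact aggregate or dispersed cells).
#'
#' @param candidates data.frame with columns `D` and `secretionRate`.
#' @param baseParams the [CPMParams-class] whose other values are held fixed.
#' @param mcs simulation length per candidate.
#' @param seed RNG seed shared by all candidate runs.
#' @param minLacunaArea lacunae below this area are ignored in the counts.
#' @return data.frame with one row per candidate: the lacunae count, median
#'   lacuna area, vessel area fraction, mean field level relative to the
#'   saturation scale `secretionRate / k`, and Monte-Carlo acceptance rate.
#' @seealso [lacunaeAreas()]
#' @export
calibrateFieldParams <- function(candidates, baseParams = cpmParams(),
                                 mcs = 2000, seed = 1, minLacunaArea = 50) {
  stopifnot(is.data.frame(candidates),
            all(c("D", "secretionRate") %in% names(candidates)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    p <- baseParams
    p@diffusionConstant <- candidates$D[i]
    p@secretionRate <- candidates$secretionRate[i]
    p@pdeSubsteps <- max(p@pdeSubsteps,
      as.integer(ceiling(4 * p@diffusionConstant + p@decayRate)))
    validObject(p)
    set.seed(seed)
    st <- initState(p)
    st <- runMCS(st, p, mcs)
    mask <- cellLattice(st) > 0L
    areas <- lacunaeAreas(mask)
    big <- areas[areas >= minLacunaArea]
    cstar <- if (p@decayRate > 0) p@secretionRate / p@decayRate else NA_real_
    data.frame(D = p@diffusionConstant, secretionRate = p@secretionRate,
               nLacunae = length(big),
               medianLacunaArea = if (length(big)) median(big) else NA_real_,
               vesselFraction = mean(mask),
               fieldMeanRel = if (is.na(cstar) || cstar == 0) NA_real_
                              else mean(chemField(st)) / cstar,
               acceptanceRate = attr(st, "acceptanceRate"))
  })
  do.call(rbind, rows)
}
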