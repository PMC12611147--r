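#' Render a lattice state as a two-channel frame
#'
#' Channel 1 is the binary vessel mask (`cell id > 0`); channel 2 is the
#' field concentration divided by `normalization`.  The default
#' normalization elsewhere in the package is the saturation scale
#' `secretionRate / decayRate`, the analytic fixed point of the field
#' equation under blanket secretion, which puts typical concentrations on an
#' O(1) scale.
#'
#' @param state a [LatticeState-class].
#' @param normalization positive normalization constant for the field.
#' @param simId identifier recorded in the frame.
#' @return a [TwoChannelFrame-class].
#' @export
renderFrame <- function(state, normalization, simId = "sim") {
  stopifnot(is(state, "LatticeState"), normalization > 0)
  new("TwoChannelFrame",
      mask = (state@cellLattice > 0L) + 0,
      field = state@field / normalization,
      mcs = state@mcs, simId = simId, normalization = normalization)
}

#' Build (input, target) index pairs across the prediction horizon
#'
#' Given the saved MCS values of one simulation, returns the index pairs
#' `(t, t + horizon)` under the half-open window convention: a pair is
#' formed for every saved `t` with `t + horizon` also saved and
#' `t + horizon < max(mcsList)` (the pair whose target would be the final
#' snapshot is excluded).  On the standard protocol - unit cadence over MCS
#' 200 to 20,000 with horizon 100 - this yields 19,700 pairs per simulation.
#'
#' @param mcsList numeric vector of saved MCS values (strictly increasing).
#' @param horizon prediction horizon in MCS (default 100).
#' @return two-column integer matrix of (input, target) indices into
#'   `mcsList`; zero rows when the horizon exceeds the span.
#' @examples
#' nrow(buildPairs(200:20000))          # 19700
#' nrow(buildPairs(0:300))              # 200
#' nrow(buildPairs(0:100))              # 0
#' @export
buildPairs <- function(mcsList, horizon = 100) {
  stopifnot(length(mcsList) >= 1, all(diff(mcsList) > 0), horizon > 0)
  tgt <- match(mcsList + horizon, mcsList)
  ok <- !is.na(tgt) & (mcsList + horizon) < max(mcsList)
  cbind(input = which(ok), target = tgt[ok])
}

#' Split pairs into train and test sets
#'
#' Seeded random split over pairs (the literal protocol), or over whole
#' simulations (`by = "simulation"`, avoiding temporal leakage between
#' splits).  The train split takes `floor(fraction * n)` pairs; the test
#' split takes the remainder; the two are disjoint and exhaustive.
#'
#' @param n number of pairs, or a [PairDataset-class].
#' @param fraction train fraction in (0, 1), default 0.8.
#' @param seed integer seed for the shuffle.
#' @param by `"pair"` or `"simulation"`.
#' @return for `n` numeric: list with integer vectors `train` and `test`.
#'   For a [PairDataset-class]: the dataset with its split slots filled.
#' @examples
#' splitPairs(10, seed = 1)   # 8 train, 2 test
#' @export
splitPairs <- function(n, fraction = 0.8, seed = 1, by = c("pair", "simulation")) {
  by <- match.arg(by)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  if (is(n, "PairDataset")) {
    ds <- n
    np <- nrow(ds@pairs)
    if (np == 0L) stop("dataset has no pairs to split")
    if (by == "simulation") {
      sims <- vapply(ds@frames, function(f) f@simId, character(1))
      pairSim <- sims[ds@pairs[, 1]]
      u <- unique(pairSim)
      set.seed(seed)
      ntr <- max(1L, min(length(u) - 1L, floor(fraction * length(u))))
      trainSims <- sample(u, ntr)
      ds@trainIdx <- which(pairSim %in% trainSims)
      ds@testIdx <- which(!pairSim %in% trainSims)
    } else {
      sp <- splitPairs(np, fraction, seed)
      ds@trainIdx <- sp$train
      ds@testIdx <- sp$test
    }
    validObject(ds)
    return(ds)
  }
  n <- as.integer(n)
  if (n < 1L) stop("cannot split an empty pair set")
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- floor(fraction * n)
  list(train = sort(perm[seq_len(ntr)]),
       test = sort(perm[setdiff(seq_len(n), seq_len(ntr))]))
}

#' Assemble a paired dataset from simulation runs
#'
#' Renders every snapshot of the given runs into two-channel frames, builds
#' the (t, t + horizon) pairs within each run, and applies the seeded
#' train/test split.
#'
#' @param runs a [SimulationRun-class] or list of them.
#' @param horizon prediction horizon in MCS.
#' @param normalization field normalization; default is the saturation
#'   scale `secretionRate / decayRate` of the first run's parameters.
#' @param splitFraction train fraction.
#' @param seed seed for the split.
#' @param splitBy `"pair"` or `"simulation"`.
#' @return a [PairDataset-class].
#' @export
makeDataset <- function(runs, horizon = 100, normalization = NULL,
                        splitFraction = 0.8, seed = 1,
                        splitBy = c("pair", "simulation")) {
  splitBy <- match.arg(splitBy)
  if (is(runs, "SimulationRun")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  if (is.null(normalization)) {
    p <- runs[[1]]@params
    normalization <- if (p@decayRate > 0 && p@secretionRate > 0)
      p@secretionRate / p@decayRate else 1
  }
  frames <- list()
  pairs <- NULL
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    offset <- length(frames)
    fr <- lapply(seq_along(run@snapshots), function(i)
      renderFrame(run@snapshots[[i]], normalization,
                  simId = sprintf("sim%d_seed%d", ri, run@seed)))
    frames <- c(frames, fr)
    pr <- buildPairs(run@snapshotMCS, horizon)
    if (nrow(pr)) pairs <- rbind(pairs, pr + offset)
  }
  if (is.null(pairs)) pairs <- cbind(input = integer(0), target = integer(0))
  ds <- new("PairDataset", frames = frames, pairs = pairs,
            horizon = horizon, normalization = normalization,
            trainIdx = integer(0), testIdx = integer(0))
  if (nrow(pairs)) ds <- splitPairs(ds, splitFraction, seed, splitBy)
  ds
}

.DATASET_FORMAT <- 1L

#' Persist and reload datasets
#'
#' `writeDataset()` serializes a [PairDataset-class] to an RDS container
#' with a format-version stamp; `readDataset()` reloads it, refusing files
#' with a mismatched format version or internally inconsistent shapes.  The
#' round trip is exact.
#'
#' @param dataset a [PairDataset-class].
#' @param path file path.
#' @return `writeDataset()` returns `path` invisibly; `readDataset()`
#'   returns the [PairDataset-class].
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "PairDataset"))
  saveRDS(list(format = .DATASET_FORMAT, dataset = dataset), path)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, .DATASET_FORMAT))
    stop("not a cpmunet dataset container (or unsupported format version)")
  ds <- obj$dataset
  if (!is(ds, "PairDataset")) stop("corrupted dataset container")
  validObject(ds)
  if (length(ds@frames)) {
    d0 <- dim(ds@frames[[1]]@mask)
    same <- vapply(ds@frames, function(f) identical(dim(f@mask), d0), logical(1))
    if (!all(same)) stop("corrupted dataset: frames disagree in shape")
  }
  ds
}
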