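#' Sorenson-Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, defined as 1 when both masks are empty.
#' Numeric inputs (e.g. surrogate occupancy probabilities) are thresholded
#' at 0.5 before comparison.
#'
#' @param a,b matrices of the same shape (logical, 0/1, or probabilities).
#' @return a number in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' diceScore(m, m)                       # 1
#' diceScore(m, 1 - m)                   # 0
#' @export
diceScore <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  a <- a >= 0.5
  b <- b >= 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Mean squared error between two field images
#'
#' @param a,b numeric matrices of the same shape (normalized concentration).
#' @return mean of squared per-site differences.
#' @export
fieldMSE <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("field shape mismatch")
  mean((a - b)^2)
}

# second-central-moment (inertia-tensor) eigenvalues of a pixel region,
# rounded for signature matching
.regionEigen <- function(rows, cols, digits = 6) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  mu20 <- sum((rows - mr)^2) / n
  mu02 <- sum((cols - mc)^2) / n
  mu11 <- sum((rows - mr) * (cols - mc)) / n
  tr <- mu20 + mu02
  disc <- sqrt(max(0, (mu20 - mu02)^2 / 4 + mu11^2))
  round(sort(c(tr / 2 + disc, tr / 2 - disc)), digits)
}

#' Areas of the lacunae of a vessel mask
#'
#' A lacuna is an enclosed medium region ("hole") of the vessel network on
#' the periodic lattice.  Two extraction methods are provided:
#'
#' - `"torus"` (default, exact): connected-component labeling of the medium
#'   sites directly on the torus (wraparound adjacency), so every lacuna is
#'   counted once with its true area regardless of where it straddles the
#'   boundary.
#' - `"tiled"`: the plus-shaped tiling procedure: the mask is patterned
#'   above, below, left and right of itself, medium regions of the tiled
#'   canvas are labeled in the plane, each region is summarized by the
#'   signature (area, inertia-tensor eigenvalues) together with its
#'   canonical footprint modulo the lattice size, duplicates are dropped so
#'   torus-wrapped copies count once (the footprint keeps distinct lacunae
#'   of identical shape apart), and regions touching the outer frame of the
#'   canvas (fragments the plus arrangement cannot close, including the
#'   unbounded exterior) are discarded.
#'
#' Both methods drop regions smaller than `minArea` (default 3 sites):
#' 1-2-site holes are transient artifacts of the stochastic lattice-site
#' exchanges, not lacunae.  The tiled procedure cannot close regions that
#' wrap the corner of the lattice diagonally and is therefore an
#' approximation; the torus labeling is the authoritative semantics and the
#' two agree whenever no lacuna straddles both periodic axes at once.
#'
#' @param mask logical or 0/1 matrix, TRUE/1 = vessel.
#' @param minArea smallest lacuna area kept (sites).
#' @param connectivity 4 (default) or 8; medium regions use 4-connectivity
#'   so that they cannot leak diagonally through vessel walls.
#' @param method `"torus"` or `"tiled"`.
#' @return integer vector of lacunae areas (possibly empty).
#' @examples
#' m <- matrix(1, 16, 16); m[5:8, 5:8] <- 0     # one 16-site hole
#' lacunaeAreas(m)
#' @export
lacunaeAreas <- function(mask, minArea = 3, connectivity = 4,
                         method = c("torus", "tiled")) {
  method <- match.arg(method)
  mask <- mask >= 0.5
  if (!is.matrix(mask)) stop("mask must be a matrix")
  medium <- !mask
  if (method == "torus") {
    lab <- cpp_label(medium, as.integer(connectivity), TRUE)
    areas <- tabulate(lab[lab > 0L])
  } else {
    H <- nrow(mask); W <- ncol(mask)
    # plus-shaped arrangement; the unpatterned corners stay medium, so any
    # region fragment the plus cannot close drains into the frame-touching
    # corner sea and is discarded with it
    canvas <- matrix(FALSE, 3 * H, 3 * W)
    put <- function(ro, co) canvas[ro + seq_len(H), co + seq_len(W)] <<- mask
    put(H, W); put(0, W); put(2 * H, W); put(H, 0); put(H, 2 * W)
    lab <- cpp_label(!canvas, as.integer(connectivity), FALSE)
    n <- max(lab)
    if (n == 0L) return(integer(0))
    idx <- which(lab > 0L)
    rows <- (idx - 1L) %% (3L * H) + 1L
    cols <- (idx - 1L) %/% (3L * H) + 1L
    labs <- lab[idx]
    onFrame <- unique(labs[rows == 1L | rows == 3L * H |
                           cols == 1L | cols == 3L * W])
    areas <- integer(0)
    sigs <- character(0)
    for (l in setdiff(seq_len(n), onFrame)) {
      sel <- labs == l
      # shape signature (area + inertia-tensor eigenvalues) plus the canonical
      # torus footprint: wrapped copies of one lacuna share both, while
      # distinct lacunae that merely happen to share a shape do not
      foot <- sort(unique(((rows[sel] - 1L) %% H) + H * ((cols[sel] - 1L) %% W)))
      sig <- paste(c(sum(sel), .regionEigen(rows[sel], cols[sel]), foot),
                   collapse = "/")
      if (sig %in% sigs) next
      sigs <- c(sigs, sig)
      areas <- c(areas, sum(sel))
    }
  }
  sort(as.integer(areas[areas >= minArea]))
}

#' Earth-mover's (Wasserstein-1) distance between two area multisets
#'
#' The 1-D Wasserstein-1 distance between the empirical distributions of the
#' two samples with equal total mass (each sample normalized to weight 1),
#' computed from the closed form `integral |F_a(x) - F_b(x)| dx` over the
#' merged support.  Used to compare lacunae-area distributions, so the
#' result is in lattice sites.
#'
#' @param a,b numeric vectors (e.g. [lacunaeAreas()] outputs).  Both empty
#'   returns 0 by convention; exactly one empty is an error (an empty
#'   lacunae set carries no distribution to compare - check
#'   `length(areas) > 0` upstream).
#' @return a non-negative number.
#' @examples
#' areaEMD(c(10), c(25))        # 15
#' areaEMD(1:5, 1:5)            # 0
#' @export
areaEMD <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  if (length(a) == 0 || length(b) == 0)
    stop("one area set is empty; EMD between an empty and a non-empty ",
         "distribution is undefined - filter degenerate frames first")
  x <- sort(unique(c(a, b)))
  if (length(x) == 1L) return(0)
  Fa <- vapply(x, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(x, function(t) mean(b <= t), numeric(1))
  n <- length(x)
  sum(abs(Fa[-n] - Fb[-n]) * diff(x))
}

#' Vessel-area and field-sum divergence diagnostics
#'
#' Tracks, per rollout step, the vessel area (thresholded-mask site count)
#' and the un-normalized total field concentration of predicted frames
#' against ground truth.  These two conserved-order quantities reveal the
#' mechanism by which recursive surrogate predictions drift: loss of vessel
#' area and of total field mass.
#'
#' @param framesPred,framesTruth lists of [TwoChannelFrame-class] objects,
#'   aligned step by step.
#' @return data.frame with columns `step`, `mcs`, `vesselAreaPred`,
#'   `vesselAreaTruth`, `fieldSumPred`, `fieldSumTruth`.
#' @export
divergenceDiagnostics <- function(framesPred, framesTruth) {
  if (length(framesPred) != length(framesTruth))
    stop("prediction and truth frame lists differ in length")
  rows <- lapply(seq_along(framesPred), function(i) {
    p <- framesPred[[i]]; t <- framesTruth[[i]]
    data.frame(step = i, mcs = t@mcs,
               vesselAreaPred = sum(p@mask >= 0.5),
               vesselAreaTruth = sum(t@mask >= 0.5),
               fieldSumPred = sum(p@field) * p@normalization,
               fieldSumTruth = sum(t@field) * t@normalization)
  })
  do.call(rbind, rows)
}

#' Evaluate a surrogate rollout against ground truth and the frozen reference
#'
#' For each evaluation run, takes the true state at `t0Mcs` as the initial
#' frame, rolls the surrogate forward `nIterations` steps of `horizon` MCS,
#' and at every step compares (i) the surrogate prediction and (ii) the
#' frozen initial frame ("reference baseline", the do-nothing predictor the
#' surrogate must beat) against the true simulation state at that MCS, using
#' the Dice score on the vessel masks, MSE on the normalized field, and the
#' earth-mover's distance between lacunae-area distributions.
#'
#' @param model a trained [UNetSurrogate-class], or any function mapping a
#'   [TwoChannelFrame-class] to the next frame (useful for oracle or
#'   identity baselines).
#' @param evalRuns list of [SimulationRun-class] objects containing ground
#'   truth at `t0Mcs + horizon * (1:nIterations)`.
#' @param t0Mcs MCS of the initial configuration handed to the surrogate.
#' @param nIterations number of recursive prediction steps.
#' @param horizon MCS per prediction step.
#' @param normalization field normalization constant; defaults to the
#'   saturation scale `secretionRate / decayRate` of the run parameters.
#' @param emdMinArea smallest lacuna area entering the EMD.
#' @return list with `perStep` (data.frame, one row per run and step:
#'   `dicePred`, `diceRef`, `msePred`, `mseRef`, `emdPred`, `emdRef`, plus
#'   divergence diagnostics) and `summary` (mean and s.d. across runs per
#'   step).
#' @export
evaluateRollout <- function(model, evalRuns, t0Mcs = 2000, nIterations = 100,
                            horizon = 100, normalization = NULL,
                            emdMinArea = 3) {
  if (is(evalRuns, "SimulationRun")) evalRuns <- list(evalRuns)
  predictor <- if (is.function(model)) model else function(fr) predictFrame(model, fr)
  perRun <- lapply(seq_along(evalRuns), function(ri) {
    run <- evalRuns[[ri]]
    norm <- normalization
    if (is.null(norm)) {
      k <- run@params@decayRate
      norm <- if (k > 0 && run@params@secretionRate > 0)
        run@params@secretionRate / k else 1
    }
    need <- t0Mcs + horizon * (0:nIterations)
    if (!all(need %in% run@snapshotMCS))
      stop("run ", ri, " lacks ground-truth snapshots at MCS ",
           paste(setdiff(need, run@snapshotMCS), collapse = ", "))
    ref <- renderFrame(getSnapshot(run, t0Mcs), norm, simId = paste0("run", ri))
    fr <- ref
    rows <- vector("list", nIterations)
    for (i in seq_len(nIterations)) {
      fr <- predictor(fr)
      truth <- renderFrame(getSnapshot(run, t0Mcs + i * horizon), norm,
                           simId = paste0("run", ri))
      tArea <- lacunaeAreas(truth@mask, minArea = emdMinArea)
      pArea <- lacunaeAreas(fr@mask, minArea = emdMinArea)
      rArea <- lacunaeAreas(ref@mask, minArea = emdMinArea)
      safeEMD <- function(x, y)
        if (length(x) == 0 || length(y) == 0) NA_real_ else areaEMD(x, y)
      rows[[i]] <- data.frame(
        run = ri, step = i, mcs = truth@mcs,
        dicePred = diceScore(fr@mask, truth@mask),
        diceRef = diceScore(ref@mask, truth@mask),
        msePred = fieldMSE(fr@field, truth@field),
        mseRef = fieldMSE(ref@field, truth@field),
        emdPred = safeEMD(pArea, tArea),
        emdRef = safeEMD(rArea, tArea),
        vesselAreaPred = sum(fr@mask >= 0.5),
        vesselAreaTruth = sum(truth@mask >= 0.5),
        fieldSumPred = sum(fr@field) * norm,
        fieldSumTruth = sum(truth@field) * norm)
    }
    do.call(rbind, rows)
  })
  perStep <- do.call(rbind, perRun)
  metricCols <- setdiff(names(perStep), c("run", "step", "mcs"))
  agg <- lapply(split(perStep, perStep$step), function(d) {
    out <- data.frame(step = d$step[1], mcs = d$mcs[1])
    for (cn in metricCols) {
      out[[paste0(cn, "Mean")]] <- mean(d[[cn]], na.rm = TRUE)
      out[[paste0(cn, "SD")]] <- sd(d[[cn]], na.rm = TRUE)
    }
    out
  })
  list(perStep = perStep, summary = do.call(rbind, agg))
}
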