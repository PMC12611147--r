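#' Field-update configuration
#'
#' Settings for the explicit finite-difference solver of the
#' secretion-diffusion-decay equation `dc/dt = D lap(c) - k c + secretion`
#' on the periodic lattice.  `nSubsteps` Euler substeps of size `dt` make up
#' one MCS (`nSubsteps * dt == 1`).  Stability and positivity of the 2-D
#' explicit scheme require `(4 D + k) * dt <= 1` (the center-point weight
#' `1 - 4 D dt - k dt` must stay non-negative); violations are refused
#' rather than integrated.
#'
#' @param D diffusion constant (sites^2/MCS).
#' @param k decay rate (1/MCS).
#' @param secretionRate concentration added per MCS at secreting sites.
#' @param nSubsteps number of substeps per MCS; `dt = 1/nSubsteps`.
#' @return an object of class `FieldUpdateConfig`.
#' @examples
#' fieldUpdateConfig(D = 2, k = 0.6, secretionRate = 0.5, nSubsteps = 10)
#' @export
fieldUpdateConfig <- function(D, k, secretionRate, nSubsteps = 1L) {
  nSubsteps <- as.integer(nSubsteps)
  if (nSubsteps < 1L) stop("nSubsteps must be >= 1")
  dt <- 1 / nSubsteps
  if (D < 0 || k < 0 || secretionRate < 0) stop("D, k and secretionRate must be >= 0")
  if ((4 * D + k) * dt > 1 + 1e-12)
    stop(sprintf("explicit field update unstable/non-positive: (4D+k)*dt = %.4g > 1; increase nSubsteps",
                 (4 * D + k) * dt))
  structure(list(D = D, k = k, secretionRate = secretionRate,
                 dt = dt, nSubsteps = nSubsteps),
            class = "FieldUpdateConfig")
}

#' Advance the chemoattractant field by one MCS
#'
#' Applies `nSubsteps` explicit Euler updates of the 5-point periodic
#' Laplacian with first-order decay, adding `secretionRate * dt` per substep
#' at every site where `secretionMask` is `TRUE`.
#'
#' @param field numeric matrix of finite, non-negative concentrations.
#' @param secretionMask logical matrix of the same shape (TRUE at
#'   cell-occupied sites).
#' @param cfg a [fieldUpdateConfig()].
#' @return the updated field matrix (non-negative).
#' @examples
#' cfg <- fieldUpdateConfig(D = 1, k = 0.5, secretionRate = 1, nSubsteps = 4)
#' f <- stepField(matrix(0, 16, 16), matrix(TRUE, 16, 16), cfg)
#' max(abs(f - f[1, 1]))  # uniform secretion keeps the field uniform
#' @export
stepField <- function(field, secretionMask, cfg) {
  stopifnot(inherits(cfg, "FieldUpdateConfig"))
  if (!identical(dim(field), dim(secretionMask))) stop("field/mask shape mismatch")
  if (any(!is.finite(field)) || any(field < 0)) stop("field must be finite and >= 0")
  storage.mode(secretionMask) <- "logical"
  cpp_step_field(field, secretionMask, cfg$D, cfg$k, cfg$secretionRate,
                 cfg$dt, cfg$nSubsteps)
}

#' Mass-balance residual of a field update
#'
#' Periodic diffusion conserves total mass exactly, decay removes
#' `k * dt * total` per substep and secretion adds `rate * dt * n_sites`,
#' so the post-update total is determined by the pre-update total alone.
#' Returns the absolute discrepancy between the observed total and that
#' closed-form expectation; for a correct solver it is floating-point noise
#' (well below `1e-6 * total`).
#'
#' @param before,after field matrices around one [stepField()] call.
#' @param cfg the [fieldUpdateConfig()] used.
#' @param secretionMask the secretion mask used.
#' @return the absolute residual (a single number).
#' @export
fieldMassBalance <- function(before, after, cfg, secretionMask) {
  stopifnot(inherits(cfg, "FieldUpdateConfig"))
  if (!identical(dim(before), dim(after)) ||
      !identical(dim(before), dim(secretionMask)))
    stop("shape mismatch between fields and mask")
  total <- sum(before)
  nsec <- sum(secretionMask)
  for (i in seq_len(cfg$nSubsteps))
    total <- total * (1 - cfg$k * cfg$dt) + cfg$dt * cfg$secretionRate * nsec
  abs(sum(after) - total)
}
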