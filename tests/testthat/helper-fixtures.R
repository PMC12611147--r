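# small fixtures shared across the suite

smallParams <- function(...) {
  cpmParams(latticeSize = 16L, nCellsInitial = 2L, seedBlockSide = 3L, ...)
}

# a hand-made state: one rectangular cell on an empty lattice
rectState <- function(L = 12L, r = 4:7, c = 5:8, field = NULL) {
  lat <- matrix(0L, L, L)
  lat[r, c] <- 1L
  latticeState(lat, field)
}

# random multi-cell lattice with a random non-negative field
randomState <- function(L = 12L, nid = 3L, pCell = 0.6) {
  lat <- matrix(0L, L, L)
  pick <- runif(L * L) < pCell
  lat[pick] <- sample.int(nid, sum(pick), replace = TRUE)
  latticeState(lat, matrix(runif(L * L), L, L))
}

# a random copy attempt with distinct ids; NULL if none found
randomAttempt <- function(state, tries = 200L) {
  lat <- state@cellLattice
  L <- nrow(lat)
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (i in seq_len(tries)) {
    s <- c(sample.int(L, 1L), sample.int(L, 1L))
    d <- dirs[[sample.int(4L, 1L)]]
    dst <- (s - 1L + d) %% L + 1L
    if (lat[s[1], s[2]] != lat[dst[1], dst[2]]) return(list(source = s, dest = dst))
  }
  NULL
}

cyclicShift <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(p) - 1 - dc) %% p) + 1] <-
    m[seq_len(n), seq_len(p)]
  m
}

makeFrame <- function(mask, field = NULL, mcs = 0, norm = 1, simId = "t") {
  if (is.null(field)) field <- matrix(0, nrow(mask), ncol(mask))
  new("TwoChannelFrame", mask = mask + 0, field = field, mcs = mcs,
      simId = simId, normalization = norm)
}

# vessel mask with punched rectangular holes (all lacunae enclosed; holes may
# straddle one periodic boundary but never both)
holeMask <- function(L = 24L, nHoles = 4L) {
  m <- matrix(1L, L, L)
  for (i in seq_len(nHoles)) {
    h <- sample(2:5, 1); w <- sample(2:5, 1)
    if (runif(1) < 0.5) { r0 <- sample(c(1:(L - h), L - h + seq_len(h - 1)), 1) }
    else r0 <- sample(L - h, 1)
    c0 <- sample(L - w, 1)
    rows <- ((r0 - 1 + seq_len(h) - 1) %% L) + 1
    m[rows, c0 + seq_len(w) - 1] <- 0L
  }
  m
}

# brute-force torus union-find over the medium sites (independent oracle for
# the lacunae extraction)
torusMediumAreas <- function(mask, minArea = 3) {
  L1 <- nrow(mask); L2 <- ncol(mask)
  idx <- function(r, c) (c - 1L) * L1 + r
  parent <- seq_len(L1 * L2)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  medium <- !(mask >= 0.5)
  for (r in seq_len(L1)) for (c in seq_len(L2)) {
    if (!medium[r, c]) next
    r2 <- r %% L1 + 1L; c2 <- c %% L2 + 1L
    if (medium[r2, c]) union(idx(r, c), idx(r2, c))
    if (medium[r, c2]) union(idx(r, c), idx(r, c2))
  }
  roots <- vapply(which(medium), find, integer(1))
  areas <- as.integer(table(roots))
  sort(areas[areas >= minArea])
}
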