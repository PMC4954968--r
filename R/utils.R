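## Internal helpers shared across modules.

## Run code with a locally seeded RNG, restoring the caller's stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Promote a 2-D or 3-D stack to the canonical 4-D (row, col, slice, frame).
as4D <- function(volumes) {
  d <- dim(volumes)
  if (is.null(d)) stop("volumes must be an array", call. = FALSE)
  if (length(d) == 3L) dim(volumes) <- c(d[1:2], 1L, d[3L])
  else if (length(d) != 4L)
    stop("volumes must be a 3-D (row, col, frame) or 4-D (row, col, slice, frame) array",
         call. = FALSE)
  volumes
}

## Promote a 2-D mask/map to 3-D (row, col, slice).
as3D <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  else if (length(d) != 3L) stop("expected a 2-D or 3-D grid", call. = FALSE)
  x
}

## Rician corruption of a (possibly signed) signal: magnitude of the signal
## plus complex Gaussian noise. sigma = 0 returns |signal|.
addRician <- function(signal, sigma) {
  if (sigma == 0) return(abs(signal))
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

## Even-odd (crossing-number) point-in-polygon test for pixel centers.
## px, py: point coordinates; vx, vy: polygon vertices (not closed).
## Points exactly on an edge follow the half-open crossing rule, which is
## consistent for tiling adjacent polygons.
pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (n < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

## 8-connected labelling of a logical matrix. EBImage::bwlabel is
## 4-connected, so labels touching only diagonally are merged afterwards
## with a union-find over diagonal neighbour pairs.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbour label pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- cbind(c(a1[keep1], a2[keep2]), c(b1[keep1], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

## Structured condition helpers: I/O problems and statistical degeneracies
## get distinct classes so callers (and the CLI) can tell them apart.
stopIO <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("nephroMRI_io_error", "error", "condition")))
}
stopDegenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("nephroMRI_degenerate_error", "error",
                                "condition")))
}
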