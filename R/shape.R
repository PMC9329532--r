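# 4D discrete shape space: affinity, mutation, founder sampling.

#' BCR-epitope affinity in shape space
#'
#' Affinity is a Gaussian function of the Euclidean distance between two
#' points of the 4-dimensional discrete shape space,
#' `exp(-(d / gamma)^2)`, so it is 1 at zero distance and decays
#' monotonically with distance.
#'
#' @param bcr,epitope integer vectors of length 4 (shape-space coordinates),
#'   or matrices with 4 columns (one point per row; recycled against each
#'   other if one has a single row).
#' @param gamma Gaussian width in shape-space units.
#' @return numeric vector of affinities in `[0, 1]`.
#' @examples
#' shape_affinity(c(5, 5, 5, 5), c(5, 5, 5, 5))        # 1
#' shape_affinity(c(5, 5, 5, 5), c(5, 5, 5, 5 + 2.8))  # exp(-1)
#' @export
shape_affinity <- function(bcr, epitope, gamma = 2.8) {
  b <- if (is.matrix(bcr)) bcr else matrix(bcr, nrow = 1)
  e <- if (is.matrix(epitope)) epitope else matrix(epitope, nrow = 1)
  if (ncol(b) != 4 || ncol(e) != 4)
    stop("shape points have exactly 4 coordinates")
  if (nrow(b) == 1 && nrow(e) > 1) b <- b[rep(1, nrow(e)), , drop = FALSE]
  if (nrow(e) == 1 && nrow(b) > 1) e <- e[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) != nrow(e)) stop("row counts of bcr and epitope do not match")
  d2 <- rowSums((b - e)^2)
  exp(-d2 / gamma^2)
}

#' Mutate a shape-space point
#'
#' A mutation shifts the point by +/-1 in exactly one of the 4 dimensions,
#' chosen uniformly among the in-bounds neighbors. Uses R's RNG.
#'
#' @param point integer vector of length 4.
#' @param n number of independent mutated copies to draw.
#' @param bounds inclusive per-dimension bounds `c(lo, hi)`.
#' @return an `n` x 4 integer matrix of mutated points.
#' @export
shape_mutate <- function(point, n = 1, bounds = c(0, 9)) {
  if (length(point) != 4) stop("shape points have exactly 4 coordinates")
  if (any(point < bounds[1] | point > bounds[2]))
    stop("point outside shape-space bounds")
  moves <- cbind(rep(1:4, each = 2), rep(c(1L, -1L), 4))
  ok <- point[moves[, 1]] + moves[, 2] >= bounds[1] &
    point[moves[, 1]] + moves[, 2] <= bounds[2]
  moves <- moves[ok, , drop = FALSE]
  pick <- sample.int(nrow(moves), n, replace = TRUE)
  out <- matrix(rep(as.integer(point), n), nrow = n, byrow = TRUE)
  out[cbind(seq_len(n), moves[pick, 1])] <-
    out[cbind(seq_len(n), moves[pick, 1])] + moves[pick, 2]
  out
}

#' Sample founder BCR positions
#'
#' Founder B cell receptors are drawn uniformly from the integer shape points
#' whose Euclidean distance to the nearest epitope lies in a configurable
#' band, leaving headroom for affinity maturation. Uses R's RNG.
#'
#' @param n number of founders.
#' @param epitopes matrix with 4 columns, one epitope per row.
#' @param dmin,dmax inclusive distance band (shape-space units).
#' @param bounds inclusive per-dimension bounds.
#' @return an `n` x 4 integer matrix.
#' @export
founder_points <- function(n, epitopes = matrix(c(5, 5, 5, 5), nrow = 1),
                           dmin = 2, dmax = 5, bounds = c(0, 9)) {
  if (!is.matrix(epitopes)) epitopes <- matrix(epitopes, nrow = 1)
  out <- matrix(NA_integer_, n, 4)
  got <- 0
  span <- bounds[2] - bounds[1] + 1
  while (got < n) {
    m <- max(64, 4 * (n - got))
    cand <- matrix(sample.int(span, 4 * m, replace = TRUE) - 1L + bounds[1], ncol = 4)
    d2 <- sapply(seq_len(nrow(epitopes)), function(e)
      rowSums((cand - matrix(epitopes[e, ], m, 4, byrow = TRUE))^2))
    dmin2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    keep <- cand[dmin2 >= dmin^2 & dmin2 <= dmax^2, , drop = FALSE]
    if (nrow(keep) == 0) next
    take <- min(nrow(keep), n - got)
    out[(got + 1):(got + take), ] <- keep[seq_len(take), ]
    got <- got + take
  }
  out
}
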