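# Internal numeric helpers shared across modules.

# Population standard deviation (divisor n, not n-1).
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Fold an integer index (possibly out of range) back into 1..n by symmetric
# reflection with the edge sample duplicated: 0 -> 1, -1 -> 2, n+1 -> n, ...
reflect_index <- function(i, n) {
  stopifnot(n >= 1L)
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# Normalised 1D Gaussian kernel truncated at 4 sigma.
gauss_kernel1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur of a 2D matrix with reflective (symmetric, edge-duplicating)
# boundary handling. sigma = 0 is the identity. Convolution itself is done by
# EBImage::filter2 on a reflectively padded image so the circular wrap of the
# FFT never touches real pixels.
blur_reflect <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma == 0) {
    return(img)
  }
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  m <- ncol(img)
  ri <- reflect_index((1L - r):(n + r), n)
  ci <- reflect_index((1L - r):(m + r), m)
  padded <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, outer(k, k), boundary = "circular")
  out[(r + 1L):(r + n), (r + 1L):(r + m), drop = FALSE]
}

# 8-connected labelling of a logical/binary matrix. EBImage::bwlabel is
# 4-connected, so labels that touch only diagonally are merged afterwards
# with a union-find pass.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask != 0)
  nlab <- max(lab)
  if (nlab <= 1L) {
    return(lab)
  }
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  n <- nrow(lab)
  m <- ncol(lab)
  merge_pairs <- function(a, b) {
    w <- which(a > 0 & b > 0 & a != b)
    for (i in w) union2(a[i], b[i])
  }
  merge_pairs(lab[-n, -m, drop = FALSE], lab[-1, -1, drop = FALSE])
  merge_pairs(lab[-n, -1, drop = FALSE], lab[-1, -m, drop = FALSE])
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
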