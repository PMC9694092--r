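# Geometry utilities: mass-weighted superposition, internal coordinates and
# internal -> Cartesian reconstruction (NeRF placement).

#' Mass-weighted least-squares superposition (Kabsch)
#'
#' Finds the rigid rotation + translation minimizing the mass-weighted RMSD
#' of `mobile` onto `target` and returns the transformed coordinates.
#'
#' @param mobile `n x 3` coordinates to move (nm).
#' @param target `n x 3` reference coordinates (nm).
#' @param masses Weights (amu), length `n`; default equal weights.
#' @return `n x 3` matrix of superposed coordinates.
#' @export
superpose <- function(mobile, target, masses = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(all(dim(mobile) == dim(target)), ncol(mobile) == 3L)
  n <- nrow(mobile)
  w <- if (is.null(masses)) rep(1, n) else as.numeric(masses)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P %*% t(R), 2, ct, "+")
}

# bond angle at atom j for atoms i-j-k, radians
bond_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]
  v <- coords[k, ] - coords[j, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

# signed dihedral i-j-k-l in (-pi, pi], radians (IUPAC convention)
dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# NeRF atom placement: position D given A, B, C with bond |C-D|, angle
# B-C-D and dihedral A-B-C-D (signed, IUPAC).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(angle), sin(angle) * cos(dihedral),
                 -sin(angle) * sin(dihedral))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# numerical gradient of f at coords (n x 3), central differences
num_gradient <- function(f, coords, step = 1e-6) {
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (j in 1:3) {
    xp <- coords; xp[i, j] <- xp[i, j] + step
    xm <- coords; xm[i, j] <- xm[i, j] - step
    g[i, j] <- (f(xp) - f(xm)) / (2 * step)
  }
  g
}
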