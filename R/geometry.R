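#' Dihedral angle of four points
#'
#' Signed torsion angle in radians, wrapped to `[-pi, pi)`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in radians.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2u <- b2 / sqrt(sum(b2^2))
  wrapAngle(atan2(sum(cross(n1, n2) * b2u), sum(n1 * n2)))
}

#' Wrap angles to [-pi, pi)
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrapAngle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three placed atoms `a`, `b`, `c`, returns the position `d` with bond
#' length `|cd| = bond`, angle `b-c-d = theta` and dihedral `a-b-c-d = chi`.
#'
#' @param a,b,c numeric length-3 coordinates.
#' @param bond bond length (Angstrom).
#' @param theta bond angle (radians).
#' @param chi dihedral (radians).
#' @return numeric length-3 position.
#' @export
placeAtom <- function(a, b, c, bond, theta, chi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(theta), bond * cos(chi) * sin(theta),
          bond * sin(chi) * sin(theta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an all-backbone polypeptide from phi/psi angles
#'
#' Constructs N, CA, C positions for `n` residues from supplied backbone
#' dihedrals using ideal bond geometry (N-CA 1.458 A, CA-C 1.525 A, C-N
#' 1.329 A; angles 111.2, 116.2, 121.7 deg; omega fixed trans).  Useful for
#' torsion-extraction tests and all-atom toy ensembles.
#'
#' @param phi,psi numeric vectors of length `n` (radians); `phi[1]` and
#'   `psi[n]` are ignored (undefined at termini).
#' @return list with `coords` (3n x 3 matrix), `atomName`, `resid`.
#' @export
buildBackbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2 * pi / 180; aCACN <- 116.2 * pi / 180; aCNCA <- 121.7 * pi / 180
  omega <- pi
  coords <- matrix(NA_real_, 3 * n, 3)
  atomName <- rep(c("N", "CA", "C"), n)
  resid <- rep(seq_len(n), each = 3)
  # seed the first residue
  coords[1, ] <- c(0, 0, 0)                               # N1
  coords[2, ] <- c(bNCA, 0, 0)                            # CA1
  coords[3, ] <- placeAtom(c(-1, 1, 0), coords[1, ], coords[2, ],
                           bCAC, aNCAC, if (n > 1) psi[1] else 0) # C1
  if (n > 1) {
    for (i in 2:n) {
      iN <- 3 * (i - 1) + 1
      # N_i from (N_{i-1}, CA_{i-1}, C_{i-1}) with dihedral psi_{i-1}
      coords[iN, ] <- placeAtom(coords[iN - 3, ], coords[iN - 2, ], coords[iN - 1, ],
                                bCN, aCACN, psi[i - 1])
      # CA_i with omega (trans)
      coords[iN + 1, ] <- placeAtom(coords[iN - 2, ], coords[iN - 1, ], coords[iN, ],
                                    bNCA, aCNCA, omega)
      # C_i with phi_i
      coords[iN + 2, ] <- placeAtom(coords[iN - 1, ], coords[iN, ], coords[iN + 1, ],
                                    bCAC, aNCAC, phi[i])
    }
  }
  list(coords = coords, atomName = atomName, resid = resid)
}

#' Radius of gyration of a point set
#'
#' `sqrt(sum m_k |x_k - xbar|^2 / sum m_k)` with unit masses.
#'
#' @param xyz numeric `n x 3` matrix.
#' @return Rg in the units of `xyz`.
#' @export
rgFrame <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}
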