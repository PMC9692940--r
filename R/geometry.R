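# Geometry: distances, angles, torsions (IUPAC sign convention), idealized
# fragments and Z-matrix construction.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(a) sqrt(sum(a * a))
vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector")
  a / n
}

#' Interatomic distance
#' @param xyz n x 3 coordinate matrix (A)
#' @param i,j atom indices
#' @return distance (A)
#' @export
measure_distance <- function(xyz, i, j) {
  vnorm(xyz[i, ] - xyz[j, ])
}

#' Bond angle i-j-k
#' @param xyz n x 3 coordinate matrix (A)
#' @param i,j,k atom indices (j is the apex)
#' @return angle in degrees, [0, 180]
#' @export
measure_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(max(-1, min(1, cs))))
}

#' Torsion angle i-j-k-l (IUPAC/Klyne-Prelog sign convention)
#'
#' Positive torsion means the far bond (k-l) is rotated clockwise relative to
#' the near bond (j-i) when sighting from j toward k. The result lies in
#' (-180, 180]; an anti (trans) arrangement returns 180.
#'
#' @param xyz n x 3 coordinate matrix (A)
#' @param i,j,k,l atom indices
#' @return torsion angle in degrees
#' @export
measure_torsion <- function(xyz, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) stop("torsion requires four distinct atoms")
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 * vnorm(b1) * vnorm(b2) ||
      vnorm(n2) < 1e-10 * vnorm(b2) * vnorm(b3)) {
    stop("undefined torsion: three consecutive atoms are collinear")
  }
  phi <- rad2deg(atan2(vnorm(b2) * sum(b1 * n2), sum(n1 * n2)))
  if (phi <= -180) phi <- phi + 360
  phi
}

#' Torsion angles for many frames at once
#'
#' @param coords 3D array (frames x atoms x 3) or a single n x 3 matrix
#' @param quad integer vector of four atom indices
#' @return numeric vector of torsions (degrees, one per frame)
#' @export
torsion_series <- function(coords, quad) {
  if (is.matrix(coords)) {
    return(measure_torsion(coords, quad[1], quad[2], quad[3], quad[4]))
  }
  vapply(seq_len(dim(coords)[1]), function(f) {
    measure_torsion(coords[f, , ], quad[1], quad[2], quad[3], quad[4])
  }, numeric(1))
}

#' Idealized CH2 fragment and its geminal H-H distance
#'
#' Places a carbon at the origin with two hydrogens at the given bond length
#' and H-C-H angle, symmetric about the x axis. The geminal H-H distance is
#' 2 L sin(angle/2); with L = 1.09 A and the tetrahedral angle this is the
#' 1.780 A calibration standard used for NOE distance referencing.
#'
#' @param c_h_bond_length C-H bond length (A), > 0
#' @param h_c_h_angle H-C-H angle (degrees), in (0, 180)
#' @return list with \code{xyz} (3 x 3 matrix: C, H, H), \code{elements} and
#'   \code{hh_distance} (A)
#' @export
build_idealized_ch2 <- function(c_h_bond_length = 1.09,
                                h_c_h_angle = rad2deg(acos(-1 / 3))) {
  L <- c_h_bond_length
  if (L <= 0) stop("bond length must be positive")
  if (h_c_h_angle <= 0 || h_c_h_angle >= 180) stop("H-C-H angle must be in (0, 180)")
  half <- deg2rad(h_c_h_angle) / 2
  xyz <- rbind(
    c(0, 0, 0),
    c(L * cos(half), L * sin(half), 0),
    c(L * cos(half), -L * sin(half), 0)
  )
  list(xyz = xyz, elements = c("C", "H", "H"),
       hh_distance = vnorm(xyz[2, ] - xyz[3, ]))
}

#' Build Cartesian coordinates from a Z-matrix
#'
#' Each row places one atom: row 1 at the origin, row 2 at \code{r} from its
#' reference, row 3 using a distance and an angle, later rows using distance
#' \code{r} (to atom \code{a}), angle \code{theta} (new-a-b, degrees) and
#' torsion \code{phi} (new-a-b-c, degrees, IUPAC convention). All reference
#' indices must point to previously placed atoms.
#'
#' @param zmat data.frame with columns element, a, r, b, theta, c, phi
#'   (unused references NA)
#' @return n x 3 coordinate matrix (A)
#' @export
build_from_zmatrix <- function(zmat) {
  n <- nrow(zmat)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- zmat$a[i]; b <- zmat$b[i]; cc <- zmat$c[i]
    refs <- c(a, b, cc)[!is.na(c(a, b, cc))]
    if (any(refs >= i)) stop(sprintf("Z-matrix row %d references a not-yet-placed atom", i))
    if (i == 1) next
    r <- zmat$r[i]
    if (i == 2) {
      xyz[i, ] <- xyz[a, ] + c(r, 0, 0)
      next
    }
    theta <- deg2rad(zmat$theta[i])
    u <- vunit(xyz[b, ] - xyz[a, ])
    if (i == 3) {
      # place in the xy-plane (or any plane containing u)
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      m1 <- vunit(vcross(vcross(u, ref), u))
      xyz[i, ] <- xyz[a, ] + r * (cos(theta) * u + sin(theta) * m1)
      next
    }
    phi <- deg2rad(zmat$phi[i])
    p <- xyz[cc, ] - xyz[b, ]
    perp <- p - sum(p * u) * u
    if (vnorm(perp) < 1e-10) stop(sprintf("Z-matrix row %d: collinear a-b-c references", i))
    m1 <- vunit(perp)
    m2 <- vcross(u, m1)
    d <- cos(theta) * u + sin(theta) * (cos(phi) * m1 - sin(phi) * m2)
    xyz[i, ] <- xyz[a, ] + r * d
  }
  xyz
}

zmatrix_row <- function(element, a = NA, r = NA, b = NA, theta = NA, c = NA, phi = NA) {
  data.frame(element = element, a = a, r = r, b = b, theta = theta, c = c, phi = phi,
             stringsAsFactors = FALSE)
}

#' Re-measure the internal coordinates that built a frame
#'
#' @param zmat the Z-matrix used with \code{\link{build_from_zmatrix}}
#' @param xyz the built (or otherwise obtained) coordinates
#' @return data.frame of r, theta, phi per row (NA where not applicable)
#' @export
measure_zmatrix <- function(zmat, xyz) {
  n <- nrow(zmat)
  out <- data.frame(r = rep(NA_real_, n), theta = NA_real_, phi = NA_real_)
  for (i in seq_len(n)) {
    if (i >= 2) out$r[i] <- measure_distance(xyz, i, zmat$a[i])
    if (i >= 3) out$theta[i] <- measure_angle(xyz, i, zmat$a[i], zmat$b[i])
    if (i >= 4) out$phi[i] <- measure_torsion(xyz, i, zmat$a[i], zmat$b[i], zmat$c[i])
  }
  out
}
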