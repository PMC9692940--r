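# Back-calculation of NMR observables from coordinates: dipolar (RDC)
# tensors, NOE effective distances, vicinal 3J couplings.

#' Maximum dipolar coupling of a spin pair at distance r
#'
#' D_max(r) = -(mu0/4pi) * gamma_i * gamma_j * hbar / (2 pi r^3), in Hz, with
#' r in A. Negative for pairs of nuclei whose gyromagnetic ratios have equal
#' sign (e.g. 1H-13C). CODATA 2018 values of hbar and the gyromagnetic ratios
#' are used (see \code{\link{gyromagnetic_ratio}}).
#'
#' @param r internuclear distance (A)
#' @param gamma1,gamma2 gyromagnetic ratios (rad s^-1 T^-1)
#' @return D_max in Hz
#' @export
dmax_coupling <- function(r, gamma1, gamma2) {
  if (any(r <= 0)) stop("singular geometry: nonpositive internuclear distance")
  -MU0_OVER_4PI * gamma1 * gamma2 * HBAR / (2 * pi) * 1e30 / r^3
}

#' Laboratory-frame dipolar interaction tensor of a spin pair
#'
#' D = D_max(r) * (3 e e^T - I) / 2 with e the unit internuclear vector;
#' symmetric and traceless by construction. Units Hz.
#'
#' @param xyz n x 3 coordinates (A)
#' @param i,j atom indices of the pair
#' @param gamma1,gamma2 gyromagnetic ratios (rad s^-1 T^-1)
#' @return 3 x 3 symmetric traceless matrix (Hz)
#' @export
dipolar_tensor <- function(xyz, i, j, gamma1, gamma2) {
  dv <- xyz[j, ] - xyz[i, ]
  r <- vnorm(dv)
  if (r < 1e-6) stop("singular geometry: coincident atoms in spin pair")
  e <- dv / r
  dmax_coupling(r, gamma1, gamma2) * (3 * outer(e, e) - diag(3)) / 2
}

#' Residual dipolar coupling along a field direction
#'
#' The measured coupling is the projection b^T D b of the (time-averaged)
#' dipolar tensor onto the unit magnetic-field direction b; for the default
#' laboratory z field this is the zz element.
#'
#' @param tensor 3 x 3 dipolar tensor (Hz)
#' @param field_axis field direction (need not be normalized; must be nonzero)
#' @return coupling (Hz)
#' @export
rdc_value <- function(tensor, field_axis = c(0, 0, 1)) {
  n <- vnorm(field_axis)
  if (n < 1e-12) stop("field axis must be a nonzero vector")
  b <- field_axis / n
  drop(crossprod(b, tensor %*% b))
}

#' NOE effective distance from r^-6 averaging
#'
#' r_eff = <r^-6>^(-1/6). NOE intensities average as r^-6, so the effective
#' distance of a fluctuating pair is dominated by the close approaches; the
#' power-mean inequality guarantees min(r) <= r_eff <= mean(r).
#'
#' @param r distance series (A), or a single pre-averaged <r^-6> value if
#'   \code{is_mean_r6 = TRUE}
#' @param is_mean_r6 interpret \code{r} as an already-averaged <r^-6> (A^-6)
#' @return effective distance (A)
#' @export
effective_noe_distance <- function(r, is_mean_r6 = FALSE) {
  if (length(r) == 0) stop("empty distance series")
  if (is_mean_r6) {
    if (r <= 0) stop("<r^-6> must be positive")
    return(r^(-1 / 6))
  }
  if (any(r <= 0)) stop("distances must be positive")
  mean(r^-6)^(-1 / 6)
}

#' Bundled Haasnoot-Altona parameterization
#'
#' Returns the generalized Karplus coefficients used by default: the standard
#' 1980 six-parameter set (P1..P6 plus the beta-substituent factor P7) together
#' with Huggins group electronegativities relative to hydrogen, read from the
#' package's data file. Users may pass their own list of the same shape to
#' \code{\link{karplus_3j}}.
#'
#' @return list with numeric \code{P} (named P1..P7), \code{delta_chi} (named
#'   by element/group) and \code{uncertainty} (Hz)
#' @export
haasnoot_altona_params <- function() {
  path <- system.file("extdata", "haasnoot_altona.tsv", package = "mdoc")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  P <- stats::setNames(tab$value[tab$kind == "P"], tab$name[tab$kind == "P"])
  dchi <- stats::setNames(tab$value[tab$kind == "dchi"], tab$name[tab$kind == "dchi"])
  list(P = P, delta_chi = dchi,
       uncertainty = tab$value[tab$kind == "sigma"][1])
}

#' Vicinal 3J coupling from a dihedral angle (generalized Karplus)
#'
#' Haasnoot-Altona form:
#' J = P1 cos^2(phi) + P2 cos(phi) + P3 +
#'     sum_i dchi_i [ P4 + P5 cos^2( xi_i phi + P6 |dchi_i| ) ]
#' where dchi_i is the group electronegativity (relative to H) of substituent
#' i on the coupling path, corrected for beta substituents by
#' dchi = dchi_alpha - P7 sum(dchi_beta), and xi_i = +/-1 encodes the
#' substituent orientation. With all corrections zero the expression reduces
#' to the classic A cos^2(phi) + B cos(phi) + C curve.
#'
#' @param dihedral H-C-C-H dihedral (degrees)
#' @param substituents optional data.frame with columns \code{dchi}
#'   (corrected group electronegativity) and \code{xi} (+1 or -1)
#' @param params coefficient list as from \code{\link{haasnoot_altona_params}};
#'   only \code{P} is used
#' @return coupling (Hz)
#' @export
karplus_3j <- function(dihedral, substituents = NULL,
                       params = haasnoot_altona_params()) {
  P <- params$P
  phi <- deg2rad(dihedral)
  J <- P[["P1"]] * cos(phi)^2 + P[["P2"]] * cos(phi) + P[["P3"]]
  if (!is.null(substituents) && nrow(substituents) > 0) {
    for (s in seq_len(nrow(substituents))) {
      dchi <- substituents$dchi[s]
      xi <- substituents$xi[s]
      J <- J + dchi * (P[["P4"]] + P[["P5"]] *
                         cos(xi * phi + deg2rad(P[["P6"]]) * abs(dchi))^2)
    }
  }
  unname(J)
}

# dJ/dphi in Hz per radian (needed by the pseudo-force chain rule)
karplus_3j_deriv <- function(dihedral, substituents = NULL,
                             params = haasnoot_altona_params()) {
  P <- params$P
  phi <- deg2rad(dihedral)
  dJ <- -2 * P[["P1"]] * cos(phi) * sin(phi) - P[["P2"]] * sin(phi)
  if (!is.null(substituents) && nrow(substituents) > 0) {
    for (s in seq_len(nrow(substituents))) {
      dchi <- substituents$dchi[s]
      xi <- substituents$xi[s]
      arg <- xi * phi + deg2rad(P[["P6"]]) * abs(dchi)
      dJ <- dJ - dchi * P[["P5"]] * 2 * cos(arg) * sin(arg) * xi
    }
  }
  unname(dJ)
}
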