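# Evaluation layer: chi-square quality statistics with outlier detection,
# ambiguous-assignment resolution, torsion distributions, +/-gauche state
# classification, joint conformer probability tables and flip aggregates.

#' Chi-square quality report for back-calculated observables
#'
#' For each observable, chi_i = (q_exp - q_calc) / e_q. The report carries the
#' per-item chi_i^2 and (1/chi_i)^2, the totals chi^2 = sum chi_i^2 and the
#' quality n/chi^2: a quality above 1 means the calculated values agree with
#' experiment within the experimental errors on average. Items with
#' (1/chi_i)^2 < 1 (equivalently |q_exp - q_calc| > e_q) are outliers.
#'
#' @param comparisons data.frame with columns \code{label}, \code{q_exp},
#'   \code{q_calc}, \code{error}
#' @return object of class \code{mdoc_chi2}: the per-item table plus
#'   attributes \code{chi2}, \code{n}, \code{quality}, \code{outliers},
#'   \code{min_inv_chi2}
#' @export
chi2_report <- function(comparisons) {
  need <- c("label", "q_exp", "q_calc", "error")
  if (!all(need %in% names(comparisons))) {
    stop("comparisons must have columns: ", paste(need, collapse = ", "))
  }
  if (any(comparisons$error <= 0)) stop("errors must be positive")
  chi <- (comparisons$q_exp - comparisons$q_calc) / comparisons$error
  out <- comparisons
  out$chi2_i <- chi^2
  out$inv_chi2_i <- ifelse(chi == 0, Inf, 1 / chi^2)
  out$outlier <- out$inv_chi2_i < 1
  chi2 <- sum(out$chi2_i)
  n <- nrow(out)
  structure(out, class = c("mdoc_chi2", "data.frame"),
            chi2 = chi2, n = n,
            quality = if (chi2 == 0) Inf else n / chi2,
            n_outliers = sum(out$outlier),
            outliers = out$label[out$outlier],
            min_inv_chi2 = if (n) min(out$inv_chi2_i) else NA_real_)
}

#' @export
print.mdoc_chi2 <- function(x, ...) {
  cat(sprintf("chi-square report: n = %d, chi2 = %.3f, quality n/chi2 = %s, outliers = %d\n",
              attr(x, "n"), attr(x, "chi2"),
              format(attr(x, "quality"), digits = 4), attr(x, "n_outliers")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Resolve ambiguous assignments by chi-square minimization
#'
#' For each ambiguity group (a set of experimental values whose assignment to
#' predicted values is interchangeable), every within-group permutation of the
#' experimental values is scored by its chi-square against the predictions and
#' the minimizing permutation is returned (lexicographically smallest on
#' ties).
#'
#' @param predicted numeric vector of predicted values
#' @param experimental numeric vector of experimental values (same order)
#' @param groups list of index vectors, one per ambiguity group; indices not
#'   in any group are kept fixed
#' @param errors per-item errors (default 1, i.e. plain squared deviations)
#' @return list with \code{assignment} (for each item, the index of the
#'   experimental value assigned to it), \code{chi2} of the best assignment,
#'   \code{chi2_identity}, and per-group tables of all permutations
#' @export
resolve_assignment <- function(predicted, experimental, groups,
                               errors = rep(1, length(predicted))) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental must have equal length")
  }
  assignment <- seq_along(predicted)
  per_group <- list()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (any(idx < 1 | idx > length(predicted))) stop("group index out of range")
    perms <- permutations(length(idx))
    chi2s <- apply(perms, 1, function(p) {
      sum(((predicted[idx] - experimental[idx][p]) / errors[idx])^2)
    })
    # order(): first minimum in lexicographic row order of `perms`
    best <- which.min(chi2s)
    assignment[idx] <- idx[perms[best, ]]
    per_group[[g]] <- data.frame(
      permutation = apply(perms, 1, paste, collapse = ","), chi2 = chi2s)
  }
  chi2_best <- sum(((predicted - experimental[assignment]) / errors)^2)
  chi2_id <- sum(((predicted - experimental) / errors)^2)
  list(assignment = assignment, chi2 = chi2_best, chi2_identity = chi2_id,
       groups = per_group)
}

# all permutations of 1..n in lexicographic order (small n only)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

#' Torsion angle distribution
#'
#' Histogram over (-180, 180] with probabilities in percent (summing to 100).
#'
#' @param series torsion angles (degrees)
#' @param bin_width bin width (degrees); must divide 360
#' @return data.frame(midpoint, probability)
#' @export
torsion_distribution <- function(series, bin_width = 2) {
  if (!length(series)) stop("empty torsion series")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop("bin width must divide 360")
  }
  breaks <- seq(-180, 180, by = bin_width)
  h <- graphics::hist(wrap_angle(series), breaks = breaks, plot = FALSE,
                      right = TRUE, include.lowest = TRUE)
  data.frame(midpoint = h$mids, probability = 100 * h$counts / length(series))
}

#' Classify a torsion angle as +gauche or -gauche
#'
#' Sign-based two-state classification: angles above the boundary are +g,
#' the rest -g. The default boundary of 0 degrees matches states separated by
#' the sign of the torsion; it is configurable per torsion for states that
#' straddle unusual ranges. A three-state variant adding a trans class
#' (|angle| > 120) is available but off by default.
#'
#' @param angle torsion angle(s), degrees in (-180, 180]
#' @param boundary class boundary (degrees, default 0)
#' @param three_state also separate a trans state
#' @return character vector of labels "+g" / "-g" (and "t" if three_state)
#' @export
classify_gauche <- function(angle, boundary = 0, three_state = FALSE) {
  lab <- ifelse(angle > boundary, "+g", "-g")
  if (three_state) lab[abs(angle) > 120] <- "t"
  lab
}

#' Joint conformer-state probability table
#'
#' Classifies each monitored torsion series into +/-gauche states and counts
#' the joint state tuples across frames. Probabilities are occupancy fractions
#' in percent, sorted descending; they sum to 100 before rounding.
#'
#' @param series_list named list of torsion angle series (equal lengths)
#' @param boundaries per-torsion class boundary (degrees), recycled
#' @return object of class \code{mdoc_conformer_table}: data.frame(state,
#'   probability) where state strings read like "\{+g, +g, -g\}"
#' @export
joint_state_probabilities <- function(series_list, boundaries = 0) {
  lens <- vapply(series_list, length, integer(1))
  if (length(unique(lens)) != 1) stop("torsion series differ in length")
  boundaries <- rep_len(boundaries, length(series_list))
  labels <- mapply(function(s, b) classify_gauche(s, b),
                   series_list, boundaries, SIMPLIFY = FALSE)
  tuples <- do.call(paste, c(labels, sep = ", "))
  tab <- sort(table(tuples), decreasing = TRUE)
  out <- data.frame(
    state = paste0("{", names(tab), "}"),
    probability = 100 * as.numeric(tab) / lens[1],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("mdoc_conformer_table", "data.frame"),
            n_torsions = length(series_list),
            torsion_names = names(series_list))
}

#' Build a conformer table from explicit states and probabilities
#'
#' Used to aggregate published or externally computed tables.
#'
#' @param states character vector like "\{+g, +g, -g\}"
#' @param probabilities percentages (must be nonnegative, summing to 100
#'   within rounding tolerance)
#' @return an \code{mdoc_conformer_table}
#' @export
conformer_table <- function(states, probabilities) {
  if (any(probabilities < 0)) stop("probabilities must be nonnegative")
  k <- lengths(regmatches(states, gregexpr("g", states)))
  if (length(unique(k)) != 1) stop("states differ in torsion count")
  if (abs(sum(probabilities) - 100) > 0.05 * length(states)) {
    stop("probabilities must sum to 100% within rounding")
  }
  structure(data.frame(state = states, probability = probabilities,
                       stringsAsFactors = FALSE),
            class = c("mdoc_conformer_table", "data.frame"),
            n_torsions = unique(k), torsion_names = NULL)
}

#' @export
print.mdoc_conformer_table <- function(x, ...) {
  cat(sprintf("conformer table over %d torsion(s):\n", attr(x, "n_torsions")))
  df <- data.frame(state = x$state,
                   probability = sprintf("%.2f", round_half_up(x$probability, 2)))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

parse_state_labels <- function(states) {
  lapply(strsplit(gsub("[{}]", "", states), ",\\s*"), trimws)
}

#' Aggregate flip probability of one torsion state
#'
#' Sums the probabilities of all conformer-table rows whose state tuple has
#' the given label at the given torsion position (e.g. the total probability
#' of a ring flip regardless of the other rings).
#'
#' @param table an \code{mdoc_conformer_table}
#' @param torsion_index position in the state tuple (1-based)
#' @param label "+g" or "-g"
#' @return probability in percent (unrounded; reports round half-up to 1 d.p.)
#' @export
aggregate_flip <- function(table, torsion_index, label) {
  lab <- parse_state_labels(table$state)
  k <- length(lab[[1]])
  if (torsion_index < 1 || torsion_index > k) stop("torsion index out of range")
  sel <- vapply(lab, function(s) s[torsion_index] == label, logical(1))
  sum(table$probability[sel])
}

#' Back-calculate trajectory-mean observables for a restraint set
#'
#' RDC: field-axis component of the frame-mean dipolar tensor; NOE: r^-6
#' averaged effective distance over frames; 3J: mean Karplus coupling over
#' frames.
#'
#' @param traj an \code{mdoc_trajectory}
#' @param rs an \code{mdoc_restraint_set}
#' @param field_axis magnetic-field direction
#' @return data.frame(label, type, atom1, atom2, q_exp, q_calc, error)
#'   suitable for \code{\link{chi2_report}} (with q_exp the restraint
#'   targets)
#' @export
predict_observables <- function(traj, rs, field_axis = c(0, 0, 1)) {
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  rows <- list()
  for (r in seq_len(nrow(rs$rdc))) {
    acc <- matrix(0, 3, 3)
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      dv <- xyz[rs$rdc$j[r], ] - xyz[rs$rdc$i[r], ]
      rr <- vnorm(dv)
      e <- dv / rr
      acc <- acc + rs$rdc$coef[r] / rr^3 * (3 * outer(e, e) - diag(3)) / 2
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = paste(rs$rdc$atom1[r], rs$rdc$atom2[r], sep = "-"),
      type = "RDC", atom1 = rs$rdc$atom1[r], atom2 = rs$rdc$atom2[r],
      q_exp = rs$rdc$value[r], q_calc = rdc_value(acc / nf, field_axis),
      error = rs$rdc$error[r])
  }
  for (r in seq_len(nrow(rs$noe))) {
    d <- vapply(seq_len(nf), function(f) {
      measure_distance(frame_coords(traj, f), rs$noe$i[r], rs$noe$j[r])
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      label = paste(rs$noe$atom1[r], rs$noe$atom2[r], sep = "-"),
      type = "NOE", atom1 = rs$noe$atom1[r], atom2 = rs$noe$atom2[r],
      q_exp = rs$noe$value[r], q_calc = effective_noe_distance(d),
      error = rs$noe$error[r])
  }
  for (r in seq_len(nrow(rs$j3))) {
    quad <- rs$jpaths[[r]]$quad
    subs <- rs$jpaths[[r]]$substituents
    jj <- vapply(seq_len(nf), function(f) {
      karplus_3j(torsion_series(frame_coords(traj, f), quad), subs, rs$karplus)
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      label = paste(rs$j3$atom1[r], rs$j3$atom2[r], sep = "-"),
      type = "J3", atom1 = rs$j3$atom1[r], atom2 = rs$j3$atom2[r],
      q_exp = rs$j3$value[r], q_calc = mean(jj), error = rs$j3$error[r])
  }
  if (!length(rows)) stop("restraint set is empty")
  do.call(rbind, rows)
}
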