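#' Distance distributions on a uniform grid
#'
#' A \code{DistanceDistribution} is a probability density \eqn{P(r)} over
#' spin-spin distance r (Angstrom) on a closed uniform grid, normalised to
#' unit trapezoid integral, with an optional confidence band.
#'
#' @param r numeric grid (Angstrom), strictly increasing, uniform step
#' @param p non-negative density values
#' @param ci_lower,ci_upper optional confidence-band densities
#' @return an object of class \code{DistanceDistribution}
#' @export
distance_distribution <- function(r, p, ci_lower = NULL, ci_upper = NULL) {
  stopifnot(length(r) == length(p), length(r) >= 2L)
  dr <- diff(r)
  if (any(dr <= 0)) stop("grid must be strictly increasing")
  if (max(abs(dr - dr[1])) > 1e-6 * dr[1]) stop("non-uniform grid")
  if (any(p < 0)) stop("negative densities")
  z <- trapz(r, p)
  if (z <= 0) stop("degenerate distribution: density integrates to zero")
  obj <- structure(list(r = as.numeric(r), p = as.numeric(p) / z,
                        step = dr[1]), class = "DistanceDistribution")
  if (!is.null(ci_lower)) obj$ci_lower <- as.numeric(ci_lower) / z
  if (!is.null(ci_upper)) obj$ci_upper <- as.numeric(ci_upper) / z
  obj
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  cat(sprintf("DistanceDistribution: %d points, %.2f-%.2f A, mean %.2f A\n",
              length(x$r), min(x$r), max(x$r), distribution_mean(x)))
  invisible(x)
}

#' Trapezoid integral
#' @param x grid
#' @param y values
#' @return numeric scalar
#' @keywords internal
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Mean distance of a distribution
#' @param d a \code{DistanceDistribution}
#' @return mean in Angstrom
#' @export
distribution_mean <- function(d) trapz(d$r, d$r * d$p)

#' Standard deviation of a distribution
#' @param d a \code{DistanceDistribution}
#' @return standard deviation in Angstrom
#' @export
distribution_sd <- function(d) {
  m <- distribution_mean(d)
  sqrt(max(0, trapz(d$r, (d$r - m)^2 * d$p)))
}

#' Read a distance distribution from TSV
#'
#' Columns \code{r_angstrom}, \code{p} and optionally \code{ci_lower},
#' \code{ci_upper}; header mandatory; comment lines start with '#'.
#' The density is renormalised to unit trapezoid integral.
#'
#' @param path TSV file
#' @return a \code{DistanceDistribution}
#' @export
read_distance_distribution <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("r_angstrom", "p")
  if (!all(need %in% names(tab)))
    stop("distribution table needs columns r_angstrom, p: ", path)
  distance_distribution(tab$r_angstrom, tab$p,
                        if ("ci_lower" %in% names(tab)) tab$ci_lower,
                        if ("ci_upper" %in% names(tab)) tab$ci_upper)
}

#' Write a distance distribution as TSV
#' @param d a \code{DistanceDistribution}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_distance_distribution <- function(d, path) {
  tab <- data.frame(r_angstrom = d$r, p = d$p)
  if (!is.null(d$ci_lower)) tab$ci_lower <- d$ci_lower
  if (!is.null(d$ci_upper)) tab$ci_upper <- d$ci_upper
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regrid a distribution onto a new uniform grid
#'
#' Linear interpolation followed by renormalisation; density outside the
#' original support is zero.
#'
#' @param d a \code{DistanceDistribution}
#' @param r new grid
#' @return a \code{DistanceDistribution}
#' @export
regrid_distribution <- function(d, r) {
  p <- stats::approx(d$r, d$p, xout = r, yleft = 0, yright = 0)$y
  distance_distribution(r, p)
}

# --- PRE tables -------------------------------------------------------------

#' Read a per-residue PRE table from TSV
#'
#' Columns \code{residue}, \code{gamma2} (s^-1), \code{gamma2_err} (s^-1),
#' \code{status} (one of observed / vanished / unreliable); header
#' mandatory, '#' comments allowed.
#'
#' @param path TSV file
#' @return data.frame with the four columns, class \code{pre_table}
#' @export
read_pre_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("residue", "gamma2", "gamma2_err", "status")
  if (!all(need %in% names(tab)))
    stop("PRE table needs columns residue, gamma2, gamma2_err, status: ", path)
  bad <- setdiff(unique(tab$status), c("observed", "vanished", "unreliable"))
  if (length(bad)) stop("unknown PRE status: ", paste(bad, collapse = ", "))
  if (any(tab$gamma2_err < 0)) stop("negative gamma2_err in ", path)
  class(tab) <- c("pre_table", "data.frame")
  tab
}

#' Write a per-residue PRE table as TSV
#' @param tab PRE table (data.frame with residue, gamma2, gamma2_err, status)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_pre_table <- function(tab, path) {
  utils::write.table(tab[, c("residue", "gamma2", "gamma2_err", "status")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
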