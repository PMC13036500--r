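#' Restraint manifest
#'
#' The manifest is a YAML file tying label-site pairs to distance
#' distribution tables and label sites to PRE tables, and carrying the
#' per-system scalars.  Layout:
#'
#' \preformatted{
#' sites:
#'   S1: {residue: 10}
#'   S2: {residue: 135}
#' deer:
#'   - {pair: [S1, S2], file: dd_S1_S2.tsv}
#' pre:
#'   - {site: S1, file: pre_S1.tsv}
#' scalars:
#'   tau_c_s: 1.1e-8
#'   freq_1h_mhz: 700
#'   gamma2_cap: 170
#' options:
#'   grid_min: 10, grid_max: 100, grid_step: 0.5, kernel_sigma: 1.0
#' }
#'
#' Frequencies are given in MHz in the file and converted once at load:
#' the returned manifest carries \code{omega_h} in rad/s.  All referenced
#' files are resolved relative to the manifest and must exist and parse.
#'
#' @param path YAML manifest file
#' @return an object of class \code{RestraintManifest}: lists \code{sites},
#'   \code{deer} (with parsed distributions), \code{pre} (with parsed
#'   tables), \code{scalars} (tau_c, omega_h, cap), \code{options}
#' @export
load_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  sites <- raw$sites
  if (is.null(sites) || !length(sites)) stop("manifest has no label sites")
  resolve <- function(f) {
    full <- if (grepl("^/", f)) f else file.path(base, f)
    if (!file.exists(full)) stop("manifest references missing file: ", f)
    full
  }
  deer <- lapply(raw$deer, function(e) {
    pr <- unlist(e$pair)
    if (length(pr) != 2L) stop("deer entry needs a 2-site pair")
    miss <- setdiff(pr, names(sites))
    if (length(miss)) stop("unknown label site in manifest: ", miss[1])
    full <- resolve(e$file)
    list(pair = pr, file = full, obs = read_distance_distribution(full))
  })
  pre <- lapply(raw$pre, function(e) {
    if (!e$site %in% names(sites))
      stop("unknown label site in manifest: ", e$site)
    full <- resolve(e$file)
    list(site = e$site, file = full, obs = read_pre_table(full))
  })
  sc <- raw$scalars
  if (length(pre) > 0) {
    if (is.null(sc$tau_c_s) || is.null(sc$freq_1h_mhz))
      stop("PRE entries present but scalars tau_c_s / freq_1h_mhz missing")
  }
  scalars <- list(
    tau_c = if (!is.null(sc$tau_c_s)) as.numeric(sc$tau_c_s) else NA_real_,
    omega_h = if (!is.null(sc$freq_1h_mhz))
      2 * pi * as.numeric(sc$freq_1h_mhz) * 1e6 else NA_real_,
    cap = if (!is.null(sc$gamma2_cap)) as.numeric(sc$gamma2_cap) else 170
  )
  op <- raw$options
  defaults <- list(grid_min = 10, grid_max = 100, grid_step = 0.5,
                   kernel_sigma = 1.0, seed = 1L)
  for (k in names(defaults)) if (is.null(op[[k]])) op[[k]] <- defaults[[k]]
  structure(list(sites = sites, deer = deer, pre = pre,
                 scalars = scalars, options = op, path = path),
            class = "RestraintManifest")
}

#' @export
print.RestraintManifest <- function(x, ...) {
  cat(sprintf("RestraintManifest: %d sites, %d distance distributions, %d PRE tables\n",
              length(x$sites), length(x$deer), length(x$pre)))
  invisible(x)
}

#' Default distance grid from manifest options
#' @param manifest a \code{RestraintManifest}
#' @return numeric grid in Angstrom (closed, both endpoints included)
#' @export
manifest_grid <- function(manifest) {
  op <- manifest$options
  seq(op$grid_min, op$grid_max, by = op$grid_step)
}
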