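#' Combined amide chemical shift difference
#'
#' \eqn{\delta CS = \sqrt{\delta HN^2 + (\delta N / 6.51)^2}}, the usual
#' combined 1H/15N shift difference with the nitrogen axis scaled by the
#' ratio of shift ranges.
#'
#' @param delta_hn amide proton shift difference (ppm)
#' @param delta_n amide nitrogen shift difference (ppm)
#' @return combined shift difference (ppm)
#' @export
chemical_shift_difference <- function(delta_hn, delta_n) {
  stopifnot(is.finite(delta_hn), is.finite(delta_n))
  sqrt(delta_hn^2 + (delta_n / 6.51)^2)
}

#' Rotational correlation time from 15N T1/T2
#'
#' \eqn{\tau_c = \sqrt{6 T_1/T_2 - 7} / (4 \pi \nu_N)}, valid in the
#' slow-tumbling regime where \eqn{6 T_1/T_2 \ge 7}.  The uncertainty is
#' obtained by first-order propagation of the T1 and T2 errors through the
#' formula.
#'
#' @param t1 longitudinal relaxation time (s)
#' @param t2 transverse relaxation time (s)
#' @param nu_n 15N Larmor frequency (Hz)
#' @param t1_err,t2_err standard errors on T1, T2 (s)
#' @return list with \code{tau_c} (s) and \code{tau_c_err} (s)
#' @export
correlation_time <- function(t1, t2, nu_n, t1_err = 0, t2_err = 0) {
  stopifnot(t1 > 0, t2 > 0, nu_n > 0)
  rad <- 6 * t1 / t2 - 7
  if (rad < 0) stop("ratio below rigid-limit bound: 6*T1/T2 < 7")
  s <- sqrt(rad)
  tau <- s / (4 * pi * nu_n)
  if (s > 0) {
    d1 <- (6 / t2) / (2 * s) / (4 * pi * nu_n)          # d tau / d T1
    d2 <- (-6 * t1 / t2^2) / (2 * s) / (4 * pi * nu_n)  # d tau / d T2
    err <- sqrt((d1 * t1_err)^2 + (d2 * t2_err)^2)
  } else {
    err <- Inf  # derivative diverges at the rigid-limit root
    if (t1_err == 0 && t2_err == 0) err <- 0
  }
  list(tau_c = tau, tau_c_err = err)
}

#' Electron-amide distance from a transverse PRE rate
#'
#' Inverts the Solomon-Bloembergen relation
#' \eqn{\Gamma_2 = K/r^6 (4\tau_c + 3\tau_c/(1 + \omega_H^2 \tau_c^2))}:
#' \eqn{r = [K/\Gamma_2 (4\tau_c + 3\tau_c/(1+\omega_H^2\tau_c^2))]^{1/6}}.
#' K is the standard PRE proportionality constant for a nitroxide-amide
#' proton pair; the result is converted from cm to Angstrom.
#'
#' @param gamma2 transverse PRE rate (s^-1), > 0
#' @param tau_c rotational correlation time (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param K proportionality constant (cm^6 s^-2), default 1.23e-32
#' @return distance (Angstrom)
#' @export
gamma2_to_distance <- function(gamma2, tau_c, omega_h, K = 1.23e-32) {
  if (any(gamma2 <= 0)) stop("gamma2 must be positive")
  g <- 4 * tau_c + 3 * tau_c / (1 + omega_h^2 * tau_c^2)
  (K / gamma2 * g)^(1 / 6) * 1e8  # cm -> Angstrom
}

#' Transverse PRE rate from an electron-amide distance
#'
#' Algebraic inverse of \code{\link{gamma2_to_distance}}.
#'
#' @param r distance (Angstrom), > 0
#' @param tau_c rotational correlation time (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param K proportionality constant (cm^6 s^-2)
#' @return PRE rate (s^-1)
#' @export
distance_to_gamma2 <- function(r, tau_c, omega_h, K = 1.23e-32) {
  if (any(r <= 0)) stop("distance must be positive")
  g <- 4 * tau_c + 3 * tau_c / (1 + omega_h^2 * tau_c^2)
  K * g / (r * 1e-8)^6
}

#' Propagated distance uncertainty for a PRE-derived distance
#'
#' First-order propagation of the \eqn{\Gamma_2} and \eqn{\tau_c} errors
#' through the distance formula.  K is excluded from propagation.
#'
#' @param gamma2 PRE rate (s^-1)
#' @param gamma2_err its standard error (s^-1)
#' @param tau_c correlation time (s)
#' @param tau_c_err its standard error (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param K proportionality constant (cm^6 s^-2)
#' @return standard error of the distance (Angstrom)
#' @export
pre_distance_error <- function(gamma2, gamma2_err, tau_c, tau_c_err,
                               omega_h, K = 1.23e-32) {
  r <- gamma2_to_distance(gamma2, tau_c, omega_h, K)
  g <- 4 * tau_c + 3 * tau_c / (1 + omega_h^2 * tau_c^2)
  gp <- 4 + 3 * (1 - omega_h^2 * tau_c^2) / (1 + omega_h^2 * tau_c^2)^2
  dr_dgamma <- -r / (6 * gamma2)
  dr_dtau <- r * gp / (6 * g)
  sqrt((dr_dgamma * gamma2_err)^2 + (dr_dtau * tau_c_err)^2)
}

#' Derive distance restraints from PRE records
#'
#' Observed records become two-sided restraints with upl = r + sigma_r and
#' lol = r - sigma_r, where sigma_r propagates the Gamma2 and tau_c errors.
#' Vanished records (amide bleached beyond detection) become upper-only
#' restraints at the cap-equivalent distance.  Records whose distance error
#' exceeds 50 percent of the distance are deemed unreliable and dropped.
#'
#' @param records data.frame with columns \code{residue}, \code{gamma2},
#'   \code{gamma2_err}, \code{status} (observed / vanished / unreliable)
#' @param tau_c correlation time (s)
#' @param omega_h 1H Larmor frequency (rad/s)
#' @param tau_c_err standard error of tau_c (s)
#' @param cap detection-limit PRE rate (s^-1)
#' @param K proportionality constant (cm^6 s^-2)
#' @param site label-site id recorded on each restraint
#' @return data.frame with columns \code{site}, \code{residue}, \code{r},
#'   \code{lol}, \code{upl}, \code{kind} (two_sided / upper_only)
#' @export
derive_pre_restraints <- function(records, tau_c, omega_h, tau_c_err = 0,
                                  cap = 170, K = 1.23e-32, site = "S1") {
  out <- list()
  r_cap <- gamma2_to_distance(cap, tau_c, omega_h, K)
  for (i in seq_len(nrow(records))) {
    st <- records$status[i]
    if (st == "unreliable") next
    if (st == "vanished") {
      out[[length(out) + 1L]] <- data.frame(
        site = site, residue = records$residue[i], r = r_cap,
        lol = NA_real_, upl = r_cap, kind = "upper_only")
      next
    }
    g2 <- records$gamma2[i]
    if (g2 <= 0) next  # undetectable PRE carries no distance information
    r <- gamma2_to_distance(g2, tau_c, omega_h, K)
    sr <- pre_distance_error(g2, records$gamma2_err[i], tau_c, tau_c_err,
                             omega_h, K)
    if (sr > 0.5 * r) {
      message("dropping unreliable PRE restraint at residue ",
              records$residue[i], " (error ", signif(sr, 3), " A > 50% of ",
              signif(r, 3), " A)")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      site = site, residue = records$residue[i], r = r,
      lol = r - sr, upl = r + sr, kind = "two_sided")
  }
  if (!length(out))
    return(data.frame(site = character(), residue = integer(), r = numeric(),
                      lol = numeric(), upl = numeric(), kind = character()))
  do.call(rbind, out)
}

#' Normalised paramagnetic/diamagnetic intensity ratio
#'
#' Each intensity is first normalised by its reference peak integral:
#' \eqn{(I_{para}/ref_{para}) / (I_{dia}/ref_{dia})}.
#'
#' @param i_para,i_dia peak intensities of the paramagnetic / diamagnetic
#'   sample
#' @param ref_para,ref_dia reference peak integrals (> 0)
#' @return intensity ratio (dimensionless)
#' @export
pre_ratio <- function(i_para, i_dia, ref_para, ref_dia) {
  if (ref_para <= 0 || ref_dia <= 0) stop("reference intensities must be > 0")
  if (i_dia == 0) stop("diamagnetic intensity is zero")
  (i_para / ref_para) / (i_dia / ref_dia)
}
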