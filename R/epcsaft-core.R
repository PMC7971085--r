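# Electrolyte PC-SAFT residual Helmholtz energy and its analytic derivatives.
#
# Conventions: reduced residual Helmholtz energy a = A_res/(N kB T) per
# molecule; number density rho in molecules/Angstrom^3; temperatures in K;
# energies as eps/kB in K. Composition derivatives are unconstrained
# mole-fraction partials at fixed (T, rho).
#
# Contributions:
#   hard chain  : Boublik-Mansoori hard-sphere mixture + chain connectivity
#   dispersion  : second-order perturbation with the universal constant sets
#   association : Wertheim first order, donor/acceptor site scheme
#   ion         : finite-ion-size Debye-Hueckel with pure-water permittivity

# Universal dispersion constants
.pcsaft_a <- matrix(c(
   0.9105631445, -0.3084016918, -0.0906148351,
   0.6361281449,  0.1860531159,  0.4527842806,
   2.6861347891, -2.5030047259,  0.5962700728,
 -26.547362491,  21.419793629,  -1.7241829131,
  97.759208784, -65.255885330,  -4.1302112531,
-159.59154087,   83.318680481,  13.776631870,
  91.297774084, -33.746922930,  -8.6728470368), ncol = 3, byrow = TRUE)

.pcsaft_b <- matrix(c(
   0.7240946941, -0.5755498075,  0.0976883116,
   2.2382791861,  0.6995095521, -0.2557574982,
  -4.0025849485,  3.8925673390, -9.1558561530,
 -21.003576815, -17.215471648,  20.642075974,
  26.855641363, 192.67226447,  -38.804430052,
 206.55133841, -161.82646165,   93.626774077,
-355.60235612, -165.20769346,  -29.666905585), ncol = 3, byrow = TRUE)

# tau(x) damping of the DH term; tau(0) = 1
.dh_tau <- function(x) {
  small <- x < 1e-4
  out <- numeric(length(x))
  # series for tiny arguments avoids cancellation: tau = 1 - 3x/4 + 3x^2/5 - ...
  out[small] <- 1 - 0.75 * x[small] + 0.6 * x[small]^2
  xb <- x[!small]
  out[!small] <- 3 / xb^3 * (log1p(xb) - xb + xb^2 / 2)
  out
}
.dh_tau_prime <- function(x) {
  small <- x < 1e-4
  out <- numeric(length(x))
  out[small] <- -0.75 + 1.2 * x[small]
  xb <- x[!small]
  out[!small] <- -3 * .dh_tau(xb) / xb + 3 / (xb * (1 + xb))
  out
}

# Association site-fraction fixed point: damped successive substitution
# (damping 0.5) to tol on the mass-action residual, iteration cap per spec.
solve_site_fractions <- function(rho, x, pars, Delta, tol = 1e-12, maxit = 500L) {
  n <- length(x)
  nA <- pars$nA; nB <- pars$nB
  XA <- rep(0.2, n); XB <- rep(0.2, n)
  XA[nA == 0] <- 1; XB[nB == 0] <- 1
  damp <- 0.5
  for (it in seq_len(maxit)) {
    sumB <- as.numeric(Delta %*% (x * nB * XB))   # sum_j x_j nB_j XB_j Delta_ij
    sumA <- as.numeric(Delta %*% (x * nA * XA))
    XA_new <- 1 / (1 + rho * sumB)
    XB_new <- 1 / (1 + rho * sumA)
    XA_new[nA == 0] <- 1; XB_new[nB == 0] <- 1
    res <- max(abs(XA_new - XA), abs(XB_new - XB))
    XA <- damp * XA_new + (1 - damp) * XA
    XB <- damp * XB_new + (1 - damp) * XB
    if (res < tol) {
      # undamped polish towards machine precision (keeps finite-difference
      # cross-checks of the derivatives noise-free)
      for (jt in 1:300) {
        sumB <- as.numeric(Delta %*% (x * nB * XB))
        sumA <- as.numeric(Delta %*% (x * nA * XA))
        XA_new <- 1 / (1 + rho * sumB); XA_new[nA == 0] <- 1
        XB_new <- 1 / (1 + rho * sumA); XB_new[nB == 0] <- 1
        pres <- max(abs(XA_new - XA), abs(XB_new - XB))
        XA <- XA_new; XB <- XB_new
        if (pres < 1e-15) break
      }
      sumB <- as.numeric(Delta %*% (x * nB * XB))
      sumA <- as.numeric(Delta %*% (x * nA * XA))
      ra <- XA - 1 / (1 + rho * sumB); ra[nA == 0] <- 0
      rb <- XB - 1 / (1 + rho * sumA); rb[nB == 0] <- 0
      return(list(XA = XA, XB = XB, residual = max(abs(ra), abs(rb)),
                  iterations = it, converged = TRUE))
    }
  }
  stop("association fixed point not converged within ", maxit,
       " iterations; residual = ", format(res, digits = 3), call. = FALSE)
}

# Core evaluator. Returns the Helmholtz breakdown and, when derivs = TRUE,
# the analytic density derivative da/drho and unconstrained composition
# gradient da/dx_k of the total residual energy.
a_res_core <- function(rho, x, pars, derivs = FALSE) {
  T <- pars$T
  m <- pars$m; d <- pars$d; sig <- pars$sig; z <- pars$z
  n <- length(x)
  stopifnot(length(m) == n)

  pf <- pi / 6 * rho
  zeta0 <- pf * sum(x * m)
  zeta1 <- pf * sum(x * m * d)
  zeta2 <- pf * sum(x * m * d^2)
  zeta3 <- pf * sum(x * m * d^3)
  eta <- zeta3
  if (eta >= 0.74) stop("packing fraction eta = ", format(eta, digits = 4),
                        " >= 0.74; unphysical state", call. = FALSE)
  om <- 1 - eta
  mbar <- sum(x * m)

  ## ---- hard sphere / hard chain -------------------------------------------
  logom <- log1p(-eta)
  a_hs <- (1 / zeta0) * (3 * zeta1 * zeta2 / om +
                         zeta2^3 / (zeta3 * om^2) +
                         (zeta2^3 / zeta3^2 - zeta0) * logom)
  dd_mat <- outer(d, d) / outer(d, d, `+`)       # d_i d_j/(d_i + d_j)
  g_mat <- 1 / om + dd_mat * 3 * zeta2 / om^2 + dd_mat^2 * 2 * zeta2^2 / om^3
  gii <- diag(g_mat)
  a_hc <- mbar * a_hs - sum(x * (m - 1) * log(gii))

  ## ---- dispersion ----------------------------------------------------------
  mr <- (mbar - 1) / mbar
  mr2 <- mr * (mbar - 2) / mbar
  ai <- .pcsaft_a[, 1] + mr * .pcsaft_a[, 2] + mr2 * .pcsaft_a[, 3]
  bi <- .pcsaft_b[, 1] + mr * .pcsaft_b[, 2] + mr2 * .pcsaft_b[, 3]
  epow <- eta^(0:6)
  I1 <- sum(ai * epow); I2 <- sum(bi * epow)
  uT <- pars$uij / T
  S1 <- sum(outer(x * m, x * m) * uT * pars$sij^3)
  S2 <- sum(outer(x * m, x * m) * uT^2 * pars$sij^3)
  Dfun <- 1 + mbar * (8 * eta - 2 * eta^2) / om^4 +
    (1 - mbar) * (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
      ((1 - eta) * (2 - eta))^2
  C1 <- 1 / Dfun
  a_disp <- -2 * pi * rho * I1 * S1 - pi * rho * mbar * C1 * I2 * S2

  ## ---- association ---------------------------------------------------------
  any_assoc <- any(pars$has_assoc)
  if (any_assoc) {
    fexp <- exp(pars$eps_ab / T) - 1
    Delta <- pars$sij^3 * g_mat * pars$kap_ab * fexp
    sf <- solve_site_fractions(rho, x, pars, Delta)
    XA <- sf$XA; XB <- sf$XB
    nA <- pars$nA; nB <- pars$nB
    a_assoc <- sum(x * (nA * (log(XA) - XA / 2 + 0.5) +
                        nB * (log(XB) - XB / 2 + 0.5)))
  } else {
    Delta <- NULL; XA <- rep(1, n); XB <- rep(1, n)
    sf <- list(residual = 0, iterations = 0L)
    a_assoc <- 0
  }

  ## ---- ion (Debye-Hueckel) -------------------------------------------------
  Sz <- sum(x * z^2)
  if (Sz > 0) {
    epsr <- water_permittivity(T)
    cion <- .const$e2_eps0kB / (epsr * T)        # Angstrom
    kap2 <- cion * rho * Sz
    kappaD <- sqrt(kap2)
    tau <- .dh_tau(kappaD * sig)
    dh_scale <- getOption("actipath.dh_scale", 1)
    a_ion <- -dh_scale * cion * kappaD / (12 * pi) * sum(x * z^2 * tau)
  } else {
    kappaD <- 0; a_ion <- 0
  }

  a_res <- a_hc + a_disp + a_assoc + a_ion
  out <- list(a_hc = a_hc, a_disp = a_disp, a_assoc = a_assoc, a_ion = a_ion,
              a_res = a_res, eta = eta, XA = XA, XB = XB,
              assoc_residual = sf$residual, assoc_iterations = sf$iterations)
  if (!derivs) return(out)

  ## ======================= analytic derivatives =============================
  # zeta partials of a_hs
  da_dz0 <- (-a_hs - logom) / zeta0
  da_dz1 <- (1 / zeta0) * 3 * zeta2 / om
  da_dz2 <- (1 / zeta0) * (3 * zeta1 / om + 3 * zeta2^2 / (zeta3 * om^2) +
                             3 * zeta2^2 / zeta3^2 * logom)
  da_dz3 <- (1 / zeta0) * (3 * zeta1 * zeta2 / om^2 +
                             zeta2^3 * (-1 / (zeta3^2 * om^2) + 2 / (zeta3 * om^3)) -
                             2 * zeta2^3 / zeta3^3 * logom -
                             (zeta2^3 / zeta3^2 - zeta0) / om)
  # g partials (matrices)
  dg_dz2 <- 3 * dd_mat / om^2 + 4 * dd_mat^2 * zeta2 / om^3
  dg_dz3 <- 1 / om^2 + 6 * dd_mat * zeta2 / om^3 + 6 * dd_mat^2 * zeta2^2 / om^4

  zvec <- c(zeta0, zeta1, zeta2, zeta3)
  dahs_dz <- c(da_dz0, da_dz1, da_dz2, da_dz3)

  ## ---- density derivative --------------------------------------------------
  # zeta_n is proportional to rho: dzeta_n/drho = zeta_n/rho
  dahs_drho <- sum(dahs_dz * zvec) / rho
  dgii_drho <- (diag(dg_dz2) * zeta2 + diag(dg_dz3) * zeta3) / rho
  dahc_drho <- mbar * dahs_drho - sum(x * (m - 1) * dgii_drho / gii)

  dI1 <- sum(ai * (0:6) * c(0, epow[1:6]))   # dI1/deta
  dI2 <- sum(bi * (0:6) * c(0, epow[1:6]))
  dD_deta <- mbar * (-4 * eta^2 + 20 * eta + 8) / om^5 +
    (1 - mbar) * (2 * eta^3 + 12 * eta^2 - 48 * eta + 40) / ((1 - eta) * (2 - eta))^3
  C2 <- -C1^2 * dD_deta
  deta_drho <- eta / rho
  dadisp_drho <- -2 * pi * (I1 + rho * dI1 * deta_drho) * S1 -
    pi * mbar * S2 * (C1 * I2 + rho * (C2 * I2 + C1 * dI2) * deta_drho)

  if (any_assoc) {
    dg_drho_mat <- (dg_dz2 * zeta2 + dg_dz3 * zeta3) / rho
    dDelta_drho <- pars$sij^3 * pars$kap_ab * fexp * dg_drho_mat
    nA <- pars$nA; nB <- pars$nB
    wA <- x * nA * XA; wB <- x * nB * XB
    # d a_assoc/drho = -sum_ij wA_i wB_j d(rho Delta_ij)/drho  (Q-function)
    dassoc_drho <- -sum(outer(wA, wB) * (Delta + rho * dDelta_drho))
  } else dassoc_drho <- 0

  if (Sz > 0) {
    dkap_drho <- kappaD / (2 * rho)
    taup <- .dh_tau_prime(kappaD * sig)
    daion_drho <- -dh_scale * cion / (12 * pi) *
      (dkap_drho * sum(x * z^2 * tau) + kappaD * sum(x * z^2 * taup * sig) * dkap_drho)
  } else daion_drho <- 0

  dadrho <- dahc_drho + dadisp_drho + dassoc_drho + daion_drho

  ## ---- composition gradient (fixed rho, T) --------------------------------
  # dzeta_n/dx_k = pf * m_k d_k^n
  zk <- rbind(pf * m, pf * m * d, pf * m * d^2, pf * m * d^3)  # 4 x n
  dahs_dx <- as.numeric(dahs_dz %*% zk)
  dgii_dx <- outer(diag(dg_dz2), zk[3, ]) + outer(diag(dg_dz3), zk[4, ])  # i x k
  dahc_dx <- m * a_hs + mbar * dahs_dx -
    (m - 1) * log(gii) -
    as.numeric((x * (m - 1) / gii) %*% dgii_dx)

  deta_dx <- zk[4, ]
  dai_dm <- .pcsaft_a[, 2] / mbar^2 + .pcsaft_a[, 3] * (3 - 4 / mbar) / mbar^2
  dbi_dm <- .pcsaft_b[, 2] / mbar^2 + .pcsaft_b[, 3] * (3 - 4 / mbar) / mbar^2
  dI1_dm <- sum(dai_dm * epow); dI2_dm <- sum(dbi_dm * epow)
  dD_dm <- (8 * eta - 2 * eta^2) / om^4 -
    (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) / ((1 - eta) * (2 - eta))^2
  dI1_dx <- dI1 * deta_dx + dI1_dm * m
  dI2_dx <- dI2 * deta_dx + dI2_dm * m
  dC1_dx <- C2 * deta_dx - C1^2 * dD_dm * m
  dS1_dx <- 2 * as.numeric((uT * pars$sij^3) %*% (x * m)) * m
  dS2_dx <- 2 * as.numeric((uT^2 * pars$sij^3) %*% (x * m)) * m
  dadisp_dx <- -2 * pi * rho * (dI1_dx * S1 + I1 * dS1_dx) -
    pi * rho * (m * C1 * I2 * S2 +
                  mbar * (dC1_dx * I2 + C1 * dI2_dx) * S2 +
                  mbar * C1 * I2 * dS2_dx)

  if (any_assoc) {
    nA <- pars$nA; nB <- pars$nB
    term1 <- nA * (log(XA) - XA + 1) + nB * (log(XB) - XB + 1)
    term1[!pars$has_assoc] <- 0
    term2 <- -rho * (nA * XA * as.numeric(Delta %*% (x * nB * XB)) +
                       nB * XB * as.numeric(Delta %*% (x * nA * XA)))
    base <- sum(outer(wA, wB) * pars$sij^3 * pars$kap_ab * fexp * dg_dz2) # coeff of dz2
    base3 <- sum(outer(wA, wB) * pars$sij^3 * pars$kap_ab * fexp * dg_dz3)
    term3 <- -rho * (base * zk[3, ] + base3 * zk[4, ])
    dassoc_dx <- term1 + term2 + term3
  } else dassoc_dx <- numeric(n)

  if (Sz > 0) {
    dkap_dx <- cion * rho * z^2 / (2 * kappaD)
    Sztau <- sum(x * z^2 * tau)
    Sztaup <- sum(x * z^2 * taup * sig)
    daion_dx <- -dh_scale * cion / (12 * pi) *
      (dkap_dx * Sztau + kappaD * (z^2 * tau + dkap_dx * Sztaup))
  } else daion_dx <- numeric(n)

  out$dadrho <- dadrho
  out$dadx <- dahc_dx + dadisp_dx + dassoc_dx + daion_dx
  out$Z <- 1 + rho * dadrho
  out
}
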