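# ePC-SAFT core: limits, closed forms, derivative cross-checks, solver
# contracts, and the asymmetric activity-coefficient normalization.

test_that("all residual contributions vanish in the ideal-gas limit", {
  pars <- actipath:::saft_pars(reg, c("water", "glucose", "k", "cl"), 298.15)
  x <- c(0.97, 0.01, 0.01, 0.01)
  res <- actipath:::a_res_core(1e-14, x, pars)
  expect_lt(abs(res$a_hc), 1e-8)
  expect_lt(abs(res$a_disp), 1e-8)
  expect_lt(abs(res$a_assoc), 1e-8)
  expect_lt(abs(res$a_ion), 1e-8)
  expect_equal(res$a_res, res$a_hc + res$a_disp + res$a_assoc + res$a_ion)
})

test_that("a_ion is exactly zero without charges and negative with salt", {
  pars <- actipath:::saft_pars(reg, c("water", "glucose"), 298.15)
  res <- actipath:::a_res_core(0.03, c(0.9, 0.1), pars)
  expect_identical(res$a_ion, 0)
  pars2 <- actipath:::saft_pars(reg, c("water", "k", "cl"), 298.15)
  res2 <- actipath:::a_res_core(0.03, c(0.98, 0.01, 0.01), pars2)
  expect_lt(res2$a_ion, 0)  # Debye-Hueckel is attractive
})

test_that("hard-chain term reduces to Carnahan-Starling for m_seg = 1", {
  toy <- toy_registry(u = 0, m_seg = 1, sigma = 3.0)
  pars <- actipath:::saft_pars(toy, "ball", 298.15)
  eta <- 0.40
  rho <- eta / (pi / 6 * pars$m * pars$d^3)
  res <- actipath:::a_res_core(rho, 1, pars)
  cs <- (4 * eta - 3 * eta^2) / (1 - eta)^2
  expect_equal(res$a_hc, cs, tolerance = 1e-12)
  expect_identical(res$a_assoc, 0)  # kappa = 0: association term exactly 0
  expect_identical(res$a_disp, 0)   # u = 0
})

test_that("pressure recovers the ideal gas law when interactions are off", {
  toy <- toy_registry(u = 0, m_seg = 1, sigma = 3.0)
  # hard spheres at vanishing pressure: excluded volume becomes negligible
  st <- solve_density(toy, 300, 1e-3, c(ball = 1), phase = "vapor")
  expect_equal(st$rho, 1e-3 / (1.380649e7 * 300), tolerance = 1e-8)
  expect_equal(pressure(st, toy), 1e-3, tolerance = 1e-8)
})

test_that("liquid density solve meets its contract for pure water", {
  st <- solve_density(reg, 298.15, 1.01325e5, c(water = 1))
  hb <- residual_helmholtz(st, reg)
  eta <- attr(hb, "eta")
  expect_gt(eta, 0.2); expect_lt(eta, 0.6)
  expect_lt(abs(pressure(st, reg) - st$P) / st$P, 1e-8)
  # mass density within 1% of 997 kg/m3
  dens <- st$rho * 1e30 / 6.02214076e23 * 18.015268 / 1000
  expect_equal(dens, 997, tolerance = 0.01)
  # stable branch: +1% pressure compresses the liquid
  st2 <- solve_density(reg, 298.15, 1.01325e5 * 1.01, c(water = 1))
  expect_gt(st2$rho, st$rho)
})

test_that("analytic pressure matches finite differences to 1e-6 relative", {
  for (xx in list(c(water = 1), c(water = 0.96, k = 0.015, cl = 0.015, glucose = 0.01))) {
    st <- solve_density(reg, 298.15, 1.01325e5, xx)
    pa <- pressure(st, reg, "analytic")
    pn <- pressure(st, reg, "numeric")
    expect_lt(abs(pa - pn) / abs(pa), 1e-6)
  }
})

test_that("analytic derivatives agree with central differences at 50 seeded states", {
  set.seed(42)
  pool <- c("water", "glucose", "atp", "gap", "k", "cl", "mg", "so4", "tris")
  worst_rho <- 0; worst_x <- 0
  for (i in 1:50) {
    nsp <- sample(2:5, 1)
    sp <- c("water", sample(setdiff(pool, "water"), nsp - 1))
    w <- c(stats::runif(1, 5, 20), stats::runif(nsp - 1, 0.01, 0.5))
    x <- w / sum(w)
    # electroneutral: pair every charge with counter-charge via k/cl adjustments
    z <- reg$pure$z[match(sp, reg$pure$species_id)]
    net <- sum(x * z)
    if (abs(net) > 0) {
      cntr <- if (net > 0) "cl" else "k"
      zc <- if (net > 0) -1 else 1
      if (cntr %in% sp) {
        x[sp == cntr] <- x[sp == cntr] - net / zc
      } else { sp <- c(sp, cntr); x <- c(x, -net / zc) }
      x <- x / sum(x)
    }
    T <- stats::runif(1, 278, 343)
    pars <- actipath:::saft_pars(reg, sp, T)
    eta <- stats::runif(1, 0.15, 0.5)
    rho <- eta / (pi / 6 * sum(x * pars$m * pars$d^3))
    res <- actipath:::a_res_core(rho, x, pars, derivs = TRUE)
    h <- rho * 3e-5
    dn <- (actipath:::a_res_core(rho + h, x, pars)$a_res -
             actipath:::a_res_core(rho - h, x, pars)$a_res) / (2 * h)
    worst_rho <- max(worst_rho, abs(res$dadrho - dn) / max(abs(dn), 1e-10))
    ks <- sample(length(x), min(2, length(x)))
    for (k in ks) {
      hx <- 1e-6
      xp <- x; xm <- x; xp[k] <- xp[k] + hx; xm[k] <- xm[k] - hx
      dnx <- (actipath:::a_res_core(rho, xp, pars)$a_res -
                actipath:::a_res_core(rho, xm, pars)$a_res) / (2 * hx)
      worst_x <- max(worst_x, abs(res$dadx[k] - dnx) / max(abs(dnx), 1e-8))
    }
  }
  expect_lt(worst_rho, 1e-6)
  expect_lt(worst_x, 1e-6)
})

test_that("fugacity coefficients are zero for an ideal mixture and obey Gibbs-Duhem", {
  toy <- toy_registry(u = 0, m_seg = 1, sigma = 3.0)
  # near-ideal: low-pressure vapor of hard spheres
  st <- solve_density(toy, 300, 10, c(ball = 1), phase = "vapor")
  lp <- ln_fugacity_coefficients(st, toy)
  expect_lt(abs(lp[["ball"]]), 1e-6)

  # Gibbs-Duhem at fixed T, P on a real mixture
  x <- c(water = 0.95, glucose = 0.02, k = 0.015, cl = 0.015)
  d <- c(water = -0.002, glucose = 0.001, k = 0.0005, cl = 0.0005)
  lnphi_at <- function(xx) {
    st <- solve_density(reg, 298.15, 1.01325e5, xx)
    ln_fugacity_coefficients(st, reg)
  }
  eps <- 0.5
  lp_p <- lnphi_at((x + eps * d) / sum(x + eps * d))
  lp_m <- lnphi_at((x - eps * d) / sum(x - eps * d))
  gd <- sum(x * (lp_p - lp_m))
  expect_lt(abs(gd), 1e-6)
})

test_that("refuses fugacity coefficients of a non-converged state", {
  st <- solve_density(reg, 298.15, 1.01325e5, c(water = 1))
  st$rho <- st$rho * 1.05
  expect_error(ln_fugacity_coefficients(st, reg), "not converged")
})

test_that("gamma* is 1 at infinite dilution for every tabulated species", {
  sp_all <- setdiff(reg$pure$species_id, "water")
  expect_gte(length(sp_all), 25)
  z_of <- stats::setNames(reg$pure$z, reg$pure$species_id)
  for (sp in sp_all) {
    tr <- 1e-14
    x <- c(1 - tr, tr); names(x) <- c("water", sp)
    lg <- activity_coefficient_star(reg, 298.15, 1.01325e5, x, sp,
                                    trace = tr)$ln_gamma_star
    if (z_of[[sp]] == 0) {
      expect_lt(abs(lg), 1e-6)
    } else {
      # ionic species converge as sqrt(x) through the Debye term
      expect_lt(abs(lg), 2e-4)
      lg10 <- activity_coefficient_star(
        reg, 298.15, 1.01325e5,
        stats::setNames(c(1 - 1e-10, 1e-10), c("water", sp)), sp)$ln_gamma_star
      expect_lt(abs(lg), abs(lg10))
    }
  }
})

test_that("the infinite-dilution reference is insensitive to the trace level", {
  med <- veech_medium()
  x <- medium_composition(med, c(fbp = 1e-10 * 55.5))
  g0 <- activity_coefficient_star(reg, med$T, med$P, x, "fbp", trace = 1e-10)
  g1 <- activity_coefficient_star(reg, med$T, med$P, x, "fbp", trace = 1e-9)
  g2 <- activity_coefficient_star(reg, med$T, med$P, x, "fbp", trace = 1e-11)
  expect_equal(g1$ln_gamma_star, g0$ln_gamma_star, tolerance = 1e-6)
  expect_equal(g2$ln_gamma_star, g0$ln_gamma_star, tolerance = 1e-6)
})

test_that("trace-ion activity coefficients recover the Debye-Hueckel limiting law", {
  T <- 298.15
  epsr <- water_permittivity(T)
  lamB <- 2.0998164e6 / (4 * pi * epsr * T)      # Bjerrum length, Angstrom
  for (I in c(1e-4, 3e-5)) {
    x <- mol_to_x(c(k = I, cl = I, mg = 1e-10, so4 = 1e-10))
    ac <- activity_coefficient_star(reg, T, 1.01325e5, x, "mg")
    kap <- sqrt(8 * pi * lamB * 6.02214076e-4 * I)  # from molar ion density
    ll <- -4 * lamB / 2 * kap                       # z^2 = 4
    expect_equal(ac$ln_gamma_star, ll, tolerance = 0.05)
  }
})

test_that("neutral-metabolite gamma* responds monotonically to added KCl", {
  ms <- seq(0, 0.3, length.out = 7)
  g <- vapply(ms, function(m) {
    mol <- c(glucose = 1e-10 * 55.5)
    if (m > 0) mol <- c(mol, k = m, cl = m)
    x <- mol_to_x(mol)
    activity_coefficient_star(reg, 298.15, 1.01325e5, x, "glucose")$ln_gamma_star
  }, numeric(1))
  expect_true(all(diff(g) > 0) || all(diff(g) < 0))
})

test_that("association site fractions are valid and tightly converged", {
  st <- solve_density(reg, 298.15, 1.01325e5,
                      c(water = 0.9, glucose = 0.05, atp = 0.05))
  hb <- residual_helmholtz(st, reg)
  sf <- attr(hb, "site_fractions")
  expect_true(all(sf$X_donor > 0 & sf$X_donor <= 1))
  expect_true(all(sf$X_acceptor > 0 & sf$X_acceptor <= 1))
  expect_lt(attr(hb, "assoc_residual"), 1e-10)
})

test_that("gamma* requires water in the composition", {
  expect_error(
    activity_coefficient_star(reg, 298.15, 1.01325e5, c(glucose = 1), "glucose"),
    "water absent")
})
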