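#' Construct a mixture state
#'
#' A `mixture_state` bundles temperature, pressure, composition and number
#' density of one aqueous phase. Compositions must be normalized and (apart
#' from trace-level round-off) electroneutral.
#'
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param x named numeric vector of mole fractions (names are species ids).
#' @param rho number density, molecules/Angstrom^3.
#' @param registry an [epcsaft_registry()] used to check valences.
#' @return an object of class `mixture_state`.
#' @export
mixture_state <- function(T, P, x, rho, registry) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("composition must be a named vector of mole fractions", call. = FALSE)
  }
  if (any(x < 0)) stop("negative mole fraction", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-12) {
    stop("mole fractions sum to ", format(sum(x), digits = 15), ", not 1", call. = FALSE)
  }
  z <- registry$pure$z[match(names(x), registry$pure$species_id)]
  qnet <- sum(x * z)
  # 1e-8 tolerance admits trace-level (1e-10) charged metabolites in the
  # ideally-diluted reference composition without a counter-ion.
  if (abs(qnet) > 1e-8) {
    stop("composition not electroneutral: sum x_i z_i = ",
         format(qnet, digits = 4), call. = FALSE)
  }
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  structure(list(T = T, P = P, x = x, rho = rho), class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("<mixture_state> T =", x$T, "K, P =", x$P, "Pa, rho =",
      format(x$rho, digits = 6), "A^-3,", length(x$x), "species\n")
  invisible(x)
}

#' Residual Helmholtz energy breakdown
#'
#' Evaluates the reduced residual Helmholtz energy per molecule,
#' `a_res = a_hc + a_disp + a_assoc + a_ion`, at a converged mixture state.
#'
#' @param state a [mixture_state()].
#' @param registry an [epcsaft_registry()].
#' @return a tibble with one row per contribution plus their sum, and
#'   attributes `eta` (packing fraction), `site_fractions`, and
#'   `assoc_residual` (mass-action residual at convergence).
#' @export
residual_helmholtz <- function(state, registry) {
  pars <- saft_pars(registry, names(state$x), state$T)
  res <- a_res_core(state$rho, unname(state$x), pars)
  out <- tibble::tibble(
    term = c("a_hc", "a_disp", "a_assoc", "a_ion", "a_res"),
    value = c(res$a_hc, res$a_disp, res$a_assoc, res$a_ion, res$a_res))
  attr(out, "eta") <- res$eta
  attr(out, "site_fractions") <-
    tibble::tibble(species_id = pars$species, X_donor = res$XA, X_acceptor = res$XB)
  attr(out, "assoc_residual") <- res$assoc_residual
  out
}

# Pressure (Pa) at given rho, x, T. analytic = TRUE uses the analytic
# density derivative of a_res; FALSE uses central differences.
pressure_core <- function(rho, x, pars, analytic = TRUE) {
  if (analytic) {
    res <- a_res_core(rho, x, pars, derivs = TRUE)
    Z <- res$Z
  } else {
    # central differences with Richardson extrapolation (step-size control)
    cd <- function(h) {
      (a_res_core(rho + h, x, pars)$a_res -
         a_res_core(rho - h, x, pars)$a_res) / (2 * h)
    }
    h <- rho * 3e-5
    dadrho <- (4 * cd(h / 2) - cd(h)) / 3
    Z <- 1 + rho * dadrho
  }
  Z * rho * .const$kB_PaA3 * pars$T
}

#' Pressure of a mixture state
#'
#' @param state a [mixture_state()].
#' @param registry an [epcsaft_registry()].
#' @param method `"analytic"` (default) differentiates the residual Helmholtz
#'   energy analytically; `"numeric"` uses central differences. Both agree to
#'   1e-6 relative (tested).
#' @return pressure in Pa.
#' @export
pressure <- function(state, registry, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  pars <- saft_pars(registry, names(state$x), state$T)
  P <- pressure_core(state$rho, unname(state$x), pars, analytic = method == "analytic")
  if (!is.finite(P)) stop("non-finite pressure derivative", call. = FALSE)
  P
}

# Density root on a phase branch. Newton iteration on packing fraction with
# a bisection safeguard.
solve_density_core <- function(pars, P, x, phase = c("liquid", "vapor"),
                               tol = 1e-9) {
  phase <- match.arg(phase)
  md3 <- sum(x * pars$m * pars$d^3)
  eta_to_rho <- function(eta) eta / (pi / 6 * md3)
  f <- function(eta) pressure_core(eta_to_rho(eta), x, pars) - P
  eta <- if (phase == "liquid") 0.45 else 1e-10
  lo <- if (phase == "liquid") 0.15 else 1e-14
  hi <- if (phase == "liquid") 0.7399 else 0.2
  for (it in 1:80) {
    fe <- f(eta)
    if (abs(fe) < tol * abs(P)) {
      return(list(eta = eta, rho = eta_to_rho(eta), residual = abs(fe) / abs(P)))
    }
    h <- max(eta * 1e-6, 1e-12)
    dfe <- (f(eta + h) - f(eta - h)) / (2 * h)
    step <- fe / dfe
    eta_new <- eta - step
    if (!is.finite(eta_new) || eta_new <= lo || eta_new >= hi) {
      # fall back to a bracketing scan on the hinted branch
      grid <- if (phase == "liquid") seq(0.2, 0.7399, length.out = 60)
              else exp(seq(log(1e-14), log(0.2), length.out = 60))
      fg <- vapply(grid, f, numeric(1))
      sgn <- which(diff(sign(fg)) != 0)
      if (length(sgn) == 0) {
        stop("no density root on the ", phase, " branch; P(eta) spans [",
             format(min(fg) + P, digits = 4), ", ", format(max(fg) + P, digits = 4),
             "] Pa over eta [", format(min(grid), digits = 3), ", ",
             format(max(grid), digits = 3), "]", call. = FALSE)
      }
      idx <- if (phase == "liquid") sgn[length(sgn)] else sgn[1]
      r <- stats::uniroot(f, c(grid[idx], grid[idx + 1]), tol = 1e-14)
      eta_new <- r$root
    }
    eta <- eta_new
  }
  fe <- f(eta)
  if (abs(fe) >= tol * abs(P)) {
    stop("density solve did not converge; |dP|/P = ",
         format(abs(fe) / abs(P), digits = 3), call. = FALSE)
  }
  list(eta = eta, rho = eta_to_rho(eta), residual = abs(fe) / abs(P))
}

#' Solve the density of a mixture at fixed T and P
#'
#' Finds the number density whose EOS pressure matches `P` on the hinted
#' phase branch (liquid iteration starts at packing fraction 0.45, vapor at
#' 1e-10) and returns the corresponding [mixture_state()].
#'
#' @param registry an [epcsaft_registry()].
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param x named vector of mole fractions (electroneutral).
#' @param phase `"liquid"` or `"vapor"`.
#' @return a [mixture_state()] with relative pressure residual below 1e-8.
#' @examples
#' reg <- epcsaft_registry()
#' st <- solve_density(reg, 298.15, 1.01325e5, c(water = 1))
#' st$rho  # ~0.0333 molecules/A^3 (~997 kg/m^3)
#' @export
solve_density <- function(registry, T, P, x, phase = c("liquid", "vapor")) {
  phase <- match.arg(phase)
  pars <- saft_pars(registry, names(x), T)
  sol <- solve_density_core(pars, P, unname(x), phase)
  mixture_state(T, P, x, sol$rho, registry)
}

# ln fugacity coefficients from the analytic composition gradient.
ln_phi_core <- function(rho, x, pars) {
  res <- a_res_core(rho, x, pars, derivs = TRUE)
  Z <- res$Z
  mu_res <- res$a_res + (Z - 1) + res$dadx - sum(x * res$dadx)
  mu_res - log(Z)
}

#' Fugacity coefficients of all species in a state
#'
#' `ln phi_i` from the composition derivatives of the residual Helmholtz
#' energy at fixed T and total pressure.
#'
#' @param state a converged [mixture_state()] (from [solve_density()]).
#' @param registry an [epcsaft_registry()].
#' @return named vector of `ln phi_i`.
#' @export
ln_fugacity_coefficients <- function(state, registry) {
  # refuse states that do not satisfy their own pressure
  Pcalc <- pressure(state, registry)
  if (abs(Pcalc - state$P) / max(state$P, 1) > 1e-6) {
    stop("state is not converged: EOS pressure ", format(Pcalc, digits = 6),
         " Pa differs from state P ", format(state$P, digits = 6), " Pa",
         call. = FALSE)
  }
  pars <- saft_pars(registry, names(state$x), state$T)
  lp <- ln_phi_core(state$rho, unname(state$x), pars)
  names(lp) <- names(state$x)
  lp
}

#' Asymmetric activity coefficients
#'
#' For each requested species, the mole-fraction-scale asymmetric activity
#' coefficient `gamma*_i = phi_i(mixture) / phi_i^inf`, where `phi_i^inf` is
#' the fugacity coefficient of `i` infinitely diluted in pure water at the
#' same T and P (trace mole fraction 1e-10). The molality-scale coefficient
#' `gamma*_m,i = gamma*_i * x_water` is reported alongside, so that molality
#' products `K_m` multiply directly with `K_gamma`.
#'
#' @param registry an [epcsaft_registry()].
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param x named electroneutral mole-fraction vector including `"water"`.
#' @param species ids to evaluate; default all non-water species in `x`.
#' @param trace mole fraction used for the infinite-dilution reference.
#' @return tibble with columns `species_id`, `ln_gamma_star`, `gamma_star`,
#'   `gamma_star_m`.
#' @export
activity_coefficient_star <- function(registry, T, P, x, species = NULL,
                                      trace = 1e-10) {
  if (!"water" %in% names(x)) {
    stop("water absent from composition; the asymmetric reference is undefined",
         call. = FALSE)
  }
  if (is.null(species)) species <- setdiff(names(x), "water")
  pars <- saft_pars(registry, names(x), T)
  sol <- solve_density_core(pars, P, unname(x), "liquid")
  lp_mix <- ln_phi_core(sol$rho, unname(x), pars)
  names(lp_mix) <- names(x)

  ln_gamma <- vapply(species, function(sp) {
    xi <- c(trace, 1 - trace)
    names(xi) <- c(sp, "water")
    pars_i <- saft_pars(registry, names(xi), T)
    # true infinite-dilution limit: the Debye screening vanishes (kappa -> 0),
    # so the reference state of an ion carries no ionic contribution
    pars_i$z <- c(0, 0)
    sol_i <- solve_density_core(pars_i, P, unname(xi), "liquid")
    lp_inf <- ln_phi_core(sol_i$rho, unname(xi), pars_i)[1]
    lp_mix[[sp]] - lp_inf
  }, numeric(1))

  xw <- x[["water"]]
  tibble::tibble(species_id = species,
                 ln_gamma_star = unname(ln_gamma),
                 gamma_star = exp(unname(ln_gamma)),
                 gamma_star_m = exp(unname(ln_gamma)) * xw)
}
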