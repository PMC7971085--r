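# Equilibrium-constant algebra: Ka = Km * Kgamma, van 't Hoff transforms,
# standard Gibbs energies, and reaction quotients under arbitrary conditions.

#' Equilibrium record
#'
#' A measured equilibrium-concentration ratio with its medium description.
#'
#' @param reaction_id reaction identifier.
#' @param K_value measured ratio (dimensionless, molality or molarity based).
#' @param basis `"molality"` or `"molarity"`.
#' @param T temperature of the measurement, K.
#' @param pH pH of the measurement.
#' @param medium an `aqueous_medium` ([build_medium()]).
#' @param K_uncertainty optional 1-sigma uncertainty of `K_value`.
#' @param provenance free text.
#' @return an `equilibrium_record`.
#' @export
equilibrium_record <- function(reaction_id, K_value, basis = c("molarity", "molality"),
                               T, pH, medium, K_uncertainty = NA_real_,
                               provenance = "") {
  basis <- match.arg(basis)
  if (K_value <= 0) stop("K_value must be positive", call. = FALSE)
  structure(list(reaction_id = reaction_id, K_value = K_value, basis = basis,
                 T = T, pH = pH, medium = medium,
                 K_uncertainty = K_uncertainty, provenance = provenance),
            class = "equilibrium_record")
}

#' Molality-based K from a molarity-based record
#'
#' Identity mapping under the dilute-aqueous assumption that the solution
#' density is 1 kg/L, so concentration in mmol/L equals molality in mmol/kg.
#' The assumption is flagged in the result's attributes.
#'
#' @param record an [equilibrium_record()].
#' @return the record with `basis = "molality"`; attribute
#'   `density_assumption` is `TRUE` when the conversion was applied.
#' @export
km_from_kc <- function(record) {
  stopifnot(inherits(record, "equilibrium_record"))
  flag <- record$basis == "molarity"
  record$basis <- "molality"
  attr(record, "density_assumption") <- flag
  record
}

#' Activity-coefficient ratio of a reaction
#'
#' `K_gamma = prod_i (gamma*_m,i)^nu_i` with molality-scale asymmetric
#' activity coefficients predicted by ePC-SAFT at the medium composition.
#' H+ never enters (it is handled by the speciation layer); the phosphate
#' pool uses the speciation-weighted mean of its H2PO4-/HPO4(2-) species.
#'
#' @param registry an [epcsaft_registry()].
#' @param reaction a [reaction_spec()].
#' @param medium an `aqueous_medium` (water plus salts/buffer, charge
#'   balanced).
#' @param metabolite_molalities optional named molalities of the reaction
#'   participants. When absent, participants are evaluated at trace
#'   concentration (the standard-state derivation mode); when given, the
#'   full composition is used.
#' @param mole_fraction_scale logical; `TRUE` evaluates the ratio on the
#'   mole-fraction scale instead of the molality scale (sensitivity switch).
#' @return `K_gamma` (dimensionless), with attribute `"gammas"` (tibble).
#' @export
k_gamma <- function(registry, reaction, medium, metabolite_molalities = NULL,
                    mole_fraction_scale = FALSE) {
  stopifnot(inherits(reaction, "reaction_spec"), inherits(medium, "aqueous_medium"))
  nu <- reaction$stoichiometry
  gam <- participant_gammas(registry, reaction, medium, metabolite_molalities)
  col <- if (mole_fraction_scale) gam$gamma_star else gam$gamma_star_m
  kg <- prod(col^nu[gam$participant])
  attr(kg, "gammas") <- gam
  kg
}

# gamma*_m per participant (pi pooled; water excluded), evaluated either at
# trace or at the supplied finite molalities merged into the medium.
participant_gammas <- function(registry, reaction, medium,
                               metabolite_molalities = NULL) {
  nu <- reaction$stoichiometry
  parts <- setdiff(names(nu), "water")
  # pooled phosphate splits into its two pH-7-relevant species
  needs_pi <- "pi" %in% parts
  lad <- if (needs_pi) pka_ladders(registry)[["pi"]]
  pi_frac <- NULL
  ids <- setdiff(parts, "pi")
  extra <- NULL
  if (needs_pi) {
    fr <- species_fractions(lad, medium$pH)
    f1 <- fr$fraction[fr$state == 1]; f2 <- fr$fraction[fr$state == 2]
    pi_frac <- c(h2po4 = f1 / (f1 + f2), hpo4 = f2 / (f1 + f2))
  }
  if (is.null(metabolite_molalities)) {
    tr_molal <- 1e-10 * .const$mol_per_kg_water  # trace in molality terms
    extra <- stats::setNames(rep(tr_molal, length(ids)), ids)
    if (needs_pi) extra <- c(extra, tr_molal * pi_frac)
  } else {
    miss <- setdiff(parts, names(metabolite_molalities))
    if (length(miss) > 0) {
      stop("molalities missing for participant(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    extra <- metabolite_molalities[ids]
    if (needs_pi) extra <- c(extra, metabolite_molalities[["pi"]] * pi_frac)
    # close the charge of the added metabolites with the medium counter-ion
    z <- registry$pure$z[match(names(extra), registry$pure$species_id)]
    net <- sum(extra * z)
    if (abs(net) > 1e-15) {
      if (net > 0) stop("metabolite charge closure requires an anion; ",
                        "declare it in the medium instead", call. = FALSE)
      extra <- c(extra, k = -net)
    }
  }
  x <- medium_composition(medium, extra)
  sp_eval <- c(setdiff(ids, character(0)), if (needs_pi) c("h2po4", "hpo4"))
  ac <- activity_coefficient_star(registry, medium$T, medium$P, x, sp_eval)
  g_m <- stats::setNames(ac$gamma_star_m, ac$species_id)
  g_x <- stats::setNames(ac$gamma_star, ac$species_id)
  out_ids <- parts
  gm <- vapply(out_ids, function(sp) {
    if (sp == "pi") sum(pi_frac * g_m[names(pi_frac)]) else g_m[[sp]]
  }, numeric(1))
  gx <- vapply(out_ids, function(sp) {
    if (sp == "pi") sum(pi_frac * g_x[names(pi_frac)]) else g_x[[sp]]
  }, numeric(1))
  tibble::tibble(participant = out_ids, nu = unname(nu[out_ids]),
                 gamma_star = unname(gx), gamma_star_m = unname(gm))
}

#' Van 't Hoff temperature transform of an equilibrium constant
#'
#' `ln K2 = ln K1 - (dRh0/R) (1/T2 - 1/T1)` with a temperature-independent
#' standard reaction enthalpy; exactly invertible under swap of T1 and T2.
#'
#' @param K_at_T1 equilibrium constant at `T1`.
#' @param dRh0 standard reaction enthalpy, kJ/mol.
#' @param T1,T2 temperatures, K (273-373 K).
#' @return K at `T2`.
#' @export
vant_hoff <- function(K_at_T1, dRh0, T1, T2) {
  stopifnot(T1 >= 273, T1 <= 373, T2 >= 273, T2 <= 373)
  exp(log(K_at_T1) - dRh0 / .const$R_kJ * (1 / T2 - 1 / T1))
}

#' Standard Gibbs energy from the thermodynamic equilibrium constant
#'
#' @param Ka thermodynamic equilibrium constant (> 0).
#' @param T temperature, K.
#' @return `dRg0 = -R T ln Ka` in kJ/mol.
#' @export
dg0_from_ka <- function(Ka, T) {
  if (any(Ka <= 0)) stop("Ka must be positive", call. = FALSE)
  -.const$R_kJ * T * log(Ka)
}

#' @rdname dg0_from_ka
#' @param dg0 standard Gibbs energy of reaction, kJ/mol.
#' @export
ka_from_dg0 <- function(dg0, T) exp(-dg0 / (.const$R_kJ * T))

#' Reaction quotient under stated conditions
#'
#' Activity mode: `Qa = Qm * Qgamma` with `Qgamma` from ePC-SAFT at the full
#' medium composition and, for reactions with explicit H+, `a_H+ = 10^-pH`.
#' Concentration mode: `Qm` only (the classical approach). Molalities in
#' mol/kg against the 1 mol/kg standard state.
#'
#' @param registry an [epcsaft_registry()].
#' @param reaction a [reaction_spec()].
#' @param metabolite_molalities named molalities (mol/kg) of all reaction
#'   participants (H+ excluded; taken from `pH`).
#' @param medium an `aqueous_medium` describing salts/buffer; the
#'   metabolites are merged into it for the gamma prediction.
#' @param mode `"activity"` or `"concentration"`.
#' @param gamma_medium_extra optional named molalities of additional
#'   non-participant metabolites present in the gamma medium (conditions B).
#' @return Q (dimensionless), with attributes `Qm`, `Qgamma`.
#' @export
reaction_quotient <- function(registry, reaction, metabolite_molalities, medium,
                              mode = c("activity", "concentration"),
                              gamma_medium_extra = NULL) {
  mode <- match.arg(mode)
  nu <- reaction$stoichiometry
  parts <- setdiff(names(nu), "water")
  mm <- metabolite_molalities[parts]
  if (any(is.na(mm)) || any(mm <= 0)) {
    stop("all participants need positive molalities; missing/non-positive: ",
         paste(parts[is.na(mm) | mm <= 0], collapse = ", "), call. = FALSE)
  }
  Qm <- prod(mm^nu[parts])
  if (reaction$h_explicit) Qm <- Qm * 10^(-medium$pH * reaction$nu_h)
  Qg <- 1
  if (mode == "activity") {
    med <- medium
    if (!is.null(gamma_medium_extra) && length(gamma_medium_extra) > 0) {
      # merge non-participant metabolites (and their counter charge) into the
      # medium before predicting gammas
      med <- merge_metabolites(registry, medium, gamma_medium_extra)
    }
    gam <- participant_gammas(registry, reaction, med, mm)
    Qg <- prod(gam$gamma_star_m^gam$nu)
  }
  out <- Qm * Qg
  attr(out, "Qm") <- Qm
  attr(out, "Qgamma") <- Qg
  out
}

# add metabolites (with K+ charge closure) to a medium
merge_metabolites <- function(registry, medium, metabolites) {
  z <- registry$pure$z[match(names(metabolites), registry$pure$species_id)]
  net <- sum(metabolites * z)
  extra <- metabolites
  if (net < -1e-15) extra <- c(extra, k = -net)
  if (net > 1e-15) stop("net positive metabolite charge; declare an anion",
                        call. = FALSE)
  mol <- stats::setNames(medium$solutes$molality, medium$solutes$species_id)
  for (sp in names(extra)) {
    mol[sp] <- (if (sp %in% names(mol)) mol[[sp]] else 0) + extra[[sp]]
  }
  out <- medium
  out$solutes <- tibble::tibble(species_id = names(mol), molality = unname(mol))
  out
}

#' Gibbs energy of reaction
#'
#' `dRg = dRg0(T) + R T ln Q`; negative values mean the reaction proceeds
#' spontaneously in the stated direction.
#'
#' @param dg0 standard Gibbs energy of reaction at `T`, kJ/mol.
#' @param Q reaction quotient (activities or concentrations).
#' @param T temperature, K.
#' @return kJ/mol.
#' @export
gibbs_of_reaction <- function(dg0, Q, T) {
  dg0 + .const$R_kJ * T * log(Q)
}

#' Standard Gibbs energy at a non-reference temperature
#'
#' Obtained through the equilibrium constant (never by interpolating dg0):
#' `Ka(298.15) -> van 't Hoff -> Ka(T) -> -RT ln Ka`.
#'
#' @param dg0_ref dg0 at `T_ref`, kJ/mol.
#' @param dRh0 standard reaction enthalpy, kJ/mol.
#' @param T target temperature, K.
#' @param T_ref reference temperature, K.
#' @return dg0 at `T`, kJ/mol.
#' @export
dg0_at_T <- function(dg0_ref, dRh0, T, T_ref = 298.15) {
  Ka_ref <- ka_from_dg0(dg0_ref, T_ref)
  dg0_from_ka(vant_hoff(Ka_ref, dRh0, T_ref, T), T)
}

#' Derive standard reaction data from a measured equilibrium record
#'
#' The full activity-based chain: `Km` from the record (density
#' assumption when molarity based), `K_gamma` from ePC-SAFT in the record's
#' medium (participants at trace unless equilibrium molalities are given),
#' `Ka = Km * K_gamma`, pH transform to the reference pH via binding
#' polynomials and the proton term, van 't Hoff to the reference
#' temperature, and `dRg0 = -R T ln Ka`. First-order uncertainty propagation
#' from the record's `K_uncertainty`.
#'
#' @param registry an [epcsaft_registry()].
#' @param reaction a [reaction_spec()].
#' @param record an [equilibrium_record()].
#' @param dRh0 standard reaction enthalpy used by the van 't Hoff step,
#'   kJ/mol.
#' @param k_gamma_value optional override of the predicted `K_gamma` (e.g.
#'   1 for an isomerization whose participants are assumed to share
#'   activity coefficients).
#' @param metabolite_molalities optional equilibrium molalities for the
#'   gamma prediction.
#' @param T_ref,pH_ref reference state (298.15 K, pH 7).
#' @return one-row tibble: `reaction_id`, `Km`, `K_gamma`, `Ka_conditions`,
#'   `Ka_ref`, `dRg0`, `dRg0_uncertainty`.
#' @export
derive_standard_dg0 <- function(registry, reaction, record, dRh0,
                                k_gamma_value = NULL,
                                metabolite_molalities = NULL,
                                T_ref = 298.15, pH_ref = 7) {
  rec <- km_from_kc(record)
  Km <- rec$K_value
  Kg <- if (is.null(k_gamma_value)) {
    as.numeric(k_gamma(registry, reaction, record$medium, metabolite_molalities))
  } else k_gamma_value
  Ka_cond <- Km * Kg
  ladders <- pka_ladders(registry)
  Ka_pH <- transform_K_pH(Ka_cond, reaction, ladders, record$pH, pH_ref)
  Ka_ref <- vant_hoff(Ka_pH, dRh0, record$T, T_ref)
  dg0 <- dg0_from_ka(Ka_ref, T_ref)
  unc <- if (is.na(rec$K_uncertainty)) NA_real_ else {
    .const$R_kJ * T_ref * rec$K_uncertainty / rec$K_value
  }
  tibble::tibble(reaction_id = reaction$reaction_id, Km = Km, K_gamma = Kg,
                 Ka_conditions = Ka_cond, Ka_ref = Ka_ref,
                 dRg0 = dg0, dRg0_uncertainty = unc)
}
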