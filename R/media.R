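# Aqueous media: declared salts and buffers speciated into the tabulated
# ion species, with electroneutrality closed by a declared counter-ion.

# salt -> ions dictionary (per mole of salt)
.salt_ions <- list(
  kcl  = c(k = 1, cl = 1),
  nacl = c(na = 1, cl = 1),
  mgcl2 = c(mg = 1, cl = 2),
  ammonium_sulfate = c(nh4 = 2, so4 = 1),
  kh2po4 = c(k = 1, h2po4 = 1)
)

#' Build an aqueous medium
#'
#' Splits salts into their tabulated ions, speciates buffers at the stated pH
#' (Tris/Tris-H+ with Cl- as the declared counter-ion; phosphate into
#' H2PO4-/HPO4(2-) with Na+ or K+), adds metabolites, and closes
#' electroneutrality with the declared counter-ion only. Dithiothreitol and
#' enzymes are never part of a medium.
#'
#' @param T temperature, K.
#' @param pH pH of the medium.
#' @param salts named vector of salt molalities (mol/kg water); names from
#'   `kcl`, `nacl`, `mgcl2`, `ammonium_sulfate`, `kh2po4`, or any single ion
#'   species id.
#' @param tris_hcl total Tris molality of a Tris/HCl buffer (speciated at
#'   `pH`, chloride closes the Tris-H+ charge).
#' @param sodium_phosphate,potassium_phosphate total phosphate molality of a
#'   sodium/potassium phosphate buffer (speciated at `pH`).
#' @param metabolites named vector of metabolite molalities.
#' @param counter_ion species id used to close residual charge from
#'   metabolites (default `"k"`); never an invented species.
#' @param P pressure, Pa.
#' @param registry an [epcsaft_registry()].
#' @param label optional medium label.
#' @return an `aqueous_medium`: list with `solutes` tibble (species_id,
#'   molality), `T`, `pH`, `P`, `label`.
#' @examples
#' reg <- epcsaft_registry()
#' m <- build_medium(311.15, 7, salts = c(kcl = 0.230),
#'                   sodium_phosphate = 0.010, registry = reg)
#' m$solutes
#' @export
build_medium <- function(T, pH, salts = NULL, tris_hcl = 0,
                         sodium_phosphate = 0, potassium_phosphate = 0,
                         metabolites = NULL, counter_ion = "k",
                         P = 1.01325e5, registry = epcsaft_registry(),
                         label = NULL) {
  mol <- numeric(0)
  put <- function(sp, m) {
    if (m == 0) return(invisible(NULL))
    mol[sp] <<- (if (sp %in% names(mol)) mol[[sp]] else 0) + m
    invisible(NULL)
  }
  for (s in names(salts)) {
    if (s %in% names(.salt_ions)) {
      ions <- .salt_ions[[s]]
      for (i in names(ions)) put(i, ions[[i]] * salts[[s]])
    } else if (s %in% registry$pure$species_id) {
      put(s, salts[[s]])
    } else stop("unknown salt or species: ", s, call. = FALSE)
  }
  ladders <- pka_ladders(registry)
  if (tris_hcl > 0) {
    fr <- species_fractions(ladders[["tris"]], pH)
    f_trisH <- fr$fraction[fr$state == 0]          # protonated state
    put("trish", tris_hcl * f_trisH)
    put("tris", tris_hcl * (1 - f_trisH))
    put("cl", tris_hcl * f_trisH)                  # chloride of the titration
  }
  phos <- function(total, cation) {
    if (total <= 0) return(invisible(NULL))
    lad <- ladders[["pi"]]
    fr <- species_fractions(lad, pH)
    # states: 0 = H3PO4, 1 = H2PO4-, 2 = HPO4(2-); H3PO4 negligible at pH 7
    f1 <- fr$fraction[fr$state == 1]; f2 <- fr$fraction[fr$state == 2]
    norm <- f1 + f2
    put("h2po4", total * f1 / norm)
    put("hpo4", total * f2 / norm)
    put(cation, total * (f1 + 2 * f2) / norm)
  }
  phos(sodium_phosphate, "na")
  phos(potassium_phosphate, "k")
  for (sp in names(metabolites)) put(sp, metabolites[[sp]])

  miss <- missing_species(registry, names(mol))
  if (length(miss) > 0) stop("species not in registry: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  z <- registry$pure$z[match(names(mol), registry$pure$species_id)]
  net <- sum(mol * z)
  if (abs(net) > 1e-12) {
    zc <- registry$pure$z[registry$pure$species_id == counter_ion]
    if (length(zc) == 0 || zc == 0) {
      stop("counter ion ", counter_ion, " unknown or uncharged", call. = FALSE)
    }
    need <- -net / zc
    if (need < 0) {
      stop("electroneutrality cannot be closed with ", counter_ion,
           ": residual charge ", format(net, digits = 4), " mol/kg has the same",
           " sign as the counter-ion", call. = FALSE)
    }
    put(counter_ion, need)
  }
  sol <- tibble::tibble(species_id = names(mol) %||% character(0),
                        molality = unname(mol))
  structure(list(solutes = sol, T = T, pH = pH, P = P,
                 label = label %||% "custom"),
            class = "aqueous_medium")
}

#' @export
print.aqueous_medium <- function(x, ...) {
  cat("<aqueous_medium> '", x$label, "' T = ", x$T, " K, pH = ", x$pH, ", ",
      nrow(x$solutes), " solutes\n", sep = "")
  print(x$solutes)
  invisible(x)
}

#' Load a bundled or user medium from YAML
#'
#' @param path YAML file, or the name of a bundled medium
#'   (`"hansen_pfk"`, `"veech_aldolase"`).
#' @param registry an [epcsaft_registry()].
#' @return an `aqueous_medium`.
#' @export
medium_from_yaml <- function(path, registry = epcsaft_registry()) {
  if (!file.exists(path)) {
    cand <- system.file(file.path("extdata/media", paste0(path, ".yaml")),
                        package = "actipath")
    if (cand == "") stop("medium file not found: ", path, call. = FALSE)
    path <- cand
  }
  y <- yaml::read_yaml(path)
  build_medium(T = y$T, pH = y$pH,
               salts = unlist(y$salts),
               tris_hcl = y$tris_hcl %||% 0,
               sodium_phosphate = y$sodium_phosphate %||% 0,
               potassium_phosphate = y$potassium_phosphate %||% 0,
               metabolites = unlist(y$metabolites),
               counter_ion = y$counter_ion %||% "k",
               P = y$pressure %||% 1.01325e5,
               registry = registry, label = y$label %||% basename(path))
}

# molalities -> mole fractions (water included)
molality_to_x <- function(molalities) {
  nw <- .const$mol_per_kg_water
  tot <- nw + sum(molalities)
  c(water = nw / tot, molalities / tot)
}

#' Mole-fraction composition of a medium
#'
#' @param medium an `aqueous_medium`.
#' @param extra named molalities to merge before conversion (e.g. trace
#'   metabolites).
#' @return named mole-fraction vector including water.
#' @export
medium_composition <- function(medium, extra = NULL) {
  mol <- stats::setNames(medium$solutes$molality, medium$solutes$species_id)
  for (sp in names(extra)) {
    mol[sp] <- (if (sp %in% names(mol)) mol[[sp]] else 0) + extra[[sp]]
  }
  molality_to_x(mol[mol > 0])
}

#' Serialize a medium to YAML-compatible list (round-trips exactly)
#'
#' @param medium an `aqueous_medium`.
#' @return list suitable for `yaml::write_yaml()`.
#' @export
medium_to_list <- function(medium) {
  list(label = medium$label, T = medium$T, pH = medium$pH, P = medium$P,
       solutes = stats::setNames(as.list(medium$solutes$molality),
                                 medium$solutes$species_id))
}
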