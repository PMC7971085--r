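#' Construct a TFA condition set
#'
#' A TFA scenario: temperature, pH, pressure, salt molalities, per-metabolite
#' molality ranges, and the evaluation mode.
#'
#' @param label scenario label (`"A"`, `"B"`, or custom).
#' @param T temperature, K.
#' @param pH pH of the cytosolic scenario.
#' @param salts named vector of salt molalities (see [build_medium()]).
#' @param metabolite_ranges named list; each element `list(min =, max =)` in
#'   mol/kg.
#' @param mode `"activity"` or `"concentration"`.
#' @param pressure Pa.
#' @param counter_ion charge-closure ion for metabolite-containing media.
#' @return a `condition_set`.
#' @export
condition_set <- function(label, T, pH, salts = NULL, metabolite_ranges,
                          mode = c("activity", "concentration"),
                          pressure = 1.01325e5, counter_ion = "k") {
  mode <- match.arg(mode)
  for (sp in names(metabolite_ranges)) {
    r <- metabolite_ranges[[sp]]
    if (!is.finite(r$min) || !is.finite(r$max) || r$min > r$max || r$min < 0) {
      stop("invalid range for ", sp, ": min ", r$min, ", max ", r$max,
           call. = FALSE)
    }
  }
  structure(list(label = label, T = T, pH = pH, salts = salts,
                 metabolite_ranges = metabolite_ranges, mode = mode,
                 pressure = pressure, counter_ion = counter_ion),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set> '", x$label, "' T = ", x$T, " K, pH = ", x$pH,
      ", mode = ", x$mode, ", ", length(x$metabolite_ranges),
      " metabolite ranges\n", sep = "")
  invisible(x)
}

#' Load a condition set from YAML
#'
#' @param path YAML file, or the name of a bundled scenario (`"A"`, `"B"`).
#' @param mode optional override of the file's mode.
#' @param T optional override of the file's temperature.
#' @return a [condition_set()].
#' @export
load_conditions <- function(path, mode = NULL, T = NULL) {
  if (!file.exists(path)) {
    cand <- system.file(file.path("extdata/conditions", paste0(path, ".yaml")),
                        package = "actipath")
    if (cand == "") stop("condition file not found: ", path, call. = FALSE)
    path <- cand
  }
  y <- yaml::read_yaml(path)
  condition_set(label = y$label, T = T %||% y$T, pH = y$pH,
                salts = unlist(y$salts),
                metabolite_ranges = y$metabolite_ranges,
                mode = mode %||% y$mode,
                pressure = y$pressure %||% 1.01325e5,
                counter_ion = y$counter_ion %||% "k")
}

#' Synthesize random condition sets
#'
#' Seeded generator of plausible cytosolic scenarios for testing: metabolite
#' ranges, KCl and MgCl2 molalities drawn uniformly within the template
#' bounds. Defaults span the scenarios of interest (metabolites 0.01-20
#' mmol/kg, KCl 0-300 mmol/kg, MgCl2 0-10 mmol/kg).
#'
#' @param seed integer seed; identical seeds give identical sets.
#' @param n_sets number of condition sets.
#' @param metabolites character vector of metabolite ids (default: the
#'   glycolytic set).
#' @param template list of bounds: `metabolite = c(lo, hi)`,
#'   `kcl = c(lo, hi)`, `mgcl2 = c(lo, hi)` in mol/kg.
#' @param mode evaluation mode for the generated sets.
#' @return list of [condition_set()]s.
#' @export
synthesize_conditions <- function(seed, n_sets,
                                  metabolites = NULL,
                                  template = list(metabolite = c(1e-5, 2e-2),
                                                  kcl = c(0, 0.3),
                                                  mgcl2 = c(0, 0.01)),
                                  mode = "activity") {
  if (is.null(metabolites)) {
    metabolites <- unique(unlist(lapply(load_reactions(),
                                        function(r) names(r$stoichiometry))))
    metabolites <- setdiff(metabolites, "water")
  }
  if (n_sets == 0) return(list())
  set.seed(seed)
  out <- lapply(seq_len(n_sets), function(i) {
    rg <- lapply(metabolites, function(sp) {
      b <- sort(stats::runif(2, template$metabolite[1], template$metabolite[2]))
      list(min = b[1], max = b[2])
    })
    names(rg) <- metabolites
    condition_set(label = paste0("synthetic_", i),
                  T = sample(c(298.15, 310.15), 1), pH = 7,
                  salts = c(kcl = stats::runif(1, template$kcl[1], template$kcl[2]),
                            mgcl2 = stats::runif(1, template$mgcl2[1], template$mgcl2[2])),
                  metabolite_ranges = rg, mode = mode)
  })
  out
}
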