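#' Define a biochemical reaction
#'
#' @param reaction_id identifier.
#' @param stoichiometry named numeric vector of signed integer coefficients
#'   (substrates negative, products positive), excluding H+ and water.
#' @param nu_h chemical proton production (+1 when the reaction releases one
#'   H+); used by pH transforms and, for `h_explicit` reactions, by the
#'   reaction quotient via `a_H+ = 10^-pH`.
#' @param h_explicit logical; `TRUE` when the standard data are on the
#'   chemical scale so H+ is an explicit participant of Q.
#' @param display_name human-readable name.
#' @param number position in the pathway (1-10 for glycolysis).
#' @return a `reaction_spec` object.
#' @export
reaction_spec <- function(reaction_id, stoichiometry, nu_h = 0,
                          h_explicit = FALSE, display_name = reaction_id,
                          number = NA_integer_) {
  stoichiometry <- unlist(stoichiometry)
  if (any(stoichiometry != round(stoichiometry))) {
    stop("stoichiometric coefficients must be integers", call. = FALSE)
  }
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("reaction needs at least one substrate and one product", call. = FALSE)
  }
  structure(list(reaction_id = reaction_id, stoichiometry = stoichiometry,
                 nu_h = nu_h, h_explicit = isTRUE(h_explicit),
                 display_name = display_name, number = number),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  nu <- x$stoichiometry
  lhs <- paste(paste0(ifelse(abs(nu[nu < 0]) > 1, abs(nu[nu < 0]), ""),
                      names(nu[nu < 0])), collapse = " + ")
  rhs <- paste(paste0(ifelse(nu[nu > 0] > 1, nu[nu > 0], ""),
                      names(nu[nu > 0])), collapse = " + ")
  cat("<reaction_spec> ", x$reaction_id, ": ", lhs, " -> ", rhs,
      if (x$nu_h != 0) paste0("  (nu_H = ", x$nu_h,
                              if (x$h_explicit) ", explicit" else ", absorbed", ")"),
      "\n", sep = "")
  invisible(x)
}

#' Load a reaction pathway from YAML
#'
#' With no argument the bundled ten-reaction glycolysis scheme is loaded.
#'
#' @param path YAML file with a top-level `reactions` list.
#' @return named list of [reaction_spec()] objects, ordered by `number`.
#' @examples
#' gly <- load_reactions()
#' gly$pfk
#' @export
load_reactions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata/reactions/glycolysis.yaml", package = "actipath")
  }
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$reactions, function(r) {
    reaction_spec(r$id, unlist(r$stoichiometry), nu_h = r$nu_h %||% 0,
                  h_explicit = r$h_explicit %||% FALSE,
                  display_name = r$name %||% r$id,
                  number = r$number %||% NA_integer_)
  })
  names(specs) <- vapply(specs, function(s) s$reaction_id, character(1))
  ord <- order(vapply(specs, function(s) s$number %||% NA_integer_, numeric(1)))
  specs[ord]
}

#' Participant species of a reaction
#'
#' @param reaction a [reaction_spec()].
#' @return character vector of participant ids (excluding H+).
#' @export
reaction_participants <- function(reaction) names(reaction$stoichiometry)

`%||%` <- function(a, b) if (is.null(a)) b else a
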