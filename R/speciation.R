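#' Acid-base ladder of a metabolite
#'
#' @param metabolite_id identifier.
#' @param pka_values ascending numeric vector of pKa values at the reference
#'   temperature (may be empty: single species).
#' @param charge_most_protonated integer charge of the fully protonated state.
#' @return an `acid_base_ladder` object.
#' @export
acid_base_ladder <- function(metabolite_id, pka_values = numeric(0),
                             charge_most_protonated = 0L) {
  pka_values <- as.numeric(pka_values)
  if (length(pka_values) > 1 && any(diff(pka_values) <= 0)) {
    stop("pKa values must be strictly increasing", call. = FALSE)
  }
  structure(list(metabolite_id = metabolite_id, pka_values = pka_values,
                 charge_most_protonated = as.integer(charge_most_protonated)),
            class = "acid_base_ladder")
}

#' Load the bundled pKa ladders
#'
#' @param registry an [epcsaft_registry()] (its `pka` table is used).
#' @return named list of [acid_base_ladder()] objects.
#' @export
pka_ladders <- function(registry = epcsaft_registry()) {
  tab <- registry$pka
  out <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- tab$pka_values[i]
    pk <- if (is.na(vals) || vals == "") numeric(0)
          else as.numeric(strsplit(vals, ";")[[1]])
    acid_base_ladder(tab$metabolite_id[i], pk, tab$charge_most_protonated[i])
  })
  names(out) <- tab$metabolite_id
  out
}

#' Species distribution over protonation states
#'
#' Binding-polynomial (Henderson-Hasselbalch ladder) fractions. State 0 is
#' the most protonated; state k has lost k protons.
#'
#' @param ladder an [acid_base_ladder()].
#' @param pH pH in `[0, 14]`.
#' @return tibble with `state` (protons lost), `charge`, `fraction`.
#' @examples
#' f <- species_fractions(acid_base_ladder("x", 7), 7)
#' f$fraction  # 0.5, 0.5 at the midpoint
#' @export
species_fractions <- function(ladder, pH) {
  stopifnot(inherits(ladder, "acid_base_ladder"))
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  pk <- ladder$pka_values
  nst <- length(pk) + 1
  # log10 relative abundance of state k vs state 0: sum_{j<=k}(pH - pKa_j)
  lw <- c(0, cumsum(pH - pk))
  lw <- lw - max(lw)
  w <- 10^lw
  fr <- w / sum(w)
  tibble::tibble(state = 0:(nst - 1),
                 charge = ladder$charge_most_protonated - 0:(nst - 1),
                 fraction = fr)
}

#' Binding polynomial
#'
#' Sum of relative abundances of all protonation states with respect to the
#' fully deprotonated reference state; always >= 1.
#'
#' @param ladder an [acid_base_ladder()].
#' @param pH pH in `[0, 14]`.
#' @return dimensionless P >= 1.
#' @export
binding_polynomial <- function(ladder, pH) {
  pk <- ladder$pka_values
  if (length(pk) == 0) return(1)
  # abundance of state k relative to the fully deprotonated state
  lw <- rev(cumsum(rev(pk - pH)))       # log10 of [state k]/[deprotonated]
  sum(10^lw) + 1
}

#' Transform an apparent equilibrium constant between pH values
#'
#' `K(pH2) = K(pH1) * prod_i [P_i(pH2)/P_i(pH1)]^nu_i * 10^(nu_H*(pH2-pH1))`,
#' where `P_i` are binding polynomials of the reaction participants and
#' `nu_H` is the chemical proton production of the reaction (+1 when one H+
#' is produced). A pure, exactly invertible function.
#'
#' @param K_at_pH1 apparent equilibrium constant at `pH1`.
#' @param reaction a [reaction_spec()] (uses `stoichiometry` and `nu_h`).
#' @param ladders named list of [acid_base_ladder()]s; every participant
#'   present in the list is transformed (participants without a ladder are
#'   treated as pH-insensitive).
#' @param pH1,pH2 source and target pH.
#' @param require_ladders character vector of participant ids that must have
#'   a ladder (error if missing); default none.
#' @return K at `pH2`.
#' @export
transform_K_pH <- function(K_at_pH1, reaction, ladders, pH1, pH2,
                           require_ladders = NULL) {
  stopifnot(inherits(reaction, "reaction_spec"))
  nu <- reaction$stoichiometry
  if (!is.null(require_ladders)) {
    miss <- setdiff(intersect(require_ladders, names(nu)), names(ladders))
    if (length(miss) > 0) {
      stop("missing pKa ladder for participant(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  logK <- log10(K_at_pH1)
  for (sp in names(nu)) {
    lad <- ladders[[sp]]
    if (is.null(lad) || length(lad$pka_values) == 0) next
    logK <- logK + nu[[sp]] *
      (log10(binding_polynomial(lad, pH2)) - log10(binding_polynomial(lad, pH1)))
  }
  logK <- logK + reaction$nu_h * (pH2 - pH1)
  10^logK
}
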