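# The two-step thermodynamic feasibility analysis of a pathway.

#' Best-case molality assignment for one reaction
#'
#' Substrates at their maximum, products at their minimum molality (the
#' optimal best-case situation: if dRg is positive here, the reaction is
#' unfeasible at every concentration ratio inside the declared ranges).
#'
#' @param reaction a [reaction_spec()].
#' @param conditions a [condition_set()].
#' @return named molalities of the participants; attribute
#'   `"gamma_medium_extra"` holds the non-participant metabolites at their
#'   maxima when the scenario is a full-medium one (label `"B"`).
#' @export
best_case_quotient <- function(reaction, conditions) {
  nu <- reaction$stoichiometry
  parts <- setdiff(names(nu), "water")
  rng <- conditions$metabolite_ranges
  miss <- setdiff(parts, names(rng))
  if (length(miss) > 0) {
    stop("no molality range declared for participant(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mm <- vapply(parts, function(sp) {
    if (nu[[sp]] < 0) rng[[sp]]$max else rng[[sp]]$min
  }, numeric(1))
  extra <- NULL
  if (identical(conditions$label, "B")) {
    others <- setdiff(names(rng), parts)
    extra <- vapply(others, function(sp) rng[[sp]]$max, numeric(1))
    if ("pi" %in% names(extra)) {
      # non-participant phosphate enters the gamma medium speciated
      tot <- extra[["pi"]]
      extra <- extra[names(extra) != "pi"]
      lad <- pka_ladders(epcsaft_registry())[["pi"]]
      fr <- species_fractions(lad, conditions$pH)
      f1 <- fr$fraction[fr$state == 1]; f2 <- fr$fraction[fr$state == 2]
      extra <- c(extra, h2po4 = tot * f1 / (f1 + f2), hpo4 = tot * f2 / (f1 + f2))
    }
  }
  attr(mm, "gamma_medium_extra") <- extra
  mm
}

#' Run a thermodynamic feasibility analysis
#'
#' For every reaction of the pathway: transform its standard Gibbs energy to
#' the scenario temperature through the equilibrium constant (van 't Hoff),
#' evaluate the best-case reaction quotient from the declared ranges, and in
#' activity mode predict `Q_gamma` with ePC-SAFT in the scenario medium
#' (participants only for conditions A; all glycolytic metabolites plus the
#' declared salts for conditions B). A reaction is feasible when `dRg < 0`
#' strictly; `dRg = 0` is "at equilibrium", not feasible.
#'
#' @param pathway named list of [reaction_spec()]s (e.g. [load_reactions()]).
#' @param standard data frame of standard data (columns `reaction_id`,
#'   `dRg0`, `dRh0`), e.g. `epcsaft_registry()$standard`.
#' @param conditions a [condition_set()].
#' @param registry an [epcsaft_registry()].
#' @param mode optional override of `conditions$mode`.
#' @return a `tfa_report`: tibble with one row per reaction (`reaction_id`,
#'   `number`, `dRg0_T`, `Qm`, `Qgamma`, `lnQ_term`, `dRg`, `feasible`,
#'   `status`) plus metadata attributes; EOS failures mark the affected
#'   reaction `indeterminate` and the run continues.
#' @examples
#' \donttest{
#' reg <- epcsaft_registry()
#' rep <- run_tfa(load_reactions(), reg$standard, load_conditions("B"), reg)
#' glance(rep)
#' }
#' @export
run_tfa <- function(pathway, standard, conditions, registry,
                    mode = NULL) {
  mode <- mode %||% conditions$mode
  medium <- build_medium(conditions$T, conditions$pH, salts = conditions$salts,
                         counter_ion = conditions$counter_ion,
                         P = conditions$pressure, registry = registry,
                         label = conditions$label)
  rows <- lapply(pathway, function(rx) {
    sd <- standard[standard$reaction_id == rx$reaction_id, ]
    if (nrow(sd) == 0) stop("no standard data for ", rx$reaction_id, call. = FALSE)
    dg0T <- dg0_at_T(sd$dRg0[1], sd$dRh0[1], conditions$T)
    mm <- best_case_quotient(rx, conditions)
    res <- tryCatch({
      Q <- reaction_quotient(registry, rx, mm, medium, mode = mode,
                             gamma_medium_extra = attr(mm, "gamma_medium_extra"))
      lnQ_term <- .const$R_kJ * conditions$T * log(as.numeric(Q))
      dRg <- gibbs_of_reaction(dg0T, as.numeric(Q), conditions$T)
      tibble::tibble(reaction_id = rx$reaction_id, number = rx$number,
                     dRg0_T = dg0T, Qm = attr(Q, "Qm"),
                     Qgamma = attr(Q, "Qgamma"), lnQ_term = lnQ_term,
                     dRg = dRg, feasible = dRg < 0, status = "ok")
    }, error = function(e) {
      tibble::tibble(reaction_id = rx$reaction_id, number = rx$number,
                     dRg0_T = dg0T, Qm = NA_real_, Qgamma = NA_real_,
                     lnQ_term = NA_real_, dRg = NA_real_, feasible = NA,
                     status = paste0("indeterminate: ", conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "conditions") <- conditions$label
  attr(out, "T") <- conditions$T
  attr(out, "pH") <- conditions$pH
  class(out) <- c("tfa_report", class(out))
  out
}

#' Compare activity- and concentration-based feasibility
#'
#' Runs [run_tfa()] twice on identical conditions and reports per-reaction
#' `dRg` (activity) and `dRg_c` (concentration) with sign-disagreement
#' flags.
#'
#' @inheritParams run_tfa
#' @return a `tfa_comparison` tibble.
#' @export
compare_modes <- function(pathway, standard, conditions, registry) {
  act <- run_tfa(pathway, standard, conditions, registry, mode = "activity")
  con <- run_tfa(pathway, standard, conditions, registry, mode = "concentration")
  out <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(act), "reaction_id", "number",
                  "dRg0_T", "Qgamma", dRg = "dRg"),
    dplyr::select(tibble::as_tibble(con), "reaction_id", dRg_c = "dRg"),
    by = "reaction_id")
  out$sign_disagrees <- sign(out$dRg) != sign(out$dRg_c)
  attr(out, "conditions") <- conditions$label
  attr(out, "T") <- conditions$T
  class(out) <- c("tfa_comparison", class(out))
  out
}

#' @export
print.tfa_report <- function(x, ...) {
  cat("TFA report - conditions ", attr(x, "conditions"), ", ",
      attr(x, "mode"), " mode, T = ", attr(x, "T"), " K, pH = ",
      attr(x, "pH"), "\n", sep = "")
  NextMethod()
  ok <- x$feasible[!is.na(x$feasible)]
  cat(if (length(ok) == nrow(x) && all(ok)) "pathway verdict: all reactions feasible\n"
      else "pathway verdict: not all reactions feasible\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TFA report
#'
#' @param x a `tfa_report`.
#' @param ... unused.
#' @return tibble of per-reaction results (energies in kJ/mol).
#' @method tidy tfa_report
#' @export
tidy.tfa_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "mode") <- NULL; attr(out, "conditions") <- NULL
  out
}

#' One-row summary of a TFA report
#'
#' @param x a `tfa_report`.
#' @param ... unused.
#' @return tibble: conditions, mode, T, n reactions, n feasible,
#'   `all_feasible` pathway verdict.
#' @method glance tfa_report
#' @export
glance.tfa_report <- function(x, ...) {
  tibble::tibble(conditions = attr(x, "conditions"), mode = attr(x, "mode"),
                 T = attr(x, "T"), n_reactions = nrow(x),
                 n_feasible = sum(x$feasible, na.rm = TRUE),
                 n_indeterminate = sum(is.na(x$feasible)),
                 all_feasible = all(x$feasible %in% TRUE))
}

#' Serialize a TFA report
#'
#' @param report a `tfa_report` or `tfa_comparison`.
#' @param path output file; format from extension (`.json` or `.csv`).
#' @param seed seed recorded in the metadata (JSON only).
#' @return `path`, invisibly.
#' @export
write_tfa_report <- function(report, path, seed = NULL) {
  if (grepl("\\.json$", path)) {
    payload <- list(
      metadata = list(mode = attr(report, "mode"),
                      conditions = attr(report, "conditions"),
                      T = attr(report, "T"), pH = attr(report, "pH"),
                      seed = seed),
      reactions = tibble::as_tibble(report))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    tab <- tibble::as_tibble(report)
    num <- vapply(tab, is.numeric, logical(1)) & names(tab) %in%
      c("dRg0_T", "lnQ_term", "dRg", "dRg_c")
    tab[num] <- lapply(tab[num], round, 2)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
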