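#' Load the ePC-SAFT parameter registry
#'
#' Reads pure-component parameters, binary interaction parameters, standard
#' reaction data and pKa ladders from plain-text tables and validates them.
#' With no arguments the tables bundled with the package are used.
#'
#' @param pure path to a pure-component CSV, or a data frame.
#' @param binary path to a binary-interaction CSV, or a data frame.
#' @param standard path to a standard-reaction-data CSV, or a data frame.
#' @param pka path to a pKa CSV, or a data frame.
#' @return an object of class `epcsaft_registry`: a list with tibbles
#'   `pure`, `binary`, `standard`, `pka`.
#' @examples
#' reg <- epcsaft_registry()
#' dplyr::filter(reg$pure, species_id == "glucose")
#' @export
epcsaft_registry <- function(pure = NULL, binary = NULL, standard = NULL, pka = NULL) {
  path_or_df <- function(x, default) {
    if (is.null(x)) x <- system.file("extdata/parameters", default, package = "actipath")
    if (is.character(x)) {
      if (!file.exists(x)) stop("parameter file not found: ", x, call. = FALSE)
      x <- utils::read.csv(x, stringsAsFactors = FALSE)
    }
    tibble::as_tibble(x)
  }
  pure <- path_or_df(pure, "pure.csv")
  binary <- path_or_df(binary, "binary.csv")
  standard <- path_or_df(standard, "standard_data.csv")
  pka <- path_or_df(pka, "pka.csv")

  # -- validation: hard failures name the offending row -----------------------
  if (anyDuplicated(pure$species_id)) {
    stop("duplicate species_id in pure table: ",
         paste(unique(pure$species_id[duplicated(pure$species_id)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("m_seg", "u_kB", "n_donor", "n_acceptor", "eps_AB_kB", "kappa_AB", "z")
  for (cc in num_cols) {
    bad <- !is.finite(as.numeric(pure[[cc]]))
    if (any(bad)) {
      stop("malformed numeric cell in pure table, column ", cc, ", row(s): ",
           paste(pure$species_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  # sigma may be NA only for species on the water sigma(T) correlation
  bad_sig <- is.na(pure$sigma) & !pure$sigma_T
  if (any(bad_sig)) {
    stop("malformed numeric cell in pure table, column sigma, row(s): ",
         paste(pure$species_id[bad_sig], collapse = ", "), call. = FALSE)
  }
  if (any(pure$m_seg <= 0)) {
    stop("non-positive m_seg for: ",
         paste(pure$species_id[pure$m_seg <= 0], collapse = ", "), call. = FALSE)
  }
  sig_ok <- pure$sigma_T | (is.finite(pure$sigma) & pure$sigma > 0)
  if (any(!sig_ok)) {
    stop("non-positive or missing sigma for: ",
         paste(pure$species_id[!sig_ok], collapse = ", "), call. = FALSE)
  }
  if (any(pure$kappa_AB < 0 | pure$kappa_AB > 1)) {
    stop("kappa_AB outside [0, 1] for: ",
         paste(pure$species_id[pure$kappa_AB < 0 | pure$kappa_AB > 1], collapse = ", "),
         call. = FALSE)
  }
  # species without sites: kappa treated as absent
  no_sites <- (pure$n_donor + pure$n_acceptor) == 0
  pure$kappa_AB[no_sites] <- 0
  pure$eps_AB_kB[no_sites] <- 0

  unknown <- setdiff(unique(c(binary$species_i, binary$species_j)), pure$species_id)
  if (length(unknown) > 0) {
    stop("binary table references unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  structure(list(pure = pure, binary = binary, standard = standard, pka = pka),
            class = "epcsaft_registry")
}

#' @export
print.epcsaft_registry <- function(x, ...) {
  cat("<epcsaft_registry> ", nrow(x$pure), " species, ", nrow(x$binary),
      " binary pairs, ", nrow(x$standard), " reactions with standard data\n", sep = "")
  invisible(x)
}

#' Binary interaction parameter at temperature T
#'
#' `kij(T) = kij_T0 + kij_slope * T`; symmetric in pair order. Pairs absent
#' from the table return 0 (the documented default) with a one-time notice.
#'
#' @param registry an [epcsaft_registry()].
#' @param species_i,species_j species identifiers (order irrelevant).
#' @param T temperature in K. Values outside 273-373 K warn but still return.
#' @return dimensionless kij.
#' @examples
#' reg <- epcsaft_registry()
#' kij_at_T(reg, "glucose", "water", 298.15)  # -0.04764
#' @export
kij_at_T <- function(registry, species_i, species_j, T) {
  stopifnot(inherits(registry, "epcsaft_registry"))
  if (T < 273 || T > 373) {
    warning("T = ", T, " K outside the 273-373 K validity window of kij(T)")
  }
  b <- registry$binary
  hit <- (b$species_i == species_i & b$species_j == species_j) |
         (b$species_i == species_j & b$species_j == species_i)
  if (!any(hit)) {
    message("no binary parameters for pair (", species_i, ", ", species_j,
            "); using kij = 0")
    return(0)
  }
  row <- b[which(hit)[1], ]
  row$kij_T0 + row$kij_slope * T
}

# Full kij(T) matrix for a species vector (internal; no notice for absent pairs).
kij_matrix <- function(registry, species, T) {
  n <- length(species)
  K <- matrix(0, n, n, dimnames = list(species, species))
  b <- registry$binary
  keep <- b$species_i %in% species & b$species_j %in% species
  b <- b[keep, , drop = FALSE]
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      v <- b$kij_T0[r] + b$kij_slope[r] * T
      K[b$species_i[r], b$species_j[r]] <- v
      K[b$species_j[r], b$species_i[r]] <- v
    }
  }
  K
}

#' List species missing from the registry
#'
#' @param registry an [epcsaft_registry()].
#' @param species character vector of species identifiers to check.
#' @return character vector of identifiers without a pure-component row
#'   (empty when all are present).
#' @export
missing_species <- function(registry, species) {
  setdiff(unique(species), registry$pure$species_id)
}

#' Write registry tables back to CSV
#'
#' Round-trips bit-identically with [epcsaft_registry()].
#'
#' @param registry an [epcsaft_registry()].
#' @param dir directory in which to write `pure.csv` and `binary.csv`.
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(registry$pure, file.path(dir, "pure.csv"), row.names = FALSE, na = "")
  utils::write.csv(registry$binary, file.path(dir, "binary.csv"), row.names = FALSE)
  invisible(dir)
}

# Extract the per-calculation parameter set (vectors + pair matrices) for a
# species list at temperature T. Internal workhorse for the EOS.
saft_pars <- function(registry, species, T) {
  miss <- missing_species(registry, species)
  if (length(miss) > 0) {
    stop("species not in registry: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- registry$pure[match(species, registry$pure$species_id), ]
  sig <- ifelse(p$sigma_T, water_sigma(T), p$sigma)
  m <- p$m_seg
  u <- p$u_kB
  # temperature-dependent effective hard-sphere diameter (applied uniformly)
  d <- sig * (1 - 0.12 * exp(-3 * u / T))
  K <- kij_matrix(registry, species, T)
  sij <- outer(sig, sig, function(a, b) (a + b) / 2)
  uij <- sqrt(outer(u, u)) * (1 - K)
  nA <- p$n_donor
  nB <- p$n_acceptor
  has_assoc <- (nA + nB) > 0 & p$kappa_AB > 0
  eps <- p$eps_AB_kB
  kap <- p$kappa_AB
  # cross-association: arithmetic-mean energy, geometric-mean volume with the
  # sigma correction; zero between an associating and a non-associating species
  eps_ab <- outer(eps, eps, function(a, b) (a + b) / 2)
  kap_ab <- sqrt(outer(kap, kap)) *
    (sqrt(outer(sig, sig)) / ((outer(sig, sig, `+`)) / 2))^3
  kap_ab[!has_assoc, ] <- 0
  kap_ab[, !has_assoc] <- 0
  list(species = species, T = T, m = m, sig = sig, u = u, d = d, z = p$z,
       kij = K, sij = sij, uij = uij,
       nA = nA, nB = nB, eps_ab = eps_ab, kap_ab = kap_ab,
       has_assoc = has_assoc)
}
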