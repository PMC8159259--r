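#' Molecular fitness for n-type organic semiconductors
#'
#' Two fitness functions drive the search, both in eV and both minimised.
#' `"F_A"` is the electron reorganisation energy \eqn{\lambda_-} alone.
#' `"F_B"` adds a Schottky-barrier penalty
#' \eqn{\Phi = W - A_s} whenever the solid-state electron affinity
#' \eqn{A_s} lies below the electrode work function \eqn{W}:
#' \deqn{F_B = \lambda_- + \max(W - A_s, 0)}
#' so molecules that already match the electrode (\eqn{A_s \ge W}) are
#' judged on \eqn{\lambda_-} alone and the penalty is continuous at
#' \eqn{A_s = W}.
#'
#' @param kind `"F_A"` or `"F_B"`.
#' @param work_function Electrode work function \eqn{W} in eV (default 4.1,
#'   matching Ag/Cu/Au-type electrodes).
#' @param calibration An [ea_calibration()] mapping gas-phase to
#'   solid-state electron affinities.
#' @return `fitness_spec()` returns an object of class `azc_fitness_spec`.
#' @examples
#' spec <- fitness_spec("F_B")
#' fitness_value(data.frame(lambda_minus_eV = 0.2, ea_gas_eV = 1.7), spec)
#' @export
fitness_spec <- function(kind = c("F_A", "F_B"), work_function = 4.1,
                         calibration = ea_calibration()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(work_function), length(work_function) == 1L, work_function > 0)
  structure(
    list(kind = kind, work_function = work_function, calibration = calibration),
    class = "azc_fitness_spec"
  )
}

#' Linear gas-to-solid electron affinity calibration
#'
#' Solid-state electron affinities are approximated from gas-phase
#' adiabatic values through a linear map \eqn{A_s = a \cdot A_{gas} + b}.
#' The default slope 1 and intercept 1.4 eV are a placeholder of the right
#' magnitude for thin-film acene semiconductors (a polarisation shift of
#' roughly 1-2 eV); fit your own against experimental inverse photoemission
#' data when available.
#'
#' @param slope Dimensionless slope (> 0).
#' @param intercept Intercept in eV.
#' @export
ea_calibration <- function(slope = 1.0, intercept = 1.4) {
  stopifnot(is.numeric(slope), slope > 0, is.numeric(intercept))
  structure(list(slope = slope, intercept = intercept), class = "azc_ea_calibration")
}

#' @rdname ea_calibration
#' @param ea_gas Gas-phase adiabatic electron affinity (eV), vectorised.
#' @param calibration An `azc_ea_calibration`.
#' @export
solid_state_ea <- function(ea_gas, calibration = ea_calibration()) {
  stopifnot(inherits(calibration, "azc_ea_calibration"))
  calibration$slope * ea_gas + calibration$intercept
}

#' Four-point electron reorganisation energy
#'
#' \deqn{\lambda_- = [E_-(R_0) - E_0(R_0)] + [E_0(R_-) - E_-(R_-)]}
#' where \eqn{E_-} and \eqn{E_0} are anion and neutral single-molecule
#' energies evaluated at the optimised anion (\eqn{R_-}) and neutral
#' (\eqn{R_0}) geometries.  All energies in eV.  A negative result (only
#' possible with inconsistent input surfaces) is returned with a warning.
#'
#' @param e_anion_r0,e_neutral_r0 Anion and neutral energies at the neutral
#'   geometry.
#' @param e_neutral_rm,e_anion_rm Neutral and anion energies at the anion
#'   geometry.
#' @return \eqn{\lambda_-} in eV (vectorised).
#' @examples
#' reorganisation_energy(-100.00, -100.10, -100.05, -100.02)  # 0.07 eV
#' @export
reorganisation_energy <- function(e_anion_r0, e_neutral_r0, e_neutral_rm, e_anion_rm) {
  stopifnot(
    all(is.finite(e_anion_r0)), all(is.finite(e_neutral_r0)),
    all(is.finite(e_neutral_rm)), all(is.finite(e_anion_rm))
  )
  lam <- (e_anion_r0 - e_neutral_r0) + (e_neutral_rm - e_anion_rm)
  if (any(lam < 0)) {
    warn("negative reorganisation energy: anion/neutral surfaces are inconsistent")
  }
  lam
}

#' Evaluate a fitness function on molecular properties
#'
#' @param properties A data frame (or list) with `lambda_minus_eV` and, for
#'   `"F_B"`, `ea_gas_eV`.  If `lambda_minus_eV` is absent it is assembled
#'   from the four energies `e_anion_r0_eV`, `e_neutral_r0_eV`,
#'   `e_neutral_rm_eV`, `e_anion_rm_eV`; a directly supplied value wins.
#' @param spec A [fitness_spec()].
#' @return Numeric fitness in eV (vectorised), lower is fitter.
#' @export
fitness_value <- function(properties, spec = fitness_spec()) {
  stopifnot(inherits(spec, "azc_fitness_spec"))
  lam <- properties$lambda_minus_eV
  if (is.null(lam)) {
    need <- c("e_anion_r0_eV", "e_neutral_r0_eV", "e_neutral_rm_eV", "e_anion_rm_eV")
    if (!all(need %in% names(properties))) {
      abort("properties must supply lambda_minus_eV or the four point energies")
    }
    lam <- reorganisation_energy(
      properties$e_anion_r0_eV, properties$e_neutral_r0_eV,
      properties$e_neutral_rm_eV, properties$e_anion_rm_eV
    )
  }
  if (spec$kind == "F_A") return(lam)
  if (is.null(properties$ea_gas_eV)) {
    abort("F_B requires ea_gas_eV in the property set")
  }
  a_s <- solid_state_ea(properties$ea_gas_eV, spec$calibration)
  lam + pmax(spec$work_function - a_s, 0)
}

# ---- property oracles -------------------------------------------------------

#' Deterministic surrogate property oracle
#'
#' A stand-in for quantum-chemical single-molecule calculations with a
#' documented, graph-derived structure: the reorganisation energy is
#' smallest for the linear unsubstituted skeleton and grows with both the
#' degree of non-linearity and the nitrogen count, while the gas-phase
#' electron affinity grows with nitrogen count.  Under this surrogate the
#' global fitness minimum of `"F_A"` over the five-ring aza-acene space is
#' pentacene by construction.  A small deterministic per-molecule term
#' (hashed from the canonical key, amplitude 0.002 eV) breaks ties without
#' disturbing those orderings.
#'
#' The functional form (eV) is
#' \deqn{\lambda_- = 0.10 + 0.03 d + 0.005 n_N + 0.002 h}
#' \deqn{A_{gas} = 1.30 + 0.12 n_N - 0.02 d + 0.002 h}
#' with \eqn{d} the non-linearity degree, \eqn{n_N} the nitrogen count and
#' \eqn{h \in [0, 1)} the key hash.  Consistent four-point energies are also
#' returned (neutral reference at 0 eV).
#'
#' @return `surrogate_oracle()` returns a function mapping an `azc_mol` to
#'   a one-row property tibble; `surrogate_properties()` is the vectorised
#'   data-frame interface used on enumeration tables.
#' @examples
#' ora <- surrogate_oracle()
#' ora(parse_molecule("c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1"))  # pentacene
#' @export
surrogate_oracle <- function() {
  function(mol) {
    stopifnot(is_molecule(mol))
    surrogate_properties(tibble(
      canonical_key = canonical_key(mol),
      n_nitrogens = n_nitrogens(mol),
      nonlinearity_degree = nonlinearity_degree(mol)
    ))
  }
}

#' @rdname surrogate_oracle
#' @param molecules A data frame with columns `canonical_key`,
#'   `n_nitrogens`, `nonlinearity_degree` (as returned by
#'   [describe_molecules()] or [enumerate_space()]).
#' @export
surrogate_properties <- function(molecules) {
  h <- vapply(molecules$canonical_key, key_fraction, numeric(1), USE.NAMES = FALSE)
  d <- molecules$nonlinearity_degree
  nn <- molecules$n_nitrogens
  lam <- 0.10 + 0.03 * d + 0.005 * nn + 0.002 * h
  ea <- 1.30 + 0.12 * nn - 0.02 * d + 0.002 * h
  tibble(
    canonical_key = molecules$canonical_key,
    lambda_minus_eV = lam,
    ea_gas_eV = ea,
    e_neutral_r0_eV = 0,
    e_anion_r0_eV = -ea + lam / 2,
    e_neutral_rm_eV = lam / 2,
    e_anion_rm_eV = -ea
  )
}

#' Lookup-table property oracle
#'
#' Wraps a canonical-key to property table (for example real quantum
#' chemistry results) as an oracle for the evolutionary engine.  Missing
#' molecules signal oracle failure, which the engine records as
#' worst-possible fitness.
#'
#' @param table A data frame with a `canonical_key` column plus
#'   `lambda_minus_eV` (or the four point energies) and optionally
#'   `ea_gas_eV`, or a path to a CSV/JSON file with those columns.
#' @return A function mapping an `azc_mol` to a one-row property tibble, or
#'   `NULL` when the molecule is not in the table.
#' @export
table_oracle <- function(table) {
  if (is.character(table)) {
    table <- if (grepl("\\.json$", table, ignore.case = TRUE)) {
      as_tibble(jsonlite::read_json(table, simplifyVector = TRUE))
    } else {
      as_tibble(utils::read.csv(table, stringsAsFactors = FALSE))
    }
  }
  table <- as_tibble(table)
  if (is.null(table$canonical_key)) abort("property table needs a canonical_key column")
  has_lambda <- !is.null(table$lambda_minus_eV) ||
    all(c("e_anion_r0_eV", "e_neutral_r0_eV", "e_neutral_rm_eV", "e_anion_rm_eV") %in% names(table))
  if (!has_lambda) {
    abort("property table needs lambda_minus_eV or the four point energies")
  }
  dup <- duplicated(table$canonical_key)
  if (any(dup)) {
    conflicting <- table |>
      dplyr::group_by(.data$canonical_key) |>
      dplyr::filter(dplyr::n() > 1L) |>
      dplyr::summarise(
        distinct = dplyr::n_distinct(dplyr::pick(dplyr::everything())), .groups = "drop"
      )
    if (any(conflicting$distinct > 1L)) {
      abort("property table has duplicate keys with conflicting values")
    }
    table <- table[!dup, ]
  }
  idx <- stats::setNames(seq_len(nrow(table)), table$canonical_key)
  function(mol) {
    key <- if (is_molecule(mol)) canonical_key(mol) else as.character(mol)
    i <- idx[key]
    if (is.na(i)) return(NULL)
    table[i, ]
  }
}
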