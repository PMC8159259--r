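#' Toy crystals with known transport behaviour
#'
#' Small synthetic molecular crystals for exercising the transport stack
#' offline, each paired with a consistent coupling set:
#'
#' * `"stack_1d"`: one molecule per triclinic-like cell, coupled only along
#'   the stacking axis by default — a pure 1-D chain whose diffusion
#'   constant is exactly \eqn{k a^2}.  A non-zero `transverse_coupling`
#'   adds weak perpendicular pathways (an order of magnitude down by
#'   default), emulating a predominantly 1-D conductor.
#' * `"cubic"`: one molecule per cubic cell with equal couplings along all
#'   three axes: an isotropic reference.
#' * `"herringbone"`: two molecules per cell in alternating orientations
#'   with a distance-decaying coupling generator, giving several distinct
#'   dimer classes for the deduplication machinery.
#'
#' @param motif `"stack_1d"`, `"cubic"` or `"herringbone"`.
#' @param spacing Stacking distance in Å (default 3.8).
#' @param coupling Principal electronic coupling in eV, before the network
#'   scaling (default 0.010).
#' @param transverse_coupling Perpendicular coupling (eV) for
#'   `"stack_1d"`; 0 disables the transverse pathways.
#' @param lambda Reorganisation energy (eV) used for rates.
#' @return A list with `crystal` (an [crystal_structure()]), `couplings`
#'   (tibble or function, ready for [build_network()]) and `lambda`.
#' @examples
#' toy <- make_toy_crystal("cubic")
#' net <- build_network(toy$crystal, toy$couplings, lambda = toy$lambda)
#' @export
make_toy_crystal <- function(motif = c("stack_1d", "cubic", "herringbone"),
                             spacing = 3.8, coupling = 0.010,
                             transverse_coupling = 0, lambda = 0.14) {
  motif <- match.arg(motif)
  stopifnot(spacing > 0, coupling >= 0, transverse_coupling >= 0, lambda > 0)
  # a small rigid asymmetric plate (Å), compact enough that only
  # nearest-neighbour contacts fall inside the vdW + 1.5 Å cutoff
  plate <- rbind(
    c(0.00, 0.00, 0.00),
    c(1.39, 0.00, 0.00),
    c(0.70, 1.20, 0.00),
    c(0.70, 0.40, 1.00)
  )
  elements <- c("C", "C", "N", "C")

  if (motif == "stack_1d") {
    lat <- rbind(c(spacing, 0, 0), c(0, 14, 0), c(0, 0, 16))
    cr <- crystal_structure(lat, list(list(label = "M1", elements = elements,
                                           coords = plate)))
    cp <- tibble(
      site_i = 1L, site_j = 1L,
      n1 = c(1L, 0L, 0L), n2 = c(0L, 1L, 0L), n3 = c(0L, 0L, 1L),
      v_ab_eV = c(coupling, transverse_coupling, transverse_coupling)
    )
    if (transverse_coupling == 0) {
      cp <- cp[1L, ]
    } else {
      # bring the transverse neighbours inside the contact cutoff while
      # keeping the cell diagonals out of range
      lat <- rbind(c(spacing, 0, 0), c(0, 5.6, 0), c(0, 0, 5.5))
      cr <- crystal_structure(lat, list(list(label = "M1", elements = elements,
                                             coords = plate)))
    }
    return(list(crystal = cr, couplings = cp, lambda = lambda))
  }

  if (motif == "cubic") {
    a <- spacing + 1.7
    lat <- diag(c(a, a, a))
    cr <- crystal_structure(lat, list(list(label = "M1", elements = elements,
                                           coords = plate)))
    cp <- tibble(
      site_i = 1L, site_j = 1L,
      n1 = c(1L, 0L, 0L), n2 = c(0L, 1L, 0L), n3 = c(0L, 0L, 1L),
      v_ab_eV = coupling
    )
    return(list(crystal = cr, couplings = cp, lambda = lambda))
  }

  # herringbone: second molecule rotated 90 degrees about z, offset to the
  # cell centre
  rot90z <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  lat <- rbind(c(2 * spacing, 0, 0), c(0, 7.6, 0), c(0, 0, 12))
  m2 <- plate %*% t(rot90z)
  m2 <- sweep(m2, 2L, c(spacing, 3.8, 0), `+`)
  cr <- crystal_structure(lat, list(
    list(label = "M1", elements = elements, coords = plate),
    list(label = "M2", elements = elements, coords = m2)
  ))
  cp_fun <- function(dimer) {
    # exponential distance decay, a common toy for pi-stacking couplings
    coupling * exp(-2.0 * (dimer$distance - spacing))
  }
  list(crystal = cr, couplings = cp_fun, lambda = lambda)
}

#' Surrogate property table over a whole space
#'
#' Runs the deterministic surrogate oracle over every molecule of an
#' enumerated space, producing a table usable with [table_oracle()].  The
#' global reorganisation-energy minimum of the table is pentacene by
#' construction of the surrogate.
#'
#' @param space An [space_definition()] or an [enumerate_space()] tibble.
#' @param complement_paired Passed to [enumerate_space()] when a space
#'   definition is given.
#' @return A tibble: `canonical_key`, `lambda_minus_eV`, `ea_gas_eV`.
#' @export
make_surrogate_table <- function(space, complement_paired = TRUE) {
  tab <- if (inherits(space, "azc_space")) {
    enumerate_space(space, complement_paired = complement_paired)
  } else {
    as_tibble(space)
  }
  surrogate_properties(tab)[, c("canonical_key", "lambda_minus_eV", "ea_gas_eV")]
}

#' Random reference landscape
#'
#' Draws a synthetic crystal-structure landscape with the broad statistical
#' shape of predicted-landscape maps: a dense low-energy region (relative
#' energies exponential with mean `energy_scale` above a global minimum at
#' 0) and log-normal mean mobilities.
#'
#' @param n Number of structures (>= 1).
#' @param seed Optional integer seed.
#' @param energy_scale Mean of the exponential relative-energy density
#'   (kJ/mol).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of the mobilities.
#' @inheritParams landscape
#' @return An `azc_landscape`.
#' @export
make_reference_landscape <- function(n, seed = NULL, energy_scale = 3,
                                     mu_meanlog = 0.5, mu_sdlog = 0.8,
                                     tau = 2.70, energy_window = 7) {
  stopifnot(is_count(n))
  if (!is.null(seed)) set.seed(seed)
  de <- c(0, stats::rexp(n - 1L, rate = 1 / energy_scale))
  mu <- stats::rlnorm(n, meanlog = mu_meanlog, sdlog = mu_sdlog)
  landscape(
    tibble(
      structure_id = sprintf("s%03d", seq_len(n)),
      relative_energy = de,
      mean_mobility = mu
    ),
    tau = tau, energy_window = energy_window
  )
}
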