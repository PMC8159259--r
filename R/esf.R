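#' Energy-structure-function landscapes
#'
#' A landscape is the set of predicted crystal structures of one molecule,
#' each carrying its lattice energy above the global minimum (kJ/mol) and
#' its mean electron mobility.  Structures within an energy window of the
#' global minimum (default 7 kJ/mol, inclusive — chosen to include most
#' experimentally observable polymorphs) are assigned Boltzmann-like
#' observation probabilities
#' \deqn{P_i \propto \exp(-\Delta E_i / \tau)}
#' with \eqn{\tau = 2.70} kJ/mol by default (an empirical polymorph
#' energy-difference scale), normalised over the windowed structures only:
#' structures outside the window are treated as unobservable and their
#' mobilities are never computed.
#'
#' @param data A data frame with columns `structure_id`,
#'   `relative_energy` (kJ/mol, minimum must be 0) and `mean_mobility`
#'   (cm^2/V/s; may be `NA` outside the window).
#' @param tau Boltzmann-like scale in kJ/mol (> 0).
#' @param energy_window Window above the global minimum in kJ/mol.
#' @return `landscape()` returns a tibble of class `azc_landscape` with
#'   attributes `tau` and `energy_window`.
#' @examples
#' l <- landscape(data.frame(
#'   structure_id = c("s1", "s2"),
#'   relative_energy = c(0, 2.70),
#'   mean_mobility = c(10, 2)
#' ))
#' summarise_landscape(l)
#' @export
landscape <- function(data, tau = 2.70, energy_window = 7) {
  data <- as_tibble(data)
  need <- c("structure_id", "relative_energy", "mean_mobility")
  if (!all(need %in% names(data))) {
    abort(sprintf("landscape needs columns %s", paste(need, collapse = ", ")))
  }
  stopifnot(is.numeric(tau), tau > 0, is.numeric(energy_window), energy_window >= 0)
  if (nrow(data) == 0L) abort("empty landscape")
  if (abs(min(data$relative_energy)) > 1e-9) {
    abort("relative energies must include the global minimum (min = 0)")
  }
  if (any(data$relative_energy < -1e-9)) abort("negative relative energy")
  structure(data, class = c("azc_landscape", class(data)),
            tau = tau, energy_window = energy_window)
}

#' @rdname landscape
#' @param l An `azc_landscape`.
#' @export
window_landscape <- function(l) {
  stopifnot(inherits(l, "azc_landscape"))
  keep <- l$relative_energy <= attr(l, "energy_window") + 1e-12
  out <- l[keep, ]
  structure(out, class = class(l), tau = attr(l, "tau"),
            energy_window = attr(l, "energy_window"))
}

#' @rdname landscape
#' @export
landscape_probabilities <- function(l) {
  w <- window_landscape(l)
  p <- exp(-w$relative_energy / attr(w, "tau"))
  w$probability <- p / sum(p)
  w
}

#' Summarise a landscape: expected mobility and its spread
#'
#' Computes the mobility of the global-minimum structure
#' (\eqn{\bar\mu_{GM}}), the probability-weighted landscape average
#' \eqn{\langle\bar\mu\rangle = \sum_i P_i \bar\mu_i} and the weighted
#' spread \eqn{\langle\Delta\bar\mu^2\rangle^{1/2} =
#' (\sum_i P_i (\bar\mu_i - \langle\bar\mu\rangle)^2)^{1/2}}, a risk
#' measure that vanishes for a landscape of uniform mobility.
#'
#' @inheritParams window_landscape
#' @return A one-row tibble: `n_structures_in_window`, `mu_gm`, `mu_avg`,
#'   `mu_spread`.
#' @export
summarise_landscape <- function(l) {
  w <- landscape_probabilities(l)
  if (anyNA(w$mean_mobility)) {
    abort("every structure inside the energy window needs a mean_mobility")
  }
  gm <- which(abs(w$relative_energy) <= 1e-9)
  if (length(gm) > 1L) {
    inform("multiple structures at the global minimum; mu_gm taken from the first")
  }
  mu_avg <- sum(w$probability * w$mean_mobility)
  tibble(
    n_structures_in_window = nrow(w),
    mu_gm = w$mean_mobility[gm[1L]],
    mu_avg = mu_avg,
    mu_spread = sqrt(sum(w$probability * (w$mean_mobility - mu_avg)^2))
  )
}

#' Read a landscape from CSV
#'
#' Expects columns `structure_id`, `relative_energy_kjmol`,
#' `mean_mobility_cm2Vs`.
#'
#' @param path CSV file path.
#' @inheritParams landscape
#' @export
read_landscape <- function(path, tau = 2.70, energy_window = 7) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  landscape(
    tibble(
      structure_id = as.character(d$structure_id),
      relative_energy = d$relative_energy_kjmol,
      mean_mobility = d$mean_mobility_cm2Vs
    ),
    tau = tau, energy_window = energy_window
  )
}

#' @rdname tidy.azc_evo_run
#' @param object An `azc_landscape`.
#' @export
autoplot.azc_landscape <- function(object, ...) {
  d <- as_tibble(object)
  d$in_window <- d$relative_energy <= attr(object, "energy_window") + 1e-12
  ggplot2::ggplot(d, ggplot2::aes(x = .data$relative_energy,
                                  y = .data$mean_mobility)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window,
                                     size = .data$mean_mobility), alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "energy_window"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey70"),
                                 guide = "none") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = expression(Delta * E ~ "(kJ/mol)"),
                  y = expression(bar(mu) ~ "(cm"^2 * "/Vs)")) +
    ggplot2::theme_minimal()
}
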