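#' Physical constants (eV-based unit system)
#' @noRd
.const <- list(
  hbar_eVs = 6.582119569e-16,   # reduced Planck constant, eV s
  kB_eVK = 8.617333262e-5,      # Boltzmann constant, eV / K
  A2_to_cm2 = 1e-16             # square angstrom to square centimetre
)

# Bondi van der Waals radii (Å) for the elements this package meets
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Non-adiabatic Marcus hopping rate
#'
#' \deqn{k = \frac{2\pi}{\hbar} |V_{ab}|^2 (4\pi\lambda k_B T)^{-1/2}
#'       \exp\left(-\frac{(\Delta G + \lambda)^2}{4\lambda k_B T}\right)}
#'
#' @param coupling Electronic coupling \eqn{|V_{ab}|} in eV (already scaled
#'   if a scaling factor applies), vectorised.
#' @param lambda Reorganisation energy in eV (> 0).
#' @param delta_g Site energy difference \eqn{\Delta G} in eV (default 0:
#'   hops between identical molecules).
#' @param temperature Temperature in K.
#' @return Hopping rate in 1/s.
#' @export
marcus_rate <- function(coupling, lambda, delta_g = 0, temperature = 300) {
  if (!is.numeric(lambda) || any(lambda <= 0)) abort("lambda must be positive")
  if (any(temperature <= 0)) abort("temperature must be positive")
  kt <- .const$kB_eVK * temperature
  (2 * pi / .const$hbar_eVs) * coupling^2 / sqrt(4 * pi * lambda * kt) *
    exp(-(delta_g + lambda)^2 / (4 * lambda * kt))
}

#' Kabsch superposition RMSD
#'
#' Root-mean-square deviation between two conformations after optimal
#' rigid-body superposition (proper rotations only, so mirror-image dimers
#' are not identified).
#'
#' @param p,q n x 3 coordinate matrices with corresponding rows.
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3L, ncol(q) == 3L)
  p <- sweep(p, 2L, colMeans(p))
  q <- sweep(q, 2L, colMeans(q))
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((q - p %*% t(rot))^2)))
}

#' Build a Marcus hopping network from a crystal structure
#'
#' Enumerates all molecular dimers with at least one atom-atom contact
#' closer than the sum of the van der Waals radii plus `cutoff_pad`,
#' including hops to the same site in adjacent unit cells.  Geometrically
#' identical dimers (Kabsch RMSD below `rmsd_tol`) form one class and share
#' one electronic coupling, which is multiplied by `coupling_scale` before
#' entering the Marcus rate.  Every edge is stored in both directions with
#' its periodic image shift and centroid displacement vector.
#'
#' @param crystal An [crystal_structure()].
#' @param couplings Either a data frame with columns `site_i`, `site_j`,
#'   `n1`, `n2`, `n3`, `v_ab_eV` (one row per symmetry-unique contact
#'   dimer; the shift `n1 n2 n3` is from site i to site j), or a function
#'   `dimer -> eV` receiving a list with `site_i`, `site_j`, `shift`,
#'   `distance` (centroid Å).  A missing coupling for a unique dimer is an
#'   error naming the dimer.
#' @param lambda Reorganisation energy (eV) of the molecule.
#' @param temperature Temperature in K.
#' @param coupling_scale Multiplier applied to all couplings (default
#'   1.325, aligning fragment-orbital DFT couplings with high-level
#'   reference values).
#' @param cutoff_pad Distance added to the van der Waals radii sum (Å).
#' @param rmsd_tol Kabsch threshold for dimer identity (Å).
#' @param delta_g Site energy difference for all hops (eV).
#' @return An object of class `azc_network`: list with `sites` (tibble:
#'   site, label, centroid) and `edges` (tibble: from, to, n1, n2, n3,
#'   dx, dy, dz, v_ab_eV, rate).
#' @export
build_network <- function(crystal, couplings, lambda, temperature = 300,
                          coupling_scale = 1.325, cutoff_pad = 1.5,
                          rmsd_tol = 0.001, delta_g = 0) {
  stopifnot(inherits(crystal, "azc_crystal"))
  lat <- crystal$lattice
  ns <- length(crystal$sites)
  cent <- t(vapply(crystal$sites, function(s) colMeans(s$coords), numeric(3)))
  radii <- lapply(crystal$sites, function(s) {
    r <- .vdw_radii[s$elements]
    if (anyNA(r)) abort("unknown element in crystal (no van der Waals radius)")
    r
  })
  span <- vapply(seq_len(ns), function(i) {
    max(sqrt(rowSums(sweep(crystal$sites[[i]]$coords, 2L, cent[i, ])^2)))
  }, numeric(1))
  dmax <- max(vapply(radii, max, numeric(1))) * 2 + cutoff_pad
  reach <- 2 * max(span) + dmax

  # how many cells to scan along each axis: spacing between lattice planes
  vol <- det(lat)
  plane_d <- vapply(1:3, function(k) {
    others <- setdiff(1:3, k)
    cr <- crossprod_vec(lat[others[1L], ], lat[others[2L], ])
    vol / sqrt(sum(cr^2))
  }, numeric(1))
  nmax <- pmax(1L, ceiling(reach / plane_d))

  shifts <- as.matrix(expand.grid(n1 = -nmax[1L]:nmax[1L],
                                  n2 = -nmax[2L]:nmax[2L],
                                  n3 = -nmax[3L]:nmax[3L]))

  # canonical directed dimers: i < j any shift, or i == j with shift > 0
  dimers <- list()
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      for (r in seq_len(nrow(shifts))) {
        sh <- shifts[r, ]
        if (i == j && !shift_positive(sh)) next
        tvec <- as.numeric(sh %*% lat)
        ci <- crystal$sites[[i]]$coords
        cj <- sweep(crystal$sites[[j]]$coords, 2L, tvec, `+`)
        # cheap centroid prefilter
        if (sqrt(sum((colMeans(cj) - colMeans(ci))^2)) > span[i] + span[j] + dmax) next
        dd <- pair_min_contact(ci, radii[[i]], cj, radii[[j]], cutoff_pad)
        if (!dd) next
        dimers[[length(dimers) + 1L]] <- list(
          i = i, j = j, shift = as.integer(sh),
          coords = rbind(ci, cj),
          elements = c(crystal$sites[[i]]$elements, crystal$sites[[j]]$elements),
          n_i = nrow(ci),
          dist = sqrt(sum((colMeans(cj) - colMeans(ci))^2))
        )
      }
    }
  }
  if (!length(dimers)) abort("no contact dimers found: crystal sites are isolated")

  # Kabsch dedup into classes sharing one coupling evaluation
  class_of <- integer(length(dimers))
  reps <- list()
  for (d in seq_along(dimers)) {
    assigned <- 0L
    for (cidx in seq_along(reps)) {
      if (dimers_identical(dimers[[d]], reps[[cidx]], rmsd_tol)) {
        assigned <- cidx
        break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- dimers[[d]]
      assigned <- length(reps)
    }
    class_of[d] <- assigned
  }

  v_class <- vapply(seq_along(reps), function(cidx) {
    members <- dimers[class_of == cidx]
    lookup_coupling(couplings, members, crystal)
  }, numeric(1))

  rows <- lapply(seq_along(dimers), function(d) {
    dm <- dimers[[d]]
    v <- v_class[class_of[d]]
    tvec <- as.numeric(dm$shift %*% lat)
    disp <- cent[dm$j, ] + tvec - cent[dm$i, ]
    tibble(
      from = c(dm$i, dm$j), to = c(dm$j, dm$i),
      n1 = c(dm$shift[1L], -dm$shift[1L]),
      n2 = c(dm$shift[2L], -dm$shift[2L]),
      n3 = c(dm$shift[3L], -dm$shift[3L]),
      dx = c(disp[1L], -disp[1L]), dy = c(disp[2L], -disp[2L]),
      dz = c(disp[3L], -disp[3L]),
      v_ab_eV = v * coupling_scale,
      dimer_class = class_of[d]
    )
  })
  edges <- dplyr::bind_rows(rows)
  edges$rate <- marcus_rate(edges$v_ab_eV, lambda, delta_g, temperature)

  if (!all(seq_len(ns) %in% edges$from)) {
    abort("isolated site in the hopping network")
  }
  structure(
    list(
      sites = tibble(site = seq_len(ns),
                     label = vapply(crystal$sites, `[[`, character(1), "label"),
                     cx = cent[, 1L], cy = cent[, 2L], cz = cent[, 3L]),
      edges = edges,
      n_dimer_classes = length(reps),
      params = list(lambda = lambda, temperature = temperature,
                    coupling_scale = coupling_scale, cutoff_pad = cutoff_pad,
                    rmsd_tol = rmsd_tol, delta_g = delta_g)
    ),
    class = "azc_network"
  )
}

#' @export
print.azc_network <- function(x, ...) {
  cat(sprintf(
    "<azc_network> %d site(s), %d directed edges, %d unique dimer class(es)\n",
    nrow(x$sites), nrow(x$edges), x$n_dimer_classes
  ))
  invisible(x)
}

crossprod_vec <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

shift_positive <- function(sh) {
  if (sh[1L] != 0L) return(sh[1L] > 0L)
  if (sh[2L] != 0L) return(sh[2L] > 0L)
  sh[3L] > 0L
}

# at least one atom-atom pair closer than vdW_i + vdW_j + pad?
pair_min_contact <- function(ci, ri, cj, rj, pad) {
  for (a in seq_len(nrow(ci))) {
    d2 <- rowSums(sweep(cj, 2L, ci[a, ])^2)
    if (any(d2 < (ri[a] + rj + pad)^2)) return(TRUE)
  }
  FALSE
}

# same dimer class? try both molecule orderings (elements permitting)
dimers_identical <- function(d1, d2, tol) {
  if (nrow(d1$coords) != nrow(d2$coords)) return(FALSE)
  if (abs(d1$dist - d2$dist) > 1) return(FALSE)
  if (identical(d1$elements, d2$elements)) {
    if (kabsch_rmsd(d1$coords, d2$coords) < tol) return(TRUE)
  }
  # swapped molecule order
  o <- c(seq_len(nrow(d2$coords) - d2$n_i) + d2$n_i, seq_len(d2$n_i))
  if (identical(d1$elements, d2$elements[o])) {
    if (kabsch_rmsd(d1$coords, d2$coords[o, , drop = FALSE]) < tol) return(TRUE)
  }
  FALSE
}

lookup_coupling <- function(couplings, members, crystal) {
  if (is.function(couplings)) {
    m <- members[[1L]]
    return(couplings(list(site_i = m$i, site_j = m$j, shift = m$shift,
                          distance = m$dist)))
  }
  tb <- as_tibble(couplings)
  need <- c("site_i", "site_j", "n1", "n2", "n3", "v_ab_eV")
  if (!all(need %in% names(tb))) {
    abort("couplings table needs columns site_i, site_j, n1, n2, n3, v_ab_eV")
  }
  labels <- vapply(crystal$sites, `[[`, character(1), "label")
  si <- if (is.character(tb$site_i)) match(tb$site_i, labels) else tb$site_i
  sj <- if (is.character(tb$site_j)) match(tb$site_j, labels) else tb$site_j
  for (m in members) {
    hit <- which((si == m$i & sj == m$j &
                    tb$n1 == m$shift[1L] & tb$n2 == m$shift[2L] & tb$n3 == m$shift[3L]) |
                   (si == m$j & sj == m$i &
                      tb$n1 == -m$shift[1L] & tb$n2 == -m$shift[2L] & tb$n3 == -m$shift[3L]))
    if (length(hit)) return(tb$v_ab_eV[hit[1L]])
  }
  m <- members[[1L]]
  abort(sprintf(
    "no coupling supplied for unique dimer: site %d -> site %d, shift (%d, %d, %d)",
    m$i, m$j, m$shift[1L], m$shift[2L], m$shift[3L]
  ))
}

#' Electron mobility by rejection-free kinetic Monte Carlo
#'
#' Propagates random walkers over a hopping network with the n-fold-way
#' algorithm (hop chosen with probability rate/total, clock advanced by an
#' exponential waiting time), accumulates the diffusion tensor
#' \eqn{D_{\alpha\beta} = \langle \Delta r_\alpha \Delta r_\beta \rangle / 2t}
#' pooled over trajectories, and converts to the mobility tensor with the
#' Einstein relation \eqn{\mu = q D / k_B T}.  Trajectories start uniformly
#' cycled over the sites.
#'
#' @param network An [build_network()] result.
#' @param n_traj Number of trajectories (default 100,000).
#' @param n_steps Hops per trajectory (default 1,000).
#' @param temperature Temperature (K); defaults to the network's.
#' @param seed Optional integer seed.
#' @return An `azc_transport` object: `D` (cm^2/s), `mu` (cm^2/V/s), both
#'   symmetric 3x3; `mu_mean` = tr(mu)/3 with standard error
#'   `mu_mean_se`; the call parameters.
#' @export
kmc_mobility <- function(network, n_traj = 1e5, n_steps = 1000,
                         temperature = NULL, seed = NULL) {
  stopifnot(inherits(network, "azc_network"))
  temperature <- temperature %||% network$params$temperature
  if (!is.null(seed)) set.seed(seed)
  ed <- network$edges[order(network$edges$from), ]
  ns <- nrow(network$sites)
  counts <- tabulate(ed$from, nbins = ns)
  if (any(counts == 0L)) abort("isolated site in the hopping network")
  offset <- c(0L, cumsum(counts))
  cum_rate <- unlist(lapply(split(ed$rate, ed$from), cumsum), use.names = FALSE)
  res <- kmc_walk(
    offset, ed$rate, cum_rate,
    as.matrix(ed[, c("dx", "dy", "dz")]), as.integer(ed$to) - 1L,
    ns, as.double(n_traj), as.integer(n_steps)
  )
  d_A2 <- res$moment / (2 * res$time_sum)      # A^2 / s
  D <- d_A2 * .const$A2_to_cm2
  kt <- .const$kB_eVK * temperature
  mu <- D / kt
  iso_mean <- res$iso_sum / n_traj
  iso_se <- sqrt(pmax(res$iso_sq_sum / n_traj - iso_mean^2, 0) / n_traj)
  structure(
    list(
      D = D, mu = mu,
      mu_mean = sum(diag(mu)) / 3,
      mu_mean_se = iso_se * .const$A2_to_cm2 / kt,
      n_traj = n_traj, n_steps = n_steps, temperature = temperature
    ),
    class = "azc_transport"
  )
}

#' @export
print.azc_transport <- function(x, ...) {
  ev <- sort(eigen(x$mu, symmetric = TRUE)$values, decreasing = TRUE)
  cat(sprintf(
    "<azc_transport> mean mobility %.4g cm^2/(V s) (se %.2g), eigenvalues %s\n",
    x$mu_mean, x$mu_mean_se, paste(signif(ev, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Mean electron mobility, tr(mu)/3
#'
#' The orientational average of the mobility tensor: one third of its
#' trace, equal to the arithmetic mean of its eigenvalues and invariant
#' under rotation.
#'
#' @param x An `azc_transport` result or a 3x3 mobility matrix.
#' @return Scalar mobility in the units of the tensor.
#' @examples
#' mean_mobility(diag(c(30.18, 2.12, 0.30)))
#' @export
mean_mobility <- function(x) {
  m <- if (inherits(x, "azc_transport")) x$mu else as.matrix(x)
  stopifnot(all(dim(m) == c(3L, 3L)))
  sum(diag(m)) / 3
}

#' Closed-form transport for single-site networks
#'
#' For a network with one molecule per unit cell (every site equivalent)
#' the walk has independent increments and the diffusion tensor is exactly
#' \eqn{D = \tfrac12 \sum_e k_e d_e d_e^T} over directed edges.  Used as
#' the analytic reference for the kinetic Monte Carlo estimator.
#'
#' @param network A single-site [build_network()] result.
#' @param temperature Temperature (K); defaults to the network's.
#' @return An `azc_transport`-like list with exact `D`, `mu`, `mu_mean`.
#' @export
analytic_transport <- function(network, temperature = NULL) {
  stopifnot(inherits(network, "azc_network"))
  if (nrow(network$sites) != 1L) {
    abort("analytic transport is exact only for single-site networks")
  }
  temperature <- temperature %||% network$params$temperature
  ed <- network$edges
  d <- as.matrix(ed[, c("dx", "dy", "dz")])
  D <- matrix(0, 3L, 3L)
  for (r in seq_len(nrow(ed))) {
    D <- D + ed$rate[r] * tcrossprod(d[r, ])
  }
  D <- D / 2 * .const$A2_to_cm2
  mu <- D / (.const$kB_eVK * temperature)
  structure(
    list(D = D, mu = mu, mu_mean = sum(diag(mu)) / 3, mu_mean_se = 0,
         n_traj = Inf, n_steps = Inf, temperature = temperature),
    class = "azc_transport"
  )
}

#' @rdname tidy.azc_evo_run
#' @export
tidy.azc_transport <- function(x, ...) {
  idx <- expand.grid(alpha = 1:3, beta = 1:3)
  tibble(
    alpha = c("x", "y", "z")[idx$alpha],
    beta = c("x", "y", "z")[idx$beta],
    D_cm2_s = x$D[cbind(idx$alpha, idx$beta)],
    mu_cm2_Vs = x$mu[cbind(idx$alpha, idx$beta)]
  )
}

#' @rdname tidy.azc_evo_run
#' @export
glance.azc_transport <- function(x, ...) {
  ev <- sort(eigen(x$mu, symmetric = TRUE)$values, decreasing = TRUE)
  tibble(
    mu_mean = x$mu_mean, mu_mean_se = x$mu_mean_se,
    mu_1 = ev[1L], mu_2 = ev[2L], mu_3 = ev[3L],
    anisotropy = ev[1L] / max(ev[3L], .Machine$double.eps),
    n_traj = x$n_traj, n_steps = x$n_steps, temperature = x$temperature
  )
}
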