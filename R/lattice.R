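# Integer hexagonal-lattice geometry.
#
# Rings of a fused aromatic are hexagonal cells of a triangular lattice and
# atoms are cell vertices.  Coordinates are stored as complex integers
# (x + yi) in a skewed frame in which a flat-top hexagon centred at the
# origin has vertices (+-2, 0) and (+-1, +-1); the true Cartesian point is
# (x, sqrt(3) * y) up to scale.  In this frame every lattice symmetry
# (rotations by 60 degrees and reflections) is an integer map, so cell and
# atom identities are exact and canonicalisation is a finite minimisation.

# neighbour cell-centre offsets, counter-clockwise starting at 30 degrees
.hex_nb <- c(3 + 1i, 0 + 2i, -3 + 1i, -3 - 1i, 0 - 2i, 3 - 1i)

# vertex offsets from a cell centre, counter-clockwise starting at 0 degrees;
# vertex j touches the neighbour cells .hex_nb[j] and .hex_nb[j - 1]
.hex_vx <- c(2 + 0i, 1 + 1i, -1 + 1i, -2 + 0i, -1 - 1i, 1 - 1i)

hex_rot60 <- function(z) {
  complex(real = (Re(z) - 3 * Im(z)) / 2, imaginary = (Re(z) + Im(z)) / 2)
}

.hex_ops <- do.call(rbind, lapply(0:5, function(k) {
  rbind(c(k = k, mirror = 0L), c(k = k, mirror = 1L))
}))

# Every point-group operation is an R-linear map on the complex plane and
# can be written z -> A z + B Conj(z); the (A, B) pairs are exact in binary
# (halves and integers), so coordinates stay exact.  Row r matches .hex_ops.
.hex_opAB <- local({
  rotA <- 0.5 + 1i  # rot60: (x, y) -> ((x - 3y)/2, (x + y)/2)
  rotB <- -0.5i
  compose <- function(f, g) {
    # (f after g): A = fA gA + fB Conj(gB); B = fA gB + fB Conj(gA)
    list(A = f$A * g$A + f$B * Conj(g$B), B = f$A * g$B + f$B * Conj(g$A))
  }
  ident <- list(A = 1 + 0i, B = 0 + 0i)
  mirror <- list(A = 0 + 0i, B = 1 + 0i)  # Conj
  rot <- list(A = rotA, B = rotB)
  out <- vector("list", 12L)
  cur <- ident
  for (k in 0:5) {
    out[[2L * k + 1L]] <- cur
    out[[2L * k + 2L]] <- compose(cur, mirror)
    cur <- compose(rot, cur)
  }
  out
})

# apply point-group operation: k rotations by 60 degrees, optional mirror
# (mirror first, matching hex_op(z, k, m) = rot^k(Conj(z)))
hex_op <- function(z, k, mirror) {
  ab <- .hex_opAB[[2L * k + 1L + as.integer(mirror)]]
  ab$A * z + ab$B * Conj(z)
}

hex_op_r <- function(z, r) {
  ab <- .hex_opAB[[r]]
  ab$A * z + ab$B * Conj(z)
}

# stable lexicographic order on complex coordinates: by Re, then Im
hex_order <- function(z) order(Re(z), Im(z))

hex_sort <- function(z) z[hex_order(z)]

hex_key <- function(z) paste(Re(z), Im(z), sep = ",", collapse = ";")

# all 6 vertices of each cell; returns list(vertex = complex, cell = index)
hex_cell_vertices <- function(cells) {
  n <- length(cells)
  list(
    vertex = rep(cells, each = 6L) + rep(.hex_vx, times = n),
    cell = rep(seq_len(n), each = 6L)
  )
}

# unique vertices with the number of member cells each belongs to (1 = CH
# perimeter position, 2 = ring-fusion carbon, 3 = interior peri carbon)
hex_vertex_counts <- function(cells) {
  v <- hex_cell_vertices(cells)$vertex
  u <- unique(v)
  list(vertex = u, count = tabulate(match(v, u), nbins = length(u)))
}

# cell adjacency as an index list (cells sharing an edge)
hex_adjacency <- function(cells) {
  lapply(seq_along(cells), function(i) {
    which(cells %in% (cells[i] + .hex_nb))
  })
}

hex_connected <- function(cells) {
  n <- length(cells)
  if (n <= 1L) return(TRUE)
  adj <- hex_adjacency(cells)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    nxt <- adj[[i]][!seen[adj[[i]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

# perimeter bonds: hexagon edges used by exactly one cell.  Returns a list
# with the two vertex coordinates, the owning cell and the empty cell on the
# far side of the bond (v1 + v2 - cell).
hex_perimeter_bonds <- function(cells) {
  n <- length(cells)
  v1 <- rep(cells, each = 6L) + rep(.hex_vx, times = n)
  v2 <- rep(cells, each = 6L) + rep(.hex_vx[c(2:6, 1L)], times = n)
  own <- rep(seq_len(n), each = 6L)
  lo <- ifelse(Re(v1) < Re(v2) | (Re(v1) == Re(v2) & Im(v1) < Im(v2)), v1, v2)
  hi <- ifelse(lo == v1, v2, v1)
  ekey <- paste(Re(lo), Im(lo), Re(hi), Im(hi))
  keep <- ekey %in% names(which(table(ekey) == 1L))
  list(
    v1 = v1[keep], v2 = v2[keep], cell = own[keep],
    outside = v1[keep] + v2[keep] - cells[own[keep]]
  )
}
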