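# Shared molecular fixtures, all built in code.

smi <- list(
  benzene      = "c1ccccc1",
  pyridine     = "c1ccncc1",
  naphthalene  = "c1ccc2ccccc2c1",
  anthracene   = "c1ccc2cc3ccccc3cc2c1",
  phenanthrene = "c1ccc2ccc3ccccc3c2c1",
  tetracene    = "c1ccc2cc3cc4ccccc4cc3cc2c1",
  pentacene    = "c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1"
)

mol <- lapply(smi, parse_molecule)

pentacene_key <- canonical_key(mol$pentacene)

# geometric fixtures straight from lattice cells (axial (q, r) converted to
# the package's integer frame (3q, q + 2r))
cells_from_axial <- function(qr) {
  complex(real = 3 * qr[, 1L], imaginary = qr[, 1L] + 2 * qr[, 2L])
}

helicene4 <- azacene:::new_molecule(
  cells_from_axial(rbind(c(0, 0), c(1, 0), c(2, -1), c(2, -2)))
)
helicene5 <- azacene:::new_molecule(
  cells_from_axial(rbind(c(0, 0), c(1, 0), c(2, -1), c(2, -2), c(1, -2)))
)

# independent region oracle: walk the molecular perimeter and classify each
# maximal run of consecutive fusion atoms flanked by CH atoms.  A run of f
# fusion atoms spans f + 2 perimeter atoms: f = 1 fissure, 2 bay, 3 cove,
# 4 fjord.  (Different algorithm from the implementation, which works from
# empty fill cells.)
perimeter_region_oracle <- function(m) {
  cells <- m$cells
  pb <- azacene:::hex_perimeter_bonds(cells)
  vc <- azacene:::hex_vertex_counts(cells)
  fusion <- vc$vertex[vc$count >= 2L]
  # build the perimeter cycle from its bonds
  verts <- unique(c(pb$v1, pb$v2))
  nb <- lapply(verts, function(v) {
    c(pb$v2[pb$v1 == v], pb$v1[pb$v2 == v])
  })
  names(nb) <- as.character(verts)
  walk <- verts[1L]
  prev <- NA
  repeat {
    cur <- walk[length(walk)]
    nxt <- nb[[as.character(cur)]]
    nxt <- nxt[is.na(prev) | nxt != prev][1L]
    if (nxt == walk[1L]) break
    walk <- c(walk, nxt)
    prev <- cur
  }
  isf <- walk %in% fusion
  if (!any(isf) || all(isf)) return(character(0))
  # rotate so the walk starts at a CH atom, then scan runs
  start <- which(!isf)[1L]
  isf <- isf[c(start:length(isf), seq_len(start - 1L))]
  runs <- rle(isf)
  f <- runs$lengths[runs$values]
  kinds <- c("fissure", "bay", "cove", "fjord")[pmin(f, 4L)]
  sort(kinds[kinds != "fissure"])
}

resample1 <- azacene:::resample1

# canonical string of a colored graph via igraph BLISS labelling, with the
# edge list itself canonically sorted (edge storage order is not canonical)
igraph_canonical_string <- function(g, col) {
  cp <- igraph::canonical_permutation(g, colors = col)
  gc <- igraph::permute(g, cp$labeling)
  el <- igraph::as_edgelist(gc)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(paste(col[order(cp$labeling)], collapse = ""),
        paste(t(el), collapse = ","))
}
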