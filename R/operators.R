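#' Molecular transformation operators
#'
#' The four moves that drive the evolutionary search.  All operators keep
#' molecules inside the defined region of chemical space: six-membered
#' aromatic C/N rings only, ring-count limits, and no attachment into
#' forbidden concave regions (see [classify_fusion_regions()]).
#'
#' * `mol_addition()` ortho-fuses a fragment across a randomly chosen
#'   perimeter bond of the molecule (random bond first, then random
#'   orientation, as in the search algorithm's initial-population builder).
#' * `mol_crossover()` cuts each parent at a random ring-fusion bond and
#'   recombines one fragment from each parent into two children.
#' * `mol_recombination()` cuts a single molecule and re-fuses its two
#'   fragments at a new random position, producing an isomer with the same
#'   molecular formula and ring count.
#' * `mol_mutation()` replaces one randomly chosen position matched by a
#'   SMARTS pattern with a different fragment from the same list (the
#'   aza-substitution walk `[cH]` <-> `n`).
#'
#' Operators that run out of legal moves return `NULL` (addition,
#' crossover) or the input molecule unchanged (recombination, mutation), so
#' a calling search loop can re-draw.
#'
#' @param mol,parent_a,parent_b `azc_mol` objects.
#' @param fragment An `azc_mol` used as the attached building block.
#' @param forbid Character vector of forbidden region kinds, a subset of
#'   `c("bay", "cove", "fjord")`.  Forbidding `"bay"` also excludes the
#'   3-atom fissure fills, since either creates pyrene-type peri-fusion.
#' @param max_rings Maximum allowed ring count of the product.
#' @param min_rings,max_retry Minimum product ring count for
#'   crossover children, and the number of random re-draws before the
#'   operator gives up.
#' @param smarts Character vector of single-atom aromatic SMARTS patterns
#'   (supported dialect: `c`, `n`, `[cH]`, `[nH0]` and bracketed variants).
#'   Each entry is both a match pattern and a replacement fragment.
#' @return A new `azc_mol`, a list of two for `mol_crossover()`, or
#'   `NULL`/the unchanged input when no legal move exists.
#' @examples
#' set.seed(1)
#' py <- parse_molecule("c1ccncc1")
#' mol_addition(py, py)                      # a naphthyridine-type molecule
#' mol_mutation(py, c("[cH]", "n"))          # pyridazine, pyrimidine or pyrazine
#' @name operators
NULL

#' @rdname operators
#' @export
mol_addition <- function(mol, fragment, forbid = c("bay", "cove", "fjord"),
                         max_rings = Inf) {
  stopifnot(is_molecule(mol), is_molecule(fragment))
  if (ring_count(mol) + ring_count(fragment) > max_rings) return(NULL)
  pl <- addition_placements(mol, fragment, forbid)
  if (length(pl) == 0L) return(NULL)
  # random bonding position first, then random orientation
  bonds <- unique(vapply(pl, function(p) p$bond, character(1)))
  b <- resample1(bonds)
  pl_b <- pl[vapply(pl, function(p) p$bond == b, logical(1))]
  p <- resample1(pl_b)
  new_molecule(p$cells, p$nitro)
}

# every distinct legal attachment of `fragment` to `mol`, as raw cell/nitro
# sets tagged with the perimeter-bond id used
addition_placements <- function(mol, fragment, forbid) {
  cells <- mol$cells
  nitro <- mol$nitro
  vc <- hex_vertex_counts(cells)
  atoms <- vc$vertex
  out <- list()

  if (ring_count(fragment) == 1L) {
    # single-ring fragments may also fill an allowed concave region
    pb <- hex_perimeter_bonds(cells)
    frag_off <- fragment$nitro - fragment$cells[1L]
    fills <- region_fills(cells)
    fill_kind <- list()
    for (f in fills) fill_kind[[hex_key(f$cell)]] <- c(fill_kind[[hex_key(f$cell)]], f$kind)
    for (i in seq_along(pb$v1)) {
      e <- pb$outside[i]
      kinds <- fill_kind[[hex_key(e)]]
      if (!is.null(kinds)) {
        if (any(vapply(kinds, exclusion_kind, character(1)) %in% forbid)) next
        if (any(vapply(kinds, function(k) k == "enclosed", logical(1)))) next
      }
      # merged vertices (already-existing atoms of the new ring) must be C
      merged <- intersect(e + .hex_vx, atoms)
      if (any(merged %in% nitro)) next
      bond_id <- hex_key(e)
      for (r in seq_len(12L)) {
        nn <- e + hex_op_r(frag_off, r)
        if (any(nn %in% merged)) next  # fragment N may not land on a fused atom
        out[[length(out) + 1L]] <- list(
          bond = paste(bond_id, i), cells = c(cells, e), nitro = c(nitro, nn)
        )
      }
    }
  } else {
    out <- fuse_placements(mol, fragment)
  }
  # drop exact duplicates (same cell set and nitrogen set)
  if (length(out)) {
    keys <- vapply(out, function(p) {
      paste(hex_key(hex_sort(p$cells)), hex_key(hex_sort(p$nitro)))
    }, character(1))
    out <- out[!duplicated(paste(vapply(out, `[[`, character(1), "bond"), keys))]
  }
  out
}

# rigid fusions of fragment onto mol across exactly one shared bond (both
# sides of the bond all-carbon, no other cell contacts): the cata-preserving
# attachment used by crossover/recombination and by multi-ring addition
fuse_placements <- function(mol, fragment) {
  pb_m <- hex_perimeter_bonds(mol$cells)
  pb_f <- hex_perimeter_bonds(fragment$cells)
  out <- list()
  for (i in seq_along(pb_m$v1)) {
    v1 <- pb_m$v1[i]; v2 <- pb_m$v2[i]
    if (v1 %in% mol$nitro || v2 %in% mol$nitro) next
    e <- pb_m$outside[i]
    for (j in seq_along(pb_f$v1)) {
      w1 <- pb_f$v1[j]; w2 <- pb_f$v2[j]
      if (w1 %in% fragment$nitro || w2 %in% fragment$nitro) next
      f_in <- fragment$cells[pb_f$cell[j]]
      for (swap in c(FALSE, TRUE)) {
        t1 <- if (swap) v2 else v1
        t2 <- if (swap) v1 else v2
        for (r in seq_len(12L)) {
          if (hex_op_r(w2, r) - hex_op_r(w1, r) != t2 - t1) next
          shift <- t1 - hex_op_r(w1, r)
          if (hex_op_r(f_in, r) + shift != e) next
          fc <- hex_op_r(fragment$cells, r) + shift
          if (any(fc %in% mol$cells)) break
          # exactly one cell contact: the fused bond itself
          contacts <- sum(vapply(fc, function(z) sum(mol$cells %in% (z + .hex_nb)), numeric(1)))
          if (contacts != 1) break
          fn <- hex_op_r(fragment$nitro, r) + shift
          out[[length(out) + 1L]] <- list(
            bond = paste0("b", i), cells = c(mol$cells, fc), nitro = c(mol$nitro, fn)
          )
          break  # the op mapping a directed edge + side is unique
        }
      }
    }
  }
  out
}

# cut a cata-fused molecule at a ring-fusion (dualist tree) edge
cut_molecule <- function(mol, edge = NULL) {
  cells <- mol$cells
  adj <- hex_adjacency(cells)
  pairs <- list()
  for (i in seq_along(adj)) {
    for (j in adj[[i]]) if (j > i) pairs <- c(pairs, list(c(i, j)))
  }
  if (length(pairs) != length(cells) - 1L) {
    abort("molecule is not cata-fused: cut position is ambiguous")
  }
  if (is.null(edge)) edge <- resample1(pairs) else edge <- pairs[[edge]]
  # component containing edge[1] with the cut adjacency removed
  seen <- logical(length(cells))
  seen[edge[1L]] <- TRUE
  queue <- edge[1L]
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    nxt <- setdiff(adj[[i]], which(seen))
    if (i == edge[1L]) nxt <- setdiff(nxt, edge[2L])
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  split_frag <- function(idx) {
    cc <- cells[idx]
    vv <- hex_cell_vertices(cc)$vertex
    list(cells = cc, nitro = mol$nitro[mol$nitro %in% vv])
  }
  list(a = split_frag(which(seen)), b = split_frag(which(!seen)))
}

as_fragment <- function(raw) {
  structure(list(cells = raw$cells, nitro = raw$nitro), class = "azc_mol")
}

# random single-contact fusion by rejection sampling (random bond of each
# fragment, random flip), with an exhaustive fallback so that NULL means no
# placement exists at all
fuse_random <- function(f1, f2, max_attempts = 40L) {
  pb_m <- hex_perimeter_bonds(f1$cells)
  pb_f <- hex_perimeter_bonds(f2$cells)
  ok_m <- which(!(pb_m$v1 %in% f1$nitro | pb_m$v2 %in% f1$nitro))
  ok_f <- which(!(pb_f$v1 %in% f2$nitro | pb_f$v2 %in% f2$nitro))
  if (length(ok_m) && length(ok_f)) {
    for (a in seq_len(max_attempts)) {
      i <- resample1(ok_m)
      j <- resample1(ok_f)
      swap <- stats::runif(1) < 0.5
      t1 <- if (swap) pb_m$v2[i] else pb_m$v1[i]
      t2 <- if (swap) pb_m$v1[i] else pb_m$v2[i]
      e <- pb_m$outside[i]
      w1 <- pb_f$v1[j]; w2 <- pb_f$v2[j]
      f_in <- f2$cells[pb_f$cell[j]]
      for (r in seq_len(12L)) {
        if (hex_op_r(w2, r) - hex_op_r(w1, r) != t2 - t1) next
        shift <- t1 - hex_op_r(w1, r)
        if (hex_op_r(f_in, r) + shift != e) next
        fc <- hex_op_r(f2$cells, r) + shift
        if (any(fc %in% f1$cells)) break
        contacts <- sum(vapply(fc, function(z) sum(f1$cells %in% (z + .hex_nb)), numeric(1)))
        if (contacts != 1) break
        fn <- hex_op_r(f2$nitro, r) + shift
        return(new_molecule(c(f1$cells, fc), c(f1$nitro, fn)))
      }
    }
  }
  pl <- fuse_placements(f1, f2)
  if (length(pl) == 0L) return(NULL)
  p <- resample1(pl)
  new_molecule(p$cells, p$nitro)
}

#' @rdname operators
#' @export
mol_crossover <- function(parent_a, parent_b, min_rings = 1L, max_rings = Inf,
                          max_retry = 50L) {
  stopifnot(is_molecule(parent_a), is_molecule(parent_b))
  if (ring_count(parent_a) < 2L || ring_count(parent_b) < 2L) return(NULL)
  for (try in seq_len(max_retry)) {
    ca <- cut_molecule(parent_a)
    cb <- cut_molecule(parent_b)
    # random pairing of fragments
    if (stats::runif(1) < 0.5) {
      pair <- list(list(ca$a, cb$a), list(ca$b, cb$b))
    } else {
      pair <- list(list(ca$a, cb$b), list(ca$b, cb$a))
    }
    sizes <- vapply(pair, function(p) length(p[[1L]]$cells) + length(p[[2L]]$cells), numeric(1))
    if (any(sizes < min_rings) || any(sizes > max_rings)) next
    kids <- lapply(pair, function(p) fuse_random(as_fragment(p[[1L]]), as_fragment(p[[2L]])))
    if (any(vapply(kids, is.null, logical(1)))) next
    return(kids)
  }
  NULL
}

#' @rdname operators
#' @export
mol_recombination <- function(mol, max_retry = 50L) {
  stopifnot(is_molecule(mol))
  if (ring_count(mol) < 2L) return(mol)
  for (try in seq_len(max_retry)) {
    cut <- cut_molecule(mol)
    out <- fuse_random(as_fragment(cut$a), as_fragment(cut$b))
    if (!is.null(out)) return(out)
  }
  mol
}

# ---- mutation ---------------------------------------------------------------

# parse a single-atom aromatic SMARTS primitive into an element/H constraint
parse_atom_smarts <- function(pattern) {
  body <- gsub("^\\[|\\]$", "", pattern)
  if (grepl("^c(H1?)?$", body)) {
    list(elem = "C", pattern = pattern)
  } else if (grepl("^n(H0)?$", body)) {
    list(elem = "N", pattern = pattern)
  } else {
    abort(sprintf(
      "unsupported SMARTS '%s': this package matches single aromatic atom patterns (c, n, [cH], [nH0])",
      pattern
    ))
  }
}

# positions (among substitutable CH/N perimeter sites) matched by a pattern
match_positions <- function(positions, nitro, pat) {
  if (pat$elem == "C") positions[!(positions %in% nitro)] else positions[positions %in% nitro]
}

#' @rdname operators
#' @export
mol_mutation <- function(mol, smarts, max_retry = 50L) {
  stopifnot(is_molecule(mol), is.character(smarts), length(smarts) >= 1L)
  pats <- lapply(smarts, parse_atom_smarts)
  vc <- hex_vertex_counts(mol$cells)
  positions <- vc$vertex[vc$count == 1L]
  res <- mutate_pattern(positions, mol$nitro, pats, max_retry)
  if (is.null(res)) return(mol)
  new_molecule(mol$cells, res)
}

# one mutation step on a raw nitrogen set; returns the new set or NULL when
# no legal replacement was drawn.  Used directly by the fast
# initial-population loop, which defers canonicalisation.
mutate_pattern <- function(positions, nitro, pats, max_retry = 50L) {
  for (try in seq_len(max_retry)) {
    hits <- lapply(pats, function(p) match_positions(positions, nitro, p))
    n_hits <- vapply(hits, length, integer(1))
    if (sum(n_hits) == 0L) return(NULL)
    pick <- sample.int(sum(n_hits), 1L)
    pi <- findInterval(pick - 1L, cumsum(c(0L, n_hits)), rightmost.closed = FALSE)
    site <- hits[[pi]][pick - c(0L, cumsum(n_hits))[pi]]
    repl <- pats[-pi]
    if (length(repl) == 0L) return(NULL)
    to <- resample1(repl)
    if (to$elem == parse_atom_smarts(pats[[pi]]$pattern)$elem) next
    if (to$elem == "N") {
      if (site %in% nitro) next
      return(c(nitro, site))
    } else {
      if (!(site %in% nitro)) next
      return(nitro[nitro != site])
    }
  }
  NULL
}
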