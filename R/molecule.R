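#' Molecules as fused aromatic ring systems
#'
#' An `azc_mol` is a cata- or peri-fused system of six-membered aromatic
#' rings whose heavy atoms are carbon or (pyridine-type) nitrogen.  Rings
#' are cells of an integer hexagonal lattice and atoms are cell vertices,
#' which makes molecular identity exact: two molecules are the same
#' compound if and only if their canonical lattice forms coincide.  The
#' canonical form is the minimum over the twelve lattice point-group
#' operations (six rotations, with and without reflection) followed by a
#' translation; nitrogen patterns are tie-broken by their position bitmask.
#'
#' Nitrogens are only allowed at perimeter CH positions (a ring-fusion
#' carbon bears no hydrogen and an aza nitrogen there would be a charged
#' bridgehead).
#'
#' @param smiles A SMILES string using aromatic atoms (`c`, `n`, optionally
#'   bracketed as `[cH]`/`[nH0]`), ring-closure digits and branches.  Bond
#'   symbols other than the aromatic `:` are rejected: every bond of these
#'   molecules is an aromatic ring bond.
#' @return `parse_molecule()` returns an `azc_mol` object in canonical form.
#' @examples
#' m <- parse_molecule("c1ccc2ccccc2c1")   # naphthalene
#' ring_count(m)
#' canonical_key(parse_molecule("c1ccnnc1")) == canonical_key(parse_molecule("c1cnncc1"))
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- parse_smiles_graph(smiles)
  emb <- embed_ring_graph(g$elem, g$edges)
  new_molecule(emb$cells, emb$nitro)
}

# construct + validate + canonicalise
new_molecule <- function(cells, nitro = complex(0)) {
  cells <- unique(cells)
  if (length(cells) < 1L) abort("a molecule needs at least one ring")
  if (!hex_connected(cells)) abort("rings do not form a connected fused system")
  vc <- hex_vertex_counts(cells)
  if (any(vc$count > 3L)) abort("invalid ring arrangement")
  nitro <- unique(nitro)
  if (length(nitro)) {
    sub <- vc$vertex[vc$count == 1L]
    if (!all(nitro %in% sub)) {
      abort("nitrogen at a ring-fusion position is not a valid aza-substitution")
    }
  }
  cf <- canonical_form(cells, nitro)
  structure(list(cells = cf$cells, nitro = cf$nitro), class = "azc_mol")
}

# minimum over the 12 point-group operations + translation; ties between
# operations that fix the cell set are broken by the nitrogen bitmask over
# the lexicographically sorted substitutable positions
canonical_form <- function(cells, nitro) {
  best_key <- NULL
  best <- list()
  for (r in seq_len(12L)) {
    cc <- hex_op_r(cells, r)
    shift <- cc[hex_order(cc)[1L]]
    cc <- hex_sort(cc - shift)
    key <- hex_key(cc)
    if (is.null(best_key) || key < best_key) {
      best_key <- key
      best <- list(list(cells = cc, r = r, shift = shift))
    } else if (key == best_key) {
      best <- c(best, list(list(cells = cc, r = r, shift = shift)))
    }
  }
  cells_c <- best[[1L]]$cells
  if (!length(nitro)) return(list(cells = cells_c, nitro = complex(0)))
  vc <- hex_vertex_counts(cells_c)
  pos <- hex_sort(vc$vertex[vc$count == 1L])
  best_bm <- Inf
  best_nn <- NULL
  for (b in best) {
    nn <- hex_op_r(nitro, b$r) - b$shift
    ranks <- match(nn, pos)
    bm <- sum(2^(ranks - 1))
    if (bm < best_bm) {
      best_bm <- bm
      best_nn <- pos[sort(ranks)]
    }
  }
  list(cells = cells_c, nitro = best_nn)
}

is_molecule <- function(x) inherits(x, "azc_mol")

#' @rdname parse_molecule
#' @param mol,x An `azc_mol` object.
#' @export
ring_count <- function(mol) length(mol$cells)

#' @rdname parse_molecule
#' @export
n_nitrogens <- function(mol) length(mol$nitro)

#' Degree of non-linearity of a fused ring system
#'
#' Counts, over all rings fused to two or more neighbours, the pairs of
#' fusion bonds that are not in the para (opposite, linear) arrangement.
#' An unbranched linear acene scores 0; each angular ring junction adds 1;
#' a branch ring with three neighbours adds 3 (its fusion bonds are
#' pairwise non-opposite).
#'
#' @inheritParams parse_molecule
#' @return Integer scalar (0 for a linear acene).
#' @examples
#' nonlinearity_degree(parse_molecule("c1ccc2cc3ccccc3cc2c1"))  # anthracene: 0
#' nonlinearity_degree(parse_molecule("c1ccc2ccc3ccccc3c2c1"))  # phenanthrene: 1
#' @export
nonlinearity_degree <- function(mol) {
  cells <- mol$cells
  deg <- 0L
  for (i in seq_along(cells)) {
    dirs <- cells[cells %in% (cells[i] + .hex_nb)] - cells[i]
    nd <- length(dirs)
    if (nd < 2L) next
    for (a in seq_len(nd - 1L)) {
      for (b in seq((a + 1L), nd)) {
        if (dirs[a] != -dirs[b]) deg <- deg + 1L
      }
    }
  }
  deg
}

#' @rdname parse_molecule
#' @export
is_cata_fused <- function(mol) {
  max(hex_vertex_counts(mol$cells)$count) <= 2L
}

#' Canonical identity and serialisation
#'
#' `canonical_key()` returns the canonical aromatic SMILES of a molecule,
#' written deterministically from its canonical lattice form: identical for
#' any two representations of the same compound, distinct otherwise.
#' `to_smiles()` is an alias.
#'
#' @inheritParams parse_molecule
#' @return A SMILES string.
#' @export
canonical_key <- function(mol) {
  stopifnot(is_molecule(mol))
  tpl <- smiles_template_cached(mol$cells)
  elem <- ifelse(tpl$atoms %in% mol$nitro, "n", "c")
  render_smiles_template(tpl, matrix(elem, nrow = 1L))
}

# skeleton-keyed memoisation: canonical molecules of the same skeleton share
# one depth-first template
.azc_tpl_cache <- new.env(parent = emptyenv(), hash = TRUE)

smiles_template_cached <- function(cells) {
  key <- hex_key(hex_sort(cells))
  tpl <- get0(key, envir = .azc_tpl_cache, inherits = FALSE)
  if (is.null(tpl)) {
    tpl <- smiles_template(cells)
    assign(key, tpl, envir = .azc_tpl_cache)
  }
  tpl
}

#' @rdname canonical_key
#' @export
to_smiles <- canonical_key

#' @export
print.azc_mol <- function(x, ...) {
  cat(sprintf(
    "<azc_mol> %s  (%d rings, %d N, nonlinearity %d)\n",
    canonical_key(x), ring_count(x), n_nitrogens(x), nonlinearity_degree(x)
  ))
  invisible(x)
}

#' @export
format.azc_mol <- function(x, ...) canonical_key(x)

# ---- SMILES writing ---------------------------------------------------------

# Deterministic depth-first SMILES template for a cell set: atom emission
# order and the punctuation (branches, ring closures) are fixed by the
# sorted-vertex order, so the same template serves every aza-substitution
# pattern of a skeleton.  Returns the sorted atom coordinates, the emission
# order and the string pieces surrounding each emitted atom.
smiles_template <- function(cells) {
  vc <- hex_vertex_counts(cells)
  atoms <- hex_sort(vc$vertex)
  n <- length(atoms)
  ed <- ring_edges(cells, atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(ed))) {
    adj[[ed[r, 1L]]] <- c(adj[[ed[r, 1L]]], ed[r, 2L])
    adj[[ed[r, 2L]]] <- c(adj[[ed[r, 2L]]], ed[r, 1L])
  }
  adj <- lapply(adj, sort)

  visited <- logical(n)
  parent <- integer(n)
  children <- vector("list", n)
  back_from <- vector("list", n)  # back edges recorded at the descendant
  preorder <- integer(0)
  stack <- 1L
  visited[1L] <- TRUE
  # iterative DFS matching the recursive child order
  dfs <- function(a) {
    preorder <<- c(preorder, a)
    for (b in adj[[a]]) {
      if (!visited[b]) {
        visited[b] <<- TRUE
        parent[b] <<- a
        children[[a]] <<- c(children[[a]], b)
        dfs(b)
      } else if (b != parent[a] && !(a %in% back_from[[b]])) {
        back_from[[a]] <<- c(back_from[[a]], b)
      }
    }
  }
  dfs(1L)

  # ring-closure digits in order of the ancestor's emission
  pre_rank <- integer(n)
  pre_rank[preorder] <- seq_len(n)
  be <- list()
  for (a in seq_len(n)) {
    for (b in back_from[[a]]) be <- c(be, list(c(a, b)))
  }
  if (length(be)) {
    anc <- vapply(be, function(e) min(pre_rank[e]), numeric(1))
    dsc <- vapply(be, function(e) max(pre_rank[e]), numeric(1))
    be <- be[order(anc, dsc)]
  }
  digits <- vector("list", n)
  for (d in seq_along(be)) {
    tag <- if (d <= 9L) as.character(d) else paste0("%", d)
    for (a in be[[d]]) digits[[a]] <- c(digits[[a]], tag)
  }

  pieces <- character(0)
  order_out <- integer(0)
  cur <- ""
  emit <- function(a) {
    pieces <<- c(pieces, cur)
    cur <<- paste0(digits[[a]], collapse = "")
    order_out <<- c(order_out, a)
    kids <- children[[a]]
    nk <- length(kids)
    for (i in seq_len(nk)) {
      if (i < nk) {
        cur <<- paste0(cur, "(")
        emit(kids[i])
        cur <<- paste0(cur, ")")
      } else {
        emit(kids[i])
      }
    }
  }
  emit(1L)
  pieces <- c(pieces, cur)  # n + 1 pieces around n atom slots
  list(atoms = atoms[order_out], order = order_out, pieces = pieces)
}

# fill a template with one element row per molecule; elem is a matrix with
# one column per emitted atom (in template order)
render_smiles_template <- function(tpl, elem) {
  n <- ncol(elem)
  args <- vector("list", 2L * n + 1L)
  args[[1L]] <- tpl$pieces[1L]
  for (i in seq_len(n)) {
    args[[2L * i]] <- elem[, i]
    args[[2L * i + 1L]] <- tpl$pieces[i + 1L]
  }
  do.call(paste0, args)
}

# undirected bonds between atoms, as index pairs into `atoms`
ring_edges <- function(cells, atoms) {
  n <- length(cells)
  a <- rep(cells, each = 6L) + rep(.hex_vx, times = n)
  b <- rep(cells, each = 6L) + rep(.hex_vx[c(2:6, 1L)], times = n)
  ia <- match(a, atoms)
  ib <- match(b, atoms)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  unique(cbind(lo, hi))
}

# ---- SMILES parsing ---------------------------------------------------------

# Restricted aromatic SMILES reader: atoms c/n (optionally bracketed with an
# H count), digits and %nn ring closures, branches, aromatic ':' bonds.
parse_smiles_graph <- function(smiles) {
  chars <- strsplit(smiles, "")[[1L]]
  elem <- character(0)
  edges <- matrix(integer(0), ncol = 2L)
  prev_stack <- integer(0)
  prev <- 0L
  ring_open <- list()
  i <- 1L
  add_edge <- function(a, b) edges <<- rbind(edges, c(min(a, b), max(a, b)))
  add_atom <- function(e) {
    elem <<- c(elem, e)
    id <- length(elem)
    if (prev > 0L) add_edge(prev, id)
    prev <<- id
  }
  n_ch <- length(chars)
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch %in% c("c", "n")) {
      add_atom(toupper(ch))
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n_ch && chars[j] != "]") j <- j + 1L
      if (j > n_ch) abort("unterminated bracket atom in SMILES")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^(c|n)(H[0-9]?)?$", body)) {
        abort(sprintf("unsupported atom '[%s]': only aromatic C/N molecules are handled", body))
      }
      add_atom(toupper(substr(body, 1L, 1L)))
      i <- j + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        tag <- paste0(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        tag <- ch
        i <- i + 1L
      }
      if (is.null(ring_open[[tag]])) {
        ring_open[[tag]] <- prev
      } else {
        add_edge(ring_open[[tag]], prev)
        ring_open[[tag]] <- NULL
      }
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == ":") {
      i <- i + 1L
    } else if (ch %in% c("C", "N", "=", "#", "-", "/", "\\")) {
      abort(sprintf(
        "'%s' in SMILES: only fully aromatic c/n ring systems are in scope", ch
      ))
    } else {
      abort(sprintf("unexpected character '%s' in SMILES", ch))
    }
  }
  if (length(Filter(Negate(is.null), ring_open))) abort("unclosed ring bond in SMILES")
  if (length(elem) == 0L) abort("empty SMILES")
  list(elem = elem, edges = edges)
}

# all distinct 6-cycles of the bond graph, in cycle order
find_hex_rings <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
    adj[[edges[r, 2L]]] <- c(adj[[edges[r, 2L]]], edges[r, 1L])
  }
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    a <- path[length(path)]
    for (b in adj[[a]]) {
      if (length(path) == 6L) {
        if (b == path[1L]) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1L]] <<- path
          }
        }
      } else if (!(b %in% path) && b > path[1L]) {
        walk(c(path, b))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  rings
}

# lift a parsed C/N ring graph onto the hexagonal lattice
embed_ring_graph <- function(elem, edges) {
  n <- length(elem)
  rings <- find_hex_rings(n, edges)
  nr <- length(rings)
  if (nr == 0L) abort("no six-membered ring found: molecule is outside the space")
  if (nr != nrow(edges) - n + 1L) {
    abort("ring system is not a simply fused set of six-membered rings")
  }
  in_ring <- sort(unique(unlist(rings)))
  if (!identical(in_ring, seq_len(n))) {
    abort("every atom must belong to a six-membered aromatic ring")
  }

  pos <- rep(NA_complex_, n)
  cellpos <- rep(NA_complex_, nr)
  pos[rings[[1L]]] <- .hex_vx
  cellpos[1L] <- 0 + 0i
  placed <- 1L
  repeat {
    progressed <- FALSE
    for (s in seq_len(nr)) {
      if (s %in% placed) next
      cyc <- rings[[s]]
      # need a placed bond of this ring
      hit <- NULL
      for (t in seq_len(6L)) {
        u <- cyc[t]
        v <- cyc[if (t == 6L) 1L else t + 1L]
        if (!is.na(pos[u]) && !is.na(pos[v])) {
          # identify which placed ring owns this bond to find the far cell
          for (r in placed) {
            if (u %in% rings[[r]] && v %in% rings[[r]]) {
              hit <- list(u = u, v = v, r = r)
              break
            }
          }
          if (!is.null(hit)) break
        }
      }
      if (is.null(hit)) next
      cell_s <- pos[hit$u] + pos[hit$v] - cellpos[hit$r]
      if (cell_s %in% cellpos[placed]) {
        abort("overlapping rings: molecule cannot be drawn as a planar fused system")
      }
      hexv <- cell_s + .hex_vx
      iu <- which(hexv == pos[hit$u])
      iv <- which(hexv == pos[hit$v])
      tu <- which(cyc == hit$u)
      step_c <- if (cyc[if (tu == 6L) 1L else tu + 1L] == hit$v) 1L else -1L
      step_h <- if ((iu %% 6L) + 1L == iv) 1L else -1L
      for (t in 0:5) {
        a <- cyc[((tu - 1L + step_c * t) %% 6L) + 1L]
        p <- hexv[((iu - 1L + step_h * t) %% 6L) + 1L]
        if (!is.na(pos[a]) && pos[a] != p) {
          abort("inconsistent ring fusion: molecule cannot be embedded")
        }
        pos[a] <- p
      }
      cellpos[s] <- cell_s
      placed <- c(placed, s)
      progressed <- TRUE
    }
    if (length(placed) == nr) break
    if (!progressed) abort("disconnected or inconsistent ring system")
  }
  if (anyNA(pos)) abort("unplaced atoms: invalid ring system")
  if (anyDuplicated(pos)) {
    abort("two atoms fall on the same lattice point: molecule cannot be drawn as a planar fused system")
  }
  # every bond must be a lattice edge
  d <- pos[edges[, 1L]] - pos[edges[, 2L]]
  if (!all(d %in% c(2 + 0i, -2 + 0i, 1 + 1i, -1 - 1i, 1 - 1i, -1 + 1i))) {
    abort("bond inconsistent with a fused hexagonal ring system")
  }
  list(cells = cellpos, nitro = pos[elem == "N"])
}
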