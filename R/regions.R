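#' Concave perimeter regions of a fused ring system
#'
#' Classifies every concave span of the molecular perimeter by the number of
#' consecutive perimeter atoms it comprises: a *bay* spans 4 atoms (as in
#' phenanthrene), a *cove* 5 (as in benzo[c]phenanthrene) and a *fjord* 6
#' (as in pentahelicene).  Shallow 3-atom fissures (the notch of a linear
#' acene) are not reported: they are a normal feature of any fused system.
#'
#' Internally a concave span is found as an empty lattice cell whose
#' occupied neighbours form a contiguous arc of k >= 2 cells; the span then
#' covers the k + 1 perimeter atoms facing that cell.  Placing a new ring on
#' such a cell is exactly the "filling" move that creates pyrene-like
#' peri-fused arrangements, which is why additions into these regions can be
#' forbidden in a [space_definition()].
#'
#' @inheritParams canonical_key
#' @return A tibble with one row per region: `kind` (`"bay"`, `"cove"` or
#'   `"fjord"`) and `atoms`, a list column of perimeter atom indices into
#'   the canonical atom ordering (sorted lattice vertices).
#' @examples
#' classify_fusion_regions(parse_molecule("c1ccc2cc3ccccc3cc2c1"))  # anthracene: none
#' classify_fusion_regions(parse_molecule("c1ccc2ccc3ccccc3c2c1"))  # phenanthrene: one bay
#' @export
classify_fusion_regions <- function(mol) {
  stopifnot(is_molecule(mol))
  fills <- region_fills(mol$cells)
  fills <- fills[vapply(fills, function(f) f$kind != "fissure", logical(1))]
  atoms <- hex_sort(hex_vertex_counts(mol$cells)$vertex)
  tibble(
    kind = vapply(fills, function(f) f$kind, character(1)),
    atoms = lapply(fills, function(f) sort(match(f$span, atoms)))
  )
}

# All concave spans (including fissures), each described by the empty fill
# cell, the arc of occupied neighbour directions and the span vertices.
region_fills <- function(cells) {
  empties <- setdiff(unique(rep(cells, each = 6L) + rep(.hex_nb, times = length(cells))), cells)
  out <- list()
  for (e in empties) {
    occ <- (e + .hex_nb) %in% cells
    if (sum(occ) < 2L) next
    # maximal cyclic runs of occupied directions
    runs <- cyclic_runs(occ)
    for (run in runs) {
      k <- length(run)
      if (k < 2L) next
      kind <- switch(as.character(k + 1L),
        "3" = "fissure", "4" = "bay", "5" = "cove", "6" = "fjord",
        "enclosed"
      )
      # span vertices: vertex j of the empty cell touches directions j-1 and
      # j, so the arc d..d+k-1 exposes vertices d..d+k
      span <- e + .hex_vx[unique(((run[1L]:(run[1L] + k)) - 1L) %% 6L + 1L)]
      out[[length(out) + 1L]] <- list(cell = e, kind = kind, k = k, span = span)
    }
  }
  out
}

# maximal runs of TRUE in a cyclic logical vector of length 6, as lists of
# direction indices
cyclic_runs <- function(occ) {
  if (all(occ)) return(list(1:6))
  if (!any(occ)) return(list())
  # rotate so position 1 is FALSE
  start <- which(!occ)[1L]
  idx <- ((start - 1L + 1:6 - 1L) %% 6L) + 1L
  runs <- list()
  cur <- integer(0)
  for (j in idx) {
    if (occ[j]) {
      cur <- c(cur, j)
    } else if (length(cur)) {
      runs <- c(runs, list(cur))
      cur <- integer(0)
    }
  }
  if (length(cur)) runs <- c(runs, list(cur))
  runs
}

# region kind used for exclusion decisions: 3-atom fissures behave like bays
# (filling either produces pyrene-type peri-fusion)
exclusion_kind <- function(kind) {
  if (kind == "fissure") "bay" else kind
}
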