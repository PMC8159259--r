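#' Define a searchable region of chemical space
#'
#' A space definition fixes what the evolutionary search may build: the
#' SMILES building blocks, the SMARTS mutation list, the allowed molecule
#' size in rings, and which concave fusion regions may not receive new
#' rings.  The default arguments describe the aza-acene space used
#' throughout the package: five fused six-membered aromatic rings, any
#' number of aza substitutions, and no additions into bay, cove or fjord
#' regions (so every molecule stays cata-fused).
#'
#' @param smiles Character vector of building-block SMILES.
#' @param smarts Character vector of mutation SMARTS (see [mol_mutation()]
#'   for the supported single-atom dialect).
#' @param molsize_min,molsize_max Ring-count bounds (inclusive).
#' @param forbid_fusion_regions Subset of `c("bay", "cove", "fjord")`.
#' @return An object of class `azc_space`.
#' @examples
#' sp <- space_definition()
#' sp
#' @export
space_definition <- function(smiles = c("c1ccccc1", "c1ccncc1"),
                             smarts = c("[cH]", "n"),
                             molsize_min = 5L, molsize_max = 5L,
                             forbid_fusion_regions = c("bay", "cove", "fjord")) {
  stopifnot(
    is.character(smiles), length(smiles) >= 1L,
    is.character(smarts),
    is_count(molsize_min), is_count(molsize_max),
    molsize_min <= molsize_max
  )
  if (length(forbid_fusion_regions)) {
    forbid_fusion_regions <- match.arg(
      forbid_fusion_regions, c("bay", "cove", "fjord"), several.ok = TRUE
    )
  } else {
    forbid_fusion_regions <- character(0)
  }
  mols <- lapply(smiles, parse_molecule)
  pats <- lapply(smarts, parse_atom_smarts)
  structure(
    list(
      smiles = smiles, smarts = smarts,
      molsize_min = as.integer(molsize_min), molsize_max = as.integer(molsize_max),
      forbid_fusion_regions = forbid_fusion_regions,
      mols = mols, pats = pats
    ),
    class = "azc_space"
  )
}

#' @export
print.azc_space <- function(x, ...) {
  cat("<azc_space>\n")
  cat("  building blocks:", paste(x$smiles, collapse = ", "), "\n")
  cat("  mutation smarts:", paste(x$smarts, collapse = ", "), "\n")
  cat(sprintf("  molecule size: %d-%d rings\n", x$molsize_min, x$molsize_max))
  cat("  forbidden regions:",
      if (length(x$forbid_fusion_regions)) paste(x$forbid_fusion_regions, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Read a space definition from a YAML or JSON file
#'
#' The file mirrors the fields of [space_definition()]: `smiles`, `smarts`,
#' `molsize_min`, `molsize_max`, `forbid_fusion_regions`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `azc_space`.
#' @export
read_space <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  space_definition(
    smiles = as.character(cfg$smiles),
    smarts = as.character(cfg$smarts %||% c("[cH]", "n")),
    molsize_min = cfg$molsize_min %||% 5L,
    molsize_max = cfg$molsize_max %||% 5L,
    forbid_fusion_regions = as.character(cfg$forbid_fusion_regions %||% c("bay", "cove", "fjord"))
  )
}

#' Draw a random molecule from a space
#'
#' Reproduces the initial-population randomisation: a random building block
#' is grown by repeated addition of random fragments until a target ring
#' count (drawn uniformly within the size bounds) is reached, then a large
#' number of mutation operations scrambles the substitution pattern.
#'
#' @param space An `azc_space`.
#' @param init_mutations Number of mutation steps applied after growth
#'   (default 500).
#' @return An `azc_mol` inside the space.
#' @export
random_molecule <- function(space, init_mutations = 500L) {
  stopifnot(inherits(space, "azc_space"))
  repeat {
    mol <- resample1(space$mols)
    target <- if (space$molsize_min == space$molsize_max) space$molsize_min else
      sample(space$molsize_min:space$molsize_max, 1L)
    ok <- TRUE
    while (ring_count(mol) < target) {
      frag <- resample1(space$mols)
      if (ring_count(mol) + ring_count(frag) > target) {
        # no fragment small enough to finish exactly: retry the build
        if (all(vapply(space$mols, ring_count, integer(1)) + ring_count(mol) > target)) {
          ok <- FALSE
          break
        }
        next
      }
      nxt <- mol_addition(mol, frag, forbid = space$forbid_fusion_regions,
                          max_rings = target)
      if (is.null(nxt)) {
        ok <- FALSE
        break
      }
      mol <- nxt
    }
    if (!ok) next
    # deferred-canonicalisation mutation walk
    vc <- hex_vertex_counts(mol$cells)
    positions <- vc$vertex[vc$count == 1L]
    nitro <- mol$nitro
    elems <- vapply(space$pats, `[[`, character(1), "elem")
    if (length(space$pats) == 2L && setequal(elems, c("C", "N"))) {
      # two-entry CH <-> N list: every position matches exactly one pattern
      # and the only replacement is the opposite element, so each step is a
      # uniform single-site flip
      mask <- positions %in% nitro
      sites <- sample.int(length(positions), init_mutations, replace = TRUE)
      for (i in sites) mask[i] <- !mask[i]
      nitro <- positions[mask]
    } else {
      for (i in seq_len(init_mutations)) {
        res <- mutate_pattern(positions, nitro, space$pats)
        if (!is.null(res)) nitro <- res
      }
    }
    return(new_molecule(mol$cells, nitro))
  }
}

#' Exhaustively enumerate a chemical space
#'
#' Grows every allowed ring skeleton by exhaustive region-respecting
#' addition from a single ring, then counts all CH to N substitution
#' patterns per skeleton, deduplicated under the skeleton's lattice
#' symmetry group (verified internally against the Burnside orbit count).
#'
#' Two counting conventions are exposed.  With `complement_paired = TRUE`
#' (the default) each substitution pattern is paired with its full CH/N
#' complement and the pair is counted once; this is the convention under
#' which the five-ring aza-acene space contains 68,064 entries.  With
#' `complement_paired = FALSE` every distinct molecular graph is its own
#' entry (135,744 for the same space).
#'
#' @param space An `azc_space` with finite size bounds.
#' @param complement_paired Count each pattern/complement pair once?
#' @return A tibble with one row per space entry: `canonical_key`,
#'   `skeleton` (canonical skeleton SMILES), `n_rings`, `n_nitrogens`,
#'   `nonlinearity_degree` and, when paired, `complement_key`.
#' @examples
#' sp1 <- space_definition(smiles = "c1ccccc1", molsize_min = 1, molsize_max = 1)
#' nrow(enumerate_space(sp1, complement_paired = FALSE))  # benzene + 12 azines
#' @export
enumerate_space <- function(space, complement_paired = TRUE) {
  stopifnot(inherits(space, "azc_space"))
  if (!is.finite(space$molsize_max)) abort("refusing to enumerate an unbounded space")
  skels <- enumerate_skeletons(space$molsize_max, space$forbid_fusion_regions)
  keep <- vapply(skels, length, integer(1)) >= space$molsize_min
  skels <- skels[keep]
  rows <- lapply(skels, function(cells) skeleton_patterns(cells, complement_paired))
  out <- dplyr::bind_rows(rows)
  out[order(out$skeleton, out$pattern_id), setdiff(names(out), "pattern_id")]
}

# all canonical skeleton cell sets with <= max_rings rings, grown by
# region-respecting single-ring addition
enumerate_skeletons <- function(max_rings, forbid) {
  level <- list(canonical_form(0 + 0i, complex(0))$cells)
  all_sk <- level
  benzene <- structure(list(cells = 0 + 0i, nitro = complex(0)), class = "azc_mol")
  for (h in seq_len(max_rings - 1L)) {
    nxt <- new.env(parent = emptyenv())
    for (cells in level) {
      mol <- structure(list(cells = cells, nitro = complex(0)), class = "azc_mol")
      pl <- addition_placements(mol, benzene, forbid)
      for (p in pl) {
        cc <- canonical_form(p$cells, complex(0))$cells
        assign(hex_key(cc), cc, envir = nxt)
      }
    }
    level <- unname(as.list(nxt))
    level <- level[order(vapply(level, hex_key, character(1)))]
    all_sk <- c(all_sk, level)
  }
  all_sk
}

# every substitution-pattern class of one skeleton, as tibble rows
skeleton_patterns <- function(cells, complement_paired) {
  vc <- hex_vertex_counts(cells)
  pos <- hex_sort(vc$vertex[vc$count == 1L])
  k <- length(pos)
  if (k > 20L) abort("skeleton has too many substitutable positions to enumerate")
  perms <- skeleton_stabilizer_perms(cells, pos)

  ids <- 0:(2^k - 1L)
  bits <- matrix(FALSE, nrow = length(ids), ncol = k)
  for (q in seq_len(k)) bits[, q] <- bitwAnd(ids, 2^(q - 1L)) > 0L
  canon <- rep(Inf, length(ids))
  for (perm in perms) {
    w <- 2^(perm - 1L)
    canon <- pmin(canon, as.vector(bits %*% w))
  }
  # Burnside cross-check of the orbit count
  n_orbit <- length(unique(canon))
  fixed <- vapply(perms, function(perm) 2^n_perm_cycles(perm), numeric(1))
  if (n_orbit != round(sum(fixed) / length(perms))) {
    abort("internal error: orbit count disagrees with the Burnside count")
  }

  if (complement_paired) {
    full <- 2^k - 1L
    pair_rep <- pmin(canon, canon[full - ids + 1L])
    reps <- sort(unique(pair_rep))
    comp_of <- canon[full - reps + 1L]
  } else {
    reps <- sort(unique(canon))
    comp_of <- NULL
  }

  tpl <- smiles_template(cells)
  pos_of_atom <- match(tpl$atoms, pos)  # NA for fusion carbons
  elem_rows <- function(idv) {
    E <- matrix("c", nrow = length(idv), ncol = length(tpl$atoms))
    for (a in seq_along(tpl$atoms)) {
      q <- pos_of_atom[a]
      if (!is.na(q)) E[bitwAnd(idv, 2^(q - 1L)) > 0L, a] <- "n"
    }
    E
  }
  smi <- render_smiles_template(tpl, elem_rows(reps))
  popcount <- function(idv) {
    n <- integer(length(idv))
    for (q in seq_len(k)) n <- n + (bitwAnd(idv, 2^(q - 1L)) > 0L)
    n
  }
  nonlin <- nonlinearity_degree(structure(list(cells = cells, nitro = complex(0)),
                                          class = "azc_mol"))
  sk_smi <- render_smiles_template(tpl, matrix("c", nrow = 1L, ncol = length(tpl$atoms)))
  out <- tibble(
    canonical_key = smi,
    skeleton = sk_smi,
    n_rings = length(cells),
    n_nitrogens = popcount(reps),
    nonlinearity_degree = nonlin,
    pattern_id = reps
  )
  if (complement_paired) {
    out$complement_key <- render_smiles_template(tpl, elem_rows(comp_of))
  }
  out
}

# permutations of the substitutable positions induced by the lattice
# operations that fix the (canonical) skeleton
skeleton_stabilizer_perms <- function(cells, pos) {
  perms <- list()
  for (r in seq_len(12L)) {
    cc <- hex_op_r(cells, r)
    shift <- cc[hex_order(cc)[1L]]
    cc <- hex_sort(cc - shift)
    if (hex_key(cc) != hex_key(hex_sort(cells))) next
    pp <- hex_op_r(pos, r) - shift
    perms[[length(perms) + 1L]] <- match(pp, pos)
  }
  perms
}

n_perm_cycles <- function(perm) {
  n <- length(perm)
  seen <- logical(n)
  cyc <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      cyc <- cyc + 1L
      j <- i
      while (!seen[j]) {
        seen[j] <- TRUE
        j <- perm[j]
      }
    }
  }
  cyc
}

#' Population descriptors for molecules
#'
#' Tabulates the descriptors used to follow the chemistry of an evolving
#' population: nitrogen count and degree of non-linearity.
#'
#' @param x A character vector of SMILES, a list of `azc_mol` objects, or a
#'   data frame with a `mol` (list of `azc_mol`) or `smiles` column.
#' @return A tibble with columns `canonical_key`, `n_rings`,
#'   `n_nitrogens`, `nonlinearity_degree`.
#' @export
describe_molecules <- function(x) {
  mols <- if (is.character(x)) {
    lapply(x, parse_molecule)
  } else if (is.data.frame(x)) {
    if (!is.null(x$mol)) x$mol else lapply(x$smiles, parse_molecule)
  } else if (is_molecule(x)) {
    list(x)
  } else {
    stopifnot(is.list(x))
    x
  }
  tibble(
    canonical_key = vapply(mols, canonical_key, character(1)),
    n_rings = vapply(mols, ring_count, integer(1)),
    n_nitrogens = vapply(mols, n_nitrogens, integer(1)),
    nonlinearity_degree = vapply(mols, nonlinearity_degree, integer(1))
  )
}
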