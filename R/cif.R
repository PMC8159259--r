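#' Crystal structures
#'
#' A minimal container for molecular crystals: a 3x3 lattice matrix (rows
#' are the cell vectors a, b, c in ångström) and a list of molecules, each
#' with a site label, element symbols and Cartesian coordinates.  The
#' companion [read_cif()]/[write_cif()] pair covers the small subset of the
#' CIF format the transport workflow needs: cell parameters, an atom_site
#' loop with fractional coordinates, and (on reading) an optional
#' `symmetry_equiv_pos_as_xyz` loop that is expanded to P1.
#'
#' Atoms are grouped into molecules by the part of `_atom_site_label`
#' before the first underscore (labels like `M1_C1`, `M1_C2`, `M2_C1`);
#' unlabelled files become a single one-molecule site.
#'
#' @param lattice 3x3 numeric matrix, rows = cell vectors (Å).
#' @param sites List of molecules: each a list with `label` (character),
#'   `elements` (character vector) and `coords` (n x 3 matrix, Cartesian Å).
#' @param relative_energy Optional lattice energy above the landscape's
#'   global minimum (kJ/mol).
#' @return An object of class `azc_crystal`.
#' @export
crystal_structure <- function(lattice, sites, relative_energy = NA_real_) {
  lattice <- as.matrix(lattice)
  stopifnot(all(dim(lattice) == c(3L, 3L)), det(lattice) > 0)
  for (s in sites) {
    stopifnot(is.character(s$label), is.character(s$elements),
              nrow(s$coords) == length(s$elements), ncol(s$coords) == 3L)
  }
  structure(
    list(lattice = lattice, sites = sites, relative_energy = relative_energy),
    class = "azc_crystal"
  )
}

#' @export
print.azc_crystal <- function(x, ...) {
  cat(sprintf(
    "<azc_crystal> %d molecule site(s), %d atoms, cell volume %.1f A^3\n",
    length(x$sites), sum(vapply(x$sites, function(s) length(s$elements), integer(1))),
    det(x$lattice)
  ))
  invisible(x)
}

lattice_from_parameters <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(c^2 - cx^2 - cy^2)
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

#' @rdname crystal_structure
#' @param path Path to a CIF file.
#' @export
read_cif <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  val <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) abort(sprintf("CIF item %s missing", tag))
    as.numeric(sub("\\(.*\\)", "", strsplit(hit[1L], "\\s+")[[1L]][2L]))
  }
  lat <- lattice_from_parameters(
    val("_cell_length_a"), val("_cell_length_b"), val("_cell_length_c"),
    val("_cell_angle_alpha"), val("_cell_angle_beta"), val("_cell_angle_gamma")
  )

  # collect loops
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "loop_") {
      hdr <- character(0)
      i <- i + 1L
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        hdr <- c(hdr, strsplit(lines[i], "\\s+")[[1L]][1L])
        i <- i + 1L
      }
      body <- character(0)
      while (i <= length(lines) && !startsWith(lines[i], "_") && lines[i] != "loop_") {
        body <- c(body, lines[i])
        i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(header = hdr, body = body)
    } else {
      i <- i + 1L
    }
  }

  # symmetry operators (default P1)
  symops <- "x,y,z"
  for (lp in loops) {
    hit <- grep("symmetry_equiv_pos_as_xyz|space_group_symop_operation_xyz", lp$header)
    if (length(hit)) {
      raw <- gsub("^[0-9]+\\s+", "", lp$body)
      symops <- gsub("'|\"", "", raw)
    }
  }

  atoms <- NULL
  for (lp in loops) {
    if (any(grepl("^_atom_site_label$", lp$header))) {
      parts <- strsplit(lp$body, "\\s+")
      get_col <- function(tag) {
        j <- match(tag, lp$header)
        vapply(parts, `[[`, character(1), j)
      }
      atoms <- tibble(
        label = get_col("_atom_site_label"),
        element = if ("_atom_site_type_symbol" %in% lp$header) {
          get_col("_atom_site_type_symbol")
        } else {
          gsub("[0-9_].*$", "", get_col("_atom_site_label"))
        },
        fx = as.numeric(sub("\\(.*\\)", "", get_col("_atom_site_fract_x"))),
        fy = as.numeric(sub("\\(.*\\)", "", get_col("_atom_site_fract_y"))),
        fz = as.numeric(sub("\\(.*\\)", "", get_col("_atom_site_fract_z")))
      )
    }
  }
  if (is.null(atoms)) abort("no _atom_site loop found in CIF")

  # P1 expansion
  frac <- as.matrix(atoms[, c("fx", "fy", "fz")])
  all_frac <- list()
  all_lab <- character(0)
  all_el <- character(0)
  for (op in symops) {
    f2 <- t(apply(frac, 1L, apply_symop, op = op))
    f2 <- f2 - floor(f2)
    all_frac[[length(all_frac) + 1L]] <- f2
    all_lab <- c(all_lab, atoms$label)
    all_el <- c(all_el, atoms$element)
  }
  frac_all <- do.call(rbind, all_frac)
  # deduplicate symmetry-equivalent atoms
  key <- paste(all_lab, round(frac_all[, 1L], 4L), round(frac_all[, 2L], 4L),
               round(frac_all[, 3L], 4L))
  keep <- !duplicated(key)
  frac_all <- frac_all[keep, , drop = FALSE]
  all_lab <- all_lab[keep]
  all_el <- all_el[keep]

  cart <- frac_all %*% lat
  grp <- ifelse(grepl("_", all_lab), sub("_.*$", "", all_lab), "M1")
  sites <- lapply(unique(grp), function(g) {
    sel <- grp == g
    list(label = g, elements = all_el[sel], coords = cart[sel, , drop = FALSE])
  })
  crystal_structure(lat, sites)
}

apply_symop <- function(xyz, op) {
  env <- list2env(list(x = xyz[1L], y = xyz[2L], z = xyz[3L]))
  parts <- strsplit(op, ",")[[1L]]
  vapply(parts, function(p) eval(parse(text = p), envir = env), numeric(1),
         USE.NAMES = FALSE)
}

#' @rdname crystal_structure
#' @param crystal An `azc_crystal`.
#' @export
write_cif <- function(crystal, path) {
  lat <- crystal$lattice
  a <- sqrt(sum(lat[1L, ]^2)); b <- sqrt(sum(lat[2L, ]^2)); c3 <- sqrt(sum(lat[3L, ]^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  inv <- solve(lat)
  out <- c(
    "data_azacene",
    "_symmetry_space_group_name_H-M 'P 1'",
    sprintf("_cell_length_a %.6f", a),
    sprintf("_cell_length_b %.6f", b),
    sprintf("_cell_length_c %.6f", c3),
    sprintf("_cell_angle_alpha %.6f", ang(lat[2L, ], lat[3L, ])),
    sprintf("_cell_angle_beta %.6f", ang(lat[1L, ], lat[3L, ])),
    sprintf("_cell_angle_gamma %.6f", ang(lat[1L, ], lat[2L, ])),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  )
  for (s in crystal$sites) {
    frac <- s$coords %*% inv
    for (i in seq_along(s$elements)) {
      out <- c(out, sprintf("%s_%s%d %s %.6f %.6f %.6f",
                            s$label, s$elements[i], i, s$elements[i],
                            frac[i, 1L], frac[i, 2L], frac[i, 3L]))
    }
  }
  writeLines(out, path)
  invisible(path)
}
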