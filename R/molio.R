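#' 3D molecule objects and structure file input/output
#'
#' A `mol3d` holds one small molecule as two tibbles: `atoms` (1-based
#' `index`, `element`, Cartesian `x`, `y`, `z` in Angstrom, formal `charge`,
#' perceived `n_hydrogens` and an `is_heavy` flag) and `bonds`
#' (`a1`, `a2`, MDL `order` code where 4 means aromatic). Atom ordinals
#' follow the order of the source MOL block.
#'
#' @param id character label for the molecule.
#' @param atoms tibble with columns `index`, `element`, `x`, `y`, `z` and
#'   optionally `charge`.
#' @param bonds tibble with columns `a1`, `a2`, `order`.
#' @return A `mol3d` object.
#' @export
mol3d <- function(id, atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$index <- as.integer(seq_len(nrow(atoms)))
  atoms$is_heavy <- atoms$element != "H"
  if (nrow(bonds) > 0) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(is.na(idx)) || any(idx < 1L | idx > nrow(atoms))) {
      abort(sprintf("molecule '%s': bond atom index out of range", id))
    }
  }
  bad <- setdiff(unique(atoms$element), known_elements())
  if (length(bad) > 0) {
    abort(sprintf("molecule '%s': unknown element(s) %s", id,
                  paste(bad, collapse = ", ")))
  }
  atoms$n_hydrogens <- perceive_hydrogens(atoms, bonds)
  out <- structure(list(id = id, atoms = atoms, bonds = bonds),
                   class = "mol3d")
  validate_mol3d(out)
  out
}

validate_mol3d <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  bad <- setdiff(unique(atoms$element), known_elements())
  if (length(bad) > 0) {
    abort(sprintf("molecule '%s': unknown element(s) %s", mol$id,
                  paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort(sprintf("molecule '%s': non-finite coordinates", mol$id))
  }
  if (nrow(bonds) > 0) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > nrow(atoms))) {
      abort(sprintf("molecule '%s': bond atom index out of range", mol$id))
    }
    if (any(bonds$a1 == bonds$a2)) {
      abort(sprintf("molecule '%s': bond connecting an atom to itself", mol$id))
    }
  }
  if (any(atoms$n_hydrogens < 0L | atoms$n_hydrogens > 4L)) {
    abort(sprintf("molecule '%s': implausible hydrogen count", mol$id))
  }
  heavy <- atoms$index[atoms$is_heavy]
  if (length(heavy) > 1) {
    g <- heavy_graph(mol)
    if (igraph::components(g)$no != 1L) {
      abort(sprintf("molecule '%s': heavy-atom subgraph is disconnected", mol$id))
    }
  }
  invisible(mol)
}

# Effective bond order of an MDL order code (aromatic counts 1.5).
bond_order_value <- function(code) c(1, 2, 3, 1.5)[code]

# Hydrogen policy: explicit hydrogens in the file are authoritative; when a
# heavy atom's bonded valence falls short of the default valence of the
# neutral (charge-adjusted) element, the difference is filled with implicit
# hydrogens. Hydrogen atoms themselves carry n_hydrogens = 0.
perceive_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  explicit <- integer(n)
  occupied <- numeric(n)
  if (nrow(bonds) > 0) {
    ov <- bond_order_value(bonds$order)
    for (k in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
      occupied[a1] <- occupied[a1] + ov[k]
      occupied[a2] <- occupied[a2] + ov[k]
      if (atoms$element[a2] == "H") explicit[a1] <- explicit[a1] + 1L
      if (atoms$element[a1] == "H") explicit[a2] <- explicit[a2] + 1L
    }
  }
  el <- element_data()
  val <- el$valence[match(atoms$element, el$element)]
  adj <- ifelse(atoms$element %in% c("N", "P", "O", "S"),
                val + atoms$charge,
                ifelse(atoms$element == "C", val - abs(atoms$charge), val))
  implicit <- pmax(0, round(adj - occupied))
  out <- ifelse(atoms$element == "H", 0, explicit + implicit)
  as.integer(out)
}

#' @export
print.mol3d <- function(x, ...) {
  cat(sprintf("<mol3d> %s: %d atoms (%d heavy), %d bonds\n",
              x$id, nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms
#'
#' Invariant to whether hydrogens are represented explicitly or implicitly.
#'
#' @param mol a `mol3d`.
#' @return integer count.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "mol3d"))
  sum(mol$atoms$is_heavy)
}

# igraph over heavy atoms only; vertex names are atom ordinals.
heavy_graph <- function(mol) {
  heavy <- mol$atoms$index[mol$atoms$is_heavy]
  b <- mol$bonds
  if (nrow(b) > 0) {
    keep <- b$a1 %in% heavy & b$a2 %in% heavy
    edges <- as.character(rbind(b$a1[keep], b$a2[keep]))
  } else {
    edges <- character(0)
  }
  igraph::graph_from_data_frame(
    d = matrix(edges, ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("from", "to"))),
    directed = FALSE,
    vertices = data.frame(name = as.character(heavy))
  )
}

#' Read 3D structures from MDL MOL / SDF V2000 input
#'
#' Parses one or more V2000 records into a list of [mol3d()] objects,
#' preserving atom order. Explicit hydrogens are retained as atoms and
#' reflected in the heavy neighbour's `n_hydrogens`; implicit hydrogens are
#' perceived from standard valences. Formal charges are taken from the
#' atom-block charge field.
#'
#' @param input a file path, or SDF/MOL text (detected by embedded newlines).
#' @return list of `mol3d`, named by record title (blank titles become
#'   `mol_<k>`).
#' @export
read_sdf <- function(input) {
  if (length(input) > 1 || grepl("\n", input)) {
    lines <- strsplit(paste(input, collapse = "\n"), "\n")[[1]]
  } else {
    if (!file.exists(input)) abort(sprintf("file not found: %s", input))
    lines <- readLines(input, warn = FALSE)
  }
  if (all(trimws(lines) == "")) return(list())
  # transport only: make sure the last record carries an SDF terminator
  nonblank <- lines[trimws(lines) != ""]
  if (tail1(nonblank) != "$$$$") lines <- c(lines, "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp, skipErrors = FALSE)
  titles <- as.character(ChemmineR::sdfid(sdfset))
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    id <- trimws(titles[k])
    if (is.na(id) || id == "") id <- sprintf("mol_%d", k)
    out[[k]] <- tryCatch(
      sdf_to_mol3d(sdfset[[k]], id),
      error = function(e) abort(sprintf("record %d ('%s'): %s", k, id,
                                        conditionMessage(e)))
    )
  }
  names(out) <- vapply(out, function(m) m$id, character(1))
  out
}

tail1 <- function(x) x[length(x)]

sdf_to_mol3d <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  charge_code <- if ("C5" %in% colnames(ab)) as.integer(ab[, "C5"]) else
    integer(nrow(ab))
  code_map <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)
  charge <- ifelse(charge_code >= 1 & charge_code <= 7,
                   code_map[pmax(charge_code, 1L)], 0L)
  atoms <- tibble(
    index = seq_len(nrow(ab)),
    element = element,
    x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]), z = as.numeric(ab[, 3]),
    charge = as.integer(charge)
  )
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  mol3d(id, atoms, bonds)
}

#' Write molecules as SDF V2000 text
#'
#' @param mols a `mol3d` or list of them.
#' @param path optional output path; when `NULL` the SDF text is returned.
#' @return `path` (invisibly) or the SDF text as a single string.
#' @export
write_sdf <- function(mols, path = NULL) {
  if (inherits(mols, "mol3d")) mols <- list(mols)
  txt <- vapply(mols, sdf_record, character(1))
  all_txt <- paste(txt, collapse = "\n")
  if (is.null(path)) return(all_txt)
  writeLines(all_txt, path)
  invisible(path)
}

sdf_record <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  header <- c(mol$id, "  mcphd", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element)
  bond_lines <- if (nrow(b) > 0) {
    sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order)
  } else character(0)
  chg <- which(a$charge != 0L)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, a$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

#' Read an activity table
#'
#' Expects a CSV with columns `id`, `ic50` (micromolar, positive) and
#' `active` (0/1). Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return tibble with columns `id`, `ic50`, `active`.
#' @export
read_activity_table <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("id", "ic50", "active")
  if (!all(need %in% names(tab))) {
    abort(sprintf("activity table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  tab <- dplyr::select(tab, dplyr::all_of(need))
  if (anyDuplicated(tab$id)) {
    abort(sprintf("duplicate molecule id(s): %s",
                  paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
  }
  if (nrow(tab) > 0 && any(!is.finite(tab$ic50) | tab$ic50 <= 0)) {
    abort("ic50 values must be positive")
  }
  if (nrow(tab) > 0 && !all(tab$active %in% c(0, 1))) {
    abort("active flags must be 0 or 1")
  }
  tab$active <- as.integer(tab$active)
  tab
}
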