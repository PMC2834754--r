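# Structure container: a light S3 wrapper around an atom table.  Columns
# follow PDB semantics (serial, name, altloc, resname, chain, resno, insert,
# x, y, z, occ, het, element).  Parsing is delegated to bio3d; the wrapper
# enforces the conventions every descriptor relies on: waters out, one
# (highest-occupancy) altloc per atom, model 1 only.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR",
                         "CD", "NI", "CO", "SE", "MO", "CA")

#' Build a structure object from an atom table
#'
#' @param atoms data.frame with columns serial, name, altloc, resname, chain,
#'   resno, insert, x, y, z, occ, het, element.
#' @param id Optional identifier.
#' @return Object of class `ppi_structure`.
#' @export
new_structure <- function(atoms, id = "") {
  needed <- c("serial", "name", "altloc", "resname", "chain", "resno",
              "insert", "x", "y", "z", "occ", "het", "element")
  stopifnot(all(needed %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty structure")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat(sprintf("ppi_structure '%s': %d atoms, chains %s\n", x$id,
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

#' Read a PDB-format structure
#'
#' Reads fixed-column PDB text (a path or a character vector of lines) into a
#' structure object.  Waters are dropped, only the highest-occupancy
#' alternate location of each atom is kept, and only model 1 of multi-model
#' (e.g. NMR) files is used.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param keep_waters Keep water residues (default FALSE).
#' @return A `ppi_structure`.
#' @export
read_structure <- function(source, keep_waters = FALSE) {
  if (length(source) > 1L || grepl("\n", source[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(source) > 1L) source else
               strsplit(source, "\n")[[1]], path)
  } else {
    path <- source
    if (!file.exists(path)) stop("no such file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    bad <- which(rec &
      is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
      rec & is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
      rec & is.na(suppressWarnings(as.numeric(substr(lines, 47, 54)))))
    if (length(bad) > 0) {
      stop("unparseable coordinate columns at line ", bad[1])
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse failed: ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: no atoms parsed")
  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    altloc  = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    resno   = as.integer(at$resno),
    insert  = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    element = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
    stringsAsFactors = FALSE)
  if (!keep_waters) atoms <- atoms[!atoms$resname %in% WATER_RESNAMES, ]
  if (nrow(atoms) == 0L) stop("empty structure after water removal")
  atoms$element <- ifelse(atoms$element == "",
                          infer_element(atoms$name, atoms$het),
                          toupper(atoms$element))
  atoms <- resolve_altloc(atoms)
  new_structure(atoms, id = if (file.exists(path)) basename(path) else "")
}

# keep, per (chain, resno, insert, name), the highest-occupancy altloc
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c("", " "))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$name, sep = "|")), ]
  atoms[order(atoms$serial), ]
}

#' Infer element symbols from PDB atom names
#' @param name Atom name (trimmed).
#' @param het Logical, HETATM record.
#' @return Uppercase element symbols.
#' @keywords internal
infer_element <- function(name, het = FALSE) {
  nm <- toupper(name)
  # leading digits (1HB etc.) mark hydrogens in old files
  lead_digit <- grepl("^[0-9]", nm)
  nm2 <- sub("^[0-9]+", "", nm)
  el <- substr(nm2, 1, 1)
  el[lead_digit | el == "H"] <- "H"
  el[el == "D"] <- "H"
  two <- substr(nm2, 1, 2)
  is_two <- het & two %in% TWO_LETTER_ELEMENTS & nchar(nm2) == 2
  el[is_two] <- two[is_two]
  if (any(el == "" | is.na(el))) stop("cannot infer element for atom name(s): ",
                                      paste(unique(name[el == "" | is.na(el)]),
                                            collapse = ", "))
  el
}

#' Write a structure as PDB-format text
#'
#' @param structure A `ppi_structure`.
#' @param file Optional output path; if `NULL` the lines are returned.
#' @return Invisibly (or visibly when `file` is NULL) the PDB lines.
#' @export
write_structure <- function(structure, file = NULL) {
  a <- structure$atoms
  fmt_name <- function(name, element) {
    # element right-justified in cols 13-14 => 1-char elements indent by one
    ifelse(nchar(name) >= 4, substr(name, 1, 4),
           ifelse(nchar(element) == 1, sprintf(" %-3s", name),
                  sprintf("%-4s", name)))
  }
  lines <- sprintf("%-6s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$het, "HETATM", "ATOM"),
                   a$serial %% 100000L,
                   fmt_name(a$name, a$element),
                   ifelse(a$altloc == "", " ", a$altloc),
                   a$resname, a$chain, a$resno,
                   ifelse(a$insert == "", " ", a$insert),
                   a$x, a$y, a$z, a$occ, 0,
                   a$element)
  # TER between chains, END at the end
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    invisible(out)
  } else out
}

#' Coordinates of a structure (or atom subset) as an n x 3 matrix
#' @param structure A `ppi_structure`.
#' @param idx Optional row indices.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(structure, idx = NULL) {
  a <- structure$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Partner selection for a two-sided complex
#'
#' @param side_a,side_b Character vectors of chain identifiers; disjoint.
#' @param ligand Optional ligand identifier `list(resname=, chain=, resno=)`
#'   (chain/resno may be `NULL` to match any).
#' @return Object of class `partner_selection`.
#' @export
partner_selection <- function(side_a, side_b, ligand = NULL) {
  side_a <- as.character(side_a); side_b <- as.character(side_b)
  if (length(intersect(side_a, side_b)) > 0) {
    stop("side_a and side_b share chains: ",
         paste(intersect(side_a, side_b), collapse = ", "))
  }
  structure(list(side_a = side_a, side_b = side_b, ligand = ligand),
            class = "partner_selection")
}

#' Row indices of the atoms belonging to one side of a selection
#' @keywords internal
side_indices <- function(structure, selection, side = c("a", "b"),
                         heavy_only = FALSE) {
  side <- match.arg(side)
  chains <- if (side == "a") selection$side_a else selection$side_b
  a <- structure$atoms
  idx <- which(a$chain %in% chains & !a$het)
  if (heavy_only) idx <- idx[a$element[idx] != "H"]
  idx
}

#' Classify heavy atoms as polar or non-polar
#'
#' Interface-composition convention: nitrogen and oxygen are polar, carbon
#' and sulfur non-polar.  Hydrogens inherit the class of their nearest heavy
#' atom (use [classify_structure_atoms()] for that).
#'
#' @param element Element symbol(s).
#' @return Character vector `"polar"` / `"non_polar"`.
#' @export
classify_atom <- function(element) {
  el <- toupper(element)
  out <- rep(NA_character_, length(el))
  out[el %in% c("N", "O")] <- "polar"
  out[el %in% c("C", "S", "P")] <- "non_polar"
  if (anyNA(out)) {
    stop("unknown element(s) for polarity classification: ",
         paste(unique(el[is.na(out)]), collapse = ", "))
  }
  out
}

#' Per-atom polarity classes for a whole structure
#'
#' @param structure A `ppi_structure`.
#' @return Character vector aligned with the atom table; hydrogens take the
#'   class of the nearest heavy atom (their bonded partner).
#' @export
classify_structure_atoms <- function(structure) {
  a <- structure$atoms
  out <- rep(NA_character_, nrow(a))
  heavy <- a$element != "H"
  out[heavy] <- classify_atom(a$element[heavy])
  if (any(!heavy)) {
    xyz <- coords(structure)
    hxyz <- xyz[!heavy, , drop = FALSE]
    heavy_xyz <- xyz[heavy, , drop = FALSE]
    for (i in seq_len(nrow(hxyz))) {
      d2 <- colSums((t(heavy_xyz) - hxyz[i, ])^2)
      out[which(!heavy)[i]] <- out[heavy][which.min(d2)]
    }
  }
  out
}

CHARGED_RESIDUES  <- c("ASP", "GLU", "LYS", "ARG", "HIS")
POLAR_RESIDUES    <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "TRP")
NONPOLAR_RESIDUES <- c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET")

# common modified residues mapped to their parent
MODIFIED_PARENT <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                     CSO = "CYS", MLY = "LYS", HYP = "PRO")

#' Classify residues as charged, polar or non-polar
#'
#' Charged: Asp, Glu, Lys, Arg, His (His counted charged, consistent with the
#' salt-bridge rule listing it among the basics).  Polar: Ser, Thr, Asn, Gln,
#' Tyr, Cys, Trp.  Non-polar: the remaining eight standard residues.
#'
#' @param residue_name 3-letter residue code(s).
#' @return Character vector `"charged"` / `"polar"` / `"non_polar"`.
#' @export
classify_residue <- function(residue_name) {
  rn <- toupper(residue_name)
  known_mod <- rn %in% names(MODIFIED_PARENT)
  rn[known_mod] <- MODIFIED_PARENT[rn[known_mod]]
  out <- rep(NA_character_, length(rn))
  out[rn %in% CHARGED_RESIDUES] <- "charged"
  out[rn %in% POLAR_RESIDUES] <- "polar"
  out[rn %in% NONPOLAR_RESIDUES] <- "non_polar"
  if (anyNA(out)) {
    stop("unknown residue(s): ", paste(unique(residue_name[is.na(out)]),
                                       collapse = ", "))
  }
  out
}

#' Extract a non-covalent ligand from a structure
#'
#' Returns the hetero atoms matching the selection's ligand identifier and
#' asserts that the ligand is not covalently bound to the protein (minimum
#' heavy-atom distance > 1.9 Angstrom), matching the dataset curation rule
#' that covalent inhibitors are excluded.
#'
#' @param structure A `ppi_structure`.
#' @param selection A `partner_selection` with a `ligand` entry.
#' @return Atom table rows of the ligand.
#' @export
extract_ligand <- function(structure, selection) {
  lig <- selection$ligand
  if (is.null(lig)) stop("selection carries no ligand identifier")
  a <- structure$atoms
  keep <- a$het & a$resname == lig$resname &
    !a$resname %in% WATER_RESNAMES
  if (!is.null(lig$chain)) keep <- keep & a$chain == lig$chain
  if (!is.null(lig$resno)) keep <- keep & a$resno == lig$resno
  if (!any(keep)) stop("ligand absent: no HETATM matches ", lig$resname)
  lig_atoms <- a[keep, , drop = FALSE]
  prot <- a[!a$het & a$element != "H", , drop = FALSE]
  ligh <- lig_atoms[lig_atoms$element != "H", , drop = FALSE]
  if (nrow(prot) > 0 && nrow(ligh) > 0) {
    dmin <- min_cross_distance(as.matrix(ligh[, c("x", "y", "z")]),
                               as.matrix(prot[, c("x", "y", "z")]))
    if (dmin <= 1.9) {
      stop("covalent ligand excluded by dataset rules (min heavy-atom ",
           sprintf("distance %.2f A)", dmin))
    }
  }
  lig_atoms
}

# minimum pairwise distance between two coordinate sets (chunked)
min_cross_distance <- function(A, B) {
  dmin <- Inf
  step <- 2000L
  for (i in seq(1, nrow(A), by = step)) {
    ii <- i:min(i + step - 1L, nrow(A))
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  dmin
}

#' Subset a structure by chains
#'
#' @param structure A `ppi_structure`.
#' @param chains Chain identifiers to keep.
#' @param drop_het Drop HETATM records (default TRUE).
#' @return A `ppi_structure`.
#' @export
subset_chains <- function(structure, chains, drop_het = TRUE) {
  a <- structure$atoms
  keep <- a$chain %in% chains
  if (drop_het) keep <- keep & !a$het
  if (!any(keep)) stop("no atoms in chains: ", paste(chains, collapse = ","))
  new_structure(a[keep, , drop = FALSE], id = structure$id)
}

#' Per-residue table of a structure
#'
#' @param structure A `ppi_structure`.
#' @param chains Optional chain subset.
#' @return data.frame with one row per residue (chain, resno, insert,
#'   resname, het), ordered by chain then sequence position.
#' @export
residue_table <- function(structure, chains = NULL) {
  a <- structure$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  r <- data.frame(chain = a$chain[first], resno = a$resno[first],
                  insert = a$insert[first], resname = a$resname[first],
                  het = a$het[first], stringsAsFactors = FALSE)
  r[order(r$chain, r$resno, r$insert), ]
}
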