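#' Write a membrane frame as a GRO coordinate file
#'
#' Fixed-column GROMACS GRO format (positions in nm, three decimals).  The
#' species name becomes the residue name and the particle role is encoded
#' in the atom name (`HD` for heads, `T1`, `T2`, ... for tails, `W` for
#' water, `P` for other polar beads); the molecule id becomes the residue
#' number (modulo the format's five digits).  The species/role mapping
#' needed to re-read the file is the side-car YAML of [write_role_map()].
#'
#' @param frame A [membrane_frame()].
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "poremech frame") {
  box <- frame_box(frame)
  # GRO groups atoms by residue: order by molecule (stable within molecules)
  frame <- frame[order(frame$molecule_id), ]
  atom_names <- gro_atom_names(frame)
  n <- nrow(frame)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   frame$molecule_id %% 100000L,
                   substr(frame$species, 1, 5),
                   substr(atom_names, 1, 5),
                   seq_len(n) %% 100000L,
                   frame$x, frame$y, frame$z)
  writeLines(c(title, sprintf("%d", n), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  invisible(path)
}

gro_atom_names <- function(frame) {
  nm <- character(nrow(frame))
  nm[frame$role == "head"] <- "HD"
  nm[frame$role == "water"] <- "W"
  nm[frame$role == "polar"] <- "P"
  ti <- which(frame$role == "tail")
  if (length(ti) > 0) {
    ord <- stats::ave(seq_along(ti), frame$molecule_id[ti], FUN = seq_along)
    nm[ti] <- paste0("T", ord)
  }
  nm
}

#' Species/role mapping side-car files
#'
#' A role map assigns each (residue name, atom name) pair a species and a
#' role; it is stored as YAML of the form
#' `species: {POPC: {HD: head, T1: tail, ...}, W: {W: water}}`.
#' `write_role_map()` derives the map from a frame written with
#' [write_gro()]; `read_role_map()` loads one.
#'
#' @param frame A [membrane_frame()].
#' @param path YAML path.
#' @return `write_role_map()`: `path` invisibly; `read_role_map()`: a named
#'   nested list.
#' @export
write_role_map <- function(frame, path) {
  an <- gro_atom_names(frame)
  pairs <- unique(tibble(species = frame$species, atom = an, role = frame$role))
  m <- lapply(split(pairs, pairs$species), function(d) {
    stats::setNames(as.list(d$role), d$atom)
  })
  yaml::write_yaml(list(species = m), path)
  invisible(path)
}

#' @rdname write_role_map
#' @export
read_role_map <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$species)) {
    abort("role map must have a top-level `species` key.",
          class = "poremech_validation_error")
  }
  m$species
}

#' Read a GRO coordinate file into a membrane frame
#'
#' Parses the fixed-column GRO format and assigns species (the residue
#' name) and roles via a role map (see [read_role_map()]); atom names
#' missing from the map raise an error.  Residue numbers are unwrapped
#' into consecutive molecule ids.
#'
#' @param path GRO file path.
#' @param role_map A role map list, or a path to its YAML file.
#' @return A [membrane_frame()].
#' @export
read_gro <- function(path, role_map) {
  if (is.character(role_map)) role_map <- read_role_map(role_map)
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  atoms <- lines[3:(2 + n)]
  boxline <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  resid <- as.integer(substr(atoms, 1, 5))
  resname <- trimws(substr(atoms, 6, 10))
  atomname <- trimws(substr(atoms, 11, 15))
  x <- as.numeric(substr(atoms, 21, 28))
  y <- as.numeric(substr(atoms, 29, 36))
  z <- as.numeric(substr(atoms, 37, 44))
  role <- vapply(seq_len(n), function(i) {
    r <- role_map[[resname[i]]][[atomname[i]]]
    if (is.null(r)) {
      abort(sprintf("no role for %s/%s in the role map.",
                    resname[i], atomname[i]),
            class = "poremech_validation_error")
    }
    r
  }, character(1))
  # unwrap residue numbering (the format wraps at 100000)
  new_mol <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
  molecule_id <- cumsum(new_mol)
  membrane_frame(
    tibble(x = x, y = y, z = z, species = resname, role = role,
           molecule_id = molecule_id),
    box = boxline[1:3]
  )
}

#' Write a membrane frame as a PDB file
#'
#' Standard fixed-column `ATOM` records with coordinates converted from nm
#' to Angstrom (factor 10) and a `CRYST1` record for the orthorhombic box.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path, title = "poremech frame") {
  box <- frame_box(frame) * 10
  atom_names <- gro_atom_names(frame)
  n <- nrow(frame)
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(n) %% 100000L,
    substr(atom_names, 1, 4),
    substr(frame$species, 1, 4),
    frame$molecule_id %% 10000L,
    frame$x * 10, frame$y * 10, frame$z * 10
  )
  writeLines(c(
    paste0("TITLE     ", title),
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            box[1], box[2], box[3], 90, 90, 90),
    lines, "END"
  ), path)
  invisible(path)
}
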