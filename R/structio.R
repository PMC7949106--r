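#' Read a protein structure from PDB-format text
#'
#' Parses `ATOM`/`HETATM` records into a tidy atom table. Parsing of the
#' fixed-column format is delegated to [bio3d::read.pdb()]; this wrapper adds
#' element inference for files lacking an element column, alternate-location
#' filtering, and validation of serials and coordinates.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline, or of length > 1, is treated as text).
#' @param id Free-text label for the structure; defaults to the file name.
#' @param keep_altloc Alternate-location indicators to retain. The default
#'   keeps blank and `"A"` records only, so site extraction is deterministic.
#' @return An object of class `mate_structure`: a list with `atoms` (a tibble
#'   with one row per atom: `serial`, `name`, `element`, `residue_name`,
#'   `chain`, `residue_number`, `x`, `y`, `z`, `record_kind`, `is_hydrogen`)
#'   and `id`.
#' @examples
#' pdb <- gen_coordination_site(seed = 1)
#' s <- read_pdb(pdb$pdb_text, id = "toy-site")
#' atoms(s)
#' @export
read_pdb <- function(file, id = NULL, keep_altloc = c("", "A")) {
  if (length(file) > 1L || any(grepl("\n", file, fixed = TRUE)) ||
      grepl("^(ATOM|HETATM|HEADER|TITLE|REMARK)", file[1])) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines, tmp)
    file <- tmp
    id <- id %||% "text"
  }
  if (!file.exists(file)) {
    abort(paste0("PDB file not found: ", file))
  }
  id <- id %||% sub("\\.(pdb|ent)$", "", basename(file))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, verbose = FALSE)),
    error = function(e) abort(paste0("failed to parse PDB file '", file, "': ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort("structure contains no ATOM or HETATM records")
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% keep_altloc, , drop = FALSE]
  if (nrow(at) == 0L) {
    abort("no atoms left after alternate-location filtering")
  }
  element <- at$elesy
  element[is.na(element)] <- ""
  element <- toupper(trimws(element))
  missing_el <- element == ""
  if (any(missing_el)) {
    element[missing_el] <- infer_element(at$elety[missing_el],
                                         at$resid[missing_el])
  }
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    abort(paste0("malformed coordinate fields for atom serial(s): ",
                 paste(at$eleno[bad], collapse = ", ")))
  }
  atoms <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = element,
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    residue_number = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    record_kind = ifelse(at$type == "HETATM", "hetero", "polymer"),
    is_hydrogen = element %in% c("H", "D")
  )
  if (anyDuplicated(atoms$serial)) {
    abort("atom serial numbers are not unique within the structure")
  }
  structure(list(atoms = atoms, id = id), class = "mate_structure")
}

# Element from the atom-name column when no element column is present.
# Handles leading digits (e.g. "1HB2"), primes, and common monatomic ions
# whose two-letter symbol fills columns 13-14 ("NA", "CL", "MG", ...).
infer_element <- function(name, resid = NULL) {
  two_letter <- c("NA", "CL", "MG", "ZN", "FE", "MN", "CA", "BR", "CU", "NI")
  nm <- toupper(gsub("[0-9'\"]", "", trimws(name)))
  el <- substr(nm, 1L, 1L)
  if (!is.null(resid)) {
    resid <- toupper(trimws(resid))
    ion <- nm %in% two_letter & resid == nm
    el[ion] <- nm[ion]
  }
  el
}

#' @export
print.mate_structure <- function(x, ...) {
  cat("<mate_structure> ", x$id, ": ", nrow(x$atoms), " atoms (",
      sum(x$atoms$record_kind == "hetero"), " hetero)\n", sep = "")
  print(x$atoms, n = 5)
  invisible(x)
}

#' Atom table of a structure
#' @param x A `mate_structure`.
#' @return The atoms tibble.
#' @export
atoms <- function(x) {
  stopifnot(inherits(x, "mate_structure"))
  x$atoms
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column `ATOM`/`HETATM` records via
#' [bio3d::write.pdb()]; coordinates are stored at the format's 3-decimal
#' precision.
#'
#' @param structure A `mate_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  a <- atoms(structure)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(a$record_kind == "hetero", "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, resid = a$residue_name,
    chain = a$chain, resno = a$residue_number, elesy = a$element
  )
  invisible(file)
}

#' Download a PDB entry from the RCSB archive
#'
#' Fetches `https://files.rcsb.org/download/<ID>.pdb` into a local cache
#' directory and returns the cached path; an existing cached copy is reused
#' without network access.
#'
#' @param id 4-character PDB identifier (e.g. `"6IDR"`).
#' @param dir Cache directory.
#' @return Path to the cached PDB file.
#' @export
fetch_pdb <- function(id, dir = file.path(tempdir(), "matekit-pdb")) {
  stopifnot(is.character(id), nchar(id) == 4L)
  id <- toupper(id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
    status <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
      error = function(e) -1L, warning = function(w) -1L
    )
    if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      abort(paste0("could not download PDB entry ", id,
                   " (no network access?)"))
    }
  }
  dest
}

#' Extract a candidate ion coordination site
#'
#' Collects the protein ligand contacts around a site centre: all atoms that
#' pass the element filter and lie within `cutoff` of the centre, with exact
#' Euclidean distances, sorted by ascending distance. The default filter
#' (non-hydrogen O and N atoms of polymer records) captures the polar
#' contacts that define alkali-ion sites in membrane transporters.
#'
#' @param structure A `mate_structure`.
#' @param center Either a numeric 3-vector (x, y, z in Angstrom) or a single
#'   atom serial number. When a serial is given (typically the modelled
#'   water/ion `HETATM` at the centre of the site), that atom's position is
#'   used and the atom itself is excluded from the contact search.
#' @param cutoff Contact cutoff in Angstrom (default 3).
#' @param elements Element symbols eligible as ligands.
#' @param include_hetero Also consider `HETATM` records as ligands?
#' @return A `coord_site`: list with `center` (3-vector), `contacts` (tibble
#'   with atom fields and `distance`), `cutoff`.
#' @examples
#' site <- gen_coordination_site(seed = 1)
#' extract_site(site$structure, center = site$truth$center_serial)
#' @export
extract_site <- function(structure, center, cutoff = 3,
                         elements = c("O", "N"), include_hetero = FALSE) {
  stopifnot(inherits(structure, "mate_structure"))
  if (cutoff <= 0) abort("cutoff must be positive")
  if (length(elements) == 0L) abort("ligand element filter must be non-empty")
  a <- atoms(structure)
  exclude_serial <- integer(0)
  if (length(center) == 1L) {
    hit <- a[a$serial == as.integer(center), , drop = FALSE]
    if (nrow(hit) != 1L) {
      abort(paste0("no atom with serial ", center, " in structure"))
    }
    exclude_serial <- hit$serial
    center <- c(hit$x, hit$y, hit$z)
  }
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))

  cand <- a[!a$is_hydrogen &
              a$element %in% toupper(elements) &
              !(a$serial %in% exclude_serial), , drop = FALSE]
  if (!include_hetero) cand <- cand[cand$record_kind == "polymer", , drop = FALSE]
  d <- sqrt((cand$x - center[1])^2 + (cand$y - center[2])^2 +
              (cand$z - center[3])^2)
  keep <- d <= cutoff & d > 0
  contacts <- cand[keep, , drop = FALSE]
  contacts$distance <- d[keep]
  contacts <- contacts[order(contacts$distance), , drop = FALSE]
  if (nrow(contacts) == 0L) {
    warn("no ligand contacts found within the cutoff (empty site)")
  }
  structure(
    list(center = center, contacts = as_tibble(contacts), cutoff = cutoff,
         structure_id = structure$id),
    class = "coord_site"
  )
}

#' @export
print.coord_site <- function(x, ...) {
  cat("<coord_site> ", nrow(x$contacts), " contact(s) within ", x$cutoff,
      " A of (", paste(sprintf("%.2f", x$center), collapse = ", "), ")\n",
      sep = "")
  if (nrow(x$contacts)) {
    print(x$contacts[, c("name", "residue_name", "chain", "residue_number",
                         "distance")])
  }
  invisible(x)
}

#' @rdname extract_site
#' @param x A `coord_site`.
#' @export
site_contacts <- function(x) {
  stopifnot(inherits(x, "coord_site"))
  x$contacts
}

#' Write a coordination site as delimited text
#'
#' One row per contact: atom name, residue, chain, residue number, element,
#' distance (Angstrom). Tab-separated with a header.
#'
#' @param site A `coord_site`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_site <- function(site, file) {
  stopifnot(inherits(site, "coord_site"))
  tab <- site$contacts[, c("name", "residue_name", "chain", "residue_number",
                           "element", "distance")]
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
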