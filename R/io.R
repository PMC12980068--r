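# File formats: PDB structures/ensembles (via bio3d), CSV tables with a
# fixed column schema, and JSON planted-truth sidecars.

# canonical CSV column schemas, validated on read
.CSV_SCHEMAS <- list(
  curve = c("turns", "extension_um"),
  rdf = c("r_nm", "g_cc", "g_ca"),
  twist_table = c("salt", "conc_M", "delta_tw_deg_per_bp", "sd", "n"),
  activity = c("concentration", "a_cc")
)

#' Read a numeric CSV with schema validation
#'
#' @param path CSV file path.
#' @param schema one of `names(saltwist:::.CSV_SCHEMAS)` or a character
#'   vector of required column names.
#' @return data frame.
#' @export
read_schema_csv <- function(path, schema) {
  if (!file.exists(path)) stop("input file not found: ", path)
  cols <- if (is.character(schema) && length(schema) == 1 &&
              schema %in% names(.CSV_SCHEMAS)) .CSV_SCHEMAS[[schema]]
  else schema
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(missing, collapse = ", ")))
  df
}

#' Write a rotation curve to CSV
#'
#' Columns `turns`, `extension_um`; planted truth (if any) goes to a JSON
#' sidecar `<path>.truth.json`.
#'
#' @param curve a `rotation_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(turns = curve$turns,
                              extension_um = curve$extension),
                   path, row.names = FALSE)
  if (!is.null(curve$truth)) .write_truth(curve$truth, path)
  invisible(path)
}

#' Read a rotation curve from CSV
#'
#' @param path CSV path with columns `turns`, `extension_um`.
#' @param force,n_bp,salt,concentration metadata not stored in the CSV.
#' @return a `rotation_curve`.
#' @export
read_curve <- function(path, force = NA_real_, n_bp = NA_integer_,
                       salt = NA_character_, concentration = NA_real_) {
  df <- read_schema_csv(path, "curve")
  rotation_curve(df$turns, df$extension_um, force = force, n_bp = n_bp,
                 salt = salt, concentration = concentration)
}

.write_truth <- function(truth, path) {
  jsonlite::write_json(.unclass_deep(truth),
                       paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

.unclass_deep <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, .unclass_deep)
    x[!vapply(x, is.null, logical(1))]
  } else if (is.matrix(x)) unclass(x) else {
    attributes(x) <- NULL
    x
  }
}

#' Write a duplex or ensemble (and optional ions) to PDB
#'
#' PDB v3.3 via bio3d, one structure per MODEL record for ensembles,
#' coordinates in Angstrom. Cations/anions are appended as HETATM records
#' with residue/element LI or CL.
#'
#' @param x a `dna_duplex` or `dna_ensemble`.
#' @param path output PDB path.
#' @param ions optional `ion_set` (written into the same file, every
#'   MODEL).
#' @param element ion element symbol, `"LI"` or `"CL"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, ions = NULL, element = "LI") {
  atoms <- x$atoms
  nf <- n_frames(x)
  xyzmat <- if (inherits(x, "dna_ensemble")) x$xyz
  else matrix(as.numeric(t(duplex_xyz(x))), nrow = 1)
  elety <- atoms$elety; resid <- atoms$resid; chain <- atoms$chain
  resno <- atoms$resno
  n_dna <- nrow(atoms)
  n_ion <- 0L
  if (!is.null(ions)) {
    ion_xyz <- ions$cation_xyz
    n_ion <- nrow(ion_xyz)
    elety <- c(elety, rep(element, n_ion))
    resid <- c(resid, rep(element, n_ion))
    chain <- c(chain, rep("I", n_ion))
    resno <- c(resno, max(resno) + seq_len(n_ion))
    xyzmat <- cbind(xyzmat,
                    matrix(rep(as.numeric(t(ion_xyz)), nf), nrow = nf,
                           byrow = TRUE))
  }
  elesy <- ifelse(elety %in% c("LI", "CL"), elety, substr(elety, 1, 1))
  bio3d::write.pdb(file = path, xyz = xyzmat, elety = elety, resid = resid,
                   chain = chain, resno = resno, elesy = elesy)
  if (n_ion > 0) {
    # bio3d writes everything as ATOM; ion records must be HETATM
    lines <- readLines(path)
    is_ion <- startsWith(lines, "ATOM") &
      trimws(substr(lines, 18, 20)) %in% c("LI", "CL")
    lines[is_ion] <- sub("^ATOM  ", "HETATM", lines[is_ion])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a PDB structure or multi-MODEL ensemble
#'
#' ATOM records become the DNA structure (single `dna_duplex` for one
#' MODEL, `dna_ensemble` for several); HETATM records with residue LI or CL
#' are returned separately as ion coordinates. Malformed ATOM records and
#' inconsistent atom counts across MODELs are reported with the offending
#' line.
#'
#' @param path PDB file path.
#' @return list with `structure` (`dna_duplex` or `dna_ensemble`) and
#'   `ions` (N x 3 matrix or NULL).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  rec <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  bad <- rec[nchar(lines[rec]) < 54]
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                 bad[1], lines[bad[1]]))
  models <- which(startsWith(lines, "MODEL"))
  if (length(models) > 1) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(models))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(models), function(i)
      sum(rec > models[i] & rec < ends[i]), integer(1))
    if (length(unique(counts)) != 1)
      stop(sprintf("inconsistent atom counts across MODELs (line %d)",
                   models[which(counts != counts[1])[1]]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  is_ion <- at$resid %in% c("LI", "CL")
  dna <- at[!is_ion, , drop = FALSE]
  if (!nrow(dna)) stop("no DNA ATOM records in ", path)
  atoms <- data.frame(eleno = dna$eleno, elety = dna$elety,
                      resid = dna$resid, chain = dna$chain,
                      resno = dna$resno, x = dna$x, y = dna$y, z = dna$z,
                      stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  dna_cols <- as.vector(t(cbind((which(!is_ion) - 1) * 3 + 1,
                                (which(!is_ion) - 1) * 3 + 2,
                                (which(!is_ion) - 1) * 3 + 3)))
  if (nf > 1) {
    frames <- lapply(seq_len(nf), function(f)
      matrix(pdb$xyz[f, dna_cols], ncol = 3, byrow = TRUE))
    structure_obj <- make_ensemble(atoms, frames)
  } else {
    structure_obj <- structure(list(atoms = atoms, spec = NULL,
                                    truth = NULL), class = "dna_duplex")
  }
  ion_xyz <- NULL
  if (any(is_ion)) {
    ii <- which(is_ion)
    ion_xyz <- cbind(at$x[ii], at$y[ii], at$z[ii])
  }
  list(structure = structure_obj, ions = ion_xyz)
}

#' Write a spectra set to CSV
#'
#' First column `wavelength_nm`, remaining columns named by concentration.
#'
#' @param set a `spectra_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  df <- data.frame(wavelength_nm = set$wavelengths, set$dEps,
                   check.names = FALSE)
  names(df)[-1] <- as.character(set$concentrations)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(set$truth))
    .write_truth(list(weights = set$truth$weights), path)
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' @param path CSV with first column `wavelength_nm` and one column per
#'   concentration (numeric column names).
#' @return a `spectra_set`.
#' @export
read_spectra <- function(path) {
  df <- read_schema_csv(path, "wavelength_nm")
  conc <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(conc)) stop("spectra columns must be named by concentration")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  spectra_set(df$wavelength_nm, conc, m)
}

#' Write an RDF table to CSV
#' @param rdf an `rdf_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rdf <- function(rdf, path) {
  utils::write.csv(rdf$table, path, row.names = FALSE)
  if (!is.null(rdf$truth))
    .write_truth(list(G_cc = rdf$truth$G_cc, G_ca = rdf$truth$G_ca,
                      rho_c = rdf$rho_c), path)
  invisible(path)
}

#' Read an RDF table from CSV
#' @param path CSV with columns `r_nm`, `g_cc`, `g_ca`.
#' @param rho_c cation number density, ions/nm^3.
#' @return an `rdf_table`.
#' @export
read_rdf <- function(path, rho_c = NA_real_) {
  df <- read_schema_csv(path, "rdf")
  structure(list(table = df, rho_c = rho_c, truth = NULL),
            class = "rdf_table")
}
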