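#' @keywords internal
"_PACKAGE"

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Carbon atoms bonded to >= 2 N/O in the residue template are treated polar
# (e.g. amide/carboxylate/guanidinium carbons); everything else carbon-like is
# apolar.  Met SD is apolar (bonded only to carbons), Cys SG polar.
POLAR_CARBONS <- list(
  ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD", ARG = "CZ", HIS = "CE1"
)

#' Classify a heavy atom as polar or apolar
#'
#' Pure function of (residue name, atom name): nitrogen and oxygen are polar,
#' Cys SG is polar while Met SD is apolar, and carbons are apolar unless the
#' residue template bonds them to at least two N/O atoms (amide, carboxylate
#' and guanidinium carbons, plus the backbone carbonyl carbon).  Atoms of
#' residues without a template default to polar with a warning, so that
#' marginal chemistry is never silently dropped from polar-contact searches.
#'
#' @param res_name character vector of 3-letter residue codes.
#' @param atom_name character vector of atom labels (PDB atom names).
#' @param element optional element symbols; inferred from the atom name when
#'   missing.
#' @return character vector, each element `"polar"` or `"apolar"`.
#' @export
#' @examples
#' classify_atom_polarity("ALA", "CB")   # apolar
#' classify_atom_polarity("ASN", "CG")   # polar (bonded to OD1 and ND2)
classify_atom_polarity <- function(res_name, atom_name, element = NULL) {
  n <- max(length(res_name), length(atom_name))
  res_name <- rep_len(toupper(res_name), n)
  atom_name <- rep_len(toupper(trimws(atom_name)), n)
  if (is.null(element)) {
    element <- substr(gsub("[0-9']", "", atom_name), 1, 1)
  } else {
    element <- rep_len(toupper(trimws(element)), n)
  }
  out <- character(n)
  known <- res_name %in% STANDARD_AA | res_name %in% c("HOH", "WAT")
  if (any(!known)) {
    warning("no residue template for: ",
            paste(unique(res_name[!known]), collapse = ", "),
            "; defaulting atoms to polar")
    out[!known] <- "polar"
  }
  for (i in which(known)) {
    el <- element[i]
    if (el %in% c("N", "O")) {
      out[i] <- "polar"
    } else if (el == "S") {
      out[i] <- if (res_name[i] == "MET" && atom_name[i] == "SD") "apolar" else "polar"
    } else if (el == "C") {
      pc <- POLAR_CARBONS[[res_name[i]]]
      if (atom_name[i] == "C") {
        out[i] <- "polar"  # carbonyl carbon: bonded to O and the peptide N
      } else if (!is.null(pc) && atom_name[i] %in% pc) {
        out[i] <- "polar"
      } else {
        out[i] <- "apolar"
      }
    } else {
      out[i] <- "polar"
    }
  }
  out
}

new_gh20_structure <- function(atoms, accession = NA_character_,
                               resolution = NA_real_) {
  rownames(atoms) <- NULL
  structure(list(accession = accession, resolution = resolution, atoms = atoms),
            class = "gh20_structure")
}

#' @export
print.gh20_structure <- function(x, ...) {
  rt <- residues(x)
  cat("<gh20_structure>", if (!is.na(x$accession)) x$accession else "",
      "\n  chains:", paste(unique(x$atoms$chain[!x$atoms$water]), collapse = ", "),
      "\n  residues:", sum(!rt$water), "(+", sum(rt$water), "waters)",
      "\n  atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

residue_key <- function(chain, resno, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste0(chain, ":", resno, ins)
}

#' Residue-level view of a structure
#'
#' @param structure a `gh20_structure`.
#' @return data.frame with one row per residue in file order: `key`, `chain`,
#'   `resno`, `ins`, `resid`, `pos` (ordinal position), `het`, `water`, and
#'   `complete` (standard amino acids with N, CA and C present).
#' @export
residues <- function(structure) {
  a <- structure$atoms
  key <- residue_key(a$chain, a$resno, a$ins)
  first <- !duplicated(key)
  rt <- data.frame(key = key[first], chain = a$chain[first],
                   resno = a$resno[first], ins = a$ins[first],
                   resid = a$resid[first], het = a$het[first],
                   water = a$water[first], stringsAsFactors = FALSE)
  rt$pos <- seq_len(nrow(rt))
  has <- function(atom) {
    tapply(a$elety == atom, factor(key, levels = rt$key), any)
  }
  std <- rt$resid %in% STANDARD_AA
  rt$complete <- !std | (as.vector(has("N")) & as.vector(has("CA")) &
                           as.vector(has("C")))
  rt
}

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates via \pkg{bio3d}, keeping the first model of
#' multi-model files and, for alternate locations, the highest-occupancy
#' conformer.  Author residue numbering and insertion codes are preserved;
#' hydrogens are dropped (all downstream contact chemistry is heavy-atom, and
#' amide hydrogens are inferred geometrically where needed); waters are kept
#' but flagged.
#'
#' @param source path to a `.pdb`/`.ent` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a `gh20_structure`.
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("cannot read structure: no such file ", source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(source, verbose = FALSE)
    else bio3d::read.pdb(source, verbose = FALSE, multi = FALSE),
    error = function(e) stop("parse error in ", source, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atoms in ", source)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc: keep the highest-occupancy conformer per (chain, resno, ins, elety)
  akey <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(factor(akey, levels = unique(akey)), -a$o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
  elesy <- toupper(trimws(a$elesy))
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- substr(gsub("[0-9']", "", toupper(a$elety[miss])), 1, 1)
  keep <- !elesy %in% c("H", "D")
  a <- a[keep, , drop = FALSE]
  elesy <- elesy[keep]
  water <- a$resid %in% c("HOH", "WAT", "DOD")
  het <- a$type == "HETATM" & !water
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    ins = as.character(a$insert), resid = as.character(a$resid),
    elety = as.character(a$elety), elesy = elesy,
    x = a$x, y = a$y, z = a$z, o = a$o,
    het = het, water = water, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$backbone <- !atoms$water & atoms$elety %in% BACKBONE_ATOMS
  atoms$polar <- suppressWarnings(
    classify_atom_polarity(atoms$resid, atoms$elety, atoms$elesy))
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", source)
  new_gh20_structure(atoms, accession = toupper(
    sub("\\.(pdb|ent|cif|mmcif)$", "", basename(source), ignore.case = TRUE)))
}

#' Subset a structure to selected chains
#'
#' Returns the requested chains plus any water molecules within 5 angstrom of a
#' retained atom (waters can mediate active-site hydrogen bonds and must follow
#' their chain).  Coordinates of retained atoms are untouched.
#'
#' @param structure a `gh20_structure`.
#' @param chain_ids non-empty character vector of chain identifiers.
#' @param water_radius distance (angstrom) within which waters are kept.
#' @return a `gh20_structure` containing exactly the requested chains.
#' @export
select_chains <- function(structure, chain_ids, water_radius = 5) {
  if (length(chain_ids) == 0) stop("empty chain selection")
  a <- structure$atoms
  avail <- unique(a$chain[!a$water])
  bad <- setdiff(chain_ids, avail)
  if (length(bad))
    stop("unknown chain id(s) ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  keep <- !a$water & a$chain %in% chain_ids
  wat <- which(a$water)
  if (length(wat)) {
    xyz <- as.matrix(a[keep, c("x", "y", "z")])
    wxyz <- as.matrix(a[wat, c("x", "y", "z")])
    near <- vapply(seq_along(wat), function(i) {
      d2 <- (xyz[, 1] - wxyz[i, 1])^2 + (xyz[, 2] - wxyz[i, 2])^2 +
        (xyz[, 3] - wxyz[i, 3])^2
      any(d2 <= water_radius^2)
    }, logical(1))
    wkey <- residue_key(a$chain[wat], a$resno[wat], a$ins[wat])
    keep_w <- wkey %in% unique(wkey[near])
    keep[wat[keep_w]] <- TRUE
  }
  new_gh20_structure(a[keep, , drop = FALSE], accession = structure$accession,
                     resolution = structure$resolution)
}

#' Write a structure as a PDB file
#'
#' @param structure a `gh20_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(structure, file) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het | a$water, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = ifelse(a$chain == " ", "", a$chain),
    insert = a$ins, o = a$o, b = rep(0, nrow(a)), elesy = a$elesy,
    end = TRUE)
  invisible(file)
}

#' Fetch a structure file from the PDB, with a local cache
#'
#' Idempotent: once `cache_dir/<accession>.cif` exists it is returned without
#' touching the network.  A failed download with an empty cache raises an
#' explicit error (never a silent empty file).
#'
#' @param accession 4-character PDB accession.
#' @param cache_dir cache directory (created if needed).
#' @return path to the cached mmCIF file.
#' @export
fetch_structure <- function(accession, cache_dir = "cache") {
  accession <- tolower(accession)
  if (!grepl("^[0-9][a-z0-9]{3}$", accession))
    stop("fetch failed: '", accession, "' is not a valid PDB accession")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(accession, ".cif"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(accession), ".cif")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("fetch failed for ", toupper(accession),
         ": no network and no cached copy in ", cache_dir)
  }
  dest
}

#' Amino-acid sequence of a chain
#'
#' @param structure a `gh20_structure`.
#' @param chain chain identifier.
#' @param span optional `c(start, end)` author-numbering range.
#' @return single-letter amino-acid string (non-standard residues as `X`).
#' @export
structure_sequence <- function(structure, chain, span = NULL) {
  rt <- residues(structure)
  rt <- rt[rt$chain == chain & !rt$water & !rt$het, , drop = FALSE]
  if (!is.null(span)) rt <- rt[rt$resno >= span[1] & rt$resno <= span[2], ,
                               drop = FALSE]
  aa <- AA_321[rt$resid]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# xyz matrix (n x 3) of selected atoms; keys optionally restrict residues
atom_coords <- function(structure, keys = NULL, elety = NULL) {
  a <- structure$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(keys)) sel <- sel & residue_key(a$chain, a$resno, a$ins) %in% keys
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}
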