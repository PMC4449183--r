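# Sequence utilities: global alignment with percent identity, truncation
# construct assembly with expression-vector tags, and theoretical molecular
# mass.

# average (isotope-weighted) residue masses, Da
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# expression-vector tag leaders; the N-terminal tag carries its own
# initiator methionine and a thrombin-site linker, the C-terminal tag is the
# two-residue XhoI junction plus His6
TAG_SEQUENCES <- c(none = "", n_his6 = "MGSSHHHHHHSSGLVPRGSHM",
                   c_his6 = "LEHHHHHH")

validate_aa <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nchar(sequence)) stop("empty sequence")
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% names(AA_RESIDUE_MASS))
  if (length(bad))
    stop("invalid amino-acid letter '", letters[bad[1]], "' at position ",
         bad[1])
  sequence
}

#' Theoretical average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water (18.015 Da).
#'
#' @param sequence amino-acid string (20 standard letters).
#' @return mass in Da.
#' @export
#' @examples
#' theoretical_mw("G")    # 75.07 Da
theoretical_mw <- function(sequence) {
  sequence <- validate_aa(sequence)
  letters <- strsplit(sequence, "")[[1]]
  sum(AA_RESIDUE_MASS[letters]) + WATER_MASS
}

#' Assemble a truncation construct with an expression tag
#'
#' Takes `parent[start:end]` and adds the vector-encoded tag: `"n_his6"`
#' prepends the pET28a thrombin-site His6 leader, `"c_his6"` appends the
#' pET24b XhoI-junction His6 tail.  When the construct's N-terminus is not the
#' tag (tag `"none"` or `"c_his6"`) and its first residue is not Met, an
#' initiator Met is added, as translation would supply.
#'
#' @param parent named list/record with `id` and `sequence`, or a plain
#'   amino-acid string.
#' @param start,end 1-based inclusive residue range within the parent.
#' @param tag `"none"`, `"n_his6"` or `"c_his6"`.
#' @return a `gh20_construct`: list with `parent_id`, `start`, `end`, `tag`,
#'   `tag_sequence`, `full_sequence`, `mass_da`, `mass_kda`.
#' @export
build_construct <- function(parent, start, end, tag = c("none", "n_his6",
                                                        "c_his6")) {
  tag <- match.arg(tag)
  if (is.character(parent) && length(parent) == 1)
    parent <- list(id = "parent", sequence = parent)
  pseq <- validate_aa(parent$sequence)
  n <- nchar(pseq)
  if (start > end) stop("start must not exceed end")
  if (start < 1 || end > n)
    stop("range ", start, "-", end, " outside parent length ", n)
  core <- substr(pseq, start, end)
  tag_seq <- TAG_SEQUENCES[[tag]]
  if (tag == "n_his6") {
    full <- paste0(tag_seq, core)
  } else {
    init <- if (substr(core, 1, 1) != "M") "M" else ""
    full <- paste0(init, core, tag_seq)
  }
  mass <- theoretical_mw(full)
  structure(list(parent_id = parent$id, start = as.integer(start),
                 end = as.integer(end), tag = tag, tag_sequence = tag_seq,
                 full_sequence = full, mass_da = mass,
                 mass_kda = mass / 1000),
            class = "gh20_construct")
}

#' @export
print.gh20_construct <- function(x, ...) {
  cat(sprintf("<gh20_construct> %s %d-%d (%s): %d aa, %.1f kDa\n",
              x$parent_id, x$start, x$end, x$tag, nchar(x$full_sequence),
              x$mass_kda))
  invisible(x)
}

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment via \pkg{Biostrings}; percent identity is
#' the fraction of identical columns among aligned columns after discarding
#' terminal-gap columns (end gaps are a length artefact, not divergence).
#'
#' @param a,b amino-acid strings or records with a `sequence` field.
#' @param gap_opening,gap_extension gap penalties (defaults 10, 0.5).
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @return a `gh20_alignment`: list with `aligned_a`, `aligned_b`,
#'   `identity_pct`, `score`.
#' @export
global_align <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                         substitution_matrix = "BLOSUM62") {
  seq_of <- function(x) if (is.list(x)) x$sequence else x
  sa <- validate_aa(seq_of(a))
  sb <- validate_aa(seq_of(b))
  mat <- get(utils::data(list = substitution_matrix,
                         package = "Biostrings", envir = environment()),
             envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  ga <- as.character(Biostrings::pattern(pa))
  gb <- as.character(Biostrings::subject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  gap <- ca == "-" | cb == "-"
  # trim terminal-gap columns
  inner <- which(!gap)
  if (!length(inner)) stop("alignment has no aligned columns")
  use <- seq(min(inner), max(inner))
  ident <- 100 * sum(ca[use] == cb[use] & ca[use] != "-") / length(use)
  structure(list(aligned_a = ga, aligned_b = gb, identity_pct = ident,
                 score = Biostrings::score(pa)),
            class = "gh20_alignment")
}

#' @export
print.gh20_alignment <- function(x, ...) {
  cat(sprintf("<gh20_alignment> %.1f%% identity, score %.1f\n",
              x$identity_pct, x$score))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named list of records (`id`, `sequence`).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i)
    list(id = ids[i], sequence = as.character(set[[i]])))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param records list of records (`id`, `sequence`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.null(records$sequence)) records <- list(records)
  set <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Fetch a UniProt sequence, with a local cache
#'
#' Idempotent counterpart of [fetch_structure()] for sequences; a failed
#' download with an empty cache raises an explicit error.
#'
#' @param accession UniProt accession.
#' @param cache_dir cache directory.
#' @return record (`id`, `sequence`).
#' @export
fetch_sequence <- function(accession, cache_dir = "cache") {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(toupper(accession), ".fasta"))
  if (!file.exists(dest) || file.size(dest) == 0) {
    url <- paste0("https://rest.uniprot.org/uniprotkb/", toupper(accession),
                  ".fasta")
    ok <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("fetch failed for ", toupper(accession),
           ": no network and no cached copy in ", cache_dir)
    }
  }
  rec <- read_fasta(dest)[[1]]
  rec$id <- toupper(accession)
  rec
}
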