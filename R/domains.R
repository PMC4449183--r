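# Consensus domain architecture: per-database annotation integration,
# Model A / Model B classification, and the GH20b-GH20 interface.

DOMAIN_VOCAB <- c("GH20", "GH20b", "alpha", "Lectin", "CBM32", "CHB_HEX",
                  "CHB_HEX_C", "G5", "Ig_like", "DomainIII", "CBD")

SOURCE_PRIORITY <- c(cazy = 1, pfam = 2, superfamily = 3, scop = 4,
                     psiblast = 5, manual = 6)

#' The packaged survey of GH20 enzymes of known structure
#'
#' One row per enzyme (two for the heterodimer, one per subunit) with the
#' consensus domain string, the GH20b-GH20-alpha block location, the PDB entry
#' and chains used for structural analysis, and the solution oligomeric state
#' (`"unknown"` where it has not been determined; never inferred from crystal
#' contacts).
#'
#' @return data.frame.
#' @export
read_survey_table <- function() {
  path <- system.file("extdata", "gh20_survey.tsv", package = "gh20arch",
                      mustWork = TRUE)
  t1 <- utils::read.delim(path, stringsAsFactors = FALSE)
  t1$subunit[t1$subunit == "."] <- NA_character_
  t1
}

#' The packaged reference active-site annotations
#'
#' Conserved subsite -1 arginine / aspartate (or glutamate) residues and the
#' published remote-element key residues, keyed by accession.  The
#' lacto-N-biosidase entry carries a glutamine that substitutes the conserved
#' arginine's function from subsite -2; it is flagged in `note`.  New
#' structures receive these labels only by transfer through
#' [transfer_annotations()], never by inference.
#'
#' @return data.frame: `enzyme`, `accession`, `subunit`, `chain`,
#'   `auth_index`, `label`, `note`.
#' @export
reference_sites <- function() {
  path <- system.file("extdata", "gh20_reference_sites.tsv",
                      package = "gh20arch", mustWork = TRUE)
  rs <- utils::read.delim(path, stringsAsFactors = FALSE)
  rs$subunit[rs$subunit == "."] <- NA_character_
  rs$chain[rs$chain == "."] <- NA_character_
  rs
}

#' The packaged loop-2 / remote-element reference spans
#'
#' Published loop-2 boundaries and remote-element provenance for the Model A
#' enzymes, used for desk-scale length classification and for checking survey
#' output against the published assignments.
#'
#' @return data.frame.
#' @export
loop2_reference <- function() {
  path <- system.file("extdata", "gh20_loop2_reference.tsv",
                      package = "gh20arch", mustWork = TRUE)
  l2 <- utils::read.delim(path, stringsAsFactors = FALSE)
  l2$subunit[l2$subunit == "."] <- NA_character_
  l2
}

#' Load a per-source domain-annotation table
#'
#' Expects tab-separated columns `source`, `domain`, `start`, `end`, `chain`
#' (plus optional `enzyme`, `subunit`).  Rows with `start >= end` are rejected
#' with a message; domain names outside the controlled vocabulary are kept but
#' re-sourced as `"manual"` with a warning.
#'
#' @param table path to the TSV.
#' @return data.frame of validated annotations.
#' @export
load_annotations <- function(table) {
  ann <- utils::read.delim(table, stringsAsFactors = FALSE)
  need <- c("source", "domain", "start", "end", "chain")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(ann)) return(ann)
  bad <- ann$start >= ann$end
  if (any(bad)) {
    message("rejecting ", sum(bad), " annotation row(s) with start >= end")
    ann <- ann[!bad, , drop = FALSE]
  }
  unknown <- !ann$domain %in% DOMAIN_VOCAB
  if (any(unknown)) {
    warning("domain name(s) outside the controlled vocabulary kept as ",
            "manual: ", paste(unique(ann$domain[unknown]), collapse = ", "))
    ann$source[unknown] <- "manual"
  }
  ann$source <- tolower(ann$source)
  ann
}

#' Consensus domain architecture for one enzyme
#'
#' Overlapping spans are resolved by source priority (cazy > pfam >
#' superfamily > scop > psiblast > manual); surviving spans are ordered
#' N-terminus to C-terminus.  Same-priority overlaps that disagree on the
#' domain name are both kept and flagged in the `"conflicts"` attribute.
#'
#' @param annotations data.frame from [load_annotations()].
#' @param enzyme enzyme label to select (ignored if the table has no `enzyme`
#'   column).
#' @param subunit optional subunit label.
#' @return character vector of domain names in sequence order; attributes
#'   `spans` (the surviving rows) and `conflicts`.
#' @export
consensus_architecture <- function(annotations, enzyme = NULL,
                                   subunit = NULL) {
  ann <- annotations
  if (!is.null(enzyme) && "enzyme" %in% names(ann))
    ann <- ann[ann$enzyme == enzyme, , drop = FALSE]
  if (!is.null(subunit) && !is.na(subunit) && "subunit" %in% names(ann))
    ann <- ann[!is.na(ann$subunit) & ann$subunit == subunit, , drop = FALSE]
  if (!nrow(ann)) stop("no annotations for ", enzyme)
  pr <- SOURCE_PRIORITY[ann$source]
  pr[is.na(pr)] <- max(SOURCE_PRIORITY) + 1
  ord <- order(pr, ann$start)
  ann <- ann[ord, , drop = FALSE]
  pr <- pr[ord]
  keep <- logical(nrow(ann))
  conflicts <- character()
  for (i in seq_len(nrow(ann))) {
    prev <- which(keep)
    overl <- prev[ann$start[prev] < ann$end[i] &
                    ann$end[prev] > ann$start[i]]
    if (!length(overl)) {
      keep[i] <- TRUE
    } else if (all(pr[overl] == pr[i])) {
      # same-priority disagreement: keep both, flag
      keep[i] <- TRUE
      dis <- overl[ann$domain[overl] != ann$domain[i]]
      if (length(dis))
        conflicts <- c(conflicts, paste0(ann$domain[i], "@", ann$start[i],
                                         "-", ann$end[i]))
    }
  }
  out <- ann[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  arch <- out$domain
  attr(arch, "spans") <- out
  attr(arch, "conflicts") <- unique(conflicts)
  arch
}

#' Classify a domain architecture as Model A or Model B
#'
#' Model A: a non-catalytic GH20b domain sits immediately N-terminal to a
#' catalytic GH20 domain (the trailing alpha-helix is recorded when found but
#' not required for the call).  Model B: at least one GH20 domain and no
#' GH20b.  Anything else with a GH20 domain is `"unclassified"`; an
#' architecture without a catalytic GH20 domain is an error.
#'
#' @param architecture character vector of ordered domain names, or a single
#'   hyphen-separated string.
#' @return `"A"`, `"B"` or `"unclassified"`.
#' @export
#' @examples
#' classify_architecture("GH20b-GH20-alpha")   # "A"
#' classify_architecture("GH20")               # "B"
classify_architecture <- function(architecture) {
  if (length(architecture) == 1 && grepl("-", architecture))
    architecture <- strsplit(architecture, "-", fixed = TRUE)[[1]]
  architecture <- architecture[architecture != ""]
  if (!length(architecture)) stop("empty architecture")
  if (!"GH20" %in% architecture)
    stop("not a GH20 enzyme: no catalytic GH20 domain in ",
         paste(architecture, collapse = "-"))
  n <- length(architecture)
  a_pair <- any(architecture[-n] == "GH20b" & architecture[-1] == "GH20")
  if (a_pair) return("A")
  if (!"GH20b" %in% architecture) return("B")
  "unclassified"
}

#' Architecture calls for every enzyme in an annotation table
#'
#' Runs [consensus_architecture()] and [classify_architecture()] per
#' (enzyme, subunit); heterodimer subunits are classified separately but the
#' per-enzyme summary counts each enzyme once.
#'
#' @param annotations data.frame with at least `enzyme`, `source`, `domain`,
#'   `chain`, `start`, `end` (and optional `subunit`).
#' @return data.frame: `enzyme`, `subunit`, `architecture`, `model`.
#' @export
classify_survey <- function(annotations) {
  if (!"subunit" %in% names(annotations))
    annotations$subunit <- NA_character_
  units <- unique(annotations[, c("enzyme", "subunit")])
  rows <- lapply(seq_len(nrow(units)), function(i) {
    arch <- consensus_architecture(annotations, units$enzyme[i],
                                   units$subunit[i])
    data.frame(enzyme = units$enzyme[i], subunit = units$subunit[i],
               architecture = paste(arch, collapse = "-"),
               model = classify_architecture(arch),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-enzyme model tally
#'
#' @param calls data.frame from [classify_survey()].
#' @return data.frame `enzyme`, `model` with one row per enzyme (subunits
#'   collapsed; mixed-model subunits would be reported as `"mixed"`).
#' @export
enzyme_models <- function(calls) {
  sp <- split(calls$model, calls$enzyme)
  data.frame(enzyme = names(sp),
             model = vapply(sp, function(m)
               if (length(unique(m)) == 1) m[1] else "mixed", ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Residue contacts across a two-domain interface
#'
#' All residue pairs with any heavy-atom distance at or below `cutoff`
#' between two disjoint spans of one chain, with per-side merged segments.
#'
#' @param structure a `gh20_structure`.
#' @param span_a,span_b `c(start, end)` author-number ranges (disjoint).
#' @param chain chain identifier (default: first protein chain).
#' @param cutoff heavy-atom distance cutoff, angstrom (default 4.5).
#' @return list with `pairs` (data.frame `res_a`, `res_b`, `min_distance`)
#'   and `segments_a`, `segments_b` (merged author-number ranges).
#' @export
interface_residues <- function(structure, span_a, span_b, chain = NULL,
                               cutoff = 4.5) {
  if (span_a[1] <= span_b[2] && span_b[1] <= span_a[2])
    stop("interface spans overlap")
  a <- structure$atoms
  if (is.null(chain)) chain <- a$chain[!a$water][1]
  sel <- function(span) {
    idx <- which(!a$water & a$chain == chain & a$resno >= span[1] &
                   a$resno <= span[2])
    if (!length(idx)) stop("span ", span[1], "-", span[2], " is empty")
    idx
  }
  ia <- sel(span_a); ib <- sel(span_b)
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  ka <- residue_key(a$chain[ia], a$resno[ia], a$ins[ia])
  kb <- residue_key(a$chain[ib], a$resno[ib], a$ins[ib])
  pairs <- list()
  for (ra in unique(ka)) {
    m <- xa[ka == ra, , drop = FALSE]
    for (rb in unique(kb)) {
      nmat <- xb[kb == rb, , drop = FALSE]
      d2 <- outer(rowSums(m^2), rowSums(nmat^2), "+") - 2 * m %*% t(nmat)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= cutoff)
        pairs[[length(pairs) + 1L]] <- data.frame(
          res_a = ra, res_b = rb, min_distance = dmin,
          stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(res_a = character(), res_b = character(),
               min_distance = numeric())
  seg <- function(keys) {
    if (!length(keys)) return(data.frame(start = integer(), end = integer()))
    resno <- sort(unique(as.integer(sub("^.*:", "", keys))))
    grp <- cumsum(c(1, diff(resno) > 1))
    do.call(rbind, lapply(split(resno, grp), function(r)
      data.frame(start = min(r), end = max(r))))
  }
  list(pairs = pairs, segments_a = seg(pairs$res_a),
       segments_b = seg(pairs$res_b))
}
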