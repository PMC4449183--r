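# Subsite -1 anchoring, loop-2 classification, typed contact detection and
# the remote-element search that explains how the substrate-binding cavity is
# completed (long loop 2, an accompanying domain, or the dimer partner).

POLAR_CUTOFF <- 3.5      # angstrom, donor/acceptor heavy atoms
NONPOLAR_CUTOFF <- 4.5   # angstrom, apolar heavy-atom pairs
LIGAND_SHELL <- 4.0      # angstrom, first-shell exclusion around a ligand
NEIGHBOR_EXCLUSION <- 5  # sequence window excluded around the anchor pair
LOOP2_LONG_MIN <- 12     # residues: published short loops are 6-11, long 15-30

#' Anchor the conserved subsite -1 Arg/Asp(Glu) pair
#'
#' One active site per labeled catalytic-domain instance: the labels
#' (`cons_arg`, `cons_acid`) come from the packaged reference
#' ([reference_sites()]) or from [transfer_annotations()]; they are never
#' inferred.  Multiple label pairs on one chain (tandem catalytic domains)
#' are paired in sequence order.
#'
#' @param structure a `gh20_structure`.
#' @param annotations data.frame with columns `chain`, `resno` (author
#'   number), `label`, and optional `note`.
#' @return list of `gh20_active_site` objects: `chain`, `arg_key`,
#'   `acid_key`, `site_center`, `subsite_note`.
#' @export
anchor_active_site <- function(structure, annotations) {
  need <- c("chain", "resno", "label")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns ", paste(need, collapse = ", "))
  rt <- residues(structure)
  sites <- list()
  for (ch in unique(annotations$chain)) {
    ann <- annotations[annotations$chain == ch, , drop = FALSE]
    args <- sort(ann$resno[ann$label == "cons_arg"])
    acids <- sort(ann$resno[ann$label == "cons_acid"])
    if (!length(args) || !length(acids) || length(args) != length(acids))
      stop("structure ", structure$accession, ": chain ", ch,
           " lacks a complete cons_arg/cons_acid label pair")
    for (i in seq_along(args)) {
      akey <- residue_key(ch, args[i])
      dkey <- residue_key(ch, acids[i])
      for (k in c(akey, dkey)) if (!k %in% rt$key)
        stop("structure ", structure$accession, ": labeled residue ", k,
             " is absent")
      cen <- (side_chain_centroid(structure, akey) +
                side_chain_centroid(structure, dkey)) / 2
      note <- if ("note" %in% names(ann))
        paste(unique(stats::na.omit(ann$note[ann$resno %in%
                                               c(args[i], acids[i])])),
              collapse = "; ") else ""
      sites[[length(sites) + 1L]] <- structure(
        list(chain = ch, arg_key = akey, acid_key = dkey, site_center = cen,
             subsite_note = note),
        class = "gh20_active_site")
    }
  }
  sites
}

side_chain_centroid <- function(structure, key) {
  a <- structure$atoms
  sel <- residue_key(a$chain, a$resno, a$ins) == key
  sc <- a[sel & !a$elety %in% BACKBONE_ATOMS, c("x", "y", "z"), drop = FALSE]
  if (!nrow(sc)) sc <- a[sel & a$elety == "CA", c("x", "y", "z"),
                         drop = FALSE]
  colMeans(as.matrix(sc))
}

#' @export
print.gh20_active_site <- function(x, ...) {
  cat("<gh20_active_site>", x$arg_key, "/", x$acid_key,
      if (nzchar(x$subsite_note)) paste0("(", x$subsite_note, ")") else "",
      "\n")
  invisible(x)
}

#' Classify barrel loop 2 as Long or Short
#'
#' Loop 2 (after barrel strand beta-2) supplies the remote element itself
#' when long; the published short loops are 6-11 residues and the long ones
#' 15-30, so the boundary sits at `threshold` (>= 12 residues is Long).
#'
#' @param barrel a `gh20_barrel`.
#' @param threshold minimum Long length (default 12).
#' @return list with `loop` (one-row data.frame) and `class` (`"Long"` or
#'   `"Short"`).
#' @export
classify_loop2 <- function(barrel, threshold = LOOP2_LONG_MIN) {
  loop <- extract_loop(barrel, 2)
  list(loop = loop,
       class = if (loop$length >= threshold) "Long" else "Short")
}

#' Detect typed residue-residue contacts
#'
#' Polar contact: two polar heavy atoms within `polar_cutoff` (3.5 angstrom);
#' non-polar: two apolar heavy atoms within `nonpolar_cutoff` (4.5 angstrom);
#' water-mediated (only with `water_mode`): both residues have a polar atom
#' within `polar_cutoff` of the same water oxygen.  One row per (pair, kind)
#' with the minimum distance and the atom pair realizing it.
#'
#' @param structure a `gh20_structure`.
#' @param targets,probes disjoint character vectors of residue keys
#'   (`"chain:resno"`).
#' @param water_mode include water-mediated bridges?
#' @param polar_cutoff,nonpolar_cutoff distance cutoffs, angstrom.
#' @return data.frame: `from` (target), `to` (probe), `kind`,
#'   `min_distance`, `atom_from`, `atom_to`, `bridging_water`.
#' @export
detect_contacts <- function(structure, targets, probes, water_mode = FALSE,
                            polar_cutoff = POLAR_CUTOFF,
                            nonpolar_cutoff = NONPOLAR_CUTOFF) {
  if (length(intersect(targets, probes)))
    stop("targets and probes must be disjoint")
  a <- structure$atoms
  key <- residue_key(a$chain, a$resno, a$ins)
  empty <- data.frame(from = character(), to = character(),
                      kind = character(), min_distance = numeric(),
                      atom_from = character(), atom_to = character(),
                      bridging_water = character(), stringsAsFactors = FALSE)
  rows <- list()
  ti <- which(key %in% targets & !a$water)
  pi <- which(key %in% probes & !a$water)
  if (!length(ti) || !length(pi)) return(empty)
  xt <- as.matrix(a[ti, c("x", "y", "z")])
  xp <- as.matrix(a[pi, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(xt^2), rowSums(xp^2), "+") -
                   2 * xt %*% t(xp), 0))
  pol_t <- a$polar[ti] == "polar"; pol_p <- a$polar[pi] == "polar"
  for (tk in unique(key[ti])) {
    it <- which(key[ti] == tk)
    for (pk in unique(key[pi])) {
      ip <- which(key[pi] == pk)
      sub <- d[it, ip, drop = FALSE]
      for (kind in c("polar", "nonpolar")) {
        if (kind == "polar") {
          mask <- outer(pol_t[it], pol_p[ip], "&")
          cut <- polar_cutoff
        } else {
          mask <- outer(!pol_t[it], !pol_p[ip], "&")
          cut <- nonpolar_cutoff
        }
        if (!any(mask)) next
        dm <- sub
        dm[!mask] <- Inf
        best <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        if (dm[best[1], best[2]] <= cut) {
          rows[[length(rows) + 1L]] <- data.frame(
            from = tk, to = pk, kind = kind,
            min_distance = dm[best[1], best[2]],
            atom_from = a$elety[ti[it[best[1]]]],
            atom_to = a$elety[pi[ip[best[2]]]],
            bridging_water = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (water_mode) {
    wi <- which(a$water & a$elety == "O")
    if (length(wi)) {
      xw <- as.matrix(a[wi, c("x", "y", "z"), drop = FALSE])
      dtw <- sqrt(pmax(outer(rowSums(xt^2), rowSums(xw^2), "+") -
                         2 * xt %*% t(xw), 0))
      dpw <- sqrt(pmax(outer(rowSums(xp^2), rowSums(xw^2), "+") -
                         2 * xp %*% t(xw), 0))
      for (w in seq_along(wi)) {
        t_near <- unique(key[ti][pol_t & dtw[, w] <= polar_cutoff])
        p_near <- unique(key[pi][pol_p & dpw[, w] <= polar_cutoff])
        for (tk in t_near) for (pk in p_near) {
          d1 <- min(dtw[key[ti] == tk & pol_t, w])
          d2 <- min(dpw[key[pi] == pk & pol_p, w])
          rows[[length(rows) + 1L]] <- data.frame(
            from = tk, to = pk, kind = "water_mediated",
            min_distance = max(d1, d2), atom_from = "", atom_to = "",
            bridging_water = key[wi[w]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$min_distance), , drop = FALSE]
}

#' Find the remote element completing the substrate-binding cavity
#'
#' Searches every residue contacting the conserved Arg or Asp/Glu, excluding
#' sequence neighbours (within `exclude_window` positions of either anchor)
#' and the catalytic domain's own non-loop-2 first shell.  The surviving
#' best-contacting residue assigns the source class by provenance: `loop2`
#' when it lies in barrel loop 2, `partner_chain` when it comes from another
#' chain, `accompanying_domain` otherwise.  Key residues are chosen purely by
#' contact distance (ties to the smaller author number) - residue chemistry
#' is reported, not used for selection.
#'
#' @param structure a `gh20_structure`.
#' @param site a `gh20_active_site`.
#' @param loop2 list from [classify_loop2()] (or `NULL` when no barrel was
#'   detectable).
#' @param gh20_span `c(start, end)` author-number range of the catalytic
#'   domain on the site's chain.
#' @param domains optional data.frame (`domain`, `start`, `end`) naming
#'   accompanying-domain spans for labeling.
#' @param water_mode passed to [detect_contacts()].
#' @param polar_cutoff,nonpolar_cutoff,exclude_window tunable cutoffs.
#' @return a `gh20_remote_element`: `source` (`"loop2"`,
#'   `"accompanying_domain"`, `"partner_chain"` or `"none"`), `source_label`,
#'   `span`, `key_residues`, `contacts`.
#' @export
find_remote_element <- function(structure, site, loop2, gh20_span,
                                domains = NULL, water_mode = FALSE,
                                polar_cutoff = POLAR_CUTOFF,
                                nonpolar_cutoff = NONPOLAR_CUTOFF,
                                exclude_window = NEIGHBOR_EXCLUSION) {
  rt <- residues(structure)
  rt <- rt[!rt$water & !rt$het, , drop = FALSE]
  anchors <- c(site$arg_key, site$acid_key)
  anchor_resno <- as.integer(sub("^.*:", "", anchors))
  in_loop2 <- function(chain, resno) {
    !is.null(loop2) && chain == loop2$loop$chain &&
      resno >= loop2$loop$start && resno <= loop2$loop$end
  }
  cand <- character()
  for (i in seq_len(nrow(rt))) {
    ch <- rt$chain[i]; rn <- rt$resno[i]; k <- rt$key[i]
    if (k %in% anchors) next
    if (ch == site$chain && any(abs(rn - anchor_resno) <= exclude_window))
      next
    if (ch == site$chain && rn >= gh20_span[1] && rn <= gh20_span[2] &&
        !in_loop2(ch, rn)) next
    cand <- c(cand, k)
  }
  none <- structure(list(source = "none", source_label = NA_character_,
                         span = NULL, key_residues = character(),
                         contacts = NULL),
                    class = "gh20_remote_element")
  if (!length(cand)) return(none)
  ct <- detect_contacts(structure, anchors, cand, water_mode = water_mode,
                        polar_cutoff = polar_cutoff,
                        nonpolar_cutoff = nonpolar_cutoff)
  if (!nrow(ct)) return(none)
  ct$to_chain <- sub(":.*$", "", ct$to)
  ct$to_resno <- as.integer(sub("^.*:", "", ct$to))
  src_of <- function(chain, resno) {
    if (chain != site$chain) "partner_chain"
    else if (in_loop2(chain, resno)) "loop2"
    else "accompanying_domain"
  }
  ct$src <- mapply(src_of, ct$to_chain, ct$to_resno)
  ord <- order(ct$min_distance, ct$to_resno)
  best <- ct[ord[1], ]
  source <- best$src
  sel <- ct[ct$src == source, , drop = FALSE]
  span <- c(min(sel$to_resno), max(sel$to_resno))
  label <- switch(source,
    loop2 = "loop2",
    partner_chain = best$to_chain,
    accompanying_domain = {
      lab <- NA_character_
      if (!is.null(domains)) {
        hit <- which(domains$start <= best$to_resno &
                       domains$end >= best$to_resno)
        if (length(hit)) lab <- domains$domain[hit[1]]
      }
      if (is.na(lab)) "accompanying" else lab
    })
  structure(list(source = source, source_label = label, span = span,
                 key_residues = best$to, contacts = sel),
            class = "gh20_remote_element")
}

#' @export
print.gh20_remote_element <- function(x, ...) {
  if (x$source == "none") {
    cat("<gh20_remote_element> no remote element\n")
  } else {
    cat("<gh20_remote_element>", x$source, "(", x$source_label, ") span",
        paste(x$span, collapse = "-"), "key", x$key_residues, "\n")
  }
  invisible(x)
}

#' Second-shell membership of a residue
#'
#' A residue is second shell when it contacts the conserved Arg or Asp/Glu
#' (any contact kind) while not touching the ligand itself (no heavy atom
#' within `ligand_cutoff` of the ligand, when one is present).  The anchor
#' residues themselves are excluded.
#'
#' @param structure a `gh20_structure`.
#' @param residue residue key.
#' @param site a `gh20_active_site`.
#' @param ligand optional ligand residue key.
#' @param ligand_cutoff first-shell distance, angstrom (default 4.0).
#' @return logical flag.
#' @export
second_shell_membership <- function(structure, residue, site, ligand = NULL,
                                    ligand_cutoff = LIGAND_SHELL) {
  if (residue %in% c(site$arg_key, site$acid_key)) return(FALSE)
  ct <- detect_contacts(structure, c(site$arg_key, site$acid_key), residue)
  if (!nrow(ct)) return(FALSE)
  if (!is.null(ligand)) {
    a <- structure$atoms
    key <- residue_key(a$chain, a$resno, a$ins)
    xr <- as.matrix(a[key == residue, c("x", "y", "z"), drop = FALSE])
    xl <- as.matrix(a[key == ligand, c("x", "y", "z"), drop = FALSE])
    if (nrow(xl)) {
      d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * xr %*% t(xl)
      if (min(d2) <= ligand_cutoff^2) return(FALSE)
    }
  }
  TRUE
}

#' Assemble a remote-element survey report
#'
#' One row per (enzyme, active site): loop-2 length class and span, remote
#' element source and span, the conserved pair, and the non-polar / polar
#' contact partners.  Enzymes listed in `calls` with no analysis get
#' `"missing"` markers rather than being dropped.
#'
#' @param calls data.frame from [classify_survey()] (needs `enzyme`,
#'   `model`).
#' @param elements named list: for each analyzed unit, a list with fields
#'   `enzyme`, `site` (label), `loop2` (from [classify_loop2()]), `element`
#'   (from [find_remote_element()]), `cons_pair` (label).
#' @return a `gh20_report` data.frame.
#' @export
build_report <- function(calls, elements) {
  rows <- list()
  fmt_span <- function(sp) if (is.null(sp)) "." else paste(sp, collapse = "-")
  partners <- function(el, kind) {
    if (is.null(el$contacts) || !nrow(el$contacts)) return(".")
    p <- unique(el$contacts$to[el$contacts$kind == kind])
    if (!length(p)) "." else paste(p, collapse = ",")
  }
  done <- character()
  for (e in elements) {
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = e$enzyme, site = e$site,
      loop2_class = if (is.null(e$loop2)) "missing" else e$loop2$class,
      loop2_span = if (is.null(e$loop2)) "missing" else
        fmt_span(c(e$loop2$loop$start, e$loop2$loop$end)),
      remote_source = e$element$source,
      remote_span = fmt_span(e$element$span),
      cons_pair = e$cons_pair,
      nonpolar_partners = partners(e$element, "nonpolar"),
      polar_partners = partners(e$element, "polar"),
      status = "analyzed", stringsAsFactors = FALSE)
    done <- c(done, e$enzyme)
  }
  need <- unique(calls$enzyme[calls$model == "A"])
  for (enz in setdiff(need, done)) {
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = enz, site = "missing", loop2_class = "missing",
      loop2_span = "missing", remote_source = "missing",
      remote_span = "missing", cons_pair = "missing",
      nonpolar_partners = "missing", polar_partners = "missing",
      status = "missing", stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(), site = character(),
               loop2_class = character(), loop2_span = character(),
               remote_source = character(), remote_span = character(),
               cons_pair = character(), nonpolar_partners = character(),
               polar_partners = character(), status = character())
  class(out) <- c("gh20_report", class(out))
  out
}
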