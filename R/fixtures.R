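# Synthetic structure generators with embedded ground truth.
#
# Everything here is deliberately idealized: backbone (+CB) geometry tuned so
# that the Kabsch-Sander hydrogen-bond model recovers exactly the designed
# bonds, and nothing else.  Fixtures are written/read as standard PDB so the
# same I/O path is exercised as for deposited structures.

# --- internal geometry helpers ------------------------------------------

unitv <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D given A-B-C, bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

atom_row <- function(chain, resno, resid, elety, xyz, het = FALSE,
                     water = FALSE) {
  elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  data.frame(chain = chain, resno = as.integer(resno), ins = "",
             resid = resid, elety = elety, elesy = elesy,
             x = xyz[1], y = xyz[2], z = xyz[3], o = 1,
             het = het, water = water, stringsAsFactors = FALSE)
}

finish_fixture <- function(rows, ground_truth, accession) {
  atoms <- do.call(rbind, rows)
  atoms$backbone <- !atoms$water & atoms$elety %in% BACKBONE_ATOMS
  atoms$polar <- suppressWarnings(
    classify_atom_polarity(atoms$resid, atoms$elety, atoms$elesy))
  s <- new_gh20_structure(atoms, accession = accession)
  attr(s, "ground_truth") <- ground_truth
  s
}

#' Generate an ideal alpha-helix
#'
#' Backbone built from ideal internal coordinates (phi = -57, psi = -47,
#' omega = 180 degrees), which places every N--H(i) donor 2.9-3.0 angstrom
#' from the O(i-4) acceptor, so hydrogen-bond based secondary-structure
#' assignment recovers the helix by construction.  Ground truth (the expected
#' per-residue labels) is attached as `attr(x, "ground_truth")`.
#'
#' @param n number of residues (>= 5).
#' @param chain chain identifier.
#' @param resno_start author number of the first residue.
#' @return a `gh20_structure` of `n` glycine residues.
#' @export
make_ideal_helix <- function(n, chain = "A", resno_start = 1L) {
  if (n < 5) stop("a helix fixture needs at least 5 residues")
  phi <- -57; psi <- -47; omega <- 180
  rows <- list()
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.2, 60)  # seed orientation
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, 1.231, 120.5, psi + 180)
    resno <- resno_start + i - 1L
    rows[[length(rows) + 1L]] <- rbind(
      atom_row(chain, resno, "GLY", "N", N),
      atom_row(chain, resno, "GLY", "CA", CA),
      atom_row(chain, resno, "GLY", "C", C),
      atom_row(chain, resno, "GLY", "O", O))
    if (i < n) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2, psi)
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7, omega)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.2, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  gt <- list(kind = "helix", n = n, chain = chain,
             h_span = c(resno_start + 1L, resno_start + n - 1L))
  finish_fixture(rows, gt, "HELIX-FIXTURE")
}

# shared geometry constants for idealized beta elements
.BETA_RISE <- 3.5      # axial spacing per residue, angstrom
.BETA_NC <- 1.085      # N/C axial offset from CA (tuned so C(i)-N(i+1) = 1.33)
.BETA_CO <- 1.23       # C=O bond length
.BETA_SPACING <- 4.8   # inter-strand CA spacing

# one idealized strand residue: CA at `ca`, chain axis `u` (unit), carbonyl
# side direction `dO` (unit, horizontal)
strand_residue_atoms <- function(chain, resno, resid, ca, u, dO,
                                 cb_dir = NULL) {
  N <- ca - .BETA_NC * u
  C <- ca + .BETA_NC * u
  O <- C + .BETA_CO * dO
  out <- rbind(atom_row(chain, resno, resid, "N", N),
               atom_row(chain, resno, resid, "CA", ca),
               atom_row(chain, resno, resid, "C", C),
               atom_row(chain, resno, resid, "O", O))
  if (!is.null(cb_dir))
    out <- rbind(out, atom_row(chain, resno, resid, "CB",
                               ca + 1.53 * cb_dir))
  out
}

# coil residue with an explicitly chosen C->O direction (defaults to `away`)
coil_residue_atoms <- function(chain, resno, pos, dir_chain, o_dir) {
  N <- pos
  CA <- pos + 0.9 * dir_chain
  C <- pos + 1.8 * dir_chain
  O <- C - .BETA_CO * o_dir  # analyzer infers next H along (C - O)
  rbind(atom_row(chain, resno, "GLY", "N", N),
        atom_row(chain, resno, "GLY", "CA", CA),
        atom_row(chain, resno, "GLY", "C", C),
        atom_row(chain, resno, "GLY", "O", O))
}

#' Generate an idealized antiparallel beta-hairpin
#'
#' Two strands 4.8 angstrom apart with an exact mutual hydrogen-bond ladder at
#' alternating levels, joined by a displaced coil loop that forms no bonds.
#'
#' @param strand_len residues per strand (>= 4).
#' @param loop_len residues in the connecting loop.
#' @param chain chain identifier.
#' @return a `gh20_structure` with ground-truth bond list attached.
#' @export
make_hairpin <- function(strand_len = 6, loop_len = 4, chain = "A") {
  if (strand_len < 4) stop("strand_len must be >= 4")
  rows <- list()
  xhat <- c(1, 0, 0); zhat <- c(0, 0, 1)
  resno <- 0L
  gt_bonds <- NULL
  strand_span <- matrix(NA_integer_, 2, 2)
  # residues on odd levels point their C=O (and amide H) at the partner
  # strand; even levels point away.  The N-terminal cap seeds the first
  # strand residue's inferred hydrogen.
  side <- function(s, lev) {
    toward <- if (s == 0) xhat else -xhat
    if (lev %% 2 == 1) toward else -toward
  }
  resno <- resno + 1L
  rows[[length(rows) + 1L]] <- coil_residue_atoms(
    chain, resno, c(0, -5, -6), zhat, side(0, 0))
  level_resno <- matrix(NA_integer_, 2, strand_len)  # [strand, level+1]
  ztop <- .BETA_RISE * (strand_len - 1)
  for (s in 0:1) {
    x0 <- s * .BETA_SPACING
    u <- if (s == 0) zhat else -zhat
    strand_span[s + 1, 1] <- resno + 1L
    for (t in 0:(strand_len - 1)) {
      lev <- if (s == 0) t else strand_len - 1 - t
      resno <- resno + 1L
      level_resno[s + 1, lev + 1] <- resno
      ca <- c(x0, 0, .BETA_RISE * lev)
      rows[[length(rows) + 1L]] <- strand_residue_atoms(
        chain, resno, "GLY", ca, u, side(s, lev))
    }
    strand_span[s + 1, 2] <- resno
    if (s == 0) {
      # loop: vertical stack displaced in +y, far from both strands; the last
      # loop residue's C=O seeds the next strand's first amide hydrogen
      for (k in seq_len(loop_len)) {
        resno <- resno + 1L
        pos <- c(2.4, 6, ztop + 5 + .BETA_RISE * (k - 1))
        odir <- if (k == loop_len) side(1, strand_len - 1) else c(0, 1, 0)
        rows[[length(rows) + 1L]] <- coil_residue_atoms(
          chain, resno, pos, zhat, odir)
      }
    }
  }
  # designed mutual bonds: levels where the strands point at each other
  for (lev in 0:(strand_len - 1)) {
    if (lev %% 2 == 1) {
      i <- level_resno[1, lev + 1]; j <- level_resno[2, lev + 1]
      gt_bonds <- rbind(gt_bonds, data.frame(donor = c(i, j),
                                             acceptor = c(j, i)))
    }
  }
  gt <- list(kind = "hairpin", chain = chain, strand_len = strand_len,
             loop_len = loop_len,
             strands = data.frame(start = strand_span[, 1],
                                  end = strand_span[, 2]),
             bonds = gt_bonds)
  finish_fixture(rows, gt, "HAIRPIN-FIXTURE")
}

#' Generate a closed mini beta-barrel with numbered loops
#'
#' `n_strands` idealized strands arranged on a cylinder (adjacent-strand
#' spacing 4.8 angstrom) as a closed antiparallel meander: strand k is
#' hydrogen bonded to strands k-1 and k+1 (indices cyclic), so the strand
#' adjacency graph is a single cycle and the barrel closes.  Strands are
#' joined in sequence order by displaced coil loops of the requested lengths;
#' `loop_lengths[k]` follows strand k (the last entry is a C-terminal tail).
#' Residues carry CB atoms pointing outward so planted non-polar contacts have
#' a target.  Ground truth (strand spans, loop spans, bond register) is
#' attached as `attr(x, "ground_truth")`.
#'
#' @param n_strands number of strands (>= 4, even; default 8).
#' @param loop_lengths integer vector, one loop length per strand.
#' @param strand_len residues per strand (>= 4).
#' @param chain chain identifier.
#' @param loop2_waypoint optional 3-vector: the middle residue of loop 2 is
#'   pulled to this position (used to emulate a long loop 2 folding back onto
#'   the active site).
#' @return a `gh20_structure`.
#' @export
make_mini_barrel <- function(n_strands = 8, loop_lengths = rep(4, n_strands),
                             strand_len = 8, chain = "A",
                             loop2_waypoint = NULL) {
  if (n_strands < 4) stop("need at least 4 strands")
  if (n_strands %% 2 != 0)
    stop("antiparallel meander barrel needs an even strand count")
  if (length(loop_lengths) != n_strands)
    stop("loop_lengths must have one entry per strand")
  if (strand_len < 4) stop("strand_len must be >= 4")
  if (strand_len %% 2 != 0)
    stop("strand_len must be even (keeps the bond register consistent at ",
         "strand-to-strand transitions)")
  S <- n_strands; L <- strand_len
  R <- .BETA_SPACING / (2 * sin(pi / S))
  theta <- 2 * pi * (0:(S - 1)) / S
  P <- cbind(R * cos(theta), R * sin(theta), 0)
  zhat <- c(0, 0, 1)
  ztop <- .BETA_RISE * (L - 1)
  rows <- list()
  resno <- 0L
  strands_gt <- data.frame(index = seq_len(S), start = NA_integer_,
                           end = NA_integer_)
  loops_gt <- data.frame(index = seq_len(S), start = NA_integer_,
                         end = NA_integer_, length = as.integer(loop_lengths))
  # residue (s, lev) points its C=O/N-H pair at strand s+1 when (s+lev) is
  # odd, at strand s-1 otherwise; this parity makes the inferred amide H of
  # the first residue after a strand-to-strand transition come out exactly
  # right even with a zero-length loop
  side_dir <- function(s, lev) {   # unit horizontal C=O direction, 0-based s
    toward <- if ((s + lev) %% 2 == 1) (s + 1) %% S else (s - 1) %% S
    unitv(P[toward + 1, ] - P[s + 1, ])
  }
  first_dO <- function(s) {        # side of the first-in-chain strand residue
    lev0 <- if (s %% 2 == 0) 0 else L - 1
    side_dir(s, lev0)
  }
  # N-terminal cap seeds the amide hydrogen of the first strand residue
  resno <- resno + 1L
  cap_pos <- P[1, ] * ((R + 6) / R) + c(0, 0, -7)
  rows[[length(rows) + 1L]] <- coil_residue_atoms(
    chain, resno, cap_pos, zhat, first_dO(0))
  level_resno <- matrix(NA_integer_, S, L)
  for (s in 0:(S - 1)) {
    u <- if (s %% 2 == 0) zhat else -zhat
    rhat <- unitv(c(P[s + 1, 1], P[s + 1, 2], 0))
    strands_gt$start[s + 1] <- resno + 1L
    for (t in 0:(L - 1)) {
      lev <- if (s %% 2 == 0) t else L - 1 - t
      resno <- resno + 1L
      level_resno[s + 1, lev + 1] <- resno
      ca <- P[s + 1, ] + c(0, 0, .BETA_RISE * lev)
      rows[[length(rows) + 1L]] <- strand_residue_atoms(
        chain, resno, "ALA", ca, u, side_dir(s, lev), cb_dir = rhat)
    }
    strands_gt$end[s + 1] <- resno
    nl <- loop_lengths[s + 1]
    if (nl > 0) {
      loops_gt$start[s + 1] <- resno + 1L
      at_top <- s %% 2 == 0      # even strands end at the top
      s_next <- (s + 1) %% S
      th <- theta[s + 1] + pi / S     # between the two strands
      rl <- R + 5
      for (k in seq_len(nl)) {
        resno <- resno + 1L
        zl <- if (at_top) ztop + 6 + .BETA_RISE * (k - 1)
              else -6 - .BETA_RISE * (k - 1)
        pos <- c(rl * cos(th), rl * sin(th), zl)
        waypoint <- !is.null(loop2_waypoint) && s + 1 == 2 &&
          k == ceiling(nl / 2)
        if (waypoint) pos <- loop2_waypoint
        odir <- if (k == nl && s < S - 1) first_dO(s_next)
                else if (waypoint) -unitv(c(pos[1], pos[2], 0))
                else unitv(c(cos(th), sin(th), 0))
        rows[[length(rows) + 1L]] <- coil_residue_atoms(
          chain, resno, pos, if (at_top) zhat else -zhat, odir)
      }
      loops_gt$end[s + 1] <- resno
    }
  }
  gt <- list(kind = "mini_barrel", chain = chain, n_strands = S,
             strand_len = L, strands = strands_gt, loops = loops_gt,
             level_resno = level_resno, radius = R)
  finish_fixture(rows, gt, "BARREL-FIXTURE")
}

#' Plant a contact pair at a controlled distance
#'
#' Adds a probe residue whose designated atom (backbone N for polar probes, CB
#' for non-polar) sits exactly `distance` angstrom from a chosen target atom,
#' with the rest of the probe strung further away so no unintended contacts
#' appear.  Ground truth is appended to `attr(x, "ground_truth")$planted`.
#'
#' @param structure a `gh20_structure`.
#' @param kind `"polar"` or `"nonpolar"`.
#' @param distance target distance in angstrom (> 1.5).
#' @param cross_chain place the probe on a new chain `"Z"`?
#' @param target_key residue key (`"chain:resno"`) of the target residue;
#'   default: the residue whose relevant atom lies furthest from the centroid.
#' @param probe_resno author number for the probe residue (default: max + 10).
#' @return the augmented `gh20_structure`.
#' @export
plant_contact_pair <- function(structure, kind = c("polar", "nonpolar"),
                               distance, cross_chain = FALSE,
                               target_key = NULL, probe_resno = NULL) {
  kind <- match.arg(kind)
  if (distance <= 1.5) stop("distance must exceed 1.5 angstrom")
  a <- structure$atoms
  want_elety <- if (kind == "polar") "O" else "CB"
  cand <- which(!a$water & !a$het & a$elety == want_elety)
  if (!length(cand)) stop("no suitable target atom (", want_elety, ") found")
  keys <- residue_key(a$chain, a$resno, a$ins)
  if (!is.null(target_key)) {
    cand <- cand[keys[cand] == target_key]
    if (!length(cand)) stop("target residue ", target_key, " lacks a ",
                            want_elety, " atom")
  }
  cen <- colMeans(a[!a$water, c("x", "y", "z")])
  xyz <- as.matrix(a[cand, c("x", "y", "z"), drop = FALSE])
  d2 <- rowSums(sweep(xyz, 2, cen)^2)
  ti <- cand[which.max(d2)]
  tpos <- as.numeric(a[ti, c("x", "y", "z")])
  # approach horizontally (perpendicular to the fixtures' chain axes) so the
  # probe string does not graze the target's own backbone neighbours
  dir <- c(tpos[1] - cen[1], tpos[2] - cen[2], 0)
  dir <- if (sqrt(sum(dir^2)) > 1) unitv(dir) else unitv(tpos - cen)
  # and perpendicular to the target atom's bond, so the designated pair is
  # the closest atom pair at exactly the requested distance
  anchor_elety <- if (kind == "polar") "C" else "CA"
  ai <- which(keys == keys[ti] & a$elety == anchor_elety)
  if (length(ai)) {
    bvec <- unitv(tpos - as.numeric(a[ai[1], c("x", "y", "z")]))
    perp <- dir - sum(dir * bvec) * bvec
    if (sqrt(sum(perp^2)) > 0.1) dir <- unitv(perp)
  }
  p0 <- tpos + distance * dir
  chain <- if (cross_chain) "Z" else a$chain[ti]
  if (is.null(probe_resno))
    probe_resno <- if (cross_chain) 1L else max(a$resno[a$chain == chain]) + 10L
  if (kind == "polar") {
    resid <- "GLY"
    probe <- rbind(atom_row(chain, probe_resno, resid, "N", p0),
                   atom_row(chain, probe_resno, resid, "CA", p0 + 1.46 * dir),
                   atom_row(chain, probe_resno, resid, "C", p0 + 2.99 * dir),
                   atom_row(chain, probe_resno, resid, "O",
                            p0 + 2.99 * dir + 1.23 * c(0, 0, 1)))
    patom <- "N"
  } else {
    resid <- "ALA"
    probe <- rbind(atom_row(chain, probe_resno, resid, "CB", p0),
                   atom_row(chain, probe_resno, resid, "CA", p0 + 1.52 * dir),
                   atom_row(chain, probe_resno, resid, "N",
                            p0 + 1.52 * dir + 1.46 * c(0, 0, 1)),
                   atom_row(chain, probe_resno, resid, "C", p0 + 3.05 * dir),
                   atom_row(chain, probe_resno, resid, "O", p0 + 4.28 * dir))
    patom <- "CB"
  }
  # clash guard
  pxyz <- as.matrix(probe[, c("x", "y", "z")])
  axyz <- as.matrix(a[, c("x", "y", "z")])
  for (i in seq_len(nrow(pxyz))) {
    dmin <- sqrt(min(rowSums(sweep(axyz, 2, pxyz[i, ])^2)))
    if (dmin < 1.5) stop("planted probe clashes with existing atoms (",
                         round(dmin, 2), " angstrom)")
  }
  probe$backbone <- !probe$water & probe$elety %in% BACKBONE_ATOMS
  probe$polar <- suppressWarnings(
    classify_atom_polarity(probe$resid, probe$elety, probe$elesy))
  out <- new_gh20_structure(rbind(a, probe), accession = structure$accession,
                            resolution = structure$resolution)
  gt <- attr(structure, "ground_truth")
  gt$planted <- rbind(gt$planted, data.frame(
    target = keys[ti], probe = residue_key(chain, probe_resno),
    kind = kind, distance = distance, target_atom = want_elety,
    probe_atom = patom, stringsAsFactors = FALSE))
  attr(out, "ground_truth") <- gt
  out
}

#' Remove a residue span from a structure
#'
#' Utility for ablation experiments (e.g. deleting an accompanying domain
#' before re-running the remote-element search).
#'
#' @param structure a `gh20_structure`.
#' @param chain chain identifier.
#' @param from,to author-number range to drop (`to = Inf` for "onward").
#' @return the truncated `gh20_structure`.
#' @export
ablate_span <- function(structure, chain, from, to = Inf) {
  a <- structure$atoms
  drop <- a$chain == chain & a$resno >= from & a$resno <= to & !a$water
  out <- new_gh20_structure(a[!drop, , drop = FALSE],
                            accession = structure$accession,
                            resolution = structure$resolution)
  attr(out, "ground_truth") <- attr(structure, "ground_truth")
  out
}

#' Build a synthetic Model A-like assembly for remote-element analysis
#'
#' A mini barrel stands in for the catalytic domain, two mid-barrel strand
#' residues are labeled as the conserved subsite -1 pair, and a contacting
#' element is placed according to `remote`: a long loop 2 folded back onto
#' the site (`"loop2"`), a probe residue in a separate C-terminal
#' "accompanying domain" span (`"accompanying_domain"`), or a probe on a
#' second chain (`"partner_chain"`).  Ground truth records the expected
#' source class, key residue and contact distance.
#'
#' @param remote the remote-element scenario.
#' @param contact_distance planted polar contact distance, angstrom.
#' @return list: `structure`, `annotations` (for [anchor_active_site()]),
#'   `gh20_span`, `domains`, `ground_truth`.
#' @export
make_remote_demo <- function(remote = c("loop2", "accompanying_domain",
                                        "partner_chain"),
                             contact_distance = 3.2) {
  remote <- match.arg(remote)
  loops <- c(4, if (remote == "loop2") 15 else 6, 4, 4, 4, 4, 4, 3)
  base <- make_mini_barrel(8, loop_lengths = loops, strand_len = 8)
  gt0 <- attr(base, "ground_truth")
  # conserved pair: mid-level residues of strands 5 and 4 (far in sequence
  # from loop 2 and from each other's +/-5 window)
  arg_resno <- gt0$level_resno[5, 4]
  acid_resno <- gt0$level_resno[4, 4]
  a <- base$atoms
  oi <- which(a$resno == arg_resno & a$elety == "O")
  o_pos <- as.numeric(a[oi, c("x", "y", "z")])
  dir <- unitv(c(o_pos[1], o_pos[2], 0))  # radially outward
  probe_pos <- o_pos + contact_distance * dir
  if (remote == "loop2") {
    s <- make_mini_barrel(8, loop_lengths = loops, strand_len = 8,
                          loop2_waypoint = probe_pos)
    gt0 <- attr(s, "ground_truth")
    l2 <- gt0$loops[2, ]
    probe_resno <- l2$start + ceiling(l2$length / 2) - 1L
    probe_key <- residue_key("A", probe_resno)
    domains <- NULL
  } else {
    cross <- remote == "partner_chain"
    probe_resno <- if (cross) 1L else max(a$resno) + 60L
    s <- plant_contact_pair(base, "polar", contact_distance,
                            cross_chain = cross,
                            target_key = residue_key("A", arg_resno),
                            probe_resno = probe_resno)
    probe_key <- residue_key(if (cross) "Z" else "A", probe_resno)
    domains <- if (!cross)
      data.frame(domain = "Lectin", start = probe_resno - 10L,
                 end = probe_resno + 10L, stringsAsFactors = FALSE)
  }
  gh20_span <- c(min(gt0$strands$start),
                 max(gt0$loops$end, gt0$strands$end, na.rm = TRUE))
  annotations <- data.frame(
    chain = "A", resno = c(arg_resno, acid_resno),
    label = c("cons_arg", "cons_acid"), stringsAsFactors = FALSE)
  gt <- attr(s, "ground_truth")
  gt$remote <- list(source = remote, key = probe_key,
                    distance = contact_distance,
                    arg_key = residue_key("A", arg_resno),
                    acid_key = residue_key("A", acid_resno))
  attr(s, "ground_truth") <- gt
  list(structure = s, annotations = annotations, gh20_span = gh20_span,
       domains = domains, ground_truth = gt)
}

#' Write the surveyed-enzyme domain table as an annotation TSV
#'
#' Expands the packaged consensus survey of the thirteen GH20 enzymes of known
#' structure into the per-source domain-annotation schema consumed by
#' [load_annotations()].  Domain order is encoded through synthetic placeholder
#' spans (the published survey records domain order, not boundaries); spans for
#' which real boundaries are published are kept.
#'
#' @param path output TSV path (default: a deterministic file in `tempdir()`).
#' @return the path, invisibly usable by [load_annotations()].
#' @export
make_toy_annotations <- function(path = file.path(tempdir(),
                                                  "gh20_toy_annotations.tsv")) {
  t1 <- read_survey_table()
  rows <- list()
  for (i in seq_len(nrow(t1))) {
    doms <- strsplit(t1$domains[i], "-", fixed = TRUE)[[1]]
    doms <- doms[doms != ""]
    for (j in seq_along(doms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = t1$enzyme[i], subunit = t1$subunit[i], source = "cazy",
        domain = doms[j], chain = t1$chain[i],
        start = 100L * j + 1L, end = 100L * j + 90L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
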