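# Hydrogen-bond based secondary structure, (beta/alpha)8 barrel detection and
# numbered barrel loops.

KS_Q <- 27.888          # 0.084 * 332, kcal/mol * angstrom
HBOND_CUTOFF <- -0.5    # kcal/mol

# ordered protein residue table with backbone coordinate columns
backbone_table <- function(structure) {
  rt <- residues(structure)
  rt <- rt[!rt$water & !rt$het, , drop = FALSE]
  rt$pos <- seq_len(nrow(rt))
  a <- structure$atoms
  akey <- residue_key(a$chain, a$resno, a$ins)
  for (at in c("N", "CA", "C", "O")) {
    idx <- match(rt$key, akey[a$elety == at])
    sub <- a[a$elety == at, c("x", "y", "z"), drop = FALSE]
    m <- as.matrix(sub)[idx, , drop = FALSE]
    rt[[paste0(at, "x")]] <- m[, 1]
    rt[[paste0(at, "y")]] <- m[, 2]
    rt[[paste0(at, "z")]] <- m[, 3]
  }
  rt
}

#' Backbone hydrogen bonds by the Kabsch-Sander electrostatic model
#'
#' Amide hydrogens are inferred from the previous residue's C=O direction
#' (H = N + unit(C_prev - O_prev)); the bond energy is the standard
#' electrostatic dipole model `E = 27.888 (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)`
#' and a bond is recorded when `E < cutoff`.  Prolines and chain-leading
#' residues cannot donate; residues with missing backbone atoms are skipped
#' with a warning.  Donor/acceptor pairs closer than two sequence positions on
#' the same chain are excluded.
#'
#' @param structure a `gh20_structure`.
#' @param cutoff energy cutoff in kcal/mol (default -0.5).
#' @param max_ca_dist CA-CA prefilter distance, angstrom.
#' @return data.frame sorted by donor: `donor`, `acceptor` (residue keys),
#'   `donor_pos`, `acceptor_pos` (ordinal positions), `energy`, `dist_no`.
#' @export
assign_backbone_hbonds <- function(structure, cutoff = HBOND_CUTOFF,
                                   max_ca_dist = 9) {
  bt <- backbone_table(structure)
  ok <- stats::complete.cases(bt[, c("Nx", "CAx", "Cx", "Ox")])
  if (any(!ok))
    warning(sum(!ok), " residue(s) missing backbone atoms; skipped")
  n <- nrow(bt)
  empty <- data.frame(donor = character(), acceptor = character(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      energy = numeric(), dist_no = numeric())
  if (n < 2) return(empty)
  Nm <- as.matrix(bt[, c("Nx", "Ny", "Nz")])
  CAm <- as.matrix(bt[, c("CAx", "CAy", "CAz")])
  Cm <- as.matrix(bt[, c("Cx", "Cy", "Cz")])
  Om <- as.matrix(bt[, c("Ox", "Oy", "Oz")])
  # inferred H for each potential donor
  Hm <- matrix(NA_real_, n, 3)
  same_chain_prev <- c(FALSE, bt$chain[-1] == bt$chain[-n])
  for (i in which(ok & same_chain_prev & bt$resid != "PRO")) {
    if (!ok[i - 1]) next
    v <- Cm[i - 1, ] - Om[i - 1, ]
    Hm[i, ] <- Nm[i, ] + v / sqrt(sum(v^2))
  }
  res <- list()
  donors <- which(!is.na(Hm[, 1]))
  for (i in donors) {
    d2 <- rowSums(sweep(CAm, 2, CAm[i, ])^2)
    cand <- which(ok & d2 <= max_ca_dist^2)
    cand <- cand[!(bt$chain[cand] == bt$chain[i] &
                     abs(bt$pos[cand] - bt$pos[i]) < 2)]
    if (!length(cand)) next
    dON <- sqrt(rowSums(sweep(Om[cand, , drop = FALSE], 2, Nm[i, ])^2))
    dOH <- sqrt(rowSums(sweep(Om[cand, , drop = FALSE], 2, Hm[i, ])^2))
    dCN <- sqrt(rowSums(sweep(Cm[cand, , drop = FALSE], 2, Nm[i, ])^2))
    dCH <- sqrt(rowSums(sweep(Cm[cand, , drop = FALSE], 2, Hm[i, ])^2))
    E <- KS_Q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
    hit <- which(E < cutoff)
    for (k in hit) {
      j <- cand[k]
      res[[length(res) + 1L]] <- data.frame(
        donor = bt$key[i], acceptor = bt$key[j],
        donor_pos = bt$pos[i], acceptor_pos = bt$pos[j],
        energy = E[k], dist_no = dON[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$donor_pos, out$acceptor_pos), , drop = FALSE]
}

#' Assign per-residue secondary structure from hydrogen bonds
#'
#' Helices come from i -> i-4 bonds (each such 4-turn labels the four residues
#' it spans); strands come from ladders of inter-strand bridges using the
#' standard parallel/antiparallel bridge rules, with runs shorter than 3
#' residues demoted to coil.  Helix wins where labels conflict.
#'
#' @param structure a `gh20_structure`.
#' @param hbonds output of [assign_backbone_hbonds()].
#' @return data.frame: `key`, `chain`, `resno`, `ins`, `ss` (`"H"`, `"E"` or
#'   `"C"`).
#' @export
assign_secondary_structure <- function(structure, hbonds) {
  bt <- backbone_table(structure)
  n <- nrow(bt)
  lab <- rep("C", n)
  hb <- matrix(FALSE, n, n)
  if (nrow(hbonds))
    hb[cbind(hbonds$donor_pos, hbonds$acceptor_pos)] <- TRUE
  same_chain <- function(i, j) bt$chain[i] == bt$chain[j]
  # consecutive-in-chain test (ordinal neighbours on the same chain)
  consec <- function(i, j) j == i + 1 && i >= 1 && j <= n && same_chain(i, j)
  # helices: 4-turns
  is_e <- rep(FALSE, n)
  is_h <- rep(FALSE, n)
  if (nrow(hbonds)) {
    turns <- hbonds[hbonds$donor_pos - hbonds$acceptor_pos == 4 &
                      bt$chain[hbonds$donor_pos] ==
                        bt$chain[hbonds$acceptor_pos], , drop = FALSE]
    CAm2 <- as.matrix(bt[, c("CAx", "CAy", "CAz")])
    for (r in seq_len(nrow(turns))) {
      a <- turns$acceptor_pos[r]
      # accept the 4-turn as helical only when the spanned residues are
      # compact: an i,i+4 hydrogen bond can also arise between strand ends
      # joined by a short excursive loop, whose interior swings far away
      mid <- (a + 1):(a + 3)
      if (any(!stats::complete.cases(CAm2[mid, , drop = FALSE]))) next
      d_a <- sqrt(rowSums(sweep(CAm2[mid, , drop = FALSE], 2, CAm2[a, ])^2))
      d_d <- sqrt(rowSums(sweep(CAm2[mid, , drop = FALSE], 2,
                                CAm2[a + 4, ])^2))
      if (max(c(d_a, d_d)) > 7) next
      is_h[(a + 1):(a + 4)] <- TRUE
    }
  }
  # bridges
  Hb <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  pair_ok <- function(i, j) (!same_chain(i, j)) || abs(i - j) >= 3
  if (nrow(hbonds)) {
    cand <- unique(rbind(
      data.frame(i = hbonds$donor_pos, j = hbonds$acceptor_pos),
      data.frame(i = hbonds$donor_pos - 1L, j = hbonds$acceptor_pos),
      data.frame(i = hbonds$donor_pos, j = hbonds$acceptor_pos - 1L),
      data.frame(i = hbonds$donor_pos - 1L, j = hbonds$acceptor_pos + 1L),
      data.frame(i = hbonds$donor_pos + 1L, j = hbonds$acceptor_pos - 1L)))
    cand <- cand[cand$i >= 1 & cand$j >= 1 & cand$i <= n & cand$j <= n, ]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!pair_ok(i, j)) next
      par <- (Hb(i - 1, j) && Hb(j, i + 1) &&
                (i == 1 || consec(i - 1, i)) && consec(i, i + 1)) ||
             (Hb(j - 1, i) && Hb(i, j + 1) && consec(j - 1, j) &&
                (j == n || consec(j, j + 1)))
      anti <- (Hb(i, j) && Hb(j, i)) ||
              (Hb(i - 1, j + 1) && Hb(j - 1, i + 1))
      if (par || anti) { is_e[i] <- TRUE; is_e[j] <- TRUE }
    }
  }
  # demote strand runs shorter than 3
  r <- rle(is_e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < 3) is_e[starts[k]:ends[k]] <- FALSE
  }
  lab[is_e] <- "E"
  lab[is_h] <- "H"   # helix priority
  data.frame(key = bt$key, chain = bt$chain, resno = bt$resno, ins = bt$ins,
             ss = lab, stringsAsFactors = FALSE)
}

#' Contiguous secondary-structure elements
#'
#' @param ss output of [assign_secondary_structure()].
#' @param min_helix,min_strand minimum element lengths.
#' @return data.frame: `kind` (`"helix"`/`"strand"`), `chain`, `start`, `end`
#'   (author numbers), `start_pos`, `end_pos`, `length`.
#' @export
ss_elements <- function(ss, min_helix = 4, min_strand = 3) {
  n <- nrow(ss)
  if (!n) return(data.frame(kind = character(), chain = character(),
                            start = integer(), end = integer(),
                            start_pos = integer(), end_pos = integer(),
                            length = integer()))
  grp <- cumsum(c(TRUE, ss$ss[-1] != ss$ss[-n] |
                    ss$chain[-1] != ss$chain[-n]))
  out <- list()
  for (g in split(seq_len(n), grp)) {
    kind <- ss$ss[g[1]]
    if (kind == "C") next
    len <- length(g)
    if (kind == "H" && len < min_helix) next
    if (kind == "E" && len < min_strand) next
    out[[length(out) + 1L]] <- data.frame(
      kind = if (kind == "H") "helix" else "strand",
      chain = ss$chain[g[1]], start = ss$resno[g[1]],
      end = ss$resno[g[len]], start_pos = g[1], end_pos = g[len],
      length = len, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(ss_elements(ss[0, , drop = FALSE]))
  do.call(rbind, out)
}

#' Detect the (beta/alpha)8 barrel of a catalytic domain
#'
#' Collects the strands inside `search_span`, builds their pairwise
#' hydrogen-bond adjacency graph (two strands are adjacent when at least
#' `min_edge_bonds` bonds link their residues) and accepts the topology when
#' the graph on 8 strands forms a single cycle.  One missing ladder edge
#' (a bulge) is tolerated with a warning.  Strands are numbered beta1..beta8
#' in sequence order; loop k is the stretch strictly between strand k and the
#' next secondary-structure element.
#'
#' @param structure a `gh20_structure`.
#' @param ss output of [assign_secondary_structure()].
#' @param hbonds output of [assign_backbone_hbonds()].
#' @param search_span optional `c(start, end)` author-number range.
#' @param chain chain to analyze (default: first protein chain).
#' @param n_strands expected strand count (8 for this fold).
#' @param min_edge_bonds hydrogen bonds required per adjacency edge.
#' @return a `gh20_barrel`: list with `strands` (ordered data.frame),
#'   `closure`, `loops` (data.frame `index`, `chain`, `start`, `end`,
#'   `length`), `chain`.
#' @export
detect_barrel <- function(structure, ss, hbonds, search_span = NULL,
                          chain = NULL, n_strands = 8, min_edge_bonds = 2) {
  if (is.null(chain)) chain <- ss$chain[1]
  el <- ss_elements(ss)
  el <- el[el$chain == chain, , drop = FALSE]
  str <- el[el$kind == "strand", , drop = FALSE]
  if (!is.null(search_span))
    str <- str[str$start >= search_span[1] & str$end <= search_span[2], ,
               drop = FALSE]
  fail <- function(msg) {
    cond <- structure(class = c("gh20_barrel_error", "error", "condition"),
                      list(message = paste0("barrel not found: ", msg),
                           call = sys.call(-1), strands = str))
    stop(cond)
  }
  if (nrow(str) < n_strands)
    fail(sprintf("only %d strand(s) in span", nrow(str)))
  str <- str[order(str$start_pos), , drop = FALSE]
  k <- nrow(str)
  # adjacency from inter-strand hydrogen bonds
  strand_of <- rep(NA_integer_, max(c(0, str$end_pos)))
  for (i in seq_len(k)) strand_of[str$start_pos[i]:str$end_pos[i]] <- i
  edge <- matrix(0L, k, k)
  for (r in seq_len(nrow(hbonds))) {
    dp <- hbonds$donor_pos[r]; ap <- hbonds$acceptor_pos[r]
    si <- if (dp <= length(strand_of)) strand_of[dp] else NA
    sj <- if (ap <= length(strand_of)) strand_of[ap] else NA
    if (!is.na(si) && !is.na(sj) && si != sj) {
      edge[si, sj] <- edge[si, sj] + 1L
      edge[sj, si] <- edge[sj, si] + 1L
    }
  }
  adj <- edge >= min_edge_bonds
  if (k > n_strands) {
    # keep the n_strands most-connected strands (peripheral hairpins drop out)
    deg <- rowSums(adj)
    keep <- order(-deg, str$start_pos)[seq_len(n_strands)]
    keep <- sort(keep)
    str <- str[keep, , drop = FALSE]
    adj <- adj[keep, keep, drop = FALSE]
    k <- n_strands
  }
  deg <- rowSums(adj)
  n_edges <- sum(adj) / 2
  closure <- all(deg == 2) && n_edges == k && is_connected(adj)
  bulge <- FALSE
  if (!closure) {
    if (sum(deg == 1) == 2 && all(deg %in% c(1, 2)) && n_edges == k - 1 &&
        is_connected(adj)) {
      bulge <- TRUE
      warning("barrel accepted with one missing ladder edge (bulge)")
      closure <- TRUE
    } else {
      fail("strand adjacency graph is not a single cycle")
    }
  }
  str$index <- seq_len(k)
  # loops: strictly between strand k and the next SS element on the chain
  loops <- data.frame(index = integer(), chain = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  chain_rows <- which(ss$chain == chain)
  for (i in seq_len(k)) {
    after <- el[el$start_pos > str$end_pos[i], , drop = FALSE]
    nxt_start <- if (nrow(after)) min(after$start_pos) else max(chain_rows) + 1L
    span_pos <- if (nxt_start - 1L >= str$end_pos[i] + 1L)
      (str$end_pos[i] + 1L):(nxt_start - 1L) else integer(0)
    span_pos <- span_pos[span_pos %in% chain_rows]
    if (length(span_pos)) {
      loops <- rbind(loops, data.frame(
        index = i, chain = chain, start = ss$resno[span_pos[1]],
        end = ss$resno[span_pos[length(span_pos)]],
        length = length(span_pos), stringsAsFactors = FALSE))
    } else {
      loops <- rbind(loops, data.frame(
        index = i, chain = chain, start = str$end[i] + 1L,
        end = str$end[i], length = 0L, stringsAsFactors = FALSE))
    }
  }
  structure(list(strands = str, closure = closure, bulge = bulge,
                 loops = loops, chain = chain),
            class = "gh20_barrel")
}

is_connected <- function(adj) {
  k <- nrow(adj)
  if (k == 0) return(FALSE)
  seen <- rep(FALSE, k)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.gh20_barrel <- function(x, ...) {
  cat("<gh20_barrel> chain", x$chain, "-", nrow(x$strands), "strands,",
      if (x$closure) "closed" else "open",
      if (isTRUE(x$bulge)) "(one bulge)" else "", "\n")
  invisible(x)
}

#' Extract a numbered barrel loop
#'
#' @param barrel a `gh20_barrel` from [detect_barrel()].
#' @param k loop index, 1-8 (loop k follows strand beta-k).
#' @return one-row data.frame: `index`, `chain`, `start`, `end`, `length`.
#' @export
extract_loop <- function(barrel, k) {
  if (!inherits(barrel, "gh20_barrel")) stop("not a gh20_barrel")
  if (!barrel$closure) stop("barrel is not closed")
  nk <- nrow(barrel$strands)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nk)
    stop("loop index must be in 1..", nk)
  barrel$loops[barrel$loops$index == k, , drop = FALSE]
}

#' Detect the extra alpha-helix after the catalytic barrel
#'
#' Model A architectures carry a helix right after the (beta/alpha)8 barrel.
#' Returns the first helix of length >= `min_length` starting after the last
#' barrel element and (when given) before the next annotated domain.
#'
#' @param structure a `gh20_structure`.
#' @param barrel a `gh20_barrel`.
#' @param ss output of [assign_secondary_structure()].
#' @param next_domain_start optional author number where the next domain
#'   begins.
#' @param min_length minimum helix length (default 6).
#' @return one-row data.frame (a helix element) or `NULL`.
#' @export
detect_extra_helix <- function(structure, barrel, ss,
                               next_domain_start = NULL, min_length = 6) {
  el <- ss_elements(ss)
  el <- el[el$chain == barrel$chain, , drop = FALSE]
  barrel_end <- max(barrel$strands$end_pos)
  # include barrel helix alpha-8 if present: skip helices that start before
  # the final strand's loop has ended
  cand <- el[el$kind == "helix" & el$start_pos > barrel_end &
               el$length >= min_length, , drop = FALSE]
  if (!is.null(next_domain_start))
    cand <- cand[cand$end < next_domain_start, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[order(cand$start_pos)[1], , drop = FALSE]
}
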