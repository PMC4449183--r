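# Rigid-body superposition (Kabsch), sequence-based residue correspondence
# between domains, and annotation transfer onto superposed targets.

#' Optimal rigid-body superposition of paired coordinate sets
#'
#' Standard Kabsch algorithm: least-squares rotation + translation mapping
#' `tgt_coords` onto `ref_coords` via SVD of the covariance matrix, with the
#' determinant correction that excludes reflections.
#'
#' @param ref_coords,tgt_coords n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return a `gh20_superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (angstrom, over the input pairs) and
#'   `n_pairs`.  The transform maps a target point x to
#'   `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(ref_coords, tgt_coords) {
  ref <- as.matrix(ref_coords); tgt <- as.matrix(tgt_coords)
  if (!all(dim(ref) == dim(tgt)) || ncol(ref) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 paired atoms")
  cr <- colMeans(ref); ct <- colMeans(tgt)
  A <- sweep(ref, 2, cr); B <- sweep(tgt, 2, ct)
  if (qr(A)$rank < 2 || qr(B)$rank < 2)
    stop("coordinates are collinear; superposition is degenerate")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- cr - as.numeric(R %*% ct)
  fitted <- t(R %*% t(tgt)) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd, n_pairs = n),
            class = "gh20_superposition")
}

#' @export
print.gh20_superposition <- function(x, ...) {
  cat(sprintf("<gh20_superposition> %d pairs, rmsd %.3f angstrom\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `gh20_superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords <- as.matrix(coords)
  t(sp$rotation %*% t(coords)) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' Superpose two structures over stated domain spans
#'
#' Residue correspondence is built by global sequence alignment (BLOSUM62) of
#' the span sequences, then the corresponding CA atoms are superposed by
#' [kabsch_superpose()].  CA-only superposition is the standard reproducible
#' reduction of whole-domain structure alignment.
#'
#' @param ref,tgt `gh20_structure` objects.
#' @param ref_span,tgt_span `c(start, end)` author-number ranges of the
#'   aligned domains.
#' @param ref_chain,tgt_chain chain identifiers (default: first chain).
#' @param min_identity percent-identity floor below which the mapping is
#'   considered unreliable (default 15).
#' @return list with `superposition` (a `gh20_superposition`) and `mapping`
#'   (data.frame `ref_key`, `tgt_key`, `ca_dist`; attribute
#'   `identity_pct`, `method = "sequence"`).
#' @export
align_domains <- function(ref, tgt, ref_span, tgt_span,
                          ref_chain = NULL, tgt_chain = NULL,
                          min_identity = 15) {
  pick_chain <- function(s, ch) {
    if (!is.null(ch)) return(ch)
    a <- s$atoms
    a$chain[!a$water][1]
  }
  ref_chain <- pick_chain(ref, ref_chain)
  tgt_chain <- pick_chain(tgt, tgt_chain)
  span_keys <- function(s, chain, span) {
    rt <- residues(s)
    rt <- rt[rt$chain == chain & !rt$water & !rt$het &
               rt$resno >= span[1] & rt$resno <= span[2], , drop = FALSE]
    if (!nrow(rt)) stop("span ", span[1], "-", span[2],
                        " has no residues in chain ", chain)
    rt
  }
  rrt <- span_keys(ref, ref_chain, ref_span)
  trt <- span_keys(tgt, tgt_chain, tgt_span)
  rseq <- structure_sequence(ref, ref_chain, ref_span)
  tseq <- structure_sequence(tgt, tgt_chain, tgt_span)
  al <- global_align(rseq, tseq)
  if (al$identity_pct < min_identity)
    stop(sprintf("unreliable mapping: %.1f%% identity below the %.0f%% floor",
                 al$identity_pct, min_identity))
  ga <- strsplit(al$aligned_a, "")[[1]]
  gb <- strsplit(al$aligned_b, "")[[1]]
  ia <- 0L; ib <- 0L
  pairs <- list()
  for (k in seq_along(ga)) {
    if (ga[k] != "-") ia <- ia + 1L
    if (gb[k] != "-") ib <- ib + 1L
    if (ga[k] != "-" && gb[k] != "-")
      pairs[[length(pairs) + 1L]] <- c(ia, ib)
  }
  pm <- do.call(rbind, pairs)
  ref_keys <- rrt$key[pm[, 1]]
  tgt_keys <- trt$key[pm[, 2]]
  # CA coordinates in residue order for the mapped keys
  ca_of <- function(s, keys) {
    a <- s$atoms
    ca <- a[a$elety == "CA", , drop = FALSE]
    idx <- match(keys, residue_key(ca$chain, ca$resno, ca$ins))
    as.matrix(ca[idx, c("x", "y", "z")])
  }
  rxyz <- ca_of(ref, ref_keys)
  txyz <- ca_of(tgt, tgt_keys)
  ok <- stats::complete.cases(rxyz) & stats::complete.cases(txyz)
  sp <- kabsch_superpose(rxyz[ok, , drop = FALSE], txyz[ok, , drop = FALSE])
  fitted <- apply_superposition(sp, txyz[ok, , drop = FALSE])
  dists <- sqrt(rowSums((fitted - rxyz[ok, , drop = FALSE])^2))
  mapping <- data.frame(ref_key = ref_keys[ok], tgt_key = tgt_keys[ok],
                        ca_dist = dists, stringsAsFactors = FALSE)
  attr(mapping, "identity_pct") <- al$identity_pct
  attr(mapping, "method") <- "sequence"
  list(superposition = sp, mapping = mapping)
}

#' Transfer residue annotations through a mapping
#'
#' Copies labels from reference residues to their mapped targets.  Labels on
#' residues absent from the mapping, or whose mapped pair sits farther than
#' `radius` after superposition, are returned in `unmapped` - never silently
#' dropped.
#'
#' @param mapping data.frame from [align_domains()] (`ref_key`, `tgt_key`,
#'   `ca_dist`).
#' @param ref_labels data.frame with columns `key` (residue key on the
#'   reference) and `label`.
#' @param radius transfer radius in angstrom (default 5).
#' @return list with `labels` (data.frame `key`, `label` on the target) and
#'   `unmapped` (the reference rows that could not be transferred).
#' @export
transfer_annotations <- function(mapping, ref_labels, radius = 5) {
  idx <- match(ref_labels$key, mapping$ref_key)
  ok <- !is.na(idx) & mapping$ca_dist[idx] <= radius
  labels <- data.frame(key = mapping$tgt_key[idx[ok]],
                       label = ref_labels$label[ok],
                       stringsAsFactors = FALSE)
  list(labels = labels, unmapped = ref_labels[!ok, , drop = FALSE])
}
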