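# Shared fixture helpers: built once per test run to keep the suite fast.

barrel_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_mini_barrel(8, loop_lengths = c(4, 6, 4, 4, 4, 4, 4, 3),
                                 strand_len = 8)
    cache
  }
})

barrel_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- barrel_default()
      hb <- assign_backbone_hbonds(s)
      ss <- assign_secondary_structure(s, hb)
      cache <<- list(structure = s, hbonds = hb, ss = ss,
                     barrel = detect_barrel(s, ss, hb),
                     gt = attr(s, "ground_truth"))
    }
    cache
  }
})

# run the remote-element pipeline on a make_remote_demo() scenario
run_demo <- function(scenario) {
  d <- make_remote_demo(scenario)
  s <- d$structure
  hb <- assign_backbone_hbonds(s)
  ss <- assign_secondary_structure(s, hb)
  bar <- detect_barrel(s, ss, hb, chain = "A")
  l2 <- classify_loop2(bar)
  site <- anchor_active_site(s, d$annotations)[[1]]
  el <- find_remote_element(s, site, l2, d$gh20_span, domains = d$domains)
  list(demo = d, structure = s, barrel = bar, loop2 = l2, site = site,
       element = el, gt = d$ground_truth)
}

# append a one-atom HETATM "ligand" at a given position
add_fake_ligand <- function(structure, pos, chain = "L", resno = 900L) {
  row <- gh20arch:::atom_row(chain, resno, "LIG", "C1", pos, het = TRUE)
  row$elesy <- "C"
  row$backbone <- FALSE
  row$polar <- "apolar"
  out <- gh20arch:::new_gh20_structure(rbind(structure$atoms, row),
                                       accession = structure$accession)
  attr(out, "ground_truth") <- attr(structure, "ground_truth")
  out
}

# merge two structures' atoms (chains/numbering must already be distinct)
combine_structures <- function(a, b) {
  gh20arch:::new_gh20_structure(rbind(a$atoms, b$atoms),
                                accession = a$accession)
}

# rigid-body transform of every atom
transform_structure <- function(structure, rotation, translation) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new <- t(rotation %*% t(xyz)) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- new[, 1]
  structure$atoms$y <- new[, 2]
  structure$atoms$z <- new[, 3]
  structure
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
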