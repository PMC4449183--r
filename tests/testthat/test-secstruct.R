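test_that("an ideal helix yields the full i -> i-4 bond ladder and H labels", {
  h <- make_ideal_helix(12)
  hb <- assign_backbone_hbonds(h)
  four_turns <- hb[hb$donor_pos - hb$acceptor_pos == 4, ]
  expect_equal(four_turns$donor_pos, 5:12)
  expect_true(all(four_turns$energy < -0.5))
  expect_true(all(four_turns$dist_no > 2.8 & four_turns$dist_no < 3.2))
  ss <- assign_secondary_structure(h, hb)
  gt <- attr(h, "ground_truth")
  interior <- ss$resno >= gt$h_span[1] & ss$resno <= gt$h_span[2]
  expect_true(all(ss$ss[interior] == "H"))
})

test_that("minimal helices and degenerate inputs behave at the boundary", {
  h5 <- make_ideal_helix(5)
  ss <- assign_secondary_structure(h5, assign_backbone_hbonds(h5))
  expect_gte(sum(ss$ss == "H"), 4)
  expect_error(make_ideal_helix(4), "at least 5")
  # two isolated glycines far apart: no bonds, all coil
  iso <- rbind(
    gh20arch:::atom_row("A", 1L, "GLY", "N", c(0, 0, 0)),
    gh20arch:::atom_row("A", 1L, "GLY", "CA", c(1.46, 0, 0)),
    gh20arch:::atom_row("A", 1L, "GLY", "C", c(2.2, 1.2, 0)),
    gh20arch:::atom_row("A", 1L, "GLY", "O", c(2.0, 2.4, 0)),
    gh20arch:::atom_row("A", 9L, "GLY", "N", c(20, 0, 0)),
    gh20arch:::atom_row("A", 9L, "GLY", "CA", c(21.46, 0, 0)),
    gh20arch:::atom_row("A", 9L, "GLY", "C", c(22.2, 1.2, 0)),
    gh20arch:::atom_row("A", 9L, "GLY", "O", c(22.0, 2.4, 0)))
  iso$backbone <- iso$elety %in% c("N", "CA", "C", "O")
  iso$polar <- "polar"
  s <- gh20arch:::new_gh20_structure(iso)
  hb <- assign_backbone_hbonds(s)
  expect_equal(nrow(hb), 0L)
  expect_true(all(assign_secondary_structure(s, hb)$ss == "C"))
})

test_that("the antiparallel hairpin produces its designed bond ladder", {
  hp <- make_hairpin(6, 4)
  gt <- attr(hp, "ground_truth")
  hb <- assign_backbone_hbonds(hp)
  got <- paste(hb$donor, hb$acceptor)
  want <- paste(residue_key(gt$chain, gt$bonds$donor),
                residue_key(gt$chain, gt$bonds$acceptor))
  expect_true(all(want %in% got))
  # no inter-strand bonds beyond the designed register
  far <- hb[abs(hb$donor_pos - hb$acceptor_pos) > 2, ]
  expect_setequal(paste(far$donor, far$acceptor), want)
  # a lone extended strand with no partner stays coil
  lone <- ablate_span(hp, "A", from = gt$strands$start[2] - 4)
  ss <- assign_secondary_structure(lone, assign_backbone_hbonds(lone))
  expect_true(all(ss$ss == "C"))
})

test_that("barrel detection recovers the generator's topology exactly", {
  ba <- barrel_analysis()
  bar <- ba$barrel
  gt <- ba$gt
  expect_true(bar$closure)
  expect_equal(nrow(bar$strands), 8L)
  expect_equal(bar$strands$start, gt$strands$start)
  expect_equal(bar$strands$end, gt$strands$end)
  expect_equal(bar$loops$start, gt$loops$start)
  expect_equal(bar$loops$end, gt$loops$end)
  expect_equal(bar$loops$length, gt$loops$length)
})

test_that("loop extraction follows the numbering convention", {
  ba <- barrel_analysis()
  l2 <- extract_loop(ba$barrel, 2)
  expect_equal(l2$length, 6L)
  expect_equal(l2$length, l2$end - l2$start + 1L)
  expect_error(extract_loop(ba$barrel, 9), "1..8")
  expect_error(extract_loop(ba$barrel, 0), "1..8")
})

test_that("a broken cycle is reported as barrel-not-found with partial strands", {
  ba <- barrel_analysis()
  gt <- ba$gt
  s5 <- gt$strands[5, ]
  broken <- ablate_span(ba$structure, "A", s5$start, s5$end)
  hb <- assign_backbone_hbonds(broken)
  ss <- assign_secondary_structure(broken, hb)
  err <- tryCatch(detect_barrel(broken, ss, hb), error = identity)
  expect_s3_class(err, "gh20_barrel_error")
  expect_match(conditionMessage(err), "barrel not found")
  expect_true(is.data.frame(err$strands))
})

test_that("zero-length loops are a valid generator spec", {
  b0 <- make_mini_barrel(8, loop_lengths = rep(0, 8), strand_len = 8)
  gt <- attr(b0, "ground_truth")
  expect_true(all(gt$loops$length == 0L))
  expect_equal(nrow(residues(b0)), 1 + 64)
  f <- tempfile(fileext = ".pdb")
  write_structure(b0, f)
  expect_equal(nrow(residues(parse_structure(f))), 65L)
})

test_that("secondary structure is invariant under rigid motion", {
  ba <- barrel_analysis()
  s <- ba$structure
  moved <- transform_structure(s, rotation_z(1.1), c(13.2, -7.5, 4.4))
  ss0 <- ba$ss
  ss1 <- assign_secondary_structure(moved, assign_backbone_hbonds(moved))
  expect_equal(ss1$ss, ss0$ss)
  bar1 <- detect_barrel(moved, ss1, assign_backbone_hbonds(moved))
  expect_equal(bar1$loops, ba$barrel$loops)
})

test_that("strand, helix and loop residues partition the barrel span", {
  ba <- barrel_analysis()
  bar <- ba$barrel
  span <- c(min(bar$strands$start), max(bar$loops$end))
  n_span <- sum(ba$ss$resno >= span[1] & ba$ss$resno <= span[2])
  n_parts <- sum(bar$strands$end - bar$strands$start + 1L) +
    sum(bar$loops$length)
  expect_equal(n_parts, n_span)
})

test_that("the extra helix after the barrel is found only when present", {
  ba <- barrel_analysis()
  helix <- make_ideal_helix(10, resno_start = 200L)
  helix <- transform_structure(helix, diag(3), c(40, 0, 40))
  with_helix <- combine_structures(ba$structure, helix)
  hb <- assign_backbone_hbonds(with_helix)
  ss <- assign_secondary_structure(with_helix, hb)
  bar <- detect_barrel(with_helix, ss, hb,
                       search_span = c(1, max(ba$gt$loops$end)))
  found <- detect_extra_helix(with_helix, bar, ss)
  expect_false(is.null(found))
  expect_equal(found$kind, "helix")
  expect_gte(found$start, 200L)
  expect_null(detect_extra_helix(ba$structure, ba$barrel, ba$ss))
  # a domain boundary before the helix hides it
  expect_null(detect_extra_helix(with_helix, bar, ss,
                                 next_domain_start = 150L))
})
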