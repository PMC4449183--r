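test_that("the packaged survey expands to 13 annotated enzymes", {
  ann <- load_annotations(make_toy_annotations())
  expect_equal(length(unique(ann$enzyme)), 13L)
  # round trip: saving and re-loading gives an identical table
  f <- tempfile(fileext = ".tsv")
  write.table(ann, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_annotations(f), ann)
})

test_that("annotation validation rejects bad rows and flags unknown names", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("source\tdomain\tchain\tstart\tend",
               "cazy\tGH20\tA\t100\t450",
               "cazy\tGH20b\tA\t90\t40",
               "pfam\tMystery\tA\t500\t600"), f)
  expect_warning(expect_message(ann <- load_annotations(f), "rejecting 1"),
                 "Mystery")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$source[ann$domain == "Mystery"], "manual")
  empty <- tempfile(fileext = ".tsv")
  writeLines("source\tdomain\tchain\tstart\tend", empty)
  expect_equal(nrow(load_annotations(empty)), 0L)
})

test_that("consensus integrates sources by priority and stays deterministic", {
  base <- data.frame(
    enzyme = "toy",
    source = c("pfam", "pfam", "cazy", "superfamily"),
    domain = c("GH20b", "GH20", "Lectin", "GH20"),
    chain = "A",
    start = c(10, 150, 150, 140),
    end = c(140, 480, 480, 470), stringsAsFactors = FALSE)
  # cazy wins the overlap over pfam and superfamily
  arch <- consensus_architecture(base, "toy")
  expect_equal(as.character(arch), c("GH20b", "Lectin"))
  # permuting row order never changes the consensus
  set.seed(2)
  for (i in 1:5) {
    perm <- base[sample(nrow(base)), , drop = FALSE]
    expect_equal(as.character(consensus_architecture(perm, "toy")),
                 c("GH20b", "Lectin"))
  }
  # single-source input is returned verbatim in N->C order
  solo <- base[base$source == "pfam", ]
  expect_equal(as.character(consensus_architecture(solo, "toy")),
               c("GH20b", "GH20"))
  # same-priority disagreeing overlap keeps both and flags a conflict
  clash <- data.frame(enzyme = "toy", source = "pfam",
                      domain = c("GH20", "Lectin"), chain = "A",
                      start = c(100, 150), end = c(400, 450))
  arch2 <- consensus_architecture(clash, "toy")
  expect_equal(length(arch2), 2L)
  expect_gt(length(attr(arch2, "conflicts")), 0L)
})

test_that("the five-domain lacto-N-biosidase architecture is reproduced", {
  ann <- load_annotations(make_toy_annotations())
  arch <- consensus_architecture(ann, "LnbB")
  expect_equal(as.character(arch),
               c("GH20b", "GH20", "alpha", "Lectin", "CBM32", "Ig_like"))
  expect_equal(classify_architecture(arch), "A")
})

test_that("model classification follows the GH20b-before-GH20 rule", {
  expect_equal(classify_architecture("GH20b-GH20-alpha"), "A")
  expect_equal(classify_architecture("GH20"), "B")
  expect_equal(classify_architecture("GH20b-GH20-"), "A")  # truncated print
  expect_equal(classify_architecture("GH20-GH20-G5-G5"), "B")
  expect_equal(classify_architecture(c("CHB_HEX", "GH20b", "GH20", "alpha",
                                       "CHB_HEX_C")), "A")
  # GH20b present but not immediately before GH20
  expect_equal(classify_architecture(c("GH20b", "Lectin", "GH20")),
               "unclassified")
  expect_error(classify_architecture("Lectin-CBM32"), "not a GH20 enzyme")
})

test_that("the surveyed enzymes partition 11 Model A / 2 Model B", {
  ann <- load_annotations(make_toy_annotations())
  calls <- classify_survey(ann)
  em <- enzyme_models(calls)
  expect_equal(sum(em$model == "A"), 11L)
  expect_equal(sum(em$model == "B"), 2L)
  expect_setequal(em$enzyme[em$model == "B"], c("DspB", "StrH"))
  # both heterodimer subunits classify as Model A but count once
  expect_equal(sum(calls$enzyme == "HexA"), 2L)
  expect_equal(sum(em$enzyme == "HexA"), 1L)
  # the monomeric group of Model A holds 7 enzymes
  t1 <- read_survey_table()
  mono <- unique(t1$enzyme[t1$group == "monomeric"])
  expect_equal(sum(em$model[em$enzyme %in% mono] == "A"), 7L)
})

test_that("interface detection is cutoff-bounded and symmetric", {
  h1 <- make_ideal_helix(8)
  h2 <- transform_structure(make_ideal_helix(8, resno_start = 101L),
                            diag(3), c(20, 0, 0))
  far <- combine_structures(h1, h2)
  rep0 <- interface_residues(far, c(1, 8), c(101, 108), chain = "A")
  expect_equal(nrow(rep0$pairs), 0L)
  planted <- plant_contact_pair(barrel_default(), "nonpolar", 4.0,
                                target_key = "A:40", probe_resno = 300L)
  rep1 <- interface_residues(planted, c(35, 45), c(295, 305), chain = "A")
  expect_equal(nrow(rep1$pairs), 1L)
  expect_equal(rep1$pairs$res_a, "A:40")
  expect_equal(rep1$pairs$res_b, "A:300")
  expect_equal(rep1$pairs$min_distance, 4.0, tolerance = 0.01)
  # symmetry: swapping the spans mirrors the pairs
  rep2 <- interface_residues(planted, c(295, 305), c(35, 45), chain = "A")
  expect_equal(rep2$pairs$res_a, rep1$pairs$res_b)
  expect_equal(rep2$pairs$res_b, rep1$pairs$res_a)
  expect_error(interface_residues(planted, c(30, 50), c(45, 60)), "overlap")
})
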