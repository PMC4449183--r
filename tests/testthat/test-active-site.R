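test_that("active sites are anchored from labels, never inferred", {
  d <- make_remote_demo("loop2")
  sites <- anchor_active_site(d$structure, d$annotations)
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$arg_key, d$ground_truth$remote$arg_key)
  expect_equal(sites[[1]]$acid_key, d$ground_truth$remote$acid_key)
  expect_true(all(is.finite(sites[[1]]$site_center)))
  # tandem catalytic domains: two label pairs on one chain give two sites
  tandem <- rbind(d$annotations,
                  data.frame(chain = "A", resno = c(20L, 30L),
                             label = c("cons_arg", "cons_acid")))
  expect_length(anchor_active_site(d$structure, tandem), 2L)
  # missing acid label is an error naming the structure
  expect_error(anchor_active_site(d$structure, d$annotations[1, ]),
               "lacks a complete")
  # labeled residue absent from the structure
  bad <- d$annotations
  bad$resno[1] <- 9999L
  expect_error(anchor_active_site(d$structure, bad), "absent")
})

test_that("loop 2 length classification uses the >= 12 boundary", {
  mk <- function(len) {
    b <- make_mini_barrel(8, loop_lengths = c(4, len, 4, 4, 4, 4, 4, 2),
                          strand_len = 8)
    hb <- assign_backbone_hbonds(b)
    classify_loop2(detect_barrel(b, assign_secondary_structure(b, hb), hb))
  }
  at <- mk(12)
  expect_equal(at$class, "Long")
  expect_equal(at$loop$length, 12L)
  below <- mk(11)
  expect_equal(below$class, "Short")
  long <- mk(15)
  expect_equal(long$class, "Long")
})

test_that("planted contacts are recovered with their kind and distance", {
  base <- barrel_default()
  pol <- plant_contact_pair(base, "polar", 3.2, target_key = "A:40",
                            probe_resno = 300L)
  gt <- attr(pol, "ground_truth")$planted
  ct <- detect_contacts(pol, gt$target, gt$probe)
  ct_pol <- ct[ct$kind == "polar", ]
  expect_equal(nrow(ct_pol), 1L)
  expect_equal(ct_pol$min_distance, 3.2, tolerance = 0.01)
  npl <- plant_contact_pair(base, "nonpolar", 4.4, target_key = "A:40",
                            probe_resno = 300L)
  gt2 <- attr(npl, "ground_truth")$planted
  ct2 <- detect_contacts(npl, gt2$target, gt2$probe)
  expect_equal(ct2$kind, "nonpolar")
  expect_equal(ct2$min_distance, 4.4, tolerance = 0.01)
  # beyond the cutoffs nothing is reported
  far_pol <- plant_contact_pair(base, "polar", 3.8, target_key = "A:40",
                                probe_resno = 300L)
  gt3 <- attr(far_pol, "ground_truth")$planted
  ct3 <- detect_contacts(far_pol, gt3$target, gt3$probe)
  expect_false("polar" %in% ct3$kind)
  far_np <- plant_contact_pair(base, "nonpolar", 6.0, target_key = "A:40",
                               probe_resno = 300L)
  gt4 <- attr(far_np, "ground_truth")$planted
  expect_equal(nrow(detect_contacts(far_np, gt4$target, gt4$probe)), 0L)
  expect_error(detect_contacts(pol, "A:40", "A:40"), "disjoint")
  expect_error(plant_contact_pair(base, "polar", 1.0), "exceed 1.5")
})

test_that("contact detection is symmetric up to direction labels", {
  d <- make_remote_demo("accompanying_domain")
  s <- d$structure
  gt <- d$ground_truth$remote
  fwd <- detect_contacts(s, gt$arg_key, gt$key)
  rev <- detect_contacts(s, gt$key, gt$arg_key)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(fwd$from, fwd$to, fwd$kind),
                  paste(rev$to, rev$from, rev$kind))
  expect_equal(sort(fwd$min_distance), sort(rev$min_distance))
})

test_that("water-mediated bridges require water mode and a shared water", {
  d <- make_remote_demo("accompanying_domain")
  s <- d$structure
  gt <- d$ground_truth$remote
  a <- s$atoms
  o_arg <- as.numeric(a[residue_key(a$chain, a$resno, a$ins) == gt$arg_key &
                          a$elety == "O", c("x", "y", "z")])
  n_probe <- as.numeric(a[residue_key(a$chain, a$resno, a$ins) == gt$key &
                            a$elety == "N", c("x", "y", "z")])
  w <- gh20arch:::atom_row("W", 700L, "HOH", "O", (o_arg + n_probe) / 2,
                           water = TRUE)
  w$backbone <- FALSE; w$polar <- "polar"
  sw <- gh20arch:::new_gh20_structure(rbind(a, w))
  dry <- detect_contacts(sw, gt$arg_key, gt$key, water_mode = FALSE)
  expect_false("water_mediated" %in% dry$kind)
  wet <- detect_contacts(sw, gt$arg_key, gt$key, water_mode = TRUE)
  wm <- wet[wet$kind == "water_mediated", ]
  expect_equal(nrow(wm), 1L)
  expect_equal(wm$bridging_water, "W:700")
})

test_that("remote elements are classified by provenance on all three routes", {
  for (sc in c("loop2", "accompanying_domain", "partner_chain")) {
    r <- run_demo(sc)
    expect_equal(r$element$source, sc, label = sc)
    expect_equal(r$element$key_residues, r$gt$remote$key, label = sc)
    pol <- r$element$contacts[r$element$contacts$kind == "polar", ]
    expect_gte(nrow(pol), 1L)
    expect_lte(min(pol$min_distance), 3.5)
    expect_equal(r$loop2$class, if (sc == "loop2") "Long" else "Short")
  }
  r <- run_demo("accompanying_domain")
  expect_equal(r$element$source_label, "Lectin")
  rp <- run_demo("partner_chain")
  expect_equal(rp$element$source_label, "Z")
})

test_that("ablating the accompanying domain abolishes the remote element", {
  r <- run_demo("accompanying_domain")
  probe_resno <- as.integer(sub("^.*:", "", r$gt$remote$key))
  cut <- ablate_span(r$structure, "A", from = probe_resno - 20L)
  hb <- assign_backbone_hbonds(cut)
  ss <- assign_secondary_structure(cut, hb)
  bar <- detect_barrel(cut, ss, hb, chain = "A")
  site <- anchor_active_site(cut, r$demo$annotations)[[1]]
  el <- find_remote_element(cut, site, classify_loop2(bar), r$demo$gh20_span,
                            domains = r$demo$domains)
  expect_equal(el$source, "none")
})

test_that("second-shell membership excludes anchors and ligand contacts", {
  r <- run_demo("accompanying_domain")
  s <- r$structure
  site <- r$site
  expect_false(second_shell_membership(s, site$arg_key, site))
  probe <- r$gt$remote$key
  expect_true(second_shell_membership(s, probe, site))
  # with a ligand parked 3 A from the probe, the probe becomes first shell
  a <- s$atoms
  npos <- as.numeric(a[residue_key(a$chain, a$resno, a$ins) == probe &
                         a$elety == "N", c("x", "y", "z")])
  lig <- add_fake_ligand(s, npos + c(0, 0, 3))
  expect_false(second_shell_membership(lig, probe, site, ligand = "L:900"))
  # a residue with no contact to the anchors is not second shell
  expect_false(second_shell_membership(s, "A:2", site))
})

test_that("the survey report has the expected schema and missing markers", {
  ann <- load_annotations(make_toy_annotations())
  calls <- classify_survey(ann)
  r <- run_demo("accompanying_domain")
  elements <- list(list(enzyme = "LnbB", site = "A", loop2 = r$loop2,
                        element = r$element,
                        cons_pair = paste(r$site$arg_key, r$site$acid_key,
                                          sep = "/")))
  rep <- build_report(calls, elements)
  expect_equal(names(rep)[1:9],
               c("enzyme", "site", "loop2_class", "loop2_span",
                 "remote_source", "remote_span", "cons_pair",
                 "nonpolar_partners", "polar_partners"))
  expect_equal(sum(rep$status == "analyzed"), 1L)
  # every un-analyzed Model A enzyme appears with missing markers
  expect_equal(sum(rep$status == "missing"), 10L)
  empty <- build_report(calls[0, ], list())
  expect_equal(nrow(empty), 0L)
})
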