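test_that("sidechains are built on ideal geometry with the requested chis", {
  m <- build_chain(data.frame(phi = c(-120, -120, -120),
                              psi = c(135, 135, 135), omega = 180))
  m <- build_sidechain(m, 2, "N", c(-65, -20))
  chi1 <- buttress:::dihedral_deg(atom_xyz(m, 2, "N"), atom_xyz(m, 2, "CA"),
                                  atom_xyz(m, 2, "CB"), atom_xyz(m, 2, "CG"))
  chi2 <- buttress:::dihedral_deg(atom_xyz(m, 2, "CA"), atom_xyz(m, 2, "CB"),
                                  atom_xyz(m, 2, "CG"), atom_xyz(m, 2, "OD1"))
  expect_equal(chi1, -65, tolerance = 1e-6)
  expect_equal(chi2, -20, tolerance = 1e-6)
  # amide hydrogens present for the donor rules
  expect_false(is.null(atom_xyz(m, 2, "HD21")))
  expect_false(is.null(atom_xyz(m, 2, "HD22")))
  # each supported residue type builds its full heavy-atom set
  want <- list(D = c("CG", "OD1", "OD2"), Q = c("CG", "CD", "OE1", "NE2"),
               H = c("CG", "ND1", "CD2", "CE1", "NE2"),
               V = c("CG1", "CG2"), L = c("CG", "CD1", "CD2"),
               I = c("CG1", "CG2", "CD1"), M = c("CG", "SD", "CE"),
               F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  for (aa in names(want)) {
    chis <- rotamer_table(aa)[[1]]
    mm <- build_sidechain(m, 2, aa, chis)
    for (at in want[[aa]]) {
      expect_false(is.null(atom_xyz(mm, 2, at)),
                   info = paste(aa, at))
    }
  }
  expect_error(build_sidechain(m, 2, "R", c(-60, 180, 65, 85)), "recipe")
})

test_that("the rotamer table covers exactly the published scanning sets", {
  tab <- rotamer_table()
  expect_setequal(names(tab), c("N", "D", "Q", "H", "V", "L", "I", "M", "F"))
  # Arg and Lys are deliberately absent (entropic cost of long sidechains)
  expect_false(any(c("R", "K") %in% names(tab)))
})

test_that("bidentate scanning accepts a constructively planted asparagine", {
  f <- plant_bidentate_fixture(c(2.9, 2.9))
  host <- build_sidechain(f$model, f$asn, "A")  # forget the answer
  res <- scan_bidentate(host, f$asn)
  pl <- res$placements[[1]]
  expect_true(pl$accepted)
  expect_true(pl$aa %in% c("N", "D", "Q", "H"))
  bid <- find_bidentate(res$model, f$asn,
                        hbonds = buttress:::sc_hbonds_for_residue(res$model,
                                                                  f$asn))
  expect_gte(nrow(bid), 1)
  # with the partner moved 25 A away every position reverts to alanine
  lonely <- host
  far <- lonely$residues$resno[lonely$residues$repeat_unit == 3]
  lonely$xyz[lonely$atoms$resno %in% far, ] <-
    lonely$xyz[lonely$atoms$resno %in% far, ] + 25
  res2 <- scan_bidentate(lonely, f$asn)
  expect_false(res2$placements[[1]]$accepted)
  expect_equal(res2$placements[[1]]$aa, "A")
})

test_that("pseudo-bidentate rescue refines planted near-misses into bonds", {
  f <- plant_bidentate_fixture(c(2.9, 2.85))
  pl <- list(resno = f$asn, aa = "N", chis = c(-65, -20), accepted = FALSE,
             n_bidentate = 0L)
  out <- rescue_pseudo_bidentate(f$model, pl)
  expect_true(out$placement$accepted)
  hb <- buttress:::sc_hbonds_for_residue(out$model, f$asn)
  expect_gte(nrow(hb), 2)             # both bonds pass detect_hbonds rules
  expect_false(is.na(out$objective))
  # rescue never worsens the harmonic objective; rerunning from the
  # refined chis changes them by less than the grid step
  out2 <- rescue_pseudo_bidentate(out$model, out$placement)
  expect_lte(out2$objective, out$objective + 1e-9)
  expect_lt(max(abs(out2$placement$chis - out$placement$chis)), 2)
  # no pseudo-bidentate present: placement returned unchanged
  nop <- build_sidechain(f$model, f$asn, "A")
  nop$residues$aa[match(f$asn, nop$residues$resno)] <- "A"
  un <- rescue_pseudo_bidentate(nop, list(resno = f$asn, aa = "A",
                                          chis = numeric(0)))
  expect_true(is.na(un$objective))
})

test_that("hydrophobic scanning needs enough contacting sidechain atoms", {
  m <- get_connected_scaffold()
  # a residue buried between helices accepts a hydrophobic rotamer;
  # use a short-loop residue facing the bundle
  lres <- m$residues$resno[m$residues$region %in% "loop_short" &
                             m$residues$repeat_unit == 2]
  res <- scan_hydrophobic_contacts(m, lres)
  accepted <- vapply(res$placements, function(p) isTRUE(p$accepted),
                     logical(1))
  aas <- vapply(res$placements, `[[`, character(1), "aa")
  expect_true(all(aas[accepted] %in% c("V", "L", "I", "M", "F")))
  # a residue displaced far from any helix is rejected
  iso <- build_chain(data.frame(phi = rep(-120, 3), psi = rep(135, 3),
                                omega = 180))
  iso$xyz <- iso$xyz + 100
  iso$residues$region <- "loop_long"
  solo <- buttress:::concat_models(
    list(m, iso), regions = c(NA, NA), units = c(NA, NA),
    break_after_segment = c(TRUE, NA))
  pos <- n_residues(m) + 2L
  res2 <- scan_hydrophobic_contacts(solo, pos)
  expect_false(res2$placements[[1]]$accepted)
  expect_equal(res2$placements[[1]]$aa, "A")
})

test_that("buried unsatisfied counting reacts to removing one bond partner", {
  m <- place_amide_hydrogens(get_connected_scaffold())
  lay <- assign_layers(m)
  base <- count_buried_unsatisfied(m, layers = lay)
  expect_gte(base, 0)
  hb <- detect_hbonds(m, "all")
  core <- lay$resno[lay$layer == "core"]
  # find a core carbonyl satisfied by exactly one donor whose amide makes
  # only that one bond; removing that donor hydrogen unsatisfies exactly
  # one polar atom
  pick <- NULL
  for (i in core) {
    dons <- hb$don_res[hb$acc_res == i & hb$acc_atom == "O"]
    if (length(dons) != 1) next
    j <- dons[1]
    if (sum(hb$don_res == j & hb$don_atom == "N") != 1) next
    njbonds <- sum((hb$acc_res == j & hb$acc_atom == "N"))
    if (njbonds > 0) next
    if (j %in% core) next   # keep the donor's own N out of the core count
    pick <- c(i, j); break
  }
  expect_false(is.null(pick))
  m2 <- m
  keep <- !(m2$atoms$resno == pick[2] & m2$atoms$name == "H")
  m2$atoms <- m2$atoms[keep, , drop = FALSE]
  m2$xyz <- m2$xyz[keep, , drop = FALSE]
  expect_equal(count_buried_unsatisfied(m2, layers = lay), base + 1L)
})

test_that("placement propagation enforces symmetric sequences", {
  # three identical strand units related by a pure translation
  seg <- build_chain(data.frame(phi = rep(-120, 5), psi = rep(135, 5),
                                omega = 180))
  segs <- lapply(0:2, function(k) {
    s <- seg
    s$xyz <- sweep(s$xyz, 2, c(0, 0, 10 * k), "+")
    s
  })
  m <- buttress:::concat_models(segs, regions = rep("loop_long", 3),
                                units = 1:3,
                                break_after_segment = rep(TRUE, 3))
  m <- place_amide_hydrogens(m)
  pl <- list(resno = 8L, aa = "N", chis = c(-65, -20), accepted = TRUE,
             n_bidentate = 1L)
  out <- propagate_placements(m, list(pl))
  expect_length(out$kept, 1)
  for (e in c(3L, 8L, 13L)) {
    k <- match(e, out$model$residues$resno)
    expect_equal(out$model$residues$aa[k], "N")
    expect_false(is.null(atom_xyz(out$model, e, "CG")))
  }
  expect_equal(nrow(out$verified), 3)
  # an obstacle at unit 3's equivalent position drops the placement
  # everywhere, preserving per-unit sequence identity
  cg3 <- atom_xyz(out$model, 13L, "CG")
  obst <- build_chain(data.frame(phi = -120, psi = 135, omega = 180))
  obst$xyz <- sweep(obst$xyz, 2, cg3 - atom_xyz(obst, 1, "CA"), "+")
  obst$residues$region <- "cap"
  m2 <- buttress:::concat_models(list(m, obst), regions = c(NA, NA),
                                 units = c(NA, NA),
                                 break_after_segment = c(TRUE, NA))
  out2 <- propagate_placements(m2, list(pl))
  expect_length(out2$kept, 0)
  expect_length(out2$dropped, 1)
  expect_match(out2$dropped[[1]]$reason, "unit 3")
  for (e in c(3L, 8L, 13L)) {
    k <- match(e, out2$model$residues$resno)
    expect_equal(out2$model$residues$aa[k], "A")
  }
})
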