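test_that("amide hydrogens sit in the peptide plane with correct geometry", {
  h <- place_amide_hydrogens(make_ideal_helix(8))
  for (i in 2:8) {
    N <- atom_xyz(h, i, "N"); H <- atom_xyz(h, i, "H")
    CA <- atom_xyz(h, i, "CA"); Cp <- atom_xyz(h, i - 1, "C")
    expect_equal(vnorm(H - N), 1.01, tolerance = 1e-9)
    a1 <- buttress:::angle_deg(H, N, CA)
    a2 <- buttress:::angle_deg(H, N, Cp)
    expect_true(a1 > 118 && a1 < 122)
    expect_true(a2 > 118 && a2 < 122)
  }
  expect_null(atom_xyz(h, 1, "H"))
  # proline gets no amide hydrogen
  hp <- make_ideal_helix(6)
  hp$residues$aa[3] <- "P"
  hp <- place_amide_hydrogens(hp)
  expect_null(atom_xyz(hp, 3, "H"))
  expect_false(is.null(atom_xyz(hp, 4, "H")))
})

test_that("backbone hydrogen bonds match the Kabsch-Sander oracle", {
  for (m in list(make_ideal_helix(14),
                 make_fixture("beta_hairpin", length = 12))) {
    got <- detect_hbonds(m, "bb_bb")
    want <- ks_oracle_bonds(m)
    key <- function(d) sort(paste(d$don_res, d$acc_res))
    expect_identical(key(got), key(want))
    expect_equal(sort(got$energy), sort(want$energy), tolerance = 1e-9)
    expect_true(all(got$energy < 0))
  }
  # the 14-residue helix: every residue 5..14 accepts from i-4
  hb <- detect_hbonds(make_ideal_helix(14), "bb_bb")
  expect_setequal(hb$don_res, 5:14)
  expect_true(all(hb$don_res - hb$acc_res == 4))
  # two isolated residues far apart: nothing
  m2 <- build_chain(data.frame(phi = c(-120, -120), psi = c(130, 130),
                               omega = 180), aa = c("G", "G"))
  m2$residues$break_after[1] <- TRUE
  m2$xyz[m2$atoms$resno == 2, ] <- m2$xyz[m2$atoms$resno == 2, ] + 20
  expect_equal(nrow(detect_hbonds(m2, "bb_bb")), 0)
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  m <- make_fixture("beta_hairpin", length = 12)
  hb0 <- detect_hbonds(m, "bb_bb")
  tr <- dof_to_transform(six_dof(12, -7, 3, 35, -60, 110))
  hb1 <- detect_hbonds(rt_apply(tr, m), "bb_bb")
  expect_equal(hb0$don_res, hb1$don_res)
  expect_equal(hb0$energy, hb1$energy, tolerance = 1e-9)
})

test_that("beta-turn detector truth table holds", {
  g <- make_fixture("turn_gallery")
  for (ty in names(g)) expect_true(detect_beta_turn(g[[ty]], 1))
  # extended strand window: no turn
  strand <- build_chain(data.frame(phi = rep(-120, 4), psi = rep(135, 4),
                                   omega = 180))
  expect_false(detect_beta_turn(strand, 1))
  # mid-helix windows: the helical bond is i -> i+4, not i -> i+3
  h <- make_ideal_helix(12)
  hb <- detect_hbonds(h, "bb_bb")
  for (i in 2:8) expect_false(detect_beta_turn(h, i, hbonds = hb))
  expect_error(detect_beta_turn(h, 10), "out of range")
})

test_that("pseudo hydrogen bond thresholds are exact", {
  place <- function(d, ang) {
    D <- c(0, 0, 0); H <- c(1.01, 0, 0)
    # acceptor at distance d from D forming the given D-H...A angle
    th <- (180 - ang) * pi / 180
    lo <- 0; hi <- 10
    for (k in 1:60) {      # bisect the H-A distance to hit d(D,A) = d
      mid <- (lo + hi) / 2
      A <- H + mid * c(cos(th), sin(th), 0)
      if (vnorm(A - D) < d) lo <- mid else hi <- mid
    }
    list(D = D, H = H, A = H + lo * c(cos(th), sin(th), 0))
  }
  p <- place(2.9, 150)
  expect_true(is_pseudo_hbond(p$D, p$H, p$A))
  p <- place(3.1, 170)
  expect_false(is_pseudo_hbond(p$D, p$H, p$A))
  p <- place(2.5, 100)
  expect_false(is_pseudo_hbond(p$D, p$H, p$A))
})

test_that("bidentate detection needs two bonds on one neighboring unit", {
  f <- plant_bidentate_fixture(c(2.9, 2.9))
  hb <- detect_hbonds(f$model, "sc_bb")
  bid <- find_bidentate(f$model, f$asn, hbonds = hb)
  expect_equal(nrow(bid), 1)
  expect_equal(bid$partner_unit, 3L)
  expect_gte(bid$n_bonds, 2)
  # every constituent bond individually passes detect_hbonds
  cons <- bid$bonds[[1]]
  key <- paste(hb$don_res, hb$don_atom, hb$acc_res, hb$acc_atom)
  expect_true(all(paste(cons$don_res, cons$don_atom, cons$acc_res,
                        cons$acc_atom) %in% key))
  # an alanine has no polar sidechain: empty
  ala <- build_sidechain(f$model, f$asn, "A")
  expect_equal(nrow(find_bidentate(ala, f$asn)), 0)
  # two bonds on two different units are not bidentate
  split <- f$model
  k <- match(7L, split$residues$resno)
  split$residues$repeat_unit[k:nrow(split$residues)] <- 4L
  split$residues$repeat_unit[k] <- 3L
  hb2 <- buttress:::sc_hbonds_for_residue(split, f$asn)
  punit <- split$residues$repeat_unit[match(
    ifelse(hb2$don_res == f$asn, hb2$acc_res, hb2$don_res),
    split$residues$resno)]
  if (length(unique(punit)) > 1) {
    expect_equal(nrow(find_bidentate(split, f$asn, hbonds = hb2)), 0)
  }
})

test_that("secondary structure assignment follows the bond patterns", {
  h <- make_ideal_helix(14)
  expect_gte(sum(assign_ss(h) == "H"), 10)
  # property: >= 90% helical for all lengths 10..28
  for (L in seq(10, 28, by = 3)) {
    expect_gte(mean(assign_ss(make_ideal_helix(L)) == "H"), 0.9)
  }
  hp <- make_fixture("beta_hairpin", length = 12)
  ss <- assign_ss(hp)
  expect_true(any(ss == "E"))
  expect_true(all(ss[5:6] == "L"))    # the turn itself stays loop
  # a 4-residue chain is too short for any i+4 pattern
  short <- build_chain(data.frame(phi = rep(-57, 4), psi = rep(-47, 4),
                                  omega = 180))
  expect_true(all(assign_ss(short) == "L"))
})
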