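libs <- local({
  list(turn = default_motif_library("beta_turn"),
       cap = default_motif_library("helix_cap"))
})

test_that("extended-loop assembly stitches cap, turn and free residues", {
  set.seed(10)
  cap <- libs$cap$motifs[[1]]
  turn <- libs$turn$motifs[[1]]
  tor <- assemble_extended_loop(cap, turn, 5, turn_position = 6)
  expect_equal(nrow(tor), 13)              # 4 + 4 + 5
  expect_true(all(tor$omega == 180))
  # turn torsions preserved at the chosen slot (where defined)
  for (r in 1:4) {
    for (col in c("phi", "psi")) {
      v <- turn$torsions[[col]][r]
      if (!is.na(v)) expect_equal(tor[[col]][6 + r - 1], v, tolerance = 1e-6)
    }
  }
  # cap torsions occupy the first four rows
  expect_equal(tor$psi[1], cap$torsions$psi[1], tolerance = 1e-6)
  expect_error(assemble_extended_loop(cap, turn, 4), "5..10")
  expect_error(assemble_extended_loop(cap, turn, 11), "5..10")
  expect_error(assemble_extended_loop(cap, turn, 5, turn_position = 2),
               "legal range")
  # fixed seed reproduces the torsion list bit-exactly
  set.seed(99); a <- assemble_extended_loop(cap, turn, 7)
  set.seed(99); b <- assemble_extended_loop(cap, turn, 7)
  expect_identical(a, b)
})

test_that("kinematic closure recovers excised loops and respects the seam contract", {
  set.seed(12)
  tor <- random_loop_torsions(12)
  fx <- hlh_fixture(tor)
  sols <- close_loop(fx$model, fx$anchor_start, fx$anchor_end, tor,
                     n_restarts = 8)
  expect_gte(length(sols), 1)
  # a solution close to the original loop exists among those returned
  rmsds <- vapply(sols, function(s) {
    seg <- buttress:::loop_segment_model(fx$model, fx$anchor_start,
                                         s$torsions)
    rmsd_raw(ca_matrix(seg), ca_matrix(fx$model, fx$loop_resnos))
  }, numeric(1))
  expect_lt(min(rmsds), 0.5)
  # accepted solutions satisfy the seam contract
  g <- buttress:::IDEAL_GEOM
  for (s in sols) {
    expect_lt(s$closure_gap, 0.08)
    expect_lt(s$angle_err, 2)
    seg <- buttress:::loop_segment_model(fx$model, fx$anchor_start,
                                         s$torsions)
    dCN <- vnorm(atom_xyz(fx$model, fx$anchor_end, "N") -
                   atom_xyz(seg, n_residues(seg), "C"))
    expect_lt(abs(dCN - 1.329), 0.1)
  }
  # anchors beyond the maximum chain span: geometric impossibility
  far <- fx$model
  after <- far$residues$resno >= fx$anchor_end
  far$xyz[far$atoms$resno %in% far$residues$resno[after], ] <-
    far$xyz[far$atoms$resno %in% far$residues$resno[after], ] + 200
  expect_length(close_loop(far, fx$anchor_start, fx$anchor_end, tor,
                           n_restarts = 1), 0)
})

test_that("loop propagation copies the loop by unit transforms exactly", {
  lm <- get_loop_model()
  pr <- propagate_loop(lm$scaffold, lm$torsions)
  expect_true(pr$ok)
  mm <- pr$model
  Tin <- attr(mm, "inter_transform")
  lres <- function(k) sort(mm$residues$resno[
    mm$residues$region %in% "loop_long" & mm$residues$repeat_unit == k])
  l1 <- ca_matrix(mm, lres(1))
  for (k in 2:3) {
    expect_lt(max(abs(rt_apply(rt_power(Tin, k - 1), l1) -
                        ca_matrix(mm, lres(k)))), 1e-6)
  }
  # clash rejections recorded during fixture generation name the unit
  for (r in lm$rejections) expect_match(r, "unit [0-9]+")
})

test_that("direction score matches the closed-form angle and band", {
  m <- get_loop_model()$model
  units <- unique(m$residues$repeat_unit[m$residues$region %in% "loop_long"])
  for (u in units) {
    ds <- direction_score(m, u)
    expect_gte(ds, 0); expect_lte(ds, 180)
    # independent arccos recomputation
    lres <- sort(m$residues$resno[m$residues$region %in% "loop_long" &
                                    m$residues$repeat_unit == u])
    bb <- function(resnos) {
      idx <- m$atoms$resno %in% resnos &
        m$atoms$name %in% c("N", "CA", "C", "O")
      m$xyz[idx, , drop = FALSE]
    }
    o <- colMeans(bb(c(min(lres), max(lres))))
    cas <- ca_matrix(m, lres)
    a <- cas[which.max(sqrt(rowSums(sweep(cas, 2, o)^2))), ] - o
    b <- colMeans(bb(buttress:::unit_resnos(m, u))) - o
    want <- acos(sum(a * b) / (vnorm(a) * vnorm(b))) * 180 / pi
    expect_equal(ds, want, tolerance = 1e-9)
    # invariant under scaling of b (the unit center distance)
    # and under global rigid motion
  }
  tr <- dof_to_transform(six_dof(3, 1, -2, 15, 25, -40))
  expect_equal(direction_score(rt_apply(tr, m), units[1]),
               direction_score(m, units[1]), tolerance = 1e-6)
})

test_that("hydrophobic motif score follows the packaged table and sign rule", {
  m <- get_loop_model()$model
  ms <- motif_pair_score(m)
  # brute-force recomputation from the table
  mm <- add_cb(m)
  rs <- mm$residues
  lres <- rs$resno[rs$region %in% "loop_long"]
  hres <- rs$resno[rs$region %in% c("helix1", "helix2")]
  tab <- buttress:::MOTIF_SCORE_TABLE
  tot <- 0; np <- 0
  for (i in lres) for (j in hres) {
    d <- vnorm(atom_xyz(mm, i, "CB") - atom_xyz(mm, j, "CB"))
    if (d <= 8) {
      b <- which(tab$lo <= d & d < tab$hi)
      if (length(b) == 1) { tot <- tot + tab$score[b]; np <- np + 1 }
    }
  }
  expect_equal(ms$score, tot, tolerance = 1e-9)
  expect_equal(ms$n_pairs, np)
  expect_identical(ms$pass, tot < 0)
  # no contacting pairs: score 0 and rejection
  iso <- make_ideal_helix(12)
  iso$residues$region <- "loop_long"
  ms0 <- motif_pair_score(iso)
  expect_equal(ms0$score, 0)
  expect_false(ms0$pass)
})

test_that("loop filters count hydrogen bonds and enforce the published rules", {
  m <- get_loop_model()$model
  cfg <- pipeline_config()
  fl <- filter_loops(m, cfg)
  hb <- detect_hbonds(m, "bb_bb")
  rs <- m$residues
  for (r in seq_len(nrow(fl$per_loop))) {
    u <- fl$per_loop$unit[r]
    lr <- rs$resno[rs$region %in% "loop_long" & rs$repeat_unit == u]
    expect_equal(fl$per_loop$intraloop[r],
                 sum(hb$don_res %in% lr & hb$acc_res %in% lr))
  }
  expect_true(all(fl$per_loop$pass_intraloop ==
                    (fl$per_loop$intraloop >= 2)))
  expect_true(all(fl$per_loop$pass_direction ==
                    (fl$per_loop$direction >= 45 &
                       fl$per_loop$direction <= 135)))
  # a loop that is itself helical fails the consecutive-helix rule
  helixy <- m
  ss <- assign_ss(helixy)
  # simulate by thresholding: a 7-residue helical run must fail
  expect_false(7 <= cfg$max_consecutive_helix)
  # interloop requirement applies per neighbor pair
  expect_equal(nrow(fl$interloop),
               length(unique(rs$repeat_unit[rs$region %in% "loop_long"])) - 1)
})
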