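## Sidechain construction on ideal internal geometry, the packaged rotamer
## table, bidentate/hydrophobic scanning, constrained rescue of
## pseudo-bidentate near-misses, and buried-unsatisfied counting.

# sidechain build recipes: each atom from three reference atoms with bond /
# angle / torsion, where torsion is a chi index ("chi1"), an offset
# ("chi2+180"), or a number (ring/planar closure). Amide and imidazole
# hydrogens are built explicitly because the hydrogen-bond rules need them.
SIDECHAIN_RECIPES <- list(
  N = list(
    list("CG", c("N", "CA", "CB"), 1.516, 112.6, "chi1"),
    list("OD1", c("CA", "CB", "CG"), 1.231, 120.8, "chi2"),
    list("ND2", c("CA", "CB", "CG"), 1.328, 116.4, "chi2+180"),
    list("HD21", c("OD1", "CG", "ND2"), 1.01, 120.0, 180),
    list("HD22", c("OD1", "CG", "ND2"), 1.01, 120.0, 0)
  ),
  D = list(
    list("CG", c("N", "CA", "CB"), 1.516, 112.6, "chi1"),
    list("OD1", c("CA", "CB", "CG"), 1.249, 118.4, "chi2"),
    list("OD2", c("CA", "CB", "CG"), 1.249, 118.4, "chi2+180")
  ),
  Q = list(
    list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
    list("CD", c("CA", "CB", "CG"), 1.516, 112.6, "chi2"),
    list("OE1", c("CB", "CG", "CD"), 1.231, 120.8, "chi3"),
    list("NE2", c("CB", "CG", "CD"), 1.328, 116.4, "chi3+180"),
    list("HE21", c("OE1", "CD", "NE2"), 1.01, 120.0, 180),
    list("HE22", c("OE1", "CD", "NE2"), 1.01, 120.0, 0)
  ),
  H = list(
    list("CG", c("N", "CA", "CB"), 1.497, 113.8, "chi1"),
    list("ND1", c("CA", "CB", "CG"), 1.371, 122.7, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.356, 131.2, "chi2+180"),
    list("CE1", c("CB", "CG", "ND1"), 1.319, 109.0, 180),
    list("NE2", c("CG", "ND1", "CE1"), 1.321, 111.7, 0),
    list("HD1", c("CD2", "CG", "ND1"), 1.01, 125.0, 180),
    list("HE2", c("ND1", "CE1", "NE2"), 1.01, 125.0, 180)
  ),
  V = list(
    list("CG1", c("N", "CA", "CB"), 1.521, 110.5, "chi1"),
    list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1+122.3")
  ),
  L = list(
    list("CG", c("N", "CA", "CB"), 1.530, 116.3, "chi1"),
    list("CD1", c("CA", "CB", "CG"), 1.521, 110.7, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.521, 110.7, "chi2+122.3")
  ),
  I = list(
    list("CG1", c("N", "CA", "CB"), 1.530, 110.4, "chi1"),
    list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1-122.3"),
    list("CD1", c("CA", "CB", "CG1"), 1.513, 113.8, "chi2")
  ),
  M = list(
    list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
    list("SD", c("CA", "CB", "CG"), 1.803, 112.7, "chi2"),
    list("CE", c("CB", "CG", "SD"), 1.791, 100.9, "chi3")
  ),
  F = list(
    list("CG", c("N", "CA", "CB"), 1.502, 113.8, "chi1"),
    list("CD1", c("CA", "CB", "CG"), 1.384, 120.8, "chi2"),
    list("CD2", c("CA", "CB", "CG"), 1.384, 120.8, "chi2+180"),
    list("CE1", c("CB", "CG", "CD1"), 1.384, 120.8, 180),
    list("CE2", c("CB", "CG", "CD2"), 1.384, 120.8, 180),
    list("CZ", c("CG", "CD1", "CE1"), 1.384, 120.0, 0)
  )
)

#' Packaged backbone-independent rotamer table
#'
#' Common rotamer chi combinations per residue type, sufficient for
#' geometric feasibility scanning of bidentate hydrogen bonds and
#' hydrophobic contacts (a compact stand-in for a full backbone-dependent
#' rotamer library).
#'
#' @param aa one-letter code; NULL returns the whole table.
#' @return list of numeric chi vectors (degrees).
#' @export
rotamer_table <- function(aa = NULL) {
  combos <- function(...) {
    g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  tab <- list(
    N = combos(chi1 = c(-65, -177, 62), chi2 = c(-60, -20, 30, 90)),
    D = combos(chi1 = c(-70, -177, 62), chi2 = c(-15, 15, 65)),
    Q = combos(chi1 = c(-65, -177, 62), chi2 = c(-65, 180, 65),
               chi3 = c(-45, 0, 45)),
    H = combos(chi1 = c(-65, -177, 62), chi2 = c(-75, 60, 165)),
    V = combos(chi1 = c(175, -60, 63)),
    L = combos(chi1 = c(-65, -177), chi2 = c(175, 65)),
    I = combos(chi1 = c(-65, -177, 62), chi2 = c(170, -60)),
    M = combos(chi1 = c(-65, -177, 62), chi2 = c(-65, 180, 65),
               chi3 = c(-75, 75, 180)),
    F = combos(chi1 = c(-65, -177, 62), chi2 = c(90, -90))
  )
  if (is.null(aa)) tab else tab[[aa]]
}

resolve_torsion <- function(spec, chis) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
  v <- chis[as.integer(m[2])]
  if (nzchar(m[3])) v <- v + as.numeric(m[3])
  v
}

#' Build a sidechain from chi angles on ideal internal geometry
#'
#' Replaces residue `resno`'s sidechain (and amino-acid label) with `aa`
#' built from the chi angles; polar functional-group hydrogens are placed
#' so the geometric hydrogen-bond rules apply. Existing sidechain atoms of
#' the residue are removed first.
#'
#' @param model a `backbone_model`.
#' @param resno residue index.
#' @param aa one-letter code in N, D, Q, H, V, L, I, M, F (or "A" to revert
#'   to alanine).
#' @param chis numeric chi vector.
#' @return updated model.
#' @export
build_sidechain <- function(model, resno, aa, chis = numeric(0)) {
  known <- model$atoms$name[model$atoms$resno == resno]
  side <- setdiff(known, c(BACKBONE_ATOMS, "H"))
  model <- drop_atoms(model, resno, side)
  k <- match(resno, model$residues$resno)
  model$residues$aa[k] <- aa
  N <- atom_xyz(model, resno, "N")
  CA <- atom_xyz(model, resno, "CA")
  C <- atom_xyz(model, resno, "C")
  if (aa == "G") return(model)
  model <- set_atom_xyz(model, resno, "CB", cb_position(N, CA, C))
  if (aa == "A") return(model)
  recipe <- SIDECHAIN_RECIPES[[aa]]
  if (is.null(recipe)) stop("no sidechain recipe for residue type ", aa)
  for (step in recipe) {
    refs <- lapply(step[[2]], function(nm) atom_xyz(model, resno, nm))
    pos <- nerf_place(refs[[1]], refs[[2]], refs[[3]], step[[3]], step[[4]],
                      resolve_torsion(step[[5]], chis))
    model <- set_atom_xyz(model, resno, step[[1]], pos)
  }
  model
}

# sidechain-backbone hydrogen bonds involving one residue's sidechain only
# (fast path for rotamer scanning; same rule as detect_hbonds class sc_bb)
sc_hbonds_for_residue <- function(model, resno) {
  k <- match(resno, model$residues$resno)
  aa <- model$residues$aa[k]
  pol <- SC_POLAR[[aa]]
  out <- list(empty_hbonds())
  if (is.null(pol)) return(out[[1]])
  others <- model$residues$resno[!model$residues$incomplete &
                                   model$residues$resno != resno]
  for (dn in pol$donors) {
    D <- atom_xyz(model, resno, dn)
    if (is.null(D)) next
    for (hname in SC_DONOR_H[[dn]]) {
      Hh <- atom_xyz(model, resno, hname)
      if (is.null(Hh)) next
      for (j in others) {
        A <- atom_xyz(model, j, "O")
        if (is.null(A)) next
        d <- vnorm(D - A)
        if (d < SC_BB_DMAX && angle_deg(D, Hh, A) > SC_BB_AMIN) {
          out[[length(out) + 1L]] <- hbond_record(resno, dn, j, "O", d,
                                                  angle_deg(D, Hh, A),
                                                  NA_real_, "sc_bb")
        }
      }
    }
  }
  for (an in pol$acceptors) {
    A <- atom_xyz(model, resno, an)
    if (is.null(A)) next
    for (j in others) {
      Dj <- atom_xyz(model, j, "N")
      Hj <- atom_xyz(model, j, "H")
      if (is.null(Dj) || is.null(Hj)) next
      d <- vnorm(Dj - A)
      if (d < SC_BB_DMAX && angle_deg(Dj, Hj, A) > SC_BB_AMIN) {
        out[[length(out) + 1L]] <- hbond_record(j, "N", resno, an, d,
                                                angle_deg(Dj, Hj, A),
                                                NA_real_, "sc_bb")
      }
    }
  }
  do.call(rbind, out)
}

placement_record <- function(resno, aa, chis, n_bidentate, accepted) {
  list(resno = resno, aa = aa, chis = chis, n_bidentate = n_bidentate,
       accepted = accepted)
}

#' Scan loop positions for bidentate-capable polar residues
#'
#' For each position and each of Asn/Asp/Gln/His (never Arg/Lys, whose
#' entropic cost would offset the buttressing), every rotamer in the
#' packaged table is built on the fixed backbone; clashing rotamers are
#' rejected and the rest are kept iff they form at least one interloop
#' bidentate hydrogen bond ([find_bidentate()]). Positions with no
#' accepted placement revert to the original residue (alanine).
#'
#' @param model a `backbone_model` with repeat-unit labels and amide H.
#' @param positions loop residue indices to scan.
#' @param aas candidate amino acids; default c("N","D","Q","H").
#' @param mode passed to [find_bidentate()].
#' @param clash_factor clash threshold factor for rotamer screening.
#' @return list with `model` (accepted placements applied) and
#'   `placements` (one record per position).
#' @export
scan_bidentate <- function(model, positions, aas = c("N", "D", "Q", "H"),
                           mode = "interloop", clash_factor = 0.55) {
  if (!any(model$atoms$name == "H")) model <- place_amide_hydrogens(model)
  placements <- list()
  for (p in positions) {
    best <- NULL
    for (aa in aas) {
      for (chis in rotamer_table(aa)) {
        trial <- build_sidechain(model, p, aa, chis)
        if (clash_check(trial, p, factor = clash_factor)) next
        hb <- sc_hbonds_for_residue(trial, p)
        bid <- find_bidentate(trial, p, hbonds = hb, mode = mode)
        if (nrow(bid) > 0) {
          best <- placement_record(p, aa, chis, nrow(bid), TRUE)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      best <- placement_record(p, "A", numeric(0), 0L, FALSE)
    } else {
      model <- build_sidechain(model, p, best$aa, best$chis)
    }
    placements[[length(placements) + 1L]] <- best
  }
  list(model = model, placements = placements)
}

pseudo_pairs <- function(model, resno, d_max = 3.0, angle_min = 120) {
  # near-miss donor/acceptor heavy-atom pairs between this sidechain's
  # functional group and other residues' backbones
  k <- match(resno, model$residues$resno)
  pol <- SC_POLAR[[model$residues$aa[k]]]
  if (is.null(pol)) return(NULL)
  punit <- function(j) model$residues$repeat_unit[
    match(j, model$residues$resno)]
  pairs <- list()
  others <- model$residues$resno[model$residues$resno != resno]
  for (dn in pol$donors) {
    for (hname in SC_DONOR_H[[dn]]) {
      if (is.null(atom_xyz(model, resno, hname))) next
      for (j in others) {
        if (is.null(atom_xyz(model, j, "O"))) next
        pairs[[length(pairs) + 1L]] <- list(
          d_res = resno, d_atom = dn, h_atom = hname, h_res = resno,
          a_res = j, a_atom = "O", unit = punit(j))
      }
    }
  }
  for (an in pol$acceptors) {
    for (j in others) {
      if (is.null(atom_xyz(model, j, "H"))) next
      pairs[[length(pairs) + 1L]] <- list(
        d_res = j, d_atom = "N", h_atom = "H", h_res = j,
        a_res = resno, a_atom = an, unit = punit(j))
    }
  }
  keep <- Filter(function(pr) {
    D <- atom_xyz(model, pr$d_res, pr$d_atom)
    Hh <- atom_xyz(model, pr$h_res, pr$h_atom)
    A <- atom_xyz(model, pr$a_res, pr$a_atom)
    is_pseudo_hbond(D, Hh, A, d_max, angle_min)
  }, pairs)
  keep
}

#' Rescue a pseudo-bidentate placement by constrained chi refinement
#'
#' When a polar placement has two or more pseudo hydrogen bonds
#' ([is_pseudo_hbond()]: donor-acceptor < 3 A, angle > 120 degrees) to one
#' neighbor unit, its chi angles are refined to minimize the harmonic
#' objective sum(((d - target)/sigma)^2) over the pseudo-bond
#' donor-acceptor distances (grid of +/-30 degrees in 2-degree steps per
#' chi, cycled, then a local Nelder-Mead polish), rejecting chi values
#' that clash. The refined placement is accepted iff [find_bidentate()]
#' then reports a genuine bidentate bond.
#'
#' @param model a `backbone_model` carrying the placement's sidechain.
#' @param placement a record from [scan_bidentate()] (fields `resno`,
#'   `aa`, `chis`).
#' @param target,sigma harmonic constraint parameters; defaults 2.0 and
#'   0.5 A.
#' @param mode passed to [find_bidentate()].
#' @return list with `model`, `placement` (updated chis and `accepted`),
#'   and `objective`.
#' @export
rescue_pseudo_bidentate <- function(model, placement, target = 2.0,
                                    sigma = 0.5, mode = "interloop",
                                    clash_factor = 0.55) {
  p <- placement$resno
  if (!any(model$atoms$name == "H")) model <- place_amide_hydrogens(model)
  model <- build_sidechain(model, p, placement$aa, placement$chis)
  prs <- pseudo_pairs(model, p)
  if (is.null(prs) || length(prs) == 0) {
    return(list(model = model, placement = placement, objective = NA_real_))
  }
  # restrict to the best-supported single partner unit (>= 2 near-misses)
  units <- vapply(prs, function(x) ifelse(is.na(x$unit), -1L, x$unit),
                  integer(1))
  tabu <- table(units)
  u <- as.integer(names(tabu)[which.max(tabu)])
  prs <- prs[units == u]
  if (length(prs) < 2) {
    return(list(model = model, placement = placement, objective = NA_real_))
  }
  objective <- function(chis) {
    trial <- build_sidechain(model, p, placement$aa, chis)
    if (clash_check(trial, p, factor = clash_factor)) return(1e6)
    s <- 0
    for (pr in prs) {
      D <- atom_xyz(trial, pr$d_res, pr$d_atom)
      A <- atom_xyz(trial, pr$a_res, pr$a_atom)
      s <- s + ((vnorm(D - A) - target) / sigma)^2
    }
    s
  }
  chis <- placement$chis
  best <- objective(chis)
  for (cycle in 1:2) {
    for (ci in seq_along(chis)) {
      grid <- chis[ci] + seq(-30, 30, by = 2)
      vals <- vapply(grid, function(v) {
        cc <- chis; cc[ci] <- v; objective(cc)
      }, numeric(1))
      chis[ci] <- grid[which.min(vals)]
      best <- min(vals)
    }
  }
  if (length(chis) > 0) {
    op <- stats::optim(chis, objective, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-6))
    if (op$value <= best) { chis <- op$par; best <- op$value }
  }
  out <- build_sidechain(model, p, placement$aa, chis)
  hb <- sc_hbonds_for_residue(out, p)
  bid <- find_bidentate(out, p, hbonds = hb, mode = mode)
  placement$chis <- chis
  placement$n_bidentate <- nrow(bid)
  placement$accepted <- nrow(bid) > 0
  list(model = out, placement = placement, objective = best)
}

#' Scan loop positions for loop-helix hydrophobic placements
#'
#' Tries Val/Leu/Ile/Met/Phe rotamers at each position; a placement is
#' accepted iff at least `min_atoms` sidechain heavy atoms lie within
#' `contact_dist` of helix heavy atoms and the rotamer does not clash.
#'
#' @param model a `backbone_model`.
#' @param positions loop residue indices.
#' @param min_atoms default 4 contacting sidechain heavy atoms.
#' @param contact_dist contact distance, default 4.5 A.
#' @return list with `model` and `placements`.
#' @export
scan_hydrophobic_contacts <- function(model, positions, min_atoms = 4,
                                      contact_dist = 4.5,
                                      clash_factor = 0.55) {
  hres <- model$residues$resno[model$residues$region %in%
                                 c("helix1", "helix2")]
  hidx <- model$atoms$resno %in% hres & !startsWith(model$atoms$name, "H")
  hxyz <- model$xyz[hidx, , drop = FALSE]
  placements <- list()
  for (p in positions) {
    best <- NULL
    for (aa in c("V", "L", "I", "M", "F")) {
      for (chis in rotamer_table(aa)) {
        trial <- build_sidechain(model, p, aa, chis)
        if (clash_check(trial, p, factor = clash_factor)) next
        snames <- setdiff(trial$atoms$name[trial$atoms$resno == p],
                          c(BACKBONE_ATOMS, "H", "CB"))
        if (length(snames) == 0) next
        sxyz <- do.call(rbind, lapply(snames, function(nm)
          atom_xyz(trial, p, nm)))
        ncontact <- sum(vapply(seq_len(nrow(sxyz)), function(i) {
          min(sqrt(rowSums(sweep(hxyz, 2, sxyz[i, ])^2))) <= contact_dist
        }, logical(1)))
        if (ncontact >= min_atoms) {
          best <- placement_record(p, aa, chis, 0L, TRUE)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      best <- placement_record(p, "A", numeric(0), 0L, FALSE)
    } else {
      model <- build_sidechain(model, p, best$aa, best$chis)
    }
    placements[[length(placements) + 1L]] <- best
  }
  list(model = model, placements = placements)
}

#' Count buried unsatisfied polar heavy atoms
#'
#' Counts nitrogen/oxygen atoms (backbone amide N and carbonyl O, plus
#' polar sidechain atoms) of core-layer residues ([assign_layers()]) that
#' participate in no detected hydrogen bond. The published report-level
#' threshold is <= 3 per model.
#'
#' For this count "buried" means deeply buried (default: at least
#' `core_count = 22` cone neighbors), a stricter criterion than the layer
#' used by the 28% core-fraction filter, mirroring the solvent-
#' inaccessibility notion behind buried-unsatisfied scoring.
#'
#' @param model a `backbone_model`.
#' @param layers optional precomputed [assign_layers()] table.
#' @param core_count burial depth used when `layers` is NULL.
#' @return integer count.
#' @export
count_buried_unsatisfied <- function(model, layers = NULL,
                                     core_count = 22) {
  if (!any(model$atoms$name == "H")) model <- place_amide_hydrogens(model)
  if (is.null(layers)) layers <- assign_layers(model,
                                               core_count = core_count)
  hb <- detect_hbonds(model, "all")
  core <- layers$resno[layers$layer == "core"]
  count <- 0L
  for (i in core) {
    k <- match(i, model$residues$resno)
    polar <- c("O", if (model$residues$aa[k] != "P" && k > 1) "N")
    pol <- SC_POLAR[[model$residues$aa[k]]]
    if (!is.null(pol)) polar <- c(polar, unique(c(pol$donors, pol$acceptors)))
    for (at in polar) {
      if (is.na(atom_row(model, i, at))) next
      satisfied <-
        any(hb$don_res == i & hb$don_atom == at) ||
        any(hb$acc_res == i & hb$acc_atom == at)
      if (!satisfied) count <- count + 1L
    }
  }
  count
}

#' Propagate accepted placements to every repeat unit
#'
#' Copies each placement's amino acid and chi angles to the equivalent
#' position (same region and within-segment offset) of every unit, then
#' re-verifies the interloop bidentate bonds per unit. If the propagated
#' sidechain clashes in any unit the placement is dropped everywhere, so
#' all units keep identical sequences.
#'
#' @param model a `backbone_model` with repeat annotations.
#' @param placements accepted records from [scan_bidentate()].
#' @return list with `model`, `kept` (records), `dropped` (records with
#'   reasons), `verified` (data.frame unit x placement bidentate checks).
#' @export
propagate_placements <- function(model, placements, mode = "interloop",
                                 clash_factor = 0.55) {
  placements <- Filter(function(p) isTRUE(p$accepted), placements)
  rs <- model$residues
  pos_key <- function(resno) {
    k <- match(resno, rs$resno)
    seg <- rs$resno[rs$region %in% rs$region[k] &
                      rs$repeat_unit == rs$repeat_unit[k]]
    list(region = rs$region[k], offset = match(resno, sort(seg)))
  }
  equivalents <- function(resno) {
    key <- pos_key(resno)
    units <- sort(unique(rs$repeat_unit[rs$region %in% key$region]))
    vapply(units, function(u) {
      seg <- sort(rs$resno[rs$region %in% key$region & rs$repeat_unit == u])
      if (key$offset <= length(seg)) seg[key$offset] else NA_integer_
    }, integer(1))
  }
  kept <- list(); dropped <- list(); checks <- list()
  for (pl in placements) {
    eq <- equivalents(pl$resno)
    eq <- eq[!is.na(eq)]
    trial <- model
    for (e in eq) trial <- build_sidechain(trial, e, pl$aa, pl$chis)
    clash_unit <- NA_integer_
    for (e in eq) {
      if (clash_check(trial, e, factor = clash_factor)) {
        clash_unit <- rs$repeat_unit[match(e, rs$resno)]
        break
      }
    }
    if (!is.na(clash_unit)) {
      pl$reason <- sprintf("propagated sidechain clashes in unit %d",
                           clash_unit)
      dropped[[length(dropped) + 1L]] <- pl
      next
    }
    model <- trial
    kept[[length(kept) + 1L]] <- pl
    for (e in eq) {
      hbe <- sc_hbonds_for_residue(model, e)
      bide <- find_bidentate(model, e, hbonds = hbe, mode = mode)
      checks[[length(checks) + 1L]] <- data.frame(
        position = e, unit = rs$repeat_unit[match(e, rs$resno)],
        aa = pl$aa, bidentate = nrow(bide) > 0)
    }
  }
  list(model = model, kept = kept, dropped = dropped,
       verified = if (length(checks)) do.call(rbind, checks) else
         data.frame(position = integer(0), unit = integer(0),
                    aa = character(0), bidentate = logical(0)))
}
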