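## Hydrogen-bond geometry: amide-H building, Kabsch-Sander backbone bonds,
## geometric sidechain-backbone bonds, beta-turn and bidentate detection,
## and a reduced DSSP-style secondary-structure assignment.

# Kabsch-Sander electrostatic constant: q1*q2*332 = 0.084 * 332 kcal*A/mol
KS_CONST <- 27.888
KS_CUTOFF <- -0.5       # kcal/mol; bond iff E < cutoff
SC_BB_DMAX <- 3.5       # A, donor-acceptor for geometric sidechain rule
SC_BB_AMIN <- 120       # degrees, D-H...A

# sidechain donor/acceptor atoms (heavy) per residue type; donors carry the
# explicit polar hydrogens built by build_sidechain()
SC_POLAR <- list(
  N = list(donors = c("ND2"), acceptors = c("OD1")),
  D = list(donors = character(0), acceptors = c("OD1", "OD2")),
  Q = list(donors = c("NE2"), acceptors = c("OE1")),
  H = list(donors = c("ND1", "NE2"), acceptors = c("ND1", "NE2"))
)

# which hydrogen names sit on which sidechain donor
SC_DONOR_H <- list(
  ND2 = c("HD21", "HD22"), NE2 = c("HE21", "HE22", "HE2"), ND1 = c("HD1")
)

#' Build backbone amide hydrogens
#'
#' Places H in the C(i-1)-N(i)-CA(i) plane at 1.01 A from N, anti to the
#' bisector of the two N bonds (so H-N-CA and H-N-C(i-1) are both ~119-121
#' degrees). Residue 1, prolines, and residues following a declared chain
#' break get no amide hydrogen.
#'
#' @param model a `backbone_model`.
#' @return the model with `H` atoms added.
#' @export
place_amide_hydrogens <- function(model) {
  res <- model$residues
  for (k in seq_len(nrow(res))[-1]) {
    i <- res$resno[k]
    if (res$aa[k] == "P") next
    if (res$incomplete[k]) next
    kp <- k - 1L
    if (res$incomplete[kp] || isTRUE(res$break_after[kp])) next
    Cp <- atom_xyz(model, res$resno[kp], "C")
    N <- atom_xyz(model, i, "N")
    CA <- atom_xyz(model, i, "CA")
    if (is.null(Cp) || is.null(N) || is.null(CA)) next
    bis <- vunit(vunit(Cp - N) + vunit(CA - N))
    model <- set_atom_xyz(model, i, "H", N - 1.01 * bis)
  }
  model
}

ks_energy <- function(O, C, N, H) {
  rON <- vnorm(O - N); rCH <- vnorm(C - H)
  rOH <- vnorm(O - H); rCN <- vnorm(C - N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clamp, as in DSSP
  KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

hbond_record <- function(don_res, don_atom, acc_res, acc_atom, d_DA,
                         angle_DHA, energy, class) {
  data.frame(don_res = don_res, don_atom = don_atom, acc_res = acc_res,
             acc_atom = acc_atom, d_DA = d_DA, angle_DHA = angle_DHA,
             energy = energy, class = class, stringsAsFactors = FALSE)
}

empty_hbonds <- function() {
  hbond_record(integer(0), character(0), integer(0), character(0),
               numeric(0), numeric(0), numeric(0), character(0))
}

#' Detect hydrogen bonds
#'
#' Backbone-backbone (`bb_bb`) bonds use the Kabsch-Sander electrostatic
#' energy between the C=O group of the acceptor residue and the N-H group of
#' the donor residue, reported when E < -0.5 kcal/mol (the DSSP criterion).
#' Sidechain-backbone (`sc_bb`) bonds use the geometric rule d(D,A) < 3.5 A
#' and D-H...A > 120 degrees, with donors/acceptors enumerated per residue
#' type (Asn/Asp/Gln/His sidechains against backbone N-H / C=O, and backbone
#' N-H against sidechain acceptors).
#'
#' @param model a `backbone_model`; amide hydrogens are placed on the fly if
#'   absent.
#' @param class "bb_bb", "sc_bb" or "all".
#' @return data.frame with one row per bond: donor/acceptor residue and atom,
#'   `d_DA` (A), `angle_DHA` (degrees), `energy` (kcal/mol, Kabsch-Sander for
#'   bb_bb), `class`.
#' @export
detect_hbonds <- function(model, class = c("all", "bb_bb", "sc_bb")) {
  class <- match.arg(class)
  if (!any(model$atoms$name == "H")) model <- place_amide_hydrogens(model)
  res <- model$residues[!model$residues$incomplete, , drop = FALSE]
  out <- list(empty_hbonds())
  geom <- lapply(res$resno, function(i) {
    list(N = atom_xyz(model, i, "N"), H = atom_xyz(model, i, "H"),
         C = atom_xyz(model, i, "C"), O = atom_xyz(model, i, "O"),
         CA = atom_xyz(model, i, "CA"))
  })
  names(geom) <- as.character(res$resno)
  if (class %in% c("all", "bb_bb")) {
    # vectorized Kabsch-Sander energies over donor/acceptor pairs
    getm <- function(name) {
      do.call(rbind, lapply(geom, function(g) {
        if (is.null(g[[name]])) c(NA, NA, NA) else g[[name]]
      }))
    }
    Nm <- getm("N"); Hm <- getm("H"); Cm <- getm("C"); Om <- getm("O")
    nn <- nrow(res)
    if (nn >= 2) {
      pd2 <- function(A, B) {
        outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      }
      A2 <- Nm; A2[is.na(A2)] <- 1e6
      B2 <- Om; B2[is.na(B2)] <- -1e6
      dON <- sqrt(pmax(pd2(A2, B2), 0))          # donor row, acceptor col
      cand <- which(dON < 5.5, arr.ind = TRUE)
      sep_ok <- abs(res$resno[cand[, 1]] - res$resno[cand[, 2]]) >= 2
      cand <- cand[sep_ok & !is.na(Hm[cand[, 1], 1]) &
                     !is.na(Om[cand[, 2], 1]), , drop = FALSE]
      if (nrow(cand) > 0) {
        di <- cand[, 1]; aj <- cand[, 2]
        rn <- function(A, B) sqrt(rowSums((A - B)^2))
        rON <- rn(Om[aj, , drop = FALSE], Nm[di, , drop = FALSE])
        rCH <- rn(Cm[aj, , drop = FALSE], Hm[di, , drop = FALSE])
        rOH <- rn(Om[aj, , drop = FALSE], Hm[di, , drop = FALSE])
        rCN <- rn(Cm[aj, , drop = FALSE], Nm[di, , drop = FALSE])
        e <- KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
        e[pmin(rON, rCH, rOH, rCN) < 0.5] <- -9.9
        keep <- which(e < KS_CUTOFF)
        for (k in keep) {
          i <- res$resno[di[k]]; j <- res$resno[aj[k]]
          gi <- geom[[as.character(i)]]; gj <- geom[[as.character(j)]]
          out[[length(out) + 1L]] <- hbond_record(
            i, "N", j, "O", rON[k], angle_deg(gi$N, gi$H, gj$O), e[k],
            "bb_bb")
        }
      }
    }
  }
  if (class %in% c("all", "sc_bb")) {
    for (a in seq_len(nrow(res))) {
      i <- res$resno[a]
      pol <- SC_POLAR[[res$aa[a]]]
      if (is.null(pol)) next
      # sidechain donor -> backbone O
      for (dn in pol$donors) {
        D <- atom_xyz(model, i, dn)
        if (is.null(D)) next
        hs <- SC_DONOR_H[[dn]]
        for (hname in hs) {
          Hh <- atom_xyz(model, i, hname)
          if (is.null(Hh)) next
          for (b in seq_len(nrow(res))) {
            j <- res$resno[b]
            if (j == i) next
            A <- atom_xyz(model, j, "O")
            d <- vnorm(D - A)
            if (d >= SC_BB_DMAX) next
            ang <- angle_deg(D, Hh, A)
            if (ang > SC_BB_AMIN) {
              out[[length(out) + 1L]] <- hbond_record(
                i, dn, j, "O", d, ang, NA_real_, "sc_bb")
            }
          }
        }
      }
      # backbone N-H -> sidechain acceptor handled from the donor side below
    }
    # backbone donors to sidechain acceptors
    for (b in seq_len(nrow(res))) {
      j <- res$resno[b]
      pol <- SC_POLAR[[res$aa[b]]]
      if (is.null(pol) || length(pol$acceptors) == 0) next
      for (an in pol$acceptors) {
        A <- atom_xyz(model, j, an)
        if (is.null(A)) next
        for (a in seq_len(nrow(res))) {
          i <- res$resno[a]
          if (i == j) next
          gi <- geom[[as.character(i)]]
          if (is.null(gi$H)) next
          d <- vnorm(gi$N - A)
          if (d >= SC_BB_DMAX) next
          ang <- angle_deg(gi$N, gi$H, A)
          if (ang > SC_BB_AMIN) {
            out[[length(out) + 1L]] <- hbond_record(
              i, "N", j, an, d, ang, NA_real_, "sc_bb")
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Is the four-residue window starting at i a beta turn?
#'
#' TRUE iff a backbone-backbone hydrogen bond links the carbonyl of residue
#' `i` to the amide of residue `i + 3` (the classic turn criterion).
#'
#' @param model a `backbone_model`.
#' @param i window start residue.
#' @param hbonds optionally, a precomputed [detect_hbonds()] table.
#' @export
detect_beta_turn <- function(model, i, hbonds = NULL) {
  rs <- model$residues$resno
  if (!all((i:(i + 3)) %in% rs)) stop("window out of range")
  if (any(model$residues$break_after[match(i:(i + 2), rs)])) {
    stop("chain break inside the window")
  }
  if (is.null(hbonds)) hbonds <- detect_hbonds(model, "bb_bb")
  any(hbonds$class == "bb_bb" & hbonds$acc_res == i &
        hbonds$don_res == i + 3)
}

#' Pseudo hydrogen bond test
#'
#' The relaxed near-miss criterion used before constrained rescue: TRUE iff
#' the donor-acceptor distance is below 3 A and the D-H...A angle (vertex at
#' the hydrogen) exceeds 120 degrees.
#'
#' @param donor,h,acceptor coordinates of the donor heavy atom, its
#'   hydrogen, and the acceptor heavy atom.
#' @param d_max,angle_min thresholds; defaults 3.0 A and 120 degrees.
#' @export
is_pseudo_hbond <- function(donor, h, acceptor, d_max = 3.0,
                            angle_min = 120) {
  vnorm(donor - acceptor) < d_max && angle_deg(donor, h, acceptor) > angle_min
}

#' Find bidentate sidechain-to-backbone hydrogen bonds
#'
#' Groups sidechain-backbone hydrogen bonds of one residue by its sidechain
#' functional group and reports a bidentate bond whenever two or more of
#' them land on the backbone of a single neighboring repeat unit (units
#' k - 1 and k + 1 of the sidechain's unit), or, in loop-helix mode, any
#' single partner unit including the residue's own.
#'
#' @param model a `backbone_model` with repeat_unit labels.
#' @param resno the sidechain residue.
#' @param hbonds optional precomputed bond table.
#' @param mode "interloop" restricts partners to adjacent units;
#'   "loop_helix" allows any one unit.
#' @return data.frame with one row per bidentate interaction: `resno`, `aa`,
#'   `partner_unit`, `n_bonds`, plus a list-column `bonds` of the
#'   constituent bond tables.
#' @export
find_bidentate <- function(model, resno, hbonds = NULL,
                           mode = c("interloop", "loop_helix")) {
  mode <- match.arg(mode)
  k <- match(resno, model$residues$resno)
  aa <- model$residues$aa[k]
  unit <- model$residues$repeat_unit[k]
  empty <- data.frame(resno = integer(0), aa = character(0),
                      partner_unit = integer(0), n_bonds = integer(0))
  if (!aa %in% names(SC_POLAR)) return(empty)
  if (is.null(hbonds)) hbonds <- detect_hbonds(model, "sc_bb")
  hb <- hbonds[hbonds$class == "sc_bb" &
                 ((hbonds$don_res == resno & hbonds$don_atom != "N") |
                  (hbonds$acc_res == resno & hbonds$acc_atom != "O")), ,
               drop = FALSE]
  if (nrow(hb) == 0) return(empty)
  partner <- ifelse(hb$don_res == resno, hb$acc_res, hb$don_res)
  punit <- model$residues$repeat_unit[match(partner, model$residues$resno)]
  keep <- !is.na(punit)
  if (mode == "interloop" && !is.na(unit)) {
    keep <- keep & abs(punit - unit) == 1
  }
  hb <- hb[keep, , drop = FALSE]
  punit <- punit[keep]
  if (nrow(hb) == 0) return(empty)
  out <- empty
  bonds <- list()
  for (u in sort(unique(punit))) {
    sub <- hb[punit == u, , drop = FALSE]
    if (nrow(sub) >= 2) {
      out <- rbind(out, data.frame(resno = resno, aa = aa,
                                   partner_unit = u, n_bonds = nrow(sub)))
      bonds[[length(bonds) + 1L]] <- sub
    }
  }
  out$bonds <- bonds
  out
}

#' Reduced DSSP-style secondary-structure assignment
#'
#' Uses the Kabsch-Sander backbone hydrogen bonds: two consecutive i -> i+4
#' turns label the spanned residues H (alpha-helix); bridge patterns
#' (parallel or antiparallel ladders) label residues E; everything else L.
#'
#' @param model a `backbone_model`.
#' @param hbonds optional precomputed bb_bb bond table.
#' @return character vector, one of "H", "E", "L" per residue.
#' @export
assign_ss <- function(model, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(model, "bb_bb")
  rs <- model$residues$resno
  n <- length(rs)
  key <- function(acc, don) acc * 1e5 + don
  bonds <- key(hbonds$acc_res, hbonds$don_res)
  has <- function(acc, don) key(acc, don) %in% bonds
  ss <- rep("L", n)
  # alpha helices: each i -> i+4 turn labels residues i .. i+3 helical
  turn4_at <- rs[has(rs, rs + 4)]
  for (i in turn4_at) ss[rs %in% (i:(i + 3))] <- "H"
  # beta bridges (parallel and antiparallel ladder patterns)
  pr <- expand.grid(i = rs, j = rs)
  pr <- pr[abs(pr$i - pr$j) >= 3, ]
  par <- (has(pr$i - 1, pr$j) & has(pr$j, pr$i + 1)) |
         (has(pr$j - 1, pr$i) & has(pr$i, pr$j + 1))
  anti <- (has(pr$i, pr$j) & has(pr$j, pr$i)) |
          (has(pr$i - 1, pr$j + 1) & has(pr$j - 1, pr$i + 1))
  bridged <- unique(pr$i[par | anti])
  ss[rs %in% bridged & ss != "H"] <- "E"
  ss
}
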