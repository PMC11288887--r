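# Independent oracles and constructive fixtures used across the suite.

vnorm <- function(v) sqrt(sum(v * v))

# Horn's quaternion method for optimal superposition RMSD: an independent
# check on the SVD-based Kabsch implementation.
quaternion_superpose_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# plain-loop Kabsch-Sander hydrogen-bond oracle (donor i amide -> acceptor
# j carbonyl), independent of the vectorized implementation
ks_oracle_bonds <- function(model) {
  model <- place_amide_hydrogens(model)
  rs <- model$residues$resno
  out <- data.frame(don_res = integer(0), acc_res = integer(0),
                    energy = numeric(0))
  for (i in rs) for (j in rs) {
    if (abs(i - j) < 2) next
    H <- atom_xyz(model, i, "H"); N <- atom_xyz(model, i, "N")
    O <- atom_xyz(model, j, "O"); C <- atom_xyz(model, j, "C")
    if (is.null(H) || is.null(O)) next
    f <- function(a, b) sqrt(sum((a - b)^2))
    e <- 0.084 * 332 * (1 / f(O, N) + 1 / f(C, H) - 1 / f(O, H) -
                          1 / f(C, N))
    if (min(f(O, N), f(C, H), f(O, H), f(C, N)) < 0.5) e <- -9.9
    if (e < -0.5) out <- rbind(out, data.frame(don_res = i, acc_res = j,
                                               energy = e))
  }
  out
}

# exhaustive K-centers oracle: same greedy rule, written directly on a
# precomputed distance matrix
kcenters_oracle <- function(dmat, radius) {
  n <- nrow(dmat)
  centers <- 1L
  dmin <- dmat[, 1]
  while (max(dmin) > radius) {
    cand <- which.max(dmin)
    centers <- c(centers, cand)
    dmin <- pmin(dmin, dmat[, cand])
  }
  assign <- apply(dmat[, centers, drop = FALSE], 1, which.min)
  list(centers = centers, assign = as.integer(assign))
}

frag_dist_matrix <- function(frags) {
  n <- length(frags)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      d[i, j] <- d[j, i] <- superpose_kabsch(frags[[i]]$coords %||%
                                               ca16(frags[[i]]),
                                             frags[[j]]$coords %||%
                                               ca16(frags[[j]]))$rmsd
    }
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ca16 <- function(m) {
  do.call(rbind, lapply(1:4, function(r) {
    do.call(rbind, lapply(c("N", "CA", "C", "O"), function(at)
      atom_xyz(m, r, at)))
  }))
}

# helix-loop-helix fixture with a known, excisable loop: two ideal helices
# joined by a loop built from given torsions. Returns the connected model
# plus the anchors and the loop's torsion table.
hlh_fixture <- function(loop_tor, h1 = 12, h2 = 12) {
  m1 <- make_ideal_helix(h1)
  seg <- buttress:::loop_segment_model(m1, h1, loop_tor)
  # downstream helix: grown from the virtual anchor frame implied by the
  # loop, by building a fresh helix and superposing its first residue
  ch <- buttress:::chain_from_anchor(atom_xyz(m1, h1, "N"),
                                     atom_xyz(m1, h1, "CA"),
                                     atom_xyz(m1, h1, "C"),
                                     loop_tor, phi_end = -57)
  m2 <- make_ideal_helix(h2)
  tr <- superpose_kabsch(
    rbind(atom_xyz(m2, 1, "N"), atom_xyz(m2, 1, "CA"), atom_xyz(m2, 1, "C")),
    rbind(ch$vN, ch$vCA, ch$vC))$transform
  m2 <- rt_apply(tr, m2)
  m2$residues$region <- "helix2"
  out <- buttress:::concat_models(
    list(m1, seg, m2), regions = c("helix1", "loop_long", "helix2"),
    units = c(1L, 1L, 1L), break_after_segment = c(FALSE, FALSE, FALSE))
  list(model = out, anchor_start = h1, anchor_end = h1 + n_residues(seg) + 1L,
       loop_resnos = (h1 + 1):(h1 + n_residues(seg)), torsions = loop_tor)
}

random_loop_torsions <- function(n_insert) {
  rr <- buttress:::rama_sample(n_insert + 1L)
  data.frame(phi = rr$phi, psi = rr$psi, omega = 180)
}

# constructive bidentate plant: a strand host carrying an Asn whose amide
# group is met by a partner tripeptide placed by inverse geometry so the
# partner's backbone N-H donates to OD1 while its carbonyl accepts from
# HD22 (the amide hydrogen cis to OD1, whose N-H vector runs parallel to
# the C=O axis, matching a sheet-edge backbone). `da` sets the planted
# donor-acceptor distances.
plant_bidentate_fixture <- function(da = c(2.9, 2.9), tilt = 0) {
  host <- build_chain(data.frame(phi = c(-120, -120, -120, -120, -120),
                                 psi = c(135, 135, 135, 135, 135),
                                 omega = 180))
  host <- build_sidechain(host, 3, "N", c(-65, -20))
  host$residues$repeat_unit <- 2L
  host$residues$region <- "loop_long"
  OD1 <- atom_xyz(host, 3, "OD1"); CG <- atom_xyz(host, 3, "CG")
  ND2 <- atom_xyz(host, 3, "ND2"); HD22 <- atom_xyz(host, 3, "HD22")
  u1 <- (OD1 - CG) / sqrt(sum((OD1 - CG)^2))
  if (tilt != 0) {  # rotate approach direction off the ideal line
    ax <- (ND2 - OD1) / sqrt(sum((ND2 - OD1)^2))
    th <- tilt * pi / 180
    u1 <- u1 * cos(th) + buttress:::vcross(ax, u1) * sin(th) +
      ax * sum(ax * u1) * (1 - cos(th))
  }
  tN <- OD1 + da[1] * u1
  tH <- OD1 + (da[1] - 1.01) * u1
  u2 <- (HD22 - ND2) / sqrt(sum((HD22 - ND2)^2))
  tO <- ND2 + da[2] * u2
  # choose the partner's phi2/psi2 so its internal N/H/O triangle matches
  target <- rbind(tN, tH, tO)
  try_part <- function(phi2, psi2) {
    part <- build_chain(data.frame(phi = c(-120, phi2),
                                   psi = c(135, psi2), omega = 180))
    part <- place_amide_hydrogens(part)
    pts <- rbind(atom_xyz(part, 2, "N"), atom_xyz(part, 2, "H"),
                 atom_xyz(part, 2, "O"))
    fit <- superpose_kabsch(pts, target)
    list(rmsd = fit$rmsd, part = rt_apply(fit$transform, part),
         phi2 = phi2, psi2 = psi2)
  }
  best <- NULL
  for (phi2 in seq(-180, 170, by = 10)) for (psi2 in seq(-180, 170, by = 10)) {
    cand <- try_part(phi2, psi2)
    if (is.null(best) || cand$rmsd < best$rmsd) best <- cand
  }
  for (phi2 in best$phi2 + seq(-8, 8, by = 2)) {
    for (psi2 in best$psi2 + seq(-8, 8, by = 2)) {
      cand <- try_part(phi2, psi2)
      if (cand$rmsd < best$rmsd) best <- cand
    }
  }
  partner <- best$part
  partner$residues$repeat_unit <- 3L
  partner$residues$region <- "helix1"
  out <- buttress:::concat_models(
    list(host, partner), regions = c(NA, NA), units = c(NA, NA),
    break_after_segment = c(TRUE, TRUE))
  out <- place_amide_hydrogens(out)
  list(model = out, asn = 3L, fit_rmsd = best$rmsd)
}
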