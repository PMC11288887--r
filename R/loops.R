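## Long-loop assembly, kinematic closure, propagation, filters and scores.
##
## A candidate loop is assembled as helix-capping motif torsions followed by
## free residues sampled from a Ramachandran density, with a beta-turn motif
## overwriting four slots at a randomly chosen position; closure then solves
## the six pivot torsions (phi/psi of the first, middle and last inserted
## residues) so the chain meets the downstream helix anchor.

## ---- packaged Ramachandran density ----------------------------------------

# 10x10-degree binned general-case phi/psi density, built as a mixture of
# the four major basins (alpha-R, beta, PPII, alpha-L)
rama_table <- local({
  centers <- seq(-175, 175, by = 10)
  grid <- expand.grid(phi = centers, psi = centers)
  g2 <- function(phi0, psi0, s) {
    exp(-((grid$phi - phi0)^2 + (grid$psi - psi0)^2) / (2 * s^2))
  }
  p <- 0.35 * g2(-63, -43, 12) + 0.30 * g2(-120, 130, 25) +
       0.20 * g2(-70, 150, 15) + 0.15 * g2(60, 45, 12)
  grid$p <- p / sum(p)
  grid
})

# draw n phi/psi pairs from the packaged density (uses the R RNG)
rama_sample <- function(n) {
  idx <- sample.int(nrow(rama_table), n, replace = TRUE,
                    prob = rama_table$p)
  data.frame(phi = rama_table$phi[idx] + stats::runif(n, -5, 5),
             psi = rama_table$psi[idx] + stats::runif(n, -5, 5))
}

## ---- loop assembly ---------------------------------------------------------

#' Assemble an extended loop torsion list from motifs and free residues
#'
#' Returns `4 + 4 + n_kic` torsion triplets: the four helix-capping motif
#' residues first (the cap window starts at the helix C-terminal residue,
#' so triplet 1 maps onto the upstream anchor and 3 + 4 + n_kic residues
#' are actually inserted), then `n_kic` free residues whose phi/psi are
#' drawn from the packaged Ramachandran density, with the four beta-turn
#' motif torsions overwriting the window starting at `turn_position`
#' (sampled uniformly over legal slots when NULL). All omega angles are
#' fixed at 180 degrees; motif torsions that are undefined at the motif's
#' own termini fall back to the sampled values.
#'
#' @param cap a helix-cap `motif`.
#' @param turn a beta-turn `motif`.
#' @param n_kic number of free residues, 5..10.
#' @param turn_position 1-based row at which the turn starts (>= 5), or
#'   NULL to sample it.
#' @return data.frame `phi`, `psi`, `omega` with attributes `turn_position`
#'   and `n_insert`.
#' @export
assemble_extended_loop <- function(cap, turn, n_kic, turn_position = NULL) {
  if (n_kic < 5 || n_kic > 10) stop("n_kic must be within 5..10")
  M <- 8L + as.integer(n_kic)
  free <- rama_sample(M)
  tor <- data.frame(phi = free$phi, psi = free$psi, omega = 180)
  put <- function(tor, motif, at) {
    for (r in 1:4) {
      for (col in c("phi", "psi", "omega")) {
        v <- motif$torsions[[col]][r]
        if (!is.na(v)) tor[[col]][at + r - 1] <- v
      }
    }
    tor$omega <- ifelse(is.na(tor$omega), 180, tor$omega)
    tor
  }
  tor <- put(tor, cap, 1L)
  if (is.null(turn_position)) {
    slots <- 5:(M - 3)
    turn_position <- if (length(slots) == 1) slots else sample(slots, 1)
  }
  if (turn_position < 5 || turn_position > M - 3) {
    stop("turn_position out of legal range")
  }
  tor <- put(tor, turn, as.integer(turn_position))
  tor$omega <- 180  # fixed trans peptide bonds throughout
  attr(tor, "turn_position") <- as.integer(turn_position)
  attr(tor, "n_insert") <- M - 1L
  tor
}

## ---- closure ---------------------------------------------------------------

# build the inserted chain plus the virtual downstream anchor (N, CA, C)
# from torsions; row 1 of `tor` belongs to the upstream anchor residue
chain_from_anchor <- function(aN, aCA, aC, tor, phi_end = -57) {
  g <- IDEAL_GEOM
  M <- nrow(tor)
  n_ins <- M - 1L
  out <- vector("list", n_ins)
  prevN <- aN; prevCA <- aCA; prevC <- aC
  for (i in seq_len(n_ins)) {
    N <- nerf_place(prevN, prevCA, prevC, g$b_C_N, g$a_CA_C_N, tor$psi[i])
    CA <- nerf_place(prevCA, prevC, N, g$b_N_CA, g$a_C_N_CA, tor$omega[i])
    C <- nerf_place(prevC, N, CA, g$b_CA_C, g$a_N_CA_C, tor$phi[i + 1])
    out[[i]] <- list(N = N, CA = CA, C = C)
    prevN <- N; prevCA <- CA; prevC <- C
  }
  vN <- nerf_place(prevN, prevCA, prevC, g$b_C_N, g$a_CA_C_N, tor$psi[M])
  vCA <- nerf_place(prevCA, prevC, vN, g$b_N_CA, g$a_C_N_CA, 180)
  vC <- nerf_place(prevC, vN, vCA, g$b_CA_C, g$a_N_CA_C, phi_end)
  # carbonyl oxygens (anti to the next amide nitrogen)
  for (i in seq_len(n_ins)) {
    nxtN <- if (i < n_ins) out[[i + 1]]$N else vN
    out[[i]]$O <- nerf_place(nxtN, out[[i]]$CA, out[[i]]$C,
                             g$b_C_O, g$a_CA_C_O, 180)
  }
  list(residues = out, vN = vN, vCA = vCA, vC = vC)
}

closure_objective <- function(ch, tN, tCA, tC) {
  sum((ch$vN - tN)^2) + sum((ch$vCA - tCA)^2) + sum((ch$vC - tC)^2)
}

# cyclic coordinate descent over the six pivot torsions. Coordinates are
# updated in place (a rotation about the pivot bond moves only the
# downstream block), so each sweep is a handful of small matrix products.
ccd_close <- function(aN, aCA, aC, tor, tN, tCA, tC, pivots,
                      phi_end = -57, max_sweeps = 250, tol = 1e-9) {
  M <- nrow(tor)
  n_ins <- M - 1L
  targets <- rbind(tN, tCA, tC)
  ch <- chain_from_anchor(aN, aCA, aC, tor, phi_end)
  # flat coordinate matrix: N,CA,C per inserted residue, then vN,vCA,vC
  X <- matrix(0, 3 * n_ins + 3, 3)
  for (i in seq_len(n_ins)) {
    X[3 * i - 2, ] <- ch$residues[[i]]$N
    X[3 * i - 1, ] <- ch$residues[[i]]$CA
    X[3 * i, ] <- ch$residues[[i]]$C
  }
  X[3 * n_ins + 1, ] <- ch$vN
  X[3 * n_ins + 2, ] <- ch$vCA
  X[3 * n_ins + 3, ] <- ch$vC
  vrows <- 3 * n_ins + (1:3)
  pivot_dofs <- do.call(rbind, lapply(pivots, function(p) {
    rbind(c(p, 1), c(p, 2))   # 1 = phi, 2 = psi (rows of tor; p in 2..M)
  }))
  axis_rot <- function(u, theta) {
    ct <- cos(theta); st <- sin(theta)
    ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                 byrow = TRUE)
    ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
  }
  obj <- sum((X[vrows, ] - targets)^2)
  for (sweep in seq_len(max_sweeps)) {
    for (d in seq_len(nrow(pivot_dofs))) {
      p <- pivot_dofs[d, 1]; kind <- pivot_dofs[d, 2]
      r <- p - 1L                     # inserted residue index
      if (kind == 1) {                # phi: axis N(r)->CA(r), moves C(r)..
        P <- X[3 * r - 2, ]; Q <- X[3 * r - 1, ]; first <- 3 * r
      } else {                        # psi: axis CA(r)->C(r), moves N(r+1)..
        P <- X[3 * r - 1, ]; Q <- X[3 * r, ]; first <- 3 * r + 1
      }
      u <- vunit(Q - P)
      a <- 0; b <- 0
      for (i in 1:3) {
        mproj <- X[vrows[i], ] - P
        mrad <- mproj - sum(mproj * u) * u
        fproj <- targets[i, ] - P
        frad <- fproj - sum(fproj * u) * u
        a <- a + sum(mrad * frad)
        b <- b + sum(vcross(u, mrad) * frad)
      }
      if (a == 0 && b == 0) next
      theta <- atan2(b, a)
      R <- axis_rot(u, theta)
      rows <- first:nrow(X)
      X[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2, P) %*% t(R),
                         2, P, "+")
      dtheta <- rad2deg(theta)
      if (kind == 1) tor$phi[p] <- tor$phi[p] - dtheta
      else tor$psi[p] <- tor$psi[p] - dtheta
    }
    newobj <- sum((X[vrows, ] - targets)^2)
    converged <- newobj < 1e-4 || obj - newobj < tol
    obj <- newobj
    if (converged) break
  }
  tor$phi <- ((tor$phi + 180) %% 360) - 180
  tor$psi <- ((tor$psi + 180) %% 360) - 180
  ch <- chain_from_anchor(aN, aCA, aC, tor, phi_end)
  list(torsions = tor, chain = ch, objective = closure_objective(ch, tN, tCA, tC))
}

#' Kinematically close a loop between fixed helix anchors
#'
#' Solves the six pivot torsions (phi/psi of the first, middle and last
#' inserted residues) by cyclic coordinate descent so the chain built from
#' `torsions` (row 1 = upstream anchor residue) reaches the downstream
#' anchor. The input pivot values seed the first attempt; `n_restarts`
#' further attempts resample the pivots from the Ramachandran density. A
#' solution is accepted when the seam C-N bond is within `gap_tol` of
#' 1.329 A and both seam bond angles are within `angle_tol` degrees of
#' ideal; non-pivot torsions are never touched.
#'
#' @param model a `backbone_model` with a declared break after
#'   `anchor_start`.
#' @param anchor_start resno of the upstream anchor (helix C-terminus).
#' @param anchor_end resno of the downstream anchor (next helix
#'   N-terminus).
#' @param torsions assembled loop torsions ([assemble_extended_loop()]).
#' @param n_restarts random pivot restarts after the seeded attempt.
#' @param gap_tol,angle_tol acceptance tolerances (0.08 A, 2 degrees).
#' @return list of accepted solutions, each with `torsions`, `closure_gap`
#'   (A), `angle_err` (degrees) and `objective`; empty list when closure
#'   fails.
#' @export
close_loop <- function(model, anchor_start, anchor_end, torsions,
                       n_restarts = 10, gap_tol = 0.08, angle_tol = 2) {
  g <- IDEAL_GEOM
  aN <- atom_xyz(model, anchor_start, "N")
  aCA <- atom_xyz(model, anchor_start, "CA")
  aC <- atom_xyz(model, anchor_start, "C")
  tN <- atom_xyz(model, anchor_end, "N")
  tCA <- atom_xyz(model, anchor_end, "CA")
  tC <- atom_xyz(model, anchor_end, "C")
  M <- nrow(torsions)
  n_ins <- M - 1L
  # geometric impossibility: the fully extended chain cannot span the gap
  if (vnorm(tN - aC) > 3.6 * (n_ins + 1)) return(list())
  phi_end <- -57
  pivots <- c(2L, as.integer(floor((2 + M) / 2)), M)
  sols <- list()
  for (trial in 0:n_restarts) {
    tor <- torsions
    if (trial > 0) {
      rp <- rama_sample(length(pivots))
      tor$phi[pivots] <- rp$phi
      tor$psi[pivots] <- rp$psi
    }
    fit <- ccd_close(aN, aCA, aC, tor, tN, tCA, tC, pivots, phi_end)
    ch <- fit$chain
    lastC <- ch$residues[[n_ins]]$C
    lastCA <- ch$residues[[n_ins]]$CA
    dCN <- vnorm(tN - lastC)
    gap <- abs(dCN - g$b_C_N)
    aerr <- max(abs(angle_deg(lastCA, lastC, tN) - g$a_CA_C_N),
                abs(angle_deg(lastC, tN, tCA) - g$a_C_N_CA))
    if (gap < gap_tol && aerr < angle_tol) {
      sols[[length(sols) + 1L]] <- list(torsions = fit$torsions,
                                        closure_gap = gap,
                                        angle_err = aerr,
                                        objective = fit$objective)
    }
  }
  sols
}

## ---- loop insertion and propagation ---------------------------------------

loop_segment_model <- function(model, anchor_start, tor, phi_end = -57) {
  ch <- chain_from_anchor(atom_xyz(model, anchor_start, "N"),
                          atom_xyz(model, anchor_start, "CA"),
                          atom_xyz(model, anchor_start, "C"),
                          tor, phi_end)
  n_ins <- length(ch$residues)
  atoms <- data.frame(resno = rep(seq_len(n_ins), each = 4L),
                      name = rep(BACKBONE_ATOMS, n_ins),
                      stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(ch$residues, function(r) {
    rbind(r$N, r$CA, r$C, r$O)
  }))
  residues <- data.frame(resno = seq_len(n_ins), aa = "A",
                         repeat_unit = NA_integer_, region = NA_character_,
                         incomplete = FALSE, break_after = FALSE,
                         stringsAsFactors = FALSE)
  new_backbone_model(residues, atoms, xyz)
}

subset_model <- function(model, resnos) {
  keepr <- model$residues$resno %in% resnos
  keepa <- model$atoms$resno %in% resnos
  res <- model$residues[keepr, , drop = FALSE]
  atoms <- model$atoms[keepa, , drop = FALSE]
  xyz <- model$xyz[keepa, , drop = FALSE]
  remap <- match(res$resno, sort(unique(res$resno)))
  new_no <- setNames(seq_along(sort(unique(res$resno))),
                     sort(unique(res$resno)))
  res$resno <- as.integer(new_no[as.character(res$resno)])
  atoms$resno <- as.integer(new_no[as.character(atoms$resno)])
  rownames(res) <- rownames(atoms) <- NULL
  new_backbone_model(res, atoms, xyz, n_repeats = model$n_repeats,
                     repeat_len = model$repeat_len,
                     provenance = model$provenance)
}

# insert a closed-loop segment (mini model) after anchor_start, renumbering
insert_segment <- function(model, anchor_start, segment, region,
                           unit = NA_integer_, new_psi_anchor = NULL) {
  model <- drop_atoms_everywhere(model, "H")
  before <- subset_model(model, model$residues$resno[
    model$residues$resno <= anchor_start])
  after <- subset_model(model, model$residues$resno[
    model$residues$resno > anchor_start])
  # the anchor's psi changed: re-place its carbonyl O anti to the new N
  segN1 <- segment$xyz[1, ]
  bi <- nrow(before$residues)
  before$residues$break_after[bi] <- FALSE
  before <- set_atom_xyz(before, bi, "O",
                         nerf_place(segN1, atom_xyz(before, bi, "CA"),
                                    atom_xyz(before, bi, "C"),
                                    IDEAL_GEOM$b_C_O, IDEAL_GEOM$a_CA_C_O,
                                    180))
  out <- concat_models(list(before, segment, after),
                       regions = c(NA, region, NA),
                       units = c(NA, unit, NA),
                       break_after_segment = c(FALSE, FALSE, NA),
                       provenance = model$provenance)
  out$n_repeats <- model$n_repeats
  out$repeat_len <- model$repeat_len
  for (a in c("inter_transform", "repeat_spec")) {
    attr(out, a) <- attr(model, a)
  }
  out
}

drop_atoms_everywhere <- function(model, name) {
  keep <- model$atoms$name != name
  model$atoms <- model$atoms[keep, , drop = FALSE]
  model$xyz <- model$xyz[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Propagate a closed long loop to every repeat-unit gap
#'
#' The loop closed on the gap between units 1 and 2 is copied into the gap
#' between units k and k+1 by `rt_power(T, k-1)`, where T is the scaffold's
#' inter-unit transform, then inserted into the chain. Loops are inserted
#' from the last gap backward so anchor numbering stays valid. A clash in
#' any unit rejects the candidate with a reason naming that unit.
#'
#' @param model connected scaffold (short loops in place, long-loop gaps
#'   declared as breaks).
#' @param tor closed-loop torsions (a `close_loop()` solution's
#'   `torsions`).
#' @return list with `model` (complete chain) and `ok`/`reason`; on clash,
#'   `model` is NULL.
#' @export
propagate_loop <- function(model, tor, clash_factor = 0.6) {
  Tin <- attr(model, "inter_transform")
  n <- model$n_repeats
  seg1 <- loop_segment_model(model, max(unit_resnos(model, 1, "helix2")),
                             tor)
  # fast prescreen: reject candidates whose propagated copies overlap the
  # scaffold or each other before paying for chain insertion (anchor
  # residues exempt; survivors get the full bonded-aware check below)
  anchors <- unlist(lapply(seq_len(n - 1), function(k) {
    c(max(unit_resnos(model, k, "helix2")),
      min(unit_resnos(model, k + 1, "helix1")))
  }))
  sidx <- !startsWith(model$atoms$name, "H") &
    !(model$atoms$resno %in% anchors)
  S <- model$xyz[sidx, , drop = FALSE]
  s_rad <- VDW_RADII[atom_element(model$atoms$name[sidx])]
  l_rad <- VDW_RADII[atom_element(seg1$atoms$name)]
  copies <- lapply(seq_len(n - 1), function(k)
    rt_apply(rt_power(Tin, k - 1), seg1$xyz))
  pd2 <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  for (k in seq_len(n - 1)) {
    lim <- outer(l_rad, s_rad, "+") * clash_factor
    if (any(pd2(copies[[k]], S) < lim^2)) {
      return(list(model = NULL, ok = FALSE,
                  reason = sprintf(
                    "propagated loop clashes in unit %d", k)))
    }
    if (k < n - 1) {
      for (j in (k + 1):(n - 1)) {
        limll <- outer(l_rad, l_rad, "+") * clash_factor
        if (any(pd2(copies[[k]], copies[[j]]) < limll^2)) {
          return(list(model = NULL, ok = FALSE,
                      reason = sprintf(
                        "propagated loop clashes in unit %d", j)))
        }
      }
    }
  }
  gaps <- lapply(seq_len(n - 1), function(k) {
    anchor <- max(unit_resnos(model, k, "helix2"))
    seg <- seg1
    seg$xyz <- copies[[k]]
    list(anchor = anchor, seg = seg, unit = k)
  })
  out <- model
  for (gk in rev(seq_along(gaps))) {
    g <- gaps[[gk]]
    out <- insert_segment(out, g$anchor, g$seg, region = "loop_long",
                          unit = g$unit)
  }
  # per-unit clash screen on the inserted loops
  for (k in seq_len(n - 1)) {
    lres <- out$residues$resno[out$residues$region %in% "loop_long" &
                                 out$residues$repeat_unit == k]
    if (clash_check(out, lres)) {
      return(list(model = NULL, ok = FALSE,
                  reason = sprintf("propagated loop clashes in unit %d", k)))
    }
  }
  list(model = out, ok = TRUE, reason = "")
}

## ---- loop filters and scores ----------------------------------------------

max_run <- function(x) {
  if (length(x) == 0) return(0L)
  r <- rle(x)
  m <- r$lengths[r$values]
  if (length(m) == 0) 0L else max(m)
}

#' Direction score of a propagated loop
#'
#' Angle (degrees) between vector a, from the center of mass of the two
#' terminal loop residues to the farthest loop Calpha, and vector b, from
#' the same origin to the center of mass of the loop's host repeat unit.
#' Loops passing the published band protrude sideways over the scaffold:
#' acceptance is 45 to 135 degrees.
#'
#' @param model a `backbone_model` with propagated loops.
#' @param unit host unit of the loop.
#' @param reference mass center used for vector b: the loop's own repeat
#'   unit (default) or the whole protein.
#' @return angle in degrees within [0, 180].
#' @export
direction_score <- function(model, unit,
                            reference = c("unit", "protein")) {
  reference <- match.arg(reference)
  lres <- sort(model$residues$resno[model$residues$region %in% "loop_long" &
                                      model$residues$repeat_unit == unit])
  if (length(lres) < 3) stop("no long loop on unit ", unit)
  term <- c(min(lres), max(lres))
  bb_xyz <- function(resnos) {
    idx <- model$atoms$resno %in% resnos &
      model$atoms$name %in% BACKBONE_ATOMS
    model$xyz[idx, , drop = FALSE]
  }
  origin <- colMeans(bb_xyz(term))
  cas <- ca_matrix(model, lres)
  dists <- sqrt(rowSums(sweep(cas, 2, origin)^2))
  a <- cas[which.max(dists), ] - origin
  ures <- if (reference == "unit") unit_resnos(model, unit) else
    model$residues$resno
  b <- colMeans(bb_xyz(ures)) - origin
  if (vnorm(a) < 1e-9 || vnorm(b) < 1e-9) {
    stop("degenerate loop geometry: zero-length direction vector")
  }
  rad2deg(acos(max(-1, min(1, sum(vunit(a) * vunit(b))))))
}

# packaged log-odds table for loop-helix hydrophobic contact geometry:
# CB-CB distance bins (A); favorable packing bins are negative. A compact
# substitute for a mined residue-pair statistics table, same sign
# convention and selection rule (negative total = favorable).
MOTIF_SCORE_TABLE <- data.frame(
  lo = c(0.0, 4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5),
  hi = c(4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0),
  score = c(1.00, -0.20, -0.60, -0.80, -0.70, -0.40, -0.10, 0.10, 0.20)
)

#' Hydrophobic-contact motif score of the long loops
#'
#' Enumerates loop-helix residue pairs with CB-CB distance at most 8 A and
#' sums a packaged log-odds score over the pairs' distance bins (favorable
#' packing distances are negative). By the published selection rule, only
#' models with a negative total are kept; an empty pair set scores 0 and is
#' rejected.
#'
#' @param model a `backbone_model` with propagated loops.
#' @param table score table (bins `lo`, `hi`, `score`).
#' @return list with `score`, `n_pairs`, `pass`.
#' @export
motif_pair_score <- function(model, table = MOTIF_SCORE_TABLE) {
  model <- add_cb(model)
  rs <- model$residues
  lres <- rs$resno[rs$region %in% "loop_long"]
  hres <- rs$resno[rs$region %in% c("helix1", "helix2")]
  if (length(lres) == 0 || length(hres) == 0) {
    return(list(score = 0, n_pairs = 0L, pass = FALSE))
  }
  cbL <- do.call(rbind, lapply(lres, function(i) atom_xyz(model, i, "CB")))
  cbH <- do.call(rbind, lapply(hres, function(i) atom_xyz(model, i, "CB")))
  total <- 0; npairs <- 0L
  for (i in seq_len(nrow(cbL))) {
    d <- sqrt(rowSums(sweep(cbH, 2, cbL[i, ])^2))
    for (dd in d[d <= 8]) {
      bin <- which(table$lo <= dd & dd < table$hi)
      if (length(bin) == 1) {
        total <- total + table$score[bin]
        npairs <- npairs + 1L
      }
    }
  }
  list(score = total, n_pairs = npairs, pass = total < 0)
}

#' Apply all loop-level filters to a propagated model
#'
#' Computes, per long loop: intraloop backbone-backbone hydrogen bonds
#' (pass >= 2), interloop bonds to each neighboring loop (pass >= 1 per
#' neighbor pair), the longest run of helical residues inside the loop
#' (pass <= 5), the proximity count (loop residues with any helix Calpha
#' within 8 A; pass >= 5) and the direction score (pass 45-135 degrees);
#' plus the model-wide hydrophobic motif score (pass < 0) and a clash flag.
#'
#' @param model a complete `backbone_model` with propagated long loops.
#' @param config threshold list, see [pipeline_config()].
#' @return list with `per_loop` (data.frame), `interloop` (data.frame per
#'   neighbor pair), `motif_score`, `clash` and `pass`.
#' @export
filter_loops <- function(model, config = pipeline_config()) {
  hb <- detect_hbonds(model, "bb_bb")
  ss <- assign_ss(model, hbonds = hb)
  rs <- model$residues
  units <- sort(unique(rs$repeat_unit[rs$region %in% "loop_long"]))
  loop_res <- lapply(units, function(k) {
    sort(rs$resno[rs$region %in% "loop_long" & rs$repeat_unit == k])
  })
  names(loop_res) <- as.character(units)
  in_loop <- function(b, lr) b$don_res %in% lr & b$acc_res %in% lr
  per <- do.call(rbind, lapply(seq_along(units), function(j) {
    lr <- loop_res[[j]]
    intr <- sum(in_loop(hb, lr))
    helix_run <- max_run(ss[match(lr, rs$resno)] == "H")
    hres <- rs$resno[rs$region %in% c("helix1", "helix2")]
    hca <- ca_matrix(model, hres)
    prox <- sum(vapply(lr, function(i) {
      ca <- atom_xyz(model, i, "CA")
      min(sqrt(rowSums(sweep(hca, 2, ca)^2))) <= config$proximity_radius
    }, logical(1)))
    dirs <- direction_score(model, units[j])
    data.frame(unit = units[j], n_res = length(lr), intraloop = intr,
               helix_run = helix_run, proximity = prox,
               direction = dirs)
  }))
  per$pass_intraloop <- per$intraloop >= config$min_intraloop_hbonds
  per$pass_helix_run <- per$helix_run <= config$max_consecutive_helix
  per$pass_proximity <- per$proximity >= config$min_proximity_residues
  per$pass_direction <- per$direction >= config$direction_min &
    per$direction <= config$direction_max
  inter <- if (length(units) >= 2) {
    do.call(rbind, lapply(seq_len(length(units) - 1), function(j) {
      a <- loop_res[[j]]; b <- loop_res[[j + 1]]
      nb <- sum((hb$don_res %in% a & hb$acc_res %in% b) |
                  (hb$don_res %in% b & hb$acc_res %in% a))
      data.frame(unit_a = units[j], unit_b = units[j + 1], n_hbonds = nb,
                 pass = nb >= config$min_interloop_hbonds)
    }))
  } else {
    data.frame(unit_a = integer(0), unit_b = integer(0),
               n_hbonds = integer(0), pass = logical(0))
  }
  ms <- motif_pair_score(model)
  clash <- clash_check(model, unlist(loop_res), factor = config$clash_factor)
  list(per_loop = per, interloop = inter, motif_score = ms$score,
       motif_pass = ms$pass, clash = clash,
       pass = all(per$pass_intraloop) && all(per$pass_helix_run) &&
         all(per$pass_proximity) && all(per$pass_direction) &&
         all(inter$pass) && ms$pass && !clash)
}
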