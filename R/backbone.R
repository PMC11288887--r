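## Backbone model container
##
## A backbone_model holds an ordered residue table plus a flat atom table
## indexing into an n_atoms x 3 coordinate matrix, so rigid transforms act on
## one matrix multiply. Residue regions follow the repeat architecture:
## helix1 / loop_short / helix2 / loop_long / cap.

# Engh-Huber ideal backbone geometry (Angstrom / degrees)
IDEAL_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8
)

# Bondi van der Waals radii for clash checking (heavy atoms)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_backbone_model <- function(residues, atoms, xyz,
                               n_repeats = NA_integer_,
                               repeat_len = NA_integer_,
                               provenance = "") {
  structure(list(residues = residues, atoms = atoms, xyz = xyz,
                 n_repeats = n_repeats, repeat_len = repeat_len,
                 provenance = provenance),
            class = "backbone_model")
}

#' Number of residues in a backbone model
#' @param model a `backbone_model`.
#' @export
n_residues <- function(model) nrow(model$residues)

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("backbone_model: %d residues, %d atoms", n_residues(x),
              nrow(x$atoms)))
  if (!is.na(x$n_repeats)) cat(sprintf(", %d repeat units", x$n_repeats))
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

atom_row <- function(model, resno, name) {
  which(model$atoms$resno == resno & model$atoms$name == name)[1]
}

#' Coordinates of one atom
#' @param model a `backbone_model`.
#' @param resno 1-based residue index.
#' @param name atom name, e.g. "CA".
#' @return numeric 3-vector, or NULL when the atom is absent.
#' @export
atom_xyz <- function(model, resno, name) {
  i <- atom_row(model, resno, name)
  if (is.na(i)) return(NULL)
  model$xyz[i, ]
}

set_atom_xyz <- function(model, resno, name, xyz) {
  i <- atom_row(model, resno, name)
  if (is.na(i)) {
    model$atoms <- rbind(model$atoms,
                         data.frame(resno = resno, name = name,
                                    stringsAsFactors = FALSE))
    model$xyz <- rbind(model$xyz, matrix(xyz, 1, 3))
  } else {
    model$xyz[i, ] <- xyz
  }
  model
}

drop_atoms <- function(model, resno, names) {
  keep <- !(model$atoms$resno == resno & model$atoms$name %in% names)
  model$atoms <- model$atoms[keep, , drop = FALSE]
  model$xyz <- model$xyz[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' Calpha coordinate matrix of a model (or a subset of residues)
#' @param model a `backbone_model`.
#' @param resnos residue indices (default all).
#' @export
ca_matrix <- function(model, resnos = model$residues$resno) {
  idx <- which(model$atoms$name == "CA" & model$atoms$resno %in% resnos)
  ord <- order(model$atoms$resno[idx])
  model$xyz[idx[ord], , drop = FALSE]
}

residue_break_after <- function(model, resno) {
  isTRUE(model$residues$break_after[match(resno, model$residues$resno)])
}

## ---- construction from torsions ------------------------------------------

#' Build a chain from backbone torsion angles with ideal covalent geometry
#'
#' Sequentially places N, CA, C, O for each residue using Engh-Huber bond
#' lengths and angles; only the torsions vary. Carbonyl oxygens are placed
#' anti to the following amide nitrogen.
#'
#' @param torsions data.frame with columns `phi`, `psi`, `omega` (degrees),
#'   one row per residue. `phi[1]` and `psi[n]`/`omega[n]` only affect
#'   terminal-atom placement.
#' @param aa one-letter amino-acid codes (default poly-alanine... "A").
#' @param provenance free-text build record.
#' @return a `backbone_model`.
#' @export
build_chain <- function(torsions, aa = NULL, provenance = "build_chain") {
  n <- nrow(torsions)
  stopifnot(n >= 1)
  if (is.null(aa)) aa <- rep("A", n)
  g <- IDEAL_GEOM
  coords <- vector("list", n)
  # first residue in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_N_CA, 0, 0)
  a <- deg2rad(g$a_N_CA_C)
  C1 <- CA1 + g$b_CA_C * c(-cos(a), sin(a), 0)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1)) {
    prev <- coords[[i]]
    Ni <- nerf_place(prev$N, prev$CA, prev$C, g$b_C_N, g$a_CA_C_N,
                     torsions$psi[i])
    CAi <- nerf_place(prev$CA, prev$C, Ni, g$b_N_CA, g$a_C_N_CA,
                      torsions$omega[i])
    Ci <- nerf_place(prev$C, Ni, CAi, g$b_CA_C, g$a_N_CA_C,
                     torsions$phi[i + 1])
    coords[[i + 1]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl oxygens
  for (i in seq_len(n)) {
    cc <- coords[[i]]
    if (i < n) {
      coords[[i]]$O <- nerf_place(coords[[i + 1]]$N, cc$CA, cc$C,
                                  g$b_C_O, g$a_CA_C_O, 180)
    } else {
      coords[[i]]$O <- nerf_place(cc$N, cc$CA, cc$C, g$b_C_O, g$a_CA_C_O,
                                  torsions$psi[n] + 180)
    }
  }
  atoms <- data.frame(
    resno = rep(seq_len(n), each = 4L),
    name = rep(BACKBONE_ATOMS, n),
    stringsAsFactors = FALSE
  )
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C, coords[[i]]$O)
  }))
  residues <- data.frame(
    resno = seq_len(n), aa = aa,
    repeat_unit = NA_integer_, region = NA_character_,
    incomplete = FALSE, break_after = FALSE,
    stringsAsFactors = FALSE
  )
  new_backbone_model(residues, atoms, xyz, provenance = provenance)
}

#' Backbone torsion angles of a model
#'
#' @param model a `backbone_model`.
#' @param resnos residue indices (default all).
#' @return data.frame with `resno`, `phi`, `psi`, `omega` in degrees; NA at
#'   chain termini and declared chain breaks.
#' @export
backbone_torsions <- function(model, resnos = model$residues$resno) {
  out <- data.frame(resno = resnos, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  all_res <- model$residues$resno
  for (k in seq_along(resnos)) {
    i <- resnos[k]
    N <- atom_xyz(model, i, "N"); CA <- atom_xyz(model, i, "CA")
    C <- atom_xyz(model, i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if ((i - 1) %in% all_res && !residue_break_after(model, i - 1)) {
      Cp <- atom_xyz(model, i - 1, "C")
      if (!is.null(Cp)) out$phi[k] <- dihedral_deg(Cp, N, CA, C)
    }
    if ((i + 1) %in% all_res && !residue_break_after(model, i)) {
      Nn <- atom_xyz(model, i + 1, "N")
      CAn <- atom_xyz(model, i + 1, "CA")
      if (!is.null(Nn)) out$psi[k] <- dihedral_deg(N, CA, C, Nn)
      if (!is.null(Nn) && !is.null(CAn)) {
        out$omega[k] <- dihedral_deg(CA, C, Nn, CAn)
      }
    }
  }
  out
}

#' Rebuild idealized coordinates from torsions
#'
#' Inverse of [backbone_torsions()] under ideal covalent geometry: a chain
#' rebuilt from its own torsions reproduces idealized input coordinates to
#' within ~0.1 Angstrom Calpha RMSD (after superposition, since the build
#' frame is canonical).
#'
#' @param torsions data.frame with `phi`, `psi`, `omega` (degrees); NAs are
#'   replaced by ideal extended/trans values, which only affects termini.
#' @param aa optional one-letter codes.
#' @export
rebuild_from_torsions <- function(torsions, aa = NULL) {
  torsions$phi[is.na(torsions$phi)] <- -120
  torsions$psi[is.na(torsions$psi)] <- 120
  torsions$omega[is.na(torsions$omega)] <- 180
  build_chain(torsions, aa = aa, provenance = "rebuild_from_torsions")
}

## ---- ideal helix -----------------------------------------------------------

helix_canonical_transform <- function() {
  # canonicalizing transform computed from a reference 15-residue ideal
  # helix built in the raw chain frame; identical for every helix length
  # because the chain is built sequentially from residue 1
  tor <- data.frame(phi = rep(-57, 15), psi = rep(-47, 15),
                    omega = rep(180, 15))
  ref <- build_chain(tor)
  cas <- ca_matrix(ref)
  # one-residue screw transform; its rotation axis is the exact helix axis
  st <- superpose_kabsch(cas[1:14, ], cas[2:15, ])
  R1 <- st$transform$R
  t1 <- st$transform$t
  e <- eigen(R1)
  k <- which.min(abs(e$values - 1))
  u <- Re(e$vectors[, k])
  u <- u / vnorm(u)
  if (sum(t1 * u) < 0) u <- -u        # +u points N -> C (positive rise)
  # point on the screw axis: (I - R) p = t - (t.u) u, constrained p.u = 0
  A <- rbind(diag(3) - R1, matrix(u, 1, 3))
  b <- c(t1 - sum(t1 * u) * u, 0)
  p <- qr.solve(A, b)
  pc <- u
  ctr <- p
  # rotation taking pc -> z
  z <- c(0, 0, 1)
  v <- vcross(pc, z)
  s <- vnorm(v)
  if (s < 1e-12) {
    R <- diag(3)
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - sum(pc * z)) / s^2)
  }
  # after rotation, put the axis on x = y = 0 and the N-terminal CA at z = 0
  ctr_r <- as.numeric(R %*% ctr)
  ca1_r <- as.numeric(R %*% cas[1, ])
  shift <- c(-ctr_r[1], -ctr_r[2], -ca1_r[3])
  rt_compose(rigid_transform(diag(3), shift), rigid_transform(R, c(0, 0, 0)))
}

#' Build an ideal alpha-helix and place it relative to the z axis
#'
#' The helix is built with phi = -57, psi = -47, omega = 180 degrees and
#' Engh-Huber covalent geometry, oriented with its axis along +z (N terminus
#' at z = 0, axis through the origin), then translated to `radius` along x
#' and finally rotated by `orientation` about z. This fixed placement frame
#' makes sampled rigid-body degrees of freedom reproducible.
#'
#' @param length number of residues (>= 3; repeat sampling uses 12-28).
#' @param radius distance of the helix axis from the z axis, Angstrom.
#' @param orientation rotation about z after radial placement, degrees.
#' @return a `backbone_model` with all residues labeled region "helix1".
#' @export
make_ideal_helix <- function(length, radius = 0, orientation = 0) {
  if (length < 3) stop("helix length must be at least 3")
  tor <- data.frame(phi = rep(-57, length), psi = rep(-47, length),
                    omega = rep(180, length))
  m <- build_chain(tor, provenance = sprintf(
    "make_ideal_helix(length=%d, radius=%g, orientation=%g)",
    length, radius, orientation))
  place <- rt_compose(
    rigid_transform(rot_z(orientation), c(0, 0, 0)),
    rt_compose(rigid_transform(diag(3), c(radius, 0, 0)),
               helix_canonical_transform()))
  m <- rt_apply(place, m)
  m$residues$region <- "helix1"
  m
}

## ---- virtual / real CB -----------------------------------------------------

#' Idealized Cbeta position from backbone N, CA, C
#' @keywords internal
cb_position <- function(N, CA, C) {
  b <- CA - N
  cc <- C - CA
  a <- vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + CA
}

#' Add (virtual) Cbeta atoms to every residue lacking one
#' @param model a `backbone_model`.
#' @export
add_cb <- function(model) {
  for (i in model$residues$resno) {
    if (!is.na(atom_row(model, i, "CB"))) next
    N <- atom_xyz(model, i, "N"); CA <- atom_xyz(model, i, "CA")
    C <- atom_xyz(model, i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    model <- set_atom_xyz(model, i, "CB", cb_position(N, CA, C))
  }
  model
}

## ---- clash checking --------------------------------------------------------

atom_element <- function(name) {
  el <- substr(gsub("^[0-9]", "", name), 1, 1)
  ifelse(el %in% names(VDW_RADII), el, "C")
}

#' Backbone steric clash check
#'
#' TRUE (clash) when any non-bonded heavy-atom pair lies closer than
#' `factor` times the sum of its Bondi van der Waals radii. Pairs within a
#' residue, and pairs fewer than three covalent bonds apart across a peptide
#' bond, are exempt.
#'
#' @param model a `backbone_model`.
#' @param resnos if given, only pairs with at least one atom in these
#'   residues are examined (used when screening a candidate loop).
#' @param factor clash factor on the vdW-radius sum; default 0.6.
#' @return logical.
#' @export
clash_check <- function(model, resnos = NULL, factor = 0.6) {
  at <- model$atoms
  heavy <- !startsWith(at$name, "H")
  idx <- which(heavy)
  res <- at$resno[idx]
  nm <- at$name[idx]
  rad <- VDW_RADII[atom_element(nm)]
  xyz <- model$xyz[idx, , drop = FALSE]
  sel <- if (is.null(resnos)) seq_along(idx) else which(res %in% resnos)
  if (length(sel) == 0) return(FALSE)
  maxcut <- factor * 2 * max(VDW_RADII)
  for (k in sel) {
    d2 <- rowSums(sweep(xyz, 2, xyz[k, ])^2)
    near <- which(d2 < maxcut^2)
    for (j in near) {
      if (j == k) next
      if (!is.null(resnos) && j %in% sel && j < k) next  # avoid double work
      ri <- res[k]; rj <- res[j]
      if (ri == rj) next
      if (abs(ri - rj) == 1) {
        lo <- min(ri, rj); hi <- max(ri, rj)
        if (!residue_break_after(model, lo)) {
          a_lo <- if (ri < rj) nm[k] else nm[j]
          a_hi <- if (ri < rj) nm[j] else nm[k]
          # pairs < 3 bonds apart across the peptide bond C(lo)-N(hi)
          excl <- (a_lo == "C" && a_hi %in% c("N", "CA", "H")) ||
                  (a_lo %in% c("CA", "O") && a_hi == "N")
          if (excl) next
        }
      }
      if (sqrt(d2[j]) < factor * (rad[k] + rad[j])) return(TRUE)
    }
  }
  FALSE
}
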