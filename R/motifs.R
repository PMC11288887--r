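## Beta-turn and helix-capping motif mining, K-centers clustering, and
## YAML serialization of motif libraries.

MOTIF_SCHEMA_VERSION <- 1L

motif_frame_points <- function() {
  g <- IDEAL_GEOM
  a <- deg2rad(g$a_N_CA_C)
  rbind(c(0, 0, 0),
        c(g$b_N_CA, 0, 0),
        c(g$b_N_CA, 0, 0) + g$b_CA_C * c(-cos(a), sin(a), 0))
}

#' @keywords internal
new_motif <- function(kind, torsions, coords, source = "",
                      cluster_id = NA_integer_) {
  structure(list(kind = kind, torsions = torsions, coords = coords,
                 source = source, cluster_id = cluster_id),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif (%s) from %s\n", x$kind, x$source))
  print(round(x$torsions, 1))
  invisible(x)
}

# canonical coords: residue-1 N/CA/C superposed onto the fixed build frame
canonicalize_window <- function(model, i) {
  names16 <- BACKBONE_ATOMS
  coords <- do.call(rbind, lapply(i:(i + 3), function(r) {
    do.call(rbind, lapply(names16, function(a) atom_xyz(model, r, a)))
  }))
  ref3 <- coords[1:3, ]                       # N, CA, C of residue 1
  tr <- superpose_kabsch(ref3, motif_frame_points())$transform
  rt_apply(tr, coords)
}

window_motif <- function(model, i, kind, source) {
  tor <- backbone_torsions(model, i:(i + 3))
  new_motif(kind, tor[, c("phi", "psi", "omega")],
            canonicalize_window(model, i), source = source)
}

window_ok <- function(model, i) {
  rs <- model$residues
  idx <- match(i:(i + 3), rs$resno)
  if (anyNA(idx)) return(FALSE)
  if (any(rs$incomplete[idx])) return(FALSE)
  if (any(rs$break_after[idx[1:3]])) return(FALSE)
  TRUE
}

#' Mine beta-turn motifs from coordinate models
#'
#' Scans every four-residue window of each model and keeps those where the
#' carbonyl of the first residue hydrogen-bonds to the amide of the fourth
#' ([detect_beta_turn()]). Kept windows are converted to motifs with
#' torsions plus coordinates canonicalized on a fixed residue-1 frame.
#'
#' @param models a `backbone_model` or list of them.
#' @return list of `motif` objects (possibly empty).
#' @export
mine_beta_turns <- function(models) {
  if (inherits(models, "backbone_model")) models <- list(models)
  out <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    hb <- detect_hbonds(m, "bb_bb")
    for (i in m$residues$resno) {
      if (!window_ok(m, i)) next
      if (detect_beta_turn(m, i, hbonds = hb)) {
        out[[length(out) + 1L]] <- window_motif(
          m, i, "beta_turn", sprintf("model%d:res%d", mi, i))
      }
    }
  }
  out
}

#' Mine helix-capping motifs
#'
#' Finds helix C-termini (last helical residue h by [assign_ss()]) and
#' takes the window h..h+3 when it contains at least one backbone-backbone
#' hydrogen bond between a post-helix window residue and the helix's last
#' turn (h-3..h). This operationalizes capping as "the loop's first residues
#' satisfy the helix terminal backbone polar groups".
#'
#' @param models a `backbone_model` or list of them.
#' @return list of `motif` objects.
#' @export
mine_helix_caps <- function(models) {
  if (inherits(models, "backbone_model")) models <- list(models)
  out <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    hb <- detect_hbonds(m, "bb_bb")
    ss <- assign_ss(m, hbonds = hb)
    rs <- m$residues$resno
    for (k in seq_along(rs)) {
      h <- rs[k]
      if (ss[k] != "H") next
      kn <- match(h + 1, rs)
      if (!is.na(kn) && ss[kn] == "H") next     # not a C-terminus
      if (!window_ok(m, h)) next
      post <- (h + 1):(h + 3)
      turn <- (h - 3):h
      cap_bond <- any((hb$don_res %in% post & hb$acc_res %in% turn) |
                        (hb$acc_res %in% post & hb$don_res %in% turn))
      if (cap_bond) {
        out[[length(out) + 1L]] <- window_motif(
          m, h, "helix_cap", sprintf("model%d:res%d", mi, h))
      }
    }
  }
  out
}

motif_coords <- function(x) {
  if (inherits(x, "motif")) x$coords else canonicalize_window(x, 1)
}

fragment_rmsd <- function(a, b) {
  superpose_kabsch(motif_coords(a), motif_coords(b))$rmsd
}

#' K-centers clustering of four-residue fragments
#'
#' Greedy farthest-point clustering under the 16-backbone-atom RMSD (after
#' optimal superposition). The first fragment seeds cluster 1; the fragment
#' farthest from all existing centers is promoted repeatedly until every
#' fragment lies within `radius` of a center; ties break toward the lowest
#' index, so the result is deterministic for a fixed input order. Every
#' member is then assigned to its nearest center, giving the covering
#' guarantee max_i d(i, center(i)) <= radius.
#'
#' @param fragments list of `motif` objects (or 4-residue models).
#' @param radius maximum cluster distance, Angstrom (mining used 0.63).
#' @return object of class `motif_library`: representatives with cluster
#'   ids, per-cluster counts, assignments, and the radius.
#' @export
kcenters_cluster <- function(fragments, radius) {
  if (radius <= 0) stop("radius must be positive")
  n <- length(fragments)
  if (n == 0) stop("need at least one fragment")
  coords <- lapply(fragments, motif_coords)
  dist_to <- function(i, j) superpose_kabsch(coords[[i]], coords[[j]])$rmsd
  centers <- 1L
  dmin <- vapply(seq_len(n), function(i) dist_to(i, 1L), numeric(1))
  while (max(dmin) > radius) {
    cand <- which.max(dmin)          # which.max takes the lowest index on ties
    centers <- c(centers, cand)
    for (i in seq_len(n)) dmin[i] <- min(dmin[i], dist_to(i, cand))
  }
  assign <- vapply(seq_len(n), function(i) {
    d <- vapply(centers, function(c) dist_to(i, c), numeric(1))
    which.min(d)
  }, integer(1))
  reps <- lapply(seq_along(centers), function(k) {
    mo <- fragments[[centers[k]]]
    if (!inherits(mo, "motif")) mo <- window_motif(mo, 1, "beta_turn", "frag")
    mo$cluster_id <- k
    mo
  })
  kind <- if (inherits(fragments[[1]], "motif")) fragments[[1]]$kind else
    "beta_turn"
  structure(list(kind = kind, motifs = reps, cluster_radius = radius,
                 counts = as.integer(table(factor(assign,
                                                  seq_along(centers)))),
                 assignments = assign),
            class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("motif_library (%s): %d clusters, radius %.2f A, %d members\n",
              x$kind, length(x$motifs), x$cluster_radius,
              sum(x$counts)))
  invisible(x)
}

#' Save a motif library as YAML
#' @param library a `motif_library`.
#' @param path output path.
#' @export
save_library <- function(library, path) {
  obj <- list(
    schema_version = MOTIF_SCHEMA_VERSION,
    kind = library$kind,
    cluster_radius = library$cluster_radius,
    counts = as.list(library$counts),
    motifs = lapply(library$motifs, function(m) list(
      cluster_id = m$cluster_id,
      source = m$source,
      torsions = lapply(seq_len(4), function(i)
        round(as.numeric(m$torsions[i, ]), 4)),
      coords = lapply(seq_len(nrow(m$coords)), function(i)
        round(as.numeric(m$coords[i, ]), 4))
    ))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a motif library from YAML
#' @param path YAML path written by [save_library()].
#' @export
load_library <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) ||
      obj$schema_version != MOTIF_SCHEMA_VERSION) {
    stop("motif library schema version mismatch")
  }
  if (length(obj$motifs) == 0) stop("motif library contains no motifs")
  motifs <- lapply(obj$motifs, function(m) {
    tor <- as.data.frame(do.call(rbind, m$torsions))
    names(tor) <- c("phi", "psi", "omega")
    new_motif(obj$kind, tor, do.call(rbind, m$coords),
              source = m$source, cluster_id = m$cluster_id)
  })
  structure(list(kind = obj$kind, motifs = motifs,
                 cluster_radius = obj$cluster_radius,
                 counts = as.integer(unlist(obj$counts)),
                 assignments = NULL),
            class = "motif_library")
}

#' Packaged default motif libraries
#'
#' Small libraries mined in code from the synthetic fixture set (canonical
#' turn types I/I'/II/II' for beta turns; the Schellman-like capped-helix
#' fixture for helix caps), so the pipeline runs with no external data.
#' Users with a culled PDB set can mine a real library via
#' [mine_beta_turns()] / [mine_helix_caps()] and [kcenters_cluster()].
#'
#' @param kind "beta_turn" or "helix_cap".
#' @return a `motif_library`.
#' @export
default_motif_library <- function(kind = c("beta_turn", "helix_cap")) {
  kind <- match.arg(kind)
  if (kind == "beta_turn") {
    frags <- mine_beta_turns(unname(make_fixture("turn_gallery")))
    kcenters_cluster(frags, radius = 0.63)
  } else {
    mods <- list(make_fixture("capped_helix", length = 10),
                 make_fixture("capped_helix", length = 14))
    frags <- mine_helix_caps(mods)
    if (length(frags) == 0) stop("no helix-cap motifs mined from fixtures")
    lib <- kcenters_cluster(frags, radius = 0.63)
    lib$kind <- "helix_cap"
    for (i in seq_along(lib$motifs)) lib$motifs[[i]]$kind <- "helix_cap"
    lib
  }
}
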