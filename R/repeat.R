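## Parametric repeat-protein backbone generation and scaffold-level filters.

#' Specification of a two-helix repeat protein
#'
#' @param h1_length,h2_length helix lengths in residues (12-28 for repeat
#'   sampling).
#' @param radius,orientation placement of H1 relative to the z axis
#'   (see [make_ideal_helix()]).
#' @param intra_unit [six_dof()] transform taking the placed H1 onto H2.
#' @param inter_unit [six_dof()] transform taking repeat unit k onto k+1.
#' @param n_repeats number of repeat units (>= 2).
#' @return a `repeat_spec` list.
#' @export
repeat_spec <- function(h1_length = 14, h2_length = 14, radius = 0,
                        orientation = 0, intra_unit = six_dof(),
                        inter_unit = six_dof(), n_repeats = 4) {
  if (n_repeats < 2) stop("n_repeats must be at least 2")
  for (L in c(h1_length, h2_length)) {
    if (L < 12 || L > 28) stop("helix lengths must be within 12-28 residues")
  }
  structure(list(h1_length = h1_length, h2_length = h2_length,
                 radius = radius, orientation = orientation,
                 intra_unit = intra_unit, inter_unit = inter_unit,
                 n_repeats = n_repeats),
            class = "repeat_spec")
}

# concatenate models into one chain; each segment keeps its coordinates.
# NA in regions/units keeps the segment's own per-residue labels.
concat_models <- function(segments, regions, units, break_after_segment,
                          provenance = "") {
  stopifnot(length(segments) == length(regions),
            length(segments) == length(units))
  residues <- list(); atoms <- list(); xyz <- list()
  offset <- 0L
  for (s in seq_along(segments)) {
    m <- segments[[s]]
    nres <- n_residues(m)
    r <- m$residues
    r$resno <- r$resno + offset
    if (!is.na(regions[s])) r$region <- regions[s]
    if (!is.na(units[s])) r$repeat_unit <- units[s]
    if (!is.na(break_after_segment[s])) {
      r$break_after[nres] <- break_after_segment[s]
    }
    a <- m$atoms
    a$resno <- a$resno + offset
    residues[[s]] <- r; atoms[[s]] <- a; xyz[[s]] <- m$xyz
    offset <- offset + nres
  }
  new_backbone_model(do.call(rbind, residues), do.call(rbind, atoms),
                     do.call(rbind, xyz), provenance = provenance)
}

#' Build a disconnected parametric repeat backbone
#'
#' Places ideal helix H1 as given, derives H2 by applying the intra-unit
#' transform to an identically placed helix of H2's length, and propagates
#' the resulting unit R1 by integer powers of the inter-unit transform:
#' unit k equals `rt_power(T, k-1)` applied to R1 exactly. Chain breaks are
#' declared between all helices; repeat_unit and region labels are set.
#'
#' @param spec a [repeat_spec()].
#' @return a `backbone_model` with an attribute `inter_transform`.
#' @export
build_repeat_backbone <- function(spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  h1 <- make_ideal_helix(spec$h1_length, spec$radius, spec$orientation)
  h2 <- rt_apply(dof_to_transform(spec$intra_unit),
                 make_ideal_helix(spec$h2_length, spec$radius,
                                  spec$orientation))
  Tin <- dof_to_transform(spec$inter_unit)
  segments <- list(); regions <- character(0); units <- integer(0)
  for (k in seq_len(spec$n_repeats)) {
    Tk <- rt_power(Tin, k - 1)
    segments <- c(segments, list(rt_apply(Tk, h1), rt_apply(Tk, h2)))
    regions <- c(regions, "helix1", "helix2")
    units <- c(units, k, k)
  }
  m <- concat_models(segments, regions, units,
                     rep(TRUE, length(segments)),
                     provenance = sprintf(
                       "build_repeat_backbone(n_repeats=%d, h1=%d, h2=%d)",
                       spec$n_repeats, spec$h1_length, spec$h2_length))
  m$n_repeats <- spec$n_repeats
  m$repeat_len <- spec$h1_length + spec$h2_length
  attr(m, "inter_transform") <- Tin
  attr(m, "repeat_spec") <- spec
  # clashes between units are flagged, not silently dropped
  attr(m, "unit_clash") <- clash_check(m)
  m
}

#' Connect the two helices of each repeat unit with a short loop
#'
#' Closes the H1 -> H2 gap of unit 1 with a loop of 3-6 residues (torsions
#' drawn from the packaged Ramachandran density, pivots solved by the
#' closure engine), keeps the first length that closes without steric
#' clash, and propagates the identical loop to every unit by the inter-unit
#' transform so repeat exactness is preserved.
#'
#' @param model output of [build_repeat_backbone()].
#' @param lengths candidate loop lengths, tried in order; default 3:6.
#' @param n_attempts sampling attempts per length.
#' @param clash_factor clash threshold factor.
#' @return list with `model` (connected, or NULL), `ok`, `loop_len`.
#' @export
connect_short_loops <- function(model, lengths = 3:6, n_attempts = 20,
                                clash_factor = 0.6) {
  Tin <- attr(model, "inter_transform")
  n <- model$n_repeats
  anchor1 <- max(unit_resnos(model, 1, "helix1"))
  end1 <- min(unit_resnos(model, 1, "helix2"))
  for (len in lengths) {
    for (att in seq_len(n_attempts)) {
      rr <- rama_sample(len + 1L)
      tor <- data.frame(phi = rr$phi, psi = rr$psi, omega = 180)
      sols <- close_loop(model, anchor1, end1, tor, n_restarts = 3)
      for (sol in sols) {
        seg1 <- loop_segment_model(model, anchor1, sol$torsions)
        out <- model
        for (k in rev(seq_len(n))) {
          anchor <- max(unit_resnos(out, k, "helix1"))
          seg <- seg1
          seg$xyz <- rt_apply(rt_power(Tin, k - 1), seg1$xyz)
          out <- insert_segment(out, anchor, seg, region = "loop_short",
                                unit = k)
        }
        sres <- out$residues$resno[out$residues$region %in% "loop_short"]
        if (!clash_check(out, sres, factor = clash_factor)) {
          return(list(model = out, ok = TRUE, loop_len = len))
        }
      }
    }
  }
  list(model = NULL, ok = FALSE, loop_len = NA_integer_)
}

unit_resnos <- function(model, k, region = NULL) {
  r <- model$residues
  sel <- !is.na(r$repeat_unit) & r$repeat_unit == k
  if (!is.null(region)) sel <- sel & r$region %in% region
  r$resno[sel]
}

#' Termini distance filter for long-loop installation
#'
#' For each unit pair (k, k+1): distance between the C atom of the last
#' residue of helix 2 of unit k and the N atom of the first residue of
#' helix 1 of unit k+1 (the gap the buttressed long loop must bridge). The
#' pair passes iff the distance is at most `cutoff`.
#'
#' @param model a repeat `backbone_model`.
#' @param cutoff Angstrom; default 18.
#' @return data.frame with `unit`, `distance`, `pass` per bridged gap.
#' @export
termini_distance_filter <- function(model, cutoff = 18) {
  n <- model$n_repeats
  out <- data.frame(unit = seq_len(n - 1), distance = NA_real_,
                    pass = FALSE)
  for (k in seq_len(n - 1)) {
    h2 <- unit_resnos(model, k, "helix2")
    h1n <- unit_resnos(model, k + 1, "helix1")
    C <- atom_xyz(model, max(h2), "C")
    N <- atom_xyz(model, min(h1n), "N")
    out$distance[k] <- vnorm(N - C)
    out$pass[k] <- out$distance[k] <= cutoff
  }
  out
}

#' Burial layer assignment by cone-and-distance neighbor counting
#'
#' For each residue, neighbors are the other residues whose Cbeta (virtual
#' for glycine / backbone-only models) lies within `radius` of this
#' residue's Cbeta and within a cone of half-angle `cone_half_angle` about
#' the CA->CB vector (apex at CA). Residues with at least `core_count`
#' neighbors are core, at least `boundary_count` boundary, otherwise
#' surface. The count is monotone: adding a residue inside the cone can
#' only raise a residue's layer.
#'
#' @param model a `backbone_model`.
#' @param radius neighbor distance cutoff, Angstrom.
#' @param cone_half_angle degrees about the CA->CB axis.
#' @param core_count,boundary_count neighbor-count thresholds.
#' @return data.frame with `resno`, `neighbors`, `layer`.
#' @export
assign_layers <- function(model, radius = 10, cone_half_angle = 100,
                          core_count = 18, boundary_count = 12) {
  model <- add_cb(model)
  rs <- model$residues$resno
  cb <- do.call(rbind, lapply(rs, function(i) atom_xyz(model, i, "CB")))
  ca <- ca_matrix(model)
  n <- length(rs)
  counts <- integer(n)
  cosmax <- cos(deg2rad(cone_half_angle))
  for (i in seq_len(n)) {
    v <- cb[i, ] - ca[i, ]
    nv <- vnorm(v)
    if (nv < 1e-9) next
    v <- v / nv
    d <- sqrt(rowSums(sweep(cb, 2, cb[i, ])^2))
    w <- sweep(cb, 2, ca[i, ])
    wn <- sqrt(rowSums(w^2))
    cosang <- (w %*% v) / pmax(wn, 1e-9)
    counts[i] <- sum(d <= radius & cosang >= cosmax) - 1L  # exclude self
  }
  layer <- ifelse(counts >= core_count, "core",
                  ifelse(counts >= boundary_count, "boundary", "surface"))
  data.frame(resno = rs, neighbors = counts, layer = layer,
             stringsAsFactors = FALSE)
}

#' Buried-core fraction filter
#'
#' Passes iff at least `min_frac` of all residues are assigned to the core
#' layer by [assign_layers()].
#'
#' @param model a `backbone_model`.
#' @param min_frac minimum core fraction; default 0.28.
#' @param ... passed to [assign_layers()].
#' @return list with `fraction`, `pass`.
#' @export
core_fraction_filter <- function(model, min_frac = 0.28, ...) {
  lay <- assign_layers(model, ...)
  frac <- mean(lay$layer == "core")
  list(fraction = frac, pass = frac >= min_frac)
}
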