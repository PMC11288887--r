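## Synthetic structure fixtures.
##
## Deterministic stand-ins for a culled PDB set: every other module is
## testable without downloads. Identical spec + seed gives bit-identical
## coordinates.

# canonical beta-turn torsions for residues i+1 / i+2 (degrees)
TURN_TYPES <- list(
  I      = c(-60, -30, -90,    0),
  Iprime = c( 60,  30,  90,    0),
  II     = c(-60, 120,  80,    0),
  IIprime = c(60, -120, -80,   0),
  VIII   = c(-60, -30, -120, 120)
)

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

turn_fragment_torsions <- function(type) {
  tt <- TURN_TYPES[[type]]
  if (is.null(tt)) stop("unknown turn type: ", type)
  # residue i in an extended conformation, i+3 re-entering the strand
  data.frame(phi = c(-120, tt[1], tt[3], -100),
             psi = c( 140, tt[2], tt[4],  130),
             omega = 180)
}

hairpin_torsions <- function(n_strand = 4, turn_type = "Iprime") {
  tt <- TURN_TYPES[[turn_type]]
  strand <- c(-125, 135)
  data.frame(
    phi = c(rep(strand[1], n_strand), tt[1], tt[3], rep(strand[1], n_strand)),
    psi = c(rep(strand[2], n_strand), tt[2], tt[4], rep(strand[2], n_strand)),
    omega = 180)
}

capped_helix_torsions <- function(helix_len = 10) {
  # Schellman-like C-cap: a left-handed residue after the helix redirects
  # the chain so a loop amide donates back to the helix last turn
  data.frame(
    phi = c(rep(-57, helix_len), 55, -130, -120, -100),
    psi = c(rep(-47, helix_len), 40, 130, 140, 130),
    omega = 180)
}

#' Build a deterministic synthetic structure fixture
#'
#' Kinds:
#' \describe{
#'   \item{ideal_helix}{an ideal alpha-helix of `length` residues.}
#'   \item{beta_hairpin}{a 2:2 beta-hairpin (`length` = strand residues per
#'     side, default 4) with a genuine CO(i)->NH(i+3) turn hydrogen bond.}
#'   \item{turn_gallery}{a list of four 4-residue fragments, one per
#'     canonical turn type I / I' / II / II'.}
#'   \item{two_cluster_fragments}{`n` 4-residue fragments (default 12)
#'     forming two well-separated conformational clusters (intra-cluster
#'     backbone RMSD < 0.3 A, inter-cluster ~ 2 A) for clustering tests.}
#'   \item{capped_helix}{a helix followed by a Schellman-like capping loop,
#'     used to exercise helix-cap motif mining.}
#' }
#'
#' @param kind fixture kind, see Details.
#' @param length residue count where applicable.
#' @param n number of fragments for `two_cluster_fragments`.
#' @param seed RNG seed; same spec + seed is bit-identical.
#' @return a `backbone_model`, or a list of them for gallery/fragment kinds.
#' @export
make_fixture <- function(kind, length = 12, n = 12, seed = 1) {
  switch(kind,
    ideal_helix = make_ideal_helix(length),
    beta_hairpin = {
      m <- build_chain(hairpin_torsions(n_strand = max(2, length %/% 3)),
                       provenance = "fixture beta_hairpin")
      m
    },
    turn_gallery = {
      types <- c("I", "Iprime", "II", "IIprime")
      out <- lapply(types, function(ty) {
        build_chain(turn_fragment_torsions(ty),
                    provenance = paste0("fixture turn_", ty))
      })
      names(out) <- types
      out
    },
    two_cluster_fragments = with_seed(seed, {
      base <- list(
        turn_fragment_torsions("I"),
        data.frame(phi = c(-120, -130, -115, -125),
                   psi = c(140, 130, 135, 140), omega = 180))  # extended
      lapply(seq_len(n), function(i) {
        b <- base[[(i %% 2) + 1]]
        b$phi <- b$phi + stats::runif(4, -2, 2)
        b$psi <- b$psi + stats::runif(4, -2, 2)
        build_chain(b, provenance = sprintf("fixture cluster_frag %d", i))
      })
    }),
    capped_helix = {
      m <- build_chain(capped_helix_torsions(max(6, length)),
                       provenance = "fixture capped_helix")
      hl <- max(6, length)
      m$residues$region <- c(rep("helix1", hl),
                             rep("loop_long", n_residues(m) - hl))
      m
    },
    stop("unknown fixture kind: ", kind)
  )
}
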