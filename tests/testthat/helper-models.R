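# Session-cached demo models built in code (no stored fixtures): a
# connected scaffold and a model with propagated long loops. Heavy to
# build, so they are constructed once per test run on first use.

.model_cache <- new.env(parent = emptyenv())

get_connected_scaffold <- function() {
  if (!is.null(.model_cache$connected)) return(.model_cache$connected)
  set.seed(310)
  m0 <- build_repeat_backbone(do.call(repeat_spec, demo_repeat_spec()))
  sl <- connect_short_loops(m0)
  stopifnot(sl$ok)
  .model_cache$connected <- sl$model
  sl$model
}

# first propagation-viable long-loop candidate (not necessarily passing
# every loop filter); also records any clash-rejection reasons seen
get_loop_model <- function() {
  if (!is.null(.model_cache$loop)) return(.model_cache$loop)
  m <- get_connected_scaffold()
  set.seed(311)
  turn_lib <- default_motif_library("beta_turn")
  cap_lib <- default_motif_library("helix_cap")
  anchor <- max(buttress:::unit_resnos(m, 1, "helix2"))
  endres <- min(buttress:::unit_resnos(m, 2, "helix1"))
  rejections <- character(0)
  for (att in 1:200) {
    cap <- cap_lib$motifs[[sample.int(length(cap_lib$motifs), 1)]]
    turn <- turn_lib$motifs[[sample.int(length(turn_lib$motifs), 1)]]
    tor <- assemble_extended_loop(cap, turn, sample(5:6, 1))
    for (sol in close_loop(m, anchor, endres, tor, n_restarts = 4)) {
      pr <- propagate_loop(m, sol$torsions)
      if (pr$ok) {
        out <- list(model = pr$model, torsions = sol$torsions,
                    scaffold = m, rejections = rejections)
        .model_cache$loop <- out
        return(out)
      }
      rejections <- c(rejections, pr$reason)
    }
  }
  stop("no propagation-viable loop found in 200 attempts")
}
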