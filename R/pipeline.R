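## End-to-end orchestration: scaffold -> short loops -> buttressed long
## loops -> sidechain buttressing -> reports. One global RNG seeded from
## the config; per-stage child seeds derive from it so stages can be rerun
## in isolation and a full run is bit-reproducible.

#' Pipeline configuration with published default thresholds
#'
#' All filter thresholds default to the published values: termini distance
#' 18 A; core fraction 0.28; >= 2 intraloop and >= 1 interloop
#' backbone-backbone hydrogen bonds; <= 5 consecutive helical residues in
#' a loop; direction score within 45-135 degrees; >= 5 loop residues
#' within 8 A of helix Calphas; pseudo hydrogen bond < 3 A and > 120
#' degrees; harmonic rescue constraint 2.0 +/- 0.5 A; <= 3 buried
#' unsatisfied polar atoms; per-loop mean backbone hydrogen-bond energy
#' <= -1 kcal/mol. Rosetta-internal score filters without published
#' formulas (packstat, hole score, total score per residue) are carried as
#' stub report columns only.
#'
#' @param specs list of [repeat_spec()] argument lists to enumerate.
#' @param seed integer RNG seed.
#' @param n_loop_attempts long-loop sampling attempts per scaffold.
#' @param n_kic_range range free loop residues are drawn from (within
#'   5..10).
#' @param ... any threshold override (must name an existing field).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(specs = list(demo_repeat_spec()), seed = 1,
                            n_loop_attempts = 120,
                            n_kic_range = c(5, 6), ...) {
  cfg <- list(
    specs = specs, seed = as.integer(seed),
    n_loop_attempts = n_loop_attempts, n_kic_range = n_kic_range,
    termini_cutoff = 18, min_core_fraction = 0.28,
    min_intraloop_hbonds = 2, min_interloop_hbonds = 1,
    max_consecutive_helix = 5,
    direction_min = 45, direction_max = 135,
    min_proximity_residues = 5, proximity_radius = 8,
    pseudo_d_max = 3.0, pseudo_angle_min = 120,
    harmonic_target = 2.0, harmonic_sigma = 0.5,
    max_buried_unsat = 3, unsat_core_count = 22,
    loop_hbond_energy_max = -1,
    clash_factor = 0.6, sc_clash_factor = 0.55,
    closure_gap_tol = 0.08, closure_angle_tol = 2,
    n_closure_restarts = 6,
    # Rosetta-internal filters with undefined formulas: stubs only
    packstat_min = NA_real_, hole_score_max = NA_real_,
    total_score_per_res_max = NA_real_
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Demo repeat-unit geometry
#'
#' A compact, slightly curved two-helix repeat bundle (16-residue helices,
#' antiparallel at 9 A spacing, units offset 8.5 A) chosen so the packaged
#' demo passes the published scaffold filters; used by the demo pipeline
#' and examples.
#' @return argument list for [repeat_spec()].
#' @export
demo_repeat_spec <- function() {
  list(h1_length = 16, h2_length = 16, radius = 0, orientation = 0,
       intra_unit = six_dof(tx = 8.8, tz = 23.5, rx = 180),
       inter_unit = six_dof(ty = 8.3, rz = 2),
       n_repeats = 4)
}

config_hash <- function(config) {
  digest::digest(unclass(config), algo = "sha256")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Per-residue backbone hydrogen-bond energy of the long loops
#'
#' Sum of Kabsch-Sander energies of backbone bonds involving each long-loop
#' residue; reported per loop as the mean over its residues.
#' @param model a `backbone_model` with propagated loops.
#' @return data.frame `unit`, `mean_energy`.
#' @keywords internal
loop_hbond_energy <- function(model) {
  hb <- detect_hbonds(model, "bb_bb")
  rs <- model$residues
  units <- sort(unique(rs$repeat_unit[rs$region %in% "loop_long"]))
  do.call(rbind, lapply(units, function(k) {
    lr <- rs$resno[rs$region %in% "loop_long" & rs$repeat_unit == k]
    e <- vapply(lr, function(i) {
      sum(hb$energy[hb$don_res == i | hb$acc_res == i])
    }, numeric(1))
    data.frame(unit = k, mean_energy = mean(e))
  }))
}

#' Run the full design pipeline
#'
#' Stages: (1) parametric scaffold enumeration with the termini-distance
#' and buried-core filters; (2) short-loop connection; (3) long-loop
#' sampling (cap + turn + free residues, kinematic closure, propagation)
#' with all loop filters and scores; (4) bidentate and hydrophobic
#' sidechain scanning with pseudo-bidentate rescue and placement
#' propagation; (5) report emission. Outputs PDBs, per-stage TSV reports,
#' and a JSON run summary with stage attrition counts, the seed and a
#' config hash. An empty survivor set at any stage terminates cleanly with
#' the attrition recorded.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return the run summary list, invisibly; all artifacts under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 2, 4)
  summary <- list(seed = config$seed, config_hash = config_hash(config),
                  stages = list())
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("config_hash: %s", summary$config_hash),
           sprintf("threshold termini_cutoff: %g A", config$termini_cutoff),
           sprintf("threshold min_core_fraction: %g",
                   config$min_core_fraction),
           sprintf("threshold min_intraloop_hbonds: %g",
                   config$min_intraloop_hbonds),
           sprintf("threshold min_interloop_hbonds: %g",
                   config$min_interloop_hbonds),
           sprintf("threshold max_consecutive_helix: %g",
                   config$max_consecutive_helix),
           sprintf("threshold direction_band: %g-%g deg",
                   config$direction_min, config$direction_max),
           sprintf("threshold min_proximity_residues: %g within %g A",
                   config$min_proximity_residues, config$proximity_radius),
           sprintf("threshold pseudo_hbond: <%g A, >%g deg",
                   config$pseudo_d_max, config$pseudo_angle_min),
           sprintf("threshold harmonic_constraint: %g +/- %g A",
                   config$harmonic_target, config$harmonic_sigma),
           sprintf("threshold max_buried_unsat: %g",
                   config$max_buried_unsat))
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  finish <- function(summary) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(out_dir, "run.log"))
    invisible(summary)
  }

  ## stage 1: scaffolds
  set.seed(stage_seeds[1])
  scaffold_rows <- list(); scaffolds <- list()
  for (si in seq_along(config$specs)) {
    spec <- do.call(repeat_spec, config$specs[[si]])
    m <- build_repeat_backbone(spec)
    td <- termini_distance_filter(m, cutoff = config$termini_cutoff)
    cf <- core_fraction_filter(m, min_frac = config$min_core_fraction)
    pass <- all(td$pass) && cf$pass && !attr(m, "unit_clash")
    scaffold_rows[[si]] <- data.frame(
      spec = si, termini_max = max(td$distance),
      core_fraction = cf$fraction, unit_clash = attr(m, "unit_clash"),
      pass_termini = all(td$pass), pass_core = cf$pass, pass = pass)
    if (pass) scaffolds[[length(scaffolds) + 1L]] <- list(idx = si, model = m)
  }
  scaffold_report <- do.call(rbind, scaffold_rows)
  write_tsv(scaffold_report, file.path(out_dir, "scaffold_report.tsv"))
  summary$stages$scaffold <- list(entered = length(config$specs),
                                  passed = length(scaffolds))
  note("scaffold: %d/%d pass", length(scaffolds), length(config$specs))
  if (length(scaffolds) == 0) return(finish(summary))

  ## stage 2: short loops
  set.seed(stage_seeds[2])
  connected <- list()
  for (sc in scaffolds) {
    sl <- connect_short_loops(sc$model, clash_factor = config$clash_factor)
    if (sl$ok) {
      write_pdb(sl$model, file.path(out_dir,
                                    sprintf("scaffold_%02d.pdb", sc$idx)))
      connected[[length(connected) + 1L]] <-
        list(idx = sc$idx, model = sl$model)
    }
  }
  summary$stages$short_loops <- list(entered = length(scaffolds),
                                     passed = length(connected))
  note("short loops: %d/%d connected", length(connected), length(scaffolds))
  if (length(connected) == 0) return(finish(summary))

  ## stage 3: long loops
  set.seed(stage_seeds[3])
  turn_lib <- default_motif_library("beta_turn")
  cap_lib <- default_motif_library("helix_cap")
  loop_rows <- list(); survivors <- list()
  n_cand <- 0L
  for (sc in connected) {
    m <- sc$model
    anchor <- max(unit_resnos(m, 1, "helix2"))
    endres <- min(unit_resnos(m, 2, "helix1"))
    for (att in seq_len(config$n_loop_attempts)) {
      cap <- cap_lib$motifs[[sample.int(length(cap_lib$motifs), 1)]]
      turn <- turn_lib$motifs[[sample.int(length(turn_lib$motifs), 1)]]
      n_kic <- sample(seq(config$n_kic_range[1], config$n_kic_range[2]), 1)
      tor <- assemble_extended_loop(cap, turn, n_kic)
      sols <- close_loop(m, anchor, endres, tor,
                         n_restarts = config$n_closure_restarts,
                         gap_tol = config$closure_gap_tol,
                         angle_tol = config$closure_angle_tol)
      for (sol in sols) {
        n_cand <- n_cand + 1L
        pr <- propagate_loop(m, sol$torsions,
                             clash_factor = config$clash_factor)
        if (!pr$ok) {
          loop_rows[[length(loop_rows) + 1L]] <- data.frame(
            scaffold = sc$idx, attempt = att, candidate = n_cand,
            closure_gap = sol$closure_gap, n_res = attr(tor, "n_insert"),
            intraloop_min = NA, interloop_min = NA, helix_run_max = NA,
            proximity_min = NA, direction_min = NA, direction_max = NA,
            motif_score = NA, clash = TRUE, pass = FALSE,
            reason = pr$reason)
          next
        }
        fl <- filter_loops(pr$model, config)
        loop_rows[[length(loop_rows) + 1L]] <- data.frame(
          scaffold = sc$idx, attempt = att, candidate = n_cand,
          closure_gap = sol$closure_gap, n_res = attr(tor, "n_insert"),
          intraloop_min = min(fl$per_loop$intraloop),
          interloop_min = if (nrow(fl$interloop)) min(fl$interloop$n_hbonds)
            else NA,
          helix_run_max = max(fl$per_loop$helix_run),
          proximity_min = min(fl$per_loop$proximity),
          direction_min = min(fl$per_loop$direction),
          direction_max = max(fl$per_loop$direction),
          motif_score = fl$motif_score, clash = fl$clash, pass = fl$pass,
          reason = "")
        if (fl$pass) {
          survivors[[length(survivors) + 1L]] <-
            list(scaffold = sc$idx, model = pr$model, report = fl,
                 candidate = n_cand)
        }
      }
    }
  }
  loop_report <- if (length(loop_rows)) do.call(rbind, loop_rows) else
    data.frame()
  write_tsv(loop_report, file.path(out_dir, "loop_report.tsv"))
  summary$stages$loops <- list(entered = length(connected),
                               candidates = n_cand,
                               passed = length(survivors))
  note("long loops: %d candidates, %d pass all filters", n_cand,
       length(survivors))
  if (length(survivors) == 0) return(finish(summary))

  ## stage 4: buttressing sidechains on the best candidate per scaffold
  set.seed(stage_seeds[4])
  final_rows <- list(); finals <- list()
  # carry the best few survivors per scaffold (ranked by motif score) into
  # sidechain design
  ord <- order(vapply(survivors, function(s) s$report$motif_score,
                      numeric(1)))
  survivors <- survivors[ord]
  counts <- table(vapply(survivors, `[[`, numeric(1), "scaffold"))
  keep <- logical(length(survivors)); seen <- list()
  for (i in seq_along(survivors)) {
    key <- as.character(survivors[[i]]$scaffold)
    seen[[key]] <- (seen[[key]] %||% 0L) + 1L
    keep[i] <- seen[[key]] <= 3L
  }
  best_by_scaffold <- survivors[keep]
  for (sv in best_by_scaffold) {
    m <- place_amide_hydrogens(sv$model)
    # the published protocol designs the loop on the second repeat unit
    scan_pos <- sort(m$residues$resno[m$residues$region %in% "loop_long" &
                                        m$residues$repeat_unit == 2])
    sb <- scan_bidentate(m, scan_pos, clash_factor = config$sc_clash_factor)
    accepted <- Filter(function(p) p$accepted, sb$placements)
    rescued <- 0L
    if (length(accepted) == 0) {
      # three-stage rescue path: find pseudo-bidentate near-misses
      for (p in scan_pos) for (aa in c("N", "D", "Q", "H")) {
        hit <- FALSE
        for (chis in rotamer_table(aa)) {
          trial <- build_sidechain(sb$model, p, aa, chis)
          if (clash_check(trial, p, factor = config$sc_clash_factor)) next
          rp <- rescue_pseudo_bidentate(
            trial, placement_record(p, aa, chis, 0L, FALSE),
            target = config$harmonic_target, sigma = config$harmonic_sigma,
            clash_factor = config$sc_clash_factor)
          if (isTRUE(rp$placement$accepted)) {
            sb$model <- rp$model
            accepted <- c(accepted, list(rp$placement))
            rescued <- rescued + 1L
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
    }
    pp <- propagate_placements(sb$model, accepted,
                               clash_factor = config$sc_clash_factor)
    mfinal <- pp$model
    # hydrophobic loop-helix placements on remaining alanine positions
    rest <- setdiff(scan_pos, vapply(pp$kept, `[[`, numeric(1), "resno"))
    hp <- scan_hydrophobic_contacts(mfinal, rest,
                                    clash_factor = config$sc_clash_factor)
    mfinal <- hp$model
    bu <- count_buried_unsatisfied(
      mfinal, layers = assign_layers(mfinal,
                                     core_count = config$unsat_core_count))
    le <- loop_hbond_energy(mfinal)
    pass <- bu <= config$max_buried_unsat &&
      all(le$mean_energy <= config$loop_hbond_energy_max)
    name <- sprintf("final_s%02d_c%03d.pdb", sv$scaffold, sv$candidate)
    write_pdb(drop_atoms_everywhere(mfinal, "H"), file.path(out_dir, name))
    final_rows[[length(final_rows) + 1L]] <- data.frame(
      scaffold = sv$scaffold, candidate = sv$candidate,
      n_bidentate_positions = length(pp$kept), rescued = rescued,
      n_hydrophobic = sum(vapply(hp$placements, function(p)
        isTRUE(p$accepted), logical(1))),
      buried_unsat = bu, loop_energy_mean = mean(le$mean_energy),
      motif_score = sv$report$motif_score,
      packstat = config$packstat_min, hole_score = config$hole_score_max,
      total_score_per_res = config$total_score_per_res_max,
      pass = pass, model_file = name)
    if (pass) finals[[length(finals) + 1L]] <-
      list(scaffold = sv$scaffold, model = mfinal)
  }
  final_report <- do.call(rbind, final_rows)
  write_tsv(final_report, file.path(out_dir, "final_report.tsv"))
  summary$stages$buttress <- list(entered = length(best_by_scaffold),
                                  passed = length(finals))
  summary$final_report <- final_report[, setdiff(names(final_report),
                                                 "model_file")]
  note("buttress: %d/%d final models pass", length(finals),
       length(best_by_scaffold))
  finish(summary)
}
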