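#' Run the screening pipeline end to end on synthetic data
#'
#' Chains the workflow: simulate plates -> write MI traces -> battery
#' averages and lethality calls -> blue/green strobe scores (raw and
#' min-max normalized) -> solvent-null hit calling on raw blue scores ->
#' Tanimoto clustering of the hit compounds' (synthetic) fingerprints with
#' medoid representatives. Every stage reads the files written by the
#' previous one, so each artifact is independently consumable, and the run
#' is fully determined by `seed`.
#'
#' Artifacts written under `out_dir`: `schedule.yaml`, `plate_map.csv`,
#' `mi_traces.csv`, `battery_summary.csv`, `scores.csv`, `hits.csv`,
#' `clusters.csv`, `representatives.csv`, `manifest.json`.
#'
#' @param out_dir output directory (created if needed)
#' @param seed integer seed controlling the whole run
#' @param n_plates plates to simulate (default 2)
#' @param hit_fraction fraction of test compounds with a planted strobe
#'   phenotype
#' @param config optional [sim_config()]; built from `seed`/`n_plates`
#'   when omitted
#' @return (invisibly) named list of artifact paths
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_plates = 2L,
                         hit_fraction = 0.05, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config)) {
    config <- sim_config(n_plates = n_plates, rng_seed = seed)
  }
  paths <- list(
    schedule = file.path(out_dir, "schedule.yaml"),
    plate_map = file.path(out_dir, "plate_map.csv"),
    mi = file.path(out_dir, "mi_traces.csv"),
    battery = file.path(out_dir, "battery_summary.csv"),
    scores = file.path(out_dir, "scores.csv"),
    hits = file.path(out_dir, "hits.csv"),
    clusters = file.path(out_dir, "clusters.csv"),
    representatives = file.path(out_dir, "representatives.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )

  # --- simulate ---------------------------------------------------------
  schedule <- gen_battery_schedule(config, config$assays)
  write_schedule(schedule, paths$schedule)
  plate_ids <- sprintf("P%03d", seq_len(config$n_plates))
  maps <- lapply(plate_ids, function(pid) {
    default_plate_map(config, pid, hit_fraction = hit_fraction)
  })
  plates <- lapply(seq_along(plate_ids), function(i) {
    gen_plate(config, plate_ids[i], maps[[i]], schedule)
  })
  full_map <- do.call(rbind, maps)
  write_plate_map(full_map, paths$plate_map)
  all_traces <- do.call(c, lapply(plates, `[[`, "traces"))
  write_mi_csv(all_traces, paths$mi)

  # --- motion-index summaries (from the MI file, not memory) ------------
  traces <- read_mi_csv(paths$mi, frame_rate_hz = config$frame_rate_hz)
  map <- read_plate_map(paths$plate_map)
  validate_map_traces(map, traces)
  key <- vapply(traces, function(tr) paste(tr$plate, tr$well), "")
  mkey <- paste(map$plate, map$well)
  traces <- traces[match(mkey, key)]
  avg <- vapply(traces, battery_average_mi, numeric(1))
  battery <- data.frame(plate = map$plate, well = map$well,
                        compound_id = map$compound_id, role = map$role,
                        concentration_um = map$concentration_um,
                        battery_avg_mi = unname(avg),
                        lethal = lethality_flag(unname(avg)),
                        stringsAsFactors = FALSE)
  data.table::fwrite(battery, paths$battery)

  # --- strobe scores ----------------------------------------------------
  sched <- read_schedule(paths$schedule)
  plate_obj <- list(traces = traces, map = map, schedule = sched)
  scores <- score_plate(plate_obj)
  scores$normalized_blue <- normalize_scores(scores$blue_score)
  scores$normalized_green <- normalize_scores(scores$green_score)
  data.table::fwrite(scores, paths$scores)

  # --- hit calling (blue channel, raw scores) ---------------------------
  sc <- as.data.frame(data.table::fread(paths$scores))
  solvent <- sc$blue_score[sc$role == "vehicle"]
  test <- sc[sc$role == "test", ]
  hits <- call_hits(stats::setNames(test$blue_score, test$compound_id), solvent)
  data.table::fwrite(hits, paths$hits)

  # --- chemotype clustering of hits -------------------------------------
  hit_ids <- hits$compound_id[hits$is_hit]
  if (length(hit_ids) > 0L) {
    n_cl <- max(1L, ceiling(length(hit_ids) / 3))
    fps <- gen_fingerprints(n_clusters = n_cl,
                            n_per_cluster = ceiling(length(hit_ids) / n_cl),
                            seed = stable_hash(seed, "fingerprints"))
    fps <- fps[seq_along(hit_ids)]
    names(fps) <- sort(hit_ids)
    assign <- cluster_compounds(fps, threshold = 0.45)
    data.table::fwrite(data.frame(compound_id = names(assign$cluster),
                                  cluster = unname(assign$cluster)),
                       paths$clusters)
    reps <- pick_representatives(assign)
    data.table::fwrite(reps, paths$representatives)
  } else {
    data.table::fwrite(data.frame(compound_id = character(0),
                                  cluster = integer(0)), paths$clusters)
    data.table::fwrite(data.frame(cluster = integer(0),
                                  compound_id = character(0),
                                  n_members = integer(0),
                                  mean_similarity = numeric(0)),
                       paths$representatives)
  }

  # --- manifest ---------------------------------------------------------
  cfg_json <- jsonlite::toJSON(list(n_plates = config$n_plates,
                                    wells_per_plate = config$wells_per_plate,
                                    frame_rate_hz = config$frame_rate_hz,
                                    hit_fraction = hit_fraction,
                                    assays = config$assays),
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed,
                   config = jsonlite::fromJSON(cfg_json),
                   config_hash = stable_hash(as.character(cfg_json)),
                   package_version = as.character(utils::packageVersion("strobescreen")),
                   n_wells = nrow(map),
                   n_hits = sum(hits$is_hit))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
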