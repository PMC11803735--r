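#' Readers and writers for the pipeline's file dialects
#'
#' Tabular data travel as CSV, configuration and schedules as YAML, frame
#' stacks as multipage grayscale TIFF with a ROI-grid CSV. All dialects
#' round-trip losslessly through their reader/writer pair.
#'
#' MI long CSV columns: `plate`, `well`, `treatment`, `concentration_um`,
#' `frame_index` (1-based MI sample index), `mi`.
#'
#' @param traces list of [well_trace()]
#' @param path output file
#' @name io
NULL

#' @rdname io
#' @export
write_mi_csv <- function(traces, path) {
  dt <- data.table::rbindlist(lapply(traces, function(tr) {
    data.table::data.table(plate = tr$plate, well = tr$well,
                           treatment = tr$treatment,
                           concentration_um = tr$concentration_um,
                           frame_index = seq_along(tr$mi), mi = tr$mi)
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname io
#' @param frame_rate_hz sampling rate to stamp on the traces read back
#' @export
read_mi_csv <- function(path, frame_rate_hz = 25) {
  dt <- data.table::fread(path)
  req <- c("plate", "well", "treatment", "concentration_um", "frame_index", "mi")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0L) {
    stop("MI CSV ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(dt$mi < 0)
  if (length(bad) > 0L) {
    stop("MI CSV ", path, " row ", bad[1], ": negative mi value ", dt$mi[bad[1]])
  }
  key <- paste(dt$plate, dt$well, sep = "\r")
  split_idx <- split(seq_len(nrow(dt)), key)
  traces <- lapply(split_idx, function(idx) {
    idx <- idx[order(dt$frame_index[idx])]
    well_trace(dt$mi[idx], frame_rate_hz = frame_rate_hz,
               plate = dt$plate[idx[1]], well = dt$well[idx[1]],
               treatment = dt$treatment[idx[1]],
               concentration_um = dt$concentration_um[idx[1]])
  })
  names(traces) <- vapply(traces, function(tr) paste(tr$plate, tr$well), "")
  traces[order(names(traces))]
}

#' @rdname io
#' @param map plate-map data.frame (see [default_plate_map()])
#' @export
write_plate_map <- function(map, path) {
  data.table::fwrite(map, path)
  invisible(path)
}

#' @rdname io
#' @export
read_plate_map <- function(path) {
  map <- as.data.frame(data.table::fread(path))
  req <- c("plate", "well", "role", "phenotype", "compound_id", "concentration_um")
  miss <- setdiff(req, names(map))
  if (length(miss) > 0L) {
    stop("plate map ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  dup <- duplicated(paste(map$plate, map$well))
  if (any(dup)) {
    stop("plate map ", path, ": duplicate well ", map$well[dup][1],
         " on plate ", map$plate[dup][1])
  }
  map
}

#' Check that a plate map and a trace collection describe the same wells
#' @param map plate map
#' @param traces list of [well_trace()]
#' @export
validate_map_traces <- function(map, traces) {
  have <- vapply(traces, function(tr) paste(tr$plate, tr$well), "")
  want <- paste(map$plate, map$well)
  missing_tr <- setdiff(want, have)
  if (length(missing_tr) > 0L) {
    stop("plate map references wells absent from traces: ",
         paste(missing_tr, collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname io
#' @param stack a [frame_stack()]
#' @param tiff_path,roi_path output paths for frames and the ROI grid
#' @param max_intensity intensity scale for the 16-bit TIFF encoding
#' @export
write_frames_tiff <- function(stack, tiff_path, roi_path,
                              max_intensity = 65535L) {
  tiff::writeTIFF(lapply(stack$frames, function(f) f / max_intensity),
                  tiff_path, bits.per.sample = 16L, reduce = FALSE)
  rois <- do.call(rbind, lapply(names(stack$rois), function(nm) {
    r <- stack$rois[[nm]]
    data.frame(well = nm, row_min = r[1], row_max = r[2],
               col_min = r[3], col_max = r[4], stringsAsFactors = FALSE)
  }))
  rois$frame_rate_hz <- stack$frame_rate_hz
  data.table::fwrite(rois, roi_path)
  invisible(tiff_path)
}

#' @rdname io
#' @export
read_frames_tiff <- function(tiff_path, roi_path, max_intensity = 65535L) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(m) round(m * max_intensity))
  rdf <- as.data.frame(data.table::fread(roi_path))
  rois <- lapply(seq_len(nrow(rdf)), function(i) {
    as.integer(c(rdf$row_min[i], rdf$row_max[i], rdf$col_min[i], rdf$col_max[i]))
  })
  names(rois) <- rdf$well
  frame_stack(frames, frame_rate_hz = rdf$frame_rate_hz[1], rois = rois)
}

#' @rdname io
#' @param smiles_path SMILES list, one `SMILES<TAB>id` per line
#' @export
read_smiles <- function(smiles_path) {
  lines <- readLines(smiles_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 1L)
  smiles <- vapply(parts, `[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("cmp", i)
  }, "")
  if (anyDuplicated(ids)) {
    stop("SMILES file ", smiles_path, ": duplicate compound id ",
         ids[duplicated(ids)][1])
  }
  data.frame(compound_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param trace an [ephys_trace()]
#' @param csv_path,epoch_path output paths for samples and epoch annotations
#' @export
write_ephys <- function(trace, csv_path, epoch_path) {
  data.table::fwrite(data.table::data.table(time_s = trace$time_s,
                                            current_na = trace$current_na),
                     csv_path)
  jsonlite::write_json(list(sampling_rate_hz = trace$sampling_rate_hz,
                            holding_mv = trace$holding_mv,
                            oocyte_id = trace$oocyte_id,
                            treatment = trace$treatment,
                            epochs = trace$epochs),
                       epoch_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname io
#' @export
read_ephys <- function(csv_path, epoch_path) {
  dt <- data.table::fread(csv_path)
  meta <- jsonlite::read_json(epoch_path, simplifyVector = TRUE)
  ephys_trace(dt$current_na, sampling_rate_hz = meta$sampling_rate_hz,
              epochs = as.data.frame(meta$epochs),
              holding_mv = meta$holding_mv, oocyte_id = meta$oocyte_id,
              treatment = meta$treatment)
}

#' @rdname io
#' @param table mortality table (see [gen_mortality()])
#' @export
write_mortality <- function(table, path) {
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname io
#' @export
read_mortality <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  req <- c("dose_ug_per_well", "well_id", "n_larvae")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("mortality table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(tab$well_dead)) {
    if (is.null(tab$n_dead)) stop("mortality table needs well_dead or n_dead")
    tab$well_dead <- tab$n_dead >= tab$n_larvae
  }
  tab
}
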