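# The experiment file: a reloadable JSON store of analyzed tube records.
#
# The file is plain JSON so it stays diffable; the normalized greyscale
# image of each pack is written as an adjacent PNG referenced by relative
# path rather than embedded. Period estimates are derived quantities and
# are never persisted: they are recomputed from the stored features, so
# a hand-edited mark position changes the periods on the next
# computation rather than leaving stale numbers behind.

RT_SCHEMA_VERSION <- "1.0"

record_to_json_list <- function(r) {
  list(
    pack_name = r$pack_name,
    tube_index = r$tube_index,
    source_image = r$source_image,
    greyscale_image_ref = r$greyscale_image_ref,
    tube_y_bounds = r$tube_y_bounds,
    mark_x = r$mark_x,
    mark_times_h = r$mark_times_h,
    band_x = r$band_x,
    growth_rate_mm_per_h = if (is.na(r$growth_rate_mm_per_h)) "N/A"
                           else r$growth_rate_mm_per_h,
    raw_densitometry = r$raw_densitometry
  )
}

record_from_json_list <- function(l) {
  gr <- l$growth_rate_mm_per_h
  if (is.character(gr)) gr <- NA_real_
  new_tube_record(
    pack_name = l$pack_name,
    tube_index = l$tube_index,
    source_image = l$source_image %||% "",
    greyscale_image_ref = l$greyscale_image_ref %||% "",
    tube_y_bounds = as.data.frame(l$tube_y_bounds),
    mark_x = unlist(l$mark_x),
    mark_times_h = unlist(l$mark_times_h),
    band_x = unlist(l$band_x) %||% numeric(0),
    growth_rate_mm_per_h = gr,
    raw_densitometry = unlist(l$raw_densitometry))
}

#' Save analyzed tube records to an experiment file
#'
#' Writes a JSON experiment file and, when the records carry their
#' normalized image (as produced by [analyze_pack()]), a sibling
#' greyscale PNG per pack referenced by relative path.
#'
#' @param records list of `tube_record` (possibly from several packs,
#'   concatenated).
#' @param path output `.json` path.
#' @param created creation timestamp string; kept from a previous load
#'   when resaving so a load/save round trip is byte-identical.
#' @return `path`, invisibly.
#' @export
save_experiment <- function(records, path,
                            created = attr(records, "created")) {
  img <- attr(records, "image")
  if (!is.null(img)) {
    ref <- paste0(sub("\\.json$", "", basename(path)), "_",
                  gsub("[^A-Za-z0-9_-]", "_", img$pack_name), "_grey.png")
    write_greyscale_png(img, file.path(dirname(path), ref))
    records <- lapply(records, function(r) {
      if (r$pack_name == img$pack_name && !nzchar(r$greyscale_image_ref))
        r$greyscale_image_ref <- ref
      r
    })
  }
  doc <- list(
    schema_version = RT_SCHEMA_VERSION,
    created = created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    tubes = lapply(records, record_to_json_list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Load an experiment file
#'
#' @param path experiment `.json` path.
#' @return list of `tube_record` with attribute `"created"` preserved.
#' @export
load_experiment <- function(path) {
  if (!file.exists(path))
    rt_error(sprintf("experiment file not found: %s", path), "rt_io_error")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$schema_version, RT_SCHEMA_VERSION))
    rt_error(sprintf("unknown experiment schema version '%s' (expected %s)",
                     doc$schema_version %||% "<missing>", RT_SCHEMA_VERSION),
             "rt_schema_error")
  records <- lapply(doc$tubes, record_from_json_list)
  attr(records, "created") <- doc$created
  records
}
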