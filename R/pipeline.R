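#' Read / write single-channel well images
#'
#' Images are stored as single-channel TIFF (or PNG) with intensities in
#' `[0, 1]`; in memory they are numeric matrices with rows = image y.
#'
#' @param path File path (.tif/.tiff/.png).
#' @param image Numeric matrix in `[0, 1]`.
#' @return `read_well_image()` returns the image matrix.
#' @export
read_well_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2) dat <- dat[, , 1]
  t(dat)  # EBImage stores (x, y); internally rows are y
}

#' @rdname read_well_image
#' @export
write_well_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(clamp(image, 0, 1))), path)
  invisible(path)
}

#' Segment microtissues from an image with a trained classifier
#'
#' Tissue probability map -> global Otsu threshold -> distance-transform
#' watershed declumping (seed separation half the expected diameter) ->
#' morphometric filtering -> object measurement.
#'
#' @param image Numeric image matrix.
#' @param tissue_classifier A `pixel_classifier` for the microtissue class.
#' @param layout A `plate_layout` (sets the expected diameter for declump
#'   seeds and default filter bounds).
#' @param criteria Optional [filter_criteria()]; layout defaults otherwise.
#' @param map Optional precomputed tissue probability map (skips
#'   classification).
#' @return List: `map`, `mask`, `labels` (filtered label image), `objects`
#'   (a `microtissue_objects` data frame).
#' @export
segment_well <- function(image, tissue_classifier = NULL, layout,
                         criteria = NULL, map = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  map <- map %||% predict_probability(tissue_classifier, image)
  mask <- threshold_map(map)
  d_min <- 0.5 * layout$expected_diameter / layout$pixel_size
  labels <- declump(mask, sigma_d = 2, d_min = d_min)
  criteria <- criteria %||% default_filter_criteria(layout)
  labels <- filter_objects(labels, criteria, layout$pixel_size)
  objects <- measure_objects(labels, layout$pixel_size)
  list(map = map, mask = mask, labels = labels, objects = objects)
}

#' Analyze one well image end to end
#'
#' Shares one filter-bank computation between the tissue and boundary
#' classifiers (both use the same specification), segments microtissues,
#' extracts the microwell grid and calls per-microwell occupancy.
#'
#' @param image Numeric image matrix.
#' @param tissue_classifier,boundary_classifier Trained `pixel_classifier`s.
#' @param layout A `plate_layout`.
#' @param criteria Optional [filter_criteria()].
#' @return List: `segmentation` (see [segment_well()]), `boundary_map`,
#'   `cells` (`microwell_cells`), `occupancy` (`occupancy_table`),
#'   `objects`.
#' @export
analyze_well_image <- function(image, tissue_classifier, boundary_classifier,
                               layout, criteria = NULL) {
  shared_spec <- identical(tissue_classifier$spec, boundary_classifier$spec)
  if (shared_spec) {
    bank <- compute_filter_bank(image, tissue_classifier$spec)
    tissue_map <- predict_prob_from_bank(tissue_classifier, bank)
    boundary_map <- predict_prob_from_bank(boundary_classifier, bank)
    rm(bank)
  } else {
    tissue_map <- predict_probability(tissue_classifier, image)
    boundary_map <- predict_probability(boundary_classifier, image)
  }
  seg <- segment_well(image, layout = layout, criteria = criteria,
                      map = tissue_map)
  cells <- extract_microwells(boundary_map, layout)
  occupancy <- assign_occupancy(cells, seg$objects)
  list(segmentation = seg, boundary_map = boundary_map, cells = cells,
       occupancy = occupancy, objects = seg$objects)
}

#' Write the per-image CSV outputs of an analysis
#'
#' @param result An [analyze_well_image()] result.
#' @param dir Output directory (created if missing).
#' @param image_id Identifier used as file prefix and `image_id` column.
#' @return Named character vector of the files written, invisibly.
#' @export
write_analysis_outputs <- function(result, dir, image_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj_path <- file.path(dir, paste0(image_id, "_objects.csv"))
  objects <- cbind(image_id = image_id, as.data.frame(result$objects))
  write.csv(format_numeric(objects), obj_path, row.names = FALSE,
            quote = FALSE)
  occ_path <- file.path(dir, paste0(image_id, "_occupancy.csv"))
  occ <- cbind(image_id = image_id, result$occupancy$cells)
  write.csv(occ, occ_path, row.names = FALSE, quote = FALSE)
  invisible(c(objects = obj_path, occupancy = occ_path))
}

# Fixed 6-significant-digit formatting so repeated runs are byte-identical.
#' @noRd
format_numeric <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}

#' Batch-process an image manifest
#'
#' Runs the full pipeline over every image of a manifest and aggregates
#' plate-level outputs: per-image object and occupancy tables, a long-format
#' plate digitalization table, a per-(platform, day) particle summary and —
#' when the manifest varies liquid-handling factors — the factorial ANOVA of
#' empty-well percentages. Failures are isolated per manifest row.
#'
#' @param manifest Data frame (or CSV path) with columns `image_path`,
#'   `platform`, `plate_well`, `day` and optionally `aspiration`,
#'   `dispension`.
#' @param classifiers Nested classifier list as from
#'   [train_well_classifiers()].
#' @param output_dir Directory for outputs.
#' @param pixel_size um/px of the manifest images.
#' @return A list of class `batch_result`: `per_image` status table,
#'   `digitalized`, `summary` (particle summaries), `anova` (or `NULL`),
#'   `output_dir`.
#' @export
run_batch <- function(manifest, classifiers, output_dir,
                      pixel_size = 8) {
  if (is.character(manifest)) {
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  required <- c("image_path", "platform", "plate_well", "day")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop("malformed manifest: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run_log.txt")
  log_line <- function(...) {
    msg <- sprintf("%s | %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  log_line("run_batch start: %d images", nrow(manifest))

  status <- character(nrow(manifest))
  tables <- list(); keys_well <- character(0); keys_day <- numeric(0)
  occ_by_image <- list(); obj_by_image <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    image_id <- sprintf("%s_d%s", row$plate_well, format(row$day))
    res <- tryCatch({
      img <- read_well_image(row$image_path)
      layout <- make_layout(row$platform, pixel_size = pixel_size)
      cls <- classifiers[[row$platform]]
      if (is.null(cls)) stop("no classifiers for platform ", row$platform)
      out <- analyze_well_image(img, cls$tissue, cls$boundary, layout)
      write_analysis_outputs(out, output_dir, image_id)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      log_line("ERROR %s: %s", image_id, conditionMessage(res))
    } else {
      status[i] <- "ok"
      tables[[length(tables) + 1L]] <- res$occupancy
      keys_well <- c(keys_well, row$plate_well)
      keys_day <- c(keys_day, row$day)
      occ_by_image[[image_id]] <- res$occupancy
      obj_by_image[[image_id]] <- cbind(platform = row$platform,
                                        day = row$day,
                                        as.data.frame(res$objects))
      log_line("ok %s: %d objects, %.2f%% empty", image_id,
               nrow(res$objects), res$occupancy$pct_empty)
    }
  }

  digitalized <- digitalize_plate(tables, keys_well, keys_day)
  if (nrow(digitalized) > 0) {
    write.csv(digitalized, file.path(output_dir, "plate_digitalization.csv"),
              row.names = FALSE, quote = FALSE)
  }

  ok_rows <- which(status == "ok")
  summary_tab <- NULL
  if (length(ok_rows) > 0) {
    objs <- do.call(rbind, obj_by_image)
    combos <- unique(objs[, c("platform", "day")])
    summary_tab <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
      pf <- combos$platform[k]; dy <- combos$day[k]
      sel <- objs$platform == pf & objs$day == dy
      img_sel <- ok_rows[manifest$platform[ok_rows] == pf &
                           manifest$day[ok_rows] == dy]
      pct <- mean(vapply(img_sel, function(j) {
        id <- sprintf("%s_d%s", manifest$plate_well[j],
                      format(manifest$day[j]))
        occ_by_image[[id]]$pct_empty
      }, numeric(1)))
      cbind(platform = pf, day = dy,
            particle_summary(objs[sel, , drop = FALSE], pct,
                             make_layout(pf, pixel_size = pixel_size)))
    }))
    write.csv(format_numeric(summary_tab),
              file.path(output_dir, "particle_summary.csv"),
              row.names = FALSE, quote = FALSE)
  }

  anova_tab <- NULL
  if (all(c("aspiration", "dispension") %in% names(manifest)) &&
      length(ok_rows) > 0) {
    dsg <- manifest[ok_rows, , drop = FALSE]
    if (length(unique(dsg$aspiration)) > 1 ||
        length(unique(dsg$dispension)) > 1) {
      resp <- vapply(ok_rows, function(j) {
        id <- sprintf("%s_d%s", manifest$plate_well[j],
                      format(manifest$day[j]))
        occ_by_image[[id]]$pct_empty
      }, numeric(1))
      anova_tab <- tryCatch(fit_anova(dsg, resp), error = function(e) NULL)
      if (!is.null(anova_tab)) {
        write.csv(format_numeric(anova_tab),
                  file.path(output_dir, "doe_anova.csv"),
                  row.names = FALSE, quote = FALSE)
      }
    }
  }
  log_line("run_batch done: %d/%d images ok", length(ok_rows), nrow(manifest))

  out <- list(per_image = data.frame(image_path = manifest$image_path,
                                     status = status),
              digitalized = digitalized, summary = summary_tab,
              anova = anova_tab, output_dir = output_dir)
  class(out) <- "batch_result"
  out
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("batch_result: %d/%d images processed, outputs in %s\n",
              sum(x$per_image$status == "ok"), nrow(x$per_image),
              x$output_dir))
  invisible(x)
}

#' Write a ground-truth bundle to disk
#'
#' Image and masks as TIFF, occupancy and object catalog as CSV, plus a
#' JSON sidecar recording layout, parameters and seed.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "well") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if (!is.null(truth$image)) {
    paths["image"] <- file.path(dir, paste0(prefix, ".tif"))
    write_well_image(truth$image, paths[["image"]])
  }
  if (!is.null(truth$tissue_mask)) {
    paths["tissue_mask"] <- file.path(dir, paste0(prefix, "_tissue_mask.tif"))
    write_well_image(truth$tissue_mask, paths[["tissue_mask"]])
  }
  if (!is.null(truth$boundary_mask)) {
    paths["boundary_mask"] <- file.path(dir,
                                        paste0(prefix, "_boundary_mask.tif"))
    write_well_image(truth$boundary_mask, paths[["boundary_mask"]])
  }
  paths["occupancy"] <- file.path(dir, paste0(prefix, "_occupancy.csv"))
  write.csv(truth$occupancy, paths[["occupancy"]], row.names = FALSE,
            quote = FALSE)
  paths["objects"] <- file.path(dir, paste0(prefix, "_objects.csv"))
  write.csv(format_numeric(truth$objects), paths[["objects"]],
            row.names = FALSE, quote = FALSE)
  paths["sidecar"] <- file.path(dir, paste0(prefix, "_meta.json"))
  layout <- truth$layout
  jsonlite::write_json(
    list(platform = layout$platform_name,
         microwell_pitch = layout$microwell_pitch,
         microwells_per_well = layout$microwells_per_well,
         grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
         pixel_size = layout$pixel_size,
         boundary_width = layout$boundary_width,
         seed = truth$seed),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
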