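#' Write and read image stacks as multi-page TIFF with a JSON sidecar
#'
#' Channels are stored as 32-bit float TIFF pages scaled into `[0, 1]`;
#' channel roles, the intensity scale, and the stack's labels go into a
#' JSON sidecar (`<path>.json`) so a stack round-trips through disk.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_image_stack()`: the path, invisibly. `read_image_stack()`:
#'   the restored [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1, vapply(stack, max, numeric(1)))
  pages <- purrr::map(unclass(stack), ~ .x / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = names(stack), intensity_scale = scale,
               pixel_size = attr(stack, "pixel_size"),
               region = attr(stack, "region"),
               embryo = attr(stack, "embryo"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- purrr::map(pages, ~ .x * meta$intensity_scale)
  names(channels) <- meta$channels
  do.call(image_stack, c(channels,
                         list(pixel_size = meta$pixel_size,
                              region = meta$region %||% NA_character_,
                              embryo = meta$embryo %||% NA_character_)))
}

#' Read and write long-format Ct tables and cytometry event tables as CSV
#'
#' Documented column schemas: Ct tables use `sample`, `amplicon`,
#' `treatment` (`none`/`rnaser`/`no_rt`), `fraction` (integer or empty),
#' `replicate`, `ct` (empty = undetermined); event tables use `acq_index`,
#' `time_s`, `fsc_a`, `fsc_h`, `ssc_a`, `mruby`, `egfp`, `anomaly`.
#'
#' @param path CSV file path.
#' @return A tibble in the documented schema.
#' @export
read_ct_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = "c", amplicon = "c", treatment = "c",
                    fraction = "i", replicate = "i", ct = "d"))
}

#' @rdname read_ct_table
#' @param table Tibble to write.
#' @export
write_ct_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname read_ct_table
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    acq_index = "i", time_s = "d", fsc_a = "d", fsc_h = "d",
                    ssc_a = "d", mruby = "d", egfp = "d", anomaly = "l"))
}

#' @rdname read_ct_table
#' @export
write_events <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
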