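# Plain-text container for strain-field series and parameter maps: a
# directory holding CSV matrices plus a YAML metadata file. Keeps every
# artifact human-inspectable and diff-able.

#' Write a strain-field series to a text container
#'
#' Creates (or overwrites) a directory with `meta.yaml` (grid, stress, S/V,
#' geometry), `times.csv`, `mask.csv`, and the axial/lateral stacks as
#' pixels x time CSV matrices.
#'
#' @param series A `strain_series`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_strain_series <- function(series, path) {
  stopifnot(inherits(series, "strain_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$axial)
  meta <- list(dims = as.integer(d),
               pixel_spacing_mm = as.numeric(series$pixel_spacing_mm),
               sigma0_pa = series$sigma0_pa, SV_m1 = series$SV_m1,
               geometry = series$geometry)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  data.table::fwrite(data.table::data.table(time_s = series$times),
                     file.path(path, "times.csv"))
  data.table::fwrite(data.table::as.data.table(series$mask * 1L),
                     file.path(path, "mask.csv"))
  for (comp in c("axial", "lateral"))
    data.table::fwrite(
      data.table::as.data.table(matrix(series[[comp]], d[1] * d[2], d[3])),
      file.path(path, paste0(comp, ".csv")))
  invisible(path)
}

#' Read a strain-field series from a text container
#'
#' @param path Directory written by [write_strain_series()].
#' @return A `strain_series`.
#' @export
read_strain_series <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  d <- as.integer(meta$dims)
  times <- data.table::fread(file.path(path, "times.csv"))$time_s
  mask <- as.matrix(data.table::fread(file.path(path, "mask.csv"))) > 0
  dimnames(mask) <- NULL
  rd <- function(comp)
    array(as.matrix(data.table::fread(file.path(path, paste0(comp, ".csv")))),
          dim = d)
  new_strain_series(times, rd("axial"), rd("lateral"), mask,
                    pixel_spacing_mm = meta$pixel_spacing_mm,
                    sigma0_pa = meta$sigma0_pa, SV_m1 = meta$SV_m1,
                    geometry = meta$geometry)
}

#' Write a window-of-observation report as JSON
#'
#' @param report A `woo_report` from [run_stpe_experiment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_woo_report <- function(report, path) {
  out <- unclass(report)
  out$pre <- as.data.frame(out$pre)
  out$sd <- as.data.frame(out$sd)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
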