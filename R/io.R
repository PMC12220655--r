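#' Field, waveform, metrics and configuration I/O
#'
#' Velocity fields are written as ASCII VTK rectilinear-grid files (`.vtr`):
#' cell-centered components and the solid mask as CellData for visualization,
#' and the raw staggered face arrays as FieldData at full precision so that a
#' write/read round trip is lossless. A periodic field becomes a series
#' directory with one `.vtr` per phase plus a `series.json` manifest.
#' Waveforms travel as two-column CSV (`t_s`, `Q_mL_per_s`), dispersion
#' metrics as tidy CSV, configurations as YAML.
#'
#' @name field_io
NULL

fmt <- function(x) sprintf("%.17g", x)

vtr_dataarray <- function(name, values, type = "Float64") {
  paste0('      <DataArray type="', type, '" Name="', name,
         '" format="ascii">\n        ',
         paste(if (type == "Float64") fmt(values) else as.integer(values),
               collapse = " "),
         "\n      </DataArray>\n")
}

vtr_text <- function(grid, celldata, fielddata) {
  fc <- face_coords(grid)
  ext <- sprintf("0 %d 0 %d 0 0", grid$nx, grid$ny)
  paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="RectilinearGrid" version="1.0" byte_order="LittleEndian">\n',
    '  <RectilinearGrid WholeExtent="', ext, '">\n',
    "    <FieldData>\n",
    paste(vapply(names(fielddata), function(nm)
      vtr_dataarray(nm, fielddata[[nm]]), ""), collapse = ""),
    "    </FieldData>\n",
    '  <Piece Extent="', ext, '">\n',
    "    <Coordinates>\n",
    vtr_dataarray("x_cm", fc$xf),
    vtr_dataarray("y_cm", fc$yf),
    vtr_dataarray("z_cm", c(0, 1)),
    "    </Coordinates>\n",
    "    <CellData>\n",
    paste(vapply(names(celldata), function(nm)
      vtr_dataarray(nm, celldata[[nm]]), ""), collapse = ""),
    "    </CellData>\n",
    "  </Piece>\n",
    "  </RectilinearGrid>\n",
    "</VTKFile>\n")
}

vtr_read_arrays <- function(node, xpath) {
  out <- list()
  for (da in xml2::xml_find_all(node, xpath)) {
    nm <- xml2::xml_attr(da, "Name")
    out[[nm]] <- as.numeric(strsplit(trimws(xml2::xml_text(da)), "\\s+")[[1]])
  }
  out
}

grid_fielddata <- function(grid) {
  list(periodic_x = as.numeric(grid$periodic_x),
       periodic_y = as.numeric(grid$periodic_y),
       wall_y = as.numeric(grid$wall_y),
       n_segments = as.numeric(grid$n_segments))
}

grid_from_vtr <- function(coords, cd, fd, nx, ny) {
  xf <- coords$x_cm; yf <- coords$y_cm
  structured_grid(nx, ny, dx = xf[2] - xf[1], dy = yf[2] - yf[1],
                  x0 = xf[1], y0 = yf[1],
                  mask = matrix(cd$mask > 0.5, nx, ny),
                  periodic_x = fd$periodic_x > 0.5,
                  periodic_y = fd$periodic_y > 0.5,
                  wall_y = fd$wall_y > 0.5,
                  n_segments = as.integer(fd$n_segments))
}

#' @rdname field_io
#' @param field a [steady_velocity_field()] (or, for the series writer, a
#'   [periodic_velocity_field()]).
#' @param path output file (steady) or directory (series).
#' @export
write_field_vtr <- function(field, path) {
  g <- field$grid
  txt <- vtr_text(
    g,
    celldata = list(u_cm_per_s = field$u, v_cm_per_s = field$v,
                    mask = as.numeric(g$mask)),
    fielddata = c(grid_fielddata(g),
                  stats::setNames(list(as.numeric(factor(
                    field$role,
                    levels = c("eulerian_mean", "stokes_drift",
                               "lagrangian_asymptotic", "lagrangian_raw",
                               "lagrangian_solenoidal", "potential_gradient")))),
                    "role_code")))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_field_vtr <- function(path) {
  doc <- xml2::read_xml(path)
  ext <- strsplit(xml2::xml_attr(xml2::xml_find_first(doc, "//RectilinearGrid"),
                                 "WholeExtent"), "\\s+")[[1]]
  nx <- as.integer(ext[2]); ny <- as.integer(ext[4])
  coords <- vtr_read_arrays(doc, "//Coordinates/DataArray")
  cd <- vtr_read_arrays(doc, "//CellData/DataArray")
  fd <- vtr_read_arrays(doc, "//FieldData/DataArray")
  g <- grid_from_vtr(coords, cd, fd, nx, ny)
  roles <- c("eulerian_mean", "stokes_drift", "lagrangian_asymptotic",
             "lagrangian_raw", "lagrangian_solenoidal", "potential_gradient")
  steady_velocity_field(g, matrix(cd$u_cm_per_s, nx, ny),
                        matrix(cd$v_cm_per_s, nx, ny),
                        role = roles[as.integer(fd$role_code)])
}

#' @rdname field_io
#' @export
write_field_series <- function(field, path) {
  stopifnot(inherits(field, "periodic_velocity_field"))
  g <- field$grid
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(field$n_phases)
  for (p in seq_len(field$n_phases)) {
    cc <- cell_center_velocity(field, p)
    txt <- vtr_text(
      g,
      celldata = list(u_cm_per_s = cc$u, v_cm_per_s = cc$v,
                      mask = as.numeric(g$mask)),
      fielddata = c(grid_fielddata(g),
                    list(time_s = p * field$period / field$n_phases,
                         u_faces = as.numeric(field$u[, , p]),
                         v_faces = as.numeric(field$v[, , p]))))
    files[p] <- sprintf("phase_%04d.vtr", p)
    writeLines(txt, file.path(path, files[p]))
  }
  jsonlite::write_json(
    list(period_s = field$period, n_phases = field$n_phases, files = files,
         units = list(velocity = "cm/s", length = "cm"),
         mask_encoding = "CellData 'mask': 1 = solid, 0 = fluid"),
    file.path(path, "series.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname field_io
#' @export
read_field_series <- function(path) {
  man <- jsonlite::read_json(file.path(path, "series.json"),
                             simplifyVector = TRUE)
  np <- man$n_phases
  u <- NULL; v <- NULL; g <- NULL
  for (p in seq_len(np)) {
    doc <- xml2::read_xml(file.path(path, man$files[p]))
    if (is.null(g)) {
      ext <- strsplit(xml2::xml_attr(
        xml2::xml_find_first(doc, "//RectilinearGrid"), "WholeExtent"),
        "\\s+")[[1]]
      nx <- as.integer(ext[2]); ny <- as.integer(ext[4])
      coords <- vtr_read_arrays(doc, "//Coordinates/DataArray")
      cd <- vtr_read_arrays(doc, "//CellData/DataArray")
      fd0 <- vtr_read_arrays(doc, "//FieldData/DataArray")
      g <- grid_from_vtr(coords, cd, fd0, nx, ny)
      u <- array(0, c(nx + 1L, ny, np))
      v <- array(0, c(nx, ny + 1L, np))
    }
    fd <- vtr_read_arrays(doc, "//FieldData/DataArray")
    u[, , p] <- fd$u_faces
    v[, , p] <- fd$v_faces
  }
  periodic_velocity_field(g, u, v, period = man$period_s)
}

#' @rdname field_io
#' @param wf a [flow_waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(data.frame(t_s = wf$t, Q_mL_per_s = wf$Q,
                              period_s = wf$period),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname field_io
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "Q_mL_per_s") %in% names(d)))
    stop("waveform CSV must have columns t_s and Q_mL_per_s")
  period <- if ("period_s" %in% names(d)) d$period_s[1] else
    utils::tail(d$t_s, 1) + diff(utils::tail(d$t_s, 2))
  flow_waveform(d$t_s, d$Q_mL_per_s, period)
}

#' @rdname field_io
#' @param metrics a `dispersion_metrics` data frame, optionally with a
#'   `kappa_H` column.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' @rdname field_io
#' @export
read_metrics_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("dispersion_metrics", "data.frame")
  out
}

#' @rdname field_io
#' @param config a pipeline configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname field_io
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
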