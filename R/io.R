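# File formats and configuration: STL / PLY surface meshes (ASCII and
# binary), VTK XML unstructured grids (.vtu) for volume meshes and nodal
# result fields, probe-series CSV, summary JSON, and the validated YAML run
# configuration. Labels and metadata that a format cannot carry natively
# travel in a JSON sidecar next to the file.

fmt_num <- function(x) sprintf("%.17g", x)

sidecar_path <- function(path) paste0(path, ".labels.json")

write_sidecar <- function(path, mesh) {
  meta <- list(tube_info = attr(mesh, "tube_info"),
               base_plane = attr(mesh, "base_plane"))
  if (inherits(mesh, "surface_mesh")) {
    meta$face_labels <- mesh$face_labels
  } else {
    meta$boundary_faces <- mesh$boundary_faces
    meta$boundary_tags <- mesh$boundary_tags
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

restore_meta <- function(mesh, meta) {
  if (is.null(meta)) return(mesh)
  if (!is.null(meta$tube_info)) {
    ti <- lapply(meta$tube_info, function(tb) lapply(tb, unlist))
    attr(mesh, "tube_info") <- ti
  }
  if (!is.null(meta$base_plane))
    attr(mesh, "base_plane") <- lapply(meta$base_plane, unlist)
  mesh
}

#' Write a mesh to STL, PLY or VTU
#'
#' Surface meshes go to `.stl` / `.ply`, volume meshes to `.vtu` (VTK XML
#' unstructured grid). Face labels, boundary tags and tube/base-plane
#' metadata are stored in a `<path>.labels.json` sidecar, since none of the
#' formats carries them natively. ASCII output prints coordinates with 17
#' significant digits (lossless); binary STL stores the format's 32-bit
#' floats, binary PLY stores doubles.
#'
#' @param mesh `surface_mesh` (stl/ply) or `volume_mesh` (vtu)
#' @param path output path; the extension selects the format
#' @param binary write the binary variant (STL/PLY only)
#' @param point_data optional named list of nodal arrays (vectors or
#'   matrices) written as VTU PointData, e.g.
#'   `list(velocity = u, pressure = p)`
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, binary = FALSE, point_data = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = {
      stopifnot(inherits(mesh, "surface_mesh"))
      if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path)
      write_sidecar(path, mesh)
    },
    ply = {
      stopifnot(inherits(mesh, "surface_mesh"))
      write_ply(mesh, path, binary)
      write_sidecar(path, mesh)
    },
    vtu = {
      stopifnot(inherits(mesh, "volume_mesh"))
      write_vtu(mesh, path, point_data)
      write_sidecar(path, mesh)
    },
    stop_vf("unsupported mesh extension .", ext,
            " (supported: .stl, .ply, .vtu)",
            class = "ventriflow_io_error"))
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path input path (.stl, .ply or .vtu); a `<path>.labels.json`
#'   sidecar, when present, restores labels/tags and metadata
#' @return `surface_mesh` (stl/ply) or `volume_mesh` (vtu); a VTU with
#'   PointData gains a `point_data` attribute
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    stop_vf("no such file: ", path, class = "ventriflow_io_error")
  ext <- tolower(tools::file_ext(path))
  meta <- read_sidecar(path)
  out <- switch(ext,
    stl = read_stl(path, meta),
    ply = read_ply(path, meta),
    vtu = read_vtu(path, meta),
    stop_vf("unsupported mesh extension .", ext,
            " (supported: .stl, .ply, .vtu)",
            class = "ventriflow_io_error"))
  restore_meta(out, meta)
}

## ---- STL ----

write_stl_ascii <- function(mesh, path) {
  n <- normalize_rows(face_normals_raw(mesh))
  v <- lapply(1:3, function(k) face_vertex(mesh, k))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid ventriflow", con)
  body <- sprintf(
    "facet normal %s %s %s\nouter loop\nvertex %s %s %s\nvertex %s %s %s\nvertex %s %s %s\nendloop\nendfacet",
    fmt_num(n[, 1]), fmt_num(n[, 2]), fmt_num(n[, 3]),
    fmt_num(v[[1]][, 1]), fmt_num(v[[1]][, 2]), fmt_num(v[[1]][, 3]),
    fmt_num(v[[2]][, 1]), fmt_num(v[[2]][, 2]), fmt_num(v[[2]][, 3]),
    fmt_num(v[[3]][, 1]), fmt_num(v[[3]][, 2]), fmt_num(v[[3]][, 3]))
  writeLines(body, con)
  writeLines("endsolid ventriflow", con)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(formatC("ventriflow binary STL", width = -80)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  n <- normalize_rows(face_normals_raw(mesh))
  v <- lapply(1:3, function(k) face_vertex(mesh, k))
  tri <- cbind(n, v[[1]], v[[2]], v[[3]])
  for (i in seq_len(nrow(tri))) {
    writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# rebuild shared vertices from the triangle soup by exact coordinate match
soup_to_surface <- function(tri_verts, meta) {
  key <- paste(tri_verts[, 1], tri_verts[, 2], tri_verts[, 3])
  uk <- !duplicated(key)
  verts <- tri_verts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, face_labels = meta$face_labels)
}

read_stl <- function(path, meta) {
  head5 <- readBin(path, "raw", 5)
  if (rawToChar(head5) == "solid" && {
    txt <- readLines(path, warn = FALSE)
    any(grepl("^\\s*facet", txt[seq_len(min(10, length(txt)))]))
  }) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    num <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (nrow(num) %% 3 != 0)
      stop_vf("corrupt ASCII STL: vertex count ", nrow(num),
              " not divisible by 3", class = "ventriflow_io_error")
    return(soup_to_surface(num, meta))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  exp_size <- 84 + nf * 50
  if (file.info(path)$size != exp_size)
    stop_vf("corrupt binary STL: expected ", exp_size, " bytes for ", nf,
            " facets, file has ", file.info(path)$size,
            " (header at byte offset 80)", class = "ventriflow_io_error")
  tri <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
    tri[3 * i - (2:0), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  soup_to_surface(tri, meta)
}

## ---- PLY ----

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              "comment ventriflow surface",
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%s %s %s", fmt_num(mesh$vertices[, 1]),
                       fmt_num(mesh$vertices[, 2]),
                       fmt_num(mesh$vertices[, 3])), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

read_ply <- function(path, meta) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- character(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (!length(ch) || ch == charToRaw("\n")) break
      ln <- c(ln, rawToChar(ch))
    }
    ln <- paste(ln, collapse = "")
    header <- c(header, ln)
    if (identical(ln, "end_header")) break
    if (length(header) > 100)
      stop_vf("corrupt PLY: no end_header in the first 100 lines",
              class = "ventriflow_io_error")
  }
  fmt <- strsplit(grep("^format", header, value = TRUE)[1], "\\s+")[[1]][2]
  nv <- as.integer(strsplit(grep("^element vertex", header, value = TRUE)[1],
                            "\\s+")[[1]][3])
  nf <- as.integer(strsplit(grep("^element face", header, value = TRUE)[1],
                            "\\s+")[[1]][3])
  if (fmt == "binary_little_endian") {
    verts <- matrix(readBin(con, "numeric", 3 * nv, size = 8,
                            endian = "little"), nv, 3, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L)
        stop_vf("PLY face ", i, " has ", cnt, " vertices; only triangles ",
                "are supported", class = "ventriflow_io_error")
      faces[i, ] <- readBin(con, "integer", 3, size = 4,
                            endian = "little") + 1L
    }
  } else {
    txt <- readLines(con, warn = FALSE)
    verts <- do.call(rbind, lapply(strsplit(txt[seq_len(nv)], "\\s+"),
                                   function(p) as.numeric(p[1:3])))
    fl <- strsplit(txt[nv + seq_len(nf)], "\\s+")
    faces <- do.call(rbind, lapply(fl, function(p) as.integer(p[2:4]) + 1L))
  }
  surface_mesh(verts, faces, face_labels = meta$face_labels)
}

## ---- VTU ----

vtu_array <- function(name, values, ncomp, type = "Float64") {
  vals <- if (type == "Float64") fmt_num(values) else
    format(values, scientific = FALSE, trim = TRUE)
  paste0('<DataArray type="', type, '" Name="', name,
         '" NumberOfComponents="', ncomp, '" format="ascii">\n',
         paste(vals, collapse = " "), "\n</DataArray>")
}

write_vtu <- function(mesh, path, point_data = NULL) {
  nv <- nrow(mesh$vertices); nc <- nrow(mesh$cells)
  pd <- ""
  if (length(point_data)) {
    arrays <- vapply(names(point_data), function(nm) {
      a <- point_data[[nm]]
      if (is.matrix(a)) vtu_array(nm, as.vector(t(a)), ncol(a))
      else vtu_array(nm, a, 1L)
    }, character(1))
    pd <- paste0("<PointData>\n", paste(arrays, collapse = "\n"),
                 "\n</PointData>\n")
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    '<Piece NumberOfPoints="', nv, '" NumberOfCells="', nc, '">\n',
    "<Points>\n", vtu_array("Points", as.vector(t(mesh$vertices)), 3L),
    "\n</Points>\n",
    "<Cells>\n",
    vtu_array("connectivity", as.vector(t(mesh$cells)) - 1L, 1L, "Int64"),
    "\n", vtu_array("offsets", 4L * seq_len(nc), 1L, "Int64"),
    "\n", vtu_array("types", rep(10L, nc), 1L, "UInt8"),
    "\n</Cells>\n",
    "<CellData>\n",
    vtu_array("region", as.integer(mesh$cell_region == "porous"), 1L, "UInt8"),
    "\n</CellData>\n", pd,
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path)
}

read_vtu <- function(path, meta) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing"))
    stop_vf("corrupt VTU: no <Piece> element", class = "ventriflow_io_error")
  arr <- function(xpath) {
    node <- xml2::xml_find_first(piece, xpath)
    if (inherits(node, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  nv <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  nc <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  pts <- matrix(arr("./Points/DataArray"), nv, 3, byrow = TRUE)
  types <- arr('./Cells/DataArray[@Name="types"]')
  if (any(types != 10))
    stop_vf("VTU contains non-tetrahedral cells (types ",
            paste(unique(types[types != 10]), collapse = ", "), ")",
            class = "ventriflow_io_error")
  cells <- matrix(as.integer(arr('./Cells/DataArray[@Name="connectivity"]')),
                  nc, 4, byrow = TRUE) + 1L
  region <- arr('./CellData/DataArray[@Name="region"]')
  cell_region <- if (is.null(region)) rep("fluid", nc) else
    c("fluid", "porous")[region + 1L]
  if (!is.null(meta$boundary_faces)) {
    bnd <- matrix(as.integer(unlist(meta$boundary_faces)),
                  ncol = 3)
    tags <- unlist(meta$boundary_tags)
  } else {
    bnd <- boundary_of_tets(cells)
    tags <- rep("wall", nrow(bnd))
  }
  out <- volume_mesh(pts, cells, bnd, tags, cell_region)
  pd_nodes <- xml2::xml_find_all(piece, "./PointData/DataArray")
  if (length(pd_nodes)) {
    pd <- lapply(pd_nodes, function(nd) {
      ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
      vals <- scan(text = xml2::xml_text(nd), quiet = TRUE)
      if (ncomp > 1) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
    })
    names(pd) <- vapply(pd_nodes, function(nd) xml2::xml_attr(nd, "Name"),
                        character(1))
    attr(out, "point_data") <- pd
  }
  out
}

#' Write a run state as a VTU result file
#'
#' Stores the mesh plus nodal `velocity` (m/s) and `pressure` (Pa, physical)
#' point data.
#'
#' @param mesh `volume_mesh`
#' @param state `flow_state`
#' @param path output `.vtu` path
#' @param props `fluid_properties` (converts kinematic to physical pressure)
#' @return `path`, invisibly
#' @export
write_state_vtu <- function(mesh, state, path, props = fluid_properties()) {
  write_mesh(mesh, path,
             point_data = list(velocity = state$u,
                               pressure = state$p * props$density))
}

## ---- probe series and summaries ----

#' Write / read the per-step probe series of a run as CSV
#' @param run `flow_run`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_series_csv <- function(run, path) {
  utils::write.csv(run$series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path))
    stop_vf("no such file: ", path, class = "ventriflow_io_error")
  utils::read.csv(path)
}

#' Write / read a hemodynamic summary (or any flat list) as JSON
#' @param x named list of scalars
#' @param path JSON path
#' @return `path` (write) / named list (read)
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  if (!file.exists(path))
    stop_vf("no such file: ", path, class = "ventriflow_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## ---- run configuration ----

config_schema <- function() list(
  schema_version = NULL,
  geometry = list(cavity = names(formals(cavity_params)),
                  trabeculation = names(formals(trabeculation_params)),
                  max_cell_volume = NULL),
  fluid = setdiff(names(formals(fluid_properties)), "..."),
  inflow = c("type", "speed", "ramp",
             setdiff(names(formals(ea_wave_params)), "...")),
  outlet = names(formals(outlet_model)),
  solver = names(formals(solver_config)),
  porous = c("thickness", "sigma"),
  analysis = c("q_threshold", "window_frames", "probe_length"),
  output = "dir")

check_keys <- function(given, allowed, path) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop_vf("unknown config key", if (length(bad) > 1) "s", ": ",
            paste0(path, ".", bad, collapse = ", "),
            class = "ventriflow_validation_error")
}

#' Load and validate a YAML run configuration
#'
#' Every block is validated through its type constructor (so value errors
#' name the offending field) and unknown keys are rejected with their full
#' path. Missing blocks take the documented defaults.
#'
#' @param path YAML file
#' @return `run_config`: typed `cavity`, `trabeculation`, `fluid`, `inflow`
#'   (data; see [config_inflow()]), `outlet`, `solver`, `porous` (or NULL),
#'   `analysis`, `output`, `max_cell_volume`
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_vf("no such file: ", path, class = "ventriflow_io_error")
  raw <- yaml::read_yaml(path)
  validate_config(if (is.null(raw)) list() else raw)
}

#' Validate a run-configuration list
#' @param raw nested list (parsed YAML)
#' @return `run_config`
#' @export
validate_config <- function(raw) {
  schema <- config_schema()
  check_keys(raw, names(schema), "config")
  geo <- raw$geometry %||% list()
  check_keys(geo, names(schema$geometry), "geometry")
  check_keys(geo$cavity %||% list(), schema$geometry$cavity,
             "geometry.cavity")
  check_keys(geo$trabeculation %||% list(), schema$geometry$trabeculation,
             "geometry.trabeculation")
  check_keys(raw$fluid %||% list(), schema$fluid, "fluid")
  check_keys(raw$inflow %||% list(), schema$inflow, "inflow")
  check_keys(raw$outlet %||% list(), schema$outlet, "outlet")
  check_keys(raw$solver %||% list(), schema$solver, "solver")
  if (!is.null(raw$porous))
    check_keys(raw$porous, schema$porous, "porous")
  check_keys(raw$analysis %||% list(), schema$analysis, "analysis")
  check_keys(raw$output %||% list(), schema$output, "output")

  inflow <- raw$inflow %||% list()
  type <- inflow$type %||% "constant"
  if (!type %in% c("constant", "ea"))
    stop_vf("inflow.type must be \"constant\" or \"ea\"",
            class = "ventriflow_validation_error")
  inflow_data <- if (type == "constant") {
    list(type = "constant", speed = inflow$speed %||% 0.55,
         ramp = inflow$ramp %||% 0.02)
  } else {
    c(list(type = "ea"),
      unclass(do.call(ea_wave_params,
                      inflow[setdiff(names(inflow), "type")])))
  }
  if (type == "constant") {
    check_number(inflow_data$speed, "inflow.speed", 0)
    check_number(inflow_data$ramp, "inflow.ramp", 0)
  }
  porous <- NULL
  if (!is.null(raw$porous)) {
    if (is.null(raw$porous$thickness) || is.null(raw$porous$sigma))
      stop_vf("porous block needs both thickness and sigma",
              class = "ventriflow_validation_error")
    porous <- list(thickness = raw$porous$thickness,
                   sigma = raw$porous$sigma)
    check_number(porous$thickness, "porous.thickness", 0,
                 strict_lower = TRUE)
    check_number(porous$sigma, "porous.sigma", 0, strict_lower = TRUE)
  }
  ana <- raw$analysis %||% list()
  analysis <- list(q_threshold = ana$q_threshold %||% 5000,
                   window_frames = ana$window_frames %||% 10,
                   probe_length = ana$probe_length %||% 0.015)
  check_number(analysis$q_threshold, "analysis.q_threshold")
  check_number(analysis$window_frames, "analysis.window_frames", 1)
  check_number(analysis$probe_length, "analysis.probe_length", 0,
               strict_lower = TRUE)
  fluid_args <- raw$fluid %||% list()
  if (!is.null(fluid_args$body_force))
    fluid_args$body_force <- unlist(fluid_args$body_force)
  structure(list(
    schema_version = raw$schema_version %||% 1L,
    cavity = do.call(cavity_params, geo$cavity %||% list()),
    trabeculation = do.call(trabeculation_params,
                            geo$trabeculation %||% list()),
    max_cell_volume = geo$max_cell_volume %||% 1.1e-8,
    fluid = do.call(fluid_properties, fluid_args),
    inflow = inflow_data,
    outlet = do.call(outlet_model, raw$outlet %||% list()),
    solver = do.call(solver_config, raw$solver %||% list()),
    porous = porous,
    analysis = analysis,
    output = list(dir = (raw$output %||% list())$dir %||% "results")),
    class = "run_config")
}

#' Inflow speed function of a validated configuration
#' @param config `run_config`
#' @return `function(t)` in m/s
#' @export
config_inflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  d <- config$inflow
  if (d$type == "constant")
    return(function(t) constant_inflow(t, d$speed, d$ramp))
  pars <- do.call(ea_wave_params, d[setdiff(names(d), "type")])
  function(t) ea_wave(t, pars)
}

#' Save a validated configuration back to YAML
#'
#' Writes the fully resolved configuration (all defaults materialized), so
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config `run_config`
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  solver <- unclass(config$solver)
  solver$seed <- solver$seed  # NULL stays absent in YAML
  lst <- list(
    schema_version = config$schema_version,
    geometry = list(cavity = unclass(config$cavity),
                    trabeculation = unclass(config$trabeculation),
                    max_cell_volume = config$max_cell_volume),
    fluid = unclass(config$fluid)[c("density", "dynamic_viscosity",
                                    "body_force", "gravity")],
    inflow = config$inflow,
    outlet = unclass(config$outlet),
    solver = solver[!vapply(solver, is.null, logical(1))],
    porous = config$porous,
    analysis = config$analysis,
    output = config$output)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  yaml::write_yaml(lst, path)
  invisible(path)
}
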