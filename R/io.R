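# File formats: CARP-style mesh triplet (.pts/.elem/.lon), VTU (ASCII XML
# unstructured grid), per-node activation maps, patient tables, YAML run
# configuration, provenance records. All round-trip tested.

#' Write / read a mesh as a CARP-style triplet
#'
#' `basename.pts` (node count header, then x y z per line, mm),
#' `basename.elem` (element count header, then `Tt n1 n2 n3 n4 tag` with
#' 0-based node indices), `basename.lon` (header `1`, then one unit fiber
#' vector per element). Region tags map 1=LV, 2=RV, 3=septum.
#'
#' @param mesh a `bv_mesh` or compatible list (`nodes`, `elems`, optional
#'   `region`, `fibers`).
#' @param basename path without extension.
#' @return `write_carp_mesh`: the basename, invisibly. `read_carp_mesh`: a
#'   list with `nodes`, `elems`, `region`, `fibers` (a full `bv_mesh` is not
#'   reconstructed: surface tags and construction metadata are not part of
#'   the format).
#' @export
write_carp_mesh <- function(mesh, basename) {
  nodes <- mesh$nodes
  data.table::fwrite(data.table::as.data.table(nodes),
                     paste0(basename, ".pts"), sep = " ", col.names = FALSE,
                     append = FALSE, yaml = FALSE,
                     scipen = 999)
  # prepend count headers (CARP dialect)
  .prepend_line(paste0(basename, ".pts"), as.character(nrow(nodes)))
  reg <- if (!is.null(mesh$region)) as.integer(factor(mesh$region)) else
    rep(1L, nrow(mesh$elems))
  el <- data.table::data.table(t = "Tt", a = mesh$elems[, 1] - 1L,
                               b = mesh$elems[, 2] - 1L,
                               c = mesh$elems[, 3] - 1L,
                               d = mesh$elems[, 4] - 1L, tag = reg)
  data.table::fwrite(el, paste0(basename, ".elem"), sep = " ",
                     col.names = FALSE)
  .prepend_line(paste0(basename, ".elem"), as.character(nrow(el)))
  f <- mesh$fibers
  if (is.null(f)) f <- matrix(rep(c(1, 0, 0), nrow(el)), ncol = 3, byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(f), paste0(basename, ".lon"),
                     sep = " ", col.names = FALSE)
  .prepend_line(paste0(basename, ".lon"), "1")
  invisible(basename)
}

.prepend_line <- function(path, line) {
  txt <- readLines(path)
  writeLines(c(line, txt), path)
}

#' @rdname write_carp_mesh
#' @export
read_carp_mesh <- function(basename) {
  pts_path <- paste0(basename, ".pts")
  if (!file.exists(pts_path)) stop("no such mesh: ", pts_path)
  n <- as.integer(readLines(pts_path, n = 1))
  nodes <- as.matrix(data.table::fread(pts_path, skip = 1, header = FALSE))
  if (nrow(nodes) != n || ncol(nodes) != 3)
    stop(sprintf("malformed .pts: header says %d nodes, found %d x %d", n,
                 nrow(nodes), ncol(nodes)))
  dimnames(nodes) <- NULL
  el <- data.table::fread(paste0(basename, ".elem"), skip = 1, header = FALSE)
  if (!all(el[[1]] == "Tt"))
    stop("malformed .elem: only tetrahedral (Tt) elements are supported")
  elems <- as.matrix(el[, 2:5]) + 1L
  dimnames(elems) <- NULL
  if (any(elems < 1L) || any(elems > n))
    stop("malformed .elem: node index out of range")
  region <- factor(c("lv", "rv", "septum")[el[[6]]],
                   levels = c("lv", "rv", "septum"))
  lon_path <- paste0(basename, ".lon")
  fibers <- NULL
  if (file.exists(lon_path)) {
    fibers <- as.matrix(data.table::fread(lon_path, skip = 1, header = FALSE))
    dimnames(fibers) <- NULL
    if (nrow(fibers) != nrow(elems)) stop("malformed .lon: row count mismatch")
    nrm <- sqrt(rowSums(fibers^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      warning("non-unit fiber vectors in .lon; normalizing")
      fibers <- fibers / pmax(nrm, 1e-12)
    }
  }
  list(nodes = nodes, elems = elems, region = region, fibers = fibers)
}

#' Write / read a mesh as VTU (ASCII XML unstructured grid)
#'
#' Minimal VTU dialect: points, tetrahedral connectivity, one optional
#' per-point scalar array (e.g. an activation map) and one per-cell array
#' (the region tag). Readable by ParaView and by [read_vtu()].
#'
#' @param mesh list with `nodes`, `elems`, optional `region`.
#' @param path output file.
#' @param point_data optional named list of per-node numeric vectors.
#' @return the path, invisibly (writer); list with `nodes`, `elems`,
#'   `point_data`, `cell_data` (reader).
#' @export
write_vtu <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, num), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(num(seq_len(m) * 4L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(num(rep(10L, m)), con)
  w('</DataArray></Cells>')
  if (!is.null(point_data) && length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(num(as.numeric(point_data[[nm]])), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  if (!is.null(mesh$region)) {
    w('<CellData><DataArray type="Int32" Name="region" format="ascii">')
    writeLines(num(as.integer(factor(mesh$region))), con)
    w('</DataArray></CellData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' @rdname write_vtu
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(xml2::xml_name(piece))) stop("malformed VTU: no <Piece>")
  getarr <- function(xpath) {
    node <- xml2::xml_find_first(doc, xpath)
    if (is.na(xml2::xml_name(node))) return(NULL)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- getarr(".//Points/DataArray")
  conn <- getarr(".//DataArray[@Name='connectivity']")
  types <- getarr(".//DataArray[@Name='types']")
  if (is.null(pts) || is.null(conn)) stop("malformed VTU: missing arrays")
  if (!is.null(types) && any(types != 10))
    stop("only tetrahedral (type 10) VTU meshes are supported")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  elems <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  pd <- list()
  for (node in xml2::xml_find_all(doc, ".//PointData/DataArray")) {
    pd[[xml2::xml_attr(node, "Name")]] <-
      scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  cd <- list()
  for (node in xml2::xml_find_all(doc, ".//CellData/DataArray")) {
    cd[[xml2::xml_attr(node, "Name")]] <-
      scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  list(nodes = nodes, elems = elems, point_data = pd, cell_data = cd)
}

#' Write / read an activation map
#'
#' Plain-text two-column table: 0-based node index and activation time (ms,
#' `NA` for unactivated nodes).
#' @param map an `activation_map` (or numeric vector).
#' @param path file path.
#' @return path (writer) / `activation_map` (reader).
#' @export
write_activation_map <- function(map, path) {
  data.table::fwrite(data.table::data.table(
    node = seq_along(map) - 1L, time_ms = as.numeric(map)), path, sep = "\t")
  invisible(path)
}

#' @rdname write_activation_map
#' @export
read_activation_map <- function(path) {
  d <- data.table::fread(path)
  if (!all(c("node", "time_ms") %in% names(d)))
    stop("malformed activation map: need columns node, time_ms")
  structure(d$time_ms[order(d$node)], onsets_ms = 0, class = "activation_map")
}

#' Write / read a patient table
#'
#' CSV dialect with the fixed header `patient_id, sex, timepoint, qrs_ms,
#' ecv, wt_mm, lv_volume_ml, bsa_m2` (units: ms, fraction, mm, mL, m^2).
#'
#' @param records data.frame of patient records.
#' @param path file path.
#' @return path (writer) / validated data.frame (reader).
#' @export
write_patient_table <- function(records, path) {
  .check_patient_table(records)
  data.table::fwrite(records, path)
  invisible(path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path))
  .check_patient_table(d)
  d
}

.check_patient_table <- function(d) {
  need <- c("patient_id", "sex", "timepoint", "qrs_ms", "ecv", "wt_mm",
            "lv_volume_ml", "bsa_m2")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("patient table missing column(s): ", paste(missing, collapse = ", "))
  if (!all(d$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  if (any(d$ecv <= 0 | d$ecv >= 1)) stop("ecv must be a fraction in (0,1)")
  invisible(d)
}

#' Run configuration
#'
#' Flat YAML configuration with namespaced keys covering geometry, protocol,
#' fitting and engine settings. Defaults mirror the package's reference
#' values (1000 ms quiescence, 600 ms cycle length, 5% ECF step, cell-radius
#' bounds 9.6-17.8 um, reference tissue R = 15.45 um / ECV = 25.8% /
#' ECF = 0).
#'
#' @param overrides named list overriding individual keys.
#' @return named list of configuration values.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    geometry.lv_radius = 24, geometry.lv_length = 48, geometry.lv_wall = 10,
    geometry.rv_wall = 3.5, geometry.rv_gap = 5, geometry.edge_length = 1.5,
    protocol.quiescent_ms = 1000, protocol.cl_ms = 600, protocol.n_beats = 3,
    fit.r_tol_um = 0.05, fit.ecf_step = 0.05,
    fit.r_min_um = 9.6, fit.r_max_um = 17.8,
    tissue.r_ref_um = 15.45, tissue.ecv_ref = 0.258, tissue.ecf_ref = 0,
    engine = "eikonal", seed = 1, output_dir = ".", log_level = "info")
  utils::modifyList(cfg, overrides)
}

#' @rdname default_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  default_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Provenance record for an output artifact
#'
#' @param config configuration list the run used.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param timings optional named numeric vector of stage timings (s).
#' @return list with the config hash, package version, input digests and
#'   timings; attach to outputs or serialize alongside them.
#' @export
provenance_record <- function(config, inputs = character(0), timings = NULL) {
  list(config_hash = rlang::hash(config),
       package_version = as.character(utils::packageVersion("cardiotwin")),
       input_digests = if (length(inputs)) tools::md5sum(inputs) else NULL,
       timings_s = timings,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
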