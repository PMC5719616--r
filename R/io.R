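# Readers/writers: VTK legacy unstructured grids, Gmsh MSH v2 ASCII, CSV
# tables, YAML configs, JSON reports. Meshes are stored with their patch
# facets as triangle cells carrying a patch-id cell array; landmarks, patch
# names and the part axis travel in a JSON sidecar (<file>.meta.json).
# Node indices are 1-based in memory; format dialects are converted at the
# boundary (VTK is 0-based on disk, MSH 1-based).

.sidecar_path <- function(path) paste0(path, ".meta.json")

.write_sidecar <- function(mesh, path) {
  meta <- list(name = mesh$name,
               landmarks = lapply(mesh$landmarks, as.numeric),
               patch_names = as.list(names(mesh$patches)),
               axis = if (!is.null(mesh$axis)) {
                 lapply(mesh$axis, as.numeric)
               })
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write a tet part mesh
#'
#' @param mesh a [tet_part_mesh()].
#' @param path output file.
#' @param format `"vtk"` (legacy ASCII unstructured grid) or `"msh"`
#'   (Gmsh MSH v2 ASCII). A JSON sidecar `<path>.meta.json` carries the
#'   landmarks, patch names and axis.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = c("vtk", "msh")) {
  format <- match.arg(format)
  patches <- mesh$patches
  tri <- do.call(rbind, unname(patches))
  patch_id <- rep(seq_along(patches), vapply(patches, nrow, 0L))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets); k <- if (is.null(tri)) 0L else nrow(tri)
  # %.17g guarantees exact double round-trip through text
  node_lines <- sprintf("%.17g %.17g %.17g",
                        mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3])
  if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", mesh$name, "ASCII",
                 "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
    writeLines(node_lines, con)
    writeLines(sprintf("CELLS %d %d", m + k, 5L * m + 4L * k), con)
    utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE, col.names = FALSE)
    if (k) utils::write.table(cbind(3L, tri - 1L), con, row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("CELL_TYPES %d", m + k), con)
    writeLines(as.character(c(rep(10L, m), rep(5L, k))), con)
    writeLines(c(sprintf("CELL_DATA %d", m + k), "SCALARS patch_id int 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(c(rep(0L, m), patch_id)), con)
  } else {
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
                 "$Nodes", as.character(n)), con)
    writeLines(paste(seq_len(n), node_lines), con)
    writeLines(c("$EndNodes", "$Elements", as.character(m + k)), con)
    # element: id type n_tags phys geom nodes... (tets physical 0, patch
    # triangles carry the patch id as physical tag)
    utils::write.table(cbind(seq_len(m), 4L, 2L, 0L, 0L, mesh$tets), con,
                       row.names = FALSE, col.names = FALSE)
    if (k) utils::write.table(cbind(m + seq_len(k), 2L, 2L, patch_id, 0L, tri), con,
                              row.names = FALSE, col.names = FALSE)
    writeLines("$EndElements", con)
  }
  .write_sidecar(mesh, path)
  invisible(path)
}

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s: parse error at line %d: %s", path, line, msg))
}

#' Read a tet part mesh
#'
#' @param path mesh file written by [write_mesh()] (or any VTK legacy /
#'   MSH v2 ASCII file containing only tetrahedra and optional patch
#'   triangles).
#' @param format `"vtk"`, `"msh"` or `"auto"` (by extension/content).
#' @return a [tet_part_mesh()]; round-trips with [write_mesh()] are
#'   bit-identical for nodes and connectivity.
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "msh")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (length(lines) && grepl("^# vtk", lines[1])) "vtk"
    else if (length(lines) && grepl("^\\$MeshFormat", lines[1])) "msh"
    else if (grepl("\\.vtk$", path)) "vtk" else "msh"
  }
  if (format == "vtk") out <- .read_vtk(path, lines) else out <- .read_msh(path, lines)
  meta <- .read_sidecar(path)
  name <- meta$name %||% sub("\\.[^.]*$", "", basename(path))
  patches <- list()
  if (length(out$tri_id)) {
    pnames <- meta$patch_names %||% as.character(sort(unique(out$tri_id)))
    for (pi in sort(unique(out$tri_id))) {
      nm <- if (pi <= length(pnames)) pnames[[pi]] else as.character(pi)
      patches[[nm]] <- out$tris[out$tri_id == pi, , drop = FALSE]
    }
  }
  landmarks <- lapply(meta$landmarks %||% list(), as.numeric)
  axis <- if (!is.null(meta$axis)) lapply(meta$axis, as.numeric)
  tet_part_mesh(name, out$nodes, out$tets, patches = patches,
                landmarks = landmarks, axis = axis)
}

.read_vtk <- function(path, lines) {
  ln <- function(pat) grep(pat, lines)[1]
  ip <- ln("^POINTS")
  if (is.na(ip)) .parse_error(path, 1L, "no POINTS section")
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  if (length(pts) < 3 * n) .parse_error(path, ip, "truncated POINTS block")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  # POINTS block may wrap arbitrarily; find CELLS by keyword
  ic <- ln("^CELLS")
  if (is.na(ic)) .parse_error(path, ip, "no CELLS section")
  hdr <- as.integer(strsplit(trimws(lines[ic]), "\\s+")[[1]][2:3])
  vals <- scan(text = lines[(ic + 1):length(lines)], n = hdr[2], quiet = TRUE)
  it <- ln("^CELL_TYPES")
  if (is.na(it)) .parse_error(path, ic, "no CELL_TYPES section")
  types <- scan(text = lines[(it + 1):length(lines)], n = hdr[1], quiet = TRUE)
  cells <- vector("list", hdr[1]); p <- 1L
  for (i in seq_len(hdr[1])) {
    cnt <- vals[p]
    cells[[i]] <- vals[(p + 1):(p + cnt)] + 1L
    p <- p + cnt + 1L
  }
  bad <- setdiff(unique(types), c(5, 10))
  if (length(bad)) {
    .parse_error(path, it, sprintf("unsupported cell type %s (only tetrahedra and triangles)",
                                   paste(bad, collapse = ", ")))
  }
  tets <- do.call(rbind, cells[types == 10])
  tris <- do.call(rbind, cells[types == 5])
  tri_id <- integer(0)
  id_at <- ln("SCALARS patch_id")
  if (!is.na(id_at) && any(types == 5)) {
    ids <- scan(text = lines[(id_at + 2):length(lines)], n = hdr[1], quiet = TRUE)
    tri_id <- ids[types == 5]
  } else if (any(types == 5)) {
    tri_id <- rep(1L, sum(types == 5))
  }
  list(nodes = nodes, tets = if (is.null(tets)) matrix(integer(0), 0, 4) else tets,
       tris = tris, tri_id = tri_id)
}

.read_msh <- function(path, lines) {
  sec <- function(tag) {
    i <- grep(paste0("^\\$", tag, "$"), lines)[1]
    j <- grep(paste0("^\\$End", tag, "$"), lines)[1]
    if (is.na(i) || is.na(j)) .parse_error(path, 1L, sprintf("missing $%s section", tag))
    c(i, j)
  }
  nd <- sec("Nodes")
  n <- as.integer(lines[nd[1] + 1])
  ntab <- utils::read.table(text = lines[(nd[1] + 2):(nd[2] - 1)])
  if (nrow(ntab) != n) .parse_error(path, nd[1], "node count mismatch")
  nodes <- as.matrix(ntab[order(ntab[[1]]), 2:4])
  dimnames(nodes) <- NULL
  el <- sec("Elements")
  k <- as.integer(lines[el[1] + 1])
  tets <- list(); tris <- list(); tri_id <- integer(0)
  for (li in (el[1] + 2):(el[2] - 1)) {
    v <- as.integer(strsplit(trimws(lines[li]), "\\s+")[[1]])
    type <- v[2]; ntag <- v[3]
    conn <- v[(4 + ntag):length(v)]
    if (type == 4) {
      tets[[length(tets) + 1L]] <- conn
    } else if (type == 2) {
      tris[[length(tris) + 1L]] <- conn
      tri_id <- c(tri_id, if (ntag >= 1) v[4] else 1L)
    } else {
      .parse_error(path, li, sprintf("unsupported element type %d", type))
    }
  }
  if (length(tets) + length(tris) != k) .parse_error(path, el[1], "element count mismatch")
  list(nodes = nodes, tets = if (length(tets)) do.call(rbind, tets) else matrix(integer(0), 0, 4),
       tris = if (length(tris)) do.call(rbind, tris), tri_id = tri_id)
}

# ---------------------------------------------------------------------------
# tables, config, reports

#' Write / read the muscle element table as CSV
#' @param elements element table ([gen_lower_limb()]`$elements`).
#' @param path CSV path.
#' @return the table (readers) or invisibly the path (writers).
#' @export
write_muscle_table <- function(elements, path) {
  utils::write.csv(elements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_muscle_table
#' @export
read_muscle_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "muscle", "slot", "origin_part", "ox", "oy", "oz",
            "insertion_part", "ix", "iy", "iz", "strength_N")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop(sprintf("muscle table %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  }
  tab
}

#' Write / read a gait table as CSV
#' @param gait list of gait positions ([gen_gait_table()]).
#' @param path CSV path.
#' @return gait list (reader) or invisibly the path (writer).
#' @export
write_gait_table <- function(gait, path) {
  rows <- lapply(gait, function(p) data.frame(
    index = p$index, pct_gait = p$pct_gait, knee_flexion = p$knee_flexion,
    grf_x = p$grf[1], grf_y = p$grf[2], grf_z = p$grf[3],
    cop_x = p$cop[1], cop_y = p$cop[2], cop_z = p$cop[3],
    thigh_ax = p$segment_accel$thigh[1], thigh_ay = p$segment_accel$thigh[2],
    thigh_az = p$segment_accel$thigh[3],
    legfoot_ax = p$segment_accel$leg_foot[1], legfoot_ay = p$segment_accel$leg_foot[2],
    legfoot_az = p$segment_accel$leg_foot[3],
    active_muscles = paste(p$active_muscles, collapse = ";")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_table
#' @export
read_gait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(
      index = r$index, pct_gait = r$pct_gait, knee_flexion = r$knee_flexion,
      grf = c(r$grf_x, r$grf_y, r$grf_z),
      cop = c(r$cop_x, r$cop_y, r$cop_z),
      segment_accel = list(thigh = c(r$thigh_ax, r$thigh_ay, r$thigh_az),
                           leg_foot = c(r$legfoot_ax, r$legfoot_ay, r$legfoot_az)),
      active_muscles = strsplit(r$active_muscles, ";")[[1]]
    ), class = "gait_position")
  })
}

#' Read a pipeline configuration from YAML
#'
#' Unset keys take the defaults ([default_config()]); unknown keys are
#' rejected; ranges are validated.
#'
#' @param path YAML file.
#' @return validated full configuration.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # yaml reads numeric vectors as lists at times; normalise leaves
  normalise <- function(x) {
    if (is.list(x) && length(x) && is.null(names(x)) &&
        all(vapply(x, is.numeric, TRUE))) {
      return(unlist(x))
    }
    if (is.list(x)) return(lapply(x, normalise))
    x
  }
  stance_config(normalise(raw))
}

#' Write a configuration to YAML
#' @param config configuration list.
#' @param path output file.
#' @return invisibly the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# required fields of a position report in the JSON schema
.report_fields <- c("position", "rb_hip_magnitude", "fe_hip_magnitude",
                    "relative_difference_pct", "stab_spring_resultant",
                    "max_total_deformation")

#' Write a validation report as JSON
#'
#' Serialises the per-position metrics and the criteria table; re-writing
#' the parsed report yields byte-identical output (stable field order).
#'
#' @param analysis a [run_stance_analysis()] result (or a list of position
#'   reports).
#' @param path output JSON file.
#' @return invisibly the path.
#' @export
write_report <- function(analysis, path) {
  reports <- if (inherits(analysis, "stance_analysis")) analysis$reports else analysis
  positions <- lapply(reports, function(r) {
    missing <- setdiff(.report_fields, names(r))
    if (length(missing)) {
      stop(sprintf("position report lacks fields: %s", paste(missing, collapse = ", ")))
    }
    list(position = r$position,
         rb_hip_N = r$rb_hip,
         rb_hip_magnitude_N = r$rb_hip_magnitude,
         fe_hip_N = r$fe_hip,
         fe_hip_magnitude_N = r$fe_hip_magnitude,
         relative_difference_pct = r$relative_difference_pct,
         stabilisation_spring_N = r$stab_spring_force,
         stabilisation_resultant_N = r$stab_spring_resultant,
         distal_tibia_displacement_mm = r$distal_tibia_disp,
         distal_tibia_total_mm = r$distal_tibia_total,
         elastic_remainder_mm = r$elastic_remainder_norm,
         max_total_deformation_mm = r$max_total_deformation,
         max_strain_per_part = r$max_strain_per_part)
  })
  out <- list(positions = positions)
  if (inherits(analysis, "stance_analysis")) {
    out$validation <- list(pass = analysis$validation$pass,
                           thresholds = analysis$validation$thresholds,
                           table = analysis$validation$table)
    out$seed <- analysis$seed
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read back a validation report
#' @param path JSON file from [write_report()].
#' @return parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
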