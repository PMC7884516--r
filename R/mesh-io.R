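#' Triangulated bone surface mesh
#'
#' Container for a triangulated surface in millimetre coordinates, as
#' exported by CT segmentation software.  On construction the mesh is
#' validated and (by default) cleaned: duplicate vertices are merged at a
#' 1e-6 mm tolerance and zero-area faces are dropped.  Cleaning is
#' idempotent.  Units are always millimetres and are never rescaled or
#' inferred from file headers.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param name bone label, one of `"femur"`, `"tibia"`, `"fibula"`,
#'   `"patella"`, or a free label.
#' @param clean merge duplicate vertices and drop degenerate faces.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
surface_mesh <- function(vertices, faces, name = "bone", clean = TRUE) {
  vertices <- as_point_matrix(vertices, "vertices")
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3, byrow = TRUE)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) stop("'faces' must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range for the vertex set", call. = FALSE)
  }
  if (clean) {
    # merge vertices that coincide within 1e-6 mm
    key <- paste(round(vertices[, 1], 6), round(vertices[, 2], 6), round(vertices[, 3], 6))
    uid <- match(key, key)
    remap <- match(uid, sort(unique(uid)))
    keep <- sort(unique(uid))
    vertices <- vertices[keep, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
    # drop faces with repeated indices or numerically zero area
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
    faces <- faces[!dup, , drop = FALSE]
    if (nrow(faces) > 0) {
      faces <- faces[face_areas(vertices, faces) > 1e-10, , drop = FALSE]
    }
  }
  if (nrow(vertices) < 4 || nrow(faces) < 4) {
    stop(sprintf("mesh '%s' must have at least 4 vertices and 4 faces after cleaning", name),
         call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces, %.1f mm^2 area>\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              sum(face_areas(x$vertices, x$faces))))
  invisible(x)
}

is_stl_ascii <- function(path) {
  head_raw <- readBin(path, "raw", n = 512)
  printable <- head_raw >= as.raw(0x09) & head_raw <= as.raw(0x7e)
  if (mean(printable) < 0.95) return(FALSE)  # binary payload
  txt <- tolower(rawToChar(head_raw[printable]))
  startsWith(trimws(txt), "solid") && grepl("facet", txt, fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop(sprintf("'%s' is not a readable ASCII STL (no complete facets)", path), call. = FALSE)
  }
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  v <- matrix(nums, ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(nt) || nt <= 0) stop(sprintf("'%s' is not a readable STL (zero facets)", path), call. = FALSE)
  raw <- readBin(con, "raw", n = 50 * nt)
  if (length(raw) < 50 * nt) stop(sprintf("'%s' is truncated (binary STL)", path), call. = FALSE)
  m <- matrix(raw, nrow = 50)
  vb <- as.vector(m[13:48, , drop = FALSE])
  floats <- readBin(vb, "numeric", size = 4, n = 9 * nt, endian = "little")
  per_tri <- matrix(floats, nrow = 9)
  v <- matrix(as.vector(per_tri), ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    stop(sprintf("'%s' is not a PLY file", path), call. = FALSE)
  }
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop(sprintf("'%s' has no PLY end_header", path), call. = FALSE)
  hdr <- trimws(lines[1:end_hdr])
  if (any(grepl("^format\\s+binary", hdr))) {
    stop(sprintf("'%s': binary PLY is not supported, export ASCII PLY or STL", path), call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex\\s", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face\\s", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop(sprintf("'%s' lacks vertex/face elements", path), call. = FALSE)
  body <- lines[(end_hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtxt <- body[seq_len(nv)]
  v <- matrix(scan(text = vtxt, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  ftxt <- body[nv + seq_len(nf)]
  flist <- lapply(strsplit(trimws(ftxt), "\\s+"), as.integer)
  tris <- lapply(flist, function(r) {
    k <- r[1]
    idx <- r[2:(k + 1)] + 1L  # PLY indices are 0-based
    if (k == 3) return(matrix(idx, 1, 3))
    # fan-triangulate larger polygons
    cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  })
  list(vertices = v, faces = do.call(rbind, tris))
}

#' Read a surface mesh from STL or PLY
#'
#' Reads a triangulated surface in STL (binary or ASCII) or ASCII PLY
#' format.  Coordinates are taken as millimetres.  The mesh is cleaned on
#' load (see [surface_mesh()]).
#'
#' @param path path to an `.stl` or `.ply` file.
#' @param label bone label stored in the mesh.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, label = "bone") {
  if (!file.exists(path)) stop(sprintf("mesh file '%s' does not exist", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw_mesh <- if (ext == "ply") {
    read_ply_ascii(path)
  } else if (is_stl_ascii(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  if (!all(is.finite(raw_mesh$vertices))) {
    stop(sprintf("mesh file '%s' contains non-finite coordinates", path), call. = FALSE)
  }
  surface_mesh(raw_mesh$vertices, raw_mesh$faces, name = label)
}

#' Write a surface mesh to STL or PLY
#'
#' ASCII STL or ASCII PLY, chosen by file extension.  PLY preserves the
#' shared-vertex topology and full double precision; STL writes unshared
#' triangles (the format has no shared vertices).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    v <- mesh$vertices
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(mesh$faces)),
             "property list uchar int vertex_indices", "end_header")
    vtxt <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    ftxt <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
    writeLines(c(hdr, vtxt, ftxt), path)
  } else {
    a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    n <- t(vapply(seq_len(nrow(a)), function(i) {
      nv <- cross3(b[i, ] - a[i, ], c_[i, ] - a[i, ])
      l <- vnorm(nv)
      if (l < 1e-12) c(0, 0, 0) else nv / l
    }, numeric(3)))
    body <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      n[, 1], n[, 2], n[, 3],
      a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
    writeLines(c(sprintf("solid %s", mesh$name), body, sprintf("endsolid %s", mesh$name)), path)
  }
  invisible(path)
}

#' Manually selected measurement landmarks for one leg
#'
#' The landmark set the 3D technique requires: nine points on the distal
#' articular surface (tibial plafond), eight points on the tibial plateau,
#' the knee and ankle joint centres, and one anterior reference point
#' (patella centroid or tibial tuberosity).  The ankle centre defaults to
#' the centroid of the nine distal articular points.
#'
#' @param distal_articular 9 x 3 matrix (mm), points on the plafond.
#' @param plateau 8 x 3 matrix (mm), points on the tibial plateau.
#' @param knee_center length-3 point (mm).
#' @param anterior_ref length-3 point marking the anterior direction.
#' @param ankle_center optional length-3 point; default plafond centroid.
#' @param side `"left"` or `"right"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(distal_articular, plateau, knee_center, anterior_ref,
                         ankle_center = NULL, side = c("right", "left")) {
  side <- match.arg(side)
  distal_articular <- as_point_matrix(distal_articular, "distal_articular")
  plateau <- as_point_matrix(plateau, "plateau")
  if (nrow(distal_articular) != 9) {
    stop(sprintf("landmark field 'distal_articular' must contain exactly 9 points, got %d",
                 nrow(distal_articular)), call. = FALSE)
  }
  if (nrow(plateau) != 8) {
    stop(sprintf("landmark field 'plateau' must contain exactly 8 points, got %d",
                 nrow(plateau)), call. = FALSE)
  }
  knee_center <- as.numeric(knee_center)
  anterior_ref <- as.numeric(anterior_ref)
  if (length(knee_center) != 3 || !all(is.finite(knee_center))) {
    stop("landmark field 'knee_center' must be one finite 3D point", call. = FALSE)
  }
  if (length(anterior_ref) != 3 || !all(is.finite(anterior_ref))) {
    stop("landmark field 'anterior_ref' must be one finite 3D point", call. = FALSE)
  }
  if (is.null(ankle_center)) {
    ankle_center <- colMeans(distal_articular)
  } else {
    ankle_center <- as.numeric(ankle_center)
    if (length(ankle_center) != 3 || !all(is.finite(ankle_center))) {
      stop("landmark field 'ankle_center' must be one finite 3D point", call. = FALSE)
    }
  }
  structure(list(distal_articular = distal_articular, plateau = plateau,
                 knee_center = knee_center, ankle_center = ankle_center,
                 anterior_ref = anterior_ref, side = side),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: side %s, 9 plafond + 8 plateau points>\n", x$side))
  invisible(x)
}

#' Read a landmark file (JSON)
#'
#' One JSON document per leg with fields `side`, `distal_articular`
#' (9 points), `plateau` (8 points), `knee_center`, `anterior_ref` and
#' optionally `ankle_center`; coordinates in millimetres.
#'
#' @param path path to the landmark JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file '%s' does not exist", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("side", "distal_articular", "plateau", "knee_center", "anterior_ref")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop(sprintf("landmark file '%s' lacks required field(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!j$side %in% c("left", "right")) {
    stop(sprintf("landmark field 'side' must be \"left\" or \"right\", got \"%s\"", j$side),
         call. = FALSE)
  }
  landmark_set(distal_articular = j$distal_articular, plateau = j$plateau,
               knee_center = unlist(j$knee_center), anterior_ref = unlist(j$anterior_ref),
               ankle_center = if (!is.null(j$ankle_center)) unlist(j$ankle_center) else NULL,
               side = j$side)
}

#' Write a landmark file (JSON)
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(side = landmarks$side,
              distal_articular = unname(apply(landmarks$distal_articular, 1, as.list)),
              plateau = unname(apply(landmarks$plateau, 1, as.list)),
              knee_center = landmarks$knee_center,
              ankle_center = landmarks$ankle_center,
              anterior_ref = landmarks$anterior_ref)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundle of bones and landmarks for one measurement
#'
#' Collects the meshes a measurement needs.  The tibia is always required;
#' the femur is required for the 3D proximal axis; the fibula is required
#' for the 3D-TF variant and for both 2D methods.  Landmark proximity to
#' the tibia surface is validated (5 mm for bone landmarks, 60 mm for the
#' anterior reference).
#'
#' @param tibia,femur,fibula [surface_mesh()] objects (`femur`, `fibula`
#'   optional).
#' @param landmarks a [landmark_set()].
#' @param check_proximity validate landmark distance to the tibia surface.
#' @return An object of class `bone_set`.
#' @export
bone_set <- function(tibia, femur = NULL, fibula = NULL, landmarks,
                     check_proximity = TRUE) {
  stopifnot(inherits(tibia, "surface_mesh"), inherits(landmarks, "landmark_set"))
  if (!is.null(femur)) stopifnot(inherits(femur, "surface_mesh"))
  if (!is.null(fibula)) stopifnot(inherits(fibula, "surface_mesh"))
  if (check_proximity) {
    pts <- rbind(landmarks$distal_articular, landmarks$plateau,
                 landmarks$knee_center, landmarks$ankle_center)
    cp <- closest_surface_points(point_set(pts), tibia)
    d <- sqrt(rowSums((pts - cp$points)^2))
    if (any(d > 5)) {
      stop(sprintf("landmark validation: %d bone landmark(s) lie farther than 5 mm from the tibia surface (max %.1f mm)",
                   sum(d > 5), max(d)), call. = FALSE)
    }
    da <- sqrt(rowSums((matrix(landmarks$anterior_ref, 1, 3) -
                          closest_surface_points(point_set(matrix(landmarks$anterior_ref, 1, 3)), tibia)$points)^2))
    if (da > 60) {
      stop(sprintf("landmark validation: anterior_ref lies %.1f mm from the tibia surface (limit 60 mm)", da),
           call. = FALSE)
    }
  }
  structure(list(tibia = tibia, femur = femur, fibula = fibula, landmarks = landmarks),
            class = "bone_set")
}

#' @export
print.bone_set <- function(x, ...) {
  have <- c("tibia", if (!is.null(x$femur)) "femur", if (!is.null(x$fibula)) "fibula")
  cat(sprintf("<bone_set: %s; side %s>\n", paste(have, collapse = " + "), x$landmarks$side))
  invisible(x)
}

#' Read a rater/method measurement table (CSV)
#'
#' First column: subject identifier; remaining columns: one measurement
#' column per rater or method, in degrees.  Complete cases are required;
#' any missing cell is an error naming its row and column.
#'
#' @param path CSV path with a header row.
#' @return A `rater_table`: list with `values` (n x k matrix), `subject_ids`
#'   and `rater_ids`.
#' @export
read_rater_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("table file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3) stop("rater table needs a subject column plus at least 2 rater columns", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("rater table '%s' has a missing cell at subject '%s', column '%s'",
                 path, df[[1]][bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  rater_table(vals, subject_ids = as.character(df[[1]]), rater_ids = colnames(vals))
}

#' Construct a rater table from a matrix
#' @param values n x k numeric matrix of measurements (degrees).
#' @param subject_ids,rater_ids optional labels.
#' @return A `rater_table` object.
#' @export
rater_table <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("rater table needs at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("rater table must be complete (no missing cells)", call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(values)))
  if (is.null(rater_ids)) rater_ids <- paste0("rater", seq_len(ncol(values)))
  structure(list(values = values, subject_ids = subject_ids, rater_ids = rater_ids),
            class = "rater_table")
}

axis_to_list <- function(a) list(point = as.numeric(a$point), direction = as.numeric(a$direction))

#' Write a torsion result or comparison table
#'
#' A single [torsion_result] is written as a JSON report containing the
#' angle, variant, sign convention, every intermediate axis (point +
#' direction), diagnostics, the software version and, when supplied, input
#' file checksums.  A data frame is written as CSV with a header row.
#'
#' @param result a `torsion_result` or a data frame.
#' @param path output path.
#' @param checksums optional named character vector of input md5 sums.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, checksums = NULL) {
  if (is.data.frame(result)) {
    utils::write.csv(result, path, row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(result, "torsion_result"))
  axes <- list()
  for (nm in c("pta", "dta", "anatomical_axis")) {
    if (!is.null(result[[nm]])) axes[[nm]] <- axis_to_list(result[[nm]])
  }
  obj <- list(
    angle_deg = result$angle,
    variant = result$variant,
    sign_convention = "external rotation of the distal segment positive; +x lateral, +y proximal, +z anterior; left sides mirrored before alignment",
    axes = axes,
    frame = if (!is.null(result$frame)) {
      list(rotation = result$frame$rotation, translation = result$frame$translation,
           side_mirrored = result$frame$side_mirrored)
    },
    diagnostics = result$diagnostics,
    software = list(package = "tibtor",
                    version = as.character(utils::packageVersion("tibtor"))),
    input_checksums = as.list(checksums)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
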