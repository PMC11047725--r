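# File I/O for point clouds (XYZ, PLY) and triangle meshes (PLY, OBJ).
# PLY is supported in ASCII and binary little-endian form; writes default to
# ASCII so round-trip fixtures stay text-only. OBJ indices are 1-based on
# disk and internally; PLY's 0-based face indices are converted at this
# boundary.

PLY_TYPE_SIZE <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  switch(type,
    char = , int8 = readBin(con, "integer", n, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", n, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", n, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", n, size = 4L, endian = "little"),
    float = , float32 = readBin(con, "numeric", n, size = 4L, endian = "little"),
    double = , float64 = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop(sprintf("unsupported PLY property type '%s'", type))
  )
}

parse_ply_header <- function(lines) {
  if (length(lines) < 2L || trimws(lines[1]) != "ply") {
    stop("not a PLY file: missing 'ply' magic line")
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  i <- 2L
  repeat {
    if (i > length(lines)) stop("malformed PLY header: no end_header")
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") {
      i <- i + 1L
      next
    }
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(),
                  list_count_type = character())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before element")
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, tok[4])
        cur$list_count_type <- c(cur$list_count_type, tok[3])
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$list_count_type <- c(cur$list_count_type, NA_character_)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
    i <- i + 1L
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("unsupported PLY format '%s'", fmt %||% "<missing>"))
  }
  list(format = fmt, elements = elements, header_lines = i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # locate the end of the header so the binary payload offset is exact
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  lines <- character()
  for (p in nl) {
    ln <- rawToChar(raw[seq.int(prev + 1L, p - 1L)])
    ln <- sub("\r$", "", ln)
    lines <- c(lines, ln)
    prev <- p
    if (trimws(ln) == "end_header") {
      hdr_end <- p
      break
    }
    if (length(lines) > 1000L) break
  }
  if (is.na(hdr_end)) stop("malformed PLY header: no end_header")
  hdr <- parse_ply_header(lines)
  payload <- if (hdr_end < length(raw)) {
    raw[seq.int(hdr_end + 1L, length(raw))]
  } else raw(0)
  con <- rawConnection(payload, "r")
  on.exit(close(con))
  out <- list(vertices = NULL, normals = NULL, faces = NULL)
  if (hdr$format == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    for (el in hdr$elements) {
      if (el$count == 0L) next
      take <- body[seq_len(el$count) + pos]
      pos <- pos + el$count
      if (el$name == "vertex") {
        vals <- lapply(strsplit(trimws(take), "[[:space:]]+"), as.numeric)
        nprop <- length(el$props)
        bad <- which(vapply(vals, length, 0L) != nprop |
                       vapply(vals, anyNA, TRUE))
        if (length(bad)) {
          stop(sprintf("parse error in PLY vertex record %d", bad[1]))
        }
        m <- do.call(rbind, vals)
        colnames(m) <- el$props
        out <- ply_collect_vertices(out, m)
      } else if (el$name == "face") {
        out$faces <- parse_face_lines(take, "PLY")
      }
    }
  } else {
    for (el in hdr$elements) {
      if (el$count == 0L) next
      if (el$name == "vertex" && all(is.na(el$list_count_type))) {
        nprop <- length(el$props)
        if (length(unique(el$types)) == 1L) {
          vals <- ply_read_scalar(con, el$types[1], el$count * nprop)
          m <- matrix(vals, ncol = nprop, byrow = TRUE)
        } else {
          m <- matrix(0, el$count, nprop)
          for (r in seq_len(el$count)) {
            for (cix in seq_len(nprop)) {
              m[r, cix] <- ply_read_scalar(con, el$types[cix], 1L)
            }
          }
        }
        colnames(m) <- el$props
        out <- ply_collect_vertices(out, m)
      } else if (el$name == "face") {
        faces <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          nv <- ply_read_scalar(con, el$list_count_type[1], 1L)
          idx <- ply_read_scalar(con, el$types[1], nv)
          faces[[r]] <- idx
        }
        out$faces <- triangulate_polygons(faces, "PLY")
      } else {
        # skip unknown fixed-size element
        sizes <- PLY_TYPE_SIZE[el$types]
        if (anyNA(sizes)) stop("cannot skip PLY element with list properties")
        invisible(readBin(con, "raw", el$count * sum(sizes)))
      }
    }
  }
  out
}

ply_collect_vertices <- function(out, m) {
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(m))) stop("PLY vertex element lacks x/y/z")
  out$vertices <- m[, need, drop = FALSE]
  if (all(c("nx", "ny", "nz") %in% colnames(m))) {
    out$normals <- m[, c("nx", "ny", "nz"), drop = FALSE]
  }
  out
}

# face records given as integer vectors (0-based); quads fan-split, higher
# polygons rejected
triangulate_polygons <- function(faces, what) {
  nvert <- vapply(faces, length, 0L)
  if (any(nvert < 3L | nvert > 4L)) {
    stop(sprintf("%s face with %d vertices: only triangles and quads supported",
                 what, nvert[which(nvert < 3L | nvert > 4L)[1]]))
  }
  tris <- lapply(faces, function(f) {
    if (length(f) == 3L) matrix(f, 1L) else rbind(f[c(1, 2, 3)], f[c(1, 3, 4)])
  })
  do.call(rbind, tris) + 1L
}

parse_face_lines <- function(lines, what) {
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  faces <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.integer(toks[[i]]))
    if (anyNA(v) || length(v) < 2L || v[1] != length(v) - 1L) {
      stop(sprintf("parse error in %s face record %d", what, i))
    }
    v[-1]
  })
  triangulate_polygons(faces, what)
}

guess_format <- function(path, kinds) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% kinds) ext else kinds[1]
}

#' Read a point cloud from disk
#'
#' @param path file path.
#' @param format `"xyz"` (whitespace-delimited `x y z [nx ny nz]` text),
#'   `"ply"` (ASCII or binary little-endian), or `"auto"` to infer from the
#'   file extension.
#' @return a [point_cloud()]; normals are populated (and renormalized) when
#'   the file carries `nx/ny/nz` fields.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") format <- guess_format(path, c("xyz", "ply"))
  if (format == "xyz") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty XYZ file")
    vals <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(x)
      suppressWarnings(as.numeric(x)))
    nc <- vapply(vals, length, 0L)
    bad <- which(!(nc %in% c(3L, 6L)) | vapply(vals, anyNA, TRUE))
    if (length(bad)) {
      stop(sprintf("parse error in XYZ line %d: expected 3 or 6 numbers",
                   bad[1]))
    }
    if (length(unique(nc)) != 1L) stop("mixed 3- and 6-column XYZ records")
    m <- do.call(rbind, vals)
    point_cloud(m[, 1:3, drop = FALSE],
                normals = if (ncol(m) == 6L) m[, 4:6, drop = FALSE])
  } else {
    p <- read_ply(path)
    point_cloud(p$vertices, normals = p$normals)
  }
}

#' Write a point cloud to disk
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"xyz"`, `"ply"` or `"auto"` (from extension).
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return the path, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "ply"),
                              binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("xyz", "ply"))
  m <- cloud$points
  if (!is.null(cloud$normals)) m <- cbind(m, cloud$normals)
  if (format == "xyz") {
    txt <- apply(m, 1L, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
    writeLines(txt, path)
  } else {
    write_ply(path, vertices = cloud$points, normals = cloud$normals,
              faces = NULL, binary = binary)
  }
  invisible(path)
}

write_ply <- function(path, vertices, normals = NULL, faces = NULL,
                      binary = FALSE) {
  props <- c("x", "y", "z")
  m <- vertices
  if (!is.null(normals)) {
    props <- c(props, "nx", "ny", "nz")
    m <- cbind(m, normals)
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(m)),
           sprintf("property float %s", props))
  if (!is.null(faces)) {
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  }
  hdr <- c(hdr, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    if (!is.null(faces)) {
      f0 <- t(faces) - 1L
      for (i in seq_len(ncol(f0))) {
        writeBin(3L, con, size = 1L, endian = "little")
        writeBin(f0[, i], con, size = 4L, endian = "little")
      }
    }
  } else {
    body <- apply(m, 1L, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
    if (!is.null(faces)) {
      body <- c(body, paste(3L, faces[, 1] - 1L, faces[, 2] - 1L,
                            faces[, 3] - 1L))
    }
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a triangle mesh from disk
#'
#' Quadrilateral faces are fan-split into two triangles; polygons with more
#' than four vertices are rejected.
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"auto"` (from extension).
#' @return a [triangle_mesh()] with the on-disk face orientation preserved.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") format <- guess_format(path, c("ply", "obj"))
  if (format == "ply") {
    p <- read_ply(path)
    if (is.null(p$faces)) stop("PLY file carries no face element")
    triangle_mesh(p$vertices, p$faces)
  } else {
    lines <- readLines(path)
    vlines <- grep("^v[[:space:]]", lines, value = TRUE)
    flines <- grep("^f[[:space:]]", lines, value = TRUE)
    if (length(vlines) == 0L || length(flines) == 0L) {
      stop("OBJ file lacks v/f records")
    }
    verts <- t(vapply(strsplit(trimws(sub("^v", "", vlines)),
                               "[[:space:]]+"),
                      function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
    if (anyNA(verts)) {
      stop(sprintf("parse error in OBJ vertex record %d",
                   which(apply(is.na(verts), 1L, any))[1]))
    }
    faces <- lapply(seq_along(flines), function(i) {
      tok <- strsplit(trimws(sub("^f", "", flines[i])), "[[:space:]]+")[[1]]
      tok <- tok[tok != ""]
      idx <- suppressWarnings(as.integer(sub("/.*", "", tok)))
      if (anyNA(idx)) stop(sprintf("parse error in OBJ face record %d", i))
      idx - 1L  # triangulate_polygons converts back to 1-based
    })
    triangle_mesh(verts, triangulate_polygons(faces, "OBJ"))
  }
}

#' Write a triangle mesh to disk
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"auto"` (from extension).
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("ply", "obj"))
  if (format == "ply") {
    write_ply(path, vertices = mesh$vertices, faces = mesh$faces,
              binary = binary)
  } else {
    v <- apply(mesh$vertices, 1L, function(r)
      paste("v", paste(format(r, digits = 9, trim = TRUE,
                              scientific = FALSE), collapse = " ")))
    f <- paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
    writeLines(c(v, f), path)
  }
  invisible(path)
}
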