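# Mesh file I/O: PLY (ascii + binary little-endian), OBJ, STL (ascii +
# binary). Vertex indices are 0-based in PLY/STL files and 1-based in OBJ;
# internally everything is 1-based.

format_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim where shorter representations round-trip exactly
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

detect_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "obj", "stl"))
    stop("cannot detect mesh format from extension '", ext,
         "'; pass format= explicitly", call. = FALSE)
  ext
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' Reads the common surface-scan interchange formats. Polygonal faces (OBJ,
#' PLY) are fan-triangulated; OBJ's 1-based indices are kept, PLY/STL's
#' 0-based indices converted on load. STL files carry no connectivity, so
#' their per-facet corners are welded by exact coordinate equality; PLY and
#' OBJ vertices are never welded implicitly. Vertices referenced by no face
#' are dropped.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"ply"`, `"obj"` or `"stl"`.
#' @return A [trimesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read mesh: no such file: ", path, call. = FALSE)
  format <- detect_format(path, format)
  m <- switch(format,
              ply = read_ply(path),
              obj = read_obj(path),
              stl = read_stl(path))
  if (nrow(m$vertices) == 0L || nrow(m$faces) == 0L)
    stop("empty mesh: ", path, call. = FALSE)
  drop_unreferenced(m)
}

drop_unreferenced <- function(m) {
  used <- sort(unique(as.vector(m$faces)))
  if (length(used) == nrow(m$vertices)) return(m)
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  trimesh(m$vertices[used, , drop = FALSE],
          matrix(remap[m$faces], ncol = 3L))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a nonempty [trimesh()].
#' @param path file to write.
#' @param format `"auto"` (by extension), `"ply"`, `"obj"` or `"stl"`.
#' @param binary write the binary flavour (PLY little-endian or binary STL);
#'   ignored for OBJ, which is text-only.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl"),
                       binary = FALSE) {
  format <- match.arg(format)
  stopifnot_mesh(mesh)
  format <- detect_format(path, format)
  switch(format,
         ply = write_ply(mesh, path, binary),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary))
  invisible(path)
}

## ---------------------------------------------------------------- PLY ----

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(con, type, n) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", n = n, size = sz, endian = "little")
  else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = n, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end_header line in the byte stream
  marker <- charToRaw("end_header")
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    if (startsWith(trimws(line), "end_header")) { hdr_end <- pos; break }
    start <- pos + 1L
  }
  if (is.na(hdr_end))
    stop("malformed PLY header (no end_header) in ", path, call. = FALSE)
  hdr_lines <- strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\r?\n")[[1L]]
  if (!identical(trimws(hdr_lines[1L]), "ply"))
    stop("malformed PLY (missing magic) in ", path, call. = FALSE)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props=list(name,type,list?))
  for (line in hdr_lines[-1L]) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element")
      elements[[length(elements) + 1L]] <-
        list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    else if (tok[1L] == "property") {
      i <- length(elements)
      if (i == 0L) stop("malformed PLY header: property before element",
                        call. = FALSE)
      p <- if (tok[2L] == "list")
        list(name = tok[5L], type = tok[4L], count_type = tok[3L],
             list = TRUE)
      else list(name = tok[3L], type = tok[2L], list = FALSE)
      elements[[i]]$props <- c(elements[[i]]$props, list(p))
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt)) stop("malformed PLY: no format line", call. = FALSE)
  if (fmt == "binary_big_endian")
    stop("big-endian PLY not supported: ", path, call. = FALSE)
  ascii <- fmt == "ascii"
  payload <- raw[seq.int(hdr_end + 1L, length.out = length(raw) - hdr_end)]

  verts <- NULL; faces <- NULL
  if (ascii) {
    rest <- strsplit(rawToChar(payload), "\r?\n")[[1L]]
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    for (el in elements) {
      if (el$count == 0L) {
        if (el$name == "vertex") verts <- matrix(numeric(0), 0L, 3L)
        next
      }
      block <- rest[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        fields <- strsplit(trimws(block), "\\s+")
        bad <- vapply(fields, length, 0L) < length(nm)
        if (any(bad))
          stop("malformed PLY vertex record ", which(bad)[1L], " in ", path,
               call. = FALSE)
        num <- matrix(suppressWarnings(
          as.numeric(unlist(lapply(fields, `[`, seq_along(nm))))),
                      ncol = length(nm), byrow = TRUE)
        verts <- num[, match(c("x", "y", "z"), nm), drop = FALSE]
        if (anyNA(verts))
          stop("malformed PLY vertex data in ", path, call. = FALSE)
      } else if (el$name == "face") {
        faces <- ply_faces_from_ascii(block, path)
      }
    }
  } else {
    con <- rawConnection(payload, "rb")
    on.exit(close(con))
    for (el in elements) {
      if (el$count == 0L) {
        if (el$name == "vertex") verts <- matrix(numeric(0), 0L, 3L)
        next
      }
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        tp <- vapply(el$props, `[[`, "", "type")
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          stop("list property on PLY vertex element not supported",
               call. = FALSE)
        cols <- matrix(NA_real_, el$count, length(nm))
        for (i in seq_len(el$count))
          for (k in seq_along(nm))
            cols[i, k] <- ply_read_bin(con, tp[k], 1L)
        verts <- cols[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1L]]
        tris <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          k <- ply_read_bin(con, p$count_type, 1L)
          idx <- ply_read_bin(con, p$type, k)
          tris[[i]] <- fan_triangulate(idx + 1L)
        }
        faces <- do.call(rbind, tris)
      } else {
        # skip unknown element payload
        for (i in seq_len(el$count))
          for (p in el$props) {
            if (isTRUE(p$list)) {
              k <- ply_read_bin(con, p$count_type, 1L)
              ply_read_bin(con, p$type, k)
            } else ply_read_bin(con, p$type, 1L)
          }
      }
    }
  }
  if (is.null(verts)) stop("PLY has no vertex element: ", path, call. = FALSE)
  if (nrow(verts) == 0L) stop("empty mesh: ", path, call. = FALSE)
  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  trimesh(verts, faces)
}

ply_faces_from_ascii <- function(block, path) {
  fields <- strsplit(trimws(block), "\\s+")
  tris <- lapply(seq_along(fields), function(i) {
    f <- suppressWarnings(as.integer(fields[[i]]))
    if (anyNA(f) || length(f) < 4L || f[1L] != length(f) - 1L)
      stop("malformed PLY face record ", i, " in ", path, call. = FALSE)
    fan_triangulate(f[-1L] + 1L)
  })
  do.call(rbind, tris)
}

fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n < 3L) stop("face with fewer than 3 vertices", call. = FALSE)
  if (n == 3L) return(matrix(idx, 1L, 3L))
  cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else
             "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(format_num(v[, 1L]), format_num(v[, 2L]),
                     format_num(v[, 3L])), con)
    writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  }
}

## ---------------------------------------------------------------- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  vfields <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vfields, function(x) as.numeric(x[1:3]), numeric(3L)))
  if (length(vfields) && anyNA(verts))
    stop("malformed OBJ vertex record in ", path, call. = FALSE)
  tris <- lapply(seq_along(flines), function(i) {
    toks <- strsplit(sub("^f\\s+", "", flines[[i]]), "\\s+")[[1L]]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", toks)))
    if (anyNA(idx) || length(idx) < 3L)
      stop("malformed OBJ face record ", i, " in ", path, call. = FALSE)
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    fan_triangulate(idx)
  })
  faces <- if (length(tris)) do.call(rbind, tris) else
    matrix(integer(0), 0L, 3L)
  trimesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(paste("v", format_num(v[, 1L]), format_num(v[, 2L]),
                   format_num(v[, 3L])), con)
  writeLines(paste("f", f[, 1L], f[, 2L], f[, 3L]), con)
}

## ---------------------------------------------------------------- STL ----

read_stl <- function(path) {
  # binary unless the file begins with "solid" and parses as ascii
  head <- readBin(path, "raw", n = 5L)
  is_ascii <- identical(rawToChar(head), "solid")
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- lines[startsWith(lines, "vertex")]
    if (length(vlines) > 0L) {
      coords <- strsplit(sub("^vertex\\s+", "", vlines), "\\s+")
      v <- t(vapply(coords, function(x) as.numeric(x[1:3]), numeric(3L)))
      if (anyNA(v) || nrow(v) %% 3L != 0L)
        stop("malformed ASCII STL in ", path, call. = FALSE)
      return(weld_stl(v))
    }
    # "solid" header but no ascii vertices: fall through to binary
  }
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(ntri) || sz < 84 + 50 * ntri)
    stop("malformed binary STL (truncated) in ", path, call. = FALSE)
  v <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    v[3L * i - 2L, ] <- rec[4:6]
    v[3L * i - 1L, ] <- rec[7:9]
    v[3L * i, ] <- rec[10:12]
  }
  weld_stl(v)
}

# weld per-facet corners by exact coordinate equality
weld_stl <- function(v) {
  key <- paste(sprintf("%.17g", v[, 1L]), sprintf("%.17g", v[, 2L]),
               sprintf("%.17g", v[, 3L]))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- v[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], a[i, ], b[i, ], cc[i, ]), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid phenomesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        paste("facet normal", paste(format_num(nrm[i, ]), collapse = " ")),
        "  outer loop",
        paste("    vertex", paste(format_num(a[i, ]), collapse = " ")),
        paste("    vertex", paste(format_num(b[i, ]), collapse = " ")),
        paste("    vertex", paste(format_num(cc[i, ]), collapse = " ")),
        "  endloop",
        "endfacet"), con)
    }
    writeLines("endsolid phenomesh", con)
  }
}
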