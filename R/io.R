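#' @include mesh-core.R
NULL

nfLog <- function(..., level = 1) {
  if (getOption("neurofold.verbose", 1) >= level)
    message("[neurofold] ", ...)
}

#' Set package logging verbosity
#' @param level 0 silences progress messages, higher values increase detail.
#' @export
setVerbosity <- function(level = 1) {
  options(neurofold.verbose = level)
  invisible(level)
}

formatExt <- function(path) tolower(sub(".*\\.", "", path))

guessFormat <- function(path, formatHint = NULL) {
  if (!is.null(formatHint)) return(tolower(formatHint))
  ext <- formatExt(path)
  if (ext == "gii") return("gifti")
  ext
}

#' Read a triangulated surface mesh
#'
#' Supported formats: OFF, PLY (ASCII), STL (ASCII), VTK (legacy ASCII
#' POLYDATA) and GIFTI (.surf.gii; ASCII, Base64Binary or GZipBase64Binary
#' encodings). Coordinates are taken to be millimetres. Vertex/face counts
#' and manifoldness diagnostics are reported through the package logger.
#'
#' @param path file to read.
#' @param formatHint optional format override ("off", "ply", "stl", "vtk",
#'   "gifti").
#' @return a \linkS4class{SurfaceMesh}; diagnostics are attached as
#'   attribute \code{"diagnostics"}.
#' @export
readSurface <- function(path, formatHint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- guessFormat(path, formatHint)
  mesh <- switch(fmt,
    off = readOFF(path),
    ply = readPLY(path),
    stl = readSTL(path),
    vtk = readVTKPolydata(path),
    gifti = readGIFTI(path),
    stop("unknown surface format: ", fmt))
  if (nFaces(mesh) == 0) stop("empty mesh: ", path)
  diag <- meshDiagnostics(mesh)
  nfLog(sprintf("read %s: %d vertices, %d faces (closed=%s manifold=%s)",
                basename(path), nVertices(mesh), nFaces(mesh),
                diag$closed, diag$manifold))
  attr(mesh, "diagnostics") <- diag
  mesh
}

#' Write a triangulated surface mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output file; format chosen from the extension unless
#'   \code{format} is given.
#' @param format optional format override.
#' @return the path, invisibly.
#' @export
writeSurface <- function(mesh, path, format = NULL) {
  fmt <- guessFormat(path, format)
  switch(fmt,
    off = writeOFF(mesh, path),
    ply = writePLY(mesh, path),
    stl = writeSTL(mesh, path),
    vtk = writeVTKPolydata(mesh, path),
    gifti = writeGIFTI(mesh, path),
    stop("unknown surface format: ", fmt))
  invisible(path)
}

numFmt <- function(x) formatC(x, format = "g", digits = 12)

# ---- OFF --------------------------------------------------------------------

readOFF <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: ", path)
  hdr <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vv <- matrix(as.numeric(unlist(strsplit(ln[3:(2 + nv)], "\\s+"))),
               nv, 3, byrow = TRUE)
  if (nf > 0) {
    fl <- strsplit(ln[(3 + nv):(2 + nv + nf)], "\\s+")
    ff <- t(vapply(fl, function(x) {
      x <- as.integer(x)
      if (x[1] != 3) stop("only triangle faces supported")
      x[2:4] + 1L
    }, integer(3)))
  } else ff <- matrix(integer(0), 0, 3)
  SurfaceMesh(vv, ff)
}

writeOFF <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(v), nrow(f), 0), con)
  writeLines(paste(numFmt(v[, 1]), numFmt(v[, 2]), numFmt(v[, 3])), con)
  if (nrow(f))
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# ---- PLY (ASCII) ------------------------------------------------------------

readPLY <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (ln[1] != "ply") stop("not a PLY file: ", path)
  endHdr <- which(ln == "end_header")[1]
  hdr <- ln[seq_len(endHdr)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  body <- ln[(endHdr + 1):length(ln)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vv <- t(vapply(vparts, function(x) as.numeric(x[1:3]), numeric(3)))
  if (is.na(nf) || nf == 0) {
    ff <- matrix(integer(0), 0, 3)
  } else {
    fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    ff <- t(vapply(fparts, function(x) {
      x <- as.integer(x)
      if (x[1] != 3) stop("only triangle faces supported")
      x[2:4] + 1L
    }, integer(3)))
  }
  SurfaceMesh(vv, ff)
}

writePLY <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y",
               "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(numFmt(v[, 1]), numFmt(v[, 2]), numFmt(v[, 3])), con)
  if (nrow(f))
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# ---- STL (ASCII) ------------------------------------------------------------

readSTL <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  if (!startsWith(ln[1], "solid")) stop("only ASCII STL supported")
  vlines <- grep("^vertex ", ln, value = TRUE)
  if (!length(vlines)) stop("empty mesh: no facets in STL")
  coords <- matrix(as.numeric(unlist(strsplit(sub("^vertex\\s+", "", vlines),
                                              "\\s+"))),
                   ncol = 3, byrow = TRUE)
  # weld identical vertices (STL stores them per facet)
  key <- apply(coords, 1, function(r) paste(formatC(r, format = "g",
                                                    digits = 12),
                                            collapse = "_"))
  uid <- !duplicated(key)
  vv <- coords[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  ff <- matrix(idx, ncol = 3, byrow = TRUE)
  SurfaceMesh(vv, ff)
}

writeSTL <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- vecCross(b - a, c_ - a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid neurofold", con)
  tx <- character(7 * nrow(f))
  for (i in seq_len(nrow(f))) {
    o <- 7 * (i - 1)
    tx[o + 1] <- paste("facet normal", paste(numFmt(n[i, ]), collapse = " "))
    tx[o + 2] <- "  outer loop"
    tx[o + 3] <- paste("    vertex", paste(numFmt(a[i, ]), collapse = " "))
    tx[o + 4] <- paste("    vertex", paste(numFmt(b[i, ]), collapse = " "))
    tx[o + 5] <- paste("    vertex", paste(numFmt(c_[i, ]), collapse = " "))
    tx[o + 6] <- "  endloop"
    tx[o + 7] <- "endfacet"
  }
  writeLines(tx, con)
  writeLines("endsolid neurofold", con)
}

# ---- VTK legacy -------------------------------------------------------------

readVTKPolydata <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!any(grepl("ASCII", ln[1:5])))
    stop("only ASCII legacy VTK supported")
  pi_ <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[pi_], "\\s+")[[1]][2])
  # points may be wrapped arbitrarily; collect until 3*np numbers
  acc <- c(); i <- pi_ + 1
  while (length(acc) < 3 * np) {
    acc <- c(acc, as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  vv <- matrix(acc[seq_len(3 * np)], np, 3, byrow = TRUE)
  ci <- grep("^POLYGONS", ln)[1]
  if (is.na(ci)) stop("VTK file has no POLYGONS section")
  hdr <- as.integer(strsplit(ln[ci], "\\s+")[[1]][2:3])
  nf <- hdr[1]
  acc <- c(); i <- ci + 1
  while (length(acc) < hdr[2]) {
    acc <- c(acc, as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  ff <- matrix(0L, nf, 3)
  pos <- 1
  for (k in seq_len(nf)) {
    cnt <- acc[pos]
    if (cnt != 3) stop("only triangle faces supported")
    ff[k, ] <- acc[(pos + 1):(pos + 3)] + 1L
    pos <- pos + cnt + 1
  }
  SurfaceMesh(vv, ff)
}

writeVTKPolydata <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "neurofold surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "double")), con)
  writeLines(paste(numFmt(v[, 1]), numFmt(v[, 2]), numFmt(v[, 3])), con)
  writeLines(paste("POLYGONS", nrow(f), 4 * nrow(f)), con)
  if (nrow(f))
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

#' Write a bilayer tetrahedral mesh as legacy VTK
#'
#' Unstructured grid with per-cell region labels (1 = cortex, 2 = white)
#' and optional per-cell scalars.
#'
#' @param bilayer a \linkS4class{BilayerTetMesh}.
#' @param path output .vtk path.
#' @param nodes optional deformed node positions.
#' @param cellData optional named list of per-element numeric vectors.
#' @return the path, invisibly.
#' @export
writeTetMeshVTK <- function(bilayer, path, nodes = NULL, cellData = list()) {
  if (is.null(nodes)) nodes <- bilayer@nodes
  tt <- bilayer@tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "neurofold bilayer", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(nodes), "double")), con)
  writeLines(paste(numFmt(nodes[, 1]), numFmt(nodes[, 2]),
                   numFmt(nodes[, 3])), con)
  writeLines(paste("CELLS", nrow(tt), 5 * nrow(tt)), con)
  writeLines(paste(4, tt[, 1] - 1L, tt[, 2] - 1L, tt[, 3] - 1L,
                   tt[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", nrow(tt)), con)
  writeLines(as.character(rep(10L, nrow(tt))), con)
  writeLines(paste("CELL_DATA", nrow(tt)), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(bilayer@region), con)
  for (nm in names(cellData)) {
    writeLines(c(paste("SCALARS", nm, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(numFmt(cellData[[nm]]), con)
  }
  invisible(path)
}

#' @rdname writeTetMeshVTK
#' @param path input .vtk path (legacy ASCII unstructured grid with
#'   tetrahedral cells and a \code{region} cell scalar).
#' @export
readTetMeshVTK <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  pi_ <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[pi_], "\\s+")[[1]][2])
  acc <- c(); i <- pi_ + 1
  while (length(acc) < 3 * np) {
    acc <- c(acc, as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  nodes <- matrix(acc[seq_len(3 * np)], np, 3, byrow = TRUE)
  ci <- grep("^CELLS", ln)[1]
  hdr <- as.integer(strsplit(ln[ci], "\\s+")[[1]][2:3])
  acc <- c(); i <- ci + 1
  while (length(acc) < hdr[2]) {
    acc <- c(acc, as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  tets <- matrix(0L, hdr[1], 4)
  pos <- 1
  for (k in seq_len(hdr[1])) {
    if (acc[pos] != 4) stop("only tetrahedral cells supported")
    tets[k, ] <- acc[(pos + 1):(pos + 4)] + 1L
    pos <- pos + 5
  }
  region <- rep(2L, nrow(tets))
  ri <- grep("^SCALARS region", ln)[1]
  if (!is.na(ri)) {
    acc <- c(); i <- ri + 2
    while (length(acc) < nrow(tets)) {
      acc <- c(acc, as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    region <- acc[seq_len(nrow(tets))]
  }
  new("BilayerTetMesh", nodes = nodes, tets = tets,
      region = as.integer(region),
      pialFaces = matrix(integer(0), 0, 3),
      interfaceFaces = matrix(integer(0), 0, 3),
      normal0 = matrix(0, nrow(tets), 3),
      pialVertices = integer(0), whiteVertices = integer(0))
}

# ---- GIFTI ------------------------------------------------------------------

readGIFTI <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  vv <- NULL; ff <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    enc <- xml2::xml_attr(a, "Encoding")
    dtype <- xml2::xml_attr(a, "DataType")
    n <- as.integer(xml2::xml_attr(a, "Dim0"))
    dat <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    vals <- if (enc == "ASCII") {
      as.numeric(strsplit(trimws(dat), "\\s+")[[1]])
    } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
      raw <- jsonlite::base64_dec(gsub("\\s", "", dat))
      if (enc == "GZipBase64Binary")
        raw <- memDecompress(raw, type = "gzip")
      sz <- if (grepl("64", dtype)) 8L else 4L
      readBin(raw, if (grepl("INT", dtype)) "integer" else "double",
              n = length(raw) / sz, size = sz, endian = "little")
    } else stop("unsupported GIFTI encoding: ", enc)
    ord <- xml2::xml_attr(a, "ArrayIndexingOrder")
    m <- if (identical(ord, "ColumnMajorOrder"))
      matrix(vals, nrow = n) else matrix(vals, nrow = n, byrow = TRUE)
    if (intent == "NIFTI_INTENT_POINTSET") vv <- m
    if (intent == "NIFTI_INTENT_TRIANGLE") ff <- m + 1L
  }
  if (is.null(vv) || is.null(ff))
    stop("GIFTI file lacks pointset/triangle arrays")
  SurfaceMesh(vv, ff)
}

writeGIFTI <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  vdat <- paste(apply(v, 1, function(r) paste(numFmt(r), collapse = " ")),
                collapse = "\n")
  fdat <- paste(apply(f - 1L, 1, paste, collapse = " "), collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT64" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', nrow(v),
    '" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n<Data>',
    vdat, '</Data>\n</DataArray>\n',
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', nrow(f),
    '" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n<Data>',
    fdat, '</Data>\n</DataArray>\n</GIFTI>\n')
  writeLines(xml, path)
}

# ---- pit clouds -------------------------------------------------------------

#' Write / read sulcal-pit clouds
#'
#' CSV (header \code{x,y,z,basin_id,depth,basin_area}; comma-separated,
#' '.' decimal) or JSON. Round trips are lossless to at least 12
#' significant digits.
#'
#' @param cloud a \linkS4class{PitCloud}.
#' @param path .csv or .json file.
#' @return \code{readPitCloud}: a \linkS4class{PitCloud};
#'   \code{writePitCloud}: the path, invisibly.
#' @export
writePitCloud <- function(cloud, path) {
  df <- data.frame(x = cloud@positions[, 1], y = cloud@positions[, 2],
                   z = cloud@positions[, 3], basin_id = cloud@basinId,
                   depth = cloud@depth, basin_area = cloud@basinArea)
  if (formatExt(path) == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "columns")
  } else {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g",
                                                   digits = 17))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writePitCloud
#' @export
readPitCloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (formatExt(path) == "json") {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pit cloud is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (cn in need)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric coordinate column: ", cn)
  PitCloud(cbind(df$x, df$y, df$z),
           basinId = if ("basin_id" %in% names(df)) df$basin_id else NULL,
           depth = if ("depth" %in% names(df)) df$depth else NULL,
           basinArea = if ("basin_area" %in% names(df)) df$basin_area
                       else NULL)
}

#' Write a match report as JSON
#'
#' Records the six coarse factors, the refined rigid transform, the matched
#' pairs with similarities, the SDSP and any condition flags.
#'
#' @param result a \linkS4class{MatchResult}.
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
writeMatchReport <- function(result, path) {
  rep_ <- list(
    sdsp = result@sdsp,
    n_pairs = nrow(result@pairs),
    n_strong = sum(result@strong),
    scale_factors = as.list(result@scaleFactors),
    rotation = result@transform$rotation,
    translation = result@transform$translation,
    pairs = data.frame(p = result@pairs[, 1], q = result@pairs[, 2],
                       similarity = result@similarity,
                       strong = result@strong),
    flags = result@flags)
  jsonlite::write_json(rep_, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a run-configuration file
#'
#' Single YAML or JSON file validated against the documented schema:
#' known sections (\code{surface}, \code{growth}, \code{pits},
#' \code{match}) with numeric leaf values; unknown keys are rejected.
#'
#' @param path .yaml/.yml/.json configuration file.
#' @return nested named list of configuration values.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (formatExt(path) %in% c("yaml", "yml"))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  schema <- list(
    surface = c("iterations", "edge", "offset"),
    growth = c("mu", "k", "Gctx", "Gsub", "pressureCoeff", "thetaSubTarget",
               "nSteps", "nSnapshots"),
    pits = c("alpha", "thrR", "thrD", "thrA", "distance"),
    match = c("sigma", "threshold"))
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(unknown))
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
    for (k in setdiff(schema[[sec]], "distance")) {
      if (k %in% names(cfg[[sec]]) && !is.numeric(cfg[[sec]][[k]]))
        stop("configuration value ", sec, "$", k, " must be numeric")
    }
  }
  cfg
}
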