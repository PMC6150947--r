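#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a [cortical_mesh()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Only `v` and `f` records are interpreted (triangular faces, plain vertex
#' indices).
#'
#' @param path OBJ file.
#' @return a [cortical_mesh()].
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  cortical_mesh(v, f)
}

#' Write a mesh as a GIfTI surface (ASCII encoding)
#'
#' Emits a minimal GIFTI 1.0 document with a POINTSET and a TRIANGLE data
#' array, ASCII-encoded (plain text). Triangle indices are 0-based in the
#' file, per the format.
#'
#' @param mesh a [cortical_mesh()].
#' @param path output file (conventionally `.surf.gii`).
#' @return invisibly `path`.
#' @export
write_gifti <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  pts <- paste(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), collapse = "\n")
  tri <- paste(apply(mesh$faces - 1L, 1, paste, collapse = " "), collapse = "\n")
  da <- function(intent, dtype, dims, data)
    sprintf(paste0(
      '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
      'Dimensionality="2" Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian" ',
      'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
      intent, dtype, dims, data)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", n, pts), "\n",
    da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", m, tri), "\n",
    "</GIFTI>\n")
  writeLines(doc, path)
  invisible(path)
}

#' Read a GIfTI surface (ASCII encoding)
#'
#' @param path GIfTI file written by [write_gifti()] or any ASCII-encoded
#'   surface GIfTI.
#' @return a [cortical_mesh()].
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  get_da <- function(intent) {
    da <- das[vapply(das, function(d) xml2::xml_attr(d, "Intent") == intent,
                     logical(1))][[1]]
    if (xml2::xml_attr(da, "Encoding") != "ASCII")
      stop("only ASCII-encoded GIfTI is supported")
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    matrix(vals, ncol = 3, byrow = TRUE)
  }
  v <- get_da("NIFTI_INTENT_POINTSET")
  f <- get_da("NIFTI_INTENT_TRIANGLE") + 1L
  cortical_mesh(v, matrix(as.integer(f), ncol = 3))
}

#' Write / read a sensor array as TSV
#'
#' Columns: label, x, y, z, ox, oy, oz; conductor centre and radius are
#' kept in comment header lines.
#'
#' @param sensors a `sensor_array`.
#' @param path file path.
#' @return invisibly `path` (write) or a `sensor_array` (read).
#' @export
write_sensors_tsv <- function(sensors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# conductor_center\t%g\t%g\t%g", sensors$conductor_center[1],
                     sensors$conductor_center[2], sensors$conductor_center[3]), con)
  writeLines(sprintf("# conductor_radius\t%g", sensors$conductor_radius), con)
  df <- data.frame(label = sensors$labels, sensors$positions,
                   sensors$orientations)
  colnames(df) <- c("label", "x", "y", "z", "ox", "oy", "oz")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensors_tsv
#' @export
read_sensors_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  ctr <- as.numeric(strsplit(hdr[1], "\t")[[1]][2:4])
  rad <- as.numeric(strsplit(hdr[2], "\t")[[1]][2])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(labels = df$label,
                 positions = as.matrix(df[, c("x", "y", "z")]),
                 orientations = as.matrix(df[, c("ox", "oy", "oz")]),
                 conductor_center = ctr, conductor_radius = rad),
            class = "sensor_array")
}

#' Write / read a sensor recording as TSV
#'
#' Header comment lines carry fs and the optional ground-truth statepath;
#' one row per channel (label followed by samples).
#'
#' @param rec a [sensor_recording()].
#' @param path file path.
#' @return invisibly `path` (write) or a [sensor_recording()] (read).
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs\t%g", rec$fs), con)
  if (!is.null(rec$state_truth))
    writeLines(paste0("# state_truth\t",
                      paste(rec$state_truth, collapse = "\t")), con)
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(c(rec$labels[i], sprintf("%.9g", rec$data[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  fs <- as.numeric(strsplit(hdr[startsWith(hdr, "# fs")], "\t")[[1]][2])
  truth <- NULL
  st <- hdr[startsWith(hdr, "# state_truth")]
  if (length(st))
    truth <- as.integer(strsplit(st, "\t")[[1]][-1])
  parts <- strsplit(body, "\t")
  labels <- vapply(parts, `[`, character(1), 1)
  data <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  sensor_recording(data, fs, labels, truth)
}

#' Serialize a mesh library to a directory
#'
#' Writes every mesh (orders and the true mesh) as GIfTI plus a JSON
#' manifest (subject, orders, sigma).
#'
#' @param library a `mesh_library`.
#' @param dir output directory (created if needed).
#' @return invisibly `dir` (write) or a `mesh_library` (read).
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mi in names(library$meshes))
    write_gifti(library$meshes[[mi]],
                file.path(dir, sprintf("mesh_%s.surf.gii", mi)))
  write_gifti(library$true_mesh, file.path(dir, "mesh_true.surf.gii"))
  jsonlite::write_json(
    list(subject_id = library$subject_id,
         harmonic_orders = library$harmonic_orders, sigma = library$sigma),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  orders <- man$harmonic_orders
  meshes <- lapply(orders, function(L)
    read_gifti(file.path(dir, sprintf("mesh_%d.surf.gii", L))))
  names(meshes) <- as.character(orders)
  structure(list(meshes = meshes,
                 true_mesh = read_gifti(file.path(dir, "mesh_true.surf.gii")),
                 harmonic_orders = orders, sigma = man$sigma,
                 subject_id = man$subject_id),
            class = "mesh_library")
}
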