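# ASCII point-cloud I/O. PLY carries optional per-vertex integer
# properties "label" (ground truth) and "segment" (segmentation output);
# PCD is supported for x y z interchange with external tools. Both writers
# round-trip coordinates losslessly well beyond 6 significant digits.

#' Read a point cloud from ASCII PLY or PCD
#'
#' Format is chosen by file extension (`.ply` / `.pcd`). PLY vertex
#' elements must provide `x y z`; integer properties named `label` or
#' `segment` are attached if present. Malformed headers raise an error
#' naming the offending line.
#'
#' @param path input file
#' @return a `labeled_cloud`; a `segment` property, if present, is attached
#'   as attribute `"segment"`
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         pcd = read_pcd(path),
         stop(sprintf("unsupported cloud format '.%s' (use .ply or .pcd)", ext)))
}

#' Write a point cloud to ASCII PLY or PCD
#'
#' @param cloud `labeled_cloud` (or N x 3 matrix)
#' @param path output file; extension selects the format
#' @param segment optional per-point integer segment ids written as a PLY
#'   `segment` property
#' @return `path`, invisibly
#' @export
write_cloud <- function(cloud, path, segment = NULL) {
  if (!inherits(cloud, "labeled_cloud")) cloud <- labeled_cloud(as_points(cloud))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(cloud, path, segment),
         pcd = write_pcd(cloud, path),
         stop(sprintf("unsupported cloud format '.%s' (use .ply or .pcd)", ext)))
  invisible(path)
}

ply_fail <- function(line_no, msg) {
  stop(sprintf("malformed PLY header at line %d: %s", line_no, msg))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") ply_fail(1, "missing 'ply' magic")
  n_vertex <- NA_integer_
  props <- character(0)
  header_end <- NA_integer_
  in_vertex <- FALSE
  i <- 2
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok)) ply_fail(i, "empty header line")
    if (tok[1] == "format") {
      if (length(tok) < 2 || tok[2] != "ascii") ply_fail(i, "only ascii format is supported")
    } else if (tok[1] == "element") {
      if (length(tok) < 3) ply_fail(i, "incomplete element declaration")
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property") {
      if (in_vertex) {
        if (length(tok) < 3) ply_fail(i, "incomplete property declaration")
        props <- c(props, tok[length(tok)])
      }
    } else if (tok[1] == "end_header") {
      header_end <- i
      break
    } else if (!(tok[1] %in% c("comment", "obj_info"))) {
      ply_fail(i, sprintf("unknown keyword '%s'", tok[1]))
    }
    i <- i + 1
  }
  if (is.na(header_end)) ply_fail(length(lines), "no end_header")
  if (is.na(n_vertex)) ply_fail(header_end, "no vertex element declared")
  if (!all(c("x", "y", "z") %in% props))
    ply_fail(header_end, "vertex element must have x, y, z properties")
  if (n_vertex == 0)
    return(labeled_cloud(matrix(0, 0, 3), integer(0), source = "file"))
  body <- if (header_end < length(lines)) lines[(header_end + 1):length(lines)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vertex)
    stop(sprintf("truncated PLY: %d vertex rows declared, %d found",
                 n_vertex, length(body)))
  body <- body[seq_len(n_vertex)]
  vals <- utils::read.table(text = body, col.names = props,
                            colClasses = "numeric")
  if (nrow(vals) != n_vertex || ncol(vals) != length(props))
    stop("truncated PLY vertex data")
  labels <- if ("label" %in% props) as.integer(vals$label) else
    integer(n_vertex)
  xyz <- unname(as.matrix(vals[, c("x", "y", "z")]))
  cl <- labeled_cloud(xyz, labels, source = "file")
  if ("segment" %in% props) attr(cl, "segment") <- as.integer(vals$segment)
  cl
}

write_ply <- function(cloud, path, segment = NULL) {
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0",
              "comment produced by phenorover",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "property int label",
              if (!is.null(segment)) "property int segment",
              "end_header")
  cols <- list(format(cloud$points[, 1], digits = 17, trim = TRUE, scientific = FALSE),
               format(cloud$points[, 2], digits = 17, trim = TRUE, scientific = FALSE),
               format(cloud$points[, 3], digits = 17, trim = TRUE, scientific = FALSE),
               cloud$labels)
  if (!is.null(segment)) {
    if (length(segment) != n) stop("'segment' must have one id per point")
    cols <- c(cols, list(as.integer(segment)))
  }
  rows <- do.call(paste, cols)
  writeLines(c(header, rows), path)
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_keys <- c("FIELDS", "POINTS", "DATA")
  fields <- NULL; n_pts <- NA_integer_; data_line <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "FIELDS") fields <- tok[-1]
    if (tok[1] == "POINTS") n_pts <- as.integer(tok[2])
    if (tok[1] == "DATA") {
      if (length(tok) < 2 || tok[2] != "ascii")
        stop(sprintf("malformed PCD at line %d: only DATA ascii is supported", i))
      data_line <- i
      break
    }
  }
  if (is.na(data_line)) stop("malformed PCD: no DATA line")
  if (is.null(fields) || !all(c("x", "y", "z") %in% fields))
    stop("malformed PCD: FIELDS must include x y z")
  if (is.na(n_pts)) stop("malformed PCD: no POINTS line")
  body <- lines[(data_line + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_pts)
    stop(sprintf("truncated PCD: %d points declared, %d found", n_pts, length(body)))
  vals <- utils::read.table(text = body[seq_len(n_pts)], col.names = fields)
  labels <- if ("label" %in% fields) as.integer(vals$label) else integer(n_pts)
  labeled_cloud(unname(as.matrix(vals[, c("x", "y", "z")])), labels,
                source = "file")
}

write_pcd <- function(cloud, path) {
  n <- nrow(cloud$points)
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
              "COUNT 1 1 1", sprintf("WIDTH %d", n), "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", n), "DATA ascii")
  rows <- paste(format(cloud$points[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                format(cloud$points[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                format(cloud$points[, 3], digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(c(header, rows), path)
}

#' Export a segmentation as JSON
#'
#' @param seg `leaf_segmentation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "leaf_segmentation"))
  jsonlite::write_json(
    list(n_points = seg$n_points,
         params = unclass(seg$params),
         segments = seg$segments,
         noise = seg$noise),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segmentation written by [write_segmentation()]
#'
#' @param path JSON file
#' @return `leaf_segmentation`
#' @export
read_segmentation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- x$segments
  if (is.matrix(segs)) segs <- lapply(seq_len(nrow(segs)), function(i) segs[i, ])
  if (!is.list(segs)) segs <- list(segs)
  structure(list(segments = lapply(segs, as.integer),
                 noise = as.integer(x$noise),
                 params = do.call(segmentation_params, as.list(x$params)),
                 n_points = as.integer(x$n_points)),
            class = "leaf_segmentation")
}
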