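#' Write a velocity field to NIfTI
#'
#' Either three scalar volumes (`<prefix>_vx.nii`, `_vy.nii`, `_vz.nii`) or
#' a single 4D multi-component volume (`<prefix>.nii`). Voxel spacing is
#' stored in the header pixdim and the grid origin in the sform; velocities
#' are stored in m/s.
#'
#' @param field A [velocity_field()].
#' @param prefix Output path prefix (no extension).
#' @param layout `"three_scalar_volumes"` or `"single_multicomponent"`.
#' @return The written file path(s), invisibly.
#' @export
write_velocity_field <- function(field, prefix,
                                 layout = c("three_scalar_volumes", "single_multicomponent")) {
  layout <- match.arg(layout)
  g <- field$grid
  xf <- diag(4)
  diag(xf)[1:3] <- g$spacing
  xf[1:3, 4] <- g$origin
  put <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    attr(img, "pixdim") <- g$spacing
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path)
    path
  }
  if (layout == "three_scalar_volumes") {
    paths <- c(put(field$vx, paste0(prefix, "_vx.nii")),
               put(field$vy, paste0(prefix, "_vy.nii")),
               put(field$vz, paste0(prefix, "_vz.nii")))
  } else {
    arr <- array(c(field$vx, field$vy, field$vz), c(g$shape, 3L))
    paths <- put(arr, paste0(prefix, ".nii"))
  }
  invisible(paths)
}

#' Read a velocity field from NIfTI
#'
#' Inverse of [write_velocity_field()]. Component shapes must agree and the
#' header must carry positive voxel spacing; unit-less or inconsistent
#' inputs fail loudly.
#'
#' @param paths One 4D file, or three scalar-volume files ordered
#'   (vx, vy, vz).
#' @param venc Optional velocity-encoding limit, m/s.
#' @export
read_velocity_field <- function(paths, venc = NULL) {
  imgs <- lapply(paths, RNifti::readNifti)
  meta <- function(img) {
    pd <- attr(img, "pixdim")[1:3]
    if (is.null(pd) || any(!is.finite(pd)) || any(pd <= 0))
      stop_af("missing or non-positive voxel spacing in NIfTI header")
    xf <- RNifti::xform(img)
    list(spacing = pd, origin = xf[1:3, 4])
  }
  strip <- function(img) array(as.numeric(img), dim = dim(img))
  if (length(paths) == 1L) {
    arr <- strip(imgs[[1]])
    if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
      stop_af("single-file layout expects a 4D volume with 3 components")
    m <- meta(imgs[[1]])
    g <- grid_spec(dim(arr)[1:3], m$spacing, m$origin)
    return(velocity_field(g, arr[, , , 1], arr[, , , 2], arr[, , , 3], venc = venc))
  }
  if (length(paths) != 3L) stop_af("supply one 4D file or three scalar volumes")
  arrs <- lapply(imgs, strip)
  shapes <- vapply(arrs, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_af("component shapes differ: %s", paste(shapes, collapse = " vs "))
  m <- meta(imgs[[1]])
  g <- grid_spec(dim(arrs[[1]]), m$spacing, m$origin)
  velocity_field(g, arrs[[1]], arrs[[2]], arrs[[3]], venc = venc)
}

#' Select the peak-systolic phase from a multi-phase acquisition
#'
#' Reduces a list of single-phase fields to the phase whose lumen-mean
#' through-plane speed is maximal.
#'
#' @param fields List of [velocity_field()] objects (the phases).
#' @param mask Logical lumen array; defaults to each field's own mask.
#' @param normal Through-plane direction (default +z).
#' @return The selected field, with attribute `phase` (index).
#' @export
select_peak_phase <- function(fields, mask = NULL, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  score <- vapply(fields, function(f) {
    m <- mask %||% f$lumen %||% array(TRUE, f$grid$shape)
    vth <- f$vx * normal[1] + f$vy * normal[2] + f$vz * normal[3]
    mean(abs(vth[m]))
  }, numeric(1))
  out <- fields[[which.max(score)]]
  attr(out, "phase") <- which.max(score)
  out
}

#' Write a surface as ASCII STL
#' @param surface A [tri_surface()].
#' @param path Output `.stl` path.
#' @export
write_stl <- function(surface, path) {
  fg <- face_geometry(surface)
  fc <- face_corners_(surface$vertices, surface$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aortaflow", con)
  fmt <- function(v) paste(formatC(v, format = "g", digits = 9), collapse = " ")
  for (f in seq_len(nrow(surface$faces))) {
    writeLines(c(paste("facet normal", fmt(fg$normals[f, ])),
                 "  outer loop",
                 paste("    vertex", fmt(fc$a[f, ])),
                 paste("    vertex", fmt(fc$b[f, ])),
                 paste("    vertex", fmt(fc$c[f, ])),
                 "  endloop",
                 "endfacet"), con)
  }
  writeLines("endsolid aortaflow", con)
  invisible(path)
}

#' Read an STL surface (ASCII or binary)
#'
#' Shared vertices are merged by exact coordinate key. Binary files are
#' detected by the 84 + 50 x n_triangles size signature.
#'
#' @param path `.stl` file path.
#' @export
read_stl <- function(path) {
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(ntri) && ntri > 0 && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  tri <- if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    m <- matrix(NA_real_, 3 * ntri, 3)
    for (f in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", 2))
      m[(3 * f - 2):(3 * f), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    m
  } else {
    ln <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
    if (!length(vl)) stop_af("no vertices found in %s", path)
    m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    m
  }
  if (nrow(tri) %% 3 != 0) stop_af("corrupt STL: vertex count not a multiple of 3")
  key <- apply(round(tri, 9), 1, paste, collapse = "_")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_surface(verts, faces)
}

#' Write a surface as ASCII PLY
#' @inheritParams write_stl
#' @export
write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(surface$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(surface$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(surface$vertices, trim = TRUE, digits = 10),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, surface$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface
#' @param path `.ply` file path.
#' @export
read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  endh <- which(ln == "end_header")[1]
  if (is.na(endh)) stop_af("not an ASCII PLY file: %s", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
  vl <- ln[(endh + 1):(endh + nv)]
  fl <- ln[(endh + nv + 1):(endh + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"),
                                 function(x) as.integer(x[2:4]) + 1L))
  tri_surface(verts, faces)
}

#' Read a surface by file extension (.stl or .ply)
#' @param path Surface file path.
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop_af("unsupported surface format '.%s'", ext))
}

#' Read a paired cohort from CSV
#'
#' Expects columns `subject` (or `subject_id`), `predicted`, `observed`;
#' UTF-8, header row, '.' decimal separator.
#'
#' @param path CSV path.
#' @inheritParams paired_cohort
#' @export
read_cohort_csv <- function(path, metric_name = "metric", units = "") {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if ("subject" %in% names(tab) && !"subject_id" %in% names(tab))
    tab <- dplyr::rename(tab, subject_id = "subject")
  paired_cohort(tab, metric_name = metric_name, units = units)
}

#' Read a flow-grade table from CSV
#'
#' Expects columns `subject`, `method` and one column per graded pattern
#' (e.g. `helicity`, `vorticity`, `eccentricity`) with values
#' none/mild/marked.
#'
#' @param path CSV path.
#' @export
read_grades_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("subject", "method") %in% names(tab)))
    stop_af("grade CSV needs `subject` and `method` columns")
  tab
}

# md5 hash of an arbitrary R object (via a serialized temp file)
object_hash_ <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}
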