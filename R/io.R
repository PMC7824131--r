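# Volume, plane and image I/O.
#
# Volumes travel as NIfTI (.nii/.nii.gz, via RNifti) or uncompressed
# MetaImage (.mha, minimal reader/writer below); plane annotations as JSON
# records; extracted 2D MSP images as 8-bit PNG.

#' Read a 3D volume
#'
#' @param path `.nii`, `.nii.gz` or `.mha` file.
#' @return 3D numeric array (spacing, if present, in attribute `spacing`;
#'   all package geometry is in voxel units).
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(read_mha(path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)
  arr
}

#' Write a 3D volume
#'
#' @param volume 3D numeric array.
#' @param path output `.nii`, `.nii.gz` or `.mha` file.
#' @param spacing per-axis voxel spacing metadata (default 1).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    write_mha(volume, path, spacing)
  } else {
    img <- RNifti::asNifti(volume)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# -- minimal MetaImage (.mha) support: plain-text header + raw block -------

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data is supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], " +")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  vals <- switch(type,
    "MET_FLOAT" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "MET_DOUBLE" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    "MET_UCHAR" = as.numeric(readBin(con, "integer", n, size = 1L,
                                     signed = FALSE)) / 255,
    stop("unsupported MetaImage element type: ", type, call. = FALSE))
  arr <- array(vals, dims)
  if (!is.null(hdr[["ElementSpacing"]]))
    attr(arr, "spacing") <- as.numeric(strsplit(hdr[["ElementSpacing"]], " +")[[1]])
  arr
}

write_mha <- function(volume, path, spacing = c(1, 1, 1)) {
  dims <- dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    sprintf("ElementSpacing = %s\n", paste(spacing, collapse = " ")),
    sprintf("DimSize = %s\n", paste(dims, collapse = " ")),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(volume), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write a plane annotation record as JSON
#'
#' @param plane an `msp_plane`.
#' @param path output file.
#' @param seed,theta_axi,theta_cor optional annotation fields.
#' @return `path`, invisibly.
#' @export
write_plane_json <- function(plane, path, seed = NULL, theta_axi = NULL,
                             theta_cor = NULL) {
  p <- as_plane(plane)
  rec <- list(a = p[["a"]], b = p[["b"]], c = p[["c"]], d = p[["d"]])
  if (!is.null(seed)) rec$seed <- as.numeric(seed)
  if (!is.null(theta_axi)) rec$theta_axi <- theta_axi
  if (!is.null(theta_cor)) rec$theta_cor <- theta_cor
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plane annotation record
#'
#' @param path JSON file written by [write_plane_json()].
#' @return List with `plane` (`msp_plane`) and any of `seed`, `theta_axi`,
#'   `theta_cor` present in the record.
#' @export
read_plane_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(plane = normalize_plane(c(rec$a, rec$b, rec$c, rec$d)))
  for (f in c("seed", "theta_axi", "theta_cor"))
    if (!is.null(rec[[f]])) out[[f]] <- rec[[f]]
  out
}

#' Write a 2D MSP image as 8-bit PNG
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msp_png <- function(image, path) {
  png::writePNG(clamp(t(image), 0, 1), path)
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' One NIfTI volume and one ground-truth JSON per sample, plus a manifest
#' CSV.
#'
#' @param samples list of `msp_phantom`.
#' @param dir output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    vol_file <- sprintf("phantom_%03d.nii.gz", i)
    lab_file <- sprintf("phantom_%03d_label.nii.gz", i)
    gt_file <- sprintf("phantom_%03d_gt.json", i)
    write_volume(s$volume, file.path(dir, vol_file))
    write_volume(s$head_label, file.path(dir, lab_file))
    write_plane_json(s$gt_plane, file.path(dir, gt_file), seed = s$gt_seed,
                     theta_axi = s$theta_axi, theta_cor = s$theta_cor)
    bb <- s$head_bbox
    tibble::tibble(id = i, volume = vol_file, label = lab_file,
                   ground_truth = gt_file,
                   head_side = s$head_side, theta_axi = s$theta_axi,
                   theta_cor = s$theta_cor,
                   bbox_lo_x = bb["lo", 1], bbox_lo_y = bb["lo", 2],
                   bbox_lo_z = bb["lo", 3], bbox_hi_x = bb["hi", 1],
                   bbox_hi_y = bb["hi", 2], bbox_hi_z = bb["hi", 3])
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return List of `msp_phantom` samples (the ground-truth mask is
#'   re-rasterized from the stored plane).
#' @export
read_phantom_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i) {
    vol <- read_volume(file.path(dir, man$volume[i]))
    attr(vol, "spacing") <- NULL
    lab <- read_volume(file.path(dir, man$label[i]))
    attr(lab, "spacing") <- NULL
    gt <- read_plane_json(file.path(dir, man$ground_truth[i]))
    bb <- rbind(lo = c(man$bbox_lo_x[i], man$bbox_lo_y[i], man$bbox_lo_z[i]),
                hi = c(man$bbox_hi_x[i], man$bbox_hi_y[i], man$bbox_hi_z[i]))
    structure(list(volume = vol, gt_plane = gt$plane, gt_seed = gt$seed,
                   gt_mask = rasterize_plane(gt$plane, dim(vol), 0.5),
                   theta_axi = gt$theta_axi, theta_cor = gt$theta_cor,
                   head_side = man$head_side[i],
                   head_label = round(lab), head_bbox = bb, spec = NULL),
              class = "msp_phantom")
  })
}
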