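# File I/O: NIfTI volumes and PNG slices in, PNG/JSON/CSV out, plus the
# dataset manifest used by the CLI.

#' Read an image volume or slice
#'
#' NIfTI (`.nii`/`.nii.gz`) volumes are returned as stored, with spacing
#' from the header; PNG files are returned as a single slice. No implicit
#' normalization: PNG values are in \[0, 1\] as decoded (set
#' `rescale = FALSE` to get the raw 0..255 integers back).
#'
#' @param path file path.
#' @param pixel_spacing_mm spacing to attach to PNG slices (PNG stores
#'   none).
#' @param rescale for PNG: keep the decoded \[0, 1\] scale (`TRUE`) or
#'   return integer levels (`FALSE`).
#' @return list with `data` (2D or 3D array), `spacing_mm`, and `format`.
#' @export
read_volume <- function(path, pixel_spacing_mm = c(1, 1), rescale = TRUE) {
  if (!file.exists(path)) stop_mf("file not found: %s", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    list(data = unclass(img)[, , , drop = TRUE], spacing_mm = sp,
         format = "nifti")
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]          # first channel of RGB(A)
    if (!rescale) m <- round(m * 255)
    list(data = m, spacing_mm = pixel_spacing_mm, format = "png")
  } else {
    stop_mf("unsupported image format '%s' (expected .nii, .nii.gz or .png)", ext)
  }
}

#' Write a slice or volume
#'
#' PNG for 2D matrices (values clipped to \[0, 1\], 8-bit), NIfTI for 2D
#' or 3D arrays with spacing stored in the header.
#'
#' @param data numeric matrix or 3D array.
#' @param path output path; format chosen by extension.
#' @param spacing_mm voxel spacing for NIfTI output.
#' @export
write_volume <- function(data, path, spacing_mm = c(1, 1, 1)) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    if (length(dim(data)) != 2) stop_mf("PNG output requires a 2D matrix")
    png::writePNG(clip01(data), path)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- spacing_mm[seq_along(dim(data))]
    RNifti::writeNifti(img, path)
  } else stop_mf("unsupported output format '%s'", ext)
  invisible(path)
}

#' Load a slice pair from two image files
#'
#' @param mri_path,ct_path image paths (PNG or NIfTI; NIfTI must be 2D or
#'   a single slice selected with `slice`).
#' @param slice slice index along the third axis for 3D volumes.
#' @param pixel_spacing_mm spacing for PNG input.
#' @return a [slice_pair()].
#' @export
read_slice_pair <- function(mri_path, ct_path, slice = NULL,
                            pixel_spacing_mm = c(1, 1)) {
  pick <- function(v) {
    d <- v$data
    if (length(dim(d)) == 3) {
      if (is.null(slice)) stop_mf("3D volume: a slice index is required")
      d <- d[, , slice]
    }
    d
  }
  mv <- read_volume(mri_path, pixel_spacing_mm)
  cv <- read_volume(ct_path, pixel_spacing_mm)
  m <- pick(mv); ct <- pick(cv)
  if (!identical(dim(m), dim(ct)))
    stop_mf("paired loading failed: MRI %s vs CT %s",
            paste(dim(m), collapse = "x"), paste(dim(ct), collapse = "x"))
  slice_pair(mri = m, ct = ct,
             pixel_spacing_mm = mv$spacing_mm[1:2])
}

#' Write a phantom dataset as paired PNG slices with a JSON manifest
#'
#' Emits `{id}_mri.png`, `{id}_ct.png` and mask PNGs per pair, plus
#' `manifest.json` listing ids, patient ids, paths and split.
#'
#' @param dataset output of [make_phantom_dataset()].
#' @param out_dir output directory (created if absent).
#' @param split split label stored in the manifest.
#' @param nifti also write `mri.nii.gz` / `ct.nii.gz` volumes stacking the
#'   slices along the third axis.
#' @return the manifest (invisibly), written as `manifest.json`.
#' @export
write_phantom_dataset <- function(dataset, out_dir, split = "train",
                                  nifti = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nifti) {
    n <- dataset[[1]]$pair
    stack <- function(field) {
      v <- array(0, c(dim(n[[field]]), length(dataset)))
      for (i in seq_along(dataset)) v[, , i] <- dataset[[i]]$pair[[field]]
      v
    }
    sp <- c(n$pixel_spacing_mm, 1)
    write_volume(stack("mri"), file.path(out_dir, "mri.nii.gz"), sp)
    write_volume(stack("ct"), file.path(out_dir, "ct.nii.gz"), sp)
  }
  records <- lapply(seq_along(dataset), function(i) {
    id <- sprintf("phantom%04d", i)
    item <- dataset[[i]]
    paths <- list(mri = sprintf("%s_mri.png", id),
                  ct = sprintf("%s_ct.png", id),
                  head = sprintf("%s_mask_head.png", id),
                  bone = sprintf("%s_mask_bone.png", id),
                  tumor = sprintf("%s_mask_tumor.png", id))
    write_volume(item$pair$mri, file.path(out_dir, paths$mri))
    write_volume(item$pair$ct, file.path(out_dir, paths$ct))
    write_volume(item$truth$head_mask, file.path(out_dir, paths$head))
    write_volume(item$truth$bone_mask, file.path(out_dir, paths$bone))
    write_volume(item$truth$tumor_mask, file.path(out_dir, paths$tumor))
    list(id = id, patient_id = id, mri_path = paths$mri, ct_path = paths$ct,
         mask_path = paths$tumor, split = split)
  })
  jsonlite::write_json(records, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(records)
}

#' Load a dataset manifest
#'
#' Validates that ids are unique, referenced files exist, and splits are
#' `train`/`test`.
#'
#' @param path path to a `manifest.json`.
#' @return data frame of records.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (anyDuplicated(man$id)) stop_mf("manifest ids are not unique")
  if (!all(man$split %in% c("train", "test")))
    stop_mf("manifest split values must be 'train' or 'test'")
  base <- dirname(path)
  for (col in c("mri_path", "ct_path")) {
    missing <- !file.exists(file.path(base, man[[col]]))
    if (any(missing))
      stop_mf("manifest references missing files: %s",
              paste(man[[col]][missing], collapse = ", "))
  }
  man
}
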