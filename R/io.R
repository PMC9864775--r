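# Cohort I/O: one volume file plus three mask files per patient, NIfTI
# (.nii.gz, via RNifti) or NRRD, plus a cohort manifest CSV. No R package in
# the dependency set reads NRRD, so a minimal reader/writer for the format's
# raw-encoding core (text header + little-endian raw block) lives here.

write_nrrd <- function(arr, spacing, origin, path, type = c("double", "uint8")) {
  type <- match.arg(type)
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", if (type == "double") "double" else "unsigned char"),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "encoding: raw",
           "endian: little",
           "space dimension: 3",
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   origin[1], origin[2], origin[3]),
           "")
  writeLines(hdr, con, sep = "\n")
  if (type == "double")
    writeBin(as.double(arr), con, size = 8, endian = "little")
  else
    writeBin(as.raw(as.integer(arr)), con)
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unexpected end of NRRD header in ", path)
    if (ln == "") break
    hdr <- c(hdr, ln)
  }
  if (!grepl("^NRRD", hdr[1])) stop(path, " is not an NRRD file")
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  type <- field("type")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  enc <- field("encoding")
  if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(field("space origin"))
  n <- prod(sizes)
  vals <- if (type %in% c("double")) {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else if (type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) {
    as.integer(readBin(con, "raw", n = n))
  } else stop("unsupported NRRD type: ", type)
  list(voxels = array(vals, dim = sizes), spacing = spacing, origin = origin)
}

write_image <- function(arr, spacing, origin, path, format, mask = FALSE) {
  if (format == "nrrd") {
    write_nrrd(arr, spacing, origin, path, type = if (mask) "uint8" else "double")
  } else {
    img <- RNifti::asNifti(if (mask) array(as.integer(arr), dim(arr)) else arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

read_image <- function(path, origin) {
  if (grepl("\\.nrrd$", path)) {
    r <- read_nrrd(path)
    list(voxels = r$voxels, spacing = r$spacing, origin = r$origin)
  } else {
    img <- RNifti::readNifti(path)
    list(voxels = array(as.numeric(img), dim = dim(img)),
         spacing = RNifti::pixdim(img)[1:3], origin = origin)
  }
}

#' Write a synthetic cohort to disk
#'
#' One volume file and three mask files per patient plus `manifest.csv`
#' (patient id, file paths, true lesion radii, seed, grid geometry).
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` (.nii.gz) or `"nrrd"`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "rr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  rows <- lapply(cohort, function(p) {
    vf <- file.path(dir, paste0(p$id, "_volume", ext))
    write_image(p$volume$voxels, p$volume$spacing, p$volume$origin, vf, format)
    mf <- vapply(segmentation_styles(), function(s) {
      f <- file.path(dir, paste0(p$id, "_mask_", s, ext))
      write_image(p$masks[[s]]$voxels, p$masks[[s]]$spacing,
                  p$masks[[s]]$origin, f, format, mask = TRUE)
      f
    }, "")
    data.frame(patient_id = p$id,
               volume_file = basename(vf),
               mask_accurate = basename(mf[1]),
               mask_rough_freehand = basename(mf[2]),
               mask_rough_polygon = basename(mf[3]),
               seed = p$spec$seed,
               radius_x = p$spec$lesion_radii[1],
               radius_y = p$spec$lesion_radii[2],
               radius_z = p$spec$lesion_radii[3],
               origin_x = p$volume$origin[1],
               origin_y = p$volume$origin[2],
               origin_z = p$volume$origin[3],
               spacing_x = p$volume$spacing[1],
               spacing_y = p$volume$spacing[2],
               spacing_z = p$volume$spacing[3],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort from disk
#'
#' Loads the volumes and masks listed in `manifest.csv`, validating that each
#' mask is aligned to its volume. Patients with missing or misaligned files
#' are rejected with a warning naming the problem; the remaining patients are
#' returned.
#'
#' @param dir Directory containing `manifest.csv` and the image files.
#' @return An `rr_cohort` list (see [generate_cohort()]; `spec` carries only
#'   the manifest metadata).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  out <- list()
  errs <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    origin <- c(row$origin_x, row$origin_y, row$origin_z)
    spacing <- if (!is.null(row$spacing_x))
      c(row$spacing_x, row$spacing_y, row$spacing_z) else NULL
    files <- c(row$volume_file, row$mask_accurate, row$mask_rough_freehand,
               row$mask_rough_polygon)
    paths <- file.path(dir, files)
    if (any(!file.exists(paths))) {
      errs <- c(errs, sprintf("%s: missing file(s) %s", row$patient_id,
                              paste(files[!file.exists(paths)], collapse = ", ")))
      next
    }
    res <- tryCatch({
      v <- read_image(paths[1], origin)
      # manifest spacing is authoritative (NIfTI headers store pixdim in
      # float32); the file header must agree to within that precision
      use_sp <- function(file_sp) {
        if (is.null(spacing)) return(file_sp)
        if (max(abs(file_sp - spacing)) > 1e-4)
          stop("file spacing disagrees with manifest spacing")
        spacing
      }
      vol <- rr_volume(v$voxels, use_sp(v$spacing), v$origin)
      masks <- lapply(paths[2:4], function(f) {
        m <- read_image(f, origin)
        msk <- rr_mask(m$voxels, use_sp(m$spacing), m$origin)
        check_aligned(vol, msk)
        msk
      })
      names(masks) <- segmentation_styles()
      list(id = row$patient_id, volume = vol, masks = masks, spec = as.list(row))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("%s: %s", row$patient_id, conditionMessage(res)))
      next
    }
    out[[length(out) + 1L]] <- res
  }
  if (length(errs) > 0)
    warning("rejected patients:\n  ", paste(errs, collapse = "\n  "))
  class(out) <- "rr_cohort"
  attr(out, "rejected") <- errs
  out
}
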