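## read a grayscale PNG or TIFF into a [0, 255] matrix; multi-channel
## images are averaged; 16-bit input is linearly rescaled by its own
## min/max
read_gray_image <- function(path, rescale_16bit = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path, as.is = FALSE)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  v <- img * 255
  # heuristically detect 16-bit content compressed into [0,1]: rescale by
  # the image's own range when requested or when dynamic range is tiny
  if (isTRUE(rescale_16bit) ||
      (is.null(rescale_16bit) && diff(range(v)) > 0 && max(v) < 2)) {
    v <- (v - min(v)) / diff(range(v)) * 255
  }
  v
}

#' Load a cohort manifest
#'
#' @param path CSV with columns `cell_id`, `condition`, `gray_path`,
#'   `cell_mask_path` and optionally `nucleus_mask_path` (paths relative
#'   to the manifest's directory or absolute).
#' @return data frame with absolute paths.
#' @export
load_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "gray_path", "cell_mask_path")
  if (!all(need %in% colnames(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(p == "" | is.na(p), "",
                            ifelse(startsWith(p, "/"), p, file.path(base, basename(p))))
  for (col in intersect(c("gray_path", "cell_mask_path", "nucleus_mask_path"),
                        colnames(m)))
    m[[col]] <- fix(m[[col]])
  m
}

#' Load the cells listed in a manifest
#'
#' Reads each gray/mask image pair (and nucleus mask when listed) and
#' wraps them as [cell_image()] objects; images are assumed already
#' centered (as written by [make_population()] or `preprocess_manifest`).
#'
#' @param manifest data frame from [load_manifest()] (or a path to one).
#' @return list of [cell_image()] objects.
#' @export
load_cells <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    gray <- read_gray_image(manifest$gray_path[i])
    mask <- as_binary_matrix(read_gray_image(manifest$cell_mask_path[i]) > 127)
    nuc <- NULL
    np <- manifest$nucleus_mask_path[i]
    if (!is.null(np) && !is.na(np) && nzchar(np))
      nuc <- as_binary_matrix(read_gray_image(np) > 127)
    cell_image(gray, mask, nuc, cell_id = manifest$cell_id[i],
               condition = manifest$condition[i], check = FALSE)
  })
}

#' Preprocess raw frames listed in a manifest into centered cell images
#'
#' Applies [preprocess_cell()] (threshold, largest object, hole filling,
#' centering) to each listed gray image and writes `<cell_id>_gray.png`
#' and `<cell_id>_mask.png` pairs plus a new manifest into `out_dir`.
#'
#' @param manifest data frame from [load_manifest()] or a path.
#' @param out_dir output directory.
#' @param frame_side output frame (default 1024).
#' @param threshold `"auto"` (Otsu) or a fixed numeric level.
#' @param fill fill mask holes?
#' @return path of the written manifest, invisibly.
#' @export
preprocess_manifest <- function(manifest, out_dir, frame_side = 1024L,
                                threshold = "auto", fill = TRUE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    gray <- read_gray_image(manifest$gray_path[i])
    cell <- preprocess_cell(gray, threshold = threshold,
                            frame_side = frame_side, fill = fill,
                            cell_id = manifest$cell_id[i],
                            condition = manifest$condition[i])
    gp <- file.path(out_dir, paste0(cell$cell_id, "_gray.png"))
    mp <- file.path(out_dir, paste0(cell$cell_id, "_mask.png"))
    png::writePNG(cell$gray / 255, gp)
    png::writePNG(cell$cell_mask + 0, mp)
    data.frame(cell_id = cell$cell_id, condition = cell$condition,
               gray_path = gp, cell_mask_path = mp, nucleus_mask_path = "")
  })
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  invisible(mpath)
}
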