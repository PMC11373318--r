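# Reading and writing expression tables and image patches, plus the in-memory
# dataset container shared by all pipeline stages.

#' Construct a spot-level dataset
#'
#' Bundles paired spot expression vectors and image patches with their
#' patient (WSI) labels. Patches are optional: preprocessing operations work
#' on expression alone.
#'
#' @param expression numeric matrix, spots x markers.
#' @param patient character or factor of patient / WSI ids, one per spot.
#' @param marker_names column names of `expression`.
#' @param patches `H x W x 3 x n_spots` array in `[0, 1]`, or `NULL`.
#' @param meta data frame of per-spot metadata (`wsi_id`, `row`, `col`, ...).
#' @param transformed logical flag: is `expression` in transformed z-space?
#' @return an object of class `"ouro_dataset"`.
#' @export
ouro_dataset <- function(expression, patient,
                         marker_names = colnames(expression), patches = NULL,
                         meta = NULL, transformed = FALSE) {
  expression <- as.matrix(expression)
  if (is.null(marker_names))
    marker_names <- paste0("marker", seq_len(ncol(expression)))
  colnames(expression) <- marker_names
  patient <- as.character(patient)
  if (length(patient) != nrow(expression))
    stop("patient labels and expression rows differ in length")
  if (!is.null(patches) && dim(patches)[4L] != nrow(expression))
    stop("patch count does not match number of spots")
  if (is.null(meta))
    meta <- data.frame(wsi_id = patient, row = seq_along(patient) - 1L,
                       col = 0L)
  structure(list(expression = expression, patient = patient,
                 marker_names = marker_names, patches = patches,
                 meta = meta, transformed = transformed),
            class = "ouro_dataset")
}

#' @export
print.ouro_dataset <- function(x, ...) {
  cat(sprintf("Spot dataset: %d spots, %d markers, %d patients%s\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$patient)),
              if (is.null(x$patches)) " (no patches)" else
                sprintf(", patches %dx%d px",
                        dim(x$patches)[1L], dim(x$patches)[2L])))
  cat("  expression space:", if (x$transformed) "transformed" else "raw", "\n")
  invisible(x)
}

#' Subset a dataset by spot index
#' @param x an `"ouro_dataset"`.
#' @param i integer or logical spot index.
#' @param ... unused.
#' @return the subsetted `"ouro_dataset"`.
#' @export
`[.ouro_dataset` <- function(x, i, ...) {
  ouro_dataset(x$expression[i, , drop = FALSE], x$patient[i],
               x$marker_names,
               if (!is.null(x$patches)) x$patches[, , , i, drop = FALSE],
               x$meta[i, , drop = FALSE], x$transformed)
}

#' Read a wide-format spot expression table
#'
#' The table must contain columns `wsi_id`, `row`, `col` and one numeric
#' column per requested marker; marker columns may appear in any order and
#' are re-ordered to `marker_names`.
#'
#' @param path CSV or TSV file (separator inferred from the extension).
#' @param marker_names markers to extract, in the desired order.
#' @return an `"ouro_dataset"` without patches, in raw expression space.
#' @export
read_spots_table <- function(path, marker_names = default_marker_names()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("wsi_id", "row", "col"))
    if (!col %in% names(df)) stop("missing required column '", col, "'")
  miss <- setdiff(marker_names, names(df))
  if (length(miss))
    stop("missing marker column(s): ", paste(miss, collapse = ", "))
  expr <- as.matrix(df[, marker_names, drop = FALSE])
  if (!is.numeric(expr)) {
    bad <- which(!vapply(df[marker_names], is.numeric, logical(1)))[1L]
    badrow <- which(is.na(suppressWarnings(
      as.numeric(df[[marker_names[bad]]]))))[1L]
    stop("non-numeric value in marker column '", marker_names[bad],
         "' at row ", badrow)
  }
  if (any(expr < 0))
    warning("expression table contains negative values; ",
            "accepted (values may already be transformed)")
  ouro_dataset(expr, df$wsi_id, marker_names,
               meta = df[, c("wsi_id", "row", "col")])
}

#' Write a dataset's spot expression as a wide CSV/TSV table
#'
#' @param dataset an `"ouro_dataset"`.
#' @param path output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_spots_table <- function(dataset, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(dataset$meta[, c("wsi_id", "row", "col")],
              as.data.frame(dataset$expression))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an RGB patch losslessly
#'
#' PNG or uncompressed TIFF, 8 bits per channel. Values already on the 8-bit
#' grid round-trip bit-exactly through [read_patch()].
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_patch <- function(img, path) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("img must be an H x W x 3 array")
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  } else {
    stop("unsupported extension '.", ext, "'; supported formats: png, tif, ",
         "tiff")
  }
  invisible(path)
}

#' Read an RGB patch
#'
#' @param path PNG or TIFF file.
#' @param promote_gray if `TRUE` (default) a single-channel image is promoted
#'   to three identical channels; if `FALSE` it is an error.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_patch <- function(path, promote_gray = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported extension '.", ext, "'; supported formats: png, tif, ",
         "tiff")
  }
  if (length(dim(img)) == 2L) {
    if (!promote_gray) stop("grayscale image and promote_gray = FALSE: ", path)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]      # drop alpha
  } else if (dim(img)[3L] == 1L) {
    if (!promote_gray) stop("grayscale image and promote_gray = FALSE: ", path)
    img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  }
  img
}

# convert between display space [0, 1] and model space [-1, 1]
patch_to_model <- function(img) img * 2 - 1
model_to_patch <- function(img) pmin(pmax((img + 1) / 2, 0), 1)

# snap to the 8-bit grid used by the lossless writers
quantize8 <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255
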