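# Multi-page TIFF I/O for two-channel confocal stacks, with a JSON sidecar
# carrying voxel size (and optionally ground truth).

#' Write a two-channel confocal stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered channel-major (CZYX): all z planes of channel A, then
#' all z planes of channel B. Intensities are scaled to 16-bit by the joint
#' maximum, which is recorded in the sidecar.
#'
#' @param channel_a,channel_b 3D arrays (z, y, x).
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param voxel_size nm per axis (scalar or length-3 z, y, x).
#' @param truth optional ground-truth list stored in the sidecar (matrices
#'   are serialized as nested arrays; logical masks are omitted).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(channel_a, channel_b, path, voxel_size,
                             truth = NULL) {
  if (!identical(dim(channel_a), dim(channel_b)))
    stop("channels must have identical dimensions", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  top <- max(max(channel_a), max(channel_b), 1)
  pages <- c(lapply(seq_len(dim(channel_a)[1L]),
                    function(z) channel_a[z, , ] / top),
             lapply(seq_len(dim(channel_b)[1L]),
                    function(z) channel_b[z, , ] / top))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(shape = dim(channel_a), n_channels = 2L,
               voxel_size_nm = voxel_size, intensity_scale = top,
               page_order = "CZYX")
  if (!is.null(truth)) {
    keep <- truth[setdiff(names(truth), c("mask_a", "mask_b"))]
    side$truth <- keep
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a two-channel confocal stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar (or pass `voxel_size`).
#' @param voxel_size override when no sidecar exists.
#' @return list with `channel_a`, `channel_b`, `voxel_size_nm`, and any
#'   sidecar `truth`.
#' @export
read_stack_tiff <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  if (is.null(side) && is.null(voxel_size))
    stop("no JSON sidecar at ", side_path,
         "; supply voxel_size explicitly", call. = FALSE)
  nz <- length(pages) %/% 2L
  scale <- if (!is.null(side)) side$intensity_scale else 1
  to_stack <- function(pp) {
    a <- array(0, dim = c(length(pp), dim(pp[[1L]])))
    for (z in seq_along(pp)) a[z, , ] <- pp[[z]] * scale
    a
  }
  list(channel_a = to_stack(pages[seq_len(nz)]),
       channel_b = to_stack(pages[nz + seq_len(nz)]),
       voxel_size_nm = if (!is.null(side)) side$voxel_size_nm else
         rep_len(as.numeric(voxel_size), 3L),
       truth = side$truth)
}
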