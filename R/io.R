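#' Read and write volumetric images (NIfTI-1)
#'
#' Volumes travel as plain R arrays with a `grid` attribute; on disk they are
#' NIfTI-1 files (float32) whose pixel dimensions and offset carry the grid.
#' A write-then-read round trip preserves float32 data bit-exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: array (3-D or 4-D) with a `grid` attribute.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  orig <- if (isTRUE(attr(xf, "code") > 0)) unname(xf[1:3, 4]) else c(0, 0, 0)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  attr(arr, "grid") <- volume_grid(dim(arr)[1:3], pd, orig)
  arr
}

#' @rdname read_volume
#' @param image 3-D or 4-D numeric array.
#' @param grid a [volume_grid()]; defaults to the image's attribute.
#' @export
write_volume <- function(image, path, grid = attr(image, "grid")) {
  if (is.null(grid)) grid <- volume_grid(dim(image)[1:3])
  arr <- unclass(image)
  attributes(arr) <- list(dim = dim(arr))
  vs <- grid$voxel_size_mm
  hdr <- list(pixdim = c(-1, vs, rep(1, 4)),
              sform_code = 2L,
              srow_x = c(vs[1], 0, 0, grid$origin_mm[1]),
              srow_y = c(0, vs[2], 0, grid$origin_mm[2]),
              srow_z = c(0, 0, vs[3], grid$origin_mm[3]))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "float")
  invisible(RNifti::writeNifti(img, path))
}

#' Read and write block schedules as BIDS-style events tables
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`.
#'
#' @param schedule a [make_block_schedule()] result.
#' @param path file path (`.tsv`).
#' @export
write_events <- function(schedule, path) {
  df <- data.frame(onset = schedule$onset_s, duration = schedule$duration_s,
                   trial_type = schedule$condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_events
#' @param tr_s,n_volumes run geometry (not stored in the events dialect).
#' @return `read_events`: a `block_schedule`.
#' @export
read_events <- function(path, tr_s = 2.5, n_volumes = 179L) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  sched <- data.frame(condition = df$trial_type, onset_s = df$onset,
                      duration_s = df$duration, stringsAsFactors = FALSE)
  lead_in <- if (nrow(sched)) min(sched$onset_s) else 0
  structure(sched, tr_s = tr_s, n_volumes = as.integer(n_volumes),
            lead_in_rest_s = lead_in, run_index = NA_integer_,
            class = c("block_schedule", "data.frame"))
}

#' Write a physiological trace as two-column TSV files
#'
#' The cardiac file holds peak times (column `time`, `value` fixed at 1); the
#' respiratory file holds sample times and belt amplitudes.
#'
#' @param trace a [simulate_physio()] result.
#' @param cardiac_path,resp_path output paths (`.tsv`).
#' @export
write_physio <- function(trace, cardiac_path, resp_path) {
  write.table(data.frame(time = trace$cardiac_peaks_s, value = 1),
              cardiac_path, sep = "\t", quote = FALSE, row.names = FALSE)
  t <- (seq_along(trace$resp_waveform) - 1L) / trace$sampling_rate_hz
  write.table(data.frame(time = t, value = trace$resp_waveform),
              resp_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_physio
#' @return `read_physio`: a `physio_trace`.
#' @export
read_physio <- function(cardiac_path, resp_path) {
  card <- read.delim(cardiac_path, sep = "\t")
  resp <- read.delim(resp_path, sep = "\t")
  dt <- diff(resp$time)
  structure(list(cardiac_peaks_s = card$time,
                 resp_waveform = resp$value,
                 sampling_rate_hz = 1 / median(dt),
                 duration_s = max(resp$time) + median(dt)),
            class = "physio_trace")
}

#' Write a labelled numeric matrix (design or nuisance) as TSV
#'
#' @param mat numeric matrix with column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  write.table(as.data.frame(unclass(mat)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.delim(path, sep = "\t", check.names = FALSE))
}
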