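#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti; voxel spacing (mm) is stored in the header
#' pixel dimensions.
#'
#' @param v A 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sp A [spacing()].
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a list with `data` (3D array) and
#'   `spacing`.
#' @export
write_volume_nifti <- function(v, path, sp = spacing(4, 4, 5)) {
  sp <- as_spacing(sp)
  img <- RNifti::asNifti(v, reference = NULL)
  RNifti::pixdim(img) <- as.numeric(sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), dim(img)),
       spacing = spacing(pd[1], pd[2], pd[3]))
}

#' Read / write boxes as JSON-lines
#'
#' One JSON record per line with `subject_id`, the six voxel-space box
#' coordinates and optional `score` and `round` fields — the interchange
#' format for ground truth, detections and pseudo labels.
#'
#' @param boxes A box matrix or detections data frame.
#' @param path File path.
#' @param subject_id Subject identifier stored in each record.
#' @param round Optional round index stored in each record.
#' @param append Append to an existing file.
#' @return `write_boxes_jsonl()` returns `path` invisibly.
#' @export
write_boxes_jsonl <- function(boxes, path, subject_id = 1L, round = NULL,
                              append = FALSE) {
  df <- if (is.data.frame(boxes)) boxes else as.data.frame(as_box_matrix(boxes))
  lines <- vapply(seq_len(nrow(df)), function(i) {
    rec <- list(subject_id = subject_id,
                x0 = df$x0[i], y0 = df$y0[i], z0 = df$z0[i],
                x1 = df$x1[i], y1 = df$y1[i], z1 = df$z1[i])
    if (!is.null(df$score)) rec$score <- df$score[i]
    if (!is.null(round)) rec$round <- round
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  if (append) {
    cat(lines, file = path, sep = "\n", append = TRUE)
    if (length(lines)) cat("\n", file = path, append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_boxes_jsonl
#' @return `read_boxes_jsonl()` returns a data frame with `subject_id`,
#'   box columns and (when present) `score` and `round`.
#' @export
read_boxes_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- empty_detections()
    out$subject_id <- integer(0)
    return(out)
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  cols <- unique(unlist(lapply(recs, names)))
  out <- as.data.frame(lapply(cols, function(cn) {
    vapply(recs, function(r) as.numeric(r[[cn]] %||% NA_real_), numeric(1))
  }))
  names(out) <- cols
  out
}

#' Checkpoint the round state as JSON
#'
#' Serializes the audit trail of one adaptation round: round index, mu,
#' the size histogram, the bin edges and the anchor shapes.
#'
#' @param state A list with `r`, `prior`, `anchors`, `binning` (as inside
#'   the adaptation loop) or a fitted `"uda_detector"`.
#' @param path File path.
#' @return `write_prior_checkpoint()` returns `path` invisibly;
#'   `read_prior_checkpoint()` the parsed list.
#' @export
write_prior_checkpoint <- function(state, path) {
  prior <- state$prior
  anchors <- state$anchors
  binning <- state$binning
  rec <- list(round = state$r %||% anchors$round, mu = prior$mu,
              h = prior$h, edges = binning$edges,
              anchors = anchors$shapes)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_prior_checkpoint
#' @export
read_prior_checkpoint <- function(path) {
  rec <- jsonlite::fromJSON(path)
  rec$anchors <- matrix(unlist(rec$anchors), ncol = 3L)
  rec
}
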