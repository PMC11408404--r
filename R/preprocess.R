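# Data preparation: mean imputation, min-max normalization, 30-s epoch /
# 10-s frame segmentation, stratified train/test splitting.

#' Fill missing samples with the channel mean
#'
#' Missing positions are replaced by the arithmetic mean of the observed
#' samples of the same channel; observed positions are untouched.
#'
#' @param signal numeric sample vector.
#' @param mask logical vector, `TRUE` = missing; `NA`s in `signal` are also
#'   treated as missing when `mask` is `NULL`.
#' @return imputed numeric vector.
#' @examples
#' impute_missing(c(1, NA, 3))
#' @export
impute_missing <- function(signal, mask = NULL) {
  if (is.null(mask)) mask <- is.na(signal)
  if (length(mask) != length(signal))
    stop("`mask` must have the same length as `signal`", call. = FALSE)
  mask <- mask | is.na(signal)
  if (all(mask)) stop("all samples missing: no mean defined", call. = FALSE)
  if (any(mask)) signal[mask] <- mean(signal[!mask])
  signal
}

#' Min-max normalization to [0, 1]
#'
#' `y = (x - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#' A constant vector maps to all zeros (the degenerate 0/0 is defined as 0).
#' Applied per channel per recording, so amplitude contrast between frames
#' of one recording is preserved.
#'
#' @param values finite numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(values) {
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  r <- range(values)
  if (r[1] == r[2]) return(rep(0, length(values)))
  (values - r[1]) / (r[2] - r[1])
}

#' Normalize every channel of a recording to [0, 1]
#' @param recording an [eeg_recording()].
#' @return the recording with each channel min-max normalized.
#' @export
normalize_recording <- function(recording) {
  recording$samples <- t(apply(recording$samples, 1, minmax_normalize))
  rownames(recording$samples) <- recording$channel_labels
  recording
}

#' Slice a recording into 30-s epochs and 10-s frames
#'
#' Each channel is cut into consecutive `epoch_s` epochs, each subdivided
#' into `epoch_s / frame_s` frames; a trailing partial epoch is discarded.
#' Frames are half-open intervals `[start, start + frame_s)` with 0-based
#' sample indices.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_s epoch length in seconds (default 30).
#' @param frame_s frame length in seconds (default 10); must divide `epoch_s`
#'   and give an integral number of samples.
#' @return object of class `eeg_segments`: a list with `index` (data frame:
#'   channel, epoch_index, frame_index, start_sample, all 0-based except
#'   channel) and `values` (matrix, one row per segment, `frame_s * fs`
#'   columns).
#' @export
segment_recording <- function(recording, epoch_s = 30, frame_s = 10) {
  fs <- recording$fs
  if (epoch_s %% frame_s != 0)
    stop("`frame_s` must divide `epoch_s`", call. = FALSE)
  n_per_frame <- frame_s * fs
  if (abs(n_per_frame - round(n_per_frame)) > 1e-9)
    stop("`frame_s * fs` must be an integer sample count", call. = FALSE)
  n_per_frame <- as.integer(round(n_per_frame))
  frames_per_epoch <- epoch_s %/% frame_s
  n <- ncol(recording$samples)
  n_epochs <- floor(n / (epoch_s * fs))
  if (n_epochs < 1) stop("recording shorter than one epoch", call. = FALSE)
  n_seg_per_ch <- n_epochs * frames_per_epoch
  chs <- recording$channel_labels
  idx <- data.frame(
    channel = rep(chs, each = n_seg_per_ch),
    epoch_index = rep(rep(seq_len(n_epochs) - 1L, each = frames_per_epoch),
                      times = length(chs)),
    frame_index = rep(rep(seq_len(frames_per_epoch) - 1L, times = n_epochs),
                      times = length(chs)),
    stringsAsFactors = FALSE)
  idx$start_sample <- as.integer(
    (idx$epoch_index * frames_per_epoch + idx$frame_index) * n_per_frame)
  vals <- matrix(0, nrow = nrow(idx), ncol = n_per_frame)
  for (r in seq_len(nrow(idx))) {
    s0 <- idx$start_sample[r]
    vals[r, ] <- recording$samples[idx$channel[r], (s0 + 1):(s0 + n_per_frame)]
  }
  structure(list(index = idx, values = vals, fs = fs,
                 frame_s = frame_s, epoch_s = epoch_s),
            class = "eeg_segments")
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf("%d segments of %g s (%d samples at %g Hz), %d channels\n",
              nrow(x$index), x$frame_s, ncol(x$values), x$fs,
              length(unique(x$index$channel))))
  invisible(x)
}

#' Stratified 70/30 train/test split
#'
#' Deterministic given `seed`. With `stratified = TRUE` the train fraction is
#' applied within each class (rounded to the nearest segment), so class
#' balance carries over to both partitions.
#'
#' @param segment_ids vector of unique segment identifiers.
#' @param labels binary (0/1) labels aligned to `segment_ids`; required when
#'   `stratified = TRUE`.
#' @param train_frac fraction of segments assigned to training (default 0.7).
#' @param seed integer seed.
#' @param stratified stratify on the labels? (default `TRUE`).
#' @return object of class `split_indices`: list with `train_ids` /
#'   `test_ids` (disjoint id sets whose union is `segment_ids`), the
#'   matching integer positions `train_idx` / `test_idx`, `seed` and
#'   `stratified`.
#' @export
split_dataset <- function(segment_ids, labels = NULL, train_frac = 0.7,
                          seed = 1L, stratified = TRUE) {
  n <- length(segment_ids)
  if (n < 2) stop("need at least two segments to split", call. = FALSE)
  if (anyDuplicated(segment_ids)) stop("segment ids must be unique", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  if (stratified) {
    if (is.null(labels) || length(labels) != n)
      stop("stratified split needs labels aligned to segment_ids", call. = FALSE)
    if (!is_binary(labels)) stop("labels must be binary 0/1", call. = FALSE)
    if (length(unique(labels)) < 2)
      stop("stratified split requires both classes present", call. = FALSE)
    train <- with_seed(seed, {
      unlist(lapply(c(0, 1), function(cl) {
        ids <- segment_ids[labels == cl]
        sample(ids, round(train_frac * length(ids)))
      }), use.names = FALSE)
    })
  } else {
    train <- with_seed(seed, sample(segment_ids, round(train_frac * n)))
  }
  train_idx <- sort(match(train, segment_ids))
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train_ids = segment_ids[train_idx],
                 test_ids = segment_ids[test_idx],
                 train_idx = train_idx, test_idx = test_idx,
                 seed = as.integer(seed), stratified = stratified),
            class = "split_indices")
}
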