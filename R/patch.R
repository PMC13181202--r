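#' Clip-and-rescale HU intensity normalization
#'
#' Clips intensities to a CT window and min-max scales the window to `[0, 1]`.
#' The default window `[-1000, 400]` HU spans air to bone and is the standard
#' preprocessing window for lung nodule CNNs.
#'
#' @param x numeric array of HU intensities.
#' @param window length-2 clip window in HU.
#' @return array of the same shape, values in `[0, 1]`.
#' @export
normalize_hu <- function(x, window = c(-1000, 400)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  x <- pmin(pmax(x, window[1]), window[2])
  (x - window[1]) / (window[2] - window[1])
}

#' Extract a cubic nodule patch from a CT volume
#'
#' Cuts a `size`^3 cube centred on the annotated nodule. Regions falling
#' outside the volume are padded with the volume's minimum intensity
#' (air-equivalent), avoiding spurious bright borders. Intensities are
#' normalized with [normalize_hu()] unless `normalize = FALSE`; padding is
#' applied before normalization so pad voxels map to the window floor.
#'
#' @param volume a [ct_volume()].
#' @param annotation one annotation row as returned by [parse_annotations()]
#'   (fields `coordX, coordY, coordZ`, optional `ratings`).
#' @param size cube edge in voxels (default 32).
#' @param normalize apply [normalize_hu()] (default TRUE).
#' @param window HU window passed to [normalize_hu()].
#' @param aggregate rating aggregation rule for [assign_label()].
#' @return an object of class `labeled_patch`: list with `cube` (size^3 array,
#'   `(z,y,x)`), `label` (`"benign"`, `"malignant"`, `"excluded"`, or NA when
#'   unrated), `source_uid`, `center_voxel` (zero-based `(z,y,x)`).
#' @export
extract_patch <- function(volume, annotation, size = 32L, normalize = TRUE,
                          window = c(-1000, 400), aggregate = "mean") {
  ctr <- world_to_voxel(volume, c(annotation$coordX, annotation$coordY,
                                  annotation$coordZ))
  d <- dim(volume$voxels)
  half <- size %/% 2L
  lo <- ctr - half          # zero-based inclusive
  hi <- lo + size - 1L
  pad_val <- min(volume$voxels)
  cube <- array(pad_val, c(size, size, size))
  src_lo <- pmax(lo, 0L); src_hi <- pmin(hi, d - 1L)
  dst_lo <- src_lo - lo
  cube[dst_lo[1] + seq_len(src_hi[1] - src_lo[1] + 1L),
       dst_lo[2] + seq_len(src_hi[2] - src_lo[2] + 1L),
       dst_lo[3] + seq_len(src_hi[3] - src_lo[3] + 1L)] <-
    volume$voxels[src_lo[1] + seq_len(src_hi[1] - src_lo[1] + 1L),
                  src_lo[2] + seq_len(src_hi[2] - src_lo[2] + 1L),
                  src_lo[3] + seq_len(src_hi[3] - src_lo[3] + 1L)]
  if (normalize) cube <- normalize_hu(cube, window)
  ratings <- annotation$ratings
  if (is.list(ratings) && length(ratings) == 1L) ratings <- ratings[[1L]]
  label <- if (length(ratings)) assign_label(ratings, aggregate) else NA_character_
  structure(list(cube = cube, label = label, source_uid = volume$series_uid,
                 center_voxel = ctr),
            class = "labeled_patch")
}

#' @export
print.labeled_patch <- function(x, ...) {
  cat(sprintf("<labeled_patch %s: %s, label %s, center (%s)>\n", x$source_uid,
              paste(dim(x$cube), collapse = "x"), x$label,
              paste(x$center_voxel, collapse = ",")))
  invisible(x)
}

#' Stochastic augmentation of a nodule patch
#'
#' Reproducible pipeline: zero-pad the 32-cube to `pad_to`^3 at uniformly
#' drawn offsets, crop a random 32-cube back out, flip along the width axis
#' with probability 1/2, and with probability `cutout_prob` zero out one
#' axis-aligned cuboid with sides uniform in `cutout_range`. The label is
#' never touched. The RNG draw order (the reproducibility contract) is: 3 pad
#' offsets, 3 crop offsets, 1 flip uniform, 1 cutout uniform, then - only if
#' the cutout fires - 3 sizes and 3 positions.
#'
#' @param patch a `labeled_patch` or bare 3D cube.
#' @param seed integer seed; the same seed always yields the same output.
#' @param pad_to padded edge length (default 36).
#' @param flip_axes array axes eligible for flipping (default 3, the width
#'   axis; "horizontal" flip in the scanner frame).
#' @param cutout_prob probability of applying the cutout (default 0.5).
#' @param cutout_range inclusive side-length range of the cutout cuboid.
#' @return object of the same type as `patch`, cube dimensions unchanged.
#' @export
augment_patch <- function(patch, seed, pad_to = 36L, flip_axes = 3L,
                          cutout_prob = 0.5, cutout_range = c(4L, 8L)) {
  cube <- if (inherits(patch, "labeled_patch")) patch$cube else patch
  d <- dim(cube)
  stopifnot(length(d) == 3L, all(d == d[1L]), pad_to >= d[1L])
  size <- d[1L]; slack <- pad_to - size
  out <- with_seed(seed, {
    pad_off <- sample(0:slack, 3L, replace = TRUE)
    crop_off <- sample(0:slack, 3L, replace = TRUE)
    do_flip <- runif(1L) < 0.5
    do_cut <- runif(1L) < cutout_prob
    big <- array(0, rep(pad_to, 3L))
    big[pad_off[1] + seq_len(size), pad_off[2] + seq_len(size),
        pad_off[3] + seq_len(size)] <- cube
    res <- big[crop_off[1] + seq_len(size), crop_off[2] + seq_len(size),
               crop_off[3] + seq_len(size)]
    if (do_flip) for (ax in flip_axes) {
      idx <- rep(list(quote(expr = )), 3L); idx[[ax]] <- size:1
      res <- do.call(`[`, c(list(res), idx))
    }
    if (do_cut) {
      sides <- sample(cutout_range[1]:cutout_range[2], 3L, replace = TRUE)
      pos <- vapply(sides, function(s) sample(0:(size - s), 1L), numeric(1))
      res[pos[1] + seq_len(sides[1]), pos[2] + seq_len(sides[2]),
          pos[3] + seq_len(sides[3])] <- 0
    }
    res
  })
  if (inherits(patch, "labeled_patch")) { patch$cube <- out; patch } else out
}

#' Stratified train/validation/test split
#'
#' Splits patch indices into disjoint, exhaustive partitions stratified by
#' label, reproducibly for a given seed. Per-class partition sizes use the
#' largest-remainder method so they always sum to the class count.
#'
#' @param labels character/factor vector of patch labels.
#' @param fractions length-3 nonnegative fractions `(train, validation, test)`
#'   summing to 1.
#' @param seed integer RNG seed.
#' @return object of class `dataset_split`: list with integer index vectors
#'   `train`, `validation`, `test`, the `assignment` factor, and a
#'   `counts` table (partition x label).
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  labels <- as.character(labels)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("fractions must be 3 values summing to 1", call. = FALSE)
  parts <- c("train", "validation", "test")
  n_parts <- sum(fractions > 0)
  assignment <- character(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_parts)
        stop("class '", cl, "' has fewer patches (", length(idx),
             ") than partitions (", n_parts, ")", call. = FALSE)
      idx <- sample(idx)
      raw <- fractions * length(idx)
      sizes <- floor(raw)
      rem <- length(idx) - sum(sizes)
      if (rem > 0) {
        order_frac <- order(raw - sizes, decreasing = TRUE)
        sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1L
      }
      bounds <- cumsum(c(0L, sizes))
      for (p in 1:3) if (sizes[p] > 0)
        assignment[idx[(bounds[p] + 1L):bounds[p + 1L]]] <- parts[p]
    }
  })
  assignment <- factor(assignment, levels = parts)
  structure(list(train = which(assignment == "train"),
                 validation = which(assignment == "validation"),
                 test = which(assignment == "test"),
                 assignment = assignment,
                 counts = table(partition = assignment, label = labels)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  print(x$counts)
  invisible(x)
}

#' Persist a dataset split as CSV
#'
#' @param split a [split_dataset()] result.
#' @param uids per-patch identifiers.
#' @param labels per-patch labels.
#' @param path output CSV path (columns uid, partition, label).
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, uids, labels, path) {
  write.csv(data.frame(uid = uids, partition = split$assignment,
                       label = labels),
            path, row.names = FALSE)
  invisible(path)
}
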