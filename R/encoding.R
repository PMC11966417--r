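#' Construct a sequence-classification dataset
#'
#' The container consumed by every training and analysis routine: a
#' time-major array of input sequences plus zero-based integer class labels.
#'
#' @param sequences numeric array of dimension n_samples x T x d with finite
#'   values (for image-derived data, bounded in \[0, 1\]).
#' @param labels integer vector of length n_samples with values in
#'   `0:(n_classes - 1)`.
#' @param n_classes number of classes; defaults to `max(labels) + 1`.
#' @param split `"train"` or `"test"`.
#' @return an object of class `sequence_dataset` with elements `sequences`,
#'   `labels`, `n_classes`, `split`.
#' @export
sequence_dataset <- function(sequences, labels,
                             n_classes = max(labels) + 1L,
                             split = c("train", "test")) {
  split <- match.arg(split)
  if (!is.array(sequences) || length(dim(sequences)) != 3L) {
    stop_param("`sequences` must be an n_samples x T x d array")
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(sequences)[1]) {
    stop_param("`labels` length must match the number of samples")
  }
  if (any(labels < 0L) || any(labels >= n_classes)) {
    stop_param("labels must lie in [0, n_classes)")
  }
  if (any(!is.finite(sequences))) stop_param("sequences must be finite")
  structure(
    list(
      sequences = sequences,
      labels = labels,
      n_classes = as.integer(n_classes),
      split = split
    ),
    class = "sequence_dataset"
  )
}

#' @export
print.sequence_dataset <- function(x, ...) {
  d <- dim(x$sequences)
  cat(sprintf(
    "<sequence_dataset> %s: %d samples, T=%d, d=%d, %d classes\n",
    x$split, d[1], d[2], d[3], x$n_classes
  ))
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset a [sequence_dataset()].
#' @return integer sample count.
#' @export
n_samples <- function(dataset) {
  dim(dataset$sequences)[1]
}

#' Encode an image as a row-scanned sequence
#'
#' Images are presented to recurrent networks one row per timestep: a H x W
#' grayscale image becomes T = H timesteps of d = W values; an H x W x 3 RGB
#' image becomes T = H timesteps of d = 3 W values with the three channel
#' values of each pixel interleaved per pixel (r1, g1, b1, r2, g2, b2, ...).
#' Intensities are divided by `scale_max` so they land in \[0, 1\].
#'
#' @param image 2-D (H x W) or 3-D (H x W x 3) numeric array.
#' @param scale_max intensity maximum of the source format (255 for 8-bit
#'   images; use 1 for data already in \[0, 1\]).
#' @return a T x d numeric matrix.
#' @export
#' @examples
#' img <- matrix(0:255, 16, 16)
#' dim(image_to_sequence(img))  # 16 x 16
image_to_sequence <- function(image, scale_max = 255) {
  nd <- length(dim(image))
  if (is.matrix(image)) {
    return(image / scale_max)
  }
  if (nd == 3L) {
    if (dim(image)[3] == 1L) {
      return(image[, , 1] / scale_max)
    }
    if (dim(image)[3] != 3L) {
      stop_param("unsupported channel count: ", dim(image)[3],
                 " (expected 1 or 3)")
    }
    h <- dim(image)[1]
    w <- dim(image)[2]
    out <- matrix(0, h, 3L * w)
    for (t in seq_len(h)) {
      # image[t, , ] is W x 3; transposing and flattening interleaves the
      # channels per pixel.
      out[t, ] <- as.vector(t(image[t, , ])) / scale_max
    }
    return(out)
  }
  if (is.numeric(image) && is.null(dim(image))) {
    # length-L single-channel timeseries -> T = L, d = 1
    return(matrix(image / scale_max, ncol = 1L))
  }
  stop_param("`image` must be a 2-D or 3-D array or a numeric vector")
}

#' Encode a stack of images as a sequence dataset
#'
#' @param images list of images, or an array with the sample index last
#'   (H x W x n or H x W x 3 x n).
#' @param labels zero-based integer labels, one per image.
#' @inheritParams image_to_sequence
#' @inheritParams sequence_dataset
#' @return a [sequence_dataset()].
#' @export
images_to_dataset <- function(images, labels, n_classes = max(labels) + 1L,
                              split = c("train", "test"), scale_max = 255) {
  split <- match.arg(split)
  if (is.array(images) && !is.list(images)) {
    nd <- length(dim(images))
    n <- dim(images)[nd]
    images <- lapply(seq_len(n), function(i) {
      if (nd == 3L) images[, , i] else images[, , , i]
    })
  }
  seqs <- lapply(images, image_to_sequence, scale_max = scale_max)
  td <- dim(seqs[[1]])
  arr <- array(0, dim = c(length(seqs), td[1], td[2]))
  for (i in seq_along(seqs)) {
    if (!identical(dim(seqs[[i]]), td)) {
      stop_param("all images must share the same dimensions")
    }
    arr[i, , ] <- seqs[[i]]
  }
  sequence_dataset(arr, labels, n_classes = n_classes, split = split)
}

#' Reduce a training set to a fixed number of examples per class
#'
#' Emulates data-limited training: samples exactly `per_class` examples from
#' every class, without replacement, leaving the test split untouched (apply
#' this to the training dataset only).
#'
#' @param dataset a [sequence_dataset()].
#' @param per_class examples to keep per class.
#' @param seed integer seed.
#' @return a [sequence_dataset()] with `per_class * n_classes` samples in a
#'   shuffled order.
#' @export
reduce_training_set <- function(dataset, per_class, seed = 1L) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  if (!is_count(per_class)) stop_param("`per_class` must be a positive integer")
  counts <- tabulate(dataset$labels + 1L, nbins = dataset$n_classes)
  if (per_class > min(counts)) {
    stop_param("`per_class` (", per_class, ") exceeds the smallest class count (",
               min(counts), ")")
  }
  idx <- with_seed(seed, {
    kept <- unlist(lapply(0:(dataset$n_classes - 1L), function(cl) {
      members <- which(dataset$labels == cl)
      members[sample.int(length(members), per_class)]
    }))
    sample(kept)  # mix classes so minibatches are not class-blocked
  })
  sequence_dataset(
    dataset$sequences[idx, , , drop = FALSE],
    dataset$labels[idx],
    n_classes = dataset$n_classes,
    split = dataset$split
  )
}

read_idx_array <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L || magic[3] != 8L) {
    stop_param("not an IDX file of unsigned bytes: ", path)
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims <= 0)) {
    stop_param("corrupt IDX header in ", path)
  }
  total <- prod(dims)
  data <- readBin(con, "integer", n = total, size = 1L, signed = FALSE)
  if (length(data) != total) {
    stop_param("truncated IDX file: ", path, " (expected ", total,
               " bytes, got ", length(data), ")")
  }
  # IDX data are row-major (last index fastest); fill with reversed dims and
  # transpose back so element [i1, i2, ...] matches the file's indexing.
  aperm(array(data, dim = rev(dims)), perm = rev(seq_len(ndim)))
}

#' Load an MNIST-style IDX image/label pair as a sequence dataset
#'
#' Reads the standard IDX binary format (big-endian dimensions, unsigned
#' bytes), row-encodes each image via [image_to_sequence()] and pairs it
#' with its labels file.
#'
#' @param images_path path to an `idx3-ubyte` images file.
#' @param labels_path path to the matching `idx1-ubyte` labels file.
#' @param split dataset split tag.
#' @return a [sequence_dataset()] with T = image height and d = image width.
#' @export
load_mnist_idx <- function(images_path, labels_path,
                           split = c("train", "test")) {
  split <- match.arg(split)
  images <- read_idx_array(images_path)
  if (length(dim(images)) != 3L) {
    stop_param("expected a 3-D images file (n x H x W)")
  }
  labels <- as.integer(read_idx_array(labels_path))
  if (length(labels) != dim(images)[1]) {
    stop_param("images and labels files disagree on the number of samples")
  }
  sequence_dataset(images / 255, labels, n_classes = max(labels) + 1L,
                   split = split)
}

#' Flatten sequences for feedforward networks
#'
#' The feedforward control receives the whole image at once as a 1-D vector;
#' this flattens each T x d sequence to a length T*d row (time-major:
#' row 1, row 2, ...).
#'
#' @param dataset a [sequence_dataset()].
#' @return an n_samples x (T*d) matrix.
#' @export
flatten_sequences <- function(dataset) {
  d <- dim(dataset$sequences)
  out <- matrix(0, d[1], d[2] * d[3])
  for (t in seq_len(d[2])) {
    out[, ((t - 1) * d[3] + 1):(t * d[3])] <- dataset$sequences[, t, ]
  }
  out
}
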