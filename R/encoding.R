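#' Pixel intensities to Poisson firing rates
#'
#' Rate coding: each 8-bit pixel intensity is divided by \code{gain_divisor}
#' to give its firing rate in Hz, so the default divisor of 4 maps the
#' maximum intensity 255 to 63.75 Hz.
#'
#' @param image numeric matrix or vector of intensities in [0, 255].
#' @param gain_divisor intensity-to-rate divisor (> 0).
#' @return numeric vector of per-pixel rates (Hz), in column-major pixel
#'   order.
#' @examples
#' encode_rates(255)   # 63.75
#' @export
encode_rates <- function(image, gain_divisor = 4) {
  if (gain_divisor <= 0) stop("gain_divisor must be > 0")
  as.numeric(image) / gain_divisor
}

#' Poisson spike-train encoding of an image
#'
#' Generates one independent Bernoulli-thinned Poisson train per pixel:
#' in each time step of length \code{dt} ms a pixel with rate \eqn{r} Hz
#' spikes with probability \eqn{r \cdot dt / 1000} (exact in the
#' \eqn{dt \to 0} limit, bias of order \eqn{r\,dt}).
#'
#' @inheritParams encode_rates
#' @param duration presentation time (ms).
#' @param dt time step (ms).
#' @return logical matrix, \code{steps x pixels}; \code{TRUE} marks a spike.
#' @export
encode_poisson <- function(image, gain_divisor = 4, duration = 350,
                           dt = 0.5) {
  rates <- encode_rates(image, gain_divisor)
  steps <- round(duration / dt)
  p <- pmin(rates * dt / 1000, 1)
  matrix(stats::runif(steps * length(p)) <
           rep(p, each = steps), steps, length(p))
}

#' Synthetic MNIST-like labeled pattern sets
#'
#' Generates small grayscale images of sparse bright strokes on a dark
#' background: each class has a fixed random-walk stroke prototype and
#' samples add per-pixel Gaussian intensity jitter. Presentation order is
#' randomized across classes so features are reinforced in interleaved
#' order, as in the digit-classification setting this stands in for.
#'
#' @param n_classes number of classes (>= 2).
#' @param image_size side length in pixels.
#' @param samples_per_class samples generated per class.
#' @param stroke_density approximate fraction of bright prototype pixels.
#' @param noise_sd per-sample jitter, as a fraction of full scale (255);
#'   0 makes all samples of a class identical.
#' @param seed RNG seed for reproducibility (controls the class
#'   prototypes).
#' @param sample_seed optional separate seed for the per-sample jitter and
#'   presentation order; two calls sharing \code{seed} but differing in
#'   \code{sample_seed} yield train/test splits from the same classes.
#' @return list of class \code{labeled_image_set}: \code{images} (list of
#'   integer matrices), \code{labels} (0-based integer classes, in
#'   presentation order), \code{prototypes}, \code{image_size},
#'   \code{n_classes}.
#' @export
generate_synthetic_patterns <- function(n_classes = 3, image_size = 12,
                                        samples_per_class = 200,
                                        stroke_density = 0.18,
                                        noise_sd = 0.08, seed = 1,
                                        sample_seed = NULL) {
  if (n_classes < 2) stop("need at least 2 classes")
  set.seed(seed)
  npix <- image_size^2
  n_stroke <- max(3L, ceiling(stroke_density * npix))
  protos <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    repeat {
      mask <- stroke_walk(image_size, n_stroke)
      ok <- TRUE
      if (k > 1) {
        cors <- vapply(protos[seq_len(k - 1)], function(p)
          stats::cor(as.numeric(p), as.numeric(mask)), numeric(1))
        ok <- all(abs(cors) < 0.4)
      }
      if (ok) break
    }
    protos[[k]] <- mask
  }
  if (!is.null(sample_seed)) set.seed(sample_seed)
  n_total <- n_classes * samples_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = samples_per_class)
  images <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    base <- protos[[labels[i] + 1L]] * 255
    img <- base + if (noise_sd > 0)
      stats::rnorm(npix, 0, noise_sd * 255) else 0
    images[[i]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                          image_size, image_size)
  }
  ord <- sample.int(n_total)
  out <- list(images = images[ord], labels = labels[ord],
              prototypes = protos, image_size = image_size,
              n_classes = n_classes)
  class(out) <- "labeled_image_set"
  out
}

# random-walk stroke mask: n_on pixels switched on by a jittered walk
stroke_walk <- function(size, n_on) {
  mask <- matrix(0, size, size)
  pos <- c(sample.int(size, 1), sample.int(size, 1))
  on <- 0
  while (on < n_on) {
    if (mask[pos[1], pos[2]] == 0) {
      mask[pos[1], pos[2]] <- 1
      on <- on + 1
    }
    step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    pos <- pmin(pmax(pos + step, 1L), size)
    if (stats::runif(1) < 0.05)  # occasional jump starts a new stroke
      pos <- c(sample.int(size, 1), sample.int(size, 1))
  }
  mask
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %d images (%dx%d), %d classes\n",
              length(x$images), x$image_size, x$image_size, x$n_classes))
  invisible(x)
}

#' Read / write IDX datasets
#'
#' The big-endian IDX container used by the standard handwritten-digit
#' distributions: magic \code{0x00000803} for an image tensor
#' (N x rows x cols of unsigned bytes) and \code{0x00000801} for a label
#' vector. Gzip files are handled transparently. \code{read_idx_dataset}
#' pairs an image file with a label file into a
#' \code{labeled_image_set}.
#'
#' @param path file path (plain or .gz).
#' @return \code{read_idx} returns an array (images: N x rows x cols;
#'   labels: integer vector).
#' @export
read_idx <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  ndim <- bitwAnd(magic, 0xFF)
  dtype <- bitwAnd(bitwShiftR(magic, 8), 0xFF)
  if (bitwAnd(magic, bitwNot(0xFFFF)) != 0 || dtype != 0x08)
    stop(sprintf("bad IDX magic 0x%08X at byte offset 0", magic))
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  n <- prod(dims)
  payload <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(payload) < n)
    stop(sprintf("truncated IDX payload: expected %d bytes, got %d (offset %d)",
                 n, length(payload), 4 + 4 * ndim + length(payload)))
  if (ndim == 1) return(as.integer(payload))
  aperm(array(payload, dim = rev(dims)), rev(seq_len(ndim)))
}

#' @rdname read_idx
#' @param x array (N x rows x cols) or integer label vector.
#' @export
write_idx <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (is.null(dim(x))) {
    writeBin(0x00000801L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  } else {
    d <- dim(x)
    writeBin(bitwOr(0x00000800L, length(d)), con, size = 4, endian = "big")
    for (di in d) writeBin(as.integer(di), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(aperm(x, rev(seq_along(d))))), con)
  }
  invisible(path)
}

#' @rdname read_idx
#' @param image_path,label_path paths to the paired IDX files.
#' @export
read_idx_dataset <- function(image_path, label_path) {
  imgs <- read_idx(image_path)
  labels <- read_idx(label_path)
  if (length(dim(imgs)) != 3)
    stop("image file must hold a 3-dimensional tensor")
  if (dim(imgs)[1] != length(labels))
    stop(sprintf("image/label count mismatch: %d images vs %d labels",
                 dim(imgs)[1], length(labels)))
  images <- lapply(seq_len(dim(imgs)[1]), function(i)
    matrix(imgs[i, , ], dim(imgs)[2], dim(imgs)[3]))
  out <- list(images = images, labels = as.integer(labels),
              prototypes = NULL, image_size = dim(imgs)[2],
              n_classes = length(unique(labels)))
  class(out) <- "labeled_image_set"
  out
}

#' Export a labeled image set to IDX files
#'
#' @param dataset a \code{labeled_image_set}.
#' @param image_path,label_path output paths.
#' @export
write_idx_dataset <- function(dataset, image_path, label_path) {
  n <- length(dataset$images)
  sz <- dim(dataset$images[[1]])
  arr <- array(0L, c(n, sz[1], sz[2]))
  for (i in seq_len(n)) arr[i, , ] <- dataset$images[[i]]
  write_idx(arr, image_path)
  write_idx(dataset$labels, label_path)
  invisible(c(image_path, label_path))
}

#' Partition a presentation stream into evaluation iterations
#'
#' Contiguous, non-overlapping slices of the presentation order; the model
#' is evaluated at each slice boundary during training. A final short
#' slice is kept and flagged.
#'
#' @param n_images total number of images (or a \code{labeled_image_set}).
#' @param images_per_iteration slice length (>= 1).
#' @return data.frame with columns \code{iteration}, \code{from},
#'   \code{to}, \code{short}.
#' @export
partition_iterations <- function(n_images, images_per_iteration) {
  if (inherits(n_images, "labeled_image_set"))
    n_images <- length(n_images$images)
  if (images_per_iteration < 1) stop("images_per_iteration must be >= 1")
  starts <- seq(1L, n_images, by = images_per_iteration)
  ends <- pmin(starts + images_per_iteration - 1L, n_images)
  data.frame(iteration = seq_along(starts), from = starts, to = ends,
             short = (ends - starts + 1L) < images_per_iteration)
}

#' Sum-normalize image intensities
#'
#' Rescales every image so its intensity sum equals the dataset median sum
#' (useful for datasets with high per-sample intensity variance).
#'
#' @param dataset a \code{labeled_image_set}.
#' @return the normalized dataset.
#' @export
normalize_intensity_sum <- function(dataset) {
  sums <- vapply(dataset$images, sum, numeric(1))
  target <- stats::median(sums[sums > 0])
  dataset$images <- lapply(dataset$images, function(img) {
    s <- sum(img)
    if (s == 0) return(img)
    matrix(as.integer(pmin(pmax(round(img * target / s), 0), 255)),
           nrow(img), ncol(img))
  })
  dataset
}
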