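#' Read and write fixation tables
#'
#' The on-disk format is a plain CSV with header
#' `subject,image,x_deg,y_deg,dur_s`, one row per fixation. Positions are
#' in degrees of visual angle (not pixels); durations in seconds. Rows
#' belonging to the same `(subject, image)` pair form one scan path, in
#' row order.
#'
#' @param path CSV file path.
#' @param fixations A tibble with columns `subject`, `image`, `x_deg`,
#'   `y_deg`, `dur_s`.
#' @return `read_fixations()` returns a tibble with those columns;
#'   `write_fixations()` returns `path` invisibly.
#' @export
read_fixations <- function(path) {
  fx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_fixations(fx)
  fx
}

#' @rdname read_fixations
#' @export
write_fixations <- function(fixations, path) {
  validate_fixations(fixations)
  readr::write_csv(fixations[, c("subject", "image", "x_deg", "y_deg", "dur_s")],
                   path, progress = FALSE)
  invisible(path)
}

validate_fixations <- function(fx) {
  need <- c("subject", "image", "x_deg", "y_deg", "dur_s")
  if (!all(need %in% names(fx))) {
    stop("fixation table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(fx$x_deg)) || !all(is.finite(fx$y_deg))) {
    stop("non-finite fixation coordinates", call. = FALSE)
  }
  if (any(fx$dur_s <= 0)) stop("fixation durations must be positive", call. = FALSE)
  invisible(fx)
}

#' Read a saliency map
#'
#' Accepts either a whitespace/comma-delimited numeric matrix file or an
#' 8/16-bit grayscale PNG. The matrix is oriented so that `S[i, j]` is the
#' value at grid cell `(i, j)` (x increasing with row index, y with column
#' index); PNG images, whose rows run top-to-bottom, are transposed and
#' flipped accordingly. Negative values and all-zero maps are rejected.
#'
#' @param path File path (`.png` or a text matrix).
#' @return A nonnegative numeric matrix.
#' @export
read_saliency <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of gray+alpha
    # img[row, col]: row 1 = top. Map to S[i, j] with j = 1 at bottom.
    S <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  } else {
    first <- readLines(path, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    S <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(S) <- NULL
  }
  storage.mode(S) <- "double"
  validate_saliency(S)
  S
}

#' @rdname read_saliency
#' @param S Nonnegative numeric matrix.
#' @export
write_saliency <- function(S, path) {
  validate_saliency(S)
  utils::write.table(S, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_saliency <- function(S) {
  if (!is.matrix(S) || !is.numeric(S)) {
    stop("saliency map must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(S))) stop("saliency map has non-finite values", call. = FALSE)
  if (any(S < 0)) stop("saliency map has negative values", call. = FALSE)
  if (sum(S) == 0) stop("saliency map is identically zero", call. = FALSE)
  invisible(S)
}

# split a fixation tibble into per-path matrices (x, y, dur), keeping ids;
# an optional `path` column separates multiple paths per (subject, image)
split_paths <- function(fixations) {
  validate_fixations(fixations)
  key <- paste(fixations$subject, fixations$image, sep = "\r")
  if ("path" %in% names(fixations)) {
    key <- paste(key, fixations$path, sep = "\r")
  }
  idx <- split(seq_len(nrow(fixations)), factor(key, levels = unique(key)))
  lapply(idx, function(ii) {
    list(
      subject = fixations$subject[ii[1]],
      image = fixations$image[ii[1]],
      mat = cbind(x = fixations$x_deg[ii], y = fixations$y_deg[ii],
                  dur = fixations$dur_s[ii])
    )
  })
}

#' Split images into training and test sets
#'
#' Convenience helper mirroring the corpus protocol of holding out one
#' third of the images per subject for likelihood-based model comparison.
#'
#' @param images Character or integer vector of image identifiers.
#' @param prop_train Fraction of images assigned to training (default 2/3).
#' @param seed Optional integer seed for the split.
#' @return A list with `train` and `test` image id vectors.
#' @export
train_test_split <- function(images, prop_train = 2 / 3, seed = NULL) {
  images <- unique(images)
  if (!is.null(seed)) {
    old <- .Random.seed_store()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  n_train <- max(1, round(prop_train * length(images)))
  train <- sort(sample(seq_along(images), n_train))
  list(train = images[train], test = images[-train])
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
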