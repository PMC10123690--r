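#' Elementary image transforms
#'
#' Grayscale images are numeric matrices (rows = y, columns = x).
#' \code{flip_horizontal} reverses column order, \code{flip_vertical}
#' reverses row order, and \code{rotate90} rotates counter-clockwise by 90
#' degrees. All three are their own inverses up to the dihedral group; for
#' square images they preserve the grid dimensions.
#'
#' @param img Non-empty numeric matrix.
#' @return The transformed matrix.
#' @export
flip_horizontal <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0L)
  img[, rev(seq_len(ncol(img))), drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0L)
  img[rev(seq_len(nrow(img))), , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
rotate90 <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0L)
  t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
}

apply_op <- function(img, op) {
  switch(op,
         hflip = flip_horizontal(img),
         vflip = flip_vertical(img),
         rot90 = rotate90(img),
         stop("unknown augmentation op: ", op, call. = FALSE))
}

#' Replay a chain of augmentation ops
#'
#' @param img Numeric matrix.
#' @param ops Character vector of op names from \code{hflip}, \code{vflip},
#'   \code{rot90}, applied left to right.
#' @return The transformed matrix.
#' @export
apply_op_chain <- function(img, ops) {
  for (op in ops) img <- apply_op(img, op)
  img
}

# Fixed-order op chains covering the 7 non-identity symmetries of the square
# (dihedral group generated by the two flips and the quarter rotation):
# base ops first, then compositions of increasing length.
augmentation_op_chains <- function() {
  list(c("hflip"), c("vflip"), c("rot90"),
       c("hflip", "vflip"),              # 180-degree rotation
       c("hflip", "rot90"),              # diagonal reflection
       c("vflip", "rot90"),              # anti-diagonal reflection
       c("hflip", "vflip", "rot90"))     # 270-degree rotation
}

#' Augment each class up to a fixed image quota
#'
#' Expands every class to exactly \code{quota} images using the three label
#' preserving transforms (horizontal flip, vertical flip, 90-degree rotation)
#' and their compositions. All originals are retained. New images are
#' generated deterministically: composite transforms are enumerated in a
#' fixed order (the 7 non-identity symmetries of the square, shortest chains
#' first), cycling round-robin over the source images within each transform.
#' When the 7-per-source symmetry pool is exhausted the cycle restarts,
#' producing exact duplicates, and a warning is emitted.
#'
#' @param images_by_class Named list of classes, each a list of numeric
#'   square matrices (or of \code{list(pixels = ...)} records).
#' @param quota Target per-class count (default 4000); must be at least every
#'   current class count.
#' @param seed Integer recorded in the manifest; the procedure itself is
#'   deterministic.
#' @return A list of class \code{augmented_dataset}: \code{classes} (named
#'   list of records, each \code{list(pixels, class_label, provenance, ops,
#'   source_index)}), \code{quota}, \code{seed}, and \code{counts}.
#' @export
augment_to_quota <- function(images_by_class, quota = 4000L, seed = 1L) {
  stopifnot(is.list(images_by_class), !is.null(names(images_by_class)))
  quota <- as.integer(quota)
  chains <- augmentation_op_chains()
  classes <- lapply(names(images_by_class), function(cl) {
    imgs <- images_by_class[[cl]]
    if (length(imgs) == 0L)
      stop("class '", cl, "' has no images", call. = FALSE)
    imgs <- lapply(imgs, function(im) if (is.list(im)) im$pixels else im)
    if (quota < length(imgs))
      stop("quota ", quota, " is below the current count of class '", cl, "'",
           call. = FALSE)
    if (any(!vapply(imgs, function(im) nrow(im) == ncol(im), logical(1L))))
      stop("class '", cl, "' contains non-square images; the 90-degree ",
           "rotation would change the grid dimensions", call. = FALSE)
    records <- lapply(seq_along(imgs), function(i)
      list(pixels = imgs[[i]], class_label = cl, provenance = "original",
           ops = character(0), source_index = i))
    needed <- quota - length(imgs)
    n_src <- length(imgs)
    pool <- length(chains) * n_src
    if (needed > pool)
      warning("class '", cl, "': symmetry pool exhausted (",
              pool, " distinct augmentations for ", needed,
              " needed); exact duplicates will be produced", call. = FALSE)
    aug <- vector("list", needed)
    for (j in seq_len(needed)) {
      k <- (j - 1L) %% pool
      chain <- chains[[k %/% n_src + 1L]]
      src <- k %% n_src + 1L
      aug[[j]] <- list(pixels = apply_op_chain(imgs[[src]], chain),
                       class_label = cl, provenance = "augmented",
                       ops = chain, source_index = src)
    }
    c(records, aug)
  })
  names(classes) <- names(images_by_class)
  structure(list(classes = classes, quota = quota, seed = as.integer(seed),
                 counts = vapply(classes, length, integer(1L))),
            class = "augmented_dataset")
}

#' @export
print.augmented_dataset <- function(x, ...) {
  cat("augmented_dataset: quota ", x$quota, " per class\n", sep = "")
  for (cl in names(x$classes)) {
    orig <- sum(vapply(x$classes[[cl]], function(r) r$provenance == "original",
                       logical(1L)))
    cat("  ", cl, ": ", length(x$classes[[cl]]), " images (",
        orig, " original)\n", sep = "")
  }
  invisible(x)
}
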