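# ---------------------------------------------------------------------------
# Dataset generation, reading and writing.
#
# On-disk layout follows the YOLO convention: one normalized
# `class cx cy w h` text line per box, one label file per image with a
# matching stem, plus a dataset YAML naming the split directories, the class
# count and the ordered class-name list.
# ---------------------------------------------------------------------------

#' Largest-remainder split apportionment
#'
#' @param n total count.
#' @param ratio positive split weights (e.g. c(7, 2, 1)).
#' @return integer vector summing to `n`.
#' @export
apportionSplit <- function(n, ratio) {
  stopifnot(all(ratio > 0))
  q <- n * ratio / sum(ratio)
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    ord <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[ord] <- fl[ord] + 1
  }
  as.integer(fl)
}

#' Read YOLO-format labels
#'
#' Parses `class cx cy w h` lines (normalized floats); an empty file is a
#' background image with zero boxes.  Malformed lines and out-of-range
#' values raise errors naming the file and line.
#'
#' @param path label file path.
#' @param nc optional class count for range validation.
#' @return list(cls = 0-based integer vector, boxes = cxcywh matrix).
#' @export
readYoloLabels <- function(path, nc = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(list(cls = integer(0), boxes = matrix(numeric(0), 0, 4)))
  cls <- integer(length(lines))
  boxes <- matrix(0, length(lines), 4)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("%s:%d: expected 5 fields, got %d", path, i, length(parts)))
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v)))
      stop(sprintf("%s:%d: non-numeric field", path, i))
    if (v[1] != round(v[1]) || v[1] < 0)
      stop(sprintf("%s:%d: class id must be a non-negative integer", path, i))
    if (!is.null(nc) && v[1] >= nc)
      stop(sprintf("%s:%d: class id %d out of range [0, %d)", path, i, v[1], nc))
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop(sprintf("%s:%d: coordinates must lie in [0, 1]", path, i))
    cls[i] <- as.integer(v[1])
    boxes[i, ] <- v[2:5]
  }
  list(cls = cls, boxes = boxes)
}

#' Write YOLO-format labels
#'
#' @param path output file.
#' @param cls 0-based class vector.
#' @param boxes normalized cxcywh matrix.
#' @param digits decimal places (default 6).
#' @export
writeYoloLabels <- function(path, cls, boxes, digits = 6L) {
  if (!length(cls)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fmt <- paste0("%d %.", digits, "f %.", digits, "f %.", digits, "f %.", digits, "f")
  writeLines(sprintf(fmt, cls, boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4]),
             path)
  invisible(path)
}

#' Generate a synthetic dataset on disk
#'
#' Writes class-balanced PNG images with YOLO label files into
#' train/val/test splits apportioned by the largest-remainder rule, plus a
#' dataset YAML.  Deterministic: the same seed yields byte-identical label
#' files and images.
#'
#' @param n_images total image count (spread equally over classes).
#' @param out_dir output directory (created).
#' @param class_names class-name vector (default the 15 A1..C5 classes).
#' @param ratio split weights, default 7:2:1.
#' @param size image side in pixels.
#' @param seed base RNG seed.
#' @param ... forwarded to [randomSceneSpec()] (lesion radii, noise, ...).
#' @return the dataset YAML path, invisibly.
#' @export
generateDataset <- function(n_images, out_dir,
                            class_names = defaultClassNames(),
                            ratio = c(7, 2, 1), size = 640L, seed = 0L, ...) {
  nc <- length(class_names)
  splits <- c("train", "val", "test")
  for (s in splits) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  per_class <- rep(n_images %/% nc, nc)
  extra <- n_images - sum(per_class)
  if (extra > 0) per_class[seq_len(extra)] <- per_class[seq_len(extra)] + 1
  for (ci in seq_len(nc)) {
    counts <- apportionSplit(per_class[ci], ratio)
    k <- 0L
    for (si in seq_along(splits)) {
      for (j in seq_len(counts[si])) {
        k <- k + 1L
        sseed <- as.integer((as.numeric(seed) * 1000003 +
                               (ci - 1) * 65536 + k) %% 2100000000)
        spec <- randomSceneSpec(ci - 1L, size = size, seed = sseed, ...)
        sc <- generateScene(spec)
        stem <- sprintf("%s_%04d", class_names[ci], k)
        png::writePNG(sc$image,
                      file.path(out_dir, "images", splits[si],
                                paste0(stem, ".png")))
        writeYoloLabels(file.path(out_dir, "labels", splits[si],
                                  paste0(stem, ".txt")),
                        sc$cls, sc$boxes)
      }
    }
  }
  ypath <- file.path(out_dir, "data.yaml")
  yaml::write_yaml(list(train = "images/train", val = "images/val",
                        test = "images/test",
                        nc = nc, names = as.list(class_names)), ypath)
  invisible(ypath)
}

#' Read and validate a dataset descriptor
#'
#' @param yaml_path path to the dataset YAML.
#' @param check verify that every image has a label file.
#' @return list with root, split directories, nc and names.
#' @export
datasetDescriptor <- function(yaml_path, check = TRUE) {
  y <- yaml::read_yaml(yaml_path)
  nms <- unlist(y$names)
  if (y$nc != length(nms))
    stop("dataset descriptor: nc (", y$nc, ") != number of class names (",
         length(nms), ")")
  root <- if (!is.null(y$path)) y$path else dirname(yaml_path)
  desc <- list(root = root, splits = list(train = y$train, val = y$val,
                                          test = y$test),
               nc = as.integer(y$nc), names = nms)
  if (check) {
    for (s in names(desc$splits)) {
      idir <- file.path(root, desc$splits[[s]])
      if (!dir.exists(idir)) next
      imgs <- list.files(idir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
      for (im in imgs) {
        lb <- file.path(root, sub("^images", "labels", desc$splits[[s]]),
                        paste0(tools::file_path_sans_ext(im), ".txt"))
        if (!file.exists(lb))
          stop("missing label file for image ", im, " in split ", s)
      }
    }
  }
  desc
}

#' Load a dataset split into memory
#'
#' @param desc a [datasetDescriptor()] or a YAML path.
#' @param split one of "train", "val", "test".
#' @return list(images, targets, nc, names, stems).
#' @export
loadDataset <- function(desc, split = "train") {
  if (is.character(desc)) desc <- datasetDescriptor(desc)
  idir <- file.path(desc$root, desc$splits[[split]])
  ldir <- file.path(desc$root, sub("^images", "labels", desc$splits[[split]]))
  files <- sort(list.files(idir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  images <- list(); targets <- list(); stems <- character(0)
  for (f in files) {
    img <- png::readPNG(file.path(idir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    lb <- readYoloLabels(file.path(ldir, paste0(tools::file_path_sans_ext(f),
                                                ".txt")), desc$nc)
    images[[length(images) + 1L]] <- img
    targets[[length(targets) + 1L]] <- list(boxes = lb$boxes, cls = lb$cls)
    stems <- c(stems, tools::file_path_sans_ext(f))
  }
  list(images = images, targets = targets, nc = desc$nc, names = desc$names,
       stems = stems)
}
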