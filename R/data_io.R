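# Image and annotation I/O, input conformance (proportional resize + stride
# padding) and the dataset split.

#' Annotated image record
#'
#' @param id image identifier (file stem).
#' @param image (H, W, 3) array in `[0, 1]`, or `NULL` when boxes are handled
#'   without pixels.
#' @param boxes corner-form box matrix (n x 4), possibly 0 rows.
#' @param source free-form source tag.
#' @return an `annotated_image` list.
#' @export
annotated_image <- function(id, image = NULL, boxes = matrix(numeric(0), 0, 4),
                            source = "") {
  if (NROW(boxes) > 0) boxes <- wl_as_boxes(boxes)
  if (!is.null(image)) {
    stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
    if (NROW(boxes) > 0 &&
        (any(boxes[, c(1, 3)] < -1e-6) || any(boxes[, c(1, 3)] > dim(image)[2] + 1e-6) ||
         any(boxes[, c(2, 4)] < -1e-6) || any(boxes[, c(2, 4)] > dim(image)[1] + 1e-6)))
      stop("annotated_image: boxes outside image bounds")
  }
  structure(list(id = as.character(id), image = image, boxes = boxes,
                 source = as.character(source)), class = "annotated_image")
}

#' Read and write images
#'
#' PNG via the png package; JPEG reading via the jpeg package when
#' installed. Images are plain (H, W, 3) arrays in `[0, 1]` (grayscale and
#' alpha inputs are expanded/dropped to RGB).
#'
#' @param path file path (.png, .jpg/.jpeg).
#' @return (H, W, 3) array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the jpeg package")
    jpeg::readJPEG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  img
}

#' @rdname read_image
#' @param img (H, W, 3) array in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read GWHD-style CSV annotations
#'
#' One row per image with an `image_name` column and a `BoxesString` column:
#' boxes as four space-separated corner coordinates `x1 y1 x2 y2`, multiple
#' boxes joined by `;`, and the sentinel `no_box` for box-free images. A
#' `domain` column, when present, becomes the source tag. Images themselves
#' are not loaded (`image = NULL`); use [read_image()] alongside.
#'
#' @param path CSV path.
#' @return list of [annotated_image()] records.
#' @export
read_gwhd_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_name", "BoxesString") %in% names(df)))
    stop("GWHD CSV needs image_name and BoxesString columns")
  lapply(seq_len(nrow(df)), function(i) {
    bs <- trimws(df$BoxesString[i])
    boxes <- if (bs == "no_box" || bs == "") {
      matrix(numeric(0), 0, 4)
    } else {
      parts <- strsplit(strsplit(bs, ";", fixed = TRUE)[[1]], "\\s+")
      bad <- which(vapply(parts, length, integer(1)) != 4)
      if (length(bad) > 0)
        stop("malformed box string in row ", i, " (", df$image_name[i], ")")
      m <- do.call(rbind, lapply(parts, as.numeric))
      if (any(!is.finite(m))) stop("non-numeric box coordinates in row ", i)
      m
    }
    annotated_image(df$image_name[i], NULL, boxes,
                    if ("domain" %in% names(df)) df$domain[i] else "")
  })
}

#' @rdname read_gwhd_csv
#' @param anns list of [annotated_image()] records.
#' @export
write_gwhd_csv <- function(anns, path) {
  rows <- vapply(anns, function(a) {
    if (NROW(a$boxes) == 0) "no_box"
    else paste(apply(a$boxes, 1, function(b) paste(b, collapse = " ")), collapse = ";")
  }, character(1))
  df <- data.frame(image_name = vapply(anns, function(a) a$id, character(1)),
                   BoxesString = rows,
                   domain = vapply(anns, function(a) a$source, character(1)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write normalized-box annotation files
#'
#' The detector-family label format: one line per box, `class cx cy w h`
#' with center-form coordinates normalized to `[0, 1]` by the image size.
#'
#' @param path text file path.
#' @param image_size `(H, W)` of the image the boxes belong to.
#' @return matrix of corner-form pixel boxes with a `class` attribute.
#' @export
read_normalized_boxes <- function(path, image_size) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(structure(matrix(numeric(0), 0, 4), class_id = integer(0)))
  vals <- lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(v) != 5 || any(!is.finite(v)))
      stop("malformed normalized box at line ", i, " of ", path)
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop("normalized value outside [0,1] at line ", i, " of ", path)
    v
  })
  m <- do.call(rbind, vals)
  H <- image_size[1]; W <- image_size[2]
  corner <- center_to_corner(cbind(m[, 2] * W, m[, 3] * H, m[, 4] * W, m[, 5] * H))
  structure(corner, class_id = as.integer(m[, 1]))
}

#' @rdname read_normalized_boxes
#' @param boxes corner-form pixel box matrix.
#' @param class_id integer class per box (single-class data uses 0).
#' @export
write_normalized_boxes <- function(boxes, image_size, path, class_id = 0L) {
  H <- image_size[1]; W <- image_size[2]
  if (NROW(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ctr <- corner_to_center(boxes)
  class_id <- rep_len(class_id, nrow(ctr))
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", class_id,
                   ctr[, 1] / W, ctr[, 2] / H, ctr[, 3] / W, ctr[, 4] / H)
  writeLines(lines, path)
  invisible(path)
}

# Bilinear resampling of an (H, W, 3) array to (out_h, out_w).
wl_resize_bilinear <- function(img, out_h, out_w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(pmax(floor(xs), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    a <- ch[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
    b <- ch[cbind(rep(y0 + 1, length(x1)), rep(x1 + 1, each = length(y0)))]
    d <- ch[cbind(rep(y1 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
    e <- ch[cbind(rep(y1 + 1, length(x1)), rep(x1 + 1, each = length(y0)))]
    A <- matrix(a, out_h, out_w); B <- matrix(b, out_h, out_w)
    D <- matrix(d, out_h, out_w); E <- matrix(e, out_h, out_w)
    WX <- matrix(rep(wx, each = out_h), out_h, out_w)
    WY <- matrix(rep(wy, out_w), out_h, out_w)
    out[, , c] <- (A * (1 - WX) + B * WX) * (1 - WY) + (D * (1 - WX) + E * WX) * WY
  }
  out
}

#' Conform an image to the network input
#'
#' Scales the longest side to `target_long_side` (bilinear), scales the short
#' side by the same factor, and zero-pads bottom/right up to the next
#' multiple of `stride_multiple`. Boxes are transformed by the same pure
#' scaling, and the returned transform record allows exact inverse mapping of
#' detections back to original coordinates.
#'
#' @param ann an [annotated_image()] with pixels.
#' @param target_long_side network input long side (default 640).
#' @param stride_multiple pad H and W to multiples of this.
#' @return list with `ann` (conformed record) and `transform`
#'   (`scale`, `orig_hw`, `net_hw`).
#' @export
resize_to_input <- function(ann, target_long_side = 640, stride_multiple = 32) {
  img <- ann$image
  stopifnot(!is.null(img))
  H <- dim(img)[1]; W <- dim(img)[2]
  sc <- target_long_side / max(H, W)
  nh <- round(H * sc); nw <- round(W * sc)
  resized <- if (nh == H && nw == W) img else wl_resize_bilinear(img, nh, nw)
  ph <- ceiling(nh / stride_multiple) * stride_multiple
  pw <- ceiling(nw / stride_multiple) * stride_multiple
  out <- array(0, c(ph, pw, 3))
  out[seq_len(nh), seq_len(nw), ] <- resized
  boxes <- ann$boxes
  if (NROW(boxes) > 0) boxes <- boxes * sc
  list(ann = annotated_image(ann$id, out, boxes, ann$source),
       transform = list(scale = sc, orig_hw = c(H, W), net_hw = c(ph, pw)))
}

#' Map detection boxes back to original image coordinates
#'
#' Inverts the [resize_to_input()] transform (padding is bottom/right only,
#' so the inverse is a pure scaling plus clipping to the original bounds).
#'
#' @param dets detection data frame in network coordinates.
#' @param transform the transform record from [resize_to_input()].
#' @return data frame with boxes in original pixel coordinates.
#' @export
detections_to_original <- function(dets, transform) {
  if (NROW(dets) == 0) return(dets)
  sc <- transform$scale
  for (cl in c("x1", "x2")) dets[[cl]] <- pmin(pmax(dets[[cl]] / sc, 0), transform$orig_hw[2])
  for (cl in c("y1", "y2")) dets[[cl]] <- pmin(pmax(dets[[cl]] / sc, 0), transform$orig_hw[1])
  dets
}

#' Random train/validation/test split
#'
#' Shuffles the ids with the given seed and splits with round-half-up sizes:
#' `round(r_train * n)` to train, `round(r_val * n)` to validation, the
#' remainder to test. Sizes depend only on `n`; the seed only permutes
#' membership. Splitting 6387 ids at 7:2:1 yields 4471 / 1277 / 639.
#'
#' @param ids unique identifiers.
#' @param ratios nonnegative triple summing to 1.
#' @param seed integer RNG seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(ids, ratios = c(0.7, 0.2, 0.1), seed = 0) {
  if (anyDuplicated(ids)) stop("split_dataset: duplicate ids")
  stopifnot(length(ratios) == 3, all(ratios >= 0), abs(sum(ratios) - 1) < 1e-9)
  n <- length(ids)
  half_up <- function(x) floor(x + 0.5)
  n_train <- half_up(ratios[1] * n)
  n_val <- half_up(ratios[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  perm <- wl_with_seed(seed, sample.int(n))
  list(train = ids[perm[seq_len(n_train)]],
       val = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[setdiff(seq_len(n), seq_len(n_train + n_val))]])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
wl_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
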