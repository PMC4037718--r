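# PCA chemical-space maps: fit a PCA model on a reference MQN set, project
# any collection onto its (PC1, PC2) plane, rasterize onto a pixel grid and
# colour pixels by a property in HSL space.

#' Fit a PCA model to an MQN reference set
#'
#' Covariance PCA of the centered (by default unscaled) MQN columns:
#' integer counts share a scale, and the size-dominated first component
#' with all-positive loadings characteristic of MQN data only appears
#' without standardization. Each component's sign is flipped if its
#' loading sum is negative, so a size-like PC1 has positive loadings in
#' all descriptors. `standardize = TRUE` gives the correlation-PCA
#' alternative.
#'
#' @param x an MQN matrix ([mqn_table()]) or a `molset`.
#' @param standardize scale columns to unit variance first.
#' @return an object of class `mqn_pca`: column means (and scales),
#'   orthonormal loading matrix, explained-variance fractions, and the
#'   reference score ranges used by [rasterize_map()].
#' @export
fit_pca <- function(x, standardize = FALSE) {
  m <- if (inherits(x, "molset")) mqn_table(x) else as.matrix(x)
  if (nrow(m) < 3) stop("need at least 3 molecules to fit a PCA")
  if (nrow(unique(m)) < 2) stop("rank < 2: fewer than 2 distinct MQN rows")
  sds <- apply(m, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    # constant columns carry no variance; leave them unscaled
    scale_vec <- ifelse(sds == 0, 1, sds)
  } else scale_vec <- if (standardize) sds else rep(1, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = if (standardize) scale_vec else FALSE)
  flip <- colSums(pc$rotation) < 0
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- max(3L, sum(pc$sdev > 1e-10))
  keep <- min(keep, ncol(pc$rotation))
  ranges <- apply(pc$x[, 1:keep, drop = FALSE], 2, range)
  model <- list(center = pc$center,
                scale = if (standardize) scale_vec else NULL,
                loadings = pc$rotation[, 1:keep, drop = FALSE],
                var_frac = var_frac[1:keep],
                ref_ranges = ranges, n = nrow(m))
  class(model) <- "mqn_pca"
  model
}

#' @export
print.mqn_pca <- function(x, ...) {
  cat(sprintf("<mqn_pca: fitted on %d molecules>\n", x$n))
  vf <- round(100 * x$var_frac[1:min(3, length(x$var_frac))], 2)
  cat("  variance explained: ", paste0("PC", seq_along(vf), " ", vf, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Project molecules onto a fitted PCA model
#'
#' Uses the reference model's means and loadings; the model is never refit
#' on the projected set.
#'
#' @param object an `mqn_pca` model.
#' @param newdata MQN matrix or `molset` to project.
#' @param ... ignored.
#' @return numeric matrix of scores (columns PC1, PC2, PC3, ...).
#' @export
predict.mqn_pca <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "molset")) mqn_table(newdata) else as.matrix(newdata)
  cm <- sweep(m, 2, object$center)
  if (!is.null(object$scale)) cm <- sweep(cm, 2, object$scale, "/")
  cm %*% object$loadings
}

#' @rdname predict.mqn_pca
#' @param model an `mqn_pca` model.
#' @param x MQN matrix or `molset`.
#' @export
mqn_project <- function(model, x) predict(model, x)

#' Rasterize projections onto a pixel grid
#'
#' Axis ranges are the reference set's PC1/PC2 ranges expanded by 1%
#' (taken from the model); each projected molecule maps to exactly one
#' pixel by flooring the linear rescale, and out-of-range points are
#' clamped to the border pixels.
#'
#' @param model an `mqn_pca` model (source of the axis ranges).
#' @param scores score matrix from [predict.mqn_pca()] with rownames ids.
#' @param grid_size pixels per axis (default 1000).
#' @return an object of class `pixel_map`: the occupied pixels (0-based
#'   x/y coordinates and counts), their member ids, the grid size and the
#'   axis ranges.
#' @export
rasterize_map <- function(model, scores, grid_size = 1000L) {
  stopifnot(inherits(model, "mqn_pca"))
  ranges <- model$ref_ranges[, 1:2, drop = FALSE]
  span <- ranges[2, ] - ranges[1, ]
  lo <- ranges[1, ] - 0.005 * span
  hi <- ranges[2, ] + 0.005 * span
  px <- pmin(pmax(floor((scores[, 1] - lo[1]) / (hi[1] - lo[1]) * grid_size), 0), grid_size - 1)
  py <- pmin(pmax(floor((scores[, 2] - lo[2]) / (hi[2] - lo[2]) * grid_size), 0), grid_size - 1)
  key <- px * grid_size + py
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  groups <- split(ids, key)
  ukey <- as.numeric(names(groups))
  map <- list(grid_size = as.integer(grid_size),
              ranges = rbind(lo = lo, hi = hi),
              pixels = data.frame(x = as.integer(ukey %/% grid_size),
                                  y = as.integer(ukey %% grid_size),
                                  count = lengths(groups)),
              members = unname(groups))
  class(map) <- "pixel_map"
  map
}

#' @export
print.pixel_map <- function(x, ...) {
  cat(sprintf("<pixel_map: %dx%d grid, %d occupied pixels, %d molecules>\n",
              x$grid_size, x$grid_size, nrow(x$pixels), sum(x$pixels$count)))
  invisible(x)
}

# HSL -> sRGB hex
hsl_to_hex <- function(h, s, l) {
  h <- (h %% 360) / 60
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- l - c / 2
  sector <- floor(h) %% 6
  r <- c(c, x, 0, 0, x, c)[sector + 1]
  g <- c(x, c, c, x, 0, 0)[sector + 1]
  b <- c(0, 0, x, c, c, x)[sector + 1]
  grDevices::rgb(r + m, g + m, b + m)
}

#' Colour map pixels by a molecular property
#'
#' HSL colour coding: the hue runs along the path
#' blue (240) - cyan (180) - green (120) - yellow (60) - red (0) -
#' magenta (-60, i.e. 300) with increasing per-pixel property mean over
#' the occupied-pixel mean range (passing naturally through orange between
#' yellow and red); saturation fades towards grey with increasing
#' standard deviation, `s = max(0, 1 - sd/sd95)` where `sd95` is the 95th
#' percentile of the positive pixel SDs; lightness is fixed at 0.5.
#' Single-member pixels have SD 0 and therefore full saturation.
#'
#' @param map a `pixel_map`.
#' @param property named numeric vector (names = molecule ids), e.g. the
#'   `hac` column of an MQN table.
#' @return the map with per-pixel `mean`, `sd`, `h`, `s`, `l` and `hex`
#'   columns added.
#' @export
colour_pixels <- function(map, property) {
  stopifnot(inherits(map, "pixel_map"))
  vals <- lapply(map$members, function(ids) unname(property[ids]))
  mu <- vapply(vals, mean, 0)
  sdv <- vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else 0, 0)
  if (nrow(map$pixels) == 0) {
    map$pixels$mean <- numeric(0); map$pixels$sd <- numeric(0)
    map$pixels$h <- numeric(0); map$pixels$s <- numeric(0)
    map$pixels$l <- numeric(0); map$pixels$hex <- character(0)
    return(map)
  }
  rng <- range(mu)
  t <- if (diff(rng) == 0) rep(0, length(mu)) else (mu - rng[1]) / diff(rng)
  hue <- 240 - 300 * t
  pos_sd <- sdv[sdv > 0]
  sd95 <- if (length(pos_sd)) stats::quantile(pos_sd, 0.95, names = FALSE) else Inf
  sat <- pmax(0, 1 - sdv / sd95)
  map$pixels$mean <- mu
  map$pixels$sd <- sdv
  map$pixels$h <- hue %% 360
  map$pixels$s <- sat
  map$pixels$l <- 0.5
  map$pixels$hex <- vapply(seq_along(mu), function(i)
    hsl_to_hex(hue[i], sat[i], 0.5), "")
  map
}

#' Average molecule of each pixel
#'
#' For every occupied pixel the component-wise mean of the members' 42 MQN
#' values is computed; the member with the smallest city-block distance to
#' that mean is the pixel's average molecule (ties broken by lowest id).
#'
#' @param map a `pixel_map`.
#' @param mqn MQN matrix covering all member ids.
#' @return the map with an `avg_id` column added.
#' @export
average_molecules <- function(map, mqn) {
  stopifnot(inherits(map, "pixel_map"))
  map$pixels$avg_id <- vapply(map$members, function(ids) {
    sub <- mqn[ids, , drop = FALSE]
    # exact arithmetic: compare n*CBD-to-mean so integer counts never tie-break
    # on floating-point noise
    csum <- colSums(sub)
    d <- cbd_to(sub * length(ids), csum)
    ord <- order(d, ids)
    ids[ord[1]]
  }, "")
  map
}

#' Save / load a PCA model as JSON
#'
#' Stores column means (and scales), loading vectors, explained-variance
#' fractions and the reference axis ranges.
#'
#' @param model an `mqn_pca`.
#' @param path JSON file.
#' @export
save_pca <- function(model, path) {
  jsonlite::write_json(list(
    format = "flspace-mqn-pca", version = 1L,
    center = as.list(model$center),
    scale = if (is.null(model$scale)) NULL else as.list(model$scale),
    loadings = apply(model$loadings, 2, identity, simplify = FALSE),
    descriptor = rownames(model$loadings),
    var_frac = model$var_frac,
    ref_ranges = apply(model$ref_ranges, 2, identity, simplify = FALSE),
    n = model$n), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_pca
#' @export
load_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "flspace-mqn-pca")) stop("not an flspace PCA model: ", path)
  loadings <- do.call(cbind, j$loadings)
  rownames(loadings) <- j$descriptor
  model <- list(center = unlist(j$center),
                scale = if (is.null(j$scale)) NULL else unlist(j$scale),
                loadings = loadings,
                var_frac = as.numeric(j$var_frac),
                ref_ranges = do.call(cbind, j$ref_ranges),
                n = j$n)
  class(model) <- "mqn_pca"
  model
}

#' Export a pixel map as PNG and TSV
#'
#' The PNG is `grid_size x grid_size` with white background and one
#' coloured pixel per occupied grid cell (PC1 increases to the right, PC2
#' upwards). The TSV lists occupied pixels only, with columns x, y,
#' count, mean, sd, avg_id, hex.
#'
#' @param map a coloured `pixel_map` (see [colour_pixels()]).
#' @param png_path,tsv_path output files (`NULL` to skip either).
#' @export
export_map <- function(map, png_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(map, "pixel_map"))
  px <- map$pixels
  if (!is.null(png_path)) {
    gs <- map$grid_size
    img <- array(1, dim = c(gs, gs, 3))
    if (nrow(px) > 0) {
      hex <- if ("hex" %in% names(px)) px$hex else rep("#000000", nrow(px))
      rgbv <- grDevices::col2rgb(hex) / 255
      rows <- gs - px$y           # PC2 up
      cols <- px$x + 1L
      for (k in seq_len(nrow(px))) img[rows[k], cols[k], ] <- rgbv[, k]
    }
    png::writePNG(img, png_path)
  }
  if (!is.null(tsv_path)) {
    cols <- intersect(c("x", "y", "count", "mean", "sd", "avg_id", "hex"), names(px))
    utils::write.table(px[, cols, drop = FALSE], tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(map)
}
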