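test_that("PCA fitting enforces preconditions and orthonormal loadings", {
  m <- unit_mqn()
  expect_error(fit_pca(m[1:2, ]), "at least 3")
  same <- m[c(1, 1, 1), ]
  expect_error(fit_pca(same), "rank < 2")

  model <- fit_pca(m)
  G <- crossprod(model$loadings)
  expect_equal(G, diag(ncol(model$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(model$var_frac) <= 1e-12))
  expect_true(all(model$var_frac >= 0 & model$var_frac <= 1))
  expect_lte(sum(model$var_frac), 1 + 1e-8)
  # sign convention: every component's loading sum is non-negative, and the
  # size descriptors load positively on the size-dominated PC1
  expect_true(all(colSums(model$loadings) >= -1e-8))
  expect_gt(model$loadings["hac", 1], 0)
  expect_gt(model$loadings["c", 1], 0)
})

test_that("one-dimensional data loads entirely on PC1", {
  m <- matrix(0, 5, 42, dimnames = list(paste0("m", 1:5), mqn_names()))
  m[, 1] <- c(0, 2, 4, 6, 8)
  model <- fit_pca(m)
  expect_equal(model$var_frac[1], 1)
})

test_that("projection reuses the reference frame and never refits", {
  m <- unit_mqn()
  model <- fit_pca(m)
  # the reference mean projects to the origin
  ctr <- matrix(model$center, 1, dimnames = list("ctr", names(model$center)))
  expect_equal(unname(predict(model, ctr))[1, 1:3], c(0, 0, 0),
               tolerance = 1e-10)
  # projecting the reference reproduces the fitted variance fractions
  sc <- predict(model, m)
  vf <- apply(sc, 2, stats::var)
  vf <- vf / (sum(vf) / sum(model$var_frac))
  expect_equal(unname(vf), unname(model$var_frac[seq_len(ncol(sc))]),
               tolerance = 1e-8)
  # two-molecule hand check: centered rows times loadings
  two <- m[1:2, ]
  hand <- sweep(two, 2, model$center) %*% model$loadings
  expect_equal(predict(model, two), hand)
})

test_that("rasterization maps range bounds to border pixels, one pixel each", {
  m <- unit_mqn()
  model <- fit_pca(m)
  lo <- model$ref_ranges[1, 1:2]; hi <- model$ref_ranges[2, 1:2]
  span <- hi - lo
  bounds <- rbind(corner_lo = lo - 0.005 * span, corner_hi = hi + 0.005 * span,
                  below = lo - span, above = hi + span)
  map <- rasterize_map(model, bounds, grid_size = 1000)
  px <- map$pixels[order(map$pixels$x), ]
  got <- do.call(rbind, Map(function(ids, x, y) data.frame(id = ids, x = x, y = y),
                            map$members, map$pixels$x, map$pixels$y))
  expect_equal(got$x[got$id == "corner_lo"], 0)
  expect_equal(got$y[got$id == "corner_lo"], 0)
  expect_equal(got$x[got$id == "corner_hi"], 999)
  expect_equal(got$y[got$id == "corner_hi"], 999)
  expect_equal(got$x[got$id == "below"], 0)      # clamped
  expect_equal(got$x[got$id == "above"], 999)

  # identical MQN vectors share a pixel; a single molecule occupies one pixel
  sc <- predict(model, m[c(1, 1), ])
  rownames(sc) <- c("x1", "x2")
  map2 <- rasterize_map(model, sc, grid_size = 100)
  expect_equal(nrow(map2$pixels), 1)
  expect_equal(map2$pixels$count, 2)
  expect_equal(sum(map2$pixels$count), 2)
})

test_that("pixel colours follow the HSL scheme", {
  m <- unit_mqn()
  model <- fit_pca(m)
  # five controlled pixels with property values 1..5
  sc <- cbind(seq(model$ref_ranges[1, 1], model$ref_ranges[2, 1], length.out = 5),
              rep(0, 5), rep(0, 5))
  rownames(sc) <- paste0("p", 1:5)
  map <- rasterize_map(model, sc, grid_size = 50)
  prop <- stats::setNames(1:5, paste0("p", 1:5))
  map <- colour_pixels(map, prop)
  px <- map$pixels[order(px_mean <- map$pixels$mean), ]
  expect_equal(px$h[1], 240)                     # minimum mean is blue
  expect_equal(px$h[5], 300)                     # maximum wraps to magenta
  expect_true(all(diff(px$h[1:4]) < 0))          # hue advances along the path
  expect_true(all(px$s == 1))                    # single members: sd 0, full sat
  expect_true(all(px$l == 0.5))
  # saturation fades toward grey with increasing spread
  sc2 <- matrix(0, 8, 3, dimnames = list(paste0("q", 1:8), NULL))
  sc2[, 1] <- rep(c(0, 5), each = 4)
  map2 <- rasterize_map(model, sc2, grid_size = 10)
  prop2 <- stats::setNames(c(5, 5, 5, 5, 0, 2, 6, 20), paste0("q", 1:8))
  map2 <- colour_pixels(map2, prop2)
  tight <- map2$pixels$s[map2$pixels$sd == 0]
  loose <- map2$pixels$s[map2$pixels$sd > 0]
  expect_true(all(tight == 1))
  expect_true(all(loose < 1))
})

test_that("average molecules match the exhaustive arg-min with id ties", {
  m <- unit_mqn()
  model <- fit_pca(m)
  sc <- predict(model, m)
  map <- rasterize_map(model, sc, grid_size = 12)   # coarse: crowded pixels
  map <- average_molecules(map, m)
  for (k in seq_len(nrow(map$pixels))) {
    ids <- map$members[[k]]
    csum <- colSums(m[ids, , drop = FALSE])
    dd <- vapply(ids, function(i) sum(abs(length(ids) * m[i, ] - csum)), 0)
    best <- sort(ids[dd == min(dd)])[1]
    expect_identical(map$pixels$avg_id[k], best)
  }
  # symmetric two-member pixel: tie broken to the lower id
  mm <- m[1:2, ]; mm[2, ] <- mm[1, ] + c(2L, rep(0L, 41))
  mm[1, ] <- mm[1, ] - c(2L, rep(0L, 41))
  rownames(mm) <- c("zz", "aa")
  sc2 <- matrix(0, 2, 2, dimnames = list(c("zz", "aa"), NULL))
  map2 <- rasterize_map(model, sc2, grid_size = 10)
  map2 <- average_molecules(map2, mm)
  expect_equal(map2$pixels$avg_id, "aa")
})

test_that("map export round-trips colours through TSV and PNG", {
  m <- unit_mqn()[1:40, ]
  model <- fit_pca(unit_mqn())
  sc <- predict(model, m)
  map <- rasterize_map(model, sc, grid_size = 64)
  map <- colour_pixels(map, stats::setNames(m[, "hac"], rownames(m)))
  map <- average_molecules(map, m)
  png_f <- tempfile(fileext = ".png"); tsv_f <- tempfile(fileext = ".tsv")
  export_map(map, png_f, tsv_f)
  tab <- utils::read.table(tsv_f, sep = "\t", header = TRUE,
                           comment.char = "", colClasses = c(hex = "character", avg_id = "character"))
  expect_equal(nrow(tab), nrow(map$pixels))
  expect_identical(tab$hex, map$pixels$hex)
  img <- png::readPNG(png_f)
  expect_equal(dim(img)[1:2], c(64, 64))
  k <- 1
  expect_equal(grDevices::rgb(img[64 - tab$y[k], tab$x[k] + 1, 1],
                              img[64 - tab$y[k], tab$x[k] + 1, 2],
                              img[64 - tab$y[k], tab$x[k] + 1, 3]),
               toupper(tab$hex[k]))
  # empty map: blank PNG, header-only TSV
  empty <- rasterize_map(model, matrix(0, 0, 2), grid_size = 16)
  empty <- colour_pixels(empty, numeric(0))
  export_map(empty, png_f, tsv_f)
  expect_equal(length(readLines(tsv_f)), 1)
  expect_true(all(png::readPNG(png_f) == 1))
})

test_that("PCA models survive a JSON save/load round trip", {
  model <- fit_pca(unit_mqn())
  f <- tempfile(fileext = ".json")
  save_pca(model, f)
  model2 <- load_pca(f)
  expect_equal(model2$center, model$center)
  expect_equal(model2$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(model2$var_frac, model$var_frac)
  expect_equal(predict(model2, unit_mqn()[1:5, ]),
               predict(model, unit_mqn()[1:5, ]), tolerance = 1e-10)
})
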