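# The comparison descriptor spaces: path-based substructure fingerprint
# (Sfp, Open Babel FP2: linear paths up to 7 atoms, 1024 bits), circular
# extended-connectivity fingerprint of bond diameter 4 (ECfp4, folded to
# 1024 bits) and molecular weight. All spaces use the city-block distance,
# which on 0/1 vectors equals the Hamming distance.

# Run obabel once over a whole collection and parse the FPS hex output.
ob_fingerprints <- function(ms, fp = c("FP2", "ECFP4")) {
  fp <- match.arg(fp)
  stopifnot(inherits(ms, "molset"))
  n <- length(ms)
  if (n == 0) return(matrix(0L, 0, if (fp == "FP2") 1024 else 4096))
  smi <- tempfile(fileext = ".smi"); out <- tempfile(fileext = ".fps")
  on.exit(unlink(c(smi, out)), add = TRUE)
  writeLines(paste(ms$smiles, paste0("t", seq_len(n))), smi)
  status <- suppressWarnings(system2("obabel", c(smi, "-ofps", paste0("-xf", fp), "-O", out),
                                     stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(out)) stop("obabel fingerprint run failed")
  lines <- readLines(out, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hx <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, `[`, "", 2)
  nbits <- nchar(hx[1]) * 4L
  m <- matrix(0L, n, nbits, dimnames = list(ms$id, NULL))
  bits_of <- hex_bit_table()
  for (k in seq_along(hx)) {
    i <- as.integer(sub("^t", "", ids[k]))
    chars <- strsplit(hx[k], "")[[1]]
    m[i, ] <- as.integer(bits_of[, chars])
  }
  if (length(hx) < n) stop("fingerprints missing for ", n - length(hx), " molecules")
  m
}

hex_bit_table <- function() {
  vals <- strtoi(c(0:9, letters[1:6]), 16L)
  tab <- sapply(vals, function(v) as.integer(intToBits(v)[4:1]))
  colnames(tab) <- c(0:9, letters[1:6])
  cbind(tab, `A` = tab[, "a"], `B` = tab[, "b"], `C` = tab[, "c"],
        `D` = tab[, "d"], `E` = tab[, "e"], `F` = tab[, "f"])
}

#' Path-based substructure fingerprint (Sfp)
#'
#' Hashed linear paths up to 7 atoms, folded to 1024 bits (Open Babel FP2).
#'
#' @param x a `molset` or character vector of SMILES.
#' @return 0/1 integer matrix, one row per molecule, 1024 columns.
#' @export
encode_sfp <- function(x) {
  ob_fingerprints(as_molset(x), "FP2")
}

#' Circular extended-connectivity fingerprint of bond diameter 4 (ECfp4)
#'
#' Circular atom environments of radius 2 (Open Babel ECFP4, 4096 bits)
#' folded to 1024 bits by OR-ing the four blocks.
#'
#' @inheritParams encode_sfp
#' @return 0/1 integer matrix, one row per molecule, 1024 columns.
#' @export
encode_ecfp4 <- function(x) {
  m <- ob_fingerprints(as_molset(x), "ECFP4")
  folded <- m[, 1:1024, drop = FALSE] | m[, 1025:2048, drop = FALSE] |
    m[, 2049:3072, drop = FALSE] | m[, 3073:4096, drop = FALSE]
  storage.mode(folded) <- "integer"
  folded
}

# standard atomic weights
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                     Br = 79.904, I = 126.904, B = 10.81, Si = 28.085)

#' Molecular weight from standard atomic weights
#'
#' Computed on the pH 7.4 ionized form (protonation state changes the
#' hydrogen count and therefore the weight).
#'
#' @inheritParams encode_sfp
#' @param ionize apply [ionize_ph74()] first (default `TRUE`).
#' @return named numeric vector of weights in Da.
#' @export
mol_weight <- function(x, ionize = TRUE) {
  ms <- as_molset(x)
  w <- vapply(ms$graph, function(g) {
    if (ionize) g <- ionize_ph74(g)
    aw <- .atomic_weights[g$elem]
    if (anyNA(aw)) stop("no atomic weight for element ",
                        paste(unique(g$elem[is.na(aw)]), collapse = ","))
    sum(aw) + sum(g$nH) * .atomic_weights[["H"]]
  }, 0, USE.NAMES = FALSE)
  stats::setNames(w, ms$id)
}

#' Encode molecules in one of the four descriptor spaces
#'
#' @inheritParams encode_sfp
#' @param space `"MQN"`, `"Sfp"`, `"ECfp4"` or `"MW"`.
#' @return numeric matrix with one row per molecule; the city-block
#'   distance between rows (see [space_distance()]) is the similarity
#'   measure of the space.
#' @export
space_encode <- function(x, space = c("MQN", "Sfp", "ECfp4", "MW")) {
  space <- match.arg(space)
  ms <- as_molset(x)
  switch(space,
         MQN = mqn_table(ms),
         Sfp = encode_sfp(ms),
         ECfp4 = encode_ecfp4(ms),
         MW = matrix(mol_weight(ms), ncol = 1, dimnames = list(ms$id, "mw")))
}

#' City-block distance in any descriptor space
#'
#' On the binary fingerprint spaces this equals the Hamming distance; in
#' MW space it is the absolute weight difference in Da; in MQN space it is
#' [cbd()].
#'
#' @param a,b encoded vectors (rows of [space_encode()] output).
#' @return non-negative numeric distance.
#' @export
space_distance <- function(a, b) cbd(a, b)

#' Serialize fingerprints as hex strings
#'
#' @param m 0/1 matrix from [encode_sfp()] / [encode_ecfp4()].
#' @return character vector of hex strings (one per row).
#' @export
fp_to_hex <- function(m) {
  apply(m, 1, function(row) {
    nyb <- matrix(row, nrow = 4)
    paste(c("0","1","2","3","4","5","6","7","8","9","a","b","c","d","e","f")[
      8 * nyb[1, ] + 4 * nyb[2, ] + 2 * nyb[3, ] + nyb[4, ] + 1], collapse = "")
  })
}

#' @rdname fp_to_hex
#' @param hex character vector of hex strings.
#' @export
hex_to_fp <- function(hex) {
  bits_of <- hex_bit_table()
  t(vapply(hex, function(h) as.integer(bits_of[, strsplit(h, "")[[1]]]),
           integer(nchar(hex[1]) * 4L)))
}
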