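#' Reference stain vectors for hematoxylin + DAB
#'
#' Unit optical-density vectors for the hematoxylin/DAB stain combination
#' (the standard published H-DAB values), plus a residual axis orthogonal
#' to both, as used in color deconvolution. Columns are `hematoxylin`,
#' `dab`, `residual`; rows are the R, G, B channels.
#'
#' @param hematoxylin,dab length-3 OD vectors; normalized internally.
#' @return a 3 x 3 matrix of unit column vectors.
#' @export
hdab_stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                               dab = c(0.268, 0.570, 0.776)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6) stop("stain vectors are collinear; cannot deconvolve")
  m <- cbind(hematoxylin = h, dab = d, residual = r / nr)
  rownames(m) <- c("R", "G", "B")
  m
}

#' DAB intensity-class thresholds
#'
#' Optical-density boundaries separating negative/weak, weak/moderate and
#' moderate/strong DAB staining. The defaults (0.15, 0.40, 0.80) bracket
#' the rendering bands of [tile_spec()]; on real material they are a
#' calibration choice and should be set per staining batch.
#'
#' @param od_positive minimum DAB OD counted as stained.
#' @param od_weak_mod weak/moderate boundary.
#' @param od_mod_strong moderate/strong boundary.
#' @return an `intensity_thresholds` object (named numeric of length 3).
#' @export
intensity_thresholds <- function(od_positive = 0.15, od_weak_mod = 0.40,
                                 od_mod_strong = 0.80) {
  t <- c(od_positive = od_positive, od_weak_mod = od_weak_mod,
         od_mod_strong = od_mod_strong)
  if (!(0 < t[1] && t[1] < t[2] && t[2] < t[3])) {
    stop("thresholds must satisfy 0 < od_positive < od_weak_mod < od_mod_strong")
  }
  structure(t, class = "intensity_thresholds")
}

#' Retrospective flat-field illumination correction
#'
#' Estimates a smooth multiplicative illumination field per channel and
#' divides it out. The field is estimated from the bright-quantile
#' surface: the tile is divided into a coarse block grid, the upper
#' quantile of intensity per block (which tracks the brightest, least
#' absorbing pixels, whose true intensity is nearly constant across the
#' field) is taken per channel, and a low-order polynomial surface is
#' fitted through the block log-values. The fitted field is normalized
#' to mean 1, so a flat tile is returned unchanged up to numerical
#' tolerance. This is identifiable when stain structure is
#' high-frequency relative to the illumination drift, which holds for
#' microscope vignetting and lamp gradients at field-of-view scale.
#'
#' Degenerate tiles in which no field can be estimated (essentially
#' saturated white, black, or constant) are returned unchanged with
#' attribute `illumination_flagged = TRUE`.
#'
#' @param tile an [ihc_tile()].
#' @param degree polynomial degree of the fitted surface (default 2).
#' @param block_px approximate block edge length in pixels.
#' @param quantile upper intensity quantile tracked per block.
#' @return the corrected `ihc_tile`, with attribute
#'   `illumination_flagged`.
#' @export
correct_illumination <- function(tile, degree = 2, block_px = 8,
                                 quantile = 0.9) {
  stopifnot(inherits(tile, "ihc_tile"))
  px <- tile$px
  h <- dim(px)[1]; w <- dim(px)[2]

  mu <- mean(px)
  if (mu > 250 || mu < 5 || stats::sd(px) < 1) {
    attr(tile, "illumination_flagged") <- TRUE
    return(tile)
  }

  # coarse block grid (at least degree+2 blocks per axis)
  nbx <- max(degree + 2, floor(w / block_px))
  nby <- max(degree + 2, floor(h / block_px))
  bx <- pmin(ceiling(seq_len(w) / (w / nbx)), nbx)
  by <- pmin(ceiling(seq_len(h) / (h / nby)), nby)
  block <- matrix(by, h, w) + (matrix(bx, h, w, byrow = TRUE) - 1L) * nby
  cx <- (tapply(rep(seq_len(w), each = h), c(block), mean) - (w + 1) / 2) / w
  cy <- (tapply(rep(seq_len(h), times = w), c(block), mean) - (h + 1) / 2) / h
  basis <- cbind(1, stats::poly(cbind(cx, cy), degree = degree, raw = TRUE))

  xs <- (rep(seq_len(w), each = h) - (w + 1) / 2) / w
  ys <- (rep(seq_len(h), times = w) - (h + 1) / 2) / h
  full_basis <- cbind(1, stats::poly(cbind(xs, ys), degree = degree,
                                     raw = TRUE))

  out <- px
  for (ch in 1:3) {
    v <- px[, , ch]
    q <- tapply(c(v), c(block), stats::quantile, probs = quantile,
                names = FALSE)
    fit <- stats::lm.fit(basis, log(pmax(q, 1)))
    logfield <- drop(full_basis %*% fit$coefficients)
    logfield <- logfield - mean(logfield)   # mean-1 field: flat in = flat out
    field <- matrix(exp(logfield), h, w)
    out[, , ch] <- pmin(pmax(v / field, 0), 255)
  }
  corrected <- ihc_tile(out, tumor_id = tile$meta$tumor_id,
                        marker = tile$meta$marker,
                        field_index = tile$meta$field_index)
  attr(corrected, "illumination_flagged") <- FALSE
  corrected
}

#' Isolate the DAB signal by color deconvolution
#'
#' Converts each pixel to optical density, `OD_c = -log10(max(I_c, 1) /
#' I0)` with `I0 = 255`, and solves the Beer-Lambert mixing model for the
#' per-stain contributions along the reference stain vectors
#' (Ruifrok-Johnston color deconvolution). The DAB component is clamped
#' at zero: negative loadings are deconvolution residue, not stain.
#'
#' @param tile an [ihc_tile()], ideally illumination-corrected.
#' @param vectors stain matrix from [hdab_stain_vectors()].
#' @return numeric matrix (`height x width`) of DAB optical densities.
#' @export
separate_stains <- function(tile, vectors = hdab_stain_vectors()) {
  stopifnot(inherits(tile, "ihc_tile"),
            is.matrix(vectors), all(dim(vectors) == c(3, 3)))
  if (abs(det(vectors)) < 1e-6) {
    stop("degenerate stain matrix: vectors are (nearly) collinear")
  }
  h <- dim(tile$px)[1]; w <- dim(tile$px)[2]
  od <- -log10(pmax(tile$px, 1) / 255)
  odm <- matrix(od, nrow = h * w, ncol = 3)
  conc <- odm %*% t(solve(vectors))
  matrix(pmax(conc[, 2], 0), h, w)
}

#' Classify pixels into DAB intensity classes
#'
#' Labels each analyzed pixel negative, weak, moderate or strong by
#' half-open optical-density intervals `[0, t1)`, `[t1, t2)`, `[t2, t3)`,
#' `[t3, Inf)`; a pixel exactly on a boundary takes the upper class, so
#' the rule is deterministic and order-independent.
#'
#' @param od_map DAB OD matrix from [separate_stains()].
#' @param thresholds an [intensity_thresholds()] object.
#' @param mask optional logical matrix of analyzed pixels (default: all);
#'   must select at least one pixel.
#' @return factor matrix with levels negative/weak/moderate/strong;
#'   pixels outside the mask are `NA`.
#' @export
classify_pixels <- function(od_map, thresholds = intensity_thresholds(),
                            mask = NULL) {
  stopifnot(is.matrix(od_map))
  if (!inherits(thresholds, "intensity_thresholds")) {
    thresholds <- do.call(intensity_thresholds, as.list(unname(thresholds)))
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(od_map), ncol(od_map))
  stopifnot(identical(dim(mask), dim(od_map)))
  if (!any(mask)) stop("empty analysis mask: no pixels to classify")
  lev <- c("negative", "weak", "moderate", "strong")
  idx <- findInterval(od_map, unclass(thresholds)) + 1L
  labels <- matrix(factor(lev[idx], levels = lev),
                   nrow(od_map), ncol(od_map))
  labels[!mask] <- NA
  labels
}

#' Tissue mask by luminance (glass exclusion)
#'
#' Marks near-white pixels (glass/background) as non-tissue so they can
#' be excluded from the analyzed area. The default analysis mask of the
#' pipeline is the whole tile; this helper is for fields that contain
#' empty glass.
#'
#' @param tile an [ihc_tile()].
#' @param white_cutoff mean-RGB luminance above which a pixel counts as
#'   background.
#' @return logical matrix, `TRUE` for tissue pixels.
#' @export
tissue_mask <- function(tile, white_cutoff = 235) {
  stopifnot(inherits(tile, "ihc_tile"))
  lum <- (tile$px[, , 1] + tile$px[, , 2] + tile$px[, , 3]) / 3
  lum < white_cutoff
}

#' Area profile of a pixel label map
#'
#' Reports each intensity class's area as a percent of the analyzed area
#' (all non-`NA` labels), the quantity the web-style area readout
#' provides per field. Percentages sum to 100 by construction, and the
#' total positive area is the sum of the weak, moderate and strong
#' percentages.
#'
#' @param labels factor matrix from [classify_pixels()].
#' @return an `area_profile` object.
#' @export
quantify_areas <- function(labels) {
  stopifnot(!is.null(labels))
  n <- sum(!is.na(labels))
  if (n == 0) stop("label map has no analyzed pixels")
  counts <- table(factor(labels[!is.na(labels)],
                         levels = c("negative", "weak", "moderate", "strong")))
  pct <- 100 * as.numeric(counts) / n
  area_profile(weak = pct[2], moderate = pct[3], strong = pct[4],
               n_pixels = n)
}

#' Construct an area profile
#'
#' @param weak,moderate,strong percent of analyzed area in each positive
#'   intensity class; the negative percentage is the complement to 100.
#' @param n_pixels analyzed pixel count (optional bookkeeping).
#' @return an `area_profile`: list with fields `pct_negative`, `pct_weak`,
#'   `pct_moderate`, `pct_strong`, `pct_total_positive`, `n_pixels`.
#' @export
area_profile <- function(weak, moderate, strong, n_pixels = NA_integer_) {
  stopifnot(length(weak) == 1, length(moderate) == 1, length(strong) == 1)
  pos <- weak + moderate + strong
  if (min(weak, moderate, strong) < -1e-9 || pos > 100 + 1e-6) {
    stop("class percentages must be nonnegative and sum to at most 100")
  }
  structure(list(pct_negative = 100 - pos,
                 pct_weak = weak,
                 pct_moderate = moderate,
                 pct_strong = strong,
                 pct_total_positive = pos,
                 n_pixels = n_pixels),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf(paste0("<area_profile> negative %.2f%% | weak %.2f%% | ",
                     "moderate %.2f%% | strong %.2f%% (positive %.2f%%)\n"),
              x$pct_negative, x$pct_weak, x$pct_moderate, x$pct_strong,
              x$pct_total_positive))
  invisible(x)
}

#' Full per-tile quantification
#'
#' Convenience composition of the quantification stages: illumination
#' correction, DAB isolation by color deconvolution, intensity-class
#' labeling, and area readout.
#'
#' @param tile an [ihc_tile()].
#' @param thresholds [intensity_thresholds()].
#' @param vectors stain matrix.
#' @param correct apply [correct_illumination()] first?
#' @param mask optional analysis mask (logical matrix).
#' @return an `area_profile`.
#' @export
quantify_tile <- function(tile, thresholds = intensity_thresholds(),
                          vectors = hdab_stain_vectors(),
                          correct = TRUE, mask = NULL) {
  if (correct) tile <- correct_illumination(tile)
  od <- separate_stains(tile, vectors)
  quantify_areas(classify_pixels(od, thresholds, mask))
}
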