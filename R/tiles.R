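#' Specification of a synthetic immunohistochemistry tile
#'
#' Describes a brightfield RGB tile of DAB/hematoxylin-stained tissue used
#' to exercise the quantification pipeline against pixel-exact ground
#' truth. Each intensity class is rendered inside a distinct DAB
#' optical-density band: negative pixels carry hematoxylin only, and the
#' weak/moderate/strong bands straddle the default classification
#' thresholds (see [intensity_thresholds()]) with a safety margin so that
#' 8-bit quantization cannot flip a label. Pixels are laid out dispersed
#' (a seeded random permutation), so tissue content is high-frequency
#' while any illumination drift is low-frequency — the regime in which
#' retrospective flat-field correction is identifiable.
#'
#' @param width,height tile size in pixels.
#' @param class_fractions named fractions of pixels in the
#'   negative/weak/moderate/strong classes; together with
#'   `background_fraction` they must sum to 1.
#' @param background_fraction fraction of non-tissue (glass, near-white)
#'   pixels.
#' @param gradient_amplitude relative amplitude of a multiplicative
#'   left-to-right illumination fall-off (0 = flat field; 0.2 means the
#'   right edge is 20% darker). The default 0.1 emulates typical lamp or
#'   vignetting drift.
#' @param noise_sd additive Gaussian noise SD on the 0-255 intensity
#'   scale. The default 1.5 is chosen jointly with the rendering bands:
#'   a 3-sigma intensity perturbation at the darkest class boundary
#'   stays inside the 0.04 optical-density margin between band edge and
#'   classification threshold.
#' @param cell_layout optional list of cells to paint instead of the
#'   dispersed class layout; each element is a list with `center` (x, y in
#'   pixels), `shape` (`"spindle"` or `"polygonal"`), `category` (`"SME"`,
#'   `"HME"`, `"NME"` or `"tumor_neg"`), `intensity` (`"mild"`,
#'   `"moderate"`, `"marked"`), and optionally `size` (semi-minor axis,
#'   px), `axis_ratio` and `angle` (radians).
#' @param od_bands per-class DAB optical-density bands (named list of
#'   length-2 ranges).
#' @param hematoxylin_od counterstain OD for negative and positive pixels.
#' @return an object of class `tile_spec`.
#' @seealso [generate_tile()]
#' @export
tile_spec <- function(width = 96, height = 96,
                      class_fractions = c(negative = 0.4, weak = 0.3,
                                          moderate = 0.2, strong = 0.1),
                      background_fraction = 0,
                      gradient_amplitude = 0.1,
                      noise_sd = 1.5,
                      cell_layout = NULL,
                      od_bands = list(negative = c(0.00, 0.05),
                                      weak     = c(0.19, 0.36),
                                      moderate = c(0.44, 0.76),
                                      strong   = c(0.84, 1.20)),
                      hematoxylin_od = c(negative = 0.55, positive = 0.30)) {
  stopifnot(width >= 4, height >= 4, noise_sd >= 0,
            gradient_amplitude >= 0, gradient_amplitude < 1)
  need <- c("negative", "weak", "moderate", "strong")
  if (!all(need %in% names(class_fractions))) {
    stop("class_fractions must name all of: ", paste(need, collapse = ", "))
  }
  class_fractions <- class_fractions[need]
  tot <- sum(class_fractions) + background_fraction
  if (any(class_fractions < 0) || background_fraction < 0 ||
      abs(tot - 1) > 1e-8) {
    stop(sprintf(
      "class_fractions + background_fraction must sum to 1 (got %.6f)", tot))
  }
  structure(list(width = width, height = height,
                 class_fractions = class_fractions,
                 background_fraction = background_fraction,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd,
                 cell_layout = cell_layout,
                 od_bands = od_bands,
                 hematoxylin_od = hematoxylin_od),
            class = "tile_spec")
}

#' Render a synthetic tile with pixel-exact ground truth
#'
#' Renders the tile described by a [tile_spec()] through the Beer-Lambert
#' forward model: each pixel's DAB and hematoxylin optical densities are
#' combined along the reference stain vectors of [hdab_stain_vectors()]
#' and converted to transmitted 8-bit RGB intensity
#' `I = 255 * 10^-OD`. Class pixel counts follow the requested fractions
#' exactly (largest-remainder apportionment), so hard-edged noise-free
#' tiles quantify back to the requested fractions without error.
#'
#' @param spec a [tile_spec()].
#' @param seed integer RNG seed (pixel permutation, band draws, noise).
#' @param tumor_id,marker,field_index metadata attached to the tile.
#' @return a list with elements `tile` (an `ihc_tile`: 8-bit RGB array
#'   `height x width x 3` plus metadata) and `truth` (list with the
#'   per-pixel `labels` character matrix, the realized class `fractions`
#'   as percent of tissue pixels, and for cell layouts a per-cell
#'   annotation `cells` data frame).
#' @examples
#' tg <- generate_tile(tile_spec(width = 32, height = 32), seed = 7)
#' table(tg$truth$labels)
#' @export
generate_tile <- function(spec, seed = 1L, tumor_id = "T001",
                          marker = "calponin", field_index = 1L) {
  stopifnot(inherits(spec, "tile_spec"))
  set.seed(as.integer(seed))
  h <- spec$height; w <- spec$width
  n_px <- h * w
  lev <- c("background", "negative", "weak", "moderate", "strong")

  if (is.null(spec$cell_layout)) {
    fr <- c(background = spec$background_fraction, spec$class_fractions)
    counts <- apportion_counts(n_px, fr)
    lab <- rep(names(fr), counts)
    lab <- lab[sample.int(n_px)]               # dispersed layout
    labels <- matrix(lab, nrow = h, ncol = w)
    cells <- NULL
  } else {
    labels <- matrix("negative", nrow = h, ncol = w)
    cells <- paint_cells(labels, spec$cell_layout)
    labels <- cells$labels
    cells <- cells$table
  }

  # per-pixel DAB OD drawn uniformly within the class band
  dab <- matrix(0, h, w)
  hem <- matrix(0, h, w)
  for (cl in c("negative", "weak", "moderate", "strong")) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    b <- spec$od_bands[[cl]]
    dab[idx] <- stats::runif(length(idx), b[1], b[2])
    hem[idx] <- if (cl == "negative") spec$hematoxylin_od[["negative"]]
                else spec$hematoxylin_od[["positive"]]
  }

  v <- hdab_stain_vectors()
  od <- outer(c(hem), v[, "hematoxylin"]) + outer(c(dab), v[, "dab"])
  img <- array(255 * 10^(-od), dim = c(h, w, 3))

  if (spec$gradient_amplitude > 0) {
    g <- 1 - spec$gradient_amplitude * (seq_len(w) - 1) / (w - 1)
    img <- sweep(img, 2, g, `*`)
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  tabs <- table(factor(labels, levels = lev))
  realized <- 100 * as.numeric(tabs[lev[-1]]) / sum(tabs[lev[-1]])
  names(realized) <- lev[-1]

  list(tile = ihc_tile(img, tumor_id = tumor_id, marker = marker,
                       field_index = field_index),
       truth = list(labels = labels, fractions = realized, cells = cells))
}

# Paint elliptical cells onto a label matrix; returns updated labels and
# the per-cell annotation table. Later cells overwrite earlier ones.
paint_cells <- function(labels, layout) {
  h <- nrow(labels); w <- ncol(labels)
  int2class <- c(mild = "weak", moderate = "moderate", marked = "strong")
  rows <- list()
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_along(layout)) {
    cell <- layout[[i]]
    size <- cell$size %||% 4
    ar <- cell$axis_ratio %||% (if (identical(cell$shape, "spindle")) 4 else 1.2)
    ang <- cell$angle %||% 0
    a <- size * ar; b <- size
    dx <- xs - cell$center[1]; dy <- ys - cell$center[2]
    xr <- dx * cos(ang) + dy * sin(ang)
    yr <- -dx * sin(ang) + dy * cos(ang)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    cls <- if (identical(cell$category, "tumor_neg")) "negative"
           else int2class[[cell$intensity %||% "moderate"]]
    labels[inside] <- cls
    rows[[i]] <- data.frame(cell_id = i,
                            category = cell$category,
                            intensity = cell$intensity %||% NA_character_,
                            shape = cell$shape,
                            axis_ratio = ar,
                            area_px = sum(inside),
                            stringsAsFactors = FALSE)
  }
  list(labels = labels, table = do.call(rbind, rows))
}

#' Construct an immunohistochemistry tile object
#'
#' @param px numeric array `height x width x 3`, 8-bit scale (0-255).
#' @param tumor_id,marker tile provenance.
#' @param field_index representative field number (1-3).
#' @return an `ihc_tile` object.
#' @export
ihc_tile <- function(px, tumor_id = NA_character_, marker = NA_character_,
                     field_index = NA_integer_) {
  stopifnot(is.array(px), length(dim(px)) == 3, dim(px)[3] == 3,
            dim(px)[1] > 0, dim(px)[2] > 0)
  structure(list(px = px,
                 meta = list(tumor_id = tumor_id, marker = marker,
                             field_index = as.integer(field_index))),
            class = "ihc_tile")
}

#' @export
print.ihc_tile <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("<ihc_tile> %d x %d px, tumor %s, marker %s, field %s\n",
              d[1], d[2], x$meta$tumor_id, x$meta$marker,
              x$meta$field_index))
  invisible(x)
}

#' Read and write tiles as 8-bit PNG
#'
#' @param tile an `ihc_tile`.
#' @param path file path.
#' @param ... metadata passed to [ihc_tile()] when reading.
#' @return `write_tile` returns `path` invisibly; `read_tile` returns an
#'   `ihc_tile`.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "ihc_tile"))
  png::writePNG(tile$px / 255, target = path)
  invisible(path)
}

#' @rdname write_tile
#' @export
read_tile <- function(path, ...) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  ihc_tile(round(px * 255), ...)
}

#' Emit per-cell annotation records realizing a tumor's cell percentages
#'
#' Produces the per-cell annotation table that the cell-metrics module
#' consumes: one row per marker-positive cell with its category (SME,
#' HME, NME) and staining intensity. Category counts realize the target
#' percentages exactly up to integer apportionment (largest remainder),
#' so [aggregate_cell_percentages()] round-trips the targets to within
#' `100 / n_cells`.
#'
#' SMA and vimentin label only non-neoplastic myoepithelial cells, so a
#' nonzero NME request for those markers is an error.
#'
#' @param record either a one-row data frame from [generate_cohort()]
#'   (the `<marker>_pct_*` columns are used) or a named numeric vector
#'   `c(sme = , hme = , nme = )` of percentages summing to 100.
#' @param marker one of `"sma"`, `"vimentin"`, `"calponin"`.
#' @param n_cells number of positive cells to emit.
#' @param seed RNG seed (cell order and intensity draws).
#' @param intensity_probs sampling probabilities of the mild/moderate/
#'   marked staining intensities.
#' @return data frame with columns `tumor_id`, `marker`, `category`,
#'   `intensity`.
#' @examples
#' recs <- generate_cell_records(c(sme = 50, hme = 25, nme = 25),
#'                               marker = "calponin", n_cells = 200)
#' table(recs$category)
#' @export
generate_cell_records <- function(record, marker, n_cells = 200, seed = 1L,
                                  intensity_probs = c(mild = 0.35,
                                                      moderate = 0.4,
                                                      marked = 0.25)) {
  marker <- match.arg(marker, c("sma", "vimentin", "calponin"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    pct <- c(sme = record[[paste0(marker, "_pct_sme")]],
             hme = record[[paste0(marker, "_pct_hme")]],
             nme = record[[paste0(marker, "_pct_nme")]])
    tumor_id <- record$tumor_id %||% NA_character_
  } else {
    pct <- record[c("sme", "hme", "nme")]
    tumor_id <- NA_character_
  }
  if (any(is.na(pct)) || any(pct < 0) || abs(sum(pct) - 100) > 1e-6) {
    stop("cell percentages must be nonnegative and sum to 100")
  }
  if (marker %in% c("sma", "vimentin") && pct[["nme"]] > 0) {
    stop("marker '", marker, "' does not label neoplastic cells; ",
         "nme percentage must be 0")
  }
  set.seed(as.integer(seed))
  counts <- apportion_counts(n_cells, pct / 100)
  category <- rep(c("SME", "HME", "NME"), counts)
  category <- category[sample.int(n_cells)]
  data.frame(tumor_id = tumor_id,
             marker = marker,
             category = factor(category, levels = c("SME", "HME", "NME")),
             intensity = factor(
               sample(names(intensity_probs), n_cells, replace = TRUE,
                      prob = intensity_probs),
               levels = c("mild", "moderate", "marked")),
             stringsAsFactors = FALSE)
}
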