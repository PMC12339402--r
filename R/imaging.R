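#' Nucleus images
#'
#' A single central z-slice of one nucleus: named non-negative intensity
#' channels, a binary nucleus mask with exactly one connected component, and
#' the pixel size in micrometres.
#'
#' @param channels named list of numeric matrices.
#' @param mask logical matrix, same dimensions.
#' @param pixel_size um per pixel (> 0).
#' @return object of class `nucleus_image`.
#' @export
nucleus_image <- function(channels, mask, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), is.matrix(mask), pixel_size > 0)
  mask <- mask > 0
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(dim(ch) == dim(mask)))
      stop("channel '", nm, "' dimensions differ from mask", call. = FALSE)
    if (any(ch < 0)) stop("channel '", nm, "' has negative intensities",
                          call. = FALSE)
  }
  ncomp <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (ncomp != 1L)
    stop("mask must have exactly one connected component (found ", ncomp, ")",
         call. = FALSE)
  structure(list(channels = channels, mask = mask, pixel_size = pixel_size),
            class = "nucleus_image")
}

#' Total channel intensity over the nucleus
#'
#' Sum of the channel's pixel values inside the mask (no background
#' subtraction is applied).
#'
#' @param image a [nucleus_image()].
#' @param channel channel name.
#' @return total intensity.
#' @export
total_intensity <- function(image, channel = "marker") {
  if (!channel %in% names(image$channels))
    stop("no channel '", channel, "'", call. = FALSE)
  if (!any(image$mask)) stop("empty mask", call. = FALSE)
  sum(image$channels[[channel]][image$mask])
}

# normalized depth per mask pixel: r = 1 - EDT / max(EDT), where EDT is the
# Euclidean distance of each mask pixel to the mask complement. r = 0 at the
# deepest (most central) pixel, r -> 1 at the boundary.
mask_depth <- function(mask) {
  edt <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  edt <- matrix(as.numeric(edt), nrow(mask), ncol(mask))
  mx <- max(edt)
  list(edt = edt, max = mx, r = ifelse(mask, 1 - edt / mx, NA_real_))
}

#' Radial shell intensity profile
#'
#' Assigns every mask pixel to one of `n_shells` concentric shells by its
#' normalized depth r = 1 - EDT/max(EDT) (EDT = Euclidean distance to the
#' mask complement): shell index min(ceiling(r * n_shells), n_shells), with
#' the deepest pixel (r = 0) in shell 1 and the boundary in shell
#' `n_shells`. Reports, per shell, the fraction of total intensity, the
#' fraction of mask area, and the area-normalized mean intensity.
#'
#' @param image a [nucleus_image()].
#' @param channel channel name.
#' @param n_shells number of shells (>= 2).
#' @return data.frame of class `radial_profile`: shell, intensity_fraction,
#'   area_fraction, mean_intensity.
#' @export
radial_shell_profile <- function(image, channel = "marker", n_shells = 25L) {
  stopifnot(n_shells >= 2L)
  if (!channel %in% names(image$channels))
    stop("no channel '", channel, "'", call. = FALSE)
  d <- mask_depth(image$mask)
  if (d$max <= 1)
    stop("mask too thin for radial profiling (max interior depth <= 1 px)",
         call. = FALSE)
  r <- d$r[image$mask]
  shell <- pmin(pmax(ceiling(r * n_shells), 1L), n_shells)
  val <- image$channels[[channel]][image$mask]
  tot_i <- sum(val)
  int_by <- vapply(seq_len(n_shells), function(k) sum(val[shell == k]), 0.0)
  area_by <- vapply(seq_len(n_shells), function(k) sum(shell == k), 0.0)
  out <- data.frame(shell = seq_len(n_shells),
                    intensity_fraction = if (tot_i > 0) int_by / tot_i
                                         else rep(0, n_shells),
                    area_fraction = area_by / length(val),
                    mean_intensity = ifelse(area_by > 0, int_by / area_by,
                                            NA_real_))
  class(out) <- c("radial_profile", class(out))
  out
}

#' Nuclear envelope / nucleoplasm intensity ratio (TEM-style)
#'
#' For each coordinate, integrates the signal in a square of side
#' `square_um` centred on the point (side in pixels =
#' max(1, round(square_um / pixel_size))), then forms the ratio of the mean
#' integrated density over nuclear-envelope points to the mean over
#' nucleoplasm points.
#'
#' @param image a [nucleus_image()].
#' @param ne_points,np_points data.frames with columns x (column) and y
#'   (row), 1-based pixel coordinates.
#' @param channel channel name.
#' @param square_um square side in micrometres.
#' @return list of class `tem_quantification`: square_px, n_ne, n_np,
#'   mean_ne, mean_np, ratio.
#' @export
tem_periphery_ratio <- function(image, ne_points, np_points,
                                channel = "marker", square_um = 0.2) {
  if (!nrow(ne_points) || !nrow(np_points))
    stop("both point sets must be non-empty", call. = FALSE)
  side <- max(1L, round(square_um / image$pixel_size))
  img <- image$channels[[channel]]
  integrate_square <- function(pts, what) {
    half_lo <- (side - 1L) %/% 2L
    half_hi <- side - 1L - half_lo
    vapply(seq_len(nrow(pts)), function(i) {
      r0 <- pts$y[i] - half_lo; r1 <- pts$y[i] + half_hi
      c0 <- pts$x[i] - half_lo; c1 <- pts$x[i] + half_hi
      if (r0 < 1 || c0 < 1 || r1 > nrow(img) || c1 > ncol(img))
        stop(what, " square exceeds image bounds at point (", pts$x[i], ", ",
             pts$y[i], ")", call. = FALSE)
      sum(img[r0:r1, c0:c1])
    }, 0.0)
  }
  ne <- integrate_square(ne_points, "NE")
  np <- integrate_square(np_points, "nucleoplasm")
  if (mean(np) == 0) stop("mean nucleoplasm signal is zero", call. = FALSE)
  structure(list(square_px = side, n_ne = nrow(ne_points),
                 n_np = nrow(np_points), mean_ne = mean(ne),
                 mean_np = mean(np), ratio = mean(ne) / mean(np)),
            class = "tem_quantification")
}

#' Sample quantification points from nuclear regions
#'
#' Draws `n` pixel coordinates uniformly from the nuclear-envelope region
#' (normalized depth r > `r_ne`) or the nucleoplasm (r < `r_np`),
#' deterministic given the seed.
#'
#' @param mask logical nucleus mask.
#' @param region `"NE"` or `"nucleoplasm"`.
#' @param n number of points.
#' @param seed RNG seed.
#' @param r_ne,r_np depth cuts delimiting the regions.
#' @return data.frame (x, y), 1-based pixel coordinates.
#' @export
sample_region_points <- function(mask, region = c("NE", "nucleoplasm"),
                                 n = 40L, seed = 1L, r_ne = 0.9, r_np = 0.6) {
  region <- match.arg(region)
  d <- mask_depth(mask)
  eligible <- if (region == "NE") mask & d$r > r_ne else mask & d$r < r_np
  idx <- which(eligible, arr.ind = TRUE)
  if (nrow(idx) < n)
    stop("only ", nrow(idx), " eligible pixels for region ", region,
         " (need ", n, ")", call. = FALSE)
  set.seed(as.integer(seed))
  take <- idx[sample(nrow(idx), n), , drop = FALSE]
  data.frame(x = take[, 2L], y = take[, 1L])
}
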