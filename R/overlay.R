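# Review montage: CBF slices in grayscale with the outer WM border (isocontour
# of WM partial volume at a threshold, default 50%) drawn in red, the display
# used for visual rating of normalization quality.

slice_positions <- function(lo, hi, n) {
  round(seq(lo, hi, length.out = n + 2)[2:(n + 1)])
}

# Boundary pixels of wm > threshold within a 2-D slice (4-neighbourhood).
contour_pixels <- function(wm_slice, threshold) {
  inside <- wm_slice > threshold
  d <- dim(inside)
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, d[1], d[2])
    si <- seq_len(d[1]) + di; sj <- seq_len(d[2]) + dj
    oki <- si >= 1 & si <= d[1]; okj <- sj >= 1 & sj <= d[2]
    out[oki, okj] <- m[si[oki], sj[okj]]
    out
  }
  inside & !(shift(inside, 1, 0) & shift(inside, -1, 0) &
             shift(inside, 0, 1) & shift(inside, 0, -1))
}

#' Render a CBF / WM-border overlay montage
#'
#' Writes a PNG montage of evenly spaced axial and sagittal slices spanning
#' the brain, with CBF in grayscale and the white-matter border (WM partial
#' volume above `threshold`) overlaid in red. Rendering is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param cbf_std Standard-space CBF [volumetric_image()].
#' @param wm_template WM probability [volumetric_image()] on the same grid.
#' @param threshold WM partial-volume threshold in (0, 1); default 0.5.
#' @param n_axial,n_sagittal Number of slices per orientation (default 12).
#' @param out Output PNG path.
#' @return Invisibly, `out`.
#' @export
render_overlay <- function(cbf_std, wm_template, threshold = 0.5,
                           n_axial = 12, n_sagittal = 12, out) {
  stopifnot(inherits(cbf_std, "volumetric_image"),
            inherits(wm_template, "volumetric_image"))
  if (!same_geometry(cbf_std$geometry, wm_template$geometry))
    stop("CBF and WM template must share one geometry")
  if (threshold <= 0 || threshold >= 1)
    stop("WM threshold must lie strictly between 0 and 1")
  wm <- wm_template$voxels
  cbf <- pmax(cbf_std$voxels, 0)
  top <- max(cbf)
  if (top > 0) cbf <- pmin(cbf / top, 1)
  support <- which(wm > 0.01 | cbf > 0.01, arr.ind = TRUE)
  if (nrow(support) == 0) support <- matrix(c(1, 1, 1), 1)
  zs <- slice_positions(min(support[, 3]), max(support[, 3]), n_axial)
  xs <- slice_positions(min(support[, 1]), max(support[, 1]), n_sagittal)
  panels <- c(
    lapply(zs, function(z) list(gray = cbf[, , z],
                                edge = contour_pixels(wm[, , z], threshold))),
    lapply(xs, function(x) list(gray = cbf[x, , ],
                                edge = contour_pixels(wm[x, , ], threshold)))
  )
  ncol_grid <- max(n_axial, n_sagittal) / 2
  if (ncol_grid < 1) ncol_grid <- 1
  ncol_grid <- ceiling(ncol_grid)
  ph <- max(vapply(panels, function(p) nrow(p$gray), integer(1)))
  pw <- max(vapply(panels, function(p) ncol(p$gray), integer(1)))
  nrow_grid <- ceiling(length(panels) / ncol_grid)
  img <- array(0, c(nrow_grid * ph, ncol_grid * pw, 3))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    r0 <- (ceiling(i / ncol_grid) - 1) * ph
    c0 <- ((i - 1) %% ncol_grid) * pw
    h <- nrow(p$gray); w <- ncol(p$gray)
    tile <- array(rep(p$gray, 3), c(h, w, 3))
    tile[, , 1][p$edge] <- 1
    tile[, , 2][p$edge] <- 0
    tile[, , 3][p$edge] <- 0
    img[r0 + seq_len(h), c0 + seq_len(w), ] <- tile
  }
  png::writePNG(img, out)
  invisible(out)
}
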