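# Virtual in-situ staining: each cell's concentration of a chosen gene
# product rendered as colour intensity on the lattice, dorsal view
# (AP x mediolateral), mRNAs in blue and proteins in red; epithelialized
# cells carry a distinct glyph. Rendering is a pure function of
# (trajectory, time, spec): identical inputs give identical arrays.

#' Render specification
#'
#' @param species recorded species to stain.
#' @param colormap \code{"auto"} (blue for mRNA pools, red for proteins),
#'   \code{"blue"}, \code{"red"}, \code{"green"}, \code{"magenta"}.
#' @param normalize \code{"snapshot"} (divide by the snapshot maximum) or
#'   a fixed \code{c(lo, hi)} window for cross-time comparability.
#' @param projection \code{"max"} or \code{"mean"} over dorsoventral rows.
#' @param scale pixels per cell block.
#' @return object of class \code{psm_render_spec}.
#' @export
render_spec <- function(species, colormap = "auto", normalize = "snapshot",
                        projection = c("max", "mean"), scale = 4L) {
  projection <- match.arg(projection)
  stopifnot(scale >= 2)
  structure(list(species = species, colormap = colormap,
                 normalize = normalize, projection = projection,
                 scale = as.integer(scale)),
            class = "psm_render_spec")
}

species_is_mrna <- function(sp) {
  grepl("(_mn|_mc|_m)$", sp)
}

# normalized dorsal-view field: mediolateral cols x AP layers in [0,1],
# plus the projected epithelialized mask
project_field <- function(traj, time, species, projection, normalize) {
  ti <- match_time(traj, time)
  k <- match(species, traj$species)
  if (is.na(k)) stop("unknown species: ", species)
  lay <- traj$layer[, ti]
  alive <- !is.na(lay)
  val <- traj$data[, ti, k]
  nl <- max(lay[alive])
  nc <- max(traj$cells$col)
  f <- matrix(0, nc, nl)
  epi <- matrix(FALSE, nc, nl)
  for (ci in seq_len(nc)) {
    for (li in seq_len(nl)) {
      rows <- which(alive & lay == li & traj$cells$col == ci)
      if (!length(rows)) next
      v <- val[rows]
      f[ci, li] <- if (projection == "max") max(v) else mean(v)
      et <- traj$cells$epi_time[rows]
      epi[ci, li] <- any(!is.na(et) & et <= time)
    }
  }
  if (identical(normalize, "snapshot")) {
    m <- max(f)
    if (m > 0) f <- f / m       # all-zero fields stay background
  } else {
    lo <- normalize[1]; hi <- normalize[2]
    if (hi <= lo) stop("invalid normalization window")
    f <- pmin(pmax((f - lo) / (hi - lo), 0), 1)
  }
  list(f = f, epi = epi)
}

colormap_rgb <- function(colormap, species) {
  if (identical(colormap, "auto")) {
    colormap <- if (species_is_mrna(species)) "blue" else "red"
  }
  switch(colormap,
         blue = c(0, 0, 1), red = c(1, 0, 0), green = c(0, 1, 0),
         magenta = c(1, 0, 1),
         stop("unknown colormap: ", colormap))
}

# expand a cols x layers field into pixel blocks; epithelialized cells are
# drawn as a rounded (corner-trimmed) block to symbolize the cell-shape
# change
rasterize <- function(f, epi, rgb3, scale) {
  nc <- nrow(f); nl <- ncol(f)
  img <- array(0, dim = c(nc * scale, nl * scale, 3))
  for (ci in seq_len(nc)) {
    for (li in seq_len(nl)) {
      px <- (ci - 1) * scale + seq_len(scale)
      py <- (li - 1) * scale + seq_len(scale)
      block <- array(rep(rgb3 * f[ci, li], each = scale * scale),
                     dim = c(scale, scale, 3))
      if (epi[ci, li]) {
        # trim the four corners
        block[1, 1, ] <- 0; block[1, scale, ] <- 0
        block[scale, 1, ] <- 0; block[scale, scale, ] <- 0
      }
      img[px, py, ] <- block
    }
  }
  img
}

#' Render a virtual in-situ snapshot
#'
#' @param traj a \code{psm_trajectory}.
#' @param time recorded time (min).
#' @param spec a \code{\link{render_spec}} (or a species name, using
#'   defaults).
#' @return RGB array (mediolateral*scale x AP*scale x 3) in [0,1];
#'   anterior at index 1, growing posteriorly.
#' @export
render_snapshot <- function(traj, time, spec) {
  if (is.character(spec)) spec <- render_spec(spec)
  pf <- project_field(traj, time, spec$species, spec$projection,
                      spec$normalize)
  rasterize(pf$f, pf$epi, colormap_rgb(spec$colormap, spec$species),
            spec$scale)
}

#' Render a virtual double staining
#'
#' Additive (emissive) blending of two channels, species A in green and
#' species B in magenta: where both are equally strong the overlap reads
#' white.
#'
#' @param traj a \code{psm_trajectory}.
#' @param time recorded time.
#' @param speciesA,speciesB recorded species.
#' @param projection,normalize,scale as in \code{\link{render_spec}}.
#' @return RGB array in [0,1].
#' @export
render_double <- function(traj, time, speciesA, speciesB,
                          projection = "max", normalize = "snapshot",
                          scale = 4L) {
  a <- project_field(traj, time, speciesA, projection, normalize)
  b <- project_field(traj, time, speciesB, projection, normalize)
  imgA <- rasterize(a$f, a$epi, c(0, 1, 0), scale)
  imgB <- rasterize(b$f, b$epi, c(1, 0, 1), scale)
  pmin(imgA + imgB, 1)
}

#' Write a rendered array as PNG
#'
#' @param img RGB array from \code{\link{render_snapshot}} or
#'   \code{\link{render_double}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_render_png <- function(img, path) {
  # array is (x = mediolateral, y = AP); rasterImage wants rows = y
  ras <- aperm(img, c(1, 2, 3))
  grDevices::png(path, width = dim(img)[2], height = dim(img)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(ras, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
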