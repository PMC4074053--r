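# Synthetic multi-channel fields of view with known ground truth:
# circular cells on a jittered grid, Gaussian-profile endosome spots at
# recorded positions, a smooth background gradient and Gaussian noise.
# Not a simulation of microscope optics; spots are ideal Gaussians.

#' Write/read a field of view as 16-bit grayscale TIFFs
#'
#' Channels are written as `<channel>.tif` scaled to the 16-bit range and
#' masks as label-image TIFFs (`cell_labels.tif`, `nuc_labels.tif`).
#'
#' @param field A `synthetic_field` (or compatible list).
#' @param dir Output directory.
#' @return `write_field`: invisibly, the directory. `read_field`: a list
#'   with `images`, `cell_labels`, `nuc_labels`.
#' @export
write_field <- function(field, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in names(field$images)) {
    EBImage::writeImage(field$images[[ch]] / 65535,
                        file.path(dir, paste0(ch, ".tif")),
                        type = "tiff", bits.per.sample = 16L)
  }
  EBImage::writeImage(field$cell_labels / 65535,
                      file.path(dir, "cell_labels.tif"),
                      type = "tiff", bits.per.sample = 16L)
  EBImage::writeImage(field$nuc_labels / 65535,
                      file.path(dir, "nuc_labels.tif"),
                      type = "tiff", bits.per.sample = 16L)
  invisible(dir)
}

#' @rdname write_field
#' @param dir Directory written by `write_field`.
#' @export
read_field <- function(dir) {
  rd <- function(f) {
    m <- EBImage::imageData(EBImage::readImage(file.path(dir, f)))
    round(m * 65535)
  }
  chans <- c("nuclear", "fluid", "tf", "surface")
  imgs <- lapply(chans, function(ch) rd(paste0(ch, ".tif")))
  names(imgs) <- chans
  list(images = imgs,
       cell_labels = matrix(as.integer(rd("cell_labels.tif")),
                            nrow(imgs[[1]])),
       nuc_labels = matrix(as.integer(rd("nuc_labels.tif")),
                           nrow(imgs[[1]])))
}

#' Generate a synthetic multi-channel field of view
#'
#' @param dim Image dimensions (>= 128 x 128).
#' @param n_cells Number of cells (placed on a jittered grid).
#' @param cell_radius,nuc_radius Cell and nucleus radii in pixels.
#' @param spots Named list per spot channel (`fluid`, `tf`): list with
#'   `n` (spots per cell), `amplitude`, `sigma` (pixels).
#' @param background List with `level` (constant), `gradient` (peak-to-peak
#'   across the field) and `noise` (Gaussian SD); applied to all channels.
#' @param nuclear_level,surface_level Intensities of the nuclear fill and
#'   the per-cell surface stain.
#' @param min_separation Minimum distance (pixels) between spots of the
#'   same cell and channel; 0 (default) allows overlap.
#' @param seed Integer seed; same seed, identical images.
#' @return List of class `synthetic_field`: `images` (named list of
#'   matrices: nuclear, fluid, tf, surface; 16-bit range), `cell_labels`,
#'   `nuc_labels` (integer label matrices), and `truth` (list with `spots`
#'   data frame: cell, channel, x, y, amplitude, sigma; and `rejected`).
#' @export
generate_images <- function(dim = c(160, 160), n_cells = 9,
                            cell_radius = 20, nuc_radius = 7,
                            spots = list(
                              fluid = list(n = 5, amplitude = 4000, sigma = 1.5),
                              tf = list(n = 4, amplitude = 3500, sigma = 1.5)),
                            background = list(level = 200, gradient = 100,
                                              noise = 20),
                            nuclear_level = 8000, surface_level = 1500,
                            min_separation = 0, seed = 1L) {
  if (any(dim < 128)) stopf("image dimensions must be >= 128 x 128")
  nr <- dim[1]; nc <- dim[2]
  rows <- row(matrix(0, nr, nc)); cols <- col(matrix(0, nr, nc))
  with_seed(seed, {
    # jittered grid of cell centres
    side <- ceiling(sqrt(n_cells))
    gx <- seq(cell_radius + 4, nr - cell_radius - 4, length.out = side)
    gy <- seq(cell_radius + 4, nc - cell_radius - 4, length.out = side)
    centres <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
    centres$x <- centres$x + runif(n_cells, -3, 3)
    centres$y <- centres$y + runif(n_cells, -3, 3)
    cell_labels <- matrix(0L, nr, nc)
    nuc_labels <- matrix(0L, nr, nc)
    for (i in seq_len(n_cells)) {
      d2 <- (rows - centres$x[i])^2 + (cols - centres$y[i])^2
      cell_labels[d2 <= cell_radius^2 & cell_labels == 0L] <- i
      # nucleus offset from the cell centre
      ox <- runif(1, -4, 4); oy <- runif(1, -4, 4)
      d2n <- (rows - centres$x[i] - ox)^2 + (cols - centres$y[i] - oy)^2
      nuc_labels[d2n <= nuc_radius^2 & cell_labels == i] <- i
    }
    bg <- background$level +
      background$gradient * (cols - 1) / (nc - 1)
    imgs <- list(
      nuclear = bg + nuclear_level * (nuc_labels > 0),
      fluid = bg + 0,
      tf = bg + 0,
      surface = bg + surface_level * (cell_labels > 0))
    truth <- list()
    rejected <- list()
    for (ch in names(spots)) {
      sp <- spots[[ch]]
      for (i in seq_len(n_cells)) {
        placed <- 0
        tries <- 0
        px <- numeric(0); py <- numeric(0)
        while (placed < sp$n && tries < 50 * sp$n) {
          tries <- tries + 1
          ang <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * (cell_radius - 2)
          x <- centres$x[i] + rad * cos(ang)
          y <- centres$y[i] + rad * sin(ang)
          if (min_separation > 0 && length(px) &&
              min((px - x)^2 + (py - y)^2) < min_separation^2) next
          if (cell_labels[round(x), round(y)] != i) {
            rejected[[length(rejected) + 1]] <- data.frame(
              cell = i, channel = ch, x = x, y = y)
            warnf("spot outside its cell mask rejected (cell %d, %s)", i, ch)
            next
          }
          win <- 4 * sp$sigma
          xr <- max(1, floor(x - win)):min(nr, ceiling(x + win))
          yr <- max(1, floor(y - win)):min(nc, ceiling(y + win))
          g <- sp$amplitude * exp(-((rep(xr, length(yr)) - x)^2 +
                                      (rep(yr, each = length(xr)) - y)^2) /
                                    (2 * sp$sigma^2))
          imgs[[ch]][xr, yr] <- imgs[[ch]][xr, yr] + g
          truth[[length(truth) + 1]] <- data.frame(
            cell = i, channel = ch, x = x, y = y,
            amplitude = sp$amplitude, sigma = sp$sigma)
          px <- c(px, x); py <- c(py, y)
          placed <- placed + 1
        }
      }
    }
    imgs <- lapply(imgs, function(m) {
      m <- m + rnorm(length(m), 0, background$noise)
      matrix(pmin(pmax(round(m), 0), 65535), nr, nc)
    })
    structure(list(images = imgs, cell_labels = cell_labels,
                   nuc_labels = nuc_labels,
                   truth = list(
                     spots = if (length(truth)) do.call(rbind, truth)
                             else data.frame(),
                     rejected = if (length(rejected))
                       do.call(rbind, rejected) else data.frame())),
              class = "synthetic_field")
  })
}
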