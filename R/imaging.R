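#' Dynamic PET image
#'
#' A 4D voxel array (x, y, z, frame) in kBq/mL with its frame schedule,
#' isotropic voxel size, and an optional 3D analysis mask.
#'
#' @param data 4D numeric array; the 4th axis must match the schedule.
#' @param schedule A [frame_schedule()].
#' @param voxel_size_mm Isotropic voxel size (mm), `> 0`.
#' @param mask Optional 3D logical array marking analysis voxels.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm = 4, mask = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, frame)")
  if (dim(data)[4L] != n_frames(schedule))
    stop("frame axis length must equal the number of frames")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("'voxel_size_mm' must be > 0")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask shape does not match the image grid")
  }
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = voxel_size_mm, mask = mask),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames, %g mm\n",
              d[1L], d[2L], d[3L], d[4L], x$voxel_size_mm))
  invisible(x)
}

#' Composite frames from a dynamic image
#'
#' Duration-weighted mean 3D images over the given time windows, used as
#' the prior features for [build_kernel()]. Default windows for the 2-min
#' early-dynamic protocol are 0-30, 30-60 and 60-120 s.
#'
#' @param img A [dynamic_image()].
#' @param intervals List of `c(start_s, end_s)` windows within the scan.
#' @return A list of 3D arrays, one per window.
#' @export
composite_frames <- function(img,
                             intervals = list(c(0, 30), c(30, 60),
                                              c(60, 120))) {
  stopifnot(inherits(img, "dynamic_image"))
  s <- img$schedule
  nf <- n_frames(s)
  d <- dim(img$data)
  flat <- matrix(img$data, ncol = nf)
  lapply(intervals, function(iv) {
    if (length(iv) != 2L || iv[2L] <= iv[1L])
      stop("each interval must be c(start_s, end_s) with end > start")
    ov <- pmin(s$ends, iv[2L]) - pmax(s$starts, iv[1L])
    ov[ov < 0] <- 0
    if (sum(ov) <= 0)
      stop("interval [", iv[1L], ", ", iv[2L], "] overlaps no frames")
    array(as.numeric(flat %*% (ov / sum(ov))), dim = d[1:3])
  })
}

#' Build a kernel smoothing operator from composite images
#'
#' Constructs the nonlocal-means-like kernel operator: each masked voxel's
#' feature vector is its composite intensities (z-scored per composite over
#' the mask); its neighbors are the `k` masked voxels with smallest
#' Euclidean feature distance within a spatial window of
#' `(2 * window + 1)^3` voxels (default 9 x 9 x 9), the voxel itself always
#' included; weights are Gaussian in feature distance with bandwidth equal
#' to the per-voxel median neighbor distance (uniform when all distances are
#' zero), then row-normalized. Near image edges or sparse masks, fewer than
#' `k` candidates may be available; the available ones are used.
#'
#' @param composites List of 3D arrays from [composite_frames()].
#' @param mask 3D logical array of voxels to smooth.
#' @param k Number of nearest neighbors (default 49).
#' @param window Spatial half-width (default 4, giving a 9 x 9 x 9 box).
#' @return An object of class `kernel_operator` holding a sparse
#'   row-stochastic matrix over the masked voxels.
#' @export
build_kernel <- function(composites, mask, k = 49, window = 4) {
  if (!is.list(composites) || !length(composites))
    stop("'composites' must be a non-empty list of 3D arrays")
  dims <- dim(composites[[1L]])
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dims)) stop("mask shape mismatch")
  if (k < 1) stop("'k' must be >= 1")
  if (k > (2 * window + 1)^3)
    stop("'k' exceeds the spatial window volume")
  nmask <- sum(mask)
  if (nmask == 0L) stop("mask is empty")

  # z-scored composite features over the mask
  feat <- vapply(composites, function(cmp) {
    v <- cmp[mask]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, nmask) else (v - mean(v)) / s
  }, numeric(nmask))
  feat <- matrix(feat, nrow = nmask)

  vidx <- array(0L, dim = dims)
  vidx[mask] <- seq_len(nmask)
  coords <- which(mask, arr.ind = TRUE)

  offs <- as.matrix(expand.grid(dx = -window:window, dy = -window:window,
                                dz = -window:window))
  # self offset first so zero-distance ties always keep the voxel itself
  self <- which(rowSums(abs(offs)) == 0L)
  offs <- offs[c(self, setdiff(seq_len(nrow(offs)), self)), , drop = FALSE]
  noff <- nrow(offs)

  D2 <- matrix(Inf, nmask, noff)
  NB <- matrix(0L, nmask, noff)
  for (oi in seq_len(noff)) {
    nc <- sweep(coords, 2L, offs[oi, ], "+")
    valid <- nc[, 1L] >= 1 & nc[, 1L] <= dims[1L] &
             nc[, 2L] >= 1 & nc[, 2L] <= dims[2L] &
             nc[, 3L] >= 1 & nc[, 3L] <= dims[3L]
    nb <- integer(nmask)
    nb[valid] <- vidx[nc[valid, , drop = FALSE]]
    hit <- nb > 0L
    if (any(hit)) {
      diff2 <- (feat[hit, , drop = FALSE] -
                feat[nb[hit], , drop = FALSE])^2
      D2[hit, oi] <- rowSums(diff2)
      NB[hit, oi] <- nb[hit]
    }
  }

  ii <- vector("list", nmask)
  jj <- vector("list", nmask)
  ww <- vector("list", nmask)
  for (v in seq_len(nmask)) {
    d2 <- D2[v, ]
    avail <- sum(is.finite(d2))
    keff <- min(k, avail)
    sel <- order(d2)[seq_len(keff)]
    d <- sqrt(d2[sel])
    h <- stats::median(d)
    wgt <- if (h <= 0) rep(1, keff) else exp(-(d / h)^2)
    ii[[v]] <- rep.int(v, keff)
    jj[[v]] <- NB[v, sel]
    ww[[v]] <- wgt / sum(wgt)
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(nmask, nmask))
  structure(list(W = W, mask = mask, dims = dims, k = k, window = window,
                 n_voxels = nmask),
            class = "kernel_operator")
}

#' @export
print.kernel_operator <- function(x, ...) {
  cat(sprintf("<kernel_operator> %d masked voxels, k = %d, %dx%dx%d window\n",
              x$n_voxels, x$k, 2 * x$window + 1, 2 * x$window + 1,
              2 * x$window + 1))
  invisible(x)
}

#' Apply a kernel operator to an image or map
#'
#' Replaces each masked voxel's value by its row-normalized weighted
#' neighbor average; a 4D [dynamic_image()] is smoothed frame by frame.
#' Voxels outside the operator's mask are returned unchanged.
#'
#' @param op A [build_kernel()] operator.
#' @param x A [dynamic_image()] or a 3D array on the same grid.
#' @return The smoothed object, same type as `x`.
#' @export
apply_kernel <- function(op, x) {
  stopifnot(inherits(op, "kernel_operator"))
  if (inherits(x, "dynamic_image")) {
    if (!identical(dim(x$data)[1:3], op$dims)) stop("geometry mismatch")
    nf <- n_frames(x$schedule)
    flat <- matrix(x$data, ncol = nf)
    mvec <- as.vector(op$mask)
    flat[mvec, ] <- as.matrix(op$W %*% flat[mvec, , drop = FALSE])
    dynamic_image(array(flat, dim = dim(x$data)), x$schedule,
                  x$voxel_size_mm, x$mask)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (!identical(dim(x), op$dims)) stop("geometry mismatch")
    out <- x
    out[op$mask] <- as.numeric(op$W %*% x[op$mask])
    out
  } else {
    stop("'x' must be a dynamic_image or a 3D array")
  }
}

#' Voxelwise parametric imaging
#'
#' Fits the kinetic model to every masked voxel of a dynamic image with a
#' shared precomputed basis, optionally kernel-smoothing the dynamic frames
#' first, and assembles 3D parametric maps. Voxels with identical series
#' (e.g. noiseless phantoms) are fitted once. Outside the mask the maps
#' hold `NA`.
#'
#' @param img A [dynamic_image()]; its `mask` (or every voxel when absent)
#'   defines the fitting domain.
#' @param aif The [arterial_input()].
#' @param grid A [grid_config()]. Voxelwise work typically uses a coarser
#'   grid than regional fitting; see [grid_config()] examples.
#' @param model `"aath"` or `"s1tc"`.
#' @param smooth Kernel-smooth the dynamic frames before fitting.
#' @param kernel A prebuilt [build_kernel()] operator; when `smooth = TRUE`
#'   and `kernel` is `NULL`, one is built from default [composite_frames()].
#' @return An object of class `parametric_maps`: a named list of 3D maps
#'   (`F`, `K1`, `k2`, `Tc`, `td`, `vb`, `E`, `RSS` for AATH; `vb`, `K1`,
#'   `k2`, `td`, `RSS` for S1TC) plus geometry fields.
#' @export
fit_voxelwise <- function(img, aif, grid = grid_config(), model = "aath",
                          smooth = FALSE, kernel = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  mask <- if (is.null(img$mask)) {
    array(TRUE, dim = dim(img$data)[1:3])
  } else img$mask
  if (!any(mask)) stop("mask is empty")
  if (smooth) {
    if (is.null(kernel)) {
      kernel <- build_kernel(composite_frames(img), mask)
    }
    img <- apply_kernel(kernel, img)
  }
  basis <- build_basis(aif, img$schedule, grid, model)
  nf <- n_frames(img$schedule)
  Y <- matrix(img$data, ncol = nf)[as.vector(mask), , drop = FALSE]

  keys <- apply(Y, 1L, function(r) paste(r, collapse = ","))
  uniq <- !duplicated(keys)
  map_to <- match(keys, keys[uniq])
  Yu <- Y[uniq, , drop = FALSE]

  par_names <- if (model == "aath") {
    c("F", "K1", "k2", "Tc", "td", "vb", "E", "RSS")
  } else {
    c("vb", "K1", "k2", "td", "RSS")
  }
  est_u <- matrix(NA_real_, nrow(Yu), length(par_names),
                  dimnames = list(NULL, par_names))
  for (vi in seq_len(nrow(Yu))) {
    fit <- fit_tac(tac(img$schedule, Yu[vi, ]), basis)
    est_u[vi, ] <- c(fit$estimates[setdiff(par_names, "RSS")], fit$rss)
  }
  est <- est_u[map_to, , drop = FALSE]

  maps <- lapply(seq_along(par_names), function(ci) {
    m <- array(NA_real_, dim = dim(mask))
    m[mask] <- est[, ci]
    m
  })
  names(maps) <- par_names
  structure(list(maps = maps, mask = mask, model = model,
                 voxel_size_mm = img$voxel_size_mm,
                 schedule = img$schedule),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %s model, %d voxels, maps: %s\n",
              toupper(x$model), sum(x$mask),
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Read and write volumetric images (NIfTI)
#'
#' Thin wrappers around RNifti for the standard neuroimaging volume format:
#' 4D dynamics (with a schedule supplied by the caller, since frame timing
#' is not stored in the format), 3D masks/label maps, and per-parameter
#' output maps (filename-suffixed `_F`, `_K1`, ...).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param schedule A [frame_schedule()] describing the 4th axis.
#' @param voxel_size_mm Voxel size override; taken from the header when
#'   `NULL`.
#' @return `read_dynamic_image()` returns a [dynamic_image()];
#'   `read_volume()` a 3D array.
#' @export
read_dynamic_image <- function(path, schedule, voxel_size_mm = NULL) {
  vol <- RNifti::readNifti(path)
  arr <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(arr)) != 4L) stop("expected a 4D volume")
  if (is.null(voxel_size_mm))
    voxel_size_mm <- RNifti::pixdim(vol)[1L]
  dynamic_image(arr, schedule, voxel_size_mm = voxel_size_mm)
}

#' @rdname read_dynamic_image
#' @export
read_volume <- function(path) {
  vol <- RNifti::readNifti(path)
  arr <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  arr
}

#' @rdname read_dynamic_image
#' @param img A [dynamic_image()].
#' @export
write_dynamic_image <- function(img, path) {
  stopifnot(inherits(img, "dynamic_image"))
  vol <- RNifti::asNifti(img$data)
  RNifti::pixdim(vol) <- c(rep(img$voxel_size_mm, 3), 1)
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' @rdname read_dynamic_image
#' @param maps A [fit_voxelwise()] result.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @export
write_parametric_maps <- function(maps, dir, prefix = "param") {
  stopifnot(inherits(maps, "parametric_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps$maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    vol <- RNifti::asNifti(maps$maps[[nm]])
    RNifti::pixdim(vol) <- rep(maps$voxel_size_mm, 3)
    RNifti::writeNifti(vol, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
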