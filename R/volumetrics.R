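#' Image stacks
#'
#' An `image_stack` is a 3D intensity array indexed `[z, y, x]` with voxel
#' sizes in micrometers. The confocal acquisition this models uses a 0.2
#' um z step; lateral voxel sizes default to 0.1 um.
#'
#' @param data 3D numeric array `[z, y, x]`, intensities >= 0.
#' @param voxel_size numeric `c(dz, dy, dx)` in um, all > 0.
#' @param id optional stack identifier.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, voxel_size = c(0.2, 0.1, 0.1), id = NA_character_) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (any(data < 0)) .stopf("intensities must be >= 0")
  structure(list(data = data, voxel_size = as.numeric(voxel_size), id = id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack %s: %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              x$id, d[1L], d[2L], d[3L],
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L]))
  invisible(x)
}

#' Write / read an image stack as TIFF with a JSON voxel-size sidecar
#'
#' The stack is stored as a multi-page 32-bit float TIFF (one page per z
#' slice, intensities scaled into [0,1] by `scale`), with voxel sizes and
#' the scale recorded in `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param scale intensity divisor applied before writing.
#' @return `write_stack_tiff()` returns `path`; `read_stack_tiff()`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack$data, 1)) {
  d <- stack$data
  pages <- lapply(seq_len(dim(d)[1L]), function(z) d[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(voxel_size_um = stack$voxel_size, scale = scale, id = stack$id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- array(0, dim = c(length(pages), dim(pages[[1L]])))
  for (z in seq_along(pages)) d[z, , ] <- pages[[z]] * meta$scale
  image_stack(d, voxel_size = meta$voxel_size_um,
              id = if (is.null(meta$id)) NA_character_ else meta$id)
}

#' Subtract a background estimate from a stack
#'
#' Subtracts the mean intensity of a background region of interest from
#' every voxel, clipping at zero — mirroring the practice of measuring a
#' region outside the specimen and subtracting its mean.
#'
#' @param stack an [image_stack()].
#' @param background_roi numeric vector/array of background intensities,
#'   or a single precomputed mean.
#' @return The background-subtracted [image_stack()].
#' @export
subtract_background <- function(stack, background_roi) {
  stopifnot(inherits(stack, "image_stack"))
  bg <- mean(as.numeric(background_roi))
  out <- stack
  out$data <- pmax(stack$data - bg, 0)
  out
}

#' Li minimum cross-entropy threshold
#'
#' Finds the threshold minimizing the cross-entropy between the image and
#' its two-class mean reconstruction, by exhaustive scan over the observed
#' intensity levels (deterministic). For each candidate cut the criterion
#' is `-(S0 log mu0 + S1 log mu1)` with `S`/`mu` the intensity sum and
#' mean of the voxels below/at-or-above the cut. The returned threshold is
#' the midpoint between the two observed levels straddling the optimal
#' cut, so for a two-level image it falls strictly between the levels;
#' binarize with `>= threshold`. The criterion is scale-equivariant:
#' scaling intensities by `c > 0` scales the threshold by `c`.
#'
#' @param image numeric vector, matrix or array of intensities (>= 0; a 2D
#'   maximum-intensity projection in the granule pipeline).
#' @return The threshold (numeric scalar).
#' @export
li_threshold <- function(image) {
  x <- as.numeric(image)
  levels <- sort(unique(x))
  if (length(levels) < 2L) {
    .stopf("Li threshold undefined: image has a single intensity level")
  }
  counts <- tabulate(match(x, levels), nbins = length(levels))
  s <- levels * counts
  cs_n <- cumsum(counts)            # voxels at levels <= k
  cs_s <- cumsum(s)
  n_tot <- cs_n[length(cs_n)]
  s_tot <- cs_s[length(cs_s)]
  # cut after level k: below = levels 1..k, above = k+1..end
  k <- seq_len(length(levels) - 1L)
  n0 <- cs_n[k]; s0 <- cs_s[k]
  n1 <- n_tot - n0; s1 <- s_tot - s0
  term <- function(sx, nx) ifelse(sx > 0, sx * log(sx / nx), 0)
  crit <- -(term(s0, n0) + term(s1, n1))
  best <- which.min(crit)
  (levels[best] + levels[best + 1L]) / 2
}

#' Consensus threshold over reference stacks
#'
#' For each stack: maximum-intensity projection along z, then
#' [li_threshold()]; the consensus is the median across stacks. This
#' mirrors the practice of thresholding wild-type nuclei projections and
#' applying the median value to every stack.
#'
#' @param stacks list of [image_stack()] objects (e.g. 15 wild-type
#'   nuclei).
#' @return The median threshold (numeric scalar), with the per-stack
#'   thresholds in the `per_stack` attribute.
#' @export
consensus_threshold <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  th <- vapply(stacks, function(s) {
    proj <- apply(s$data, c(2L, 3L), max)
    li_threshold(proj)
  }, numeric(1L))
  out <- stats::median(th)
  attr(out, "per_stack") <- th
  out
}

# 3D connected-component labeling on a logical array, 26- or
# 6-connectivity, iterative BFS over linear indices.
.label_components_3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, connectivity %in% c(6L, 26L))
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  labels <- array(0L, dim = d)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(labels)
  # precompute subscripts for fast neighbor arithmetic
  arr_ind <- arrayInd(idx_all, d)
  sub_z <- integer(prod(d)); sub_y <- integer(prod(d)); sub_x <- integer(prod(d))
  sub_z[idx_all] <- arr_ind[, 1L]
  sub_y[idx_all] <- arr_ind[, 2L]
  sub_x[idx_all] <- arr_ind[, 3L]
  cur <- 0L
  for (seed in idx_all) {
    if (labels[seed] != 0L) next
    cur <- cur + 1L
    labels[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      z <- sub_z[frontier]; y <- sub_y[frontier]; x <- sub_x[frontier]
      nbr <- integer(0)
      for (r in seq_len(nrow(offs))) {
        zz <- z + offs$dz[r]; yy <- y + offs$dy[r]; xx <- x + offs$dx[r]
        ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
        if (!any(ok)) next
        lin <- zz[ok] + (yy[ok] - 1L) * nz + (xx[ok] - 1L) * nz * ny
        nbr <- c(nbr, lin[mask[lin] & labels[lin] == 0L])
      }
      nbr <- unique(nbr)
      labels[nbr] <- cur
      frontier <- nbr
    }
  }
  labels
}

#' Segment granules in a 3D stack
#'
#' Binarizes at `>= threshold`, labels 3D connected components
#' (26-connectivity by default, configurable to 6), discards components
#' below `min_voxels` (default 2, suppressing shot-noise singletons), and
#' reports volumes in cubic micrometers (`voxels x dz x dy x dx`).
#'
#' @param stack an [image_stack()].
#' @param threshold intensity threshold (e.g. from
#'   [consensus_threshold()]).
#' @param connectivity 26 (default) or 6.
#' @param min_voxels minimum component size in voxels.
#' @return data.frame of granule records: `label`, `voxels`, `volume_um3`,
#'   centroid (`cz`, `cy`, `cx`, in voxel coordinates), `stack_id`.
#' @export
segment_granules <- function(stack, threshold, connectivity = 26L,
                             min_voxels = 2L) {
  stopifnot(inherits(stack, "image_stack"))
  mask <- stack$data >= threshold
  labels <- .label_components_3d(mask, connectivity)
  empty <- data.frame(label = integer(), voxels = integer(),
                      volume_um3 = numeric(), cz = numeric(), cy = numeric(),
                      cx = numeric(), stack_id = character())
  if (!any(labels > 0L)) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  sizes <- table(lab)
  keep_labs <- as.integer(names(sizes)[sizes >= min_voxels])
  if (length(keep_labs) == 0L) return(empty)
  vox_vol <- prod(stack$voxel_size)
  sub <- arrayInd(idx, dim(stack$data))
  out <- do.call(rbind, lapply(seq_along(keep_labs), function(i) {
    sel <- lab == keep_labs[i]
    nv <- sum(sel)
    data.frame(label = i, voxels = nv, volume_um3 = nv * vox_vol,
               cz = mean(sub[sel, 1L]), cy = mean(sub[sel, 2L]),
               cx = mean(sub[sel, 3L]),
               stack_id = if (is.na(stack$id)) "" else stack$id)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize granule volumes by group
#'
#' @param groups named list of granule record data.frames (from
#'   [segment_granules()]), e.g. wild-type nuclear membrane, mutant
#'   nuclear membrane, mutant rachis.
#' @return list with `summary` (per group: n granules, mean and median
#'   volume in um^3) and `folds` (pairwise `mean(a) / mean(b)` for every
#'   ordered group pair).
#' @export
summarize_volumes <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]$volume_um3
    data.frame(group = g, n = length(v),
               mean_volume_um3 = mean(v),
               median_volume_um3 = stats::median(v))
  }))
  rownames(summ) <- NULL
  pairs <- expand.grid(a = summ$group, b = summ$group,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pairs$fold <- summ$mean_volume_um3[match(pairs$a, summ$group)] /
    summ$mean_volume_um3[match(pairs$b, summ$group)]
  rownames(pairs) <- NULL
  list(summary = summ, folds = pairs)
}

#' Fold change between two group means
#'
#' @param mean_a,mean_b group mean volumes (um^3).
#' @return `mean_a / mean_b`.
#' @export
volume_fold <- function(mean_a, mean_b) {
  stopifnot(mean_b > 0)
  mean_a / mean_b
}
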