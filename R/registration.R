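# Linear (6/9-dof) and fluid (demons-type) registration. Linear alignment
# maximises normalised cross-correlation over a 3-level coarse-to-fine
# pyramid; fluid registration is a compositive demons scheme with Gaussian
# regularisation of the update (velocity) field and step rejection that keeps
# the accumulated field diffeomorphic (positive Jacobian).

# block-average downsampling by 2 (odd trailing voxels are dropped)
downsample_volume <- function(vol) {
  a <- vol$data; d <- dim(a)
  n <- d %/% 2L
  a <- a[seq_len(2 * n[1]), seq_len(2 * n[2]), seq_len(2 * n[3]), drop = FALSE]
  i1 <- seq(1, 2 * n[1], by = 2)
  j1 <- seq(1, 2 * n[2], by = 2)
  k1 <- seq(1, 2 * n[3], by = 2)
  out <- (a[i1, j1, k1, drop = FALSE] + a[i1 + 1, j1, k1, drop = FALSE] +
          a[i1, j1 + 1, k1, drop = FALSE] + a[i1 + 1, j1 + 1, k1, drop = FALSE] +
          a[i1, j1, k1 + 1, drop = FALSE] + a[i1 + 1, j1, k1 + 1, drop = FALSE] +
          a[i1, j1 + 1, k1 + 1, drop = FALSE] +
          a[i1 + 1, j1 + 1, k1 + 1, drop = FALSE]) / 8
  g <- vol$grid
  image_volume(out, grid_spec(n, g$spacing * 2, g$origin + g$spacing / 2))
}

pyramid <- function(vol, levels) {
  out <- vector("list", levels)
  out[[levels]] <- vol
  if (levels > 1) {
    for (l in seq(levels - 1, 1)) {
      v <- out[[l + 1]]
      if (any(v$grid$shape %/% 2L < 8L)) out[[l]] <- v
      else out[[l]] <- downsample_volume(v)
    }
  }
  out  # coarsest first
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Linear registration (rigid or rigid+scaling)
#'
#' Estimates the 6-dof (rigid) or 9-dof (rigid + per-axis scaling) transform
#' maximising normalised cross-correlation between the fixed image and the
#' resampled moving image, by Nelder-Mead optimisation over a 3-level
#' coarse-to-fine pyramid. For 9 dof the product of the recovered scales
#' estimates the whole-volume ratio between the images.
#'
#' @param moving,fixed [image_volume()] objects with overlapping fields of
#'   view
#' @param dof 6 or 9
#' @param levels number of pyramid levels (default 3)
#' @param maxit Nelder-Mead iteration caps per level, coarsest first
#' @param init optional initial [linear_transform()]
#' @return a [linear_transform()] whose `meta` carries the final NCC, the
#'   per-level metric trace and a `converged` flag
#' @export
register_linear <- function(moving, fixed, dof = 6, levels = 3,
                            maxit = c(400, 250, 120), init = NULL) {
  stopifnot(dof %in% c(6, 9))
  maxit <- rep_len(maxit, levels)
  ctr <- grid_center(fixed$grid)
  npar <- if (dof == 9) 9L else 6L
  p <- numeric(npar)
  if (!is.null(init)) {
    p[1:3] <- init$rot; p[4:6] <- init$trans
    if (dof == 9) p[7:9] <- log(init$scale)
  }
  p2t <- function(p) linear_transform(
    rot = p[1:3], trans = p[4:6],
    scale = if (dof == 9) exp(p[7:9]) else c(1, 1, 1), center = ctr)
  fpyr <- pyramid(fixed, levels)
  mpyr <- pyramid(moving, levels)
  trace_ <- numeric(0)
  conv <- TRUE
  for (l in seq_len(levels)) {
    f <- fpyr[[l]]; m <- mpyr[[l]]
    fv <- as.vector(f$data)
    obj <- function(p) {
      w <- resample(m, p2t(p), grid = f$grid)
      -ncc(fv, as.vector(w$data))
    }
    scales <- c(rep(0.02, 3), rep(0.5, 3), rep(0.03, 3))[seq_len(npar)]
    res <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[l], parscale = scales,
                                       reltol = 1e-7))
    if (dof == 9) {
      # warm restart rebuilds the simplex; the 9-parameter search is prone
      # to degenerate collapse before the scales move
      res2 <- stats::optim(res$par, obj, method = "Nelder-Mead",
                           control = list(maxit = ceiling(maxit[l] / 2),
                                          parscale = scales, reltol = 1e-7))
      if (res2$value < res$value) res <- res2
    }
    p <- res$par
    trace_ <- c(trace_, -res$value)
    if (res$convergence != 0 && l == levels) conv <- FALSE
  }
  out <- p2t(p)
  out$meta <- list(ncc = trace_[length(trace_)], trace = trace_,
                   converged = conv, dof = dof)
  if (!conv && out$meta$ncc < 0.95)
    warning("register_linear: iteration cap reached at the finest level ",
            "with poor alignment (final NCC ",
            sprintf("%.4f", out$meta$ncc), "); best-so-far returned")
  out
}

#' Population mean image
#'
#' Registers every image to the reference (9 dof by default), resamples onto
#' the reference grid and averages voxel-wise.
#'
#' @param images list of [image_volume()]
#' @param reference the canonical reference [image_volume()]
#' @param dof degrees of freedom passed to [register_linear()]
#' @param ... further arguments to [register_linear()]
#' @return an [image_volume()]; attribute `transforms` carries the per-image
#'   transforms
#' @export
population_mean <- function(images, reference, dof = 9, ...) {
  stopifnot(length(images) >= 1)
  acc <- array(0, dim = reference$grid$shape)
  trs <- vector("list", length(images))
  for (i in seq_along(images)) {
    tr <- tryCatch(register_linear(images[[i]], reference, dof = dof, ...),
                   error = function(e)
                     stop("population_mean: registration failed for image ",
                          i, ": ", conditionMessage(e)))
    trs[[i]] <- tr
    acc <- acc + resample(images[[i]], tr, grid = reference$grid)$data
  }
  out <- image_volume(acc / length(images), reference$grid)
  attr(out, "transforms") <- trs
  out
}

#' Fluid registration parameters
#'
#' @param levels pyramid levels (default 3)
#' @param iters iteration caps per level, coarsest first
#' @param tol stop a level when the relative SSD improvement of an accepted
#'   step falls below this
#' @param sigma_fluid_mm Gaussian sd (mm) smoothing each update field
#'   (fluid-like regularisation of the velocity)
#' @param sigma_field_mm optional Gaussian sd (mm) smoothing the accumulated
#'   field after each accepted step (0 = off)
#' @param step_voxels per-axis displacement cap of one update, in voxels
#' @param max_reject consecutive rejected steps before a level is abandoned
#' @param force demons force: `"symmetric"` (default) averages the fixed and
#'   warped-moving gradients, `"fixed"` uses the fixed-image gradient only
#' @return list of class `fluid_params`
#' @export
fluid_params <- function(levels = 3, iters = c(60, 40, 30), tol = 1e-4,
                         sigma_fluid_mm = 0.9, sigma_field_mm = 0,
                         step_voxels = 0.4, max_reject = 10,
                         force = c("symmetric", "fixed")) {
  structure(list(levels = levels, iters = rep_len(iters, levels), tol = tol,
                 sigma_fluid_mm = sigma_fluid_mm,
                 sigma_field_mm = sigma_field_mm,
                 step_voxels = step_voxels, max_reject = max_reject,
                 force = match.arg(force)),
            class = "fluid_params")
}

# sample a coarse field onto a finer grid (mm values are grid-independent)
upsample_field <- function(field, grid) {
  cg <- field$grid
  m <- index_mesh(grid$shape)
  pi_ <- ((m$i - 1) * grid$spacing[1] + grid$origin[1] - cg$origin[1]) /
    cg$spacing[1] + 1
  pj_ <- ((m$j - 1) * grid$spacing[2] + grid$origin[2] - cg$origin[2]) /
    cg$spacing[2] + 1
  pk_ <- ((m$k - 1) * grid$spacing[3] + grid$origin[3] - cg$origin[3]) /
    cg$spacing[3] + 1
  u <- array(0, dim = c(grid$shape, 3L))
  for (c_ in 1:3)
    u[, , , c_] <- array(interp_trilinear(field$u[, , , c_], pi_, pj_, pk_,
                                          clamp = TRUE), dim = grid$shape)
  deformation_field(u, grid)
}

#' Fluid (demons-type) non-rigid registration
#'
#' Compositive demons: at each iteration the intensity difference times the
#' image gradient (by default the symmetric mean of the fixed and the
#' warped-moving gradients), stabilised by the classic normalised
#' denominator, gives an update field; the update is Gaussian-smoothed, capped to at most
#' `step_voxels` per axis, and composed with the running field. A step is
#' accepted only if the composed field keeps a positive interior Jacobian and
#' does not increase the SSD; rejected steps are retried at half length.
#' Runs coarse-to-fine over a multi-resolution pyramid.
#'
#' Images are assumed already linearly aligned.
#'
#' @param moving,fixed [image_volume()] objects on a common grid
#' @param params a [fluid_params()]
#' @return a [deformation_field()] on the fixed grid mapping fixed-image
#'   points into the moving image; `meta` carries the SSD trace, iteration
#'   counts, rejection diagnostics and the final minimum interior Jacobian
#' @export
register_fluid <- function(moving, fixed, params = fluid_params()) {
  stopifnot(same_grid(moving$grid, fixed$grid))
  fpyr <- pyramid(fixed, params$levels)
  mpyr <- pyramid(moving, params$levels)
  field <- NULL
  meta <- list(iterations = integer(0), ssd_trace = list(),
               rejected = integer(0), level_aborted = logical(0),
               converged = TRUE)
  for (l in seq_len(params$levels)) {
    f <- fpyr[[l]]; m <- mpyr[[l]]
    grid <- f$grid
    field <- if (is.null(field)) zero_field(grid)
             else upsample_field(field, grid)
    # fixed-image gradient (per mm), precomputed once per level
    gx_f <- diff_axis(f$data, 1, grid$spacing[1])
    gy_f <- diff_axis(f$data, 2, grid$spacing[2])
    gz_f <- diff_axis(f$data, 3, grid$spacing[3])
    K <- mean(grid$spacing^2)
    cap <- params$step_voxels * grid$spacing
    mw <- warp_volume(m, field)$data
    ssd <- mean((f$data - mw)^2)
    trace_ <- ssd
    it_done <- 0L; nrej <- 0L; consec_rej <- 0L; stepscale <- 1
    for (it in seq_len(params$iters[l])) {
      if (params$force == "symmetric") {
        gx <- (gx_f + diff_axis(mw, 1, grid$spacing[1])) / 2
        gy <- (gy_f + diff_axis(mw, 2, grid$spacing[2])) / 2
        gz <- (gz_f + diff_axis(mw, 3, grid$spacing[3])) / 2
      } else {
        gx <- gx_f; gy <- gy_f; gz <- gz_f
      }
      gn2 <- gx^2 + gy^2 + gz^2
      diffim <- f$data - mw
      den <- gn2 + diffim^2 / K
      fac <- ifelse(den > 1e-12, diffim / den, 0)
      v <- array(0, dim = c(grid$shape, 3L))
      v[, , , 1] <- fac * gx; v[, , , 2] <- fac * gy; v[, , , 3] <- fac * gz
      v <- smooth_field(v, params$sigma_fluid_mm, grid$spacing)
      sc <- min(1, cap[1] / max(max(abs(v[, , , 1])), 1e-12),
                cap[2] / max(max(abs(v[, , , 2])), 1e-12),
                cap[3] / max(max(abs(v[, , , 3])), 1e-12))
      accepted <- FALSE
      while (!accepted && consec_rej < params$max_reject) {
        vstep <- deformation_field(v * (sc * stepscale), grid)
        cand <- compose_fields(field, vstep)
        if (params$sigma_field_mm > 0)
          cand$u <- smooth_field(cand$u, params$sigma_field_mm, grid$spacing)
        mw_c <- warp_volume(m, cand)$data
        ssd_c <- mean((f$data - mw_c)^2)
        if (ssd_c <= ssd && min_interior_jacobian(cand) > 0) {
          accepted <- TRUE
          field <- cand; mw <- mw_c
          improve <- (ssd - ssd_c) / max(ssd, 1e-12)
          ssd <- ssd_c
          trace_ <- c(trace_, ssd)
          consec_rej <- 0L
          stepscale <- min(1, stepscale * 2)
          it_done <- it_done + 1L
          if (improve < params$tol) { it_done <- it; break }
        } else {
          nrej <- nrej + 1L; consec_rej <- consec_rej + 1L
          stepscale <- stepscale / 2
        }
      }
      if (!accepted) {
        # rejection cap hit: abandon this level with diagnostics; typical
        # when a level is already at its attainable SSD floor (finer levels
        # still run and usually accept)
        break
      }
      if (accepted && length(trace_) >= 2 &&
          (trace_[length(trace_) - 1] - ssd) / max(trace_[1], 1e-12) <
            params$tol) break
    }
    meta$iterations <- c(meta$iterations, it_done)
    meta$ssd_trace[[l]] <- trace_
    meta$rejected <- c(meta$rejected, nrej)
    meta$level_aborted <- c(meta$level_aborted, consec_rej >= params$max_reject)
  }
  meta$converged <- !meta$level_aborted[length(meta$level_aborted)]
  meta$final_ssd <- ssd
  meta$min_jacobian <- min_interior_jacobian(field)
  field$meta <- meta
  field
}
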