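# Voxel-wise group inference on Jacobian determinant maps: pooled-variance
# two-sample t-statistics, exhaustive (or Monte-Carlo) permutation p-values,
# Benjamini-Hochberg FDR masking and expansion/atrophy direction maps.

# pooled-variance two-sample t for a data matrix X (n subjects x v voxels)
# and a logical vector selecting group A; zero-variance voxels get t = 0.
pooled_t_matrix <- function(X, selA) {
  nA <- sum(selA); nB <- sum(!selA); n <- nA + nB
  sA <- colSums(X[selA, , drop = FALSE])
  sB <- colSums(X[!selA, , drop = FALSE])
  qA <- colSums(X[selA, , drop = FALSE]^2)
  qB <- colSums(X[!selA, , drop = FALSE]^2)
  sp2 <- pmax(((qA - sA^2 / nA) + (qB - sB^2 / nB)) / (n - 2), 0)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (sA / nA - sB / nB) / se
  t[!is.finite(t)] <- 0
  t[constant_columns(X)] <- 0   # guard against one-pass cancellation noise
  t
}

# columns whose subjects are all tied (exactly)
constant_columns <- function(X) {
  colSums(X != matrix(X[1, ], nrow(X), ncol(X), byrow = TRUE)) == 0
}

# all-relabelings indicator matrix (choose(n, nA) x n), observed row first
relabel_matrix <- function(n, nA, observed_first = TRUE) {
  combs <- utils::combn(n, nA)
  C <- matrix(0, ncol(combs), n)
  C[cbind(rep(seq_len(ncol(combs)), each = nA), as.vector(combs))] <- 1
  if (observed_first) {
    obs <- which(apply(C, 1, function(r) all(which(r == 1) == seq_len(nA))))
    C <- C[c(obs, setdiff(seq_len(nrow(C)), obs)), , drop = FALSE]
  }
  C
}

#' Exhaustive / Monte-Carlo permutation two-sample t-test over columns
#'
#' The workhorse behind the voxel-wise TBM inference, exposed directly so
#' that large simulations can run on plain matrices. Subjects are rows,
#' tests (voxels) are columns. If the number of distinct relabelings
#' `choose(n, nA)` does not exceed `exhaustive_cap`, all relabelings are
#' enumerated and `p = #{|t*| >= |t|} / total` (the observed labeling is one
#' of them, so `p >= 1/total`); otherwise `m` random relabelings are drawn
#' and the `(b+1)/(m+1)` estimator is used.
#'
#' @param X numeric matrix, subjects x tests
#' @param group factor/vector with exactly two levels; the FIRST level (in
#'   factor order) is group A whose rows must come first for the observed
#'   labeling to be row one
#' @param exhaustive_cap maximum number of relabelings enumerated exactly
#'   (default 10000)
#' @param n_mc Monte-Carlo draws when exhaustive enumeration is infeasible
#' @param seed seed for the Monte-Carlo branch (ignored when exhaustive)
#' @return list: `t` observed t per column, `p` permutation p per column,
#'   `n_perm` relabelings used, `exact` TRUE if exhaustive,
#'   `zero_variance` count of all-tied columns (reported, t forced to 0)
#' @export
perm_ttest_matrix <- function(X, group, exhaustive_cap = 10000,
                              n_mc = 2000, seed = 1L) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("perm_ttest_matrix: need exactly two groups")
  selA <- group == levels(group)[1]
  nA <- sum(selA); nB <- sum(!selA); n <- nA + nB
  if (nA < 2 || nB < 2)
    stop("perm_ttest_matrix: need >= 2 subjects per group")
  # reorder rows so group A is first; relabelings then permute rows directly
  X <- rbind(X[selA, , drop = FALSE], X[!selA, , drop = FALSE])
  const <- constant_columns(X)
  t_obs <- pooled_t_matrix(X, c(rep(TRUE, nA), rep(FALSE, nB)))
  zero_var <- sum(const)
  n_all <- choose(n, nA)
  Xsq <- X^2
  tot <- colSums(X); totq <- colSums(Xsq)
  t_from_C <- function(C) {
    sA <- C %*% X; qA <- C %*% Xsq
    sB <- matrix(tot, nrow(C), ncol(X), byrow = TRUE) - sA
    qB <- matrix(totq, nrow(C), ncol(X), byrow = TRUE) - qA
    sp2 <- pmax(((qA - sA^2 / nA) + (qB - sB^2 / nB)) / (n - 2), 0)
    tt <- (sA / nA - sB / nB) / sqrt(sp2 * (1 / nA + 1 / nB))
    tt[!is.finite(tt)] <- 0
    tt
  }
  if (n_all <= exhaustive_cap) {
    C <- relabel_matrix(n, nA)
    T_ <- t_from_C(C)
    thr <- matrix(abs(t_obs), nrow(T_), ncol(T_), byrow = TRUE)
    p <- colSums(abs(T_) >= thr - 1e-10) / n_all
    p[const] <- 1
    list(t = t_obs, p = p, n_perm = n_all, exact = TRUE,
         zero_variance = zero_var)
  } else {
    C <- with_local_seed(seed, {
      t(vapply(seq_len(n_mc), function(i) {
        sel <- sample.int(n, nA)
        r <- numeric(n); r[sel] <- 1; r
      }, numeric(n)))
    })
    T_ <- t_from_C(C)
    thr <- matrix(abs(t_obs), nrow(T_), ncol(T_), byrow = TRUE)
    b <- colSums(abs(T_) >= thr - 1e-10)
    p <- (b + 1) / (n_mc + 1)
    p[const] <- 1
    list(t = t_obs, p = p, n_perm = n_mc, exact = FALSE,
         zero_variance = zero_var)
  }
}

# stack masked voxels of a list of jacobian image volumes into a matrix
jacobian_matrix <- function(maps, mask, log_transform = TRUE) {
  v <- which(mask)
  X <- t(vapply(maps, function(m) {
    d <- if (inherits(m, "image_volume")) m$data else m
    d[v]
  }, numeric(length(v))))
  if (log_transform) {
    if (any(X <= 0))
      stop("jacobian maps must be positive inside the mask for the log ",
           "transform")
    X <- log(X)
  }
  X
}

#' Voxel-wise two-sample t-map on Jacobian maps
#'
#' Pooled-variance two-sample t at each masked voxel, on log-transformed
#' determinants by default (log makes expansion and contraction symmetric).
#'
#' @param group_a,group_b lists of [image_volume()] Jacobian maps (>= 2 each)
#' @param mask logical array selecting brain voxels
#' @param log_transform test log-determinants (default TRUE)
#' @return an [image_volume()] t-map (0 outside the mask)
#' @export
voxelwise_t <- function(group_a, group_b, mask, log_transform = TRUE) {
  grid <- group_a[[1]]$grid
  X <- jacobian_matrix(c(group_a, group_b), mask, log_transform)
  t_ <- pooled_t_matrix(X, c(rep(TRUE, length(group_a)),
                             rep(FALSE, length(group_b))))
  out <- array(0, dim = grid$shape)
  out[which(mask)] <- t_
  image_volume(out, grid)
}

#' Voxel-wise permutation p-map
#'
#' @param maps list of [image_volume()] Jacobian maps, all subjects
#' @param groups two-level factor/vector of group labels, aligned with `maps`
#' @param mask logical array of brain voxels
#' @param log_transform test log-determinants (default TRUE)
#' @param ... passed to [perm_ttest_matrix()] (`exhaustive_cap`, `n_mc`,
#'   `seed`)
#' @return an [image_volume()] p-map (1 outside the mask); attributes
#'   `n_perm` and `exact` document the permutation scheme
#' @export
permutation_p <- function(maps, groups, mask, log_transform = TRUE, ...) {
  grid <- maps[[1]]$grid
  X <- jacobian_matrix(maps, mask, log_transform)
  res <- perm_ttest_matrix(X, groups, ...)
  out <- array(1, dim = grid$shape)
  out[which(mask)] <- res$p
  pm <- image_volume(out, grid)
  attr(pm, "n_perm") <- res$n_perm
  attr(pm, "exact") <- res$exact
  pm
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure over the masked p-values: reject all `p <= p_(k)` with
#' `k = max{ i : p_(i) <= i q / m }`.
#'
#' @param p numeric vector of p-values, or an [image_volume()] p-map
#' @param q FDR level (default 0.05)
#' @param mask logical array restricting the family when `p` is a map
#' @return logical vector (or array, for a map input) of rejections
#' @export
fdr_mask <- function(p, q = 0.05, mask = NULL) {
  if (inherits(p, "image_volume")) {
    stopifnot(!is.null(mask))
    v <- which(mask)
    rej <- fdr_mask(p$data[v], q)
    out <- array(FALSE, dim = p$grid$shape)
    out[v[rej]] <- TRUE
    return(out)
  }
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

#' Direction (expansion/atrophy) map
#'
#' Sign of the mean log-determinant difference (group A minus group B) at
#' each masked voxel: +1 expansion, -1 atrophy, 0 equal.
#'
#' @inheritParams voxelwise_t
#' @return an [image_volume()] of {-1, 0, +1}
#' @export
direction_map <- function(group_a, group_b, mask, log_transform = TRUE) {
  grid <- group_a[[1]]$grid
  X <- jacobian_matrix(c(group_a, group_b), mask, log_transform)
  selA <- c(rep(TRUE, length(group_a)), rep(FALSE, length(group_b)))
  d <- colMeans(X[selA, , drop = FALSE]) - colMeans(X[!selA, , drop = FALSE])
  out <- array(0, dim = grid$shape)
  out[which(mask)] <- sign(d)
  image_volume(out, grid)
}

#' Full voxel-wise TBM inference
#'
#' Computes the t-map, the permutation p-map (exhaustive whenever feasible),
#' the direction map, the uncorrected voxel-threshold mask and the
#' Benjamini-Hochberg FDR mask for a two-group contrast of Jacobian maps.
#'
#' @param maps list of [image_volume()] Jacobian maps
#' @param groups two-level group vector aligned with `maps`; the first level
#'   is taken as the contrast's left side (direction = first minus second)
#' @param mask logical brain mask array
#' @param q FDR level (default 0.05)
#' @param voxel_p uncorrected voxel-wise threshold reported alongside
#'   (default 0.01)
#' @param log_transform test log-determinants (default TRUE)
#' @param ... passed to [perm_ttest_matrix()]
#' @return list of class `voxelwise_result`: `t_map`, `p_map`,
#'   `direction`, `fdr_mask`, `voxel_mask`, `q`, `voxel_p`, `n_perm`,
#'   `exact`
#' @export
tbm_voxelwise <- function(maps, groups, mask, q = 0.05, voxel_p = 0.01,
                          log_transform = TRUE, ...) {
  groups <- as.factor(groups)
  ga <- maps[groups == levels(groups)[1]]
  gb <- maps[groups == levels(groups)[2]]
  t_map <- voxelwise_t(ga, gb, mask, log_transform)
  p_map <- permutation_p(maps, groups, mask, log_transform, ...)
  dirm <- direction_map(ga, gb, mask, log_transform)
  fmask <- fdr_mask(p_map, q, mask)
  vmask <- p_map$data < voxel_p & mask
  structure(list(t_map = t_map, p_map = p_map, direction = dirm,
                 fdr_mask = fmask, voxel_mask = vmask, q = q,
                 voxel_p = voxel_p, n_perm = attr(p_map, "n_perm"),
                 exact = attr(p_map, "exact")),
            class = "voxelwise_result")
}

#' Brain mask of a label volume for TBM statistics
#'
#' Union of all brain labels, eroded by one voxel (6-neighbourhood) to keep
#' border Jacobian artefacts out of the statistics.
#'
#' @param labels a [label_volume()]
#' @param erode erosion steps (default 1)
#' @return logical array
#' @export
brain_mask <- function(labels, erode = 1) {
  ids <- unname(labels$dictionary[brain_label_names()])
  m <- array(labels$labels %in% ids, dim = labels$grid$shape)
  for (e in seq_len(erode)) {
    m <- m &
      shift_axis(m, 1, 1L) & shift_axis(m, 1, -1L) &
      shift_axis(m, 2, 1L) & shift_axis(m, 2, -1L) &
      shift_axis(m, 3, 1L) & shift_axis(m, 3, -1L)
  }
  m
}
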