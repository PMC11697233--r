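# 3D fiber/vessel orientation estimation (windowed weighted vector
# summation over a multi-Otsu foreground mask) and directional-variance
# statistics.
#
# Angle conventions, all in degrees on [0, 180): theta = azimuth of the
# xy-projection vs the x axis; beta = angle of the zx-projection vs the
# x axis; gamma = angle of the yz-projection vs the -y axis; phi = polar
# angle from the depth (z) axis, related to beta/gamma through
# tan^2 phi = 1/tan^2 beta + 1/tan^2 gamma.

#' Multi-level Otsu thresholds
#'
#' Maximizes the between-class variance over `n_levels` classes by dynamic
#' programming on a 256-bin histogram (the classical multi-Otsu
#' criterion).
#'
#' @param values numeric vector (or array) of intensities.
#' @param n_levels number of classes (default 6, i.e. 5 thresholds).
#' @param n_bins histogram resolution (default 256).
#' @return numeric vector of `n_levels - 1` threshold values (ascending).
#' @export
otsu_thresholds <- function(values, n_levels = 6, n_bins = 256) {
  v <- as.numeric(values)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant input: thresholds undefined")
  bin <- pmin(pmax(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mu <- p * (seq_len(n_bins) - 0.5)
  P <- c(0, cumsum(p)); Mu <- c(0, cumsum(mu))
  # score of one class spanning bins a..b: w * mean^2 = (Mu_b-Mu_{a-1})^2/(P..)
  cls <- function(a, b) {
    w <- P[b + 1] - P[a]
    if (w <= 0) return(0)
    (Mu[b + 1] - Mu[a])^2 / w
  }
  # best[k, b]: max score splitting bins 1..b into k classes
  best <- matrix(-Inf, n_levels, n_bins)
  argt <- array(0L, c(n_levels, n_bins))
  for (b in seq_len(n_bins)) best[1, b] <- cls(1, b)
  for (k in 2:n_levels) {
    for (b in k:n_bins) {
      sc <- vapply((k - 1):(b - 1), function(t) best[k - 1, t] + cls(t + 1, b),
                   numeric(1))
      j <- which.max(sc)
      best[k, b] <- sc[j]
      argt[k, b] <- ((k - 1):(b - 1))[j]
    }
  }
  cuts <- integer(n_levels - 1)
  b <- n_bins
  for (k in n_levels:2) {
    cuts[k - 1] <- argt[k, b]
    b <- argt[k, b]
  }
  rng[1] + cuts / n_bins * diff(rng)
}

#' Segment fiber/vessel foreground by multi-level Otsu thresholding
#'
#' Applies `n_levels`-class Otsu thresholding; the lowest class is treated
#' as background noise and everything above the first threshold as signal.
#'
#' @param volume a non-constant [volume3d()].
#' @param n_levels Otsu classes (default 6).
#' @return logical array, `TRUE` at fiber voxels.
#' @export
segment_fibers <- function(volume, n_levels = 6) {
  a <- vol_data(volume)
  thr <- otsu_thresholds(a, n_levels = n_levels)
  m <- a > thr[1]
  dim(m) <- dim(a)
  m
}

#' Orientation angles of 3D direction vectors
#'
#' Converts unit (or unnormalized) direction vectors with components
#' (x, y, z) to the four reporting angles in degrees on [0, 180).
#'
#' @param v numeric matrix, one row per vector, columns (x, y, z); a
#'   length-3 vector is accepted.
#' @return data.frame with columns theta, beta, gamma, phi (degrees).
#' @export
direction_angles <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, 1)
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  deg <- function(a) (a * 180 / pi) %% 180
  theta <- deg(atan2(y, x))
  beta <- deg(atan2(z, x))
  gamma <- deg(atan2(z, -y))
  phi <- atan2(sqrt(x^2 + y^2), z) * 180 / pi   # already in [0, 180]
  phi <- ifelse(phi >= 180, 0, phi)
  data.frame(theta = theta, beta = beta, gamma = gamma, phi = phi)
}

#' Construct an orientation field from explicit direction vectors
#'
#' Mainly for synthetic experiments: wraps per-voxel directions (no
#' spatial layout needed) as an `orientation_field` usable by
#' [directional_variance()].
#'
#' @param v matrix of directions, one row per fiber voxel, columns
#'   (x, y, z).
#' @return an `orientation_field`.
#' @export
orientation_field_from_vectors <- function(v) {
  ang <- direction_angles(v)
  structure(list(theta = ang$theta, beta = ang$beta, gamma = ang$gamma,
                 phi = ang$phi, mask = rep(TRUE, nrow(ang)),
                 window_n = NA_integer_, dim = NULL),
            class = "orientation_field")
}

# canonical deduplicated lattice directions reaching the window shell
window_directions <- function(h) {
  g <- expand.grid(dz = -h:h, dy = -h:h, dx = -h:h)
  g <- g[pmax(abs(g$dz), abs(g$dy), abs(g$dx)) == h, ]
  d <- as.matrix(g)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  red <- t(apply(d, 1, function(r) {
    gg <- Reduce(gcd2, abs(r[r != 0]))
    r / gg
  }))
  # canonical sign: first nonzero of (dz, dy, dx) positive
  flip <- red[, 1] < 0 | (red[, 1] == 0 & red[, 2] < 0) |
    (red[, 1] == 0 & red[, 2] == 0 & red[, 3] < 0)
  red[flip, ] <- -red[flip, ]
  unique(red)
}

#' Estimate per-voxel 3D fiber orientation by weighted vector summation
#'
#' For every foreground voxel, all discrete line directions through the
#' center of an n x n x n window are evaluated; each line is weighted by
#' its contiguous length inside the mask divided by (1 + the normalized
#' intensity variance along it), and the direction of the weighted vector
#' sum (directions sign-aligned to the dominant line) is the voxel's
#' orientation. The window should span roughly two to three fiber
#' diameters.
#'
#' @param volume intensity [volume3d()].
#' @param mask logical foreground mask; computed by [segment_fibers()]
#'   when omitted.
#' @param window_n odd window size >= 3.
#' @return an `orientation_field`: arrays theta/beta/gamma/phi (degrees,
#'   `NA` outside the mask), the mask, and the window size.
#' @export
estimate_orientation <- function(volume, mask = NULL, window_n = 9) {
  a <- vol_data(volume)
  d <- dim(a)
  if (window_n < 3 || window_n %% 2 != 1) stop("window_n must be odd, >= 3")
  if (is.null(mask)) mask <- segment_fibers(volume)
  if (!any(mask)) stop("empty mask")
  h <- (window_n - 1L) / 2L
  dirs <- window_directions(h)                     # D x 3, (dz, dy, dx)
  D <- nrow(dirs)
  # unit direction vectors in (x, y, z) order for angle reporting
  U <- cbind(dirs[, 3], dirs[, 2], dirs[, 1])
  U <- U / sqrt(rowSums(U^2))
  vox <- which(mask)
  K <- length(vox)
  pz <- ((vox - 1L) %% d[1]) + 1L
  py <- (((vox - 1L) %/% d[1]) %% d[2]) + 1L
  px <- ((vox - 1L) %/% (d[1] * d[2])) + 1L
  W <- matrix(0, K, D)
  S <- 2L * h + 1L
  ctr <- h + 1L
  for (di in seq_len(D)) {
    u <- dirs[di, ] / max(abs(dirs[di, ]))
    inm <- matrix(FALSE, K, S)
    ints <- matrix(NA_real_, K, S)
    for (s in 1:S) {
      st <- s - ctr
      zz <- pz + round(st * u[1]); yy <- py + round(st * u[2])
      xx <- px + round(st * u[3])
      ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
      idx <- (xx[ok] - 1L) * d[1] * d[2] + (yy[ok] - 1L) * d[1] + zz[ok]
      inm[ok, s] <- mask[idx]
      ints[ok, s] <- a[idx]
    }
    # contiguous in-mask run through the center sample
    len <- rep(1, K)
    run <- rep(TRUE, K)
    if (ctr < S) for (s in (ctr + 1L):S) {
      run <- run & inm[, s]; len <- len + run
    }
    run <- rep(TRUE, K)
    if (ctr > 1) for (s in (ctr - 1L):1L) {
      run <- run & inm[, s]; len <- len + run
    }
    mu <- rowMeans(ints, na.rm = TRUE)
    vr <- apply(ints, 1, stats::var, na.rm = TRUE)
    vr[is.na(vr)] <- 0
    nvar <- vr / pmax(mu, .Machine$double.eps)^2
    W[, di] <- len / (1 + nvar)
  }
  dmax <- max.col(W, ties.method = "first")
  # sign-align every direction to the voxel's dominant direction
  dots <- U %*% t(U)                                # D x D
  sgn <- sign(dots)
  sgn[sgn == 0] <- 1
  Vx <- rowSums(W * t(U[, 1] * t(sgn[dmax, , drop = FALSE])))
  Vy <- rowSums(W * t(U[, 2] * t(sgn[dmax, , drop = FALSE])))
  Vz <- rowSums(W * t(U[, 3] * t(sgn[dmax, , drop = FALSE])))
  nrm <- sqrt(Vx^2 + Vy^2 + Vz^2)
  keep <- nrm > 0
  ang <- direction_angles(cbind(Vx, Vy, Vz)[keep, , drop = FALSE])
  mk_arr <- function(vals) {
    out <- array(NA_real_, d)
    out[vox[keep]] <- vals
    out
  }
  mask_out <- array(FALSE, d)
  mask_out[vox[keep]] <- TRUE
  structure(list(theta = mk_arr(ang$theta), beta = mk_arr(ang$beta),
                 gamma = mk_arr(ang$gamma), phi = mk_arr(ang$phi),
                 mask = mask_out, window_n = window_n, dim = d),
            class = "orientation_field")
}

#' Directional variance of a 3D orientation field
#'
#' Summarizes orientation spread on [0, 1]: each fiber voxel contributes a
#' unit-norm 3-vector built from its doubled projection angles,
#' (f cos 2theta, f sin 2theta, SI) / sqrt(1 + f^2) with
#' f = sqrt(1/tan^2(2 beta) + 1/tan^2(2 gamma)) and SI = -sign(phi - 90)
#' (0 exactly at phi = 90, where the formula is singular); the directional
#' variance is one minus the norm of the mean vector. 0 means perfectly
#' parallel alignment, values near 1 isotropic disorder.
#'
#' @param field an `orientation_field`.
#' @param region_mask optional logical array/vector restricting the
#'   region of interest.
#' @return list with `dv`, fiber-voxel count `k`, and the mean components
#'   `c_bar`, `s_bar`, `z_bar`.
#' @export
directional_variance <- function(field, region_mask = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  sel <- !is.na(field$phi)
  if (!is.null(region_mask)) sel <- sel & region_mask
  k <- sum(sel)
  if (k < 1) stop("no fiber voxels in region")
  theta <- field$theta[sel]; beta <- field$beta[sel]
  gamma <- field$gamma[sel]; phi <- field$phi[sel]
  tan_deg <- function(x) {
    t <- tanpi(x / 180)
    t[is.nan(t)] <- Inf
    t
  }
  inv_tan2 <- function(x) {
    t <- tan_deg(x)
    out <- 1 / t^2
    out[is.infinite(t)] <- 0
    out
  }
  f <- sqrt(inv_tan2(2 * beta) + inv_tan2(2 * gamma))
  a <- ifelse(is.infinite(f), 1, f / sqrt(1 + f^2))
  b <- ifelse(is.infinite(f), 0, 1 / sqrt(1 + f^2))
  si <- -sign(phi - 90)
  c_bar <- mean(a * cospi(theta / 90))
  s_bar <- mean(a * sinpi(theta / 90))
  z_bar <- mean(b * si)
  dv <- 1 - sqrt(c_bar^2 + s_bar^2 + z_bar^2)
  list(dv = dv, k = k, c_bar = c_bar, s_bar = s_bar, z_bar = z_bar)
}
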