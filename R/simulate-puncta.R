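#' Simulate a two-channel 3D puncta stack
#'
#' Emulates a confocal stack of presynaptic ribbon-like (channel A) and
#' PSD-like (channel B) immunofluorescent puncta. Channel-A puncta are hard
#' spheres with log-normal volumes matching the requested mean and SD; a
#' Bernoulli(`pairing_fraction`) subset of them receives a channel-B partner
#' displaced by `pair_offset`, and the remaining B puncta are "orphans"
#' placed beyond the juxtaposition cutoff. Voxel intensities are a flat
#' baseline plus the punctum amplitude inside each sphere plus Gaussian
#' noise. The per-punctum ground truth (centers, analytic and rasterized
#' volumes, pairing flags) is returned alongside.
#'
#' @param n_ribbon Number of channel-A puncta.
#' @param pairing_fraction Probability that an A punctum has a juxtaposed B
#'   partner (0-1).
#' @param vol_a,vol_b Named `c(mean=, sd=)` of punctum volumes (um^3).
#' @param stack_um Stack extent (x, y, z) in um.
#' @param voxel_size Voxel size (x, y, z) in um.
#' @param pair_offset Center-to-center displacement of a paired B punctum
#'   (um); must stay below the downstream juxtaposition cutoff.
#' @param orphan_min_dist Minimal distance of orphan B puncta from any A
#'   center (um); must exceed the cutoff.
#' @param min_sep Minimal center separation of same-channel puncta (um).
#' @param amp_a,amp_b Punctum amplitudes (a.u.).
#' @param baseline Flat background level (a.u.).
#' @param noise_sd Voxel noise SD (a.u.).
#' @param max_retries Placement retries before giving up.
#' @param seed Integer seed.
#' @return Object of class `puncta_stack`: 3D arrays `channel_a`,
#'   `channel_b`, `voxel_size`, and `truth` (data.frame: channel, x, y, z,
#'   volume, volume_voxel, radius, paired, partner).
#' @export
simulate_puncta_stack <- function(n_ribbon = 22, pairing_fraction = 0.967,
                                  vol_a = c(mean = 0.16, sd = 0.09),
                                  vol_b = c(mean = 0.36, sd = 0.16),
                                  stack_um = c(12, 12, 6),
                                  voxel_size = c(0.1, 0.1, 0.2),
                                  pair_offset = 0.35,
                                  orphan_min_dist = 1.5,
                                  min_sep = 1.4,
                                  amp_a = 100, amp_b = 100,
                                  baseline = 10, noise_sd = 4,
                                  max_retries = 5000, seed = NULL) {
  stopifnot(pairing_fraction >= 0, pairing_fraction <= 1,
            vol_a["mean"] > 0, vol_b["mean"] > 0, all(voxel_size > 0))
  dm <- pmax(2L, round(stack_um / voxel_size))
  rlnorm_mv <- function(n, mean, sd) {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }
  r_of_v <- function(v) (3 * v / (4 * pi))^(1 / 3)
  with_seed(seed, {
    va <- rlnorm_mv(n_ribbon, vol_a["mean"], vol_a["sd"])
    ra <- r_of_v(va)
    margin <- max(ra) + pair_offset + 0.3
    place <- function(n, radii, avoid = NULL, min_d_avoid = 0) {
      centers <- matrix(NA_real_, n, 3)
      placed <- 0L; tries <- 0L
      while (placed < n) {
        if (tries > max_retries) {
          stop("puncta placement failed after maximum retries (stack too crowded)")
        }
        tries <- tries + 1L
        cand <- stats::runif(3, min = margin, max = stack_um - margin)
        ok <- TRUE
        if (placed > 0L) {
          dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
          ok <- all(dd >= min_sep)
        }
        if (ok && !is.null(avoid) && nrow(avoid) > 0L) {
          dd <- sqrt(colSums((t(avoid) - cand)^2))
          ok <- all(dd >= min_d_avoid)
        }
        if (ok) {
          placed <- placed + 1L
          centers[placed, ] <- cand
        }
      }
      centers
    }
    ca <- place(n_ribbon, ra)
    paired <- stats::runif(n_ribbon) < pairing_fraction
    n_pair <- sum(paired)
    vb <- rlnorm_mv(n_ribbon, vol_b["mean"], vol_b["sd"])
    rb <- r_of_v(vb)
    cb <- matrix(NA_real_, n_ribbon, 3)
    if (n_pair > 0L) {
      u <- matrix(stats::rnorm(3 * n_pair), n_pair, 3)
      u <- u / sqrt(rowSums(u^2))
      cb[paired, ] <- ca[paired, , drop = FALSE] + u * pair_offset
    }
    if (any(!paired)) {
      cb[!paired, ] <- place(sum(!paired), rb[!paired],
                             avoid = ca, min_d_avoid = orphan_min_dist)
    }
    rasterize <- function(centers, radii, amp) {
      arr <- array(0, dim = dm)
      counts <- integer(nrow(centers))
      for (i in seq_len(nrow(centers))) {
        lo <- pmax(1L, floor((centers[i, ] - radii[i]) / voxel_size))
        hi <- pmin(dm, ceiling((centers[i, ] + radii[i]) / voxel_size))
        xs <- (lo[1]:hi[1] - 0.5) * voxel_size[1] - centers[i, 1]
        ys <- (lo[2]:hi[2] - 0.5) * voxel_size[2] - centers[i, 2]
        zs <- (lo[3]:hi[3] - 0.5) * voxel_size[3] - centers[i, 3]
        d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
        inside <- d2 <= radii[i]^2
        counts[i] <- sum(inside)
        sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        sub[inside] <- sub[inside] + amp
        arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
      }
      list(arr = arr, counts = counts)
    }
    rast_a <- rasterize(ca, ra, amp_a)
    rast_b <- rasterize(cb, rb, amp_b)
    vox_vol <- prod(voxel_size)
    noise <- function(arr) {
      arr + baseline + array(stats::rnorm(length(arr), 0, noise_sd), dim = dm)
    }
    truth <- rbind(
      data.frame(channel = "a", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                 volume = va, volume_voxel = rast_a$counts * vox_vol,
                 radius = ra, paired = paired,
                 partner = ifelse(paired, seq_len(n_ribbon), NA_integer_)),
      data.frame(channel = "b", x = cb[, 1], y = cb[, 2], z = cb[, 3],
                 volume = vb, volume_voxel = rast_b$counts * vox_vol,
                 radius = rb, paired = paired,
                 partner = ifelse(paired, seq_len(n_ribbon), NA_integer_)))
    structure(list(channel_a = noise(rast_a$arr), channel_b = noise(rast_b$arr),
                   voxel_size = voxel_size, stack_um = stack_um,
                   truth = truth),
              class = "puncta_stack")
  })
}

#' @export
print.puncta_stack <- function(x, ...) {
  cat(sprintf("puncta_stack: %s voxels at (%s) um; %d A + %d B puncta\n",
              paste(dim(x$channel_a), collapse = "x"),
              paste(x$voxel_size, collapse = ", "),
              sum(x$truth$channel == "a"), sum(x$truth$channel == "b")))
  invisible(x)
}
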