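# Shared fixtures: channel models with the wild-type / knock-out whole-cell
# activation parameters used throughout the recovery tests.

wt_model <- function(g_max = 4, g_leak = 1) {
  channel_model(g_max = g_max, v_half = -29.4, k = 6.92, g_leak = g_leak)
}

ko_model <- function(g_max = 4, g_leak = 1) {
  channel_model(g_max = g_max, v_half = -26.6, k = 6.98, g_leak = g_leak)
}

az_model <- function(v_half = -30, k = 5.79) {
  channel_model(g_max = 0.5, v_half = v_half, k = k, g_leak = 0)
}

# small movie settings keep unit tests fast; geometry unchanged
quick_ramp <- function() make_ramp_pair()

# rasterize a hard sphere on a voxel grid; independent oracle for volumes
sphere_stack <- function(center, radius, voxel, dim_vox, amp = 100,
                         baseline = 10, noise_sd = 4, seed = 1) {
  xs <- (seq_len(dim_vox[1]) - 0.5) * voxel[1]
  ys <- (seq_len(dim_vox[2]) - 0.5) * voxel[2]
  zs <- (seq_len(dim_vox[3]) - 0.5) * voxel[3]
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  set.seed(seed)
  list(stack = baseline + (d2 <= radius^2) * amp +
         array(rnorm(prod(dim_vox), 0, noise_sd), dim_vox),
       voxel_count = sum(d2 <= radius^2))
}
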