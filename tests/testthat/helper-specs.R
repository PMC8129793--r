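# compact specs used across tests: a smaller canvas keeps the suite fast
small_cluster <- function(...) {
  cluster_spec(image_shape = c(120L, 120L), body_radius = 8,
               centroid_xy = c(24, 37), ...)
}

# a disk mask on an H x W pixel grid (radius/centre in pixels)
disk_mask <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# line_profile from raw vectors
profile_of <- function(x, y) {
  structure(data.frame(position_um = x, intensity = y),
            class = c("line_profile", "data.frame"))
}
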