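# Shared fixtures: materials and loss tables are deterministic, build once.

bgo_fix <- make_bgo()
bgo_tables_fix <- build_loss_tables(bgo_fix)

# dispersion with a constant refractive index over an arbitrary window
const_dispersion <- function(n = 2.15, e_lo = 1.5498, e_hi = 3.8745,
                             points = 25, absorption_mm = 3000) {
  structure(
    list(
      energy = seq(e_lo, e_hi, length.out = points),
      n = rep(n, points),
      absorption_mm = rep(absorption_mm, points)
    ),
    class = "cer_dispersion"
  )
}

# a synthetic rectilinear electron step with the columns emit_cherenkov()
# expects; constant beta by default so the local velocity is exact
synthetic_step <- function(beta_pre = 0.9, beta_post = beta_pre,
                           length = 0.1, dir = c(0, 0, 1),
                           pos = c(0, 0, 5), t0 = 0) {
  data.frame(
    pre_ke = NA_real_, post_ke = NA_real_, length = length,
    pre_x = pos[1], pre_y = pos[2], pre_z = pos[3],
    dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
    pre_time = t0, post_time = t0 + length / (beta_pre * 299.792458),
    pre_beta = beta_pre, post_beta = beta_post
  )
}

# a bare photon row for the tracer
synthetic_photon <- function(pos, dir, energy = 2.5, time = 0) {
  data.frame(
    x = pos[1], y = pos[2], z = pos[3], time = time, energy = energy,
    dir_x = dir[1], dir_y = dir[2], dir_z = dir[3]
  )
}
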