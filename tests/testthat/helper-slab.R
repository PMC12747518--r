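# Bilayer slab fixture: a clamped-base slab whose top film grows
# tangentially, with the growth/stiffness profile taken in the distance
# to the top surface only. Used for buckling-threshold and wavelength
# checks. Returns the detrended top-surface profile along the centre
# line and a derivative-ratio wavelength estimate.
grow_slab <- function(g_target, h_film, mu_ratio = 10, nx = 48L,
                      ny = 2L, nz = 8L, lx = 4, ly = 0.3, lz = 0.5,
                      n_inc = 8L, max_iters = 4000L, seed = 5,
                      noise_amp = 2e-3) {
  vol <- make_slab_volume(nx, ny, nz, lx, ly, lz)
  cfg <- growth_config(g_g = g_target, mu_g = mu_ratio, mu_w = 1,
                       max_iters = max_iters, contact_stiffness = 0,
                       fixed_vertices = which(vol$vertices[, 3] < 1e-12))
  st <- gyralkit:::init_sim_state(vol, cfg)
  cz <- (vol$vertices[vol$tets[, 1], 3] + vol$vertices[vol$tets[, 2], 3] +
           vol$vertices[vol$tets[, 3], 3] +
           vol$vertices[vol$tets[, 4], 3]) / 4
  st$d_tet <- lz - cz
  st$n_tet <- matrix(rep(c(0, 0, 1), nrow(vol$tets)), ncol = 3,
                     byrow = TRUE)
  set.seed(seed)
  for (inc in seq_len(n_inc)) {
    gs <- 1 + (g_target - 1) * inc / n_inc
    st$profiles <- list(
      g = sigmoid_profile(st$d_tet, h_film, gs, 1),
      mu = sigmoid_profile(st$d_tet, h_film, mu_ratio, 1))
    noise <- matrix(stats::runif(length(vol$vertices), -noise_amp,
                                 noise_amp), ncol = 3)
    noise[st$fixed, ] <- 0
    st$current_vertices <- st$current_vertices + noise
    st <- relax(st, cfg)
  }
  top <- which(abs(vol$vertices[, 3] - lz) < 1e-9 &
                 abs(vol$vertices[, 2]) < 1e-9)
  ord <- order(vol$vertices[top, 1])
  x <- vol$vertices[top, 1][ord]
  z <- st$current_vertices[top, 3][ord]
  keep <- x > 0.5 & x < lx - 0.5
  res <- stats::residuals(stats::lm(z[keep] ~ stats::poly(x[keep], 2)))
  dz <- diff(res) / diff(x[keep])
  list(x = x[keep], profile = res, deflection = max(abs(res)),
       wavelength = 2 * pi * stats::sd(res) / stats::sd(dz),
       state = st, lz = lz)
}
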