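# Fixture builders shared across the suite. Trajectories encode a target
# scalar-stress waveform as a pure-shear tensor (sxy = sigma), whose
# invariant equals the shear magnitude, so SA oracles are closed-form.

pure_shear_traj <- function(t, sigma, traj_id = "t1",
                            x = 0, y = 0, z = NULL) {
  n <- length(t)
  tibble::tibble(
    traj_id = traj_id, t = t,
    x = rep_len(x, n), y = rep_len(y, n),
    z = if (is.null(z)) t else rep_len(z, n),
    sxx = 0, syy = 0, szz = 0,
    sxy = rep_len(sigma, n), sxz = 0, syz = 0
  )
}

random_symmetric <- function(scale = 10) {
  m <- matrix(stats::rnorm(9, sd = scale), 3L, 3L)
  (m + t(m)) / 2
}

random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_dec)
  q %*% diag(sign(diag(qr.R(qr_dec))))  # det +1, uniform on O(3) -> SO(3)
}

# Independent scalar-stress oracle: sqrt(J2) of the deviatoric tensor,
# computed elementwise rather than through the component formula.
j2_scalar_oracle <- function(m) {
  dev <- m - diag(sum(diag(m)) / 3, 3L)
  sqrt(0.5 * sum(dev * dev))
}

# Independent SA oracle: right-rectangle product-sum evaluated directly
# from a (t, sigma) series.
sa_oracle <- function(t, sigma) sum(sigma[-1] * diff(t))
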