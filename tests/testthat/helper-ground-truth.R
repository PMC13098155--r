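# shared fixtures: ground truths with controlled noise levels

# default ground truth with every CV forced to zero (degenerate draws)
zero_noise_gt <- function() {
  gt <- default_ground_truth()
  for (h in c("bean", "pea")) {
    gt[[h]]$cv <- lapply(gt[[h]]$cv, function(x) 0)
  }
  gt
}

# numerical-integration oracle for a spherical cap with base radius a and
# height h: sphere radius R = (a^2 + h^2) / (2h), volume by quadrature of
# the circular cross-section area from z = R - h to R
cap_volume_quadrature <- function(a, h) {
  R <- (a^2 + h^2) / (2 * h)
  stats::integrate(function(z) pi * (R^2 - z^2), lower = R - h, upper = R,
                   rel.tol = 1e-10)$value
}
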