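# Fixtures built in code: spherical point clouds and small geometric
# oracles used across the test files.

# Quasi-uniform points on a sphere (Fibonacci lattice), with inward
# normals by default (the internal-aspect picking convention).
sphere_cloud <- function(n, center = c(0, 0, 0), radius = 1,
                         normal_sign = -1, label = "fixture") {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  u <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  oriented_cloud(sweep(radius * u, 2, center, "+"), normal_sign * u, label)
}

# Brute-force tangent direction: scan candidate direction angles for the
# line through p at distance rho from the circle centre, on the requested
# side, and return the best direction. Independent of the closed-form
# construction it checks.
brute_force_tangent <- function(p, circle, side, n_scan = 1e6) {
  th <- seq(0, 2 * pi, length.out = n_scan)
  dirs <- cbind(cos(th), sin(th))
  rel <- circle$center - p
  crossz <- dirs[, 1] * rel[2] - dirs[, 2] * rel[1]
  ok <- if (side == "left") crossz > 0 else crossz < 0
  # keep directions pointing towards the circle
  ok <- ok & (dirs %*% rel) > 0
  resid <- abs(abs(crossz) - circle$radius)
  resid[!ok] <- Inf
  dirs[which.min(resid), ]
}

ref_params <- function(...) shoulder_params(...)
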