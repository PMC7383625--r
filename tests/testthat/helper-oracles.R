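# Independent oracles used across the suite. These deliberately re-derive
# each quantity with a different algorithm/code path than the package.

# Brute-force cap score: explicit per-residue lookup and accumulation.
brute_force_cap_score <- function(residues, scale_values, window = 45L) {
  letters <- strsplit(residues, "")[[1]][seq_len(window)]
  h <- 0
  for (ch in letters) {
    stopifnot(ch %in% names(scale_values))
    h <- h + scale_values[[ch]]
  }
  h
}

# Brute-force candidate selection: literal evaluation of the rule
# mean < H <= Q3 (type-7 quantile) over all records.
brute_force_selection <- function(ids, H) {
  m <- mean(H)
  q3 <- as.numeric(stats::quantile(H, 0.75, type = 7))
  ids[H > m & H <= q3]
}

# Closed-form SASA of sphere 1 (radius r1, probe w) partially buried by
# sphere 2 at centre distance d: full sphere minus the spherical cap cut off
# by the radical plane of the two expanded spheres.
two_sphere_sasa_closed_form <- function(r1, r2, d, w) {
  R1 <- r1 + w
  R2 <- r2 + w
  if (d >= R1 + R2) {
    return(4 * pi * R1^2)
  }
  # height of the buried cap on sphere 1
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Independent latitude/longitude grid integration of sphere 1's accessible
# area in the two-sphere geometry (area element R^2 cos(phi) dphi dtheta).
grid_sasa_sphere1 <- function(r1, r2, d, w, n_phi = 400L, n_theta = 800L) {
  R1 <- r1 + w
  R2 <- r2 + w
  phi <- seq(-pi / 2 + pi / (2 * n_phi), pi / 2 - pi / (2 * n_phi),
    length.out = n_phi
  )
  theta <- seq(0, 2 * pi - 2 * pi / n_theta, length.out = n_theta)
  dphi <- pi / n_phi
  dtheta <- 2 * pi / n_theta
  total <- 0
  for (p in phi) {
    x <- R1 * cos(p) * cos(theta)
    y <- R1 * cos(p) * sin(theta)
    z <- R1 * sin(p)
    outside <- (x - d)^2 + y^2 + z^2 >= R2^2
    total <- total + sum(outside) * R1^2 * cos(p) * dphi * dtheta
  }
  total
}

# Independent Pearson r via the raw-sums formula (different arithmetic path
# than the package's centered-covariance implementation).
pearson_raw_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Fixed-step RK4 reference integrator for the acyl-transfer mass balances,
# with the derivative re-derived here from the kinetic scheme. Enzyme decay
# is gated on the acid load exceeding the buffer capacity.
rk4_reference <- function(params, D0, A0, t_end, dt = 1e-3) {
  deriv <- function(y) {
    D <- y[1]; A <- y[2]; P <- y[3]; Ac <- y[4]; E <- y[5]
    ft <- params$kt_over_kh * A / (1 + params$kt_over_kh * A)
    vD <- params$k_cat_donor * E * D / (params$K_D + D)
    vP <- params$k_p * E * P / (params$K_P + P)
    dE <- if (Ac >= params$buffer_capacity) -params$k_inact * E else 0
    c(
      -vD,
      -ft * vD + (1 - ft) * vP,
      ft * vD - (1 - ft) * vP,
      (1 - ft) * (vD + vP),
      dE
    )
  }
  n_steps <- ceiling(t_end / dt)
  y <- c(D0, A0, 0, 0, params$E0)
  t <- 0
  out_t <- numeric(n_steps + 1)
  out_y <- matrix(0, n_steps + 1, 5)
  out_t[1] <- 0
  out_y[1, ] <- y
  for (k in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out_t[k + 1] <- t
    out_y[k + 1, ] <- y
  }
  data.frame(
    t = out_t, D = out_y[, 1], A = out_y[, 2], P = out_y[, 3],
    Ac = out_y[, 4], E = out_y[, 5]
  )
}

# Random protein sequence of given length (uniform over the 20 canonical
# residues); callers control the seed.
random_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}

write_pdb_tempfile <- function(text) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(text, tf)
  tf
}
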