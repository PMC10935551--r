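# Small hand-built webs and an independent brute-force integrator used as
# oracles across the suite.

group_row <- function(name, class, B, PB = 0, QB = 0, EE = 0,
                      direct = FALSE, fm = 1, tc = "low", comm = FALSE) {
  data.frame(name = name, group_class = class, B = B, PB = PB, QB = QB,
             EE = EE, direct_uptake = direct, muscle_fraction = fm,
             trophic_class = tc, commercial = comm,
             stringsAsFactors = FALSE)
}

# one producer with direct uptake, nothing else
single_producer_web <- function(B = 3, PB = 10, area = 1, depth = 10) {
  g <- group_row("producer", "producer", B = B, PB = PB, direct = TRUE)
  food_web(g, matrix(0, 1, 1), area = area, depth = depth)
}

# producer (B=100, PB=10, EE=0.5) grazed by one consumer (B=10, QB=50)
two_group_web <- function(grazer_qb = 50) {
  g <- rbind(
    group_row("producer", "producer", B = 100, PB = 10, EE = 0.5,
              direct = TRUE),
    group_row("grazer", "consumer", B = 10, PB = 5, QB = grazer_qb)
  )
  dc <- rbind(c(0, 0), c(1, 0))
  food_web(g, dc, area = 1, depth = 10)
}

# producer -> zooplankton -> fish, with the fish feeding half on each
mixed_three_group_web <- function() {
  g <- rbind(
    group_row("producer", "producer", B = 50, PB = 20, EE = 0.8,
              direct = TRUE),
    group_row("zooplankton", "consumer", B = 10, PB = 4, QB = 20, EE = 0.5),
    group_row("fish", "consumer", B = 2, PB = 1, QB = 5, fm = 0.5)
  )
  dc <- rbind(c(0, 0, 0),
              c(1, 0, 0),
              c(0.5, 0.5, 0))
  food_web(g, dc, area = 100, depth = 50)
}

# Independent small-step Euler oracle for the contaminant dynamic, written
# from the rate equations themselves (no calls into the package engine).
# The dynamic is linear, so the Euler iterate x_{k+1} = x_k + dt (F x_k + f)
# equals (I + dt M)^k on the augmented state (x, 1); the oracle computes
# that power by repeated squaring, which reproduces the plain Euler loop
# exactly while allowing dt small enough for a tight comparison. Pulse
# events split the integration into segments.
# state: cw (ug/l) and pools a (ug, whole area). events: data.frame(year,
# mass_t). Returns the state at t_end.
euler_tracer <- function(web, params, influx_t_yr, events, cw0, a0,
                         t_end, dt_max = 1e-3) {
  g <- web$groups
  n <- nrow(g)
  v <- web$area * 1e6 * web$depth * 1e3
  kg <- g$B * web$area * 1000
  q <- matrix(0, n, n)
  for (i in seq_len(n)) q[i, ] <- g$B[i] * g$QB[i] * web$diet[i, ]
  det <- which(g$group_class == "detritus")
  d <- if (params$detritus_routing) g$PB * (1 - g$EE) else rep(0, n)
  if (length(det)) d[det] <- 0
  e <- params$excretion
  alpha <- params$assimilation

  # assemble the rate matrix entry by entry from the equations
  f_mat <- matrix(0, n + 1, n + 1)
  f_mat[1 + seq_len(n), 1] <- params$uptake * kg / v
  f_mat[1, 1] <- -sum(params$uptake * kg) / v
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      f_mat[1 + i, 1 + j] <- f_mat[1 + i, 1 + j] + alpha * q[i, j] / g$B[j]
    }
    loss <- sum(q[, i]) / g$B[i] + e + d[i]
    f_mat[1 + i, 1 + i] <- f_mat[1 + i, 1 + i] - loss
    f_mat[1, 1 + i] <- e + (1 - alpha) * sum(q[, i]) / g$B[i]
    if (d[i] > 0) {
      if (length(det)) {
        f_mat[1 + det[1], 1 + i] <- f_mat[1 + det[1], 1 + i] + d[i]
      } else {
        f_mat[1, 1 + i] <- f_mat[1, 1 + i] + d[i]
      }
    }
  }
  forcing <- c(influx_t_yr * 1e12, rep(0, n))

  mat_pow <- function(m, k) {       # m^k by repeated squaring
    acc <- diag(nrow(m))
    while (k > 0) {
      if (k %% 2 == 1) acc <- acc %*% m
      m <- m %*% m
      k <- k %/% 2
    }
    acc
  }

  x <- c(cw0 * v, a0)
  breaks <- sort(unique(c(0, events$year[events$year < t_end], t_end)))
  for (s in seq_len(length(breaks) - 1)) {
    if (nrow(events)) {
      hit <- events$year == breaks[s]
      if (any(hit)) x[1] <- x[1] + sum(events$mass_t[hit]) * 1e12
    }
    seg <- breaks[s + 1] - breaks[s]
    nsteps <- 2^ceiling(log2(seg / dt_max))
    dt <- seg / nsteps
    step <- rbind(cbind(diag(n + 1) + dt * f_mat, dt * forcing),
                  c(rep(0, n + 1), 1))
    x <- (mat_pow(step, nsteps) %*% c(x, 1))[seq_len(n + 1)]
  }
  if (nrow(events)) {
    hit <- events$year == t_end
    if (any(hit)) x[1] <- x[1] + sum(events$mass_t[hit]) * 1e12
  }
  list(cw = x[1] / v, pools = x[-1])
}
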