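#' Simulation protocol for the Kuramoto model
#'
#' Bundles the run protocol: total time, transient discarded from analysis,
#' integrator step and output sampling interval. Defaults follow the
#' standard connectome-simulation protocol of total time 700 with a
#' transient of 300, sampled once per time unit, so every trajectory keeps
#' exactly 400 post-transient time points. `sample_dt` must be an integer
#' multiple of `dt`.
#'
#' @param t_total total simulated time (default 700).
#' @param t_transient initial transient excluded from the output
#'   (default 300).
#' @param dt fixed RK4 integration step (default 0.05).
#' @param sample_dt interval between retained samples (default 1).
#' @param seed RNG seed used when initial phases/frequencies are drawn.
#' @return list of class `kuramoto_config`.
#' @export
kuramoto_config <- function(t_total = 700, t_transient = 300, dt = 0.05,
                            sample_dt = 1, seed = NULL) {
  if (t_transient < 0 || t_transient >= t_total)
    stopf("need 0 <= t_transient < t_total")
  if (dt <= 0) stopf("dt must be positive")
  if (sample_dt < dt) stopf("sample_dt must be >= dt")
  ratio <- sample_dt / dt
  if (abs(ratio - round(ratio)) > 1e-8)
    stopf("sample_dt must be an integer multiple of dt")
  structure(list(t_total = t_total, t_transient = t_transient, dt = dt,
                 sample_dt = sample_dt, seed = seed),
            class = "kuramoto_config")
}

#' Kuramoto phase velocities
#'
#' Instantaneous right-hand side of the Kuramoto model on a network:
#' `dtheta_i/dt = omega_i + lambda * sum_j W_ij sin(theta_j - theta_i)`.
#'
#' @param theta phase vector (radians), length N.
#' @param conn a [connectome()].
#' @param omega internal angular frequency vector, length N.
#' @param lambda cortical coupling strength (scalar).
#' @return numeric vector of phase velocities.
#' @export
kuramoto_derivative <- function(theta, conn, omega, lambda) {
  assert_connectome(conn)
  if (length(theta) != conn$N || length(omega) != conn$N)
    stopf("theta and omega must have length N = %d", conn$N)
  s <- sin(theta); cc <- cos(theta)
  as.numeric(omega + lambda * (cc * (conn$W %*% s) - s * (conn$W %*% cc)))
}

#' Simulate one trial of the Kuramoto model
#'
#' Integrates the coupled phase oscillators with a fixed-step classical
#' Runge-Kutta (RK4) scheme and keeps the post-transient samples. When
#' `theta0`/`omega` are not supplied they are drawn (under `cfg$seed`) as
#' uniform initial phases on \[-pi, pi) and uniform internal frequencies on
#' \[0, 1), the standard random initial conditions for this model. Phases
#' are returned unwrapped (cumulative), which is what frequency analyses
#' need; phasor-based metrics wrap them implicitly.
#'
#' @param conn a [connectome()].
#' @param lambda cortical coupling strength.
#' @param omega optional frequency vector (length N).
#' @param theta0 optional initial phase vector (length N).
#' @param cfg a [kuramoto_config()].
#' @return object of class `kuramoto_trajectory`: list with `times`
#'   (sample times), `theta` (N x n_times unwrapped phase matrix), `omega`,
#'   `theta0`, `lambda` and `cfg`.
#' @examples
#' conn <- connectome(matrix(c(0, 1, 1, 0), 2))
#' traj <- simulate_kuramoto(conn, lambda = 0.15, omega = c(0.4, 0.6),
#'                           theta0 = c(0, 0),
#'                           cfg = kuramoto_config(t_total = 100,
#'                                                 t_transient = 50))
#' @export
simulate_kuramoto <- function(conn, lambda, omega = NULL, theta0 = NULL,
                              cfg = kuramoto_config()) {
  assert_connectome(conn)
  if (!inherits(cfg, "kuramoto_config")) stopf("cfg must be a kuramoto_config")
  n <- conn$N
  if (is.null(theta0) || is.null(omega)) {
    drawn <- with_seed(cfg$seed, list(theta0 = runif(n, -pi, pi),
                                      omega = runif(n)))
    theta0 <- theta0 %||% drawn$theta0
    omega <- omega %||% drawn$omega
  }
  if (length(theta0) != n || length(omega) != n)
    stopf("theta0 and omega must have length N = %d", n)
  theta <- kuramoto_rk4_cpp(conn$W, as.numeric(omega), as.numeric(theta0),
                            lambda, cfg$t_total, cfg$t_transient, cfg$dt,
                            cfg$sample_dt)
  times <- cfg$t_transient + cfg$sample_dt * seq_len(ncol(theta))
  rownames(theta) <- conn$labels
  structure(list(times = times, theta = theta, omega = as.numeric(omega),
                 theta0 = as.numeric(theta0), lambda = lambda, cfg = cfg),
            class = "kuramoto_trajectory")
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat(sprintf("<kuramoto_trajectory> %d nodes, %d samples, lambda = %g\n",
              nrow(x$theta), ncol(x$theta), x$lambda))
  invisible(x)
}

as_theta <- function(x) {
  if (inherits(x, "kuramoto_trajectory")) return(x$theta)
  if (is.matrix(x)) return(x)
  stopf("expected a kuramoto_trajectory or a node-by-time phase matrix")
}

#' Per-node mean field of neighbouring oscillators
#'
#' For each node k the neighbours' unit phasors are averaged,
#' `R_k exp(i phi_k) = (1/D_k) sum_j W_kj exp(i theta_j)`, giving the
#' centroid radius `R_k` (local phase coherence among the nodes k connects
#' to, which sets the strength with which the local field pulls node k) and
#' centroid phase `phi_k`. Isolated nodes (degree 0) get `NA`.
#'
#' @param theta_t phase vector at one time point, length N.
#' @param conn a [connectome()].
#' @return data.frame with columns `node`, `degree`, `R`, `phi`.
#' @export
mean_field <- function(theta_t, conn) {
  assert_connectome(conn)
  if (length(theta_t) != conn$N) stopf("theta_t must have length N")
  d <- rowSums(conn$W)
  z <- as.complex(conn$W %*% exp(1i * theta_t))
  z <- ifelse(d > 0, z / d, NA_complex_)
  data.frame(node = seq_len(conn$N), degree = as.integer(d),
             R = ifelse(d > 0, Mod(z), NA_real_),
             phi = ifelse(d > 0, Arg(z), NA_real_))
}

#' Write a trajectory to a TSV file
#'
#' Writes a time column followed by one phase column per node (radians,
#' unwrapped); the simulation protocol is echoed in `#`-prefixed header
#' comments.
#'
#' @param traj a [simulate_kuramoto()] trajectory.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "kuramoto_trajectory")) stopf("expected a trajectory")
  hdr <- c("# hubsync trajectory",
           sprintf("# lambda=%g t_total=%g t_transient=%g dt=%g sample_dt=%g",
                   traj$lambda, traj$cfg$t_total, traj$cfg$t_transient,
                   traj$cfg$dt, traj$cfg$sample_dt),
           sprintf("# omega=%s", paste(format(traj$omega, digits = 10),
                                       collapse = ",")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(time = traj$times, t(traj$theta), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
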