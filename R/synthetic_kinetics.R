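#' Configuration for the kinetic population simulator
#'
#' Describes a cell population evolving under the two-layer kinetic model
#' du/dt = alpha - beta u (nascent), ds/dt = beta u - gamma s (old), with
#' gene-wise switching from induction (alpha on) to repression (alpha = 0) at
#' `t_switch`, evaluated at each cell's true time drawn uniformly on
#' `[0, t_max]`.
#'
#' Default rate ranges give steady-state expectations of roughly 1-10 nascent
#' and 2-25 old molecules per cell, a realistic UMI-count regime in which
#' KNN-smoothed moments still carry a usable kinetic signal.
#'
#' @param n_genes,n_cells Population size.
#' @param alpha_range,beta_range,gamma_range Uniform sampling ranges for the
#'   per-gene transcription, transfer and degradation rates (all > 0).
#' @param t_switch_range Range of the per-gene switching time as a fraction of
#'   `t_max` (each endpoint in (0, 1)).
#' @param t_max Upper end of the true-time axis.
#' @param noise `"poisson"` or `"nb"` (negative binomial with variance
#'   `mu + mu^2 / nb_dispersion`).
#' @param nb_dispersion Dispersion theta for `noise = "nb"`.
#' @param one_sided_fraction Fraction of genes observed on essentially one
#'   kinetic branch only (their switch is placed at 0.02 or 0.98 of `t_max`).
#' @param seed Integer RNG seed.
#' @return A `kinetic_sim_config` list.
#' @export
kinetic_sim_config <- function(n_genes = 200L, n_cells = 500L,
                               alpha_range = c(1, 5),
                               beta_range = c(0.5, 2),
                               gamma_range = c(0.2, 1),
                               t_switch_range = c(0.3, 0.7),
                               t_max = 10,
                               noise = c("poisson", "nb"),
                               nb_dispersion = 10,
                               one_sided_fraction = 0.2,
                               seed = 1L) {
  assert_count(n_genes, "n_genes"); assert_count(n_cells, "n_cells")
  noise <- match.arg(noise)
  for (r in list(alpha_range, beta_range, gamma_range))
    if (length(r) != 2L || any(r <= 0) || r[2] < r[1])
      stop("rate ranges must be positive and increasing", call. = FALSE)
  if (any(t_switch_range <= 0) || any(t_switch_range >= 1))
    stop("'t_switch_range' endpoints must lie in (0, 1)", call. = FALSE)
  assert_pos(t_max, "t_max"); assert_pos(nb_dispersion, "nb_dispersion")
  assert_prob(one_sided_fraction, "one_sided_fraction")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 alpha_range = alpha_range, beta_range = beta_range,
                 gamma_range = gamma_range, t_switch_range = t_switch_range,
                 t_max = t_max, noise = noise, nb_dispersion = nb_dispersion,
                 one_sided_fraction = one_sided_fraction,
                 seed = as.integer(seed)),
            class = "kinetic_sim_config")
}

# Independent closed-form evaluation of the two-layer ODE used ONLY by the
# simulator, deliberately kept separate from solve_kinetics() so that fitter
# tests against simulated truth are not circular.
sim_ode_expectation <- function(alpha, beta, gamma, t_switch, t) {
  tt <- pmin(t, t_switch)
  eb <- exp(-beta * tt); eg <- exp(-gamma * tt)
  u <- (alpha / beta) * (1 - eb)
  s <- if (abs(gamma - beta) < 1e-8 * max(gamma, beta)) {
    (alpha / gamma) * (1 - eg) - alpha * tt * eg
  } else {
    (alpha / gamma) * (1 - eg) + alpha * (eg - eb) / (gamma - beta)
  }
  late <- t > t_switch
  if (any(late)) {
    d <- t[late] - t_switch
    u0 <- (alpha / beta) * (1 - exp(-beta * t_switch))
    s0 <- if (abs(gamma - beta) < 1e-8 * max(gamma, beta)) {
      (alpha / gamma) * (1 - exp(-gamma * t_switch)) -
        alpha * t_switch * exp(-gamma * t_switch)
    } else {
      (alpha / gamma) * (1 - exp(-gamma * t_switch)) +
        alpha * (exp(-gamma * t_switch) - exp(-beta * t_switch)) / (gamma - beta)
    }
    ebd <- exp(-beta * d); egd <- exp(-gamma * d)
    u[late] <- u0 * ebd
    s[late] <- if (abs(gamma - beta) < 1e-8 * max(gamma, beta)) {
      s0 * egd + beta * u0 * d * egd
    } else {
      s0 * egd + (beta * u0 / (gamma - beta)) * (ebd - egd)
    }
  }
  list(u = u, s = s)
}

#' Simulate a kinetic cell population with layered counts and ground truth
#'
#' @param cfg A [kinetic_sim_config()].
#' @return A list of class `kinetic_sim` with a [layered_counts()] matrix
#'   (`layers$nascent`, `layers$old`, `layers$total`), per-cell true times
#'   `truth_time`, and a per-gene `truth_params` table (`gene_id`, `alpha`,
#'   `beta`, `gamma`, `t_switch`, `one_sided`).
#' @export
simulate_kinetic_population <- function(cfg) {
  stopifnot(inherits(cfg, "kinetic_sim_config"))
  with_local_seed(cfg$seed, {
    G <- cfg$n_genes; C <- cfg$n_cells
    gene_id <- sprintf("G%04d", seq_len(G))
    barcode <- sprintf("BC%04d", seq_len(C))
    alpha <- runif(G, cfg$alpha_range[1], cfg$alpha_range[2])
    beta <- runif(G, cfg$beta_range[1], cfg$beta_range[2])
    gamma <- runif(G, cfg$gamma_range[1], cfg$gamma_range[2])
    t_sw <- runif(G, cfg$t_switch_range[1], cfg$t_switch_range[2]) * cfg$t_max
    one_sided <- runif(G) < cfg$one_sided_fraction
    if (any(one_sided)) {
      idx <- which(one_sided)
      # alternate repression-only / induction-only
      t_sw[idx] <- ifelse(seq_along(idx) %% 2L == 1L,
                          0.02 * cfg$t_max, 0.98 * cfg$t_max)
    }
    t_true <- runif(C, 0, cfg$t_max)

    eu <- matrix(0, G, C); es <- matrix(0, G, C)
    for (g in seq_len(G)) {
      e <- sim_ode_expectation(alpha[g], beta[g], gamma[g], t_sw[g], t_true)
      eu[g, ] <- e$u; es[g, ] <- e$s
    }
    draw <- function(mu) {
      n <- length(mu)
      if (cfg$noise == "poisson") rpois(n, mu)
      else rnbinom(n, size = cfg$nb_dispersion, mu = mu)
    }
    nas <- matrix(draw(eu), G, C); old <- matrix(draw(es), G, C)
    dimnames(nas) <- dimnames(old) <- list(gene_id, barcode)
    lcm <- layered_counts(nascent = as(as(nas, "CsparseMatrix"), "dMatrix"),
                          old = as(as(old, "CsparseMatrix"), "dMatrix"))
    structure(list(
      counts = lcm,
      truth_time = stats::setNames(t_true, barcode),
      truth_params = data.table::data.table(
        gene_id = gene_id, alpha = alpha, beta = beta, gamma = gamma,
        t_switch = t_sw, one_sided = one_sided),
      expectation = list(nascent = eu, old = es),
      config = cfg), class = "kinetic_sim")
  })
}
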