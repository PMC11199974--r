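#' Evaluate an expression under a local, explicit RNG seed
#'
#' Saves and restores the global RNG state so generators never leak random
#' state into the caller's session.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Regular hexagon of circumradius 0.14 nm in the xy-plane, atom names of a
# Phe ring so detection runs on realistic topology, not a bypass.
.phe_ring_positions <- function(radius = 0.14) {
  ang <- 2 * pi * (0:5) / 6
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

#' Generate a two-state (bound/unbound) synthetic contact trajectory
#'
#' Emulates the on/off dwell dynamics of a glycan C-H hydrogen over an
#' aromatic ring: a two-state Markov chain with stationary bound-state
#' occupancy `occupancy` and dwell persistence `dwell_persistence`
#' (probability of remaining in the current state beyond the memoryless
#' baseline; 0 gives i.i.d. frames). Each frame holds a Phe-like ring
#' (regular hexagon, circumradius 0.14 nm, centered at the origin) and a
#' NAG-like glycan residue whose H1 sits at the state's distance from the
#' ring center along the ring normal, plus isotropic Gaussian positional
#' noise; C1 tracks H1 at 0.109 nm further along the normal.
#'
#' The expected mean contact is computed by numerically averaging the
#' switching function over the noise distribution (1e5 draws from a seeded
#' child stream), so it accounts for noise-induced bias, not just the
#' noise-free distances.
#'
#' @param n_frames number of frames
#' @param occupancy stationary probability of the bound state, in [0, 1]
#' @param bound_distance,unbound_distance H-to-ring-center distances (nm)
#' @param positional_noise_sd isotropic Gaussian noise SD per coordinate (nm)
#' @param dwell_persistence probability weight on staying, in [0, 1)
#' @param seed integer seed (all randomness derives from it)
#' @param params [contact_params()] used for the expected-contact ground truth
#' @return list with `trajectory` (a `glyco_trajectory`), `states`
#'   (per-frame 1 = bound), `expected_mean_contact`, `expected_c_bound`,
#'   `expected_c_unbound`
#' @export
generate_two_state_trajectory <- function(n_frames = 2000L, occupancy = 0.7,
                                          bound_distance = 0.3,
                                          unbound_distance = 1.0,
                                          positional_noise_sd = 0.02,
                                          dwell_persistence = 0.9,
                                          seed = 1L,
                                          params = contact_params()) {
  stopifnot(occupancy >= 0, occupancy <= 1,
            bound_distance > 0, unbound_distance > 0,
            positional_noise_sd >= 0,
            dwell_persistence >= 0, dwell_persistence < 1)
  p <- occupancy; d <- dwell_persistence
  # leave-state probabilities scaled so the stationary law is exactly p
  q_bu <- (1 - d) * (1 - p)   # bound -> unbound
  q_ub <- (1 - d) * p         # unbound -> bound
  ring_xy <- .phe_ring_positions()

  gen <- with_preserved_seed(seed, {
    states <- integer(n_frames)
    states[1L] <- stats::rbinom(1L, 1L, p)
    if (n_frames > 1L) {
      u <- stats::runif(n_frames - 1L)
      for (f in 2L:n_frames) {
        states[f] <- if (states[f - 1L] == 1L) {
          if (u[f - 1L] < q_bu) 0L else 1L
        } else {
          if (u[f - 1L] < q_ub) 1L else 0L
        }
      }
    }
    noise <- matrix(stats::rnorm(n_frames * 3L, sd = positional_noise_sd),
                    ncol = 3L)
    list(states = states, noise = noise)
  })
  states <- gen$states

  n_atoms <- 8L  # 6 ring C + H1 + C1
  topology <- data.frame(
    serial = 1:8,
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "H1", "C1"),
    element = c(rep("C", 6L), "H", "C"),
    residue_name = c(rep("PHE", 6L), "NAG", "NAG"),
    chain_id = c(rep("A", 6L), "G", "G"),
    residue_number = c(rep(23L, 6L), 1L, 1L),
    insertion_code = "", alt_loc = "",
    stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    dist <- if (states[f] == 1L) bound_distance else unbound_distance
    h <- c(0, 0, dist) + gen$noise[f, ]
    coords[f, 1:6, ] <- ring_xy
    coords[f, 7L, ] <- h
    coords[f, 8L, ] <- h + c(0, 0, 0.109)  # C1 tracks H1 rigidly
  }
  traj <- structure(list(topology = topology, coords = coords,
                         time_step_ns = NA_real_),
                    class = "glyco_trajectory")

  # noise-averaged single-state expectations from a seeded child stream
  expectations <- with_preserved_seed(seed + 104729L, {
    eps <- matrix(stats::rnorm(1e5 * 3L, sd = positional_noise_sd), ncol = 3L)
    e_for <- function(dist) {
      r <- sqrt((eps[, 1])^2 + (eps[, 2])^2 + (dist + eps[, 3])^2)
      mean(switching_value(r, params))
    }
    c(bound = e_for(bound_distance), unbound = e_for(unbound_distance))
  })

  list(trajectory = traj, states = states,
       expected_c_bound = expectations[["bound"]],
       expected_c_unbound = expectations[["unbound"]],
       expected_mean_contact = p * expectations[["bound"]] +
         (1 - p) * expectations[["unbound"]])
}

#' Generate synthetic 1:1 binding titration curves
#'
#' Forward model of the depletion isotherm: responses are
#' r_free + (r_bound - r_free) * f_b(L) plus Gaussian noise, per replicate.
#'
#' @param kd true dissociation constant, uM
#' @param target_conc_uM fixed labeled-target concentration, uM
#' @param titrant_concs_uM titrant concentrations, uM (default 16-point
#'   log-spaced 0.001-100)
#' @param r_free,r_bound response plateaus (arbitrary units)
#' @param noise_sd Gaussian response noise SD
#' @param n_replicates independent replicate curves
#' @param seed integer seed
#' @param model isotherm used for generation
#' @return list with `curve` (data.frame titrant_conc_uM, response,
#'   replicate) and `true_kd_uM`
#' @export
generate_titration <- function(kd = 1.52, target_conc_uM = 0.05,
                               titrant_concs_uM = 10^seq(-3, 2, length.out = 16L),
                               r_free = 800, r_bound = 900, noise_sd = 0,
                               n_replicates = 1L, seed = 1L,
                               model = c("quadratic", "hyperbolic")) {
  model <- match.arg(model)
  stopifnot(kd > 0, target_conc_uM > 0, noise_sd >= 0, n_replicates >= 1L)
  fb <- fraction_bound(titrant_concs_uM, target_conc_uM, kd, model = model)
  mu <- r_free + (r_bound - r_free) * fb
  curve <- with_preserved_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(titrant_conc_uM = titrant_concs_uM,
                 response = mu + stats::rnorm(length(mu), sd = noise_sd),
                 replicate = r)
    }))
  })
  list(curve = curve, true_kd_uM = kd)
}

#' Generate a synthetic two-channel quantification table
#'
#' Emulates a dimethyl-labeled experiment/control design: log-normal
#' intensities with a designated enriched subset whose experiment channel
#' is shifted by log2(true_fc); within-group variability given as a linear
#' coefficient of variation (mapped to log2 SD via
#' sqrt(log(1 + cv^2)) / log(2)); unique-peptide counts Poisson; optional
#' missingness, either completely at random or intensity-dependent (MNAR
#' as left-censoring at a detection limit: within each replicate column the
#' lowest `missing_rate` fraction of intensities is unobserved, the model
#' under which deterministic minimum imputation is the standard remedy).
#'
#' @param n_background,n_enriched protein counts
#' @param true_fc fold change of the enriched subset (experiment/control)
#' @param base_log2_mean,base_log2_sd protein baseline log2-intensity law
#' @param within_group_cv linear CV of replicate intensities
#' @param missing_rate expected fraction of missing intensity cells
#' @param missing_mode "intensity" (MNAR, default) or "random"
#' @param n_replicates replicates per channel
#' @param peptide_lambda Poisson mean of unique-peptide counts
#' @param seed integer seed
#' @return list with `table` (a `quant_table`) and `enriched_accessions`
#' @export
generate_quant_table <- function(n_background = 940L, n_enriched = 60L,
                                 true_fc = 8, base_log2_mean = 20,
                                 base_log2_sd = 2, within_group_cv = 0.2,
                                 missing_rate = 0.1,
                                 missing_mode = c("intensity", "random"),
                                 n_replicates = 3L, peptide_lambda = 4,
                                 seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_background >= 0, n_enriched >= 0, true_fc > 0,
            within_group_cv >= 0, missing_rate >= 0, missing_rate < 1,
            n_replicates >= 2L)
  n <- n_background + n_enriched
  sd_log2 <- if (within_group_cv > 0) {
    sqrt(log(1 + within_group_cv^2)) / log(2)
  } else 0
  with_preserved_seed(seed, {
    acc <- sprintf("P%04d", seq_len(n))
    enriched <- c(rep(FALSE, n_background), rep(TRUE, n_enriched))
    mu <- stats::rnorm(n, base_log2_mean, base_log2_sd)
    draw <- function(shift) {
      matrix(2^(rep(mu + shift, n_replicates) +
                  stats::rnorm(n * n_replicates, sd = sd_log2)),
             nrow = n)
    }
    exp_m <- draw(ifelse(enriched, log2(true_fc), 0))
    ctl_m <- draw(0)
    pep <- matrix(stats::rpois(n * n_replicates, peptide_lambda), nrow = n)

    apply_missing <- function(m) {
      if (missing_rate == 0) return(m)
      for (j in seq_len(ncol(m))) {
        if (missing_mode == "random") {
          m[stats::runif(nrow(m)) < missing_rate, j] <- NA_real_
        } else {
          # detection limit: the lowest missing_rate fraction is unobserved
          lod <- stats::quantile(m[, j], missing_rate, names = FALSE)
          m[m[, j] < lod, j] <- NA_real_
        }
      }
      m
    }
    exp_m <- apply_missing(exp_m)
    ctl_m <- apply_missing(ctl_m)
    list(table = quant_table(acc, exp_m, ctl_m, pep),
         enriched_accessions = acc[enriched])
  })
}
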