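# run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a linear Michaelis--Menten chain with constant influx
#'
#' A constant influx k feeds S1, which is converted through `n_reactions`
#' MM1 steps (S1 -> S2 -> ... -> P). Vmax and Km are drawn uniformly from
#' [1, 10] (nmol/L scale) and the influx is set to half the smallest Vmax,
#' so every node has the analytic steady state S_i* = k Km_i / (Vmax_i - k)
#' (the terminal product P accumulates without bound). The analytic steady
#' states are stored in `model$metadata$steady_state`, the influx in
#' `model$metadata$influx`.
#'
#' @param n_reactions Number of MM1 steps (>= 1).
#' @param seed RNG seed; the generator is a pure function of
#'   (n_reactions, seed).
#' @return A validated `thiamsim_model` with `n_reactions + 1` reactions.
#' @export
make_mm_chain <- function(n_reactions, seed = 1L) {
  stopifnot(n_reactions >= 1L)
  .with_seed(seed, {
    vmax <- stats::runif(n_reactions, 1, 10)
    km <- stats::runif(n_reactions, 1, 10)
  })
  k <- 0.5 * min(vmax)  # strictly below every Vmax: steady state exists
  s_ids <- paste0("S", seq_len(n_reactions))
  mets <- c(lapply(s_ids, function(id) metabolite(id, compartment = "cytosol")),
            list(metabolite("P", compartment = "cytosol")))
  rxns <- vector("list", n_reactions + 1L)
  rxns[[1L]] <- reaction("R_in", "transport", c(S1 = 1),
                         kinetic_law("constant_flux", k = k))
  for (i in seq_len(n_reactions)) {
    prod_id <- if (i < n_reactions) s_ids[i + 1L] else "P"
    st <- stats::setNames(c(-1, 1), c(s_ids[i], prod_id))
    rxns[[i + 1L]] <- reaction(paste0("R", i), paste0("E", i), st,
                               kinetic_law("MM1", substrate_ids = s_ids[i],
                                           vmax = vmax[i], km = km[i]))
  }
  ss <- stats::setNames(k * km / (vmax - k), s_ids)
  pathway_model(mets, rxns,
                metadata = list(kind = "mm_chain", seed = seed,
                                influx = k, steady_state = ss))
}

#' Generate the reduced thiamin biosynthesis network
#'
#' A two-branch condensation network capturing the core dynamic of plant
#' thiamin biosynthesis: THIC synthesises the pyrimidine moiety HMP-P (from
#' clamped AIR + SAM), THI1 the thiazole moiety HET-P (from clamped NAD +
#' glycine), the bifunctional TH1 first phosphorylates HMP-P to HMP-PP
#' (kinase site, MM1) and then condenses HMP-PP + HET-P into TMP (synthase
#' site, two-substrate MM); TH2 drains TMP to free thiamin. Both TH1 steps
#' share the enzyme label `"TH1"`, so perturbing TH1 scales both active
#' sites.
#'
#' The fixed rate constants encode co-substrate limitation: the thiazole
#' branch supplies HET-P more slowly than the pyrimidine branch supplies
#' HMP-PP, and the stored HMP-PP/HET-P pools are large relative to the
#' branch fluxes. Consequently (i) overexpressing THIC alone changes nothing
#' (HET-P already limits), (ii) overexpressing THI1 alone raises TMP
#' modestly (until HMP-PP limits), (iii) overexpressing TH1 alone burns the
#' stored pools into a transient TMP peak that relaxes back to the
#' supply-limited baseline, and (iv) overexpressing all three sustains a
#' high TMP plateau. The constants are fixed in code; the network is a
#' qualitative stand-in and makes no claim to reproduce any measured
#' concentration.
#'
#' @param seed Accepted for interface uniformity with the other generators;
#'   unused (the network is fully deterministic).
#' @return A validated `thiamsim_model` (9 metabolites, 6 reactions; target
#'   metabolite `"TMP"`).
#' @export
make_thiamin_toy <- function(seed = NULL) {
  mets <- list(
    metabolite("AIR", "5-aminoimidazole ribonucleotide", "plastid", 100, boundary = TRUE),
    metabolite("SAM", "S-adenosylmethionine", "plastid", 100, boundary = TRUE),
    metabolite("NAD", "nicotinamide adenine dinucleotide", "plastid", 100, boundary = TRUE),
    metabolite("GLY", "glycine", "plastid", 100, boundary = TRUE),
    metabolite("HMP_P", "hydroxymethylpyrimidine phosphate", "plastid", 1),
    metabolite("HMP_PP", "hydroxymethylpyrimidine diphosphate", "plastid", 50),
    metabolite("HET_P", "hydroxyethylthiazole phosphate", "plastid", 30),
    metabolite("TMP", "thiamin monophosphate", "plastid", 0.01),
    metabolite("THM", "thiamin", "cytosol", 0))
  # branch asymmetry: pyrimidine supply ~0.02, thiazole supply ~0.01 nmol/L/s
  rxns <- list(
    reaction("R_THIC", "THIC", c(AIR = -1, SAM = -1, HMP_P = 1),
             kinetic_law("MM2", c("AIR", "SAM"), vmax = 0.024,
                         km_a = 10, km_b = 10)),
    reaction("R_THI1", "THI1", c(NAD = -1, GLY = -1, HET_P = 1),
             kinetic_law("MM1", "NAD", vmax = 0.011, km = 10)),
    reaction("R_TH1_kinase", "TH1", c(HMP_P = -1, HMP_PP = 1),
             kinetic_law("MM1", "HMP_P", vmax = 0.1, km = 1)),
    reaction("R_TH1_synthase", "TH1", c(HMP_PP = -1, HET_P = -1, TMP = 1),
             kinetic_law("MM2", c("HMP_PP", "HET_P"), vmax = 0.13,
                         km_a = 100, km_b = 100)),
    reaction("R_TH2", "TH2", c(TMP = -1, THM = 1),
             kinetic_law("MM1", "TMP", vmax = 2, km = 2)),
    # slow pyrimidine turnover gives the HMP-PP pool a finite steady state
    reaction("R_HMP_PP_deg", "degradation", c(HMP_PP = -1),
             kinetic_law("mass_action", "HMP_PP", k = 2e-4)))
  pathway_model(mets, rxns, metadata = list(kind = "thiamin_toy",
                                            target = "TMP"))
}

#' Generate synthetic OD600 growth curves
#'
#' Logistic curves OD(t) = K / (1 + ((K - x0)/x0) exp(-r t)) sampled every
#' `dt_h` hours for `t_max_h` hours (defaults emulate a 3-day run read every
#' 30 min from a starting OD of 0.05), with i.i.d. Gaussian noise of
#' standard deviation `noise_sigma` added to each reading (clamped at 0).
#' Rate 0 gives a flat control at `od0`. Byte-identical output for identical
#' arguments and seed.
#'
#' @param groups Named list: label -> `c(rate = r, n = replicates)` (rate per
#'   hour).
#' @param noise_sigma Gaussian OD noise standard deviation.
#' @param seed RNG seed (mandatory: the generator is stochastic).
#' @param od0 Starting OD600 (default 0.05).
#' @param carrying_capacity Logistic plateau K (default 1.5).
#' @param t_max_h,dt_h Sampling horizon and interval in hours.
#' @return Tidy data.frame with columns `time_h`, `od600`, `label`,
#'   `replicate` (the [estimate_growth_rates()] input schema).
#' @export
make_growth_curves <- function(groups, noise_sigma = 0.01, seed,
                               od0 = 0.05, carrying_capacity = 1.5,
                               t_max_h = 72, dt_h = 0.5) {
  if (missing(seed)) stop("a seed is mandatory for stochastic fixtures")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list (label -> c(rate, n))")
  times <- seq(0, t_max_h, by = dt_h)
  K <- carrying_capacity
  .with_seed(seed, {
    out <- list()
    for (label in names(groups)) {
      g <- groups[[label]]
      r <- unname(g[[1L]]); n <- as.integer(unname(g[[2L]]))
      if (r < 0) stop("growth rates must be >= 0 (group '", label, "')")
      for (rep_i in seq_len(n)) {
        od <- if (r == 0) rep(od0, length(times)) else
          K / (1 + ((K - od0) / od0) * exp(-r * times))
        od <- pmax(od + stats::rnorm(length(times), 0, noise_sigma), 0)
        out[[length(out) + 1L]] <- data.frame(
          time_h = times, od600 = od, label = label, replicate = rep_i,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
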