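# Synthetic perturbation databases with planted ground truth. The
# generator emulates the structure the scoring engine consumes — a ranked
# probe profile per treatment instance with compound/cell-line metadata —
# so every pipeline stage is testable without external downloads.
#
# Generative model, per probe g and instance i of compound k:
#   baseline   b_g ~ Normal(baseline_mean, baseline_sd^2)     (shared)
#   control    x   = b_g + eps,            eps  ~ Normal(0, sigma^2)
#   treated    y   = b_g + effect_kg + eps', eps' ~ Normal(0, sigma^2)
#   amplitude  y - x   (the baseline cancels; ranks come from amplitudes)
# effect_kg = +delta on compound k's planted up set, -delta on its down
# set, 0 elsewhere, and 0 everywhere for null compounds.

#' Simulation configuration
#'
#' Defaults are the reference validation regime used throughout the test
#' suite: a 1000-probe universe, 50 compounds with 4 instances each
#' (N = 200), planted tag sets of 100 probes (50 up + 50 down), and an
#' effect size of delta = 2 on a log2-like scale against per-value noise
#' sigma = 1. Since an amplitude pairs two noise draws, the planted shift
#' of 2 stands against an amplitude noise sd of sigma * sqrt(2) ~ 1.41 —
#' a strong but not deterministic signal, so recovery is a meaningful test.
#'
#' @param n_probes Probe universe size G (>= 2 * tag_set_size).
#' @param n_compounds Number of compounds K (>= 1).
#' @param instances_per_compound Instances m per compound (>= 1).
#' @param tag_set_size Planted tag count t per compound, split evenly into
#'   up and down sets (t must be even).
#' @param effect_size Planted shift delta (>= 0), log2-like scale.
#' @param noise_sd Noise sd sigma (> 0) of each expression value.
#' @param baseline_mean,baseline_sd Baseline log2-intensity distribution.
#' @param planted Data frame with columns `compound` (index in 1..K) and
#'   `mode` (`"concordant"`, `"oppositional"` or `"null"`). Compounds not
#'   listed are null.
#' @param seed Integer seed; a single generator stream drawn in a fixed
#'   order makes the whole database reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 1000L, n_compounds = 50L,
                              instances_per_compound = 4L,
                              tag_set_size = 100L,
                              effect_size = 2, noise_sd = 1,
                              baseline_mean = 7, baseline_sd = 1.5,
                              planted = data.frame(compound = integer(),
                                                   mode = character()),
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_compounds = as.integer(n_compounds),
              instances_per_compound = as.integer(instances_per_compound),
              tag_set_size = as.integer(tag_set_size),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              planted = planted, seed = as.integer(seed))
  if (cfg$tag_set_size %% 2L != 0L)
    sc_error("config", "tag_set_size must be even (split into up/down halves)")
  if (cfg$n_probes < 2L * cfg$tag_set_size)
    sc_error("config", "n_probes must be >= 2 * tag_set_size")
  if (cfg$n_compounds < 1L || cfg$instances_per_compound < 1L)
    sc_error("config", "need at least one compound and one instance each")
  if (cfg$noise_sd <= 0) sc_error("config", "noise_sd must be > 0")
  if (cfg$effect_size < 0) sc_error("config", "effect_size must be >= 0")
  if (nrow(planted)) {
    if (!all(c("compound", "mode") %in% names(planted)))
      sc_error("config", "planted needs columns compound and mode")
    if (any(planted$compound < 1 | planted$compound > cfg$n_compounds))
      sc_error("config", "planted compound index out of 1..K")
    if (any(!planted$mode %in% c("concordant", "oppositional", "null")))
      sc_error("config", "planted mode must be concordant/oppositional/null")
    if (anyDuplicated(planted$compound))
      sc_error("config", "compound planted twice")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate an instance database with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return List with `db` (an `instance_db` of K*m instances, compounds
#'   named `cpd_<k>`, cell line `"SIM"`) and `truth` (class
#'   `simulated_truth`: per planted compound its up-shifted and
#'   down-shifted probe sets and mode, plus the seed).
#' @export
simulate_database <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  G <- config$n_probes
  K <- config$n_compounds
  m <- config$instances_per_compound
  t2 <- config$tag_set_size %/% 2L
  probes <- sprintf("probe_%0*d", nchar(as.character(G)), seq_len(G))
  with_seed(config$seed, {
    baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
    # Accession-style instance identifiers, assigned in shuffled order.
    # Real databases name instances by accession, unrelated to compound;
    # encoding the compound in the id ordering would let the deterministic
    # tie-break of the connectivity ordering cluster a compound's null
    # (s = 0) instances and bias the group enrichment.
    id_of <- sprintf("inst_%0*d", nchar(as.character(K * m)),
                     sample.int(K * m))
    modes <- rep("null", K)
    if (nrow(config$planted))
      modes[config$planted$compound] <- config$planted$mode
    truth_sets <- vector("list", K)
    profiles <- vector("list", K * m)
    for (k in seq_len(K)) {
      effect <- numeric(G)
      if (modes[k] != "null") {
        tags <- sample.int(G, 2L * t2)
        up_idx <- tags[seq_len(t2)]
        down_idx <- tags[t2 + seq_len(t2)]
        effect[up_idx] <- config$effect_size
        effect[down_idx] <- -config$effect_size
        truth_sets[[k]] <- list(compound = k, mode = modes[k],
                                up = sort(probes[up_idx]),
                                down = sort(probes[down_idx]))
      } else if (k %in% config$planted$compound) {
        truth_sets[[k]] <- list(compound = k, mode = "null",
                                up = character(), down = character())
      }
      for (i in seq_len(m)) {
        ctrl <- baseline + stats::rnorm(G, 0, config$noise_sd)
        trt <- baseline + effect + stats::rnorm(G, 0, config$noise_sd)
        amp <- trt - ctrl
        names(amp) <- probes
        profiles[[(k - 1L) * m + i]] <- rank_profile_from_amplitudes(
          amp, instance_id = id_of[(k - 1L) * m + i],
          compound = sprintf("cpd_%d", k), cell_line = "SIM")
      }
    }
    db <- build_database(profiles)
    truth <- structure(list(
      compounds = Filter(Negate(is.null), truth_sets),
      modes = modes, seed = config$seed,
      config = unclass(config)[setdiff(names(config), "planted")]),
      class = "simulated_truth")
    list(db = db, truth = truth)
  })
}

#' Build the planted query signature for a simulated compound
#'
#' For a concordant compound the query copies the compound's planted sets,
#' so the compound scores positively (self-retrieval). For an oppositional
#' compound the sides are swapped — query up tags are the compound's
#' down-shifted probes and vice versa — so the compound scores negatively,
#' mirroring the repurposing setting where a drug reverses a disease
#' signature.
#'
#' @param truth A `simulated_truth` from [simulate_database()].
#' @param compound_index Index (1..K) of a planted non-null compound.
#' @return A `gene_signature` in the simulated probe namespace.
#' @export
make_planted_query <- function(truth, compound_index) {
  stopifnot(inherits(truth, "simulated_truth"))
  hit <- Filter(function(x) x$compound == compound_index, truth$compounds)
  if (length(hit) == 0L)
    sc_error("mode", "compound %d was not planted", compound_index)
  hit <- hit[[1L]]
  if (hit$mode == "null")
    sc_error("mode", "compound %d was planted as null; no query defined",
             compound_index)
  if (hit$mode == "concordant")
    gene_signature(hit$up, hit$down, namespace = "SIM",
                   provenance = list(builder = "planted", mode = hit$mode,
                                     compound = compound_index))
  else
    gene_signature(hit$down, hit$up, namespace = "SIM",
                   provenance = list(builder = "planted", mode = hit$mode,
                                     compound = compound_index))
}

#' Write a simulated database and its ground truth to a directory
#'
#' Emits `rank_matrix.tsv`, `meta.tsv`, `truth.yaml`, and a GRP signature
#' pair per planted non-null compound (`query_cpd_<k>_up.grp` / `_down.grp`).
#'
#' @param sim List from [simulate_database()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rank_matrix(sim$db, file.path(dir, "rank_matrix.tsv"),
                    file.path(dir, "meta.tsv"))
  truth_out <- list(seed = sim$truth$seed, config = sim$truth$config,
                    compounds = lapply(sim$truth$compounds, function(x)
                      list(compound = x$compound, mode = x$mode,
                           up = as.list(x$up), down = as.list(x$down))))
  yaml::write_yaml(truth_out, file.path(dir, "truth.yaml"))
  for (x in sim$truth$compounds) {
    if (x$mode == "null") next
    write_signature(make_planted_query(sim$truth, x$compound),
                    file.path(dir, sprintf("query_cpd_%d", x$compound)))
  }
  invisible(dir)
}
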