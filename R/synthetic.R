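#' Specification of a synthetic strain panel
#'
#' Defines the conditions a generated screening experiment emulates.
#' Defaults mirror the published study panel: 102 strains in three
#' replicates, mycelial growth spanning 8.4-69.5 mm, sporulation
#' 0.3-55.7 x 10^8 conidia/ml, 7-day corrected mortality 4.7-98.1%,
#' 40-50 marked nymphs per replicate (45 used) and a small background
#' control mortality (mean 5%; the study does not print its control
#' levels, so this is a stated assumption).
#'
#' `lambda` is the loading of the mortality variables on a latent
#' virulence factor: the day-7 mortality propensity is a monotone map
#' of `lambda * v + (1 - lambda) * noise` for latent virulence
#' `v ~ Uniform(0, 1)`. Growth and sporulation are independent of `v`
#' by default (`mg_sp_coupling = 0`), reflecting the absence of a
#' growth-virulence correlation in real panels; the coupling knob
#' exists for sensitivity tests.
#'
#' @param n_strains,n_reps panel size and replicates (n_reps >= 2).
#' @param mg_range,sp_range,mo7_range trait ranges (mm, x 10^8/ml, %).
#' @param control_mortality_mean mean control mortality, %.
#' @param lambda latent-virulence loading in `[0, 1]`.
#' @param mg_sp_coupling coupling of MG/SP to the latent factor
#'   (`[0, 1]`, default 0 = independent).
#' @param n_marked nymphs marked per replicate leaf.
#' @param seed random seed used by [generate_panel()].
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_strains = 102, n_reps = 3,
                       mg_range = c(8.4, 69.5),
                       sp_range = c(0.3, 55.7),
                       mo7_range = c(4.7, 98.1),
                       control_mortality_mean = 5,
                       lambda = 0.8, mg_sp_coupling = 0,
                       n_marked = 45, seed = 1) {
  stopifnot(n_strains >= 2, n_reps >= 2, n_marked >= 1)
  for (rg in list(mg_range, sp_range, mo7_range)) {
    if (length(rg) != 2L || rg[1L] > rg[2L] || any(rg < 0)) {
      stop("panel_spec: invalid range", call. = FALSE)
    }
  }
  if (mo7_range[2L] > 100) stop("panel_spec: mortality range above 100%",
                                call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("panel_spec: lambda must be in [0, 1]",
                                     call. = FALSE)
  if (control_mortality_mean < 0 || control_mortality_mean >= 100) {
    stop("panel_spec: control mortality must be in [0, 100)", call. = FALSE)
  }
  structure(list(n_strains = n_strains, n_reps = n_reps,
                 mg_range = mg_range, sp_range = sp_range,
                 mo7_range = mo7_range,
                 control_mortality_mean = control_mortality_mean,
                 lambda = lambda, mg_sp_coupling = mg_sp_coupling,
                 n_marked = n_marked, seed = seed),
            class = "panel_spec")
}

# host-order / state composition of the real panel, used as sampling
# weights for the synthetic metadata
.host_weights <- c(Lepidoptera = 68, Coleoptera = 12, other = 9,
                   Hymenoptera = 5, Hemiptera = 3, Orthoptera = 3,
                   Diptera = 2)
.state_weights <- c(`Madhya Pradesh` = 77, Chhattisgarh = 16,
                    `Tamil Nadu` = 4, Uttarakhand = 3, Haryana = 1,
                    `Himachal Pradesh` = 1)

# map a trait propensity in [0,1] into a range
.range_map <- function(h, range) range[1L] + h * (range[2L] - range[1L])

#' Generate a synthetic strain screening panel
#'
#' Draws a latent virulence `v_i ~ Uniform(0, 1)` per strain and builds
#' every replicate-level table the pipeline ingests:
#'
#' * day-7 corrected-mortality propensity: monotone map of
#'   `lambda * v_i + (1 - lambda) * u_i` into `mo7_range`; day-5 and
#'   day-3 propensities are shrunken fractions of it, so the time-kill
#'   curve is monotone in expectation (`MO3 < MO5 < MO7`);
#' * bioassay counts: `n_dead ~ Binomial(n_marked, p)` per replicate,
#'   where `p` combines the target corrected mortality with the control
#'   background, and control rows are binomial at the control rate --
#'   noise enters as counts, the way bioassay data actually arise;
#' * growth/sporulation: uniform over their ranges (independent of
#'   `v_i` unless `mg_sp_coupling > 0`), with small replicate-level
#'   measurement noise in the two colony diameters and the conidial
#'   concentration;
#' * metadata: host orders and states sampled with the composition of
#'   the real 102-strain panel.
#'
#' @param spec a [panel_spec()].
#' @return List with `strains`, `growth`, `spores`, `bioassay`
#'   (validated tables) and `truth` (data frame of the ground truth per
#'   strain: `v`, `mg`, `sp`, `mo3`, `mo5`, `mo7`), plus `spec`.
#' @export
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_strains
  ids <- sprintf("SYN-%03d", seq_len(n))

  v <- runif(n)
  h7 <- spec$lambda * v + (1 - spec$lambda) * runif(n)
  mo7 <- .range_map(h7, spec$mo7_range)
  mo5 <- mo7 * runif(n, 0.80, 0.95)
  mo3 <- mo5 * runif(n, 0.50, 0.90)

  couple <- function(range) {
    rho <- spec$mg_sp_coupling
    .range_map(rho * v + (1 - rho) * runif(n), range)
  }
  mg <- couple(spec$mg_range)
  sp <- couple(spec$sp_range)

  strains <- data.frame(
    strain_id = ids,
    host_order = sample(names(.host_weights), n, replace = TRUE,
                        prob = .host_weights),
    host_species = NA_character_,
    state = sample(names(.state_weights), n, replace = TRUE,
                   prob = .state_weights),
    source = NA_character_,
    stringsAsFactors = FALSE
  )
  strains$source <- ifelse(strains$host_order == "other",
                           sample(c("soil", "plant"), n, replace = TRUE),
                           "cadaver")
  species_pool <- c("Helicoverpa armigera", "Spodoptera litura",
                    "Bombyx mori", "Hyblaea puera", "Oryctes rhinoceros",
                    "Drosicha mangiferae", "unidentified")
  strains$host_species <- ifelse(strains$source == "cadaver",
                                 sample(species_pool, n, replace = TRUE),
                                 "none")

  reps <- seq_len(spec$n_reps)
  grid <- expand.grid(strain = seq_len(n), replicate = reps,
                      KEEP.OUT.ATTRS = FALSE)
  growth <- data.frame(
    strain_id = ids[grid$strain], replicate = grid$replicate, day = 7L,
    diameter_a = pmin(90, pmax(0, mg[grid$strain] +
                                 rnorm(nrow(grid), 0, 1.5))),
    diameter_b = pmin(90, pmax(0, mg[grid$strain] +
                                 rnorm(nrow(grid), 0, 1.5))),
    stringsAsFactors = FALSE
  )
  spores <- data.frame(
    strain_id = ids[grid$strain], replicate = grid$replicate, day = 10L,
    conidia_conc = sp[grid$strain] * exp(rnorm(nrow(grid), 0, 0.08)),
    stringsAsFactors = FALSE
  )

  ctrl <- spec$control_mortality_mean
  days <- c(3L, 5L, 7L)
  mo_by_day <- rbind(mo3, mo5, mo7)
  bio <- expand.grid(strain = seq_len(n), replicate = reps,
                     day_i = seq_along(days), KEEP.OUT.ATTRS = FALSE)
  p_treat <- (mo_by_day[cbind(bio$day_i, bio$strain)] *
                (100 - ctrl) / 100 + ctrl) / 100
  bioassay <- data.frame(
    strain_id = ids[bio$strain], replicate = bio$replicate,
    day = days[bio$day_i],
    n_marked = spec$n_marked,
    n_dead = rbinom(nrow(bio), spec$n_marked, p_treat),
    stringsAsFactors = FALSE
  )
  ctrl_grid <- expand.grid(replicate = reps, day = days,
                           KEEP.OUT.ATTRS = FALSE)
  control <- data.frame(
    strain_id = .control_id, replicate = ctrl_grid$replicate,
    day = ctrl_grid$day, n_marked = spec$n_marked,
    n_dead = rbinom(nrow(ctrl_grid), spec$n_marked, ctrl / 100),
    stringsAsFactors = FALSE
  )
  bioassay <- rbind(bioassay, control)

  list(strains = validate_strains(strains),
       growth = validate_growth(growth),
       spores = validate_spores(spores),
       bioassay = validate_bioassay(bioassay),
       truth = data.frame(strain_id = ids, v = v, mg = mg, sp = sp,
                          mo3 = mo3, mo5 = mo5, mo7 = mo7,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Specification of a synthetic ITS-like alignment
#'
#' Sequences are evolved along a tree under the TN93 substitution model
#' (two transition rates, one transversion rate, unequal base
#' frequencies). Defaults give a 590-column alignment -- the usable
#' length of a trimmed ITS dataset -- over a random coalescent tree of
#' moderate depth, with a sprinkle of gaps and ambiguity codes so the
#' pairwise-deletion machinery is exercised.
#'
#' @param n_taxa number of sequences.
#' @param aln_length alignment columns (default 590).
#' @param base_freq frequencies `(A, C, G, T)` summing to 1.
#' @param k_purine,k_pyrimidine transition/transversion rate ratios for
#'   A/G and C/T transitions.
#' @param tree optional `phylo` to evolve along; default: a random
#'   coalescent tree ([ape::rcoal()]) rescaled to `tree_depth`.
#' @param tree_depth root-to-tip depth (substitutions/site) for the
#'   default tree.
#' @param gap_rate,ambiguity_rate per-cell probabilities of replacing a
#'   residue by a gap / an IUPAC ambiguity code.
#' @param seed random seed used by [generate_alignment()].
#' @return List of class `seqsim_spec`.
#' @export
seqsim_spec <- function(n_taxa = 102, aln_length = 590,
                        base_freq = c(A = 0.24, C = 0.27, G = 0.26,
                                      T = 0.23),
                        k_purine = 3, k_pyrimidine = 5,
                        tree = NULL, tree_depth = 0.1,
                        gap_rate = 0.02, ambiguity_rate = 0.005,
                        seed = 1) {
  stopifnot(n_taxa >= 2, aln_length >= 1,
            abs(sum(base_freq) - 1) < 1e-8, all(base_freq > 0),
            k_purine > 0, k_pyrimidine > 0,
            gap_rate >= 0, ambiguity_rate >= 0,
            gap_rate + ambiguity_rate < 1)
  structure(list(n_taxa = n_taxa, aln_length = aln_length,
                 base_freq = base_freq, k_purine = k_purine,
                 k_pyrimidine = k_pyrimidine, tree = tree,
                 tree_depth = tree_depth, gap_rate = gap_rate,
                 ambiguity_rate = ambiguity_rate, seed = seed),
            class = "seqsim_spec")
}

#' Simulate an alignment along a known tree
#'
#' Evolves sequences column-wise under TN93 ([phangorn::simSeq()] with
#' the TN93 rate matrix), optionally injecting gaps and ambiguity
#' codes, and returns both the alignment and the true tree so topology
#' recovery can be scored.
#'
#' @param spec a [seqsim_spec()].
#' @return List with `alignment` (an [epf_alignment()]) and `tree` (the
#'   true `phylo`).
#' @export
generate_alignment <- function(spec = seqsim_spec()) {
  stopifnot(inherits(spec, "seqsim_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(spec$n_taxa,
                       tip.label = sprintf("SYN-%03d",
                                           seq_len(spec$n_taxa)))
    tree$edge.length <- tree$edge.length /
      max(ape::node.depth.edgelength(tree)) * spec$tree_depth
  }
  # GTR rate order (AC, AG, AT, CG, CT, GT); TN93 = transversions 1
  Q <- c(1, spec$k_purine, 1, 1, spec$k_pyrimidine, 1)
  sim <- phangorn::simSeq(tree, l = spec$aln_length, Q = Q,
                          bf = spec$base_freq, type = "DNA")
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  n_cells <- length(m)
  u <- runif(n_cells)
  m[u < spec$gap_rate] <- "-"
  amb <- which(u >= spec$gap_rate &
                 u < spec$gap_rate + spec$ambiguity_rate)
  if (length(amb) > 0L) {
    m[amb] <- sample(c("N", "R", "Y", "W", "S", "K", "M"),
                     length(amb), replace = TRUE)
  }
  list(alignment = epf_alignment(m), tree = tree)
}

#' Published reference table of the top screened strains
#'
#' The packaged 14-row reference table of strain summaries (accession,
#' mycelial growth, sporulation, corrected mortality at 3/5/7 days with
#' their arcsine-transformed values in the `_t` columns, and the
#' bioefficacy index). Note the source table's growth column header
#' prints cm^2 while the index formula is stated over mm diameters; the
#' numeric values are consumed as printed, which the BI column's exact
#' recomputability confirms. `table1_footer()` returns the accompanying
#' LSD / SE(m) / SE(d) / CV rows.
#'
#' @return Data frame of 14 strain rows (or 4 footer statistic rows).
#' @export
table1_fixture <- function() {
  read.csv(system.file("extdata", "table1_bioefficacy.csv",
                       package = "epfscreen"),
           stringsAsFactors = FALSE)
}

#' @rdname table1_fixture
#' @export
table1_footer <- function() {
  read.csv(system.file("extdata", "table1_footer.csv",
                       package = "epfscreen"),
           stringsAsFactors = FALSE)
}
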