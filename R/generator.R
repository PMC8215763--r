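# Synthetic count-table generator emulating biphasic colonisation of fresh
# forage: a primary sub-microbiome peaking at <= 4 h of rumen incubation, an
# anticorrelated secondary sub-microbiome rising from 4 h, transcriptionally
# dominant families independent of both, a low-abundance stable tier, and
# planted low-abundance keystone "connector" families inside each block.

# Canonical latent trajectories at the design hours 1, 2, 4, 6, 8: the primary
# template declines monotonically from the 1 h peak, the secondary template is
# its mirror image, so every primary x secondary trajectory pair has rank
# correlation -1 (the anticorrelation between phases is exact by construction;
# member trajectories are jittered but rank-enforced to the template order).
# Connectorness of the planted keystones arises at the count level: members
# track the template through family-specific biological overdispersion while
# keystones, being exactly proportional to the template, track it most
# faithfully and therefore correlate more strongly with every member than
# members do with each other.
.template_hours <- c(1, 2, 4, 6, 8)
.block_templates <- list(
  primary = c(1.00, 0.78, 0.52, 0.26, 0.10),
  secondary = c(0.10, 0.26, 0.52, 0.78, 1.00)
)

#' Configuration for the synthetic biphasic-colonisation generator
#'
#' Defaults encode the in sacco study design this generator emulates: three
#' rumen-cannulated animals, bags withdrawn at 1, 2, 4, 6 and 8 h, plus one
#' pooled pre-incubation (0 h) epiphyte sample, i.e. 16 samples in total.
#'
#' @param n_primary_families,n_secondary_families Families in the primary
#'   (early-colonising) and secondary (late-colonising) blocks. Each block is
#'   split evenly between its two trajectory sub-templates.
#' @param n_independent_families Families uncorrelated with either block. A
#'   fraction `independent_high_fraction` of them is transcriptionally dominant
#'   (flat, high expression); the rest form a low-abundance stable tier.
#' @param n_keystone_per_block Planted low-abundance connector families per
#'   block, sized at `keystone_abundance_fraction` of the block template.
#' @param genes_per_family_range Integer range for the number of genes drawn
#'   per family; the minimum defaults to 10 so families survive the min-gene
#'   filter of the pre-processing chain.
#' @param n_animals Number of host animals.
#' @param timepoints_h Strictly increasing incubation hours.
#' @param include_baseline Add one 0 h epiphyte sample (reserved animal id
#'   `"A0"`), excluded by the downstream analysis defaults.
#' @param nb_dispersion Negative-binomial size parameter for the count noise;
#'   `Inf` switches to Poisson sampling.
#' @param libsize_logmean,libsize_logsd Lognormal library-size factor
#'   parameters (natural-log scale).
#' @param animal_effect_sd SD of the lognormal per-(family, animal) effect.
#' @param trajectory_jitter_sd SD of the lognormal per-timepoint jitter applied
#'   to each family's latent trajectory.
#' @param block_amplitude_sd SD of the lognormal amplitude multiplier across
#'   block families.
#' @param biol_sd_range Range of the per-family SD of the lognormal
#'   per-(family, sample) biological overdispersion for block members; each
#'   member draws its own SD uniformly from this range, which is what makes
#'   within-block correlations patchy.
#' @param independent_biol_sd_range Same, for independent families.
#' @param keystone_biol_sd Biological overdispersion SD of the planted
#'   keystones (small: keystones track their block's trajectory faithfully,
#'   which is what makes them connectors).
#' @param keystone_abundance_fraction Keystone mean as a fraction of the block
#'   template mean (default 0.05: keystones sit in the low-activity tail).
#' @param independent_high_fraction Fraction of independent families in the
#'   dominant high-expression tier.
#' @param enzyme_tag_fractions Named fractions of genes receiving an enzyme
#'   annotation (CAZy `GH*`, MEROPS peptidase codes, `LuxS`).
#' @param gene_length_range CDS length range in bp.
#' @param base_abundance Latent counts for a block family of unit amplitude at
#'   its template peak (sets the overall sequencing-depth scale).
#' @param n_functional_clusters Number of generic functional clusters genes are
#'   assigned to (enzyme-tagged genes go to umbrella clusters, mirroring
#'   coarse functional clustering of GH/peptidase/QS genes).
#' @param two_genus_blocks Number of block families given two genera instead of
#'   one (emulating a family dominated by two genera).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical outputs.
#'
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_primary_families = 12,
                             n_secondary_families = 12,
                             n_independent_families = 20,
                             n_keystone_per_block = 2,
                             genes_per_family_range = c(20L, 35L),
                             n_animals = 3,
                             timepoints_h = c(1, 2, 4, 6, 8),
                             include_baseline = TRUE,
                             nb_dispersion = 30,
                             libsize_logmean = 0,
                             libsize_logsd = 0.2,
                             animal_effect_sd = 0.08,
                             trajectory_jitter_sd = 0.1,
                             block_amplitude_sd = 0.4,
                             biol_sd_range = c(0.35, 0.65),
                             independent_biol_sd_range = c(0.15, 0.25),
                             keystone_biol_sd = 0.05,
                             keystone_abundance_fraction = 0.05,
                             independent_high_fraction = 0.3,
                             enzyme_tag_fractions = c(
                               GH3 = 0.02, GH5 = 0.02, GH9 = 0.015,
                               GH10 = 0.015, GH48 = 0.01,
                               M24b = 0.02, C25a = 0.015, S08a = 0.015,
                               M16 = 0.01, LuxS = 0.01
                             ),
                             gene_length_range = c(300L, 3000L),
                             base_abundance = 3e4,
                             n_functional_clusters = 40,
                             two_genus_blocks = 1,
                             seed = 1L) {
  cfg <- list(
    n_primary_families = as.integer(n_primary_families),
    n_secondary_families = as.integer(n_secondary_families),
    n_independent_families = as.integer(n_independent_families),
    n_keystone_per_block = as.integer(n_keystone_per_block),
    genes_per_family_range = as.integer(genes_per_family_range),
    n_animals = as.integer(n_animals),
    timepoints_h = as.numeric(timepoints_h),
    include_baseline = isTRUE(include_baseline),
    nb_dispersion = nb_dispersion,
    libsize_logmean = libsize_logmean,
    libsize_logsd = libsize_logsd,
    animal_effect_sd = animal_effect_sd,
    trajectory_jitter_sd = trajectory_jitter_sd,
    block_amplitude_sd = block_amplitude_sd,
    biol_sd_range = as.numeric(biol_sd_range),
    independent_biol_sd_range = as.numeric(independent_biol_sd_range),
    keystone_biol_sd = keystone_biol_sd,
    keystone_abundance_fraction = keystone_abundance_fraction,
    independent_high_fraction = independent_high_fraction,
    enzyme_tag_fractions = enzyme_tag_fractions,
    gene_length_range = as.integer(gene_length_range),
    base_abundance = base_abundance,
    n_functional_clusters = as.integer(n_functional_clusters),
    two_genus_blocks = as.integer(two_genus_blocks),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_animals < 1L) stop("generator_config: need at least one animal")
  if (length(cfg$timepoints_h) < 1L) {
    stop("generator_config: empty timepoint list")
  }
  if (any(diff(cfg$timepoints_h) <= 0)) {
    stop("generator_config: timepoints_h must be strictly increasing")
  }
  if (any(cfg$timepoints_h <= 0)) {
    stop("generator_config: timepoint 0 is reserved for the baseline sample")
  }
  if (length(cfg$genes_per_family_range) != 2L ||
      cfg$genes_per_family_range[1] < 1L ||
      diff(cfg$genes_per_family_range) < 0L) {
    stop("generator_config: invalid genes_per_family_range")
  }
  if (cfg$nb_dispersion <= 0) stop("generator_config: nb_dispersion must be > 0")
  if (cfg$keystone_abundance_fraction <= 0 ||
      cfg$keystone_abundance_fraction > 1) {
    stop("generator_config: keystone_abundance_fraction must be in (0, 1]")
  }
  fr <- c(cfg$independent_high_fraction, cfg$enzyme_tag_fractions)
  if (any(fr < 0) || any(fr > 1) || sum(cfg$enzyme_tag_fractions) > 1) {
    stop("generator_config: fractions must lie in [0, 1]")
  }
  if (any(cfg$gene_length_range < 1L) || diff(cfg$gene_length_range) < 0L) {
    stop("generator_config: invalid gene_length_range")
  }
  invisible(cfg)
}

#' Sample design for the in sacco incubation layout
#'
#' One sample per (animal, timepoint), plus one baseline (0 h) sample under the
#' reserved animal id `"A0"` when `include_baseline` is set. Sample ids are
#' deterministic given the configuration (`"A<i>_T<h>"`).
#'
#' @param config A [generator_config()].
#' @return A `sample_design` data frame with columns `sample_id`, `animal_id`,
#'   `timepoint_h`.
#' @export
generate_design <- function(config) {
  validate_generator_config(config)
  animals <- sprintf("A%d", seq_len(config$n_animals))
  grid <- expand.grid(
    animal_id = animals, timepoint_h = config$timepoints_h,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$animal_id, grid$timepoint_h), , drop = FALSE]
  design <- data.frame(
    sample_id = sprintf("%s_T%g", grid$animal_id, grid$timepoint_h),
    animal_id = grid$animal_id,
    timepoint_h = grid$timepoint_h,
    stringsAsFactors = FALSE
  )
  if (config$include_baseline) {
    design <- rbind(
      data.frame(
        sample_id = "A0_T0", animal_id = "A0", timepoint_h = 0,
        stringsAsFactors = FALSE
      ),
      design
    )
  }
  rownames(design) <- NULL
  class(design) <- c("sample_design", "data.frame")
  design
}

.interp_template <- function(values, hours) {
  stats::approx(.template_hours, values, xout = hours, rule = 2)$y
}

# Reorder jittered trajectory values so their ranks match the template's ranks:
# magnitudes keep the jitter, rank structure stays exactly as planted.
.enforce_ranks <- function(x, template) {
  sort(x)[rank(template, ties.method = "first")]
}

#' Latent per-family mean trajectories
#'
#' Draws one mean trajectory per family over the design timepoints. Primary
#' trajectories peak at or before 4 h and are non-increasing afterwards;
#' secondary trajectories are non-decreasing from 4 h; by construction the rank
#' correlation between any primary and any secondary trajectory is at most
#' -0.7. Keystone trajectories equal `keystone_abundance_fraction` times their
#' block's template mean. Independent trajectories are constant plus jitter.
#'
#' @param config A [generator_config()].
#' @return A `latent_profiles` list: `trajectories` (family x timepoint matrix
#'   of latent total counts), `families` (data frame with `family`, `block`,
#'   `subtemplate`), `epiphyte_mean` (per-family baseline means), and the
#'   timepoints.
#' @export
generate_profiles <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  hours <- config$timepoints_h
  A <- config$base_abundance
  jit <- function(n) exp(stats::rnorm(n, 0, config$trajectory_jitter_sd))

  fam <- character(0)
  block <- character(0)
  subt <- character(0)
  rows <- list()

  add_block <- function(block_name, n_fam, n_key, prefix) {
    template <- .interp_template(.block_templates[[block_name]], hours)
    for (i in seq_len(n_fam)) {
      amp <- exp(stats::rnorm(1, 0, config$block_amplitude_sd))
      raw <- template * amp * A * jit(length(hours))
      traj <- .enforce_ranks(raw, template)
      rows[[length(rows) + 1L]] <<- traj
      fam <<- c(fam, sprintf("%s%02d", prefix, i))
      block <<- c(block, block_name)
      subt <<- c(subt, "member")
    }
    for (i in seq_len(n_key)) {
      rows[[length(rows) + 1L]] <<- config$keystone_abundance_fraction *
        template * A
      fam <<- c(fam, sprintf("%sK%02d", prefix, i))
      block <<- c(block, paste0("keystone-", block_name))
      subt <<- c(subt, "keystone")
    }
  }

  add_block("primary", config$n_primary_families,
            config$n_keystone_per_block, "Prim")
  add_block("secondary", config$n_secondary_families,
            config$n_keystone_per_block, "Seco")

  n_ind <- config$n_independent_families
  if (n_ind > 0) {
    n_high <- round(n_ind * config$independent_high_fraction)
    tier <- rep(c("high", "low"), c(n_high, n_ind - n_high))
    for (i in seq_len(n_ind)) {
      m <- if (tier[i] == "high") {
        exp(stats::runif(1, log(0.5), log(2.5))) * A
      } else {
        exp(stats::runif(1, log(0.03), log(0.06))) * A
      }
      rows[[length(rows) + 1L]] <- m * jit(length(hours))
      fam <- c(fam, sprintf("Indp%02d", i))
      block <- c(block, "independent")
      subt <- c(subt, tier[i])
    }
  }

  traj <- do.call(rbind, rows)
  dimnames(traj) <- list(fam, sprintf("T%g", hours))
  profiles <- list(
    trajectories = traj,
    families = data.frame(
      family = fam, block = block, subtemplate = subt,
      stringsAsFactors = FALSE
    ),
    epiphyte_mean = stats::setNames(
      exp(stats::runif(length(fam), log(0.002), log(0.02))) * A, fam
    ),
    timepoints_h = hours
  )
  class(profiles) <- "latent_profiles"
  profiles
}

#' Draw an annotated count table from latent profiles
#'
#' Counts are negative-binomial with mean = family trajectory at the sample's
#' timepoint x per-gene weight x per-(family, animal) effect x per-(family,
#' sample) biological overdispersion factor x library-size factor, and size
#' `nb_dispersion` (Poisson when `nb_dispersion = Inf`). The biological
#' overdispersion SD is drawn per family (see [generator_config()]); the
#' planted keystones get the smallest, which is what makes them the most
#' faithful trackers of their block trajectory and hence network connectors.
#' Within-family gene weights are Dirichlet(1). The baseline sample, if
#' present, is drawn from an unrelated flat epiphyte profile. Gene metadata
#' (family, genus, functional cluster, optional enzyme tag, length) is drawn
#' here; identical config and seed give a bit-identical table.
#'
#' @param profiles A `latent_profiles` object.
#' @param design A `sample_design`.
#' @param config The [generator_config()] both were generated from.
#' @param keep_latent Attach the latent gene x sample mean matrix as attribute
#'   `"latent_mean"` (for noise-model diagnostics).
#' @return An `expression_table`: list with integer `counts` (gene x sample)
#'   and `gene_meta`.
#' @export
generate_counts <- function(profiles, design, config, keep_latent = FALSE) {
  validate_generator_config(config)
  stopifnot(inherits(profiles, "latent_profiles"))
  if (!setequal(rownames(profiles$trajectories), profiles$families$family)) {
    stop("generate_counts: inconsistent family sets in profiles")
  }
  tp_lab <- sprintf("T%g", design$timepoint_h)
  non_base <- design$timepoint_h > 0
  if (!all(tp_lab[non_base] %in% colnames(profiles$trajectories))) {
    stop("generate_counts: design timepoints absent from profiles")
  }
  set.seed(config$seed + 1L)

  fams <- profiles$families$family
  n_genes <- sample(
    seq(config$genes_per_family_range[1], config$genes_per_family_range[2]),
    length(fams), replace = TRUE
  )
  gene_fam <- rep(fams, n_genes)
  n_total <- length(gene_fam)
  gene_id <- sprintf("g%05d", seq_len(n_total))

  # Dirichlet(1) weights within each family
  gam <- stats::rgamma(n_total, shape = 1)
  w <- gam / stats::ave(gam, gene_fam, FUN = sum)

  # genus: one per family by default, two for the first `two_genus_blocks`
  # block families (emulating a family split between two dominant genera)
  genus_of <- stats::setNames(paste0("g_", fams), fams)
  genus <- genus_of[gene_fam]
  block_fams <- profiles$families$family[
    profiles$families$block %in% c("primary", "secondary")
  ]
  if (config$two_genus_blocks > 0 && length(block_fams) > 0) {
    split_fams <- utils::head(block_fams, config$two_genus_blocks)
    for (f in split_fams) {
      idx <- which(gene_fam == f)
      second <- sample(idx, ceiling(length(idx) / 2))
      genus[second] <- paste0(genus_of[[f]], "_2")
    }
  }

  # enzyme tags, then functional clusters (tagged genes share umbrella clusters)
  tags <- config$enzyme_tag_fractions
  tag_draw <- sample(
    c(names(tags), NA_character_), n_total, replace = TRUE,
    prob = c(tags, 1 - sum(tags))
  )
  fc <- sprintf("FC%03d", sample(config$n_functional_clusters, n_total,
                                 replace = TRUE))
  fc[!is.na(tag_draw) & startsWith(tag_draw, "GH")] <- "FC_GH"
  fc[!is.na(tag_draw) & tag_draw == "LuxS"] <- "FC_QS"
  fc[!is.na(tag_draw) & !startsWith(tag_draw, "GH") &
       tag_draw != "LuxS"] <- "FC_peptidase"

  length_bp <- sample(
    seq(config$gene_length_range[1], config$gene_length_range[2]),
    n_total, replace = TRUE
  )

  animal_fac <- matrix(
    exp(stats::rnorm(length(fams) * config$n_animals, 0,
                     config$animal_effect_sd)),
    nrow = length(fams),
    dimnames = list(fams, sprintf("A%d", seq_len(config$n_animals)))
  )
  lib_fac <- stats::setNames(
    exp(stats::rnorm(nrow(design), config$libsize_logmean,
                     config$libsize_logsd)),
    design$sample_id
  )

  # per-family biological overdispersion SD: uniform within the tier's range;
  # keystones get a fixed small value
  blk <- profiles$families$block
  biol_sd <- stats::setNames(numeric(length(fams)), fams)
  member <- blk %in% c("primary", "secondary")
  indep <- blk == "independent"
  biol_sd[member] <- stats::runif(sum(member), config$biol_sd_range[1],
                                  config$biol_sd_range[2])
  biol_sd[indep] <- stats::runif(sum(indep),
                                 config$independent_biol_sd_range[1],
                                 config$independent_biol_sd_range[2])
  biol_sd[!member & !indep] <- config$keystone_biol_sd
  biol_fac <- matrix(
    exp(stats::rnorm(length(fams) * nrow(design), 0, biol_sd)),
    nrow = length(fams),
    dimnames = list(fams, design$sample_id)
  )

  mu <- matrix(0, nrow = n_total, ncol = nrow(design),
               dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    s <- design$sample_id[j]
    if (design$timepoint_h[j] > 0) {
      fam_mean <- profiles$trajectories[gene_fam, tp_lab[j]] *
        animal_fac[cbind(gene_fam, design$animal_id[j])] *
        biol_fac[cbind(gene_fam, s)]
    } else {
      fam_mean <- profiles$epiphyte_mean[gene_fam]
    }
    mu[, j] <- fam_mean * w * lib_fac[[s]]
  }

  counts <- if (is.infinite(config$nb_dispersion)) {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }
  storage.mode(counts) <- "integer"

  gene_meta <- data.frame(
    gene_id = gene_id,
    family = gene_fam,
    genus = unname(genus),
    functional_cluster = fc,
    enzyme_tag = tag_draw,
    length_bp = as.integer(length_bp),
    stringsAsFactors = FALSE
  )
  table <- expression_table(counts, gene_meta)
  if (keep_latent) attr(table, "latent_mean") <- mu
  table
}

#' Generate a complete synthetic bundle
#'
#' Convenience wrapper running [generate_design()], [generate_profiles()] and
#' [generate_counts()] with one configuration.
#'
#' @param config A [generator_config()].
#' @param keep_latent Passed to [generate_counts()].
#' @return List with `table` (`expression_table`), `design` (`sample_design`)
#'   and `profiles` (`latent_profiles`, the ground truth).
#' @export
simulate_bundle <- function(config = generator_config(), keep_latent = FALSE) {
  design <- generate_design(config)
  profiles <- generate_profiles(config)
  table <- generate_counts(profiles, design, config, keep_latent = keep_latent)
  list(table = table, design = design, profiles = profiles)
}
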