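# Dirichlet-multinomial simulator of faecal metabarcoding datasets with
# known truth: per-sample depth variation, Bernoulli prey incidence,
# compositional read shares, a dominant host-DNA OTU, and sub-threshold
# noise/contaminant OTUs exercising every exclusion path of the filter.

#' Define a simulated prey item
#'
#' @param name prey-item label as it will appear after genus-level collapse
#'   (e.g. `"Zacco sp."`).
#' @param prey_group `"fish"` or `"benthic_invertebrate"`.
#' @param occurrence_prob probability that the item occurs in a sample
#'   (Bernoulli incidence).
#' @param mean_diet_share mean compositional share of the item's reads among
#'   prey reads, conditional on occurrence; shares are renormalised over the
#'   items present in a sample.
#' @param n_otus number of OTUs the item's reads are split across (sequence
#'   variants / congeneric species sharing a genus).
#' @param identity_range BLAST percent-identity range for the item's hits.
#' @param otu_taxa taxon names for the item's OTUs; defaults to `name`
#'   (numbered when `n_otus > 1`).
#' @param field_mean expected number of individuals of the item in the field
#'   survey; `NA` marks a taxon absent from the survey (detected only by
#'   metabarcoding).
#' @param survey_species binomial recorded in the survey for this genus;
#'   `NA` records the survey entry at genus level only.
#' @return list of class `prey_profile`.
#' @export
prey_profile <- function(name, prey_group, occurrence_prob, mean_diet_share,
                         n_otus = 1L, identity_range = c(98, 100),
                         otu_taxa = NULL, field_mean = NA_real_,
                         survey_species = NA_character_) {
  prey_group <- match.arg(prey_group, PREY_GROUPS)
  stopifnot(
    occurrence_prob >= 0, occurrence_prob <= 1,
    mean_diet_share > 0, n_otus >= 1L,
    length(identity_range) == 2L, identity_range[1] <= identity_range[2]
  )
  if (is.null(otu_taxa)) {
    otu_taxa <- if (n_otus == 1L) name else paste(name, seq_len(n_otus))
  }
  stopifnot(length(otu_taxa) == n_otus)
  structure(
    list(
      name = name, prey_group = prey_group,
      occurrence_prob = occurrence_prob, mean_diet_share = mean_diet_share,
      n_otus = as.integer(n_otus), identity_range = identity_range,
      otu_taxa = otu_taxa, field_mean = field_mean,
      survey_species = survey_species
    ),
    class = "prey_profile"
  )
}

#' Default prey profiles
#'
#' Thirteen genus-level prey items in two groups (six fish, seven benthic
#' invertebrates), structured like the diet of a small ambush-predator fish
#' in a Korean stream: one dominant cyprinid prey, a tail of occasional
#' items, two items represented by two OTUs each (so the species-level table
#' has 15 taxa), two faecal-only taxa per group, and one genus whose
#' reference-database species does not occur locally (exercising the
#' demotion rule).
#'
#' @return list of [prey_profile()] objects.
#' @export
default_prey_profiles <- function() {
  list(
    prey_profile("Zacco sp.", "fish", 0.95, 0.45,
      n_otus = 2L,
      otu_taxa = c("Zacco sp. 1", "Zacco sp. 2"),
      identity_range = c(98.5, 100), field_mean = 150,
      survey_species = "Zacco temminckii"
    ),
    prey_profile("Rhinogobius sp.", "fish", 0.55, 0.05,
      otu_taxa = "Rhinogobius brunneus", field_mean = 60,
      survey_species = "Rhinogobius brunneus"
    ),
    prey_profile("Micropterus sp.", "fish", 0.35, 0.06,
      otu_taxa = "Micropterus salmoides"
    ),
    prey_profile("Misgurnus sp.", "fish", 0.30, 0.04,
      otu_taxa = "Misgurnus anguillicaudatus", field_mean = 10,
      survey_species = "Misgurnus anguillicaudatus"
    ),
    prey_profile("Carassius sp.", "fish", 0.25, 0.03,
      otu_taxa = "Carassius cuvieri", field_mean = 15,
      survey_species = "Carassius cuvieri"
    ),
    prey_profile("Hemibarbus sp.", "fish", 0.20, 0.02,
      otu_taxa = "Hemibarbus labeo"
    ),
    prey_profile("Ephemera sp.", "benthic_invertebrate", 0.50, 0.12,
      otu_taxa = "Ephemera orientalis", field_mean = 40,
      survey_species = "Ephemera orientalis"
    ),
    prey_profile("Polypedilum sp.", "benthic_invertebrate", 0.60, 0.09,
      n_otus = 2L,
      otu_taxa = c("Polypedilum japonicum", "Polypedilum yongsanensis"),
      field_mean = 80
    ),
    prey_profile("Cricotopus sp.", "benthic_invertebrate", 0.20, 0.07,
      otu_taxa = "Cricotopus triannulatus", field_mean = 30
    ),
    prey_profile("Chironomus sp.", "benthic_invertebrate", 0.25, 0.03,
      otu_taxa = "Chironomus flaviplumus", field_mean = 90,
      survey_species = "Chironomus flaviplumus"
    ),
    prey_profile("Platycnemis sp.", "benthic_invertebrate", 0.15, 0.02,
      otu_taxa = "Platycnemis phyllopoda"
    ),
    # reference database only holds a congener that does not occur locally:
    # the survey records Radix auricularia, so "Radix plicatula" is demoted
    prey_profile("Radix sp.", "benthic_invertebrate", 0.17, 0.015,
      otu_taxa = "Radix plicatula", field_mean = 25,
      survey_species = "Radix auricularia"
    ),
    prey_profile("Limnodrilus sp.", "benthic_invertebrate", 0.12, 0.015,
      otu_taxa = "Limnodrilus sp.", field_mean = 12
    )
  )
}

#' Simulator configuration
#'
#' Defaults emulate the scale of a 24-sample faecal COI metabarcoding run on
#' an Illumina MiSeq: about 3.1e5 reads per sample with strong per-sample
#' depth variation, a majority of reads from the predator's own DNA (no
#' blocking primers), and a sub-threshold cloud of contaminant/no-match
#' OTUs.
#'
#' @param n_samples number of faecal samples S.
#' @param depth_mean mean per-sample read depth.
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution (smaller = more variable).
#' @param depth_model `"nbinom"` (default) or `"lognormal"`.
#' @param depth_sdlog sd of log depth when `depth_model = "lognormal"`.
#' @param host_fraction expected fraction of each sample's reads from the
#'   host taxon.
#' @param noise_otu_count number of noise OTUs.
#' @param noise_share expected total fraction of reads spread across all
#'   noise OTUs; with the default 200 OTUs sharing 0.5% of reads every
#'   noise OTU sits well below the 0.01% relative read threshold.
#' @param dirichlet_concentration Dirichlet concentration of per-sample prey
#'   compositions around the profile mean shares (larger = less
#'   between-sample variation).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 24L,
                             depth_mean = 311858,
                             depth_dispersion = 5,
                             depth_model = c("nbinom", "lognormal"),
                             depth_sdlog = 0.5,
                             host_fraction = 0.55,
                             noise_otu_count = 200L,
                             noise_share = 0.005,
                             dirichlet_concentration = 20,
                             seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(
    n_samples >= 1L, depth_mean > 0, depth_dispersion > 0,
    host_fraction >= 0, host_fraction < 1,
    noise_share >= 0, noise_share < 1,
    host_fraction + noise_share < 1,
    noise_otu_count >= 0L, dirichlet_concentration > 0
  )
  structure(
    list(
      n_samples = as.integer(n_samples), depth_mean = depth_mean,
      depth_dispersion = depth_dispersion, depth_model = depth_model,
      depth_sdlog = depth_sdlog, host_fraction = host_fraction,
      noise_otu_count = as.integer(noise_otu_count),
      noise_share = noise_share,
      dirichlet_concentration = dirichlet_concentration,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Genera added to the synthetic field survey but never to the diet,
# producing field-only records (D = -1 rows).
FIELD_ONLY_FISH <- c("Odontobutis", "Pseudogobio", "Squalidus", "Oryzias")
FIELD_ONLY_BENTHIC <- c("Baetis", "Hydropsyche", "Gammarus", "Semisulcospira", "Physa")

#' Generate a synthetic faecal-metabarcoding dataset
#'
#' For each sample: a read depth is drawn; prey incidence is Bernoulli per
#' item (all-zero samples are re-drawn so S stays as configured); the prey
#' composition is Dirichlet around the present items' normalised mean
#' shares; reads are then allocated multinomially among the host OTU, the
#' noise OTUs and the prey OTUs (each item's reads split across its OTUs).
#' Taxonomy hits carry identities from each profile's range; noise OTUs are
#' assigned in fixed proportions to the "no match", absent-from-file,
#' non-prey-contaminant and below-identity exclusion paths. The field survey
#' holds Poisson counts for surveyed profiles plus field-only taxa.
#'
#' @param config a [synthetic_config()].
#' @param profiles list of [prey_profile()]s.
#' @return list with `counts` (a `read_count_table`), `hits`
#'   (`taxonomy_hits`), `survey` (`field_survey`) and `truth` (incidence
#'   matrix, per-sample true compositions, expected %FOO `100 * psi`,
#'   expected mean diet shares, OTU bookkeeping).
#' @export
generate_dataset <- function(config = synthetic_config(),
                             profiles = default_prey_profiles()) {
  stopifnot(inherits(config, "synthetic_config"), length(profiles) >= 1L)
  set.seed(config$seed)
  S <- config$n_samples
  P <- length(profiles)
  psi <- vapply(profiles, `[[`, numeric(1L), "occurrence_prob")
  if (all(psi == 0)) stop("all occurrence probabilities are zero", call. = FALSE)
  item_names <- vapply(profiles, `[[`, character(1L), "name")
  groups <- vapply(profiles, `[[`, character(1L), "prey_group")
  shares <- vapply(profiles, `[[`, numeric(1L), "mean_diet_share")
  shares <- shares / sum(shares)

  # per-sample sequencing depth
  depth <- switch(config$depth_model,
    nbinom = stats::rnbinom(S, mu = config$depth_mean, size = config$depth_dispersion),
    lognormal = round(stats::rlnorm(
      S,
      meanlog = log(config$depth_mean) - config$depth_sdlog^2 / 2,
      sdlog = config$depth_sdlog
    ))
  )
  depth <- pmax(depth, 1000)

  # incidence, re-drawing samples in which no prey occurred
  incidence <- matrix(
    stats::rbinom(S * P, 1L, rep(psi, each = S)) == 1L,
    nrow = S, ncol = P
  )
  n_resampled <- 0L
  while (any(rowSums(incidence) == 0)) {
    empty <- which(rowSums(incidence) == 0)
    n_resampled <- n_resampled + length(empty)
    incidence[empty, ] <- matrix(
      stats::rbinom(length(empty) * P, 1L, rep(psi, each = length(empty))) == 1L,
      nrow = length(empty), ncol = P
    )
  }

  # OTU universe: prey OTUs, one host OTU, noise OTUs
  n_otus_per <- vapply(profiles, `[[`, integer(1L), "n_otus")
  n_prey_otus <- sum(n_otus_per)
  n_noise <- config$noise_otu_count
  n_total <- n_prey_otus + 1L + n_noise
  otu_ids <- sprintf("OTU_%04d", seq_len(n_total))
  prey_otu_ids <- otu_ids[seq_len(n_prey_otus)]
  host_otu <- otu_ids[n_prey_otus + 1L]
  noise_otus <- otu_ids[(n_prey_otus + 2L):n_total]
  otu_item <- rep(seq_len(P), n_otus_per)

  # within-item OTU weights and global noise weights, drawn once
  otu_w <- unlist(lapply(n_otus_per, function(k) {
    if (k == 1L) 1 else rdirichlet1(rep(4, k))
  }))
  noise_w <- if (n_noise > 0) rdirichlet1(rep(10, n_noise)) else numeric(0)

  prey_frac <- 1 - config$host_fraction - config$noise_share
  composition <- matrix(0, nrow = S, ncol = P, dimnames = list(NULL, item_names))
  counts <- matrix(0L,
    nrow = S, ncol = n_total,
    dimnames = list(sprintf("S%02d", seq_len(S)), otu_ids)
  )
  for (k in seq_len(S)) {
    present <- which(incidence[k, ])
    alpha <- config$dirichlet_concentration * shares[present] / sum(shares[present])
    comp <- rdirichlet1(alpha)
    composition[k, present] <- comp
    prob <- numeric(n_total)
    prob[seq_len(n_prey_otus)] <-
      prey_frac * composition[k, otu_item] * otu_w
    prob[n_prey_otus + 1L] <- config$host_fraction
    if (n_noise > 0) prob[(n_prey_otus + 2L):n_total] <- config$noise_share * noise_w
    counts[k, ] <- stats::rmultinom(1L, depth[k], prob)[, 1L]
  }
  table <- as_read_count_table(counts)

  # taxonomy hits
  prey_taxa <- unlist(lapply(profiles, `[[`, "otu_taxa"))
  id_lo <- rep(vapply(profiles, function(p) p$identity_range[1], numeric(1L)), n_otus_per)
  id_hi <- rep(vapply(profiles, function(p) p$identity_range[2], numeric(1L)), n_otus_per)
  prey_identity <- round(stats::runif(n_prey_otus, id_lo, id_hi), 1)
  hits <- data.frame(
    otu_id = c(prey_otu_ids, host_otu),
    taxon = c(prey_taxa, "Odontobutis obscurus"),
    percent_identity = c(prey_identity, 100),
    query_coverage_pct = 100,
    max_score = round(stats::runif(n_prey_otus + 1L, 520, 580)),
    accession = sprintf("SYN%05d.1", seq_len(n_prey_otus + 1L)),
    stringsAsFactors = FALSE
  )
  if (n_noise > 0) {
    # fixed proportions over the four exclusion paths
    kind <- rep(c("no_match", "absent", "nonprey", "low_identity"),
      times = diff(round(n_noise * c(0, 0.4, 0.6, 0.8, 1)))
    )
    nonprey_pool <- c(
      "Bos taurus", "Aspergillus fumigatus", "Phytophthora infestans",
      "Saccharomyces cerevisiae", "Fusarium oxysporum"
    )
    noise_rows <- data.frame(
      otu_id = noise_otus,
      taxon = "no match",
      percent_identity = NA_real_,
      query_coverage_pct = NA_real_,
      max_score = NA_real_,
      accession = NA_character_,
      stringsAsFactors = FALSE
    )
    is_np <- kind == "nonprey"
    noise_rows$taxon[is_np] <- rep_len(nonprey_pool, sum(is_np))
    noise_rows$percent_identity[is_np] <- round(stats::runif(sum(is_np), 97, 100), 1)
    noise_rows$query_coverage_pct[is_np] <- 100
    is_li <- kind == "low_identity"
    noise_rows$taxon[is_li] <- rep_len(prey_taxa, sum(is_li))
    noise_rows$percent_identity[is_li] <- round(stats::runif(sum(is_li), 88, 96.5), 1)
    noise_rows$query_coverage_pct[is_li] <- 100
    noise_rows <- noise_rows[kind != "absent", , drop = FALSE]
    hits <- rbind(hits, noise_rows)
  }
  hits <- as_taxonomy_hits(hits)

  # field survey: surveyed profiles + field-only taxa
  fm <- vapply(profiles, `[[`, numeric(1L), "field_mean")
  surveyed <- which(!is.na(fm))
  survey <- data.frame(
    group = c(
      groups[surveyed],
      rep("fish", length(FIELD_ONLY_FISH)),
      rep("benthic_invertebrate", length(FIELD_ONLY_BENTHIC))
    ),
    genus = c(
      genus_of(item_names[surveyed]),
      FIELD_ONLY_FISH, FIELD_ONLY_BENTHIC
    ),
    species = c(
      vapply(profiles[surveyed], `[[`, character(1L), "survey_species"),
      rep(NA_character_, length(FIELD_ONLY_FISH) + length(FIELD_ONLY_BENTHIC))
    ),
    count = c(
      1L + stats::rpois(length(surveyed), fm[surveyed]),
      1L + stats::rpois(
        length(FIELD_ONLY_FISH) + length(FIELD_ONLY_BENTHIC), 20
      )
    ),
    stringsAsFactors = FALSE
  )
  survey <- as_field_survey(survey)

  truth <- list(
    item_names = item_names,
    prey_group = groups,
    occurrence_prob = psi,
    expected_pct_foo = 100 * psi,
    expected_share = shares,
    incidence = incidence,
    composition = composition,
    depth = depth,
    host_otu = host_otu,
    noise_otus = noise_otus,
    prey_otus = prey_otu_ids,
    n_samples_resampled = n_resampled
  )
  list(counts = table, hits = hits, survey = survey, truth = truth)
}

#' Compare pipeline estimates with simulation truth
#'
#' Per prey item: the deviation of the estimated %FOO from its expected
#' value `100 * psi` (with the binomial standard error
#' `100 * sqrt(psi (1 - psi) / S)`), and of the estimated %RRA from the
#' expected mean diet share. Note the RRA expectation is exact only when all
#' items co-occur (`psi = 1`); with partial occupancy the renormalisation
#' over present items shifts per-sample shares upward.
#'
#' @param truth the `truth` element of [generate_dataset()] output.
#' @param metrics a [metrics_report()] computed on the same dataset after
#'   the full filter pipeline.
#' @return data frame with per-item expected/observed values, deviations
#'   and the FOO standard error.
#' @export
recovery_report <- function(truth, metrics) {
  unknown <- setdiff(metrics$item, truth$item_names)
  if (length(unknown)) {
    stop(
      "metrics contain item(s) absent from the simulation truth: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  S <- nrow(truth$incidence)
  idx <- match(truth$item_names, metrics$item)
  obs_foo <- ifelse(is.na(idx), 0, metrics$pct_foo[idx])
  obs_rra <- ifelse(is.na(idx), 0, metrics$pct_rra[idx])
  data.frame(
    item = truth$item_names,
    expected_pct_foo = truth$expected_pct_foo,
    observed_pct_foo = obs_foo,
    foo_deviation = obs_foo - truth$expected_pct_foo,
    foo_se = 100 * sqrt(truth$occurrence_prob * (1 - truth$occurrence_prob) / S),
    expected_pct_share = 100 * truth$expected_share,
    observed_pct_rra = obs_rra,
    rra_deviation = obs_rra - 100 * truth$expected_share,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `survey.tsv` and `truth.json` so the
#' pipeline can be run end-to-end from files.
#'
#' @param config a [synthetic_config()].
#' @param profiles list of [prey_profile()]s.
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
simulate_to_dir <- function(config = synthetic_config(),
                            profiles = default_prey_profiles(),
                            dir = ".") {
  dat <- generate_dataset(config, profiles)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    survey = file.path(dir, "survey.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_count_table(dat$counts, paths[["counts"]])
  write_result_tsv(as.data.frame(dat$hits), paths[["taxonomy"]])
  write_result_tsv(as.data.frame(dat$survey), paths[["survey"]])
  jsonlite::write_json(
    dat$truth, paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
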