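# Quality-filter cascade: relative read-count threshold, identity/host/
# contaminant exclusion, harmonisation with the field-survey species list,
# and collapse to a genus-level prey table.

#' Default genus-to-prey-group map
#'
#' Covers the fish and benthic macroinvertebrate genera expected in COI diet
#' metabarcoding of a Korean stream predator. Extend or replace via
#' [filter_config()] for other systems.
#'
#' @return named character vector mapping genus to prey group.
#' @export
default_prey_group_map <- function() {
  c(
    # fish
    Micropterus = "fish", Misgurnus = "fish", Carassius = "fish",
    Zacco = "fish", Rhinogobius = "fish", Hemibarbus = "fish",
    Odontobutis = "fish", Pseudogobio = "fish", Squalidus = "fish",
    Pungtungia = "fish", Oryzias = "fish", Anguilla = "fish",
    Tridentiger = "fish", Cyprinus = "fish", Opsariichthys = "fish",
    # benthic invertebrates
    Chironomus = "benthic_invertebrate", Cricotopus = "benthic_invertebrate",
    Polypedilum = "benthic_invertebrate", Ephemera = "benthic_invertebrate",
    Platycnemis = "benthic_invertebrate", Radix = "benthic_invertebrate",
    Limnodrilus = "benthic_invertebrate", Baetis = "benthic_invertebrate",
    Hydropsyche = "benthic_invertebrate", Gammarus = "benthic_invertebrate",
    Caridina = "benthic_invertebrate", Semisulcospira = "benthic_invertebrate",
    Physa = "benthic_invertebrate", Tubifex = "benthic_invertebrate"
  )
}

#' Default Chironomidae genus list
#'
#' Genera merged to the family-level item "Chironomidae" when comparing
#' faecal detections with field surveys, where midge larvae are typically
#' identified only to family.
#'
#' @return character vector of genus names.
#' @export
default_chironomidae_genera <- function() {
  c(
    "Chironomus", "Cricotopus", "Polypedilum", "Tanytarsus", "Tanypus",
    "Orthocladius", "Procladius", "Paratanytarsus", "Rheotanytarsus",
    "Glyptotendipes", "Stictochironomus", "Microtendipes", "Dicrotendipes",
    "Einfeldia"
  )
}

#' Filtering configuration
#'
#' @param min_relative_reads minimum dataset-wide relative read share for an
#'   OTU to be kept (default 1e-4, i.e. 0.01% of all reads; removes
#'   low-level background noise such as secondary predation, contamination
#'   and sequencing error).
#' @param min_identity minimum BLAST percent identity for a taxonomic
#'   assignment to be trusted (default 97).
#' @param host_taxon the predator itself; its OTUs are excluded (default
#'   `"Odontobutis obscurus"`).
#' @param nonprey_exclusions taxa or genera that are not plausible prey
#'   (fungi, Chromista, livestock contamination, ...); matched
#'   case-insensitively against the full taxon name and its genus token.
#' @param min_coverage optional minimum query coverage percent; `NULL`
#'   (default) disables the check.
#' @param per_sample_threshold if `TRUE`, the read threshold is applied per
#'   sample (cells below the per-sample cutoff are zeroed) instead of against
#'   the dataset-wide total.
#' @param collapse_rank rank at which prey items are reported,
#'   `"genus"` (default) or `"species"`.
#' @param group_map named character vector genus -> prey group.
#' @param chironomidae_genera genera merged to family Chironomidae in
#'   selectivity and overlap analyses.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_relative_reads = 1e-4,
                          min_identity = 97,
                          host_taxon = "Odontobutis obscurus",
                          nonprey_exclusions = c(
                            "Bos taurus", "Fungi", "Chromista",
                            "Aspergillus", "Penicillium", "Saccharomyces",
                            "Fusarium", "Candida", "Mucor",
                            "Phytophthora", "Saprolegnia"
                          ),
                          min_coverage = NULL,
                          per_sample_threshold = FALSE,
                          collapse_rank = c("genus", "species"),
                          group_map = default_prey_group_map(),
                          chironomidae_genera = default_chironomidae_genera()) {
  collapse_rank <- match.arg(collapse_rank)
  stopifnot(
    is.numeric(min_relative_reads), length(min_relative_reads) == 1L,
    min_relative_reads >= 0, min_relative_reads < 1,
    is.numeric(min_identity), min_identity >= 0, min_identity <= 100
  )
  if (!is.null(min_coverage)) {
    stopifnot(is.numeric(min_coverage), min_coverage >= 0, min_coverage <= 100)
  }
  if (is.null(names(group_map)) || !all(group_map %in% PREY_GROUPS)) {
    stop("group_map must be a named vector of values in ",
      paste(PREY_GROUPS, collapse = "/"),
      call. = FALSE
    )
  }
  structure(
    list(
      min_relative_reads = min_relative_reads,
      min_identity = min_identity,
      host_taxon = host_taxon,
      nonprey_exclusions = nonprey_exclusions,
      min_coverage = min_coverage,
      per_sample_threshold = per_sample_threshold,
      collapse_rank = collapse_rank,
      group_map = group_map,
      chironomidae_genera = chironomidae_genera
    ),
    class = "filter_config"
  )
}

# First whitespace-delimited token of a taxon name.
genus_of <- function(taxon) {
  vapply(strsplit(trimws(taxon), "\\s+"), `[[`, character(1L), 1L)
}

# "Zacco sp." / "Zacco sp. 2" are genus-rank morphotaxa, binomials are
# species-rank.
taxon_rank <- function(taxon) {
  ifelse(grepl("^\\S+\\s+sp\\.?(\\s|$)", trimws(taxon)), "genus", "species")
}

#' Apply the relative read-count threshold
#'
#' Removes OTUs whose dataset-wide read sum falls below
#' `min_relative_reads` of the table's total read count (the cutoff is
#' computed once from the input table). The comparison is `>=`: an OTU
#' sitting exactly on the threshold is kept. With `per_sample = TRUE` the
#' threshold is instead applied within each sample and sub-threshold cells
#' are zeroed before all-zero OTUs are dropped.
#'
#' @param table a `read_count_table`.
#' @param min_relative_reads fraction in \[0, 1).
#' @param per_sample logical, see above.
#' @return list with elements `table` (the thresholded `read_count_table`)
#'   and `audit` (data frame: `otu_id`, `reads`, `relative_share`, `kept`).
#' @export
apply_read_threshold <- function(table, min_relative_reads = 1e-4,
                                 per_sample = FALSE) {
  stopifnot(inherits(table, "read_count_table"))
  stopifnot(min_relative_reads >= 0, min_relative_reads < 1)
  counts <- table$counts
  otu_reads <- colSums(counts)
  share <- otu_reads / table$total_reads
  if (per_sample) {
    sample_tot <- rowSums(counts)
    cutoff <- sample_tot * min_relative_reads
    counts[counts < cutoff] <- 0
    keep <- colSums(counts) > 0
  } else {
    keep <- share >= min_relative_reads & otu_reads > 0
  }
  audit <- data.frame(
    otu_id = table$otu_ids,
    reads = otu_reads,
    relative_share = share,
    kept = keep,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!any(keep)) stop("read threshold removed every OTU", call. = FALSE)
  list(
    table = as_read_count_table(counts[, keep, drop = FALSE]),
    audit = audit
  )
}

ASSIGN_REASONS <- c(
  "below_read_threshold", "below_identity", "below_coverage", "host",
  "no_match", "nonprey", "kept_species", "kept_demoted_to_genus"
)

#' Assign taxa to OTUs and apply identity/host/contaminant exclusions
#'
#' Each OTU is either dropped with a reason (`no_match`, `host`,
#' `below_identity`, optionally `below_coverage`, `nonprey`) or provisionally
#' kept with its prey group inferred from the genus-to-group map. OTUs
#' present in `otu_ids` but absent from `hits` are synthesised as
#' `"no match"` rather than erroring, since an unidentifiable OTU is an
#' expected outcome of the database search.
#'
#' @param hits a `taxonomy_hits` data frame (one best hit per OTU).
#' @param config a [filter_config()].
#' @param otu_ids optional full OTU universe; defaults to `hits$otu_id`.
#' @return data frame of assignments: `otu_id`, `taxon`, `percent_identity`,
#'   `genus`, `rank`, `final_taxon`, `prey_group`, `status`, `reason`,
#'   `survey_absent`.
#' @export
assign_taxa <- function(hits, config = filter_config(), otu_ids = NULL) {
  hits <- as_taxonomy_hits(hits)
  if (is.null(otu_ids)) otu_ids <- hits$otu_id
  missing_ids <- setdiff(otu_ids, hits$otu_id)
  if (length(missing_ids)) {
    synth <- data.frame(
      otu_id = missing_ids, taxon = "no match",
      percent_identity = NA_real_, query_coverage_pct = NA_real_,
      max_score = NA_real_, accession = NA_character_,
      stringsAsFactors = FALSE
    )
    hits <- as_taxonomy_hits(rbind(as.data.frame(hits), synth))
  }
  hits <- hits[match(otu_ids, hits$otu_id), , drop = FALSE]

  n <- nrow(hits)
  status <- rep("kept", n)
  reason <- rep("kept_species", n)
  excl <- tolower(config$nonprey_exclusions)
  taxon_lc <- tolower(hits$taxon)
  genus <- genus_of(hits$taxon)
  rank <- taxon_rank(hits$taxon)

  is_no_match <- taxon_lc == "no match"
  is_host <- taxon_lc == tolower(config$host_taxon)
  is_low_id <- !is_no_match & !is_host &
    (is.na(hits$percent_identity) | hits$percent_identity < config$min_identity)
  is_low_cov <- rep(FALSE, n)
  if (!is.null(config$min_coverage)) {
    is_low_cov <- !is_no_match & !is_host & !is_low_id &
      (is.na(hits$query_coverage_pct) |
        hits$query_coverage_pct < config$min_coverage)
  }
  is_nonprey <- !is_no_match & !is_host & !is_low_id & !is_low_cov &
    (taxon_lc %in% excl | tolower(genus) %in% excl)

  status[is_no_match | is_host | is_low_id | is_low_cov | is_nonprey] <- "dropped"
  reason[is_no_match] <- "no_match"
  reason[is_host] <- "host"
  reason[is_low_id] <- "below_identity"
  reason[is_low_cov] <- "below_coverage"
  reason[is_nonprey] <- "nonprey"

  prey_group <- rep(NA_character_, n)
  kept <- status == "kept"
  if (any(kept)) {
    pg <- unname(config$group_map[genus[kept]])
    if (anyNA(pg)) {
      stop(
        "no prey-group mapping for kept taxon(s): ",
        paste(unique(hits$taxon[kept][is.na(pg)]), collapse = ", "),
        call. = FALSE
      )
    }
    prey_group[kept] <- pg
  }

  data.frame(
    otu_id = hits$otu_id,
    taxon = hits$taxon,
    percent_identity = hits$percent_identity,
    genus = ifelse(is_no_match, NA_character_, genus),
    rank = ifelse(kept, rank, NA_character_),
    final_taxon = ifelse(kept, hits$taxon, NA_character_),
    prey_group = prey_group,
    status = status,
    reason = reason,
    survey_absent = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Harmonise species-level assignments with the field survey
#'
#' A kept species that is not recorded in the field survey is considered a
#' database artefact (the true local congener lacks a reference sequence)
#' and is demoted to the genus-level morphotaxon `"<Genus> sp."`. Species
#' whose genus is also absent from the survey are still kept at genus rank
#' but flagged (`survey_absent`), since metabarcoding can legitimately detect
#' taxa the survey missed.
#'
#' @param assignments output of [assign_taxa()].
#' @param survey a `field_survey` data frame.
#' @return assignments with demotions applied.
#' @export
harmonise_with_field_survey <- function(assignments, survey) {
  survey <- as_field_survey(as.data.frame(survey))
  survey_species <- tolower(trimws(survey$species[!is.na(survey$species)]))
  survey_genera <- tolower(trimws(survey$genus))
  target <- assignments$status == "kept" & assignments$rank == "species"
  for (i in which(target)) {
    if (tolower(assignments$final_taxon[i]) %in% survey_species) next
    assignments$final_taxon[i] <- paste(assignments$genus[i], "sp.")
    assignments$rank[i] <- "genus"
    assignments$reason[i] <- "kept_demoted_to_genus"
    if (!(tolower(assignments$genus[i]) %in% survey_genera)) {
      assignments$survey_absent[i] <- TRUE
    }
  }
  assignments
}

#' Construct a prey table
#'
#' @param counts samples x items matrix of non-negative integer read counts.
#' @param items data frame with columns `item`, `prey_group`, `genus`
#'   matching the matrix columns.
#' @return object of class `prey_table`.
#' @export
as_prey_table <- function(counts, items) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(items))
  if (anyDuplicated(items$item)) stop("duplicate prey item names", call. = FALSE)
  colnames(counts) <- items$item
  validate_count_matrix(counts)
  empty <- rowSums(counts) == 0
  if (all(empty)) stop("no samples with prey reads", call. = FALSE)
  if (any(empty)) {
    warning(
      sprintf(
        "dropping %d sample(s) with zero prey reads: %s",
        sum(empty), paste(rownames(counts)[empty], collapse = ", ")
      ),
      call. = FALSE
    )
    counts <- counts[!empty, , drop = FALSE]
  }
  structure(
    list(
      counts = counts,
      items = as.data.frame(items, stringsAsFactors = FALSE),
      sample_ids = rownames(counts),
      n_samples = nrow(counts),
      n_items = ncol(counts)
    ),
    class = "prey_table"
  )
}

#' @export
print.prey_table <- function(x, ...) {
  cat(
    sprintf(
      "prey_table: %d samples x %d prey items (%s reads)\n",
      x$n_samples, x$n_items, format(sum(x$counts), big.mark = ",")
    )
  )
  invisible(x)
}

#' Collapse kept OTUs to a prey table
#'
#' Reads of all kept OTUs mapping to the same final prey item are summed per
#' sample. At `rank = "genus"` every kept OTU maps to `"<Genus> sp."`, so
#' congeneric morphotaxa and species merge into one item; at
#' `rank = "species"` the harmonised taxon names are used as-is. Samples
#' left without any prey reads are dropped with a warning.
#'
#' @param table the (thresholded) `read_count_table`.
#' @param assignments finalised assignments from
#'   [harmonise_with_field_survey()] (or [assign_taxa()]).
#' @param rank `"genus"` or `"species"`.
#' @return a `prey_table`.
#' @export
collapse_to_prey_table <- function(table, assignments,
                                   rank = c("genus", "species")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "read_count_table"))
  kept <- assignments[assignments$status == "kept" &
    assignments$otu_id %in% table$otu_ids, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no kept OTUs to collapse", call. = FALSE)
  item <- if (rank == "genus") {
    paste(kept$genus, "sp.")
  } else {
    kept$final_taxon
  }
  groups <- tapply(kept$prey_group, item, function(g) unique(g))
  if (any(lengths(groups) > 1L)) {
    stop(
      "conflicting prey groups within item(s): ",
      paste(names(groups)[lengths(groups) > 1L], collapse = ", "),
      call. = FALSE
    )
  }
  item_names <- sort(unique(item))
  m <- matrix(0,
    nrow = length(table$sample_ids), ncol = length(item_names),
    dimnames = list(table$sample_ids, item_names)
  )
  for (j in seq_len(nrow(kept))) {
    m[, item[j]] <- m[, item[j]] + table$counts[, kept$otu_id[j]]
  }
  items <- data.frame(
    item = item_names,
    prey_group = vapply(groups[item_names], `[[`, character(1L), 1L),
    genus = genus_of(item_names),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  as_prey_table(m, items)
}

#' Run the full quality-filter cascade
#'
#' In order: (1) dataset-wide relative read-count threshold, (2) taxonomy
#' assignment with identity/host/no-match/non-prey exclusion, (3) optional
#' harmonisation against the field survey, (4) collapse to the configured
#' rank. The stage order matters: the threshold cutoff is computed from the
#' raw total including host and contaminant reads.
#'
#' @param table raw `read_count_table`.
#' @param hits `taxonomy_hits`.
#' @param survey optional `field_survey` for harmonisation.
#' @param config a [filter_config()].
#' @return list with `prey` (a `prey_table`), `assignments`, `audit` (one
#'   row per input OTU: `otu_id`, `reads`, `relative_share`, `taxon`,
#'   `identity`, `status`, `reason`, `final_item`), and `thresholded` (the
#'   post-threshold `read_count_table`).
#' @export
filter_pipeline <- function(table, hits, survey = NULL,
                            config = filter_config()) {
  thr <- apply_read_threshold(table, config$min_relative_reads,
    per_sample = config$per_sample_threshold
  )
  assignments <- assign_taxa(hits, config, otu_ids = thr$table$otu_ids)
  if (!is.null(survey)) {
    assignments <- harmonise_with_field_survey(assignments, survey)
  }
  prey <- collapse_to_prey_table(thr$table, assignments, config$collapse_rank)

  hits_all <- as_taxonomy_hits(hits)
  idx <- match(thr$audit$otu_id, hits_all$otu_id)
  taxon <- ifelse(is.na(idx), "no match", hits_all$taxon[idx])
  identity <- ifelse(is.na(idx), NA_real_, hits_all$percent_identity[idx])
  aidx <- match(thr$audit$otu_id, assignments$otu_id)
  final_item <- rep(NA_character_, nrow(thr$audit))
  kept_rank <- config$collapse_rank
  kept_rows <- !is.na(aidx) & assignments$status[aidx] == "kept"
  final_item[kept_rows] <- if (kept_rank == "genus") {
    paste(assignments$genus[aidx[kept_rows]], "sp.")
  } else {
    assignments$final_taxon[aidx[kept_rows]]
  }
  audit <- data.frame(
    otu_id = thr$audit$otu_id,
    reads = thr$audit$reads,
    relative_share = thr$audit$relative_share,
    taxon = taxon,
    identity = identity,
    status = ifelse(thr$audit$kept, assignments$status[aidx], "dropped"),
    reason = ifelse(thr$audit$kept, assignments$reason[aidx],
      "below_read_threshold"
    ),
    final_item = final_item,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(
    prey = prey, assignments = assignments, audit = audit,
    thresholded = thr$table
  )
}
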