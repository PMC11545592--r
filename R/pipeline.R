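# End-to-end orchestration: read inputs, run the filter cascade and every
# downstream analysis, write all result tables plus a JSON run manifest.
# A thin command-line wrapper over run_pipeline()/simulate_to_dir() is
# installed under exec/fecaldiet.

PIPELINE_OUTPUTS <- c(
  "filter_audit.tsv", "metrics.tsv", "costello.tsv", "selectivity.tsv",
  "overlap.tsv", "group_comparison.tsv", "rarefaction.tsv", "manifest.json"
)

#' Run the full diet-analysis pipeline
#'
#' Chains the filter cascade (read threshold, taxonomy exclusions, survey
#' harmonisation, genus collapse) with the dietary metrics, the Costello
#' classification, per-group Jacobs selectivity, the faecal-vs-field
#' overlap, the Mann-Whitney group comparison and both rarefaction curves,
#' and writes one TSV per result plus a JSON manifest (input checksums,
#' configuration snapshot, package version, per-table row counts). All
#' stages are deterministic: re-running on identical inputs reproduces the
#' outputs byte for byte.
#'
#' @param counts a `read_count_table` or path to a counts TSV.
#' @param hits a `taxonomy_hits` or path to a taxonomy TSV.
#' @param survey a `field_survey` or path to a survey TSV; optional
#'   (`NULL` skips harmonisation, selectivity and overlap).
#' @param config a [filter_config()].
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @param cutline Costello quadrant boundary in percent.
#' @param dialect count-table orientation, see [read_count_table()].
#' @param report_digits decimals for percentage columns in the written
#'   report TSVs (default 1; `NULL` writes full precision). Returned data
#'   frames always carry full precision.
#' @return (invisibly) list with `prey`, `audit`, `metrics`, `costello`,
#'   `selectivity`, `overlap`, `comparison`, `rarefaction`, `manifest`.
#' @export
run_pipeline <- function(counts, hits, survey = NULL,
                         config = filter_config(), out_dir = NULL,
                         cutline = 50, dialect = "samples-as-rows",
                         report_digits = 1) {
  paths <- list()
  if (is.character(counts)) {
    paths$counts <- counts
    counts <- read_count_table(counts, dialect = dialect)
  }
  if (is.character(hits)) {
    paths$taxonomy <- hits
    hits <- read_taxonomy_hits(hits)
  }
  if (is.character(survey)) {
    paths$survey <- survey
    survey <- read_field_survey(survey)
  }

  flt <- filter_pipeline(counts, hits, survey, config)
  prey <- flt$prey
  metrics <- metrics_report(prey, cutline = cutline)
  costello <- metrics[c("item", "pct_foo", "pct_prey_specific", "costello_region")]

  selectivity <- NULL
  overlap <- NULL
  if (!is.null(survey)) {
    present_groups <- intersect(PREY_GROUPS, unique(c(
      prey$items$prey_group, survey$group
    )))
    selectivity <- do.call(rbind, lapply(
      present_groups,
      function(g) group_selectivity(prey, survey, g, config)
    ))
    overlap <- do.call(rbind, lapply(present_groups, function(g) {
      ov <- faecal_field_overlap(prey, survey, g, config)
      data.frame(
        group = g,
        item = c(ov$faecal_only, ov$shared, ov$field_only),
        membership = rep(
          c("faecal_only", "shared", "field_only"),
          c(length(ov$faecal_only), length(ov$shared), length(ov$field_only))
        ),
        stringsAsFactors = FALSE
      )
    }))
  }

  comparison <- if (length(unique(prey$items$prey_group)) >= 2L) {
    compare_prey_groups(prey)
  } else {
    NULL
  }
  rarefaction <- rbind(
    rarefaction_curve(prey, "sample_based"),
    rarefaction_curve(prey, "individual_based")
  )

  manifest <- list(
    tool = "fecaldiet",
    version = as.character(utils::packageVersion("fecaldiet")),
    inputs = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = config[c(
      "min_relative_reads", "min_identity", "host_taxon",
      "nonprey_exclusions", "min_coverage", "per_sample_threshold",
      "collapse_rank"
    )],
    cutline = cutline,
    n_samples = prey$n_samples,
    n_items = prey$n_items,
    rows = list(
      filter_audit = nrow(flt$audit),
      metrics = nrow(metrics),
      selectivity = if (is.null(selectivity)) 0L else nrow(selectivity),
      group_comparison = if (is.null(comparison)) 0L else nrow(comparison),
      rarefaction = nrow(rarefaction)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(flt$audit, file.path(out_dir, "filter_audit.tsv"))
    write_result_tsv(metrics, file.path(out_dir, "metrics.tsv"),
      pct_digits = report_digits
    )
    write_result_tsv(costello, file.path(out_dir, "costello.tsv"),
      pct_digits = report_digits
    )
    if (!is.null(selectivity)) {
      write_result_tsv(selectivity, file.path(out_dir, "selectivity.tsv"))
      write_result_tsv(overlap, file.path(out_dir, "overlap.tsv"))
    }
    if (!is.null(comparison)) {
      write_result_tsv(comparison, file.path(out_dir, "group_comparison.tsv"))
    }
    write_result_tsv(rarefaction, file.path(out_dir, "rarefaction.tsv"))
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  invisible(list(
    prey = prey, audit = flt$audit, assignments = flt$assignments,
    metrics = metrics, costello = costello, selectivity = selectivity,
    overlap = overlap, comparison = comparison, rarefaction = rarefaction,
    manifest = manifest
  ))
}

#' Path to a bundled example file
#'
#' Bundled inputs: `prey_taxonomy_hits.tsv`, the best-hit table of the 15
#' prey taxa detected in the worked example, and
#' `field_survey_synthetic.tsv`, a synthetic field-survey table constructed
#' to have the same genus-level structure as a Korean stream survey (11 fish
#' taxa, 25 benthic taxa including two chironomid genera); it is not real
#' survey data.
#'
#' @param file file name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return full path, or a character vector of file names.
#' @export
fecaldiet_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "fecaldiet")))
  }
  path <- system.file("extdata", file, package = "fecaldiet")
  if (!nzchar(path)) stop("no such example file: ", file, call. = FALSE)
  path
}
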