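# Dietary metrics: frequency of occurrence (FOO), relative read abundance
# (RRA), prey-specific abundance (%Pi) and the Costello feeding-strategy
# classification built on them.

#' Frequency of occurrence
#'
#' `occurrence_count` is the number of samples in which an item has at least
#' one read; `pct_foo = 100 * occurrence_count / S` with `S` the number of
#' samples. A high FOO marks a prey item that is widespread across
#' individuals.
#'
#' @param prey a `prey_table`.
#' @return data frame: `item`, `occurrence_count`, `pct_foo`.
#' @export
compute_foo <- function(prey) {
  stopifnot(inherits(prey, "prey_table"))
  occ <- colSums(prey$counts > 0)
  data.frame(
    item = prey$items$item,
    occurrence_count = as.integer(occ),
    pct_foo = 100 * occ / prey$n_samples,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Relative read abundance
#'
#' The mean over samples of an item's within-sample read proportion:
#' `pct_rra_i = (100 / S) * sum_k n_ik / sum_j n_jk`. Per-sample proportions
#' make the metric invariant to sequencing-depth differences between
#' samples; the values sum to 100 over items.
#'
#' @param prey a `prey_table`.
#' @return data frame: `item`, `pct_rra`.
#' @export
compute_rra <- function(prey) {
  stopifnot(inherits(prey, "prey_table"))
  totals <- rowSums(prey$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero prey reads reached compute_rra: ",
      paste(prey$sample_ids[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  props <- prey$counts / totals
  data.frame(
    item = prey$items$item,
    pct_rra = 100 * colMeans(props),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Prey-specific abundance
#'
#' For item i, `%P_i = 100 * sum(S_i) / sum(St_i)` where `S_i` is the item's
#' read total over all samples and `St_i` is the total reads (all items) of
#' only the samples in which item i occurs. It is the pooled read share of
#' the item among the individuals that actually consumed it — the vertical
#' axis of the Costello diagram. Undefined (NA) for items occurring nowhere.
#'
#' @param prey a `prey_table`.
#' @return data frame: `item`, `pct_prey_specific`.
#' @export
compute_prey_specific_abundance <- function(prey) {
  stopifnot(inherits(prey, "prey_table"))
  sample_tot <- rowSums(prey$counts)
  pct <- vapply(seq_len(prey$n_items), function(i) {
    present <- prey$counts[, i] > 0
    if (!any(present)) return(NA_real_)
    100 * sum(prey$counts[present, i]) / sum(sample_tot[present])
  }, numeric(1L))
  data.frame(
    item = prey$items$item,
    pct_prey_specific = pct,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

COSTELLO_REGIONS <- c("dominant", "rare", "specialist_bpc", "generalist_wpc")

#' Costello feeding-strategy classification
#'
#' Places a prey item in one of the four quadrants of the Costello diagram
#' (prey-specific abundance against frequency of occurrence). The cutline
#' defaults to 50% on both axes with ties (`>=`) assigned to the upper/right
#' side: `dominant` (high FOO, high %Pi), `rare` (low/low),
#' `specialist_bpc` (low FOO, high %Pi — specialisation by a subset of
#' individuals, a between-phenotype niche component), `generalist_wpc`
#' (high FOO, low %Pi — many individuals each taking modest shares, a
#' within-phenotype component).
#'
#' @param pct_foo,pct_prey_specific percent values in \[0, 100\]; vectorised.
#' @param cutline quadrant boundary in percent (default 50).
#' @return character vector of region labels.
#' @export
costello_classify <- function(pct_foo, pct_prey_specific, cutline = 50) {
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 100))
  if (!ok(pct_foo) || !ok(pct_prey_specific)) {
    stop("pct_foo and pct_prey_specific must lie in [0, 100]", call. = FALSE)
  }
  hi_foo <- pct_foo >= cutline
  hi_pi <- pct_prey_specific >= cutline
  out <- ifelse(hi_foo & hi_pi, "dominant",
    ifelse(!hi_foo & hi_pi, "specialist_bpc",
      ifelse(hi_foo & !hi_pi, "generalist_wpc", "rare")
    )
  )
  out[is.na(pct_foo) | is.na(pct_prey_specific)] <- NA_character_
  out
}

#' Full dietary-metrics report
#'
#' Composes FOO, RRA and prey-specific abundance per item and classifies
#' each item's Costello region. Items with zero occurrences are excluded.
#' Rows are sorted by `pct_rra` descending.
#'
#' @param prey a `prey_table`.
#' @param cutline Costello quadrant boundary, see [costello_classify()].
#' @return data frame: `item`, `prey_group`, `occurrence_count`, `pct_foo`,
#'   `pct_rra`, `pct_prey_specific`, `costello_region`.
#' @export
metrics_report <- function(prey, cutline = 50) {
  foo <- compute_foo(prey)
  rra <- compute_rra(prey)
  psa <- compute_prey_specific_abundance(prey)
  out <- data.frame(
    item = foo$item,
    prey_group = prey$items$prey_group,
    occurrence_count = foo$occurrence_count,
    pct_foo = foo$pct_foo,
    pct_rra = rra$pct_rra,
    pct_prey_specific = psa$pct_prey_specific,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[out$occurrence_count > 0, , drop = FALSE]
  out$costello_region <- costello_classify(
    out$pct_foo, out$pct_prey_specific, cutline
  )
  out <- out[order(-out$pct_rra, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}
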