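# Jacobs's selectivity index comparing faecal read shares with field-survey
# availability, per prey group, plus the faecal-vs-field set comparison.

#' Jacobs's selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)` where `r` is the resource's share in the
#' diet and `p` its share among the available resources. D ranges from -1
#' (complete avoidance; the item is available but never used) through 0
#' (use proportional to availability) to +1 (exclusive positive selection).
#' r = p yields 0 by convention (including r = p = 1, where the raw
#' formula is 0/0); r = p = 0 is undefined and returns NaN.
#'
#' @param r,p fractions in \[0, 1\]; vectorised and recycled.
#' @return numeric vector of index values in \[-1, 1\].
#' @export
jacobs_d <- function(r, p) {
  if (any(r < 0 | r > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("r and p must be fractions in [0, 1]", call. = FALSE)
  }
  n <- max(length(r), length(p))
  r <- rep_len(r, n)
  p <- rep_len(p, n)
  d <- (r - p) / (r + p - 2 * r * p)
  d[r == p & r > 0] <- 0
  d[r == 0 & p == 0] <- NaN
  d
}

# Map a genus to its selectivity item key: Chironomidae genera merge to the
# family, everything else stays at genus.
selectivity_key <- function(genus, chironomidae) {
  ifelse(genus %in% chironomidae, "Chironomidae", genus)
}

# Shared preparation: within-group read shares from the prey table and
# availability shares from the survey, both after Chironomidae merging.
group_shares <- function(prey, survey, group, config, renormalise) {
  survey <- as_field_survey(as.data.frame(survey))
  chir <- config$chironomidae_genera

  in_group <- prey$items$prey_group == group
  faecal_r <- numeric(0)
  if (any(in_group)) {
    rra <- compute_rra(prey)$pct_rra[in_group]
    key <- selectivity_key(prey$items$genus[in_group], chir)
    faecal_r <- tapply(rra, key, sum)
    faecal_r <- if (renormalise) {
      faecal_r / sum(faecal_r)
    } else {
      faecal_r / 100
    }
  }

  srows <- survey$group == group & survey$count > 0
  field_p <- numeric(0)
  if (any(srows)) {
    key <- selectivity_key(survey$genus[srows], chir)
    field_p <- tapply(survey$count[srows], key, sum)
    field_p <- field_p / sum(field_p)
  }

  if (!length(faecal_r) && !length(field_p)) {
    stop(sprintf("prey group '%s' is empty in both faeces and survey", group),
      call. = FALSE
    )
  }
  list(r = faecal_r, p = field_p)
}

#' Prey selectivity within a prey group
#'
#' Computes Jacobs's D for every item in the union of faecal detections and
#' field-survey records of one prey group. Items are keyed at genus level,
#' except that Chironomidae genera are merged to the family on both sides
#' (the identification limit of typical benthic field surveys). The faecal
#' share `r` is the item's relative read abundance renormalised over the
#' group's items so that r and the availability share p lie on the same
#' simplex; `renormalise = FALSE` uses the raw RRA fraction instead. Items
#' detected only in faeces get p = 0 (D = 1); items recorded only in the
#' field get r = 0 (D = -1).
#'
#' @param prey a `prey_table`.
#' @param survey a `field_survey`.
#' @param group `"fish"` or `"benthic_invertebrate"`.
#' @param config a [filter_config()] (supplies the Chironomidae genus list).
#' @param renormalise renormalise RRA within the group (default `TRUE`).
#' @return data frame: `group`, `item`, `r`, `p`, `D`, sorted by D
#'   descending.
#' @export
group_selectivity <- function(prey, survey, group = PREY_GROUPS,
                              config = filter_config(), renormalise = TRUE) {
  group <- match.arg(group)
  sh <- group_shares(prey, survey, group, config, renormalise)
  items <- sort(union(names(sh$r), names(sh$p)))
  r <- ifelse(items %in% names(sh$r), sh$r[items], 0)
  p <- ifelse(items %in% names(sh$p), sh$p[items], 0)
  out <- data.frame(
    group = group,
    item = items,
    r = unname(r),
    p = unname(p),
    D = jacobs_d(unname(r), unname(p)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[order(-out$D, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Faecal vs field-survey taxon overlap
#'
#' Splits the union of genus-level taxa (family level for Chironomidae) of
#' one prey group into the three cells of a Venn comparison: detected only
#' in faecal metabarcoding, detected by both methods, and recorded only in
#' the field survey.
#'
#' @inheritParams group_selectivity
#' @return list with character vectors `faecal_only`, `shared`,
#'   `field_only`.
#' @export
faecal_field_overlap <- function(prey, survey, group = PREY_GROUPS,
                                 config = filter_config()) {
  group <- match.arg(group)
  survey <- as_field_survey(as.data.frame(survey))
  chir <- config$chironomidae_genera
  faecal <- unique(selectivity_key(
    prey$items$genus[prey$items$prey_group == group], chir
  ))
  field <- unique(selectivity_key(
    survey$genus[survey$group == group & survey$count > 0], chir
  ))
  list(
    faecal_only = sort(setdiff(faecal, field)),
    shared = sort(intersect(faecal, field)),
    field_only = sort(setdiff(field, faecal))
  )
}
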