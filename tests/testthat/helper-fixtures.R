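# Shared fixtures: a deterministic 24-sample count table matching the
# bundled 15-taxon best-hit table, small prey-table builders, and naive
# reference (oracle) implementations of the dietary metrics.

example_hits <- function() {
  read_taxonomy_hits(fecaldiet_example("prey_taxonomy_hits.tsv"))
}

example_survey <- function() {
  read_field_survey(fecaldiet_example("field_survey_synthetic.tsv"))
}

# Occurrence pattern per OTU (sample indices with reads), chosen so the
# genus-level items occur in 24, 15, 13, 12, 8, 5, ... of the 24 samples.
example_occupancy <- function() {
  list(
    OTU_001 = 1:8,    # Micropterus salmoides
    OTU_002 = 1:7,    # Misgurnus anguillicaudatus
    OTU_003 = 2:7,    # Carassius cuvieri
    OTU_004 = 1:20,   # Zacco sp. 1
    OTU_005 = 5:24,   # Zacco sp. 2 (union with sp. 1 = all 24)
    OTU_006 = 1:13,   # Rhinogobius brunneus
    OTU_007 = 1:5,    # Hemibarbus labeo
    OTU_008 = 3:8,    # Chironomus flaviplumus
    OTU_009 = 1:5,    # Cricotopus triannulatus
    OTU_010 = 1:10,   # Polypedilum japonicum
    OTU_011 = 8:15,   # Polypedilum yongsanensis (union = 15)
    OTU_012 = 1:12,   # Ephemera orientalis
    OTU_013 = 1:3,    # Platycnemis phyllopoda
    OTU_014 = 4:7,    # Radix sp.
    OTU_015 = 10:12   # Limnodrilus sp.
  )
}

example_counts <- function() {
  occ <- example_occupancy()
  m <- matrix(0L,
    nrow = 24, ncol = length(occ),
    dimnames = list(sprintf("S%02d", 1:24), names(occ))
  )
  for (j in seq_along(occ)) {
    m[occ[[j]], j] <- 50L + 10L * j + occ[[j]]
  }
  as_read_count_table(m)
}

# Small prey table straight from a matrix; groups default to fish.
make_prey <- function(counts, groups = NULL, items = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  }
  if (is.null(items)) items <- sprintf("Item%02d sp.", seq_len(ncol(counts)))
  if (is.null(groups)) groups <- rep("fish", ncol(counts))
  as_prey_table(
    counts,
    data.frame(
      item = items, prey_group = groups, genus = genus_of_helper(items),
      stringsAsFactors = FALSE
    )
  )
}

genus_of_helper <- function(x) {
  vapply(strsplit(x, "\\s+"), `[[`, character(1L), 1L)
}

random_prey_table <- function(n_samples = 5, n_items = 6,
                              groups = NULL) {
  repeat {
    m <- matrix(
      stats::rpois(n_samples * n_items, 4),
      nrow = n_samples,
      dimnames = list(
        sprintf("S%02d", seq_len(n_samples)),
        sprintf("OTU%02d", seq_len(n_items))
      )
    )
    if (all(rowSums(m) > 0)) break
  }
  make_prey(m, groups = groups, items = sprintf("Item%02d sp.", seq_len(n_items)))
}

# Naive double-loop reference implementations of the three dietary metrics.
naive_metrics <- function(counts) {
  S <- nrow(counts)
  TT <- ncol(counts)
  foo <- numeric(TT)
  rra <- numeric(TT)
  psa <- numeric(TT)
  for (i in seq_len(TT)) {
    occ <- 0
    acc <- 0
    si <- 0
    sti <- 0
    for (k in seq_len(S)) {
      tot_k <- sum(counts[k, ])
      if (counts[k, i] > 0) {
        occ <- occ + 1
        si <- si + counts[k, i]
        sti <- sti + tot_k
      }
      acc <- acc + counts[k, i] / tot_k
    }
    foo[i] <- 100 * occ / S
    rra[i] <- 100 * acc / S
    psa[i] <- if (occ > 0) 100 * si / sti else NA_real_
  }
  list(pct_foo = foo, pct_rra = rra, pct_prey_specific = psa)
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every split of
# the pooled ranks (independent of the package's counting recurrence).
brute_force_mwu_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
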