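# Filter cascade: read threshold, taxonomy exclusions, survey harmonisation,
# genus collapse, audit bookkeeping.

test_that("read threshold keeps OTUs at the boundary and removes below it", {
  # total 10,000 reads; at 0.01% the cutoff is 1 read: an OTU with exactly
  # one read is kept (>= rule), a zero-read OTU is removed
  m <- cbind(big = c(9000L, 999L), one = c(1L, 0L), zero = c(0L, 0L))
  rownames(m) <- c("A", "B")
  tab <- as_read_count_table(m)
  thr <- apply_read_threshold(tab, 1e-4)
  expect_setequal(thr$table$otu_ids, c("big", "one"))
  expect_false(thr$audit$kept[thr$audit$otu_id == "zero"])

  # total 1,000,000 reads; 99 reads = 0.0099% < 0.01% -> removed
  m2 <- cbind(big = c(999901L, 0L), small = c(49L, 50L))
  rownames(m2) <- c("A", "B")
  thr2 <- apply_read_threshold(as_read_count_table(m2), 1e-4)
  expect_equal(thr2$table$otu_ids, "big")

  # threshold 0 keeps everything with at least one read
  thr0 <- apply_read_threshold(tab, 0)
  expect_setequal(thr0$table$otu_ids, c("big", "one"))
  m_pos <- m[, colSums(m) > 0]
  expect_equal(apply_read_threshold(as_read_count_table(m_pos), 0)$table$counts,
    as_read_count_table(m_pos)$counts)
})

test_that("threshold audit covers every OTU exactly once", {
  tab <- example_counts()
  thr <- apply_read_threshold(tab, 1e-3)
  expect_setequal(thr$audit$otu_id, tab$otu_ids)
  expect_equal(anyDuplicated(thr$audit$otu_id), 0L)
})

test_that("assign_taxa applies identity, host, no-match and non-prey rules", {
  mk <- function(taxon, id) {
    data.frame(
      otu_id = paste0("O", seq_along(taxon)), taxon = taxon,
      percent_identity = id, query_coverage_pct = 100,
      max_score = 500, accession = "X1.1", stringsAsFactors = FALSE
    )
  }
  hits <- mk(
    c("Zacco sp. 1", "Zacco platypus", "Odontobutis obscurus", "no match",
      "Bos taurus", "Aspergillus fumigatus"),
    c(96.9, 100, 100, NA, 99, 99)
  )
  asg <- assign_taxa(hits, filter_config())
  expect_equal(
    asg$reason,
    c("below_identity", "kept_species", "host", "no_match", "nonprey", "nonprey")
  )
  expect_equal(asg$status == "kept", asg$reason %in% c("kept_species"))
  expect_equal(asg$prey_group[2], "fish")

  # identity exactly at 97 is kept, no rounding before comparison
  hits97 <- mk(c("Zacco platypus", "Zacco platypus"), c(97, 96.99))
  hits97$otu_id <- c("A", "B")
  asg97 <- assign_taxa(hits97, filter_config())
  expect_equal(asg97$reason, c("kept_species", "below_identity"))

  # kept OTU with unmapped genus errors and names the taxon
  expect_error(
    assign_taxa(mk("Felis catus", 100), filter_config()),
    "Felis catus"
  )

  # OTUs absent from the hit table are synthesised as "no match"
  asg_miss <- assign_taxa(mk("Zacco platypus", 100), filter_config(),
    otu_ids = c("O1", "O_absent")
  )
  expect_equal(asg_miss$reason[asg_miss$otu_id == "O_absent"], "no_match")
})

test_that("optional coverage threshold drops low-coverage hits", {
  hits <- data.frame(
    otu_id = c("O1", "O2"), taxon = "Zacco platypus",
    percent_identity = 100, query_coverage_pct = c(100, 40),
    max_score = 500, accession = "X1.1", stringsAsFactors = FALSE
  )
  asg <- assign_taxa(hits, filter_config(min_coverage = 80))
  expect_equal(asg$reason, c("kept_species", "below_coverage"))
  # default: coverage read but not thresholded
  asg_def <- assign_taxa(hits, filter_config())
  expect_equal(asg_def$status, c("kept", "kept"))
})

test_that("harmonisation demotes species absent from the field survey", {
  survey <- as_field_survey(data.frame(
    group = c("fish", "fish"),
    genus = c("Zacco", "Micropterus"),
    species = c("Zacco temminckii", "Micropterus salmoides"),
    count = c(100L, 10L)
  ))
  hits <- data.frame(
    otu_id = c("O1", "O2", "O3"),
    taxon = c("Zacco platypus", "Micropterus salmoides", "Hemibarbus labeo"),
    percent_identity = 100, query_coverage_pct = 100,
    max_score = 500, accession = "X1.1", stringsAsFactors = FALSE
  )
  asg <- harmonise_with_field_survey(assign_taxa(hits, filter_config()), survey)
  # species absent, genus present -> demoted
  expect_equal(asg$final_taxon[1], "Zacco sp.")
  expect_equal(asg$reason[1], "kept_demoted_to_genus")
  expect_false(asg$survey_absent[1])
  # species present in survey -> untouched
  expect_equal(asg$final_taxon[2], "Micropterus salmoides")
  expect_equal(asg$reason[2], "kept_species")
  # species and genus both absent -> kept at genus, flagged
  expect_equal(asg$final_taxon[3], "Hemibarbus sp.")
  expect_true(asg$survey_absent[3])
})

test_that("the 15 example taxa collapse to 13 genus-level prey items", {
  tab <- example_counts()
  asg <- assign_taxa(example_hits(), filter_config())
  genus <- collapse_to_prey_table(tab, asg, rank = "genus")
  expect_equal(genus$n_items, 13L)
  species <- collapse_to_prey_table(tab, asg, rank = "species")
  expect_equal(species$n_items, 15L)
  # the two Zacco and the two Polypedilum OTUs merged
  expect_true(all(c("Zacco sp.", "Polypedilum sp.") %in% genus$items$item))
  # reads conserved through the collapse
  expect_equal(sum(genus$counts), sum(tab$counts))
  # additivity: same-sample reads of merged OTUs are summed
  expect_equal(
    unname(genus$counts["S08", "Polypedilum sp."]),
    unname(tab$counts["S08", "OTU_010"] + tab$counts["S08", "OTU_011"])
  )
})

test_that("samples without prey reads are dropped with a warning", {
  m <- cbind(O1 = c(5L, 0L), O2 = c(3L, 0L))
  rownames(m) <- c("A", "B")
  hits <- data.frame(
    otu_id = c("O1", "O2"), taxon = c("Zacco platypus", "Ephemera orientalis"),
    percent_identity = 100, query_coverage_pct = 100,
    max_score = 500, accession = "X1.1", stringsAsFactors = FALSE
  )
  asg <- assign_taxa(hits, filter_config())
  expect_warning(
    prey <- collapse_to_prey_table(as_read_count_table(m), asg),
    "zero prey reads"
  )
  expect_equal(prey$sample_ids, "A")
})

test_that("full cascade audit is complete, consistent and conserves reads", {
  dat <- generate_dataset(synthetic_config(depth_mean = 5000, seed = 7))
  res <- filter_pipeline(dat$counts, dat$hits, dat$survey)
  # completeness: every input OTU exactly once, exactly one reason
  expect_setequal(res$audit$otu_id, dat$counts$otu_ids)
  expect_equal(anyDuplicated(res$audit$otu_id), 0L)
  expect_true(all(res$audit$reason %in% c(
    "below_read_threshold", "below_identity", "below_coverage", "host",
    "no_match", "nonprey", "kept_species", "kept_demoted_to_genus"
  )))
  # read conservation: prey table totals the kept OTUs of the thresholded table
  kept <- res$audit$otu_id[res$audit$status == "kept"]
  expect_equal(
    sum(res$prey$counts),
    sum(res$thresholded$counts[, kept])
  )
})

test_that("the prey table is invariant to OTU and sample permutations", {
  tab <- example_counts()
  asg <- assign_taxa(example_hits(), filter_config())
  base <- collapse_to_prey_table(tab, asg)

  set.seed(11)
  perm_s <- sample(tab$sample_ids)
  perm_o <- sample(tab$otu_ids)
  tab_p <- as_read_count_table(tab$counts[perm_s, perm_o])
  asg_p <- asg[sample(nrow(asg)), ]
  permuted <- collapse_to_prey_table(tab_p, asg_p)
  expect_equal(
    permuted$counts[base$sample_ids, base$items$item],
    base$counts
  )
  expect_equal(
    permuted$items[order(permuted$items$item), ],
    base$items[order(base$items$item), ],
    ignore_attr = TRUE
  )
})

test_that("threshold-then-taxonomy differs from host-first filtering", {
  # host reads dominate the total, so the cutoff computed before host
  # removal is higher; an OTU can sit above the post-host cutoff yet below
  # the pre-host cutoff. Guards against silently reordering the cascade.
  m <- cbind(
    host = c(90000L, 0L),
    prey_big = c(5000L, 4991L),
    prey_small = c(5L, 4L) # 9 reads: 0.009% of 100,000 / 0.09% of 10,000
  )
  rownames(m) <- c("A", "B")
  tab <- as_read_count_table(m)
  hits <- data.frame(
    otu_id = c("host", "prey_big", "prey_small"),
    taxon = c("Odontobutis obscurus", "Zacco platypus", "Ephemera orientalis"),
    percent_identity = 100, query_coverage_pct = 100,
    max_score = 500, accession = "X1.1", stringsAsFactors = FALSE
  )
  res <- filter_pipeline(tab, hits)
  expect_equal(
    res$audit$reason[res$audit$otu_id == "prey_small"],
    "below_read_threshold"
  )

  # removing the host first changes the outcome
  no_host <- as_read_count_table(m[, c("prey_big", "prey_small")])
  thr <- apply_read_threshold(no_host, 1e-4)
  expect_true("prey_small" %in% thr$table$otu_ids)
})

test_that("per-sample threshold mode zeroes sub-threshold cells", {
  m <- cbind(O1 = c(10000L, 100L), O2 = c(0L, 100L))
  rownames(m) <- c("A", "B")
  tab <- as_read_count_table(m)
  # dataset-wide: O2 share = 100/10200 ~ 0.98% -> kept at 0.5% threshold
  thr_global <- apply_read_threshold(tab, 0.005)
  expect_true("O2" %in% thr_global$table$otu_ids)
  # per-sample at 60%: O2 is 50% of sample B -> zeroed everywhere
  thr_ps <- apply_read_threshold(tab, 0.6, per_sample = TRUE)
  expect_false("O2" %in% thr_ps$table$otu_ids)
})
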