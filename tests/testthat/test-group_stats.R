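# Group summaries, the Mann-Whitney U test and rarefaction.

test_that("group summaries give complementary shares and correct richness", {
  m <- rbind(
    c(50L, 30L, 15L, 5L),
    c(0L, 80L, 10L, 10L)
  )
  rownames(m) <- c("S1", "S2")
  prey <- make_prey(m,
    groups = c("fish", "fish", "benthic_invertebrate", "benthic_invertebrate"),
    items = c("Zacco sp.", "Carassius sp.", "Ephemera sp.", "Radix sp.")
  )
  s <- summarise_groups(prey)
  fish <- s[s$group == "fish", ]
  inv <- s[s$group == "benthic_invertebrate", ]
  expect_equal(fish$rel_abundance_share, c(0.8, 0.8))
  expect_equal(fish$rel_abundance_share + inv$rel_abundance_share, c(1, 1))
  expect_equal(fish$richness, c(2L, 1L))
  expect_equal(inv$richness, c(2L, 2L))

  # brute-force per-cell recomputation agrees exactly
  set.seed(8)
  prey_r <- random_prey_table(6, 5, groups = c(
    "fish", "fish", "fish", "benthic_invertebrate", "benthic_invertebrate"
  ))
  s_r <- summarise_groups(prey_r)
  for (row in seq_len(nrow(s_r))) {
    k <- which(prey_r$sample_ids == s_r$sample_id[row])
    cols <- which(prey_r$items$prey_group == s_r$group[row])
    share <- 0
    rich <- 0L
    for (j in cols) {
      share <- share + prey_r$counts[k, j] / sum(prey_r$counts[k, ])
      rich <- rich + (prey_r$counts[k, j] > 0)
    }
    expect_equal(s_r$rel_abundance_share[row], share)
    expect_equal(s_r$richness[row], as.integer(rich))
  }
})

test_that("Mann-Whitney U matches hand enumeration on the textbook case", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_two_sided, 2 / 6)

  # identical multisets: distribution-free p = 1 (ties force the normal path)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)
  expect_error(
    mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "exact"),
    "ties"
  )
})

test_that("exact p agrees with full rank-split enumeration for n1,n2 <= 5", {
  set.seed(9)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      for (rep in 1:3) {
        repeat {
          x <- round(stats::rnorm(n1), 3)
          y <- round(stats::rnorm(n2), 3)
          if (!anyDuplicated(c(x, y))) break
        }
        res <- mann_whitney_u(x, y, mode = "exact")
        expect_equal(res$p_two_sided, brute_force_mwu_p(x, y),
          info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep)
        )
      }
    }
  }
})

test_that("U statistics of the two orientations sum to n1*n2", {
  set.seed(10)
  for (rep in 1:10) {
    x <- sample(1:8, 6, replace = TRUE) # ties likely
    y <- sample(1:8, 9, replace = TRUE)
    expect_equal(
      mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
      length(x) * length(y)
    )
  }
})

test_that("exact and normal approximations agree within 0.02 at 8/8", {
  set.seed(13)
  for (rep in 1:10) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8, mean = stats::runif(1, -1, 1))
    pe <- mann_whitney_u(x, y, mode = "exact")$p_two_sided
    pn <- mann_whitney_u(x, y, mode = "normal_approx")$p_two_sided
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("p-values track the standard reference implementation", {
  set.seed(14)
  # tie-free exact
  x <- stats::rnorm(7)
  y <- stats::rnorm(6)
  expect_equal(
    mann_whitney_u(x, y, mode = "exact")$p_two_sided,
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  )
  # tied data, tie-corrected normal approximation with continuity correction
  xt <- c(1, 2, 2, 3, 5, 5, 7, 8, 9, 9, 11, 12)
  yt <- c(2, 3, 3, 4, 5, 6, 6, 8, 10, 10, 13, 14)
  expect_equal(
    mann_whitney_u(xt, yt)$p_two_sided,
    suppressWarnings(stats::wilcox.test(xt, yt, correct = TRUE)$p.value),
    tolerance = 1e-10
  )
})

test_that("compare_prey_groups tests shares and richness across samples", {
  dat <- generate_dataset(synthetic_config(depth_mean = 5000, seed = 15))
  res <- filter_pipeline(dat$counts, dat$hits, dat$survey)
  cmp <- compare_prey_groups(res$prey)
  expect_equal(cmp$statistic, c("rel_abundance_share", "richness"))
  expect_equal(cmp$n1, c(24L, 24L))
  expect_true(all(cmp$p_two_sided > 0 & cmp$p_two_sided <= 1))
  expect_true(all(cmp$U >= 0 & cmp$U <= 24 * 24))
})

test_that("individual-based rarefaction matches the hypergeometric form", {
  # counts (5, 5), m = 2: sum over both items of 1 - C(5,2)/C(10,2) = 14/9
  expect_equal(rarefy_individual(c(5, 5), 2), 14 / 9, tolerance = 1e-12)
  # boundary cases
  expect_equal(rarefy_individual(c(3, 4, 2), 9), 3)
  expect_equal(rarefy_individual(c(3, 4, 2), 1), 1)
  expect_equal(rarefy_individual(c(3, 4, 2), 0), 0)
  expect_error(rarefy_individual(c(3, 4), 8), "m must be")
  expect_error(rarefy_individual(c(3.5, 4), 2), "non-negative integers")
})

test_that("individual-based rarefaction matches vegan's reference values", {
  skip_if_not_installed("vegan")
  set.seed(16)
  for (rep in 1:5) {
    counts <- stats::rpois(8, 20) + 1L
    m <- sample.int(sum(counts) - 1L, 1)
    expect_equal(
      rarefy_individual(counts, m),
      as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), m))),
      tolerance = 1e-8,
      ignore_attr = TRUE
    )
  }
})

test_that("sample-based rarefaction matches a resampling oracle", {
  set.seed(17)
  prey <- random_prey_table(n_samples = 8, n_items = 6)
  s <- 3
  expected <- rarefy_samples(prey, s)
  hits <- replicate(4000, {
    idx <- sample(prey$n_samples, s)
    sum(colSums(prey$counts[idx, , drop = FALSE]) > 0)
  })
  expect_equal(expected, mean(hits), tolerance = 0.1)

  # boundaries: full effort = observed richness; ubiquitous item always found
  expect_equal(
    rarefy_samples(prey, prey$n_samples),
    sum(colSums(prey$counts) > 0)
  )
  m <- cbind(always = rep(1L, 6), rare = c(1L, rep(0L, 5)))
  rownames(m) <- sprintf("S%d", 1:6)
  prey_u <- make_prey(m)
  for (s in 1:6) {
    expect_gte(rarefy_samples(prey_u, s), 1)
  }
  expect_error(rarefy_samples(prey, 9), "s must be")
})

test_that("rarefaction curves are non-decreasing and concave", {
  set.seed(18)
  prey <- random_prey_table(n_samples = 10, n_items = 8)
  for (mode in c("sample_based", "individual_based")) {
    curve <- rarefaction_curve(prey, mode,
      efforts = if (mode == "sample_based") 1:10 else 1:60
    )
    d1 <- diff(curve$expected_richness)
    expect_true(all(d1 >= -1e-10))
    expect_true(all(diff(d1) <= 1e-10))
  }
  # final point of the default curves equals observed richness
  sb <- rarefaction_curve(prey, "sample_based")
  expect_equal(
    sb$expected_richness[nrow(sb)],
    sum(colSums(prey$counts) > 0)
  )
  ib <- rarefaction_curve(prey, "individual_based")
  expect_equal(
    ib$expected_richness[nrow(ib)],
    sum(colSums(prey$counts) > 0)
  )
})
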