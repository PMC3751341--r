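test_that("extract_seed returns positions 2-8 of the mature sequence", {
  expect_equal(extract_seed("UACAGUACUGUGAUAACUGAA"), "ACAGUAC")
  expect_equal(extract_seed("GUACAGUACUGUGAUAACUGA"), "UACAGUA")
  expect_error(extract_seed("ACGUACG"), "shorter than 8")
})

test_that("build_seed_profile aggregates counts by seed and by locus", {
  calls <- make_calls(seed7 = c("ACAGUAC", "ACAGUAC", "UACAGUA"),
                      mature_name = c("m1", "m1", "m1"),
                      count = c(2L, 1L, 1L))
  prof <- build_seed_profile(calls, "s1")
  expect_equal(as.numeric(prof$seed_counts[c("ACAGUAC", "UACAGUA")]), c(3, 1))
  expect_equal(prof$total_mirna_count, 4)
  expect_equal(length(prof$locus_counts), 1)

  one <- build_seed_profile(make_calls("ACAGUAC", "m1", 5L), "s2")
  expect_equal(length(one$seed_counts), 1)

  expect_warning(empty <- build_seed_profile(calls[0, ], "s3"), "no miRNA")
  expect_true(attr(empty, "empty"))
  expect_equal(empty$total_mirna_count, 0)
})

test_that("a planted 60/40 seed mixture is recovered within binomial bounds", {
  refs <- make_reference(2, rng_seed = 14)
  spec <- isomir_profile_spec(
    t5_distribution = c("0" = 1), t3_distribution = c("0" = 1),
    addition_rate = 0, substitution_rate = 0, depth = 10000, rng_seed = 15)
  sim <- simulate_reads(refs, spec, locus_weights = c(0.6, 0.4))
  calls <- call_sample(sim$reads, refs)$calls
  prof <- build_seed_profile(calls, "mix")
  seed1 <- extract_seed(mature_sequence(refs[[1]]))
  band <- binom_band(10000, 0.6)
  expect_true(prof$seed_counts[seed1] >= band[1] &&
                prof$seed_counts[seed1] <= band[2])
})

test_that("normalized seed frequency is counts per million miRNA reads", {
  prof <- build_seed_profile(
    make_calls(c("AAAAAAA", "CCCCCCC"), "m1", c(250L, 499750L)), "s")
  expect_equal(normalized_seed_frequency(prof, "AAAAAAA"), 500)
  expect_equal(normalized_seed_frequency(prof, "GGGGGGG"), 0)

  # conservation: frequencies over a full profile sum to one million
  set.seed(16)
  seeds <- replicate(30, random_rna_string(7))
  prof <- build_seed_profile(
    make_calls(seeds, "m1", sample(1:1000, 30, replace = TRUE)), "s")
  expect_equal(sum(normalized_seed_frequency(prof, names(prof$seed_counts))),
               1e6)

  bad <- build_seed_profile(make_calls("AAAAAAA", "m1", 1L), "s")
  bad$total_mirna_count <- 0
  expect_error(normalized_seed_frequency(bad, "AAAAAAA"), "no miRNA")
})

test_that("locus abundance is the percentage of all miRNA-mapped reads", {
  prof <- build_seed_profile(
    make_calls(c("AAAAAAA", "CCCCCCC"), c("m1", "m2"), c(50L, 950L)), "s")
  expect_equal(locus_abundance_percent(prof, "m1"), 5)
  single <- build_seed_profile(make_calls("AAAAAAA", "m1", 42L), "s")
  expect_equal(locus_abundance_percent(single, "m1"), 100)

  # planted 80/20 two-locus split recovered within binomial bounds
  refs <- make_reference(2, rng_seed = 17)
  spec <- isomir_profile_spec(
    t5_distribution = c("0" = 1), t3_distribution = c("0" = 1),
    addition_rate = 0, substitution_rate = 0, depth = 10000, rng_seed = 18)
  sim <- simulate_reads(refs, spec, locus_weights = c(0.8, 0.2))
  prof <- build_seed_profile(call_sample(sim$reads, refs)$calls, "s")
  pct <- locus_abundance_percent(prof, refs[[1]]$matures$mature_name)
  band <- binom_band(10000, 0.8) / 10000 * 100
  expect_true(pct >= band[1] && pct <= band[2])
})

test_that("seed_ratio recovers a planted 2:1 seed mixture", {
  prof <- build_seed_profile(
    make_calls(c("AAAAAAA", "CCCCCCC"), "m1", c(100L, 50L)), "s")
  expect_equal(seed_ratio(prof, "AAAAAAA", "CCCCCCC"), 2)
  eq <- build_seed_profile(
    make_calls(c("AAAAAAA", "CCCCCCC"), "m1", c(5L, 5L)), "s")
  expect_equal(seed_ratio(eq, "AAAAAAA", "CCCCCCC"), 1)
  expect_error(seed_ratio(prof, "AAAAAAA", "GGGGGGG"), "zero count")

  # reference vs one-base-upstream variant planted 2:1, deep sample:
  # the two seed groups come back near the planted ratio
  refs <- make_reference(1, rng_seed = 19)
  spec <- isomir_profile_spec(
    t5_distribution = c("0" = 2 / 3, "-1" = 1 / 3),
    t3_distribution = c("0" = 1),
    addition_rate = 0, substitution_rate = 0, depth = 50000, rng_seed = 20)
  sim <- simulate_reads(refs, spec)
  prof <- build_seed_profile(call_sample(sim$reads, refs)$calls, "thp1-like")
  ratio <- seed_ratio(prof, MIR101_SEED, ISOMIR101_SEED)
  band <- binom_band(50000, 2 / 3)
  expect_true(ratio >= band[1] / (50000 - band[1]) &&
                ratio <= band[2] / (50000 - band[2]))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("variant-class proportions are count-weighted and sum to one", {
  calls <- make_calls(rep("AAAAAAA", 4), "m1", rep(1L, 4),
                      variant_labels = c("reference", "reference",
                                         "reference", "trim5"))
  p <- variant_class_proportions(calls)
  expect_equal(unname(p["reference"]), 0.75)
  expect_equal(sum(p), 1)

  all_ref <- make_calls("AAAAAAA", "m1", 10L)
  expect_equal(unname(variant_class_proportions(all_ref)), 1)

  # marginal view: overlapping labels counted per elementary class
  calls <- make_calls(rep("AAAAAAA", 2), "m1", c(3L, 1L),
                      variant_labels = c("trim5+add3", "reference"))
  m <- variant_class_proportions(calls, marginal = TRUE)
  expect_equal(unname(m["trim5"]), 0.75)
  expect_equal(unname(m["add3"]), 0.75)
  expect_equal(unname(m["reference"]), 0.25)

  expect_error(variant_class_proportions(calls[0, ]), "no calls")
  two_loci <- make_calls(c("AAAAAAA", "CCCCCCC"), c("m1", "m2"), c(1L, 1L))
  expect_error(variant_class_proportions(two_loci), "one mature locus")
})

test_that("a planted variant-class mixture is recovered within binomial bounds", {
  refs <- make_reference(1, rng_seed = 22)
  # reference 0.4 via t5/t3 mass at 0 with no additions/substitutions;
  # planted rates chosen so each class is bernoulli against the truth
  spec <- isomir_profile_spec(
    t5_distribution = c("-1" = 0.3, "0" = 0.7),
    t3_distribution = c("0" = 1),
    addition_rate = 0.2, substitution_rate = 0.1,
    depth = 20000, rng_seed = 23)
  sim <- simulate_reads(refs, spec)
  calls <- call_sample(sim$reads, refs)$calls
  m <- variant_class_proportions(calls, marginal = TRUE)
  for (chk in list(c("trim5", 0.3), c("add3", 0.2),
                   c("substitution", 0.1))) {
    band <- binom_band(20000, as.numeric(chk[2])) / 20000
    expect_true(m[chk[1]] >= band[1] && m[chk[1]] <= band[2],
                label = sprintf("%s proportion %.4f in [%0.4f, %0.4f]",
                                chk[1], m[chk[1]], band[1], band[2]))
  }
})

test_that("proportions, percentages and ratios are scale invariant", {
  calls <- make_calls(c("AAAAAAA", "CCCCCCC", "GGGGGGG"), "m1",
                      c(10L, 20L, 30L),
                      variant_labels = c("reference", "trim5", "add3"))
  scaled <- calls; scaled$count <- scaled$count * 17L
  expect_equal(variant_class_proportions(calls),
               variant_class_proportions(scaled))
  p1 <- build_seed_profile(calls, "s"); p2 <- build_seed_profile(scaled, "s")
  expect_equal(normalized_seed_frequency(p1, "AAAAAAA"),
               normalized_seed_frequency(p2, "AAAAAAA"))
  expect_equal(seed_ratio(p1, "GGGGGGG", "AAAAAAA"),
               seed_ratio(p2, "GGGGGGG", "AAAAAAA"))
  expect_equal(locus_abundance_percent(p1, "m1"),
               locus_abundance_percent(p2, "m1"))
})

test_that("filter_min_count keeps rows strictly above the threshold", {
  tab <- data.frame(sequence = c("A", "B"), count = c(10L, 11L))
  out <- filter_min_count(tab, 10)
  expect_equal(out$count, 11L)
  expect_equal(nrow(filter_min_count(tab, 0)), 2)
  expect_equal(nrow(filter_min_count(tab[0, ], 10)), 0)
  expect_error(filter_min_count(tab, -1), ">= 0")
})

test_that("seed profile TSV export carries counts and normalized values", {
  prof <- build_seed_profile(
    make_calls(c("AAAAAAA", "CCCCCCC"), c("m1", "m2"), c(30L, 70L)), "s1")
  seed_path <- withr::local_tempfile(fileext = ".tsv")
  locus_path <- withr::local_tempfile(fileext = ".tsv")
  tabs <- write_seed_profile(prof, seed_path, locus_path)
  back <- read.delim(seed_path)
  expect_equal(back$normalized_per_million, c(3e5, 7e5))
  expect_equal(sum(read.delim(locus_path)$percent_of_mirna), 100)
})
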