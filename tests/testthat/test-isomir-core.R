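test_that("a read identical to the mature is the reference call", {
  ref <- hp101_reference()
  call <- map_read_to_hairpin(MIR101_MATURE, ref)
  expect_equal(call$t5, 0)
  expect_equal(call$t3, 0)
  expect_equal(call$additions, "")
  expect_equal(nrow(call$substitutions), 0)
  expect_equal(call$seed7, "ACAGUAC")
  expect_equal(classify_variant(call), "reference")
})

test_that("the abundant 5' variant maps one nucleotide upstream with a shifted seed", {
  # same length as the annotated mature, shifted one base toward the
  # hairpin 5' end: t5 = -1 (upstream), t3 = -1 (trimmed), new seed register
  ref <- hp101_reference()
  call <- map_read_to_hairpin(ISOMIR101_MATURE, ref)
  expect_equal(call$t5, -1)
  expect_equal(call$t3, -1)
  expect_equal(call$additions, "")
  expect_equal(nrow(call$substitutions), 0)
  expect_equal(call$seed7, "UACAGUA")
  expect_setequal(classify_variant(call), c("trim5", "trim3"))
})

test_that("non-templated 3' additions are detected against the hairpin flank", {
  ref <- hp101_reference()   # hairpin base after the mature end is "A"
  call <- map_read_to_hairpin(paste0(MIR101_MATURE, "U"), ref)
  expect_equal(call$t5, 0)
  expect_equal(call$t3, 0)
  expect_equal(call$additions, "U")
  expect_equal(classify_variant(call), "add3")

  # a templated base is an end shift, not an addition
  call <- map_read_to_hairpin(paste0(MIR101_MATURE, "A"), ref)
  expect_equal(call$t3, 1)
  expect_equal(call$additions, "")
})

test_that("internal substitutions are reported with 0-based read position", {
  ref <- hp101_reference()
  read <- MIR101_MATURE
  substr(read, 9, 9) <- "C"   # base 9 (1-based) changed; reference is U
  call <- map_read_to_hairpin(read, ref)
  expect_equal(call$substitutions$position, 8L)
  expect_equal(call$substitutions$ref_base, "U")
  expect_equal(call$substitutions$read_base, "C")
  expect_equal(classify_variant(call), "substitution")
})

test_that("a terminal mismatch is classified as a non-templated addition", {
  ref <- hp101_reference()
  read <- MIR101_MATURE
  substr(read, 21, 21) <- "C"   # last base; hairpin has A at that position
  call <- map_read_to_hairpin(read, ref)
  expect_equal(nrow(call$substitutions), 0)
  expect_equal(call$additions, "C")
  expect_equal(call$t3, -1)
})

test_that("reads outside the variant bounds are unassigned, not errors", {
  ref <- hp101_reference()
  # starts 4 nt upstream of the mature start: |t5| bound is 3
  upstream4 <- paste0(substr(ref$hairpin_seq, 8, 11), MIR101_MATURE)
  upstream4 <- substr(upstream4, 1, 21)
  expect_null(map_read_to_hairpin(upstream4, ref))
  expect_null(map_read_to_hairpin(random_rna_string(21), ref))
})

test_that("classify_variant covers composite and trivial label sets", {
  row <- data.frame(t5 = 0, t3 = 0, additions = "UU", n_substitutions = 0)
  expect_equal(classify_variant(row), "add3")
  row <- data.frame(t5 = -1, t3 = 2, additions = "U", n_substitutions = 1)
  expect_setequal(classify_variant(row),
                  c("trim5", "trim3", "add3", "substitution"))
  row <- data.frame(t5 = 0, t3 = 0, additions = "", n_substitutions = 0)
  expect_equal(classify_variant(row), "reference")
})

test_that("call_sample assigns to the best reference and reports unassigned reads", {
  set.seed(5)
  refA <- hp101_reference()
  refB <- random_reference(id = "unrelated")
  reads <- data.frame(sequence = c(MIR101_MATURE, random_rna_string(21)),
                      count = c(7L, 2L), stringsAsFactors = FALSE)
  res <- call_sample(reads, list(refB, refA))
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$mature_name, "miR-101")
  expect_equal(res$calls$count, 7L)
  expect_equal(nrow(res$unassigned), 1)
  expect_equal(res$unassigned$count, 2L)
})

test_that("calls are deterministic and independent of read order", {
  set.seed(6)
  refs <- make_reference(3, rng_seed = 60)
  sim <- simulate_reads(refs, isomir_profile_spec(depth = 300, rng_seed = 61))
  fwd <- call_sample(sim$reads, refs)$calls
  rev_in <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  bwd <- call_sample(rev_in, refs)$calls
  key <- function(df) df[order(df$sequence), ]
  expect_equal(key(fwd), key(bwd), ignore_attr = TRUE)
})

test_that("every call reconstructs the read from its decomposition", {
  set.seed(7)
  for (i in 1:60) {
    ref <- random_reference()
    read <- random_read(ref, "variant")
    call <- map_read_to_hairpin(read, ref)
    if (is.null(call)) next
    expect_equal(reconstruct_read(call, ref), read)
  }
})

test_that("the decomposer matches the brute-force enumeration oracle", {
  set.seed(8)
  n_checked <- 0
  for (i in 1:200) {
    ref <- random_reference(hairpin_len = sample(60:120, 1))
    read <- random_read(ref, if (i %% 4 == 0) "random" else "variant")
    got <- map_read_to_hairpin(read, ref)
    want <- oracle_decompose(read, list(ref))
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$mature_name, want$mature_name)
      expect_equal(got$t5, want$t5)
      expect_equal(got$t3, want$t3)
      expect_equal(got$additions, want$additions)
      expect_equal(isomirage:::encode_substitutions(got$substitutions),
                   want$substitutions)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)   # the fuzz must actually exercise assignments
})

test_that("emitted calls always respect the variant bounds", {
  set.seed(9)
  refs <- make_reference(3, rng_seed = 90)
  spec <- isomir_profile_spec(depth = 500, sequencing_error_rate = 0.02,
                              rng_seed = 91)
  sim <- simulate_reads(refs, spec)
  calls <- call_sample(sim$reads, refs)$calls
  expect_true(all(abs(calls$t5) <= 3))
  expect_true(all(abs(calls$t3) <= 3))
  expect_true(all(nchar(calls$additions) <= 3))
  expect_true(all(calls$n_substitutions <= 1))
})

test_that("reference sidecar and isomiR tables round-trip through TSV", {
  refs <- make_reference(2, rng_seed = 12)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_references(refs, fa, tsv)
  back <- read_mirna_references(fa, tsv)
  expect_equal(unname(lapply(back, unclass)), unname(lapply(refs, unclass)),
               ignore_attr = TRUE)

  sim <- simulate_reads(refs, isomir_profile_spec(depth = 200, rng_seed = 13))
  calls <- call_sample(sim$reads, refs)$calls
  out <- withr::local_tempfile(fileext = ".tsv")
  write_isomir_table(calls, out)
  expect_equal(read_isomir_table(out), calls, ignore_attr = TRUE)
})

test_that("invalid mature annotations are rejected", {
  expect_error(mirna_reference("h", "ACGUACGUACGUACGUACGU",
                               data.frame(mature_name = "m", start = 0,
                                          end = 30)),
               "invalid coordinates")
  expect_error(mirna_reference("h", paste(rep("ACGU", 10), collapse = ""),
                               data.frame(mature_name = "m", start = 0,
                                          end = 10)),
               "length")
})
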