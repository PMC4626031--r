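ref <- load_reference()

test_that("variant labels parse per the branch-notation grammar", {
  v <- parse_variant_label(c("15953G", "16049", "364+G", "100d", "8000h"))
  expect_equal(v$kind,
               c("transversion", "transition", "insertion", "deletion",
                 "transition"))
  expect_equal(v$position, c(15953L, 16049L, 364L, 100L, 8000L))
  expect_equal(v$allele, c("G", NA, "G", NA, NA))
  expect_equal(v$heteroplasmic, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # the Q-diagnostic site is a C in the reference, so 15953G is a transversion
  expect_identical(ref$bases[15953], "C")
})

test_that("malformed and inconsistent labels are rejected", {
  expect_error(parse_variant_label("abc"), "malformed")
  expect_error(parse_variant_label("123X"), "malformed")
  expect_error(parse_variant_label("99999", ref), "outside")
  # a "transversion" to the transition partner must be written bare
  pos <- 2536L
  partner <- transition_partner(ref$bases[pos])
  expect_error(parse_variant_label(paste0(pos, partner), ref),
               "transition partner")
  expect_error(parse_variant_label(paste0(pos, ref$bases[pos]), ref),
               "equals the reference")
})

test_that("parse and format are mutual inverses over the grammar", {
  set.seed(11)
  for (i in 1:200) {
    pos <- sample.int(16338L, 1L)
    kind <- sample(c("transition", "transversion", "insertion", "deletion"), 1L)
    lab <- switch(kind,
      transition = as.character(pos),
      transversion = paste0(pos, sample(c("A", "C", "G", "T"), 1L)),
      insertion = paste0(pos, "+", paste(
        sample(c("A", "C", "G", "T"), sample(1:3, 1L), TRUE), collapse = "")),
      deletion = paste0(pos, "d"))
    if (kind %in% c("transition", "transversion") && runif(1) < 0.3) {
      lab <- paste0(lab, "h")
    }
    expect_identical(format_variant_label(parse_variant_label(lab)), lab)
  }
})

test_that("variant calling detects substitutions, heteroplasmy and indels", {
  expect_length(call_variants(ref$sequence, ref), 0L)

  b <- ref$bases
  b[2536] <- transition_partner(b[2536])
  p <- call_variants(paste(b, collapse = ""), ref)
  expect_identical(profile_labels(p), "2536")

  # IUPAC two-base code combining reference and its transition partner
  b <- ref$bases
  code <- names(Filter(function(x) setequal(x, c(b[5000],
                                                 transition_partner(b[5000]))),
                       list(R = c("A", "G"), Y = c("C", "T"))))
  b[5000] <- code
  p <- call_variants(paste(b, collapse = ""), ref)
  expect_identical(profile_labels(p), "5000h")
  expect_true(p$variants$heteroplasmic)

  # ambiguity code not containing the reference base is an error
  b <- ref$bases
  b[5000] <- if (b[5000] %in% c("A", "G")) "Y" else "R"
  expect_error(call_variants(paste(b, collapse = ""), ref), "ambiguity")
  expect_error(call_variants(paste(c("Q", ref$bases[-1]), collapse = ""), ref),
               "non-nucleotide")
})

test_that("profiles round-trip through apply_profile and call_variants", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:12, 1L)
    pos <- sort(sample(500:15000, n))
    labs <- vapply(pos, function(p) {
      r <- ref$bases[p]
      u <- runif(1)
      if (u < 0.6) {
        as.character(p)                              # transition
      } else if (u < 0.8) {
        tv <- setdiff(c("A", "C", "G", "T"), c(r, transition_partner(r)))
        paste0(p, sample(tv, 1L))                    # transversion
      } else {
        paste0(p, "h")                               # heteroplasmic transition
      }
    }, "")
    prof <- variant_profile("rt", labs, ref = ref)
    called <- call_variants(apply_profile(ref, prof), ref, "rt")
    expect_identical(profile_labels(called), profile_labels(prof))
  }
})

test_that("indels round-trip via alignment and left-align to canonical labels", {
  # canonical (already left-aligned) indel positions: a deletion whose
  # left neighbour differs, an insertion of a base unlike its anchor's
  del_pos <- which(ref$bases[7000:8000] != ref$bases[6999:7999])[1L] + 6999L
  ins_pos <- 9400L
  ins_base <- setdiff(c("A", "C", "G", "T"), ref$bases[ins_pos])[1L]
  pdel <- variant_profile("id1", c("5000", paste0(del_pos, "d")), ref = ref)
  expect_identical(profile_labels(call_variants(apply_profile(ref, pdel),
                                                ref, "id1")),
                   profile_labels(pdel))
  pins <- variant_profile("id2", c("5000",
                                   paste0(ins_pos, "+", ins_base)), ref = ref)
  expect_identical(profile_labels(call_variants(apply_profile(ref, pins),
                                                ref, "id2")),
                   profile_labels(pins))

  # an extra C anywhere in the tract at np 222-229 normalizes to 221+C
  b <- ref$bases
  withins <- paste0(c(b[1:225], "C", b[226:length(b)]), collapse = "")
  p2 <- call_variants(withins, ref)
  expect_identical(profile_labels(p2), "221+C")

  # an extra G inside the run after np 364 normalizes to 364+G
  withg <- paste0(c(b[1:366], "G", b[367:length(b)]), collapse = "")
  expect_identical(profile_labels(call_variants(withg, ref)), "364+G")
})

test_that("hypervariable length variants are filtered, substitutions kept", {
  p <- variant_profile("f", c("364+G", "221+C", "1600+A", "16057"))
  expect_identical(profile_labels(filter_hypervariable(p)), "16057")
  expect_length(filter_hypervariable(variant_profile("e", character())), 0L)
  expect_identical(profile_labels(filter_hypervariable(
    variant_profile("q", "15953G"))), "15953G")
  # tract deletions count as length variants too; tract substitutions do not
  p2 <- variant_profile("g", c("222d", "1601d", "225", "223A"))
  expect_identical(profile_labels(filter_hypervariable(p2)),
                   c("223A", "225"))
})

test_that("region restriction is inclusive and can drop heteroplasmies", {
  p <- variant_profile("r", c("16049", "2536"))
  expect_identical(profile_labels(restrict_region(p)), "2536")
  p2 <- variant_profile("r2", c("8000h", "8010"))
  expect_identical(
    profile_labels(restrict_region(p2, exclude_heteroplasmic = TRUE)), "8010")
  expect_identical(profile_labels(restrict_region(p2)), c("8000h", "8010"))
  p3 <- variant_profile("r3", "364")
  expect_identical(profile_labels(restrict_region(p3)), "364")
  p4 <- variant_profile("r4", c("363", "15791", "15792"))
  expect_identical(profile_labels(restrict_region(p4)), "15791")
})

test_that("filtering and restriction are idempotent and commute", {
  set.seed(31)
  for (i in 1:10) {
    labs <- c(sample(c("364+G", "221+C", "1600+A", "223d"),
                     sample(0:3, 1L)),
              paste0(sample(200:16300, 6)),
              paste0(sample(400:15700, 2), "h"))
    p <- variant_profile("x", labs)
    f <- filter_hypervariable
    r <- function(q) restrict_region(q, exclude_heteroplasmic = TRUE)
    expect_identical(profile_labels(f(f(p))), profile_labels(f(p)))
    expect_identical(profile_labels(r(r(p))), profile_labels(r(p)))
    expect_identical(profile_labels(f(r(p))), profile_labels(r(f(p))))
  }
})

test_that("variant TSV round-trips, including variant-free samples", {
  tmp <- tempfile(fileext = ".tsv")
  profs <- list(variant_profile("a", c("2536", "15953G")),
                variant_profile("b", character()),
                variant_profile("c", "364+G"))
  write_variant_tsv(profs, tmp)
  back <- read_variant_tsv(tmp)
  expect_identical(names(back), c("a", "b", "c"))
  for (i in 1:3) {
    expect_identical(profile_labels(back[[i]]), profile_labels(profs[[i]]))
  }
})
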