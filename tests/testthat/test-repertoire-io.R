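test_that("ImmunoSEQ parsing maps columns, canonicalizes genes and keeps metadata", {
  tsv <- writeImmunoseqFixture(withr::local_tempfile(fileext = ".tsv"))
  rep <- readImmunoSeq(tsv)
  df <- triples(rep)
  expect_equal(nrow(df), 10L)
  expect_equal(df$amino_acid[1L], "CASSLGQGAETQYF")
  expect_equal(df$v_gene[7L], "TCRBV05-01")   # IMGT alias resolved
  expect_equal(df$j_gene[7L], "TCRBJ02-03")
  expect_true(is.na(df$v_gene[10L]))          # multi-gene call kept as NA
  expect_equal(df$templates[1L], 500)
  expect_true(all(df$count == 1L))            # template abundance is not a count
})

test_that("parsing an empty file yields an empty repertoire; missing columns fail", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("aminoAcid\tvGeneName\tjGeneName", f)
  expect_equal(nTriples(readImmunoSeq(f)), 0L)
  writeLines("vGeneName\tjGeneName\nTCRBV05-01\tTCRBJ01-01", f)
  expect_error(readImmunoSeq(f), "amino_acid")
})

test_that("filtering applies each rule once, in order, and conserves rows", {
  tsv <- writeImmunoseqFixture(withr::local_tempfile(fileext = ".tsv"))
  fl <- filterRepertoire(readImmunoSeq(tsv))
  rpt <- fl$report
  expect_equal(rpt@input, 10L)
  expect_equal(rpt@retained, 3L)
  expect_equal(sum(rpt@excluded) + rpt@retained, rpt@input)
  expect_equal(unname(rpt@excluded[c("out_of_frame", "cdr3_no_leading_C",
                                     "cdr3_bad_ending", "cdr3_too_long",
                                     "cdr3_nonstandard_residue",
                                     "ambiguous_gene", "blacklisted_gene")]),
               c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  kept <- triples(fl$repertoire)
  expect_true(all(substring(kept$amino_acid, 1L, 1L) == "C"))
  expect_true(all(nchar(kept$amino_acid) <= 30L))
})

test_that("the two readings of the CDR3-ending rule differ as documented", {
  df <- data.frame(amino_acid = c("CASSF", "CASYV", "CASSY", "CASSV"),
                   v_gene = "TCRBV05-01", j_gene = "TCRBJ01-01",
                   frame_type = "In")
  r1 <- filterRepertoire(tcrRepertoire(df), endingRule = "F_or_YV")
  expect_equal(triples(r1$repertoire)$amino_acid, c("CASSF", "CASYV"))
  r2 <- filterRepertoire(tcrRepertoire(df), endingRule = "F_Y_V")
  expect_equal(triples(r2$repertoire)$amino_acid,
               c("CASSF", "CASYV", "CASSY", "CASSV"))
})

test_that("cohort counts aggregate rows across repertoires, ignoring templates", {
  mk <- function(aa, n) {
    tcrRepertoire(data.frame(amino_acid = rep(aa, n), v_gene = "V1",
                             j_gene = "J1", templates = 500))
  }
  cc <- buildCohortCounts(list(mk("CASSF", 2L), mk("CASSF", 1L), mk("CATTF", 1L)))
  df <- triples(cc)
  expect_equal(df$count[df$amino_acid == "CASSF"], 3L)
  expect_equal(df$count[df$amino_acid == "CATTF"], 1L)
  # invariant to repertoire order and to incremental accumulation
  cc2 <- buildCohortCounts(list(mk("CATTF", 1L), mk("CASSF", 1L), mk("CASSF", 2L)))
  expect_equal(triples(cc2), df)
  cc3 <- buildCohortCounts(list(buildCohortCounts(list(mk("CASSF", 2L))),
                                buildCohortCounts(list(mk("CASSF", 1L), mk("CATTF", 1L)))))
  expect_equal(triples(cc3), df)
  expect_equal(nTriples(buildCohortCounts(list())), 0L)
})

test_that("cohort splits partition unique triples deterministically", {
  df <- data.frame(amino_acid = sprintf("CASS%dF", 1:10), v_gene = "V1",
                   j_gene = "J1", count = sample(1:50, 10))
  cc <- tcrRepertoire(df)
  for (frac in c(0.3, 0.5, 0.8)) {
    sp <- splitCohort(cc, fraction = frac, seed = 5L)
    keys <- function(x) triples(x)$amino_acid
    expect_length(intersect(keys(sp$train), keys(sp$test)), 0L)
    expect_setequal(c(keys(sp$train), keys(sp$test)), df$amino_acid)
  }
  sp1 <- splitCohort(cc, 0.5, seed = 9L)
  sp2 <- splitCohort(cc, 0.5, seed = 9L)
  expect_identical(triples(sp1$train), triples(sp2$train))
  expect_equal(nTriples(splitCohort(cc, 0.5, seed = 1L)$train), 5L)
  expect_error(splitCohort(tcrRepertoire(df[0, ]), 0.5, 1L), "empty")
})

test_that("multinomial sampling follows the count-induced distribution", {
  cc <- tcrRepertoire(data.frame(
    amino_acid = c("CAAF", "CABF"), v_gene = "V1", j_gene = "J1",
    count = c(1L, 3L)))
  s <- sampleMultinomial(cc, 1e5, seed = 2L)
  expect_equal(mean(s$amino_acid == "CABF"), 0.75, tolerance = 0.02)
  expect_identical(sampleMultinomial(cc, 100L, seed = 4L),
                   sampleMultinomial(cc, 100L, seed = 4L))
  one <- tcrRepertoire(data.frame(amino_acid = "CAAF", v_gene = "V1",
                                  j_gene = "J1", count = 2L))
  expect_true(all(sampleMultinomial(one, 10L, 1L)$amino_acid == "CAAF"))
})

test_that("canonical CSV round-trips a repertoire", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(amino_acid = c("CASSF", "CATTF"), v_gene = "V1",
                   j_gene = c("J1", "J2"), count = c(2L, 1L))
  writeRepertoireCsv(tcrRepertoire(df), f)
  back <- triples(readRepertoireCsv(f))
  expect_equal(back, df)
})
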