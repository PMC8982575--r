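test_that("the published oligo table has a single consensus layout", {
  # the prescribed oracle: every bundled pair must agree on prefix, suffix,
  # loop and bottom-strand arithmetic before the constants can be trusted
  expect_equal(unique(substr(table2$top, 1, 6)), "GATCCG")
  expect_equal(unique(substr(table2$top, 70, 75)), "TGGGCC")
  expect_equal(unique(substr(table2$top, 29, 47)), "TAGTGAAGCCACAGATGTA")
  expect_equal(as.character(revcomp(dna(substr(table2$top[5], 5, 71)))),
               table2$bottom[5])
})

test_that("validate_97 gates on length, loop and internal sites", {
  short <- random_dna(96)
  v <- validate_97(short)
  expect_false(v$ok)
  expect_match(v$issues$message[1], "expected 97 nt, got 96")

  good <- reconstruct_97(random_cassette())
  expect_true(validate_97(good, "strict")$ok)

  # one mutated loop base: strict error, lenient ok
  mut <- good
  base41 <- substr(mut, 41, 41)
  substr(mut, 41, 41) <- setdiff(c("A", "C", "G", "T"), base41)[1]
  expect_false(validate_97(mut, "strict")$ok)
  expect_true(validate_97(mut, "lenient")$ok)

  # internal BamHI site in the stem is a warning, not an error
  c2 <- cassette(sense = paste0("GGATCC", random_dna(16)),
                 guide = random_dna(22))
  v2 <- validate_97(reconstruct_97(c2), "strict")
  expect_true(v2$ok)
  expect_true(any(v2$issues$code == "internal_site"))
})

test_that("design_oligos reproduces the published human CD4 sh1 pair", {
  row <- table2[table2$name == "CD4_sh1_Human", ]
  pair <- design_oligos(parse_oligos(row$top, row$bottom))
  expect_equal(pair$top, paste0(
    "GATCCGACCTGATCATCAAGAATCTTAATAGTGAAGCCACAGATGTATTAAGATTCTTGATGATCAGGG",
    "TGGGCC"))
  expect_equal(pair$bottom, paste0(
    "CACCCTGATCATCAAGAATCTTAATACATCTGTGGCTTCACTATTAAGATTCTTGATGATCAGGTCG"))
})

test_that("every bundled pair is regenerated character-for-character", {
  for (i in seq_len(nrow(table2))) {
    pair <- design_oligos(parse_oligos(table2$top[i], table2$bottom[i]))
    expect_identical(pair$top, table2$top[i], label = table2$name[i])
    expect_identical(pair$bottom, table2$bottom[i], label = table2$name[i])
  }
})

test_that("oligo layout arithmetic holds for random valid cassettes", {
  set.seed(41)
  for (i in 1:50) {
    cass <- random_cassette()
    pair <- design_oligos(cass)
    expect_equal(nchar(pair$top), 75L)
    expect_equal(nchar(pair$bottom), 67L)
    # independent slicing oracle for the strand relation
    expect_equal(pair$bottom,
                 as.character(revcomp(substring(pair$top, 5, 71))))
    expect_equal(nchar(pair$top) - nchar(pair$bottom), 8L)
    # round trip through parsing
    back <- parse_oligos(pair)
    expect_equal(back$sense, cass$sense)
    expect_equal(back$guide, cass$guide)
    expect_equal(back$loop, cass$loop)
    r97 <- reconstruct_97(back)
    expect_equal(nchar(r97), 97L)
    expect_true(validate_97(r97, "strict")$ok)
  }
})

test_that("parse_oligos reports layout and strand-consistency errors", {
  row <- table2[table2$name == "FAS_sh1_Human", ]
  cass <- parse_oligos(row$top, row$bottom)
  expect_equal(cass$sense, "CAGTGTTTGAAAAGATTCTTAA")
  expect_equal(cass$loop, "TAGTGAAGCCACAGATGTA")
  expect_equal(cass$guide, "TTAAGAATCTTTTCAAACACTA")

  bad_prefix <- row$top
  substr(bad_prefix, 1, 1) <- "T"
  expect_error(parse_oligos(bad_prefix, row$bottom),
               class = "mirab_layout_error")

  bad_bottom <- row$bottom
  substr(bad_bottom, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                        substr(bad_bottom, 30, 30))[1]
  err <- expect_error(parse_oligos(row$top, bad_bottom),
                      class = "mirab_strand_error")
  expect_match(conditionMessage(err), "position 30")
})

test_that("batch_design keeps going past failures and round-trips its TSV", {
  recs <- tibble::tibble(
    name = c("ok1", "ok2", "ok3", "short"),
    sequence = c(replicate(3, reconstruct_97(random_cassette())),
                 random_dna(50)))
  out <- batch_design(recs)
  expect_equal(out$status, c("ok", "ok", "ok", "error"))
  expect_match(out$message[4], "expected 97")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  ok <- out[out$status == "ok", c("name", "top", "bottom")]
  write_records(ok, tsv, format = "tsv")
  reread <- read_records(tsv, format = "tsv")
  for (i in seq_len(nrow(reread))) {
    expect_equal(reconstruct_97(parse_oligos(reread$top[i],
                                             reread$bottom[i])),
                 dna(recs$sequence[i]))
  }
})

test_that("a 1,000-record batch converts without failure", {
  set.seed(97)
  seqs <- replicate(1000, as.character(reconstruct_97(random_cassette())))
  out <- batch_design(tibble::tibble(name = sprintf("sh%04d", 1:1000),
                                     sequence = seqs))
  expect_equal(nrow(out), 1000L)
  expect_true(all(out$status == "ok"))
})
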