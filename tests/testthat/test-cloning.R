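test_that("enzyme registry overhang geometry matches the oligo arithmetic", {
  bam <- enzymes("BamHI")
  apa <- enzymes("ApaI")
  expect_equal(bam$overhang, "GATC")
  expect_equal(bam$polarity, "five_prime")
  expect_equal(apa$overhang, "GGCC")
  expect_equal(apa$polarity, "three_prime")
  # the designed top oligos begin GATCC and end with the unpaired GGCC tail
  expect_true(all(startsWith(table2$top, "GATCC")))
  expect_true(all(endsWith(table2$top, "GGCC"))) # 3' tail left unpaired
  expect_error(enzymes("NotARealEnzyme"), "unknown enzyme")
})

test_that("digest fragment counts follow topology and typed ends", {
  v <- make_mock_vector(seed = 3)
  frags <- digest(v$seq, c("BamHI", "ApaI"))
  expect_length(frags, 2L)  # k sites -> k fragments on a circle

  lin <- dna(paste0(random_dna(30), "GGATCC", random_dna(30)))
  linfrags <- digest(lin, "BamHI")
  expect_length(linfrags, 2L)  # k sites -> k + 1 fragments on a line
  e1 <- fragment_ends(linfrags[[1]])
  e2 <- fragment_ends(linfrags[[2]])
  expect_equal(e1$right$polarity, "five_prime")
  expect_equal(e1$right$overhang, "GATC")
  expect_equal(e2$left$overhang, "GATC")
  expect_equal(e1$left$polarity, "blunt")

  apafrags <- digest(dna(paste0(random_dna(20), "GGGCCC", random_dna(20))),
                     "ApaI")
  ea <- fragment_ends(apafrags[[1]])
  expect_equal(ea$right$polarity, "three_prime")
  expect_equal(ea$right$overhang, "GGCC")

  expect_message(un <- digest(dna("ACGTACGTAA"), "BamHI"), "uncut")
  expect_length(un, 1L)
})

test_that("digest then re-ligation regenerates the input circle", {
  v <- make_mock_vector(seed = 9)
  frags <- digest(v$seq, c("BamHI", "ApaI"))
  products <- ligate(frags)
  keys <- vapply(products, function(p) canonical_rotation(p$seq),
                 character(1))
  expect_true(canonical_rotation(v$seq) %in% keys)
})

test_that("annealing types the miR-AB overhangs and rejects mismatches", {
  row <- table2[table2$name == "CD4_sh1_Human", ]
  dup <- anneal(row$top, row$bottom)
  e <- fragment_ends(dup)
  expect_equal(e$left$polarity, "five_prime")
  expect_equal(e$left$overhang, "GATC")
  expect_equal(e$right$polarity, "three_prime")
  expect_equal(e$right$overhang, "GGCC")

  blunt <- anneal("GGATCCAA", as.character(revcomp("GGATCCAA")))
  eb <- fragment_ends(blunt)
  expect_equal(eb$left$polarity, "blunt")
  expect_equal(eb$right$polarity, "blunt")

  bad <- row$bottom
  substr(bad, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 10, 10))[1]
  expect_error(anneal(row$top, bad), class = "mirab_anneal_error")
})

test_that("ligation restores both junction sites exactly once", {
  v <- make_mock_vector(seed = 5)
  baseline <- screen_sites(v$seq, c("BamHI", "ApaI"))
  expect_equal(sort(tapply(baseline$n_sites, baseline$enzyme, max)),
               c(ApaI = 1L, BamHI = 1L))

  row <- table2[table2$name == "FAS_sh1_Human", ]
  construct <- clone_oligos(v, list(top = row$top, bottom = row$bottom))
  expect_equal(construct$topology, "circular")
  hits <- screen_sites(construct, c("BamHI", "ApaI"))
  counts <- tapply(hits$n_sites, hits$enzyme, max)
  expect_equal(counts[["BamHI"]], 1L)
  expect_equal(counts[["ApaI"]], 1L)
  # junction strings restored around the insert
  doubled <- paste0(construct$seq, construct$seq)
  expect_true(grepl(paste0("GGATCC", substr(row$top, 6, 70), "GGGCCC"),
                    doubled, fixed = TRUE))
})

test_that("polarity-mismatched ends do not self- or cross-ligate", {
  v <- make_mock_vector(seed = 13)
  frags <- digest(v$seq, c("BamHI", "ApaI"))
  e <- lapply(frags, fragment_ends)
  backbone <- frags[[which(!vapply(frags, function(f)
    fragment_ends(f)$left$overhang == "GATC" &&
      fragment_ends(f)$left$polarity == "five_prime", logical(1)))]]
  expect_message(none <- ligate(list(backbone)), "no compatible")
  expect_length(none, 0L)

  row <- table2[1, ]
  dup <- anneal(row$top, row$bottom)
  expect_message(two <- ligate(list(dup, dup)), "no compatible")
  expect_length(two, 0L)
})

test_that("the mock vector is reproducible and correctly annotated", {
  a <- make_mock_vector(seed = 21)
  b <- make_mock_vector(seed = 21)
  expect_identical(as.character(a$seq), as.character(b$seq))
  expect_false(identical(as.character(a$seq),
                         as.character(make_mock_vector(seed = 22)$seq)))

  hits <- screen_sites(a$seq, c("BamHI", "ApaI"))
  expect_equal(as.vector(tapply(hits$n_sites, hits$enzyme, max)),
               c(1L, 1L))

  # length bookkeeping: the stuffer fragment extent spans site-to-site,
  # GGATCC..GGGCCC inclusive minus the bottom-strand-only overhang bases
  frags <- digest(a$seq, c("BamHI", "ApaI"))
  stuffer <- frags[[which(vapply(frags, function(f)
    fragment_ends(f)$left$overhang == "GATC" &&
      fragment_ends(f)$left$polarity == "five_prime", logical(1)))]]
  expect_equal(nchar(stuffer$seq), 800L - 2L)
  expect_error(make_mock_vector(stuffer_len = 10), "at least 20")
})

test_that("full cycle recovers the input cassette for every bundled pair", {
  v <- make_mock_vector(seed = 2)
  for (i in seq_len(nrow(table2))) {
    pair <- list(name = table2$name[i], top = table2$top[i],
                 bottom = table2$bottom[i])
    construct <- clone_oligos(v, pair)
    refrags <- digest(dna(construct$seq, topology = "circular"),
                      c("BamHI", "ApaI"))
    insert <- refrags[[which.min(vapply(refrags, function(f) nchar(f$seq),
                                        numeric(1)))]]
    expect_identical(insert$seq, table2$top[i], label = table2$name[i])
    back <- parse_oligos(insert$seq,
                         as.character(revcomp(substring(insert$seq, 5, 71))))
    expect_equal(back$sense,
                 parse_oligos(pair$top, pair$bottom)$sense,
                 label = table2$name[i])
  }
})

test_that("circular identity is rotation-invariant", {
  s <- random_dna(40)
  rot <- paste0(substr(s, 11, 40), substr(s, 1, 10))
  expect_equal(canonical_rotation(s), canonical_rotation(rot))
})
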