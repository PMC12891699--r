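test_that("16S extraction honours GFF3 coordinates, strand and product filter", {
  ctg <- withr::with_seed(11, rand_seq(2000))
  g <- genome_record("g1", c(chr1 = ctg))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tbarrnap\trRNA\t1\t1500\t.\t+\t.\tID=r1;product=16S ribosomal RNA",
    "chr1\tbarrnap\trRNA\t100\t400\t.\t-\t.\tID=r2;product=16S ribosomal RNA",
    "chr1\tbarrnap\trRNA\t200\t900\t.\t+\t.\tID=r3;product=23S ribosomal RNA"),
    gff)
  ssu <- extract_ssu(g, gff)
  expect_identical(nrow(ssu), 2L)  # 23S filtered out
  expect_identical(ssu$length, c(1500L, 301L))
  expect_identical(ssu$sequence[1], substr(ctg, 1, 1500))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ctg, 100, 400))))
  expect_identical(ssu$sequence[2], rc)

  writeLines(c("##gff-version 3",
               "chr1\tx\trRNA\t1\t9999\t.\t+\t.\tID=r;product=16S ribosomal RNA"),
             gff)
  expect_error(extract_ssu(g, gff), "exceeds")
})

test_that("dereplication collapses duplicates and substrings to the longest representative", {
  base <- withr::with_seed(2, rand_seq(1500))
  recs <- rbind(
    mk_ssu("sA", base),
    mk_ssu("sB", base),                      # exact duplicate of sA
    mk_ssu("sC", substr(base, 100, 1300)))   # substring of sA
  out <- dereplicate(recs)
  expect_identical(out$seq_id, "sA")
  # length boundary is strict
  short <- mk_ssu("s999", withr::with_seed(3, rand_seq(999)))
  expect_identical(nrow(dereplicate(short)), 0L)
  # distinct sequences differing at one site are both kept
  v1 <- withr::with_seed(4, rand_seq(1200))
  v2 <- v1
  substr(v2, 600, 600) <- if (substr(v1, 600, 600) == "A") "C" else "A"
  both <- dereplicate(rbind(mk_ssu("x1", v1), mk_ssu("x2", v2)))
  expect_identical(both$seq_id, c("x1", "x2"))
})

test_that("a 10-sequence set with 3 duplicates and 2 substrings yields 5 representatives", {
  uniq <- withr::with_seed(5, replicate(5, rand_seq(1500)))
  recs <- rbind(
    mk_ssu(sprintf("u%d", 1:5), uniq),
    mk_ssu("u1copy", uniq[1]), mk_ssu("u2copy", uniq[2]),
    mk_ssu("u3copy", uniq[3]),
    mk_ssu("t1", substr(uniq[4], 50, 1400)),
    mk_ssu("t2", substr(uniq[5], 1, 1100)))
  out <- dereplicate(recs)
  # representative of an equal-length duplicate pair is the smaller seq_id
  expect_identical(out$seq_id, sprintf("u%d", 1:5))
  expect_setequal(out$sequence, uniq)
  expect_identical(dereplicate(out), out)  # idempotent
  # output is pairwise substring-free
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i != j) expect_false(grepl(out$sequence[i], out$sequence[j], fixed = TRUE))
  }
})

test_that("database build routes by phenotype and quarantines cross-set strings", {
  s1 <- withr::with_seed(6, rand_seq(1400))
  s2 <- withr::with_seed(7, rand_seq(1400))
  s3 <- withr::with_seed(8, rand_seq(1400))
  ssu <- rbind(mk_ssu("a", s1, source = "gVL"),
               mk_ssu("b", s2, source = "gLK"),
               mk_ssu("c", s2, source = "gNP"),   # same string, nonproducer
               mk_ssu("d", s3, source = "gNP"))
  calls <- data.frame(genome_id = c("gVL", "gLK", "gNP"),
                      phenotype = c("very_likely", "likely", "nonproducer"),
                      stringsAsFactors = FALSE)
  db <- suppressMessages(build_db(calls, ssu))
  expect_identical(db$producers$seq_id, "a")
  expect_identical(db$nonproducers$seq_id, "d")
  expect_setequal(db$conflicted$seq_id, c("b", "c"))
  # unknown source genome errors
  expect_error(build_db(calls, mk_ssu("z", s1, source = "mystery")), "mystery")
  # empty control set warns
  expect_warning(build_db(calls[1, , drop = FALSE],
                          mk_ssu("a", s1, source = "gVL")), "control")
})

test_that("reference database files round-trip through write and read", {
  comm <- make_ssu_community(seed = 17, n_otus = 5, mutant_fraction = 0)
  dir <- tempfile()
  db <- suppressWarnings(build_db(comm$calls, comm$refs, out_dir = dir))
  db2 <- read_reference_db(dir)
  expect_identical(db2$producers[, c("seq_id", "sequence", "phenotype_label")],
                   db$producers[, c("seq_id", "sequence", "phenotype_label")])
  expect_identical(db2$nonproducers$sequence, db$nonproducers$sequence)
})

test_that("OTU annotation is exact full-coverage matching over both strands", {
  ref <- withr::with_seed(9, rand_seq(1500))
  ctl <- withr::with_seed(10, rand_seq(1500))
  db <- structure(list(
    producers = transform(mk_ssu("prod1", ref, source = "gP"),
                          phenotype_label = "very_likely"),
    nonproducers = transform(mk_ssu("ctl1", ctl, source = "gN"),
                             phenotype_label = "nonproducer"),
    conflicted = NULL, build_params = list()), class = "ReferenceDB")
  q <- substr(ref, 500, 749)
  ann <- annotate_otus(c(otu1 = q), db)
  expect_identical(ann$call, "producer")
  expect_identical(ann$phenotype, "very_likely")
  # one substitution breaks strict identity
  q2 <- q
  substr(q2, 100, 100) <- if (substr(q, 100, 100) == "G") "T" else "G"
  expect_identical(annotate_otus(c(otu2 = q2), db)$call, "unassigned")
  # reverse-complemented query gets the same call
  qrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  expect_identical(annotate_otus(c(otu3 = qrc), db)$call, "producer")
  # a query present in both sets is ambiguous
  shared <- substr(ref, 1, 200)
  db$nonproducers <- transform(
    mk_ssu("ctl2", paste0(ctl, shared), source = "gN"),
    phenotype_label = "nonproducer")
  expect_identical(annotate_otus(c(otu4 = shared), db)$call, "ambiguous")
  # empty query errors
  f <- tempfile(fileext = ".fasta"); writeLines(character(0), f)
  expect_error(annotate_otus(f, db), "empty")
})

test_that("annotation agrees with the exhaustive substring-scan oracle", {
  withr::with_seed(21, {
    producers <- replicate(6, rand_seq(80))
    controls <- replicate(6, rand_seq(80))
    db <- structure(list(
      producers = transform(mk_ssu(sprintf("p%d", 1:6), producers),
                            phenotype_label = "likely"),
      nonproducers = transform(mk_ssu(sprintf("c%d", 1:6), controls),
                               phenotype_label = "nonproducer"),
      conflicted = NULL, build_params = list()), class = "ReferenceDB")
    queries <- c(
      vapply(1:10, function(i) {  # true substrings of either set
        src <- sample(c(producers, controls), 1)
        off <- sample(60, 1)
        substr(src, off, off + 19)
      }, character(1)),
      replicate(10, rand_seq(20)))  # random, mostly unassigned
    names(queries) <- sprintf("q%02d", seq_along(queries))
    ann <- annotate_otus(queries, db)
    want <- vapply(queries, oracle_annotate_call,
                   character(1), producers, controls)
    expect_identical(ann$call, unname(want[ann$otu_id]))
  })
})

test_that("per-sample producer profiles normalize correctly and flag empties", {
  counts <- matrix(c(100, 0, 0,   60, 140, 0,   0, 0, 0),
                   nrow = 3, dimnames = list(c("o1", "o2", "o3"),
                                             c("all_prod", "mixed", "empty")))
  tab <- abundance_table(counts)
  ann <- data.frame(otu_id = c("o1", "o2", "o3"),
                    call = c("producer", "nonproducer", "producer"),
                    phenotype = c("very_likely", NA, "possible"),
                    matched_refs = "", stringsAsFactors = FALSE)
  prof <- producer_profile(tab, ann)
  expect_equal(prof$producer_fraction, c(1.0, 0.30, 0))
  expect_identical(prof$flags, c("", "", "empty_sample"))
  expect_equal(prof$very_likely_fraction[2], 0.30)
  # missing annotations are warned about and treated unassigned
  expect_warning(producer_profile(tab, ann[1:2, ]), "unassigned")
  counts[1, 1] <- -5
  expect_error(suppressWarnings(abundance_table(counts)), "non-negative")
})
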