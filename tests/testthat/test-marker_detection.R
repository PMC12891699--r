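test_that("domtbl parsing maps profiles, skips comments and unknowns, flags bad lines", {
  cat_ <- mini_catalog()
  f <- tempfile(fileext = ".domtbl")
  writeLines(c(
    "# comment line",
    domtbl_line("p1", "ringO", "ACC2", 3e-12),
    domtbl_line("ctgZ_7", "preA", "ACC1", 1e-9),
    domtbl_line("p2", "unknownProfile", "NOPE", 1e-20)), f)
  hits <- parse_domtbl(f, cat_)
  expect_identical(hits$marker_id, c("ringO", "preA"))
  expect_equal(hits$evalue[1], 3e-12)
  # prodigal-style target name recovers its contig; plain target does not
  expect_identical(hits$contig_id, c(NA, "ctgZ"))

  writeLines(c(domtbl_line("p1", "ringO", "ACC2", 1e-9), "p1 broken line"), f)
  expect_error(parse_domtbl(f, cat_), "line 2")
})

test_that("the E-value gate keeps the boundary and drops just beyond it", {
  hits <- rbind(mk_hit("p1", "ringO", evalue = 1e-6),
                mk_hit("p2", "ringX", evalue = 1.01e-6))
  pm <- resolve_hits(hits)
  expect_identical(names(pm$detected), "ringO")
})

test_that("each protein supports exactly one marker via the stated tie-breaks", {
  # bitscore wins
  hits <- rbind(mk_hit("p1", "chelO", bitscore = 80),
                mk_hit("p1", "ringO", bitscore = 75))
  pm <- resolve_hits(hits)
  expect_identical(names(pm$detected), "chelO")
  # equal bitscore -> lower evalue; fully tied -> lexicographic marker
  hits <- rbind(mk_hit("p1", "ringX", bitscore = 80, evalue = 1e-8),
                mk_hit("p1", "ringO", bitscore = 80, evalue = 1e-10),
                mk_hit("p2", "zzz9", bitscore = 50, evalue = 1e-9),
                mk_hit("p2", "aaa1", bitscore = 50, evalue = 1e-9))
  pm <- resolve_hits(hits)
  expect_setequal(names(pm$detected), c("ringO", "aaa1"))
  # two proteins, same marker -> two supports
  hits <- rbind(mk_hit("p1", "ringO"), mk_hit("p2", "ringO"))
  expect_identical(nrow(resolve_hits(hits)$detected$ringO), 2L)
})

test_that("hit resolution matches the brute-force assignment oracle", {
  for (s in 1:100) {
    hits <- withr::with_seed(s, random_hits(sample(1:20, 1)))
    pm <- resolve_hits(hits)
    got <- lapply(pm$detected, function(h) sort(h$protein_id))
    want <- oracle_resolve(hits)
    if (length(want) == 0L) {
      expect_identical(length(got), 0L, info = sprintf("seed %d", s))
    } else {
      want_by_marker <- lapply(split(names(want), unlist(want)), sort)
      expect_identical(got[order(names(got))],
                       want_by_marker[order(names(want_by_marker))],
                       info = sprintf("seed %d", s))
    }
  }
})

test_that("raising e_max never shrinks the detected set", {
  for (s in 1:25) {
    hits <- withr::with_seed(s, random_hits(15))
    d1 <- names(resolve_hits(hits, e_max = 1e-10)$detected)
    d2 <- names(resolve_hits(hits, e_max = 1e-6)$detected)
    d3 <- names(resolve_hits(hits, e_max = 1e-4)$detected)
    expect_true(all(d1 %in% d2) && all(d2 %in% d3))
  }
})

test_that("contig screening applies its three guards and never adds markers", {
  g <- genome_record("g1", c(
    big1 = rand_seq(5000), big2 = rand_seq(5000), tiny = rand_seq(800)),
    lineage = "Bacteria;Actinobacteria")
  # (a) lone marker on a short contig is dropped
  hits <- rbind(mk_hit("big1_1", "ringO", contig_id = "big1"),
                mk_hit("tiny_1", "loopA", contig_id = "tiny"))
  pm <- contig_screen(resolve_hits(hits, genome_id = "g1"), g)
  expect_identical(names(pm$detected), "ringO")
  expect_match(pm$flags, "short_contig_drop", all = FALSE)

  # (b) phylum conflict with the majority drops that contig's support
  hits <- rbind(mk_hit("big1_1", "ringO", contig_id = "big1"),
                mk_hit("big2_1", "loopA", contig_id = "big2"))
  tax <- c(big1 = "Bacteria;Actinobacteria", big2 = "Bacteria;Proteobacteria",
           tiny = "Bacteria;Actinobacteria")
  pm <- contig_screen(resolve_hits(hits, genome_id = "g1"), g,
                      contig_taxonomy = tax)
  expect_identical(names(pm$detected), "ringO")
  expect_match(pm$flags, "foreign_contig_drop", all = FALSE)

  # (c) all markers on one small contig -> suspect flag, markers retained
  g2 <- genome_record("g2", c(small = rand_seq(2000), huge = rand_seq(200000)))
  hits <- rbind(mk_hit("small_1", "ringO", contig_id = "small"),
                mk_hit("small_2", "loopA", contig_id = "small"))
  pm <- contig_screen(resolve_hits(hits, genome_id = "g2"), g2)
  expect_setequal(names(pm$detected), c("ringO", "loopA"))
  expect_true("single_contig_suspect" %in% pm$flags)

  # unknown contig errors; detected set is always a subset of the input
  hits <- mk_hit("ghost_1", "ringO", contig_id = "ghost")
  expect_error(contig_screen(resolve_hits(hits, genome_id = "g1"), g), "ghost")
  for (s in 1:10) {
    hits <- withr::with_seed(s, {
      h <- random_hits(12)
      h$contig_id <- sample(c("big1", "big2", "tiny"), nrow(h), replace = TRUE)
      h
    })
    before <- resolve_hits(hits, genome_id = "g1")
    after <- contig_screen(before, g)
    expect_true(all(names(after$detected) %in% names(before$detected)))
  }
})

test_that("the hmmsearch backend round-trips a planted exact match", {
  # toy profile built from identical copies of one peptide; searching that
  # same peptide must produce a confident hit mapped through the catalog
  pep <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKRQTLGQHD"
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("seq1 %s", pep), sprintf("seq2 %s", pep),
               sprintf("seq3 %s", pep), "//"), sto)
  hmm <- tempfile(fileext = ".hmm")
  status <- system2(Sys.which("hmmbuild"),
                    c("-n", "ACC2", "--amino", hmm, sto),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  faa <- tempfile(fileext = ".faa")
  writeLines(c(">ctgQ_1 # 1 # 258 # 1 # ID=1_1", pep), faa)
  ps <- read_proteins(faa, "g1")
  hits <- search_markers(ps, mini_catalog(), hmm)
  expect_identical(unique(hits$marker_id), "ringO")
  expect_lt(min(hits$evalue), 1e-6)
  expect_identical(unique(hits$contig_id), "ctgQ")
})

test_that("search_markers on an empty protein set returns no hits, and a missing backend is actionable", {
  ps <- structure(list(genome_id = "g", proteins = data.frame(
    protein_id = character(0), aa_sequence = character(0),
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0))), class = "ProteinSet")
  expect_identical(nrow(search_markers(ps, mini_catalog(), "unused.hmm")), 0L)
  ps2 <- structure(list(genome_id = "g", proteins = data.frame(
    protein_id = "p1", aa_sequence = "MKL", contig_id = NA_character_,
    start = NA_integer_, end = NA_integer_, strand = NA_character_)),
    class = "ProteinSet")
  withr::local_envvar(PATH = tempdir())
  expect_error(search_markers(ps2, mini_catalog(), "x.hmm"), "--hits|precomputed")
})
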