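# Synthetic fixture generators: every input the pipeline consumes can be
# produced here with known ground truth and a single explicit seed, so the
# full workflow runs and validates with no external data or search backend.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic marker catalog
#'
#' Builds a catalog with the same structure as the shipped default: shared
#' precursor/adenosylation/loop modules, branch-exclusive ring and chelation
#' modules for both oxygen branches (all required), and non-required salvage
#' markers. Each marker gets a unique synthetic profile accession. Identical
#' seeds give identical catalogs.
#'
#' @param n_per_module Markers per module (per branch for ring/chelation);
#'   must be >= 1.
#' @param seed Integer seed.
#' @return A validated `MarkerCatalog`.
#' @export
make_catalog <- function(n_per_module = 3, seed = 1) {
  stopifnot(n_per_module >= 1)
  n <- n_per_module
  rows <- list()
  add <- function(prefix, module, branch, count, required) {
    for (i in seq_len(count)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        marker_id = sprintf("%s%d", prefix, i),
        gene_symbol = sprintf("%s%d", prefix, i),
        module = module, branch = branch, required = required, weight = 1,
        stringsAsFactors = FALSE)
    }
  }
  add("prec", "precursor", "shared", n, TRUE)
  add("ringA", "ring", "aerobic", n, TRUE)
  add("ringN", "ring", "anaerobic", n, TRUE)
  add("chelA", "chelation", "aerobic", n, TRUE)
  add("chelN", "chelation", "anaerobic", n, TRUE)
  add("aden", "adenosylation", "shared", n, TRUE)
  add("loop", "loop", "shared", n, TRUE)
  add("salv", "salvage", "shared", n, FALSE)
  cat_df <- do.call(rbind, rows)
  accs <- withr::with_seed(seed, sample.int(89999, nrow(cat_df)) + 10000)
  cat_df$profile_accessions <- sprintf("SYN%05d", accs)
  validate_catalog(cat_df[, c("marker_id", "gene_symbol", "profile_accessions",
                              "module", "branch", "required", "weight")])
}

# feasible marker counts for a target class, staying `margin` away from
# every rubric boundary
feasible_counts <- function(phenotype, n_required, rubric, margin = 0.05) {
  lo_hi <- switch(phenotype,
    nonproducer = c(0, 0),
    possible = c(rubric$t_possible + margin, rubric$t_likely - margin),
    likely = c(rubric$t_likely + margin, rubric$t_very - margin),
    very_likely = c(rubric$t_very + margin, 1),
    stop("unknown phenotype: ", phenotype))
  if (phenotype == "nonproducer") return(0L)
  k <- 0:n_required
  ks <- k[k / n_required >= lo_hi[1] & k / n_required <= lo_hi[2]]
  if (!length(ks)) {
    stop(sprintf("no marker count puts completeness inside the %s band",
                 phenotype), call. = FALSE)
  }
  ks
}

#' Plant a synthetic genome with a known producer phenotype
#'
#' Samples a marker complement whose branch pathway completeness sits at
#' least 0.05 inside the target class band, writes passing hit evidence
#' (E-values in `[1e-30, 1e-7]`) plus decoy hits just beyond the gate
#' (`(1e-6, 1e-3]`), and optionally stages one of three contamination
#' scenarios so each contig-screening guard can fire: `short_contig` (an
#' extra marker alone on an 800-nt contig), `foreign_contig` (an extra
#' marker on a contig with conflicting phylum taxonomy) or `single_contig`
#' (all true markers on one contig under 5% of the genome, triggering the
#' one-class downgrade). Nonproducer genomes carry decoy hits only.
#'
#' @param phenotype Target class (`very_likely`, `likely`, `possible`,
#'   `nonproducer`).
#' @param branch Oxygen branch to plant (`aerobic` or `anaerobic`).
#' @param catalog A `MarkerCatalog` (e.g. [make_catalog()]).
#' @param seed Integer seed.
#' @param contamination_scenario One of `none`, `short_contig`,
#'   `foreign_contig`, `single_contig`.
#' @param rubric The `Rubric` the planted completeness is calibrated to.
#' @param genome_id Identifier (default derived from the arguments).
#' @return List with `genome` (`GenomeRecord`, completeness 100 /
#'   contamination 0), `hits` (data frame), `contig_taxonomy` (or `NULL`)
#'   and `truth` (planted and expected phenotype/branch/completeness,
#'   selected markers, scenario, seed).
#' @export
plant_genome <- function(phenotype, branch, catalog, seed,
                         contamination_scenario = c("none", "short_contig",
                                                    "foreign_contig",
                                                    "single_contig"),
                         rubric = default_rubric(), genome_id = NULL) {
  contamination_scenario <- match.arg(contamination_scenario)
  stopifnot(branch %in% c("aerobic", "anaerobic"))
  catalog <- validate_catalog(catalog)
  if (is.null(genome_id)) {
    genome_id <- sprintf("sim_%s_%s_%d", phenotype, substr(branch, 1, 2), seed)
  }
  withr::with_seed(seed, {
    req <- catalog[catalog$required & catalog$branch %in% c(branch, "shared"), ]
    ks <- feasible_counts(phenotype, nrow(req), rubric)
    k <- if (length(ks) > 1L) sample(ks, 1L) else ks

    must <- character(0)
    if (k > 0L) {
      ring_b <- req$marker_id[req$module == "ring" & req$branch == branch]
      must <- sample(ring_b, 1L)  # guarantees the route call
      if (phenotype == "very_likely") {
        chel_b <- req$marker_id[req$module == "chelation" & req$branch == branch]
        must <- c(must, sample(chel_b, 1L))
      }
    }
    pool <- setdiff(req$marker_id, must)
    selected <- c(must, if (k - length(must) > 0L)
      sample(pool, k - length(must)) else character(0))

    # contigs
    single <- contamination_scenario == "single_contig"
    n_main <- if (single) 4L else 5L
    main_len <- if (single) rep(20000L, n_main) else
      sample(8000:15000, n_main, replace = TRUE)
    contigs <- stats::setNames(vapply(main_len, random_dna, character(1)),
                               sprintf("ctg%02d", seq_len(n_main)))
    marker_ctg <- NULL
    if (single) {
      contigs <- c(contigs, ctg_m = random_dna(1500L))
      marker_ctg <- "ctg_m"
    }

    extra_marker <- NA_character_
    if (contamination_scenario %in% c("short_contig", "foreign_contig")) {
      bad_ctg <- if (contamination_scenario == "short_contig") "ctg_s" else "ctg_f"
      contigs <- c(contigs,
                   stats::setNames(random_dna(
                     if (contamination_scenario == "short_contig") 800L else 3000L),
                     bad_ctg))
      cand <- catalog$marker_id[catalog$branch %in% c(branch, "shared") &
                                  !catalog$marker_id %in% selected]
      pref <- cand[!catalog$required[match(cand, catalog$marker_id)]]
      extra_marker <- if (length(pref)) sample(pref, 1L) else sample(cand, 1L)
    }

    prot_counter <- stats::setNames(integer(length(contigs)), names(contigs))
    new_hit <- function(marker, contig, e_lo, e_hi) {
      prot_counter[contig] <<- prot_counter[contig] + 1L
      alen <- sample(150:400, 1L)
      data.frame(
        protein_id = sprintf("%s_%d", contig, prot_counter[contig]),
        contig_id = contig, marker_id = marker,
        evalue = 10^stats::runif(1, e_lo, e_hi),
        bitscore = round(stats::runif(1, 80, 300), 1),
        ali_from = 1L, ali_to = alen, stringsAsFactors = FALSE)
    }

    main_ids <- sprintf("ctg%02d", seq_len(n_main))
    hits <- list()
    for (m in selected) {
      ctg <- marker_ctg %||% sample(main_ids, 1L)
      hits[[length(hits) + 1L]] <- new_hit(m, ctg, -30, -7)
    }
    if (!is.na(extra_marker)) {
      bad_ctg <- setdiff(names(contigs), c(main_ids, "ctg_m"))
      hits[[length(hits) + 1L]] <- new_hit(extra_marker, bad_ctg, -30, -7)
    }
    for (d in seq_len(3L)) {  # decoys straddle the gate from above
      hits[[length(hits) + 1L]] <- new_hit(sample(catalog$marker_id, 1L),
                                           sample(main_ids, 1L), -5.995, -3)
    }
    hits <- do.call(rbind, hits)

    contig_taxonomy <- NULL
    lineage <- "Bacteria;Proteobacteria"
    if (contamination_scenario == "foreign_contig") {
      contig_taxonomy <- stats::setNames(
        c(rep("Bacteria;Proteobacteria", n_main), "Bacteria;Firmicutes"),
        c(main_ids, "ctg_f"))
    }

    expected_phenotype <- phenotype
    if (single && phenotype != "nonproducer") {
      expected_phenotype <- .PHENOTYPES[match(phenotype, .PHENOTYPES) - 1L]
    }
    truth <- data.frame(
      genome_id = genome_id,
      planted_phenotype = phenotype,
      expected_phenotype = expected_phenotype,
      planted_branch = branch,
      expected_branch = if (phenotype == "nonproducer") "none" else branch,
      planted_completeness = k / nrow(req),
      markers = paste(sort(selected), collapse = ";"),
      extra_marker = extra_marker,
      scenario = contamination_scenario,
      seed = seed, stringsAsFactors = FALSE)

    list(genome = genome_record(genome_id, contigs, completeness = 100,
                                contamination = 0, lineage = lineage,
                                source = "synthetic"),
         hits = hits, contig_taxonomy = contig_taxonomy, truth = truth)
  })
}

#' Write marker hits as a HMMER3 per-domain table
#'
#' Emits the 23-column `--domtblout` layout so fixture evidence is consumed
#' through the same [parse_domtbl()] path as real search output.
#'
#' @param hits Hit data frame (see [plant_genome()]).
#' @param catalog The `MarkerCatalog` the hits refer to (supplies profile
#'   names and accessions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(hits, catalog, path) {
  idx <- match(hits$marker_id, catalog$marker_id)
  acc <- vapply(strsplit(catalog$profile_accessions[idx], ";", fixed = TRUE),
                `[`, character(1), 1L)
  header <- c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
              "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
              "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  lines <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9s %6.1f %5.1f %3d %3d %9s %9s %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    hits$protein_id, "-", hits$ali_to + 50L,
    catalog$gene_symbol[idx], acc, 400L,
    sprintf("%.2e", hits$evalue), hits$bitscore, 0.1, 1L, 1L,
    sprintf("%.2e", hits$evalue), sprintf("%.2e", hits$evalue),
    hits$bitscore, 0.1, 1L, hits$ali_to - hits$ali_from + 1L,
    hits$ali_from, hits$ali_to, hits$ali_from, hits$ali_to, 0.95, "-")
  writeLines(c(header, lines, "#"), path)
  invisible(path)
}

#' Generate a 16S reference + OTU community with known annotation truth
#'
#' Reference sequences are independent random 16S-length nucleotide strings
#' labelled producer (with a phenotype class) or nonproducer. OTU
#' representatives are V4-length exact substrings of one reference (truth:
#' that reference's set) or single-substitution mutants of such substrings
#' (truth: unassigned, since matching is strict). Each OTU is verified
#' against every reference on both strands at generation time, so the truth
#' labels are exact by construction. Counts follow a log-normal-Poisson
#' mixture.
#'
#' @param n_producer_refs,n_control_refs Reference set sizes.
#' @param n_otus Number of OTU representatives.
#' @param mutant_fraction Fraction of OTUs mutated (rounded to a count).
#' @param seed Integer seed.
#' @param n_samples Samples in the count table (default 12).
#' @param otu_len OTU representative length, nt (default 250, typical V4).
#' @return List: `refs` (SSURecord data frame), `calls` (synthetic producer
#'   calls for the source genomes), `otus` (named sequence vector), `table`
#'   (`AbundanceTable`), `truth` (per-OTU expected call).
#' @export
make_ssu_community <- function(n_producer_refs = 6, n_control_refs = 6,
                               n_otus = 30, mutant_fraction = 0.2, seed = 1,
                               n_samples = 12, otu_len = 250) {
  stopifnot(mutant_fraction >= 0, mutant_fraction <= 1)
  withr::with_seed(seed, {
    ref_len <- function() sample(1200:1600, 1L)
    n_refs <- n_producer_refs + n_control_refs
    refs <- data.frame(
      seq_id = sprintf("ref%03d", seq_len(n_refs)),
      source_genome_id = c(sprintf("pgen%03d", seq_len(n_producer_refs)),
                           sprintf("cgen%03d", seq_len(n_control_refs))),
      sequence = vapply(seq_len(n_refs), function(i) random_dna(ref_len()),
                        character(1)),
      stringsAsFactors = FALSE)
    refs$length <- nchar(refs$sequence)
    refs$set <- rep(c("producer", "control"),
                    c(n_producer_refs, n_control_refs))
    refs$phenotype_label <- c(
      sample(c("very_likely", "likely", "possible"), n_producer_refs,
             replace = TRUE),
      rep("nonproducer", n_control_refs))
    refs$lineage <- NA_character_
    calls <- data.frame(genome_id = refs$source_genome_id,
                        phenotype = refs$phenotype_label,
                        stringsAsFactors = FALSE)

    matches_any <- function(q, seqs) {
      qrc <- revcomp(q)
      any(vapply(seqs, function(r) grepl(q, r, fixed = TRUE) ||
                   grepl(qrc, r, fixed = TRUE), logical(1)))
    }
    n_mut <- round(mutant_fraction * n_otus)
    is_mut <- seq_len(n_otus) %in%
      (if (n_mut > 0) sample(n_otus, n_mut) else integer(0))

    otus <- character(n_otus)
    truth <- vector("list", n_otus)
    for (i in seq_len(n_otus)) {
      for (try in 1:50) {
        j <- sample(n_refs, 1L)
        start <- sample(refs$length[j] - otu_len + 1L, 1L)
        q <- substr(refs$sequence[j], start, start + otu_len - 1L)
        if (is_mut[i]) {
          pos <- sample(otu_len, 1L)
          old <- substr(q, pos, pos)
          substr(q, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          ok <- !matches_any(q, refs$sequence)
          expected <- "unassigned"
        } else {
          other <- refs$set != refs$set[j]
          ok <- !matches_any(q, refs$sequence[other])
          expected <- refs$set[j]
          expected <- if (expected == "control") "nonproducer" else "producer"
        }
        if (ok) break
        if (try == 50) stop("could not generate a truth-consistent OTU")
      }
      otus[i] <- q
      truth[[i]] <- data.frame(
        otu_id = sprintf("OTU%04d", i), expected_call = expected,
        source_ref = if (is_mut[i]) NA_character_ else refs$seq_id[j],
        mutant = is_mut[i], stringsAsFactors = FALSE)
    }
    names(otus) <- sprintf("OTU%04d", seq_len(n_otus))
    truth <- do.call(rbind, truth)

    lambda <- stats::rlnorm(n_otus, meanlog = log(300), sdlog = 0.8)
    counts <- t(vapply(lambda, function(l) stats::rpois(n_samples, l),
                       integer(n_samples)))
    dimnames(counts) <- list(names(otus), sprintf("S%03d", seq_len(n_samples)))
    labels <- ifelse(truth$mutant, "unassigned",
                     ifelse(truth$expected_call == "producer",
                            refs$phenotype_label[match(truth$source_ref, refs$seq_id)],
                            "nonproducer"))
    names(labels) <- truth$otu_id

    list(refs = refs[, c("seq_id", "source_genome_id", "sequence", "length",
                         "phenotype_label", "lineage")],
         calls = calls, otus = otus,
         table = abundance_table(counts, labels), truth = truth)
  })
}

#' Generate an OTU count table with planted correlated blocks
#'
#' Latent multivariate-normal blocks with within-block correlation
#' `block_rho` are exponentiated into Poisson rates and sampled into counts,
#' so block members co-occur across samples. Blocks occupy half the OTUs
#' (equal sizes); the remaining OTUs are mutually independent background.
#' The first block is labelled `very_likely` — the planted producer hub
#' block — and every other OTU `nonproducer`, so with `block_rho` high the
#' producer group carries dense within-block connectivity against a sparse
#' background.
#'
#' @param n_otus,n_samples Table dimensions.
#' @param n_blocks Number of correlated blocks.
#' @param block_rho Within-block latent correlation in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `table` (`AbundanceTable`) and `truth` (per-OTU block
#'   membership plus the planted rho).
#' @export
make_correlated_counts <- function(n_otus = 40, n_samples = 50, n_blocks = 2,
                                   block_rho = 0.8, seed = 1) {
  stopifnot(block_rho >= 0, block_rho <= 1, n_blocks >= 1)
  withr::with_seed(seed, {
    bsize <- max(2L, n_otus %/% (2L * n_blocks))
    block <- rep(0L, n_otus)
    block[seq_len(min(n_otus, bsize * n_blocks))] <-
      rep(seq_len(n_blocks), each = bsize)[seq_len(min(n_otus, bsize * n_blocks))]
    z <- matrix(0, n_otus, n_samples)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      sigma <- matrix(block_rho, length(idx), length(idx))
      diag(sigma) <- 1
      z[idx, ] <- t(chol(sigma)) %*%
        matrix(stats::rnorm(length(idx) * n_samples), length(idx))
    }
    free <- which(block == 0L)
    if (length(free)) {
      z[free, ] <- matrix(stats::rnorm(length(free) * n_samples), length(free))
    }
    lambda <- exp(log(30) + 0.7 * z)
    counts <- matrix(stats::rpois(length(lambda), lambda), n_otus, n_samples)
    dimnames(counts) <- list(sprintf("OTU%03d", seq_len(n_otus)),
                             sprintf("S%03d", seq_len(n_samples)))
    labels <- stats::setNames(
      ifelse(block == 1L, "very_likely", "nonproducer"), rownames(counts))
    truth <- data.frame(otu_id = rownames(counts), block = block,
                        block_rho = block_rho, seed = seed,
                        stringsAsFactors = FALSE)
    list(table = abundance_table(counts, labels), truth = truth)
  })
}
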