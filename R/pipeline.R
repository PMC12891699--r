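# Fixture writing and end-to-end orchestration: simulate a full study's
# worth of inputs into plain-text files, then run classify -> build-db ->
# annotate -> network from those files alone.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a complete fixture set on disk
#'
#' Writes plain-text inputs for the requested preset under `out_dir`,
#' together with truth tables: `classifier/` (marker catalog TSV, genome
#' FASTAs, per-genome domtbl hit tables, metadata and contig-taxonomy TSVs),
#' `ssu/` (16S records, synthetic producer calls, OTU representative FASTA,
#' count table) and `network/` (count table with planted correlated blocks
#' plus labels). All randomness derives from `seed`; identical seeds give
#' byte-identical files.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param preset One of `full`, `classifier`, `ssu`, `network`.
#' @param n_rep Genomes per phenotype-by-branch combination for the
#'   classifier preset (default 2).
#' @return `out_dir`, invisibly.
#' @export
simulate_fixtures <- function(out_dir, seed = 1,
                              preset = c("full", "classifier", "ssu", "network"),
                              n_rep = 2) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))

  if (preset %in% c("full", "classifier")) {
    cdir <- file.path(out_dir, "classifier")
    dir.create(file.path(cdir, "genomes"), showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(cdir, "hits"), showWarnings = FALSE)
    catalog <- make_catalog(n_per_module = 3, seed = sub_seeds[1])
    write_tsv(catalog, file.path(cdir, "catalog.tsv"))

    combos <- expand.grid(phenotype = .PHENOTYPES,
                          branch = c("aerobic", "anaerobic"),
                          rep = seq_len(n_rep), stringsAsFactors = FALSE)
    truth <- list()
    meta <- list()
    g_seeds <- withr::with_seed(sub_seeds[1],
                                sample.int(.Machine$integer.max - 1L, nrow(combos)))
    for (i in seq_len(nrow(combos))) {
      fx <- plant_genome(combos$phenotype[i], combos$branch[i], catalog,
                         seed = g_seeds[i],
                         genome_id = sprintf("g%03d_%s_%s", i,
                                             combos$phenotype[i],
                                             substr(combos$branch[i], 1, 2)))
      write_genome_fasta(fx$genome, file.path(cdir, "genomes",
                                              paste0(fx$genome$genome_id, ".fasta")))
      write_domtbl(fx$hits, catalog, file.path(cdir, "hits",
                                               paste0(fx$genome$genome_id, ".domtbl")))
      truth[[i]] <- fx$truth
      meta[[i]] <- data.frame(genome_id = fx$genome$genome_id,
                              completeness = fx$genome$completeness,
                              contamination = fx$genome$contamination,
                              lineage = paste(fx$genome$lineage, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, truth), file.path(cdir, "truth_genomes.tsv"))
    write_tsv(do.call(rbind, meta), file.path(cdir, "metadata.tsv"))
  }

  if (preset %in% c("full", "ssu")) {
    sdir <- file.path(out_dir, "ssu")
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    comm <- make_ssu_community(seed = sub_seeds[2])
    write_tsv(comm$refs, file.path(sdir, "ssu_records.tsv"))
    write_tsv(comm$calls, file.path(sdir, "calls.tsv"))
    writeLines(paste0(">", names(comm$otus), "\n", comm$otus),
               file.path(sdir, "otus.fasta"))
    counts_df <- data.frame(otu_id = rownames(comm$table$counts),
                            comm$table$counts, check.names = FALSE,
                            stringsAsFactors = FALSE)
    write_tsv(counts_df, file.path(sdir, "counts.tsv"))
    write_tsv(comm$truth, file.path(sdir, "truth_otus.tsv"))
  }

  if (preset %in% c("full", "network")) {
    ndir <- file.path(out_dir, "network")
    dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
    net <- make_correlated_counts(seed = sub_seeds[3])
    counts_df <- data.frame(otu_id = rownames(net$table$counts),
                            net$table$counts, check.names = FALSE,
                            stringsAsFactors = FALSE)
    write_tsv(counts_df, file.path(ndir, "counts.tsv"))
    write_tsv(data.frame(otu_id = names(net$table$labels),
                         label = unname(net$table$labels),
                         stringsAsFactors = FALSE),
              file.path(ndir, "labels.tsv"))
    write_tsv(net$truth, file.path(ndir, "truth_blocks.tsv"))
  }
  invisible(out_dir)
}

#' Run the full pipeline from fixture files
#'
#' Consumes a directory laid out by [simulate_fixtures()] (or equivalently
#' structured real data) and writes: `calls.tsv` (per-genome producer
#' classification), `refdb/` (the producer/nonproducer 16S reference),
#' `annotations.tsv` and `profile.tsv` (OTU annotation and per-sample
#' producer profile), `edges.tsv`, `metrics.tsv` and `comparison.tsv`
#' (co-occurrence network, per-node topology, producer-vs-nonproducer
#' comparison). Everything is deterministic: rerunning on the same inputs
#' reproduces the outputs byte for byte.
#'
#' @param fixture_dir Input directory (see [simulate_fixtures()]).
#' @param out_dir Output directory (created).
#' @param min_reads Rare-OTU threshold for the network step (default 100).
#' @return Named list of the objects computed, invisibly.
#' @export
run_pipeline <- function(fixture_dir, out_dir, min_reads = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  cdir <- file.path(fixture_dir, "classifier")
  if (dir.exists(cdir)) {
    catalog <- read_marker_catalog(file.path(cdir, "catalog.tsv"))
    meta <- read_genome_metadata(file.path(cdir, "metadata.tsv"))
    genomes <- lapply(seq_len(nrow(meta)), function(i) {
      read_genome_fasta(file.path(cdir, "genomes",
                                  paste0(meta$genome_id[i], ".fasta")),
                        meta$genome_id[i], metadata = meta[i, ])
    })
    hits <- stats::setNames(
      file.path(cdir, "hits", paste0(meta$genome_id, ".domtbl")),
      meta$genome_id)
    res$calls <- classify_batch(genomes, as.list(hits), catalog = catalog)
    write_tsv(res$calls, file.path(out_dir, "calls.tsv"))
  }

  sdir <- file.path(fixture_dir, "ssu")
  if (dir.exists(sdir)) {
    ssu <- utils::read.delim(file.path(sdir, "ssu_records.tsv"),
                             stringsAsFactors = FALSE)
    calls <- utils::read.delim(file.path(sdir, "calls.tsv"),
                               stringsAsFactors = FALSE)
    res$db <- build_db(calls, ssu, out_dir = file.path(out_dir, "refdb"))
    res$annotations <- annotate_otus(file.path(sdir, "otus.fasta"), res$db)
    write_tsv(res$annotations, file.path(out_dir, "annotations.tsv"))
    tab <- read_abundance_tsv(file.path(sdir, "counts.tsv"))
    res$profile <- producer_profile(tab, res$annotations)
    write_tsv(res$profile, file.path(out_dir, "profile.tsv"))
  }

  ndir <- file.path(fixture_dir, "network")
  if (dir.exists(ndir)) {
    tab <- read_abundance_tsv(file.path(ndir, "counts.tsv"),
                              file.path(ndir, "labels.tsv"))
    tab <- filter_rare(tab, min_total = min_reads)
    res$network <- build_network(tab)
    write_tsv(res$network$edges, file.path(out_dir, "edges.tsv"))
    res$metrics <- topology(res$network)
    write_tsv(res$metrics, file.path(out_dir, "metrics.tsv"))
    res$comparison <- compare_groups(res$metrics)
    write_tsv(res$comparison, file.path(out_dir, "comparison.tsv"))
  }
  invisible(res)
}
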