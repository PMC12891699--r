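#' Extract 16S rRNA sequences from a genome
#'
#' Takes rRNA coordinates from a GFF3 file (e.g. barrnap output), keeps rows
#' typed `rRNA` whose `product`/`Name` attribute mentions 16S, slices the
#' corresponding contig (1-based inclusive, GFF3 convention),
#' reverse-complements minus-strand features and normalizes U to T.
#'
#' @param genome A `GenomeRecord`.
#' @param rrna_gff Path to a GFF3 file with rRNA features on this genome's
#'   contigs.
#' @return Data frame of `SSURecord`s: `seq_id`, `source_genome_id`,
#'   `sequence`, `length`, `phenotype_label`, `lineage`.
#' @export
extract_ssu <- function(genome, rrna_gff) {
  gr <- rtracklayer::import(rrna_gff)
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(empty_ssu())
  desc <- df$product %||% df$Name %||% rep("", nrow(df))
  desc[is.na(desc)] <- ""
  is16s <- tolower(df$type) == "rrna" & grepl("16S", desc, ignore.case = TRUE)
  df <- df[is16s, , drop = FALSE]
  if (nrow(df) == 0L) return(empty_ssu())

  recs <- lapply(seq_len(nrow(df)), function(i) {
    ctg <- as.character(df$seqnames[i])
    if (!ctg %in% names(genome$contigs)) {
      stop(sprintf("GFF contig '%s' absent from genome '%s'", ctg,
                   genome$genome_id), call. = FALSE)
    }
    clen <- nchar(genome$contigs[[ctg]])
    if (df$start[i] < 1L || df$end[i] > clen) {
      stop(sprintf("feature %d..%d exceeds contig '%s' length %d",
                   df$start[i], df$end[i], ctg, clen), call. = FALSE)
    }
    s <- substr(genome$contigs[[ctg]], df$start[i], df$end[i])
    if (as.character(df$strand[i]) == "-") s <- revcomp(s)
    s <- chartr("U", "T", toupper(s))
    data.frame(
      seq_id = sprintf("%s_16S_%d", genome$genome_id, i),
      source_genome_id = genome$genome_id,
      sequence = s, length = nchar(s),
      phenotype_label = NA_character_,
      lineage = if (is.null(genome$lineage)) NA_character_ else
        paste(genome$lineage, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

empty_ssu <- function() {
  data.frame(seq_id = character(0), source_genome_id = character(0),
             sequence = character(0), length = integer(0),
             phenotype_label = character(0), lineage = character(0),
             stringsAsFactors = FALSE)
}

#' Dereplicate 16S sequences into nonredundant representatives
#'
#' Drops sequences shorter than `min_len`, then collapses exact duplicates
#' and exact substrings into a single representative — the longest sequence,
#' ties broken by lexicographically smallest `seq_id`. Output is sorted by
#' `seq_id` and the operation is idempotent.
#'
#' @param records Data frame of `SSURecord`s.
#' @param min_len Minimum retained length, nt (default 1000; strictly
#'   shorter records are dropped).
#' @return The nonredundant subset, sorted by `seq_id`.
#' @export
dereplicate <- function(records, min_len = 1000) {
  records <- records[records$length >= min_len, , drop = FALSE]
  if (nrow(records) <= 1L) {
    return(records[order(records$seq_id), , drop = FALSE])
  }
  ord <- order(-records$length, records$seq_id)
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  reps <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    absorbed <- any(vapply(reps, function(r) grepl(s, r, fixed = TRUE),
                           logical(1)))
    if (!absorbed) {
      keep[i] <- TRUE
      reps <- c(reps, s)
    }
  }
  out <- records[keep, , drop = FALSE]
  out[order(out$seq_id), , drop = FALSE]
}

#' Build a producer/nonproducer 16S reference database
#'
#' Routes extracted 16S records by the producer phenotype of their source
#' genome: records from genomes called in `include_classes` form the
#' producer set, records from `nonproducer` genomes the control set; both
#' are dereplicated independently. Identical sequence strings appearing in
#' both sets are quarantined into `conflicted` and excluded from both,
#' because a single 16S cannot separate producer from nonproducer genomes.
#'
#' @param calls Classification results: the data frame from
#'   [classify_batch()] (columns `genome_id`, `phenotype`) or an equivalent.
#' @param ssu Data frame of `SSURecord`s (see [extract_ssu()]).
#' @param include_classes Producer classes routed to the producer set
#'   (default very_likely, likely, possible).
#' @param min_len Passed to [dereplicate()].
#' @param out_dir If given, writes `scp16s_producers.fasta`,
#'   `scp16s_control.fasta` and `scp16s_metadata.tsv` there.
#' @return A `ReferenceDB` list: `producers`, `nonproducers`, `conflicted`
#'   (SSURecord data frames) and `build_params`.
#' @export
build_db <- function(calls, ssu,
                     include_classes = c("very_likely", "likely", "possible"),
                     min_len = 1000, out_dir = NULL) {
  pheno <- stats::setNames(calls$phenotype, calls$genome_id)
  unknown <- setdiff(unique(ssu$source_genome_id), names(pheno))
  if (length(unknown)) {
    stop(sprintf("SSU record(s) from genome(s) with no producer call: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ssu$phenotype_label <- unname(pheno[ssu$source_genome_id])

  producers <- dereplicate(
    ssu[ssu$phenotype_label %in% include_classes, , drop = FALSE], min_len)
  nonproducers <- dereplicate(
    ssu[ssu$phenotype_label == "nonproducer", , drop = FALSE], min_len)

  clash <- intersect(producers$sequence, nonproducers$sequence)
  conflicted <- empty_ssu()
  if (length(clash)) {
    conflicted <- rbind(producers[producers$sequence %in% clash, , drop = FALSE],
                        nonproducers[nonproducers$sequence %in% clash, , drop = FALSE])
    producers <- producers[!producers$sequence %in% clash, , drop = FALSE]
    nonproducers <- nonproducers[!nonproducers$sequence %in% clash, , drop = FALSE]
    ck_msg(sprintf("%d sequence string(s) occur in both sets; quarantined as conflicted",
                   length(clash)))
  }
  if (nrow(nonproducers) == 0L) {
    warning("reference database has an empty nonproducer control set",
            call. = FALSE)
  }

  db <- structure(list(producers = producers, nonproducers = nonproducers,
                       conflicted = conflicted,
                       build_params = list(include_classes = include_classes,
                                           min_len = min_len)),
                  class = "ReferenceDB")
  if (!is.null(out_dir)) write_reference_db(db, out_dir)
  db
}

#' Write a reference database to FASTA + metadata TSV
#'
#' @param db A `ReferenceDB`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_reference_db <- function(db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fa <- function(recs, path) {
    writeLines(if (nrow(recs)) paste0(">", recs$seq_id, "\n", recs$sequence)
               else character(0), path)
  }
  write_fa(db$producers, file.path(out_dir, "scp16s_producers.fasta"))
  write_fa(db$nonproducers, file.path(out_dir, "scp16s_control.fasta"))
  meta <- rbind(
    cbind(db$producers, set = rep("producer", nrow(db$producers))),
    cbind(db$nonproducers, set = rep("control", nrow(db$nonproducers))),
    cbind(db$conflicted, set = rep("conflicted", nrow(db$conflicted))))
  utils::write.table(
    meta[, c("seq_id", "source_genome_id", "phenotype_label", "lineage",
             "length", "set")],
    file.path(out_dir, "scp16s_metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read a reference database written by [write_reference_db()]
#'
#' @param dir Directory holding the FASTA pair and metadata TSV.
#' @return A `ReferenceDB`.
#' @export
read_reference_db <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "scp16s_metadata.tsv"),
                            stringsAsFactors = FALSE)
  read_fa <- function(path) {
    set <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(set),
                    vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L))
  }
  assemble <- function(which_set, path) {
    m <- meta[meta$set == which_set, , drop = FALSE]
    seqs <- read_fa(path)
    data.frame(seq_id = m$seq_id, source_genome_id = m$source_genome_id,
               sequence = unname(seqs[m$seq_id]), length = m$length,
               phenotype_label = m$phenotype_label, lineage = m$lineage,
               stringsAsFactors = FALSE)
  }
  structure(list(
    producers = assemble("producer", file.path(dir, "scp16s_producers.fasta")),
    nonproducers = assemble("control", file.path(dir, "scp16s_control.fasta")),
    conflicted = empty_ssu(),
    build_params = list()), class = "ReferenceDB")
}

#' Annotate amplicon OTUs against the 16S reference
#'
#' A query matches a reference iff it is identical to it or an exact,
#' gap-free substring of it — 100% identity over 100% of the query — with
#' both strands of the reference searched, so reverse-complementing a query
#' never changes its call. Calls: `producer` when only producer references
#' match, `nonproducer` when only control references match, `ambiguous` when
#' both, `unassigned` when none. `phenotype` is the best class among matched
#' producer references (very_likely > likely > possible).
#'
#' @param query FASTA path of OTU representative sequences, or a named
#'   character vector of sequences.
#' @param db A `ReferenceDB`.
#' @return Data frame: `otu_id`, `call`, `phenotype`, `matched_refs`.
#' @export
annotate_otus <- function(query, db) {
  if (is.character(query) && length(query) == 1L && file.exists(query)) {
    set <- Biostrings::readDNAStringSet(query)
    if (length(set) == 0L) stop(sprintf("empty query file: %s", query), call. = FALSE)
    query <- stats::setNames(
      as.character(set),
      vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L))
  }
  if (length(query) == 0L) stop("no query sequences supplied", call. = FALSE)
  query <- chartr("U", "T", toupper(query))

  match_set <- function(q, refs) {
    if (nrow(refs) == 0L) return(character(0))
    qrc <- revcomp(q)
    hit <- vapply(refs$sequence, function(r) {
      grepl(q, r, fixed = TRUE) || grepl(qrc, r, fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE)
    refs$seq_id[hit]
  }
  class_rank <- c(very_likely = 1L, likely = 2L, possible = 3L)

  rows <- lapply(seq_along(query), function(i) {
    q <- query[[i]]
    prod_ids <- match_set(q, db$producers)
    ctrl_ids <- match_set(q, db$nonproducers)
    call <- if (length(prod_ids) && length(ctrl_ids)) "ambiguous"
      else if (length(prod_ids)) "producer"
      else if (length(ctrl_ids)) "nonproducer"
      else "unassigned"
    phenotype <- NA_character_
    if (length(prod_ids)) {
      cls <- db$producers$phenotype_label[db$producers$seq_id %in% prod_ids]
      cls <- cls[!is.na(cls)]
      if (length(cls)) phenotype <- names(sort(class_rank[unique(cls)]))[1]
    }
    data.frame(otu_id = names(query)[i], call = call, phenotype = phenotype,
               matched_refs = paste(sort(c(prod_ids, ctrl_ids)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample producer abundance profile
#'
#' Summarizes, for each sample of an OTU count table, the relative abundance
#' contributed by producer-annotated OTUs, the number of producer OTUs with
#' nonzero reads, and the per-phenotype breakdown. Samples with zero total
#' reads report fraction 0 and are flagged `empty_sample`; OTUs without an
#' annotation are treated as unassigned with a warning.
#'
#' @param otu_table An `AbundanceTable` (see [abundance_table()]).
#' @param annotations Data frame from [annotate_otus()].
#' @return Data frame, one row per sample: `sample_id`, `total_reads`,
#'   `producer_reads`, `producer_fraction`, `n_producer_otus`, fractions per
#'   phenotype class, `flags`.
#' @export
producer_profile <- function(otu_table, annotations) {
  counts <- otu_table$counts
  if (any(counts < 0)) stop("negative counts in OTU table", call. = FALSE)
  ann <- stats::setNames(annotations$call, annotations$otu_id)
  phen <- stats::setNames(annotations$phenotype, annotations$otu_id)
  missing <- setdiff(rownames(counts), names(ann))
  if (length(missing)) {
    warning(sprintf("%d OTU(s) lack annotations; treated as unassigned",
                    length(missing)), call. = FALSE)
    ann[missing] <- "unassigned"
    phen[missing] <- NA_character_
  }
  is_prod <- ann[rownames(counts)] == "producer"
  rows <- lapply(colnames(counts), function(s) {
    v <- counts[, s]
    total <- sum(v)
    prod_reads <- sum(v[is_prod])
    frac_class <- vapply(c("very_likely", "likely", "possible"), function(cl) {
      sel <- is_prod & !is.na(phen[rownames(counts)]) &
        phen[rownames(counts)] == cl
      if (total > 0) sum(v[sel]) / total else 0
    }, numeric(1))
    data.frame(sample_id = s, total_reads = total, producer_reads = prod_reads,
               producer_fraction = if (total > 0) prod_reads / total else 0,
               n_producer_otus = sum(v[is_prod] > 0),
               very_likely_fraction = frac_class[["very_likely"]],
               likely_fraction = frac_class[["likely"]],
               possible_fraction = frac_class[["possible"]],
               flags = if (total == 0) "empty_sample" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
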