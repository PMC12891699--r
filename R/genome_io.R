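#' Construct a genome record
#'
#' Container for one genome or MAG: its contigs plus the CheckM-style quality
#' estimates and taxonomy consumed downstream by [quality_filter()] and
#' [contig_screen()].
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of nucleotide sequences
#'   (IUPAC codes); names are contig ids and must be unique. Sequences are
#'   stored uppercase.
#' @param completeness,contamination Percentages in `[0, 100]` (CheckM-style
#'   estimates); may be `NA` when no quality filtering is intended.
#' @param lineage Optional taxonomy, either a character vector of ranks
#'   (domain..species) or a single semicolon-joined string. Empty ranks are
#'   allowed.
#' @param source Free-text provenance tag.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(genome_id, contigs, completeness = NA_real_,
                          contamination = NA_real_, lineage = NULL,
                          source = "") {
  stopifnot(is.character(contigs), length(genome_id) == 1L)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("contigs must be a named character vector", call. = FALSE)
  }
  dup <- unique(names(contigs)[duplicated(names(contigs))])
  if (length(dup)) {
    stop(sprintf("duplicate contig id(s) in genome '%s': %s",
                 genome_id, paste(dup, collapse = ", ")), call. = FALSE)
  }
  contigs <- toupper(contigs)
  check_alphabet(contigs, .NT_ALPHABET, sprintf("genome '%s'", genome_id))
  if (length(lineage) == 1L && grepl(";", lineage)) {
    lineage <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  }
  structure(
    list(genome_id = genome_id, contigs = contigs,
         completeness = as.numeric(completeness),
         contamination = as.numeric(contamination),
         lineage = lineage, source = source),
    class = "GenomeRecord"
  )
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d contig(s), %s bp; completeness %s%%, contamination %s%%\n",
              x$genome_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              format(x$completeness), format(x$contamination)))
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' Contig order is preserved and sequences are normalized to uppercase.
#'
#' @param path FASTA file of nucleotide contigs.
#' @param genome_id Identifier for the resulting record.
#' @param metadata Optional one-row data frame / named list with
#'   `completeness`, `contamination` and optionally `lineage`, `source`
#'   (e.g. a row of the metadata TSV read by [read_genome_metadata()]).
#' @return A `GenomeRecord`.
#' @export
read_genome_fasta <- function(path, genome_id, metadata = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate contig header(s) in %s: %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  contigs <- stats::setNames(as.character(set), ids)
  genome_record(
    genome_id, contigs,
    completeness  = if (!is.null(metadata)) metadata$completeness  else NA_real_,
    contamination = if (!is.null(metadata)) metadata$contamination else NA_real_,
    lineage = if (!is.null(metadata)) metadata$lineage else NULL,
    source  = if (!is.null(metadata) && !is.null(metadata$source)) metadata$source else ""
  )
}

#' Write a genome record to FASTA
#'
#' @param genome A `GenomeRecord`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genome quality/taxonomy metadata
#'
#' TSV with columns `genome_id`, `completeness`, `contamination` and
#' optionally `lineage` (semicolon-joined ranks) and `source`.
#'
#' @param path Metadata TSV path.
#' @return A data frame keyed by `genome_id`.
#' @export
read_genome_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genome_id", "completeness", "contamination")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop(sprintf("metadata TSV lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  meta
}

#' Read predicted proteins from FASTA
#'
#' Headers in the prodigal dialect `<contig>_<n> # <start> # <end> # <strand>
#' # ...` are parsed to recover the source contig and coordinates; the
#' dialect is auto-detected per record, so files mixing plain `<id>` headers
#' degrade gracefully (those proteins get `contig_id = NA` and are exempt
#' from contig-level screening, with a warning).
#'
#' @param path FASTA file of amino-acid sequences.
#' @param genome_id Optional genome identifier to attach.
#' @return An object of class `ProteinSet`: `genome_id` plus a data frame
#'   `proteins` with columns `protein_id`, `aa_sequence`, `contig_id`,
#'   `start`, `end`, `strand`.
#' @export
read_proteins <- function(path, genome_id = NA_character_) {
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop(sprintf("protein file %s contains residues outside the IUPAC/X alphabet",
                     path), call. = FALSE)
      }
    })
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))

  parse_one <- function(header) {
    fields <- strsplit(header, "\\s+#\\s+")[[1]]
    id <- strsplit(fields[1], "\\s+")[[1]][1]
    if (length(fields) >= 4L && grepl("_[0-9]+$", id)) {
      strand_raw <- fields[4]
      list(protein_id = id,
           contig_id = sub("_[0-9]+$", "", id),
           start = as.integer(fields[2]), end = as.integer(fields[3]),
           strand = if (strand_raw %in% c("-1", "-")) "-" else "+")
    } else {
      list(protein_id = id, contig_id = NA_character_,
           start = NA_integer_, end = NA_integer_, strand = NA_character_)
    }
  }
  parsed <- lapply(headers, parse_one)
  proteins <- data.frame(
    protein_id = vapply(parsed, `[[`, character(1), "protein_id"),
    aa_sequence = unname(seqs),
    contig_id = vapply(parsed, `[[`, character(1), "contig_id"),
    start = vapply(parsed, `[[`, integer(1), "start"),
    end = vapply(parsed, `[[`, integer(1), "end"),
    strand = vapply(parsed, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  check_alphabet(stats::setNames(proteins$aa_sequence, proteins$protein_id),
                 .AA_ALPHABET, sprintf("protein file %s", path))
  bad_coord <- !is.na(proteins$start) & proteins$start > proteins$end
  if (any(bad_coord)) {
    stop(sprintf("start > end for protein(s): %s",
                 paste(proteins$protein_id[bad_coord], collapse = ", ")),
         call. = FALSE)
  }
  n_plain <- sum(is.na(proteins$contig_id))
  if (n_plain > 0L) {
    warning(sprintf(
      "%d protein header(s) lack the prodigal dialect; contig screening will skip them",
      n_plain), call. = FALSE)
  }
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "ProteinSet")
}

#' Apply the MAG quality gate
#'
#' Retains genomes with completeness at or above `min_completeness` and
#' contamination strictly below `max_contamination` (the standard
#' medium-quality MAG gate: >=50% complete, <10% contaminated). Order is
#' preserved and the operation is idempotent.
#'
#' @param genomes List of `GenomeRecord`s with quality fields populated.
#' @param min_completeness Inclusive lower bound, percent (default 50).
#' @param max_contamination Exclusive upper bound, percent (default 10).
#' @return The retained sublist, in input order.
#' @export
quality_filter <- function(genomes, min_completeness = 50,
                           max_contamination = 10) {
  stopifnot(is.list(genomes))
  keep <- vapply(genomes, function(g) {
    if (is.na(g$completeness) || is.na(g$contamination)) {
      stop(sprintf("genome '%s' lacks completeness/contamination estimates",
                   g$genome_id), call. = FALSE)
    }
    g$completeness >= min_completeness && g$contamination < max_contamination
  }, logical(1))
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    ck_msg(sprintf("quality_filter removed %d of %d genome(s)",
                   n_removed, length(genomes)))
  }
  genomes[keep]
}
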