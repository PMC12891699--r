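# Small in-code fixture builders shared across test files.

# a hand-written minimal catalog: one required ring marker per branch,
# branch-diagnostic chelatases, shared precursor/loop markers
mini_catalog <- function() {
  validate_catalog(data.frame(
    marker_id = c("preA", "ringO", "ringX", "chelO", "chelX", "loopA"),
    gene_symbol = c("preA", "ringO", "ringX", "chelO", "chelX", "loopA"),
    profile_accessions = c("ACC1", "ACC2", "ACC3", "ACC4", "ACC5", "ACC6"),
    module = c("precursor", "ring", "ring", "chelation", "chelation", "loop"),
    branch = c("shared", "aerobic", "anaerobic", "aerobic", "anaerobic", "shared"),
    required = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    weight = 1, stringsAsFactors = FALSE))
}

mk_hit <- function(protein_id, marker_id, evalue = 1e-10, bitscore = 100,
                   contig_id = NA_character_) {
  data.frame(protein_id = protein_id, contig_id = contig_id,
             marker_id = marker_id, evalue = evalue, bitscore = bitscore,
             ali_from = 1L, ali_to = 100L, stringsAsFactors = FALSE)
}

mk_presence <- function(markers, genome_id = "g1", flags = character(0),
                        contig_id = NA_character_) {
  hits <- do.call(rbind, lapply(seq_along(markers), function(i) {
    mk_hit(sprintf("p%d", i), markers[i], contig_id = contig_id)
  }))
  pm <- resolve_hits(hits, genome_id = genome_id)
  pm$flags <- flags
  pm
}

mk_ssu <- function(seq_id, sequence, source = "g1") {
  data.frame(seq_id = seq_id, source_genome_id = source, sequence = sequence,
             length = nchar(sequence), phenotype_label = NA_character_,
             lineage = NA_character_, stringsAsFactors = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# one well-formed domtbl line (23 columns)
domtbl_line <- function(target, qname, qacc, evalue, score = 80.5,
                        ali_from = 5, ali_to = 200) {
  sprintf("%s - 500 %s %s 400 %s %.1f 0.1 1 1 %s %s %.1f 0.1 1 196 %d %d %d %d 0.95 -",
          target, qname, qacc, format(evalue, scientific = TRUE), score,
          format(evalue, scientific = TRUE), format(evalue, scientific = TRUE),
          score, ali_from, ali_to, ali_from, ali_to)
}
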