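#' Parse HMMER3 per-domain tabular output into marker hits
#'
#' Reads a `hmmsearch --domtblout` file and emits one hit per domain line
#' whose query profile (name or accession) maps to a catalog entry; profiles
#' absent from the catalog are ignored. The full-sequence E-value and bit
#' score (columns 7-8) are used, matching default hmmsearch reporting;
#' `ali_from`/`ali_to` are the alignment coordinates on the target protein.
#'
#' The target's source contig is taken from `proteins` when supplied;
#' otherwise it is recovered by stripping the trailing `_<n>` from
#' prodigal-style target names (plain names get `NA`).
#'
#' @param path Path to a `--domtblout` file.
#' @param catalog A `MarkerCatalog`.
#' @param proteins Optional `ProteinSet` used to resolve contig ids.
#' @return Data frame of hits: `protein_id`, `contig_id`, `marker_id`,
#'   `evalue`, `bitscore`, `ali_from`, `ali_to`.
#' @export
parse_domtbl <- function(path, catalog, proteins = NULL) {
  catalog <- validate_catalog(catalog)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lookup <- catalog_lookup(catalog)

  contig_map <- NULL
  if (!is.null(proteins)) {
    contig_map <- stats::setNames(proteins$proteins$contig_id,
                                  proteins$proteins$protein_id)
  }

  rows <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L) {
      stop(sprintf("malformed domtbl line %d in %s: %d column(s), expected >= 22",
                   i, path, length(f)), call. = FALSE)
    }
    marker <- unname(lookup[f[5]])
    if (is.na(marker)) marker <- unname(lookup[f[4]])
    if (is.na(marker)) next  # profile not in catalog
    target <- f[1]
    contig <- if (!is.null(contig_map)) {
      unname(contig_map[target])
    } else if (grepl("_[0-9]+$", target)) {
      sub("_[0-9]+$", "", target)
    } else {
      NA_character_
    }
    j <- j + 1L
    rows[[j]] <- data.frame(
      protein_id = target, contig_id = contig, marker_id = marker,
      evalue = as.numeric(f[7]), bitscore = as.numeric(f[8]),
      ali_from = as.integer(f[18]), ali_to = as.integer(f[19]),
      stringsAsFactors = FALSE)
  }
  if (j == 0L) return(empty_hits())
  do.call(rbind, rows[seq_len(j)])
}

empty_hits <- function() {
  data.frame(protein_id = character(0), contig_id = character(0),
             marker_id = character(0), evalue = numeric(0),
             bitscore = numeric(0), ali_from = integer(0),
             ali_to = integer(0), stringsAsFactors = FALSE)
}

#' Search proteins against profile HMMs
#'
#' Thin delegation boundary around the external `hmmsearch` binary: proteins
#' are written to a temporary FASTA, searched against `profile_db`, and the
#' resulting `--domtblout` table is parsed with [parse_domtbl()]. The rest of
#' the pipeline is indifferent to whether hits come from this function or
#' from a precomputed table, so no search backend is needed to run from
#' existing evidence.
#'
#' @param proteins A `ProteinSet`.
#' @param catalog A `MarkerCatalog`.
#' @param profile_db Path to a pressed or plain HMM flatfile containing the
#'   catalog's profiles.
#' @param e_max Reporting E-value threshold passed to `hmmsearch -E`.
#' @return Data frame of hits, as [parse_domtbl()].
#' @export
search_markers <- function(proteins, catalog, profile_db, e_max = 1e-6) {
  if (nrow(proteins$proteins) == 0L) return(empty_hits())
  hmmsearch <- Sys.which("hmmsearch")
  if (!nzchar(hmmsearch)) {
    stop("hmmsearch backend not found on PATH; run from a precomputed table instead (classify --hits table.domtbl)",
         call. = FALSE)
  }
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(faa), add = TRUE)
  writeLines(paste0(">", proteins$proteins$protein_id, "\n",
                    proteins$proteins$aa_sequence), faa)
  out <- tempfile(fileext = ".domtbl")
  on.exit(unlink(out), add = TRUE)
  status <- system2(hmmsearch,
                    c("--domtblout", out, "-E", format(e_max, scientific = TRUE),
                      "--noali", shQuote(profile_db), shQuote(faa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    stop(sprintf("hmmsearch exited with status %d", status), call. = FALSE)
  }
  parse_domtbl(out, catalog, proteins = proteins)
}

#' Resolve raw hits into a per-genome marker presence map
#'
#' Assigns each protein to exactly one marker — its highest bit-score hit
#' across all reported hits, ties broken by lower E-value, then
#' lexicographically smaller `marker_id` — so one promiscuous protein cannot
#' inflate pathway completeness. The winning assignment is kept only if it
#' passes the E-value gate (`evalue <= e_max`; the boundary value itself
#' passes). Assigning before gating keeps the detected set monotone in
#' `e_max` and means a protein whose best explanation is unconvincing never
#' falls back to a weaker marker. The detected set is every marker with at
#' least one surviving assignment.
#'
#' @param hits Data frame of hits for one genome (see [parse_domtbl()]).
#' @param e_max Inclusive E-value ceiling (default `1e-6`).
#' @param genome_id Optional genome id recorded on the map.
#' @return A `PresenceMap`: list with `genome_id`, `detected` (named list
#'   marker_id -> supporting hits) and `flags` (screening annotations).
#' @export
resolve_hits <- function(hits, e_max = 1e-6, genome_id = NA_character_) {
  pm <- structure(list(genome_id = genome_id, detected = list(),
                       flags = character(0)),
                  class = "PresenceMap")
  if (is.null(hits) || nrow(hits) == 0L) return(pm)

  # best domain line per (protein, marker), then best marker per protein,
  # then the E-value gate on the chosen assignment
  ord <- order(hits$protein_id, hits$marker_id, -hits$bitscore, hits$evalue,
               hits$ali_from)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("protein_id", "marker_id")]), , drop = FALSE]
  ord <- order(hits$protein_id, -hits$bitscore, hits$evalue, hits$marker_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(pm)

  pm$detected <- split(hits, hits$marker_id)
  pm
}

detected_markers <- function(presence) names(presence$detected)

#' Contig-level false-positive screening
#'
#' Three independent guards against spurious producer calls driven by contig
#' incompleteness or contamination, each logged into `flags`:
#' (a) marker support on contigs shorter than `min_contig_len` that carry no
#' other marker is dropped; (b) when per-contig taxonomy is available,
#' support on contigs whose phylum conflicts with the genome's majority
#' phylum is dropped; (c) if all surviving markers sit on a single contig
#' making up less than `single_contig_fraction` of the genome, the map is
#' flagged `single_contig_suspect` (consumed by [classify()] as a one-class
#' downgrade). Markers left without support are removed; the detected set
#' never grows.
#'
#' @param presence A `PresenceMap`.
#' @param genome The matching `GenomeRecord` (contig lengths).
#' @param min_contig_len Minimum trusted contig length, nt (default 2000).
#' @param contig_taxonomy Optional named vector/list contig_id -> lineage
#'   (semicolon-joined ranks, phylum second); enables guard (b).
#' @param single_contig_fraction Genome fraction below which a lone
#'   marker-bearing contig is suspect (default 0.05).
#' @return The screened `PresenceMap`.
#' @export
contig_screen <- function(presence, genome, min_contig_len = 2000,
                          contig_taxonomy = NULL,
                          single_contig_fraction = 0.05) {
  if (length(presence$detected) == 0L) return(presence)
  clens <- nchar(genome$contigs)
  all_hits <- do.call(rbind, presence$detected)
  used <- unique(all_hits$contig_id[!is.na(all_hits$contig_id)])
  unknown <- setdiff(used, names(clens))
  if (length(unknown)) {
    stop(sprintf("contig(s) in presence map absent from genome '%s': %s",
                 genome$genome_id, paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  # guard (a): lone markers on short contigs
  markers_per_contig <- tapply(all_hits$marker_id, all_hits$contig_id,
                               function(x) length(unique(x)))
  for (m in names(presence$detected)) {
    h <- presence$detected[[m]]
    drop <- !is.na(h$contig_id) &
      clens[h$contig_id] < min_contig_len &
      markers_per_contig[h$contig_id] == 1L
    if (any(drop)) {
      presence$flags <- c(presence$flags,
                          sprintf("short_contig_drop:%s@%s", m,
                                  paste(unique(h$contig_id[drop]), collapse = "+")))
      presence$detected[[m]] <- h[!drop, , drop = FALSE]
    }
  }

  # guard (b): taxonomy conflict with the genome's majority phylum
  if (!is.null(contig_taxonomy)) {
    phylum_of <- function(lin) {
      ranks <- strsplit(as.character(lin), ";", fixed = TRUE)[[1]]
      if (length(ranks) >= 2L) trimws(ranks[2]) else NA_character_
    }
    phyla <- vapply(contig_taxonomy, phylum_of, character(1))
    phyla <- phyla[!is.na(phyla) & nzchar(phyla)]
    if (length(phyla)) {
      tab <- sort(table(phyla), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      majority <- if (length(top) == 1L) {
        top
      } else {
        gphy <- if (!is.null(genome$lineage) && length(genome$lineage) >= 2L)
          trimws(genome$lineage[2]) else NA_character_
        if (!is.na(gphy) && gphy %in% top) gphy else sort(top)[1]
      }
      foreign <- names(phyla)[phyla != majority]
      for (m in names(presence$detected)) {
        h <- presence$detected[[m]]
        drop <- !is.na(h$contig_id) & h$contig_id %in% foreign
        if (any(drop)) {
          presence$flags <- c(presence$flags,
                              sprintf("foreign_contig_drop:%s@%s", m,
                                      paste(unique(h$contig_id[drop]), collapse = "+")))
          presence$detected[[m]] <- h[!drop, , drop = FALSE]
        }
      }
    }
  }

  presence$detected <- Filter(function(h) nrow(h) > 0L, presence$detected)

  # guard (c): everything on one small contig
  if (length(presence$detected)) {
    surv <- do.call(rbind, presence$detected)
    ctgs <- unique(surv$contig_id[!is.na(surv$contig_id)])
    if (length(ctgs) == 1L && !anyNA(surv$contig_id) &&
        clens[ctgs] < single_contig_fraction * sum(clens)) {
      presence$flags <- c(presence$flags, "single_contig_suspect")
    }
  }
  presence
}
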