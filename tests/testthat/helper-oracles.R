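# Brute-force reference implementations, kept deliberately independent of
# the package's code paths: plain loops and textbook formulas only.

# per-protein assignment by exhaustive scan over that protein's hits:
# the per-protein maximum is found over all hits, then kept only when it
# clears the E-value gate
oracle_resolve <- function(hits, e_max = 1e-6) {
  out <- list()
  for (p in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == p, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(h))) {
      if (is.null(best) ||
          h$bitscore[i] > best$bitscore ||
          (h$bitscore[i] == best$bitscore && h$evalue[i] < best$evalue) ||
          (h$bitscore[i] == best$bitscore && h$evalue[i] == best$evalue &&
           h$marker_id[i] < best$marker_id)) {
        best <- h[i, ]
      }
    }
    if (best$evalue <= e_max) out[[p]] <- best$marker_id
  }
  out
}

# weighted set arithmetic straight from the definition
oracle_score <- function(detected, catalog) {
  res <- c(aerobic = 0, anaerobic = 0)
  for (b in names(res)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(catalog))) {
      if (catalog$required[i] && catalog$branch[i] %in% c(b, "shared")) {
        den <- den + catalog$weight[i]
        if (catalog$marker_id[i] %in% detected) num <- num + catalog$weight[i]
      }
    }
    res[b] <- if (den > 0) num / den else 0
  }
  res
}

# all-pairs edges via stats::cor.test (an independent p-value route)
oracle_edges <- function(counts, alpha = 0.05, r_min = 0, rel = TRUE) {
  x <- if (rel) sweep(counts, 2, colSums(counts), "/") else counts
  ids <- rownames(x)
  edges <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      xi <- x[i, ]; xj <- x[j, ]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = "pearson"))
      if (!is.na(ct$p.value) && ct$p.value < alpha &&
          abs(ct$estimate) > r_min) {
        pair <- sort(c(ids[i], ids[j]))
        edges <- c(edges, paste(pair[1], pair[2]))
      }
    }
  }
  sort(edges)
}

# exhaustive (query, reference, strand, offset) scan
oracle_annotate_call <- function(q, producers, controls) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits_in <- function(q, refs) {
    found <- FALSE
    for (r in refs) {
      for (qq in c(q, rc(q))) {
        if (nchar(qq) <= nchar(r)) {
          for (off in 0:(nchar(r) - nchar(qq))) {
            if (substr(r, off + 1, off + nchar(qq)) == qq) { found <- TRUE; break }
          }
        }
        if (found) break
      }
      if (found) break
    }
    found
  }
  p <- hits_in(q, producers)
  c_ <- hits_in(q, controls)
  if (p && c_) "ambiguous" else if (p) "producer"
  else if (c_) "nonproducer" else "unassigned"
}

# random hit table generator for the resolver property test
random_hits <- function(n, n_proteins = 6, n_markers = 5) {
  data.frame(
    protein_id = sample(sprintf("p%d", seq_len(n_proteins)), n, replace = TRUE),
    contig_id = NA_character_,
    marker_id = sample(sprintf("m%d", seq_len(n_markers)), n, replace = TRUE),
    evalue = 10^stats::runif(n, -20, -4),
    bitscore = sample(seq(40, 200, by = 5), n, replace = TRUE),
    ali_from = 1L, ali_to = 100L, stringsAsFactors = FALSE)
}
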