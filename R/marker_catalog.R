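#' Read a cobamide-pathway marker catalog
#'
#' TSV with columns `marker_id`, `gene_symbol`, `profile_accessions`
#' (semicolon-joined KO/TIGRFAM/PFAM/UniProt identifiers), `module` (one of
#' precursor, ring, chelation, adenosylation, loop, salvage), `branch`
#' (aerobic, anaerobic, shared), `required` (TRUE/FALSE) and `weight`
#' (positive real).
#'
#' @param path Catalog TSV path.
#' @return A validated `MarkerCatalog` data frame.
#' @export
read_marker_catalog <- function(path) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cat_df$required <- as.logical(cat_df$required)
  cat_df$weight <- as.numeric(cat_df$weight)
  validate_catalog(cat_df)
}

.MODULES <- c("precursor", "ring", "chelation", "adenosylation", "loop", "salvage")
.BRANCHES <- c("aerobic", "anaerobic", "shared")

#' Validate a marker catalog
#'
#' Checks the structural invariants: unique marker ids, known modules and
#' branches, positive weights, at least one required ring-module marker per
#' oxygen branch and at least one required loop-module marker.
#'
#' @param catalog A data frame with the catalog columns.
#' @return The catalog, classed as `MarkerCatalog`, invisibly usable.
#' @export
validate_catalog <- function(catalog) {
  need <- c("marker_id", "gene_symbol", "profile_accessions", "module",
            "branch", "required", "weight")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) {
    stop(sprintf("catalog lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  dup <- unique(catalog$marker_id[duplicated(catalog$marker_id)])
  if (length(dup)) {
    stop(sprintf("duplicate marker_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!catalog$module %in% .MODULES)) {
    stop("catalog contains unknown module values", call. = FALSE)
  }
  if (any(!catalog$branch %in% .BRANCHES)) {
    stop("catalog contains unknown branch values", call. = FALSE)
  }
  if (any(!is.finite(catalog$weight)) || any(catalog$weight <= 0)) {
    stop("catalog weights must be positive", call. = FALSE)
  }
  for (b in c("aerobic", "anaerobic")) {
    if (!any(catalog$module == "ring" & catalog$branch == b & catalog$required)) {
      stop(sprintf("catalog lacks a required ring-module marker for the %s branch", b),
           call. = FALSE)
    }
  }
  if (!any(catalog$module == "loop" & catalog$required)) {
    stop("catalog lacks a required loop-module (nucleotide loop assembly) marker",
         call. = FALSE)
  }
  class(catalog) <- unique(c("MarkerCatalog", class(catalog)))
  catalog
}

#' Default cobamide marker catalog
#'
#' The catalog shipped with the package (`extdata/scp_markers.tsv`): corrin
#' ring markers for the oxygen-dependent (aerobic, cob genes) and
#' oxygen-independent (anaerobic, cbi genes) branches, branch-diagnostic
#' cobalt chelatases, shared precursor / adenosylation / nucleotide-loop
#' markers, and non-required salvage transporters. It is a curated
#' structural stand-in keyed by standard gene symbols and KO-style
#' accessions; an authoritative profile list with per-profile accessions can
#' be substituted via [read_marker_catalog()] without code change.
#'
#' @return A `MarkerCatalog` data frame.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "scp_markers.tsv", package = "cobakit",
                      mustWork = TRUE)
  read_marker_catalog(path)
}

# accession (and symbol/id) -> marker_id lookup used by parse_domtbl
catalog_lookup <- function(catalog) {
  acc <- strsplit(catalog$profile_accessions, ";", fixed = TRUE)
  map <- character(0)
  for (i in seq_len(nrow(catalog))) {
    keys <- unique(c(acc[[i]], catalog$gene_symbol[i], catalog$marker_id[i]))
    keys <- keys[nzchar(keys)]
    map[keys] <- catalog$marker_id[i]
  }
  map
}
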