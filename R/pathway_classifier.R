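#' Default classification rubric
#'
#' Thresholds on branch pathway completeness for the four producer classes,
#' plus two evidence safeguards: `require_chelation_for_very` demands at
#' least one detected cobalt-chelatase (chelation-module) marker before the
#' top class is awarded, and `adjust_for_genome_completeness` divides raw
#' pathway completeness by the genome's own completeness estimate (floored
#' at `q_floor`) so fragmentary MAGs are not systematically under-called.
#' All values are plain list entries, so an alternative rubric can be
#' supplied without code change.
#'
#' @param t_very,t_likely,t_possible Inclusive lower completeness bounds for
#'   the very_likely / likely / possible classes (defaults 0.75 / 0.50 / 0.25).
#' @param require_chelation_for_very Logical (default `TRUE`).
#' @param adjust_for_genome_completeness Logical (default `TRUE`).
#' @param q_floor Lower floor on the completeness divisor (default 0.5).
#' @return A `Rubric` list.
#' @export
default_rubric <- function(t_very = 0.75, t_likely = 0.50, t_possible = 0.25,
                           require_chelation_for_very = TRUE,
                           adjust_for_genome_completeness = TRUE,
                           q_floor = 0.5) {
  if (!(0 < t_possible && t_possible < t_likely && t_likely < t_very &&
        t_very <= 1)) {
    stop("rubric thresholds must satisfy 0 < t_possible < t_likely < t_very <= 1",
         call. = FALSE)
  }
  structure(list(t_very = t_very, t_likely = t_likely, t_possible = t_possible,
                 require_chelation_for_very = require_chelation_for_very,
                 adjust_for_genome_completeness = adjust_for_genome_completeness,
                 q_floor = q_floor),
            class = "Rubric")
}

.PHENOTYPES <- c("nonproducer", "possible", "likely", "very_likely")

#' Score cobamide-pathway completeness per oxygen branch
#'
#' For each branch b, completeness is the weight fraction of detected
#' required markers among all required markers whose branch is b or shared;
#' module completeness is the same fraction restricted per pathway module.
#' `diagnostic_counts` tallies detected branch-exclusive markers (any
#' required status) and later decides the oxygen route, so shared
#' early-pathway genes never vote on route.
#'
#' @param presence A `PresenceMap` (post [resolve_hits()], optionally post
#'   [contig_screen()]).
#' @param catalog A `MarkerCatalog`.
#' @return A `PathwayProfile` list: `genome_id`, `completeness_by_branch`,
#'   `module_completeness` (data frame branch/module/completeness),
#'   `diagnostic_counts`, `markers`, `has_chelation`, `flags`.
#' @export
score_pathway <- function(presence, catalog) {
  catalog <- validate_catalog(catalog)
  det <- detected_markers(presence)
  unknown <- setdiff(det, catalog$marker_id)
  if (length(unknown)) {
    stop(sprintf("detected marker(s) absent from catalog: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  comp <- c(aerobic = NA_real_, anaerobic = NA_real_)
  mods <- list()
  diag <- c(aerobic = 0L, anaerobic = 0L)
  for (b in c("aerobic", "anaerobic")) {
    req <- catalog[catalog$required & catalog$branch %in% c(b, "shared"), ]
    comp[b] <- if (nrow(req)) {
      sum(req$weight[req$marker_id %in% det]) / sum(req$weight)
    } else 0
    for (m in unique(req$module)) {
      rm_ <- req[req$module == m, ]
      mods[[length(mods) + 1L]] <- data.frame(
        branch = b, module = m,
        completeness = sum(rm_$weight[rm_$marker_id %in% det]) / sum(rm_$weight),
        stringsAsFactors = FALSE)
    }
    diag[b] <- sum(catalog$branch == b & catalog$marker_id %in% det)
  }
  structure(list(
    genome_id = presence$genome_id,
    completeness_by_branch = comp,
    module_completeness = do.call(rbind, mods),
    diagnostic_counts = diag,
    markers = sort(det),
    has_chelation = any(catalog$module == "chelation" & catalog$marker_id %in% det),
    flags = presence$flags
  ), class = "PathwayProfile")
}

#' Call the oxygen route of cobamide biosynthesis
#'
#' The branch with the strictly greater count of detected branch-exclusive
#' markers wins; equal nonzero counts are `ambiguous`; with no diagnostic
#' markers at all the call is `ambiguous` if any (necessarily shared) marker
#' was detected and `none` otherwise.
#'
#' @param profile A `PathwayProfile`.
#' @return One of `"aerobic"`, `"anaerobic"`, `"ambiguous"`, `"none"`.
#' @export
call_route <- function(profile) {
  da <- profile$diagnostic_counts[["aerobic"]]
  dn <- profile$diagnostic_counts[["anaerobic"]]
  if (da > dn) return("aerobic")
  if (dn > da) return("anaerobic")
  if (da > 0) return("ambiguous")
  if (length(profile$markers) > 0) "ambiguous" else "none"
}

#' Classify a genome into the four producer phenotypes
#'
#' Raw completeness is the better of the two branch scores; when
#' `rubric$adjust_for_genome_completeness` is on and a genome completeness
#' estimate is given, it becomes
#' `C = min(1, C_raw / max(genome_completeness/100, q_floor))`. Class
#' boundaries are inclusive below: `very_likely` at `C >= t_very` (provided
#' a chelation marker was seen, when required — otherwise the call drops to
#' `likely`), `likely` on `[t_likely, t_very)`, `possible` on
#' `[t_possible, t_likely)`, else `nonproducer`. A `single_contig_suspect`
#' screening flag downgrades any producer call by exactly one class.
#'
#' @param profile A `PathwayProfile`.
#' @param rubric A `Rubric` (default [default_rubric()]).
#' @param genome_completeness Genome completeness percent, or `NULL`.
#' @return A `ProducerCall` list: `genome_id`, `phenotype`, `branch`,
#'   `score`, `evidence`, `downgraded`, `flags`.
#' @export
classify <- function(profile, rubric = default_rubric(),
                     genome_completeness = NULL) {
  c_raw <- max(profile$completeness_by_branch)
  c_adj <- if (isTRUE(rubric$adjust_for_genome_completeness) &&
               !is.null(genome_completeness) && !is.na(genome_completeness)) {
    min(1, c_raw / max(genome_completeness / 100, rubric$q_floor))
  } else {
    c_raw
  }
  phenotype <- if (c_adj >= rubric$t_very) {
    if (!rubric$require_chelation_for_very || profile$has_chelation)
      "very_likely" else "likely"
  } else if (c_adj >= rubric$t_likely) {
    "likely"
  } else if (c_adj >= rubric$t_possible) {
    "possible"
  } else {
    "nonproducer"
  }
  downgraded <- FALSE
  if ("single_contig_suspect" %in% profile$flags && phenotype != "nonproducer") {
    phenotype <- .PHENOTYPES[match(phenotype, .PHENOTYPES) - 1L]
    downgraded <- TRUE
  }
  structure(list(
    genome_id = profile$genome_id,
    phenotype = phenotype,
    branch = call_route(profile),
    score = c_adj,
    evidence = profile$markers,
    downgraded = downgraded,
    flags = profile$flags
  ), class = "ProducerCall")
}

#' Classify a batch of genomes into a report table
#'
#' Runs resolve -> screen -> score -> classify per genome and collects one
#' row per input, in input order. Per-genome failures are captured in an
#' `error` column and do not abort the run; reruns on identical input give a
#' byte-identical report.
#'
#' @param genomes List of `GenomeRecord`s.
#' @param hits_source Named list (by genome id) whose elements are either
#'   hit data frames (see [parse_domtbl()]) or paths to `--domtblout` files.
#' @param catalog A `MarkerCatalog` (default [default_catalog()]).
#' @param rubric A `Rubric` (default [default_rubric()]).
#' @param contig_taxonomy Optional named list (by genome id) of per-contig
#'   lineages for guard (b) of [contig_screen()].
#' @param e_max E-value gate (default `1e-6`).
#' @param min_contig_len,single_contig_fraction Passed to [contig_screen()].
#' @param screen Apply contig screening (default `TRUE`).
#' @return Data frame with columns `genome_id`, `phenotype`, `branch`,
#'   `score`, `n_markers`, `flags`, `evidence`, `error`.
#' @export
classify_batch <- function(genomes, hits_source, catalog = default_catalog(),
                           rubric = default_rubric(), contig_taxonomy = NULL,
                           e_max = 1e-6, min_contig_len = 2000,
                           single_contig_fraction = 0.05, screen = TRUE) {
  catalog <- validate_catalog(catalog)
  rows <- lapply(genomes, function(g) {
    row <- data.frame(genome_id = g$genome_id, phenotype = NA_character_,
                      branch = NA_character_, score = NA_real_,
                      n_markers = NA_integer_, flags = "", evidence = "",
                      error = "", stringsAsFactors = FALSE)
    tryCatch({
      src <- hits_source[[g$genome_id]]
      if (is.null(src)) stop("no hits supplied for this genome")
      hits <- if (is.character(src)) parse_domtbl(src, catalog) else src
      pm <- resolve_hits(hits, e_max = e_max, genome_id = g$genome_id)
      if (screen) {
        pm <- contig_screen(pm, g, min_contig_len = min_contig_len,
                            contig_taxonomy = contig_taxonomy[[g$genome_id]],
                            single_contig_fraction = single_contig_fraction)
      }
      profile <- score_pathway(pm, catalog)
      call <- classify(profile, rubric, genome_completeness = g$completeness)
      row$phenotype <- call$phenotype
      row$branch <- call$branch
      row$score <- round(call$score, 6)
      row$n_markers <- length(call$evidence)
      row$flags <- paste(call$flags, collapse = ";")
      row$evidence <- paste(call$evidence, collapse = ";")
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
  })
  do.call(rbind, rows)
}
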