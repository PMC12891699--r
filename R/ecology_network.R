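#' Construct an OTU-by-sample abundance table
#'
#' @param counts Non-negative integer matrix, OTUs as rows (rownames = OTU
#'   ids) and samples as columns (colnames = sample ids).
#' @param labels Optional named character vector otu_id -> producer label
#'   (`very_likely`, `likely`, `possible`, `nonproducer`, `unassigned`);
#'   unlabelled OTUs default to `unassigned`.
#' @return An `AbundanceTable` list with `counts` and `labels`.
#' @export
abundance_table <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts matrix needs OTU rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lab <- stats::setNames(rep("unassigned", nrow(counts)), rownames(counts))
  if (!is.null(labels)) {
    known <- intersect(names(labels), rownames(counts))
    lab[known] <- labels[known]
  }
  ok <- c("very_likely", "likely", "possible", "nonproducer", "unassigned")
  if (any(!lab %in% ok)) stop("unknown producer label(s)", call. = FALSE)
  structure(list(counts = counts, labels = lab), class = "AbundanceTable")
}

#' Read an abundance table from TSV
#'
#' First column `otu_id`, remaining columns one per sample.
#'
#' @param path Counts TSV path.
#' @param labels_path Optional labels TSV with columns `otu_id`, `label`.
#' @return An `AbundanceTable`.
#' @export
read_abundance_tsv <- function(path, labels_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  labels <- NULL
  if (!is.null(labels_path)) {
    ldf <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    labels <- stats::setNames(ldf$label, ldf$otu_id)
  }
  abundance_table(counts, labels)
}

#' Exclude rare OTUs
#'
#' Keeps an OTU iff its total read count across all samples reaches
#' `min_total` (the boundary value itself is kept; strictly fewer reads are
#' excluded). Samples are unchanged and the operation is idempotent.
#'
#' @param table An `AbundanceTable`.
#' @param min_total Minimum total reads across samples (default 100).
#' @return The filtered `AbundanceTable`.
#' @export
filter_rare <- function(table, min_total = 100) {
  keep <- rowSums(table$counts) >= min_total
  if (!any(keep)) warning("all OTUs fall below min_total", call. = FALSE)
  abundance_table(table$counts[keep, , drop = FALSE],
                  table$labels[keep])
}

#' Build a Pearson co-occurrence network
#'
#' Counts are converted to per-sample relative abundances (unequal
#' sequencing depth otherwise drives spurious correlation; set
#' `on_counts = TRUE` for raw-count behaviour). For every OTU pair, Pearson
#' r and a two-sided p-value from the t-distribution with n-2 df are
#' computed; an edge is kept iff `p < alpha` (after optional
#' Benjamini-Hochberg correction across all tested pairs) and `|r| > r_min`.
#' OTUs with zero variance are skipped with a `zero_variance` note. Nodes
#' keep their producer labels; edges are undirected with canonical
#' `otu_a < otu_b` ordering.
#'
#' @param table An `AbundanceTable` with at least 3 samples.
#' @param alpha Significance level (default 0.05, uncorrected — matching
#'   common practice; `correction = "bh"` is the conservative option).
#' @param r_min Minimum absolute correlation (default 0, i.e. `|r| > 0`).
#' @param correction `"none"` or `"bh"`.
#' @param on_counts Correlate raw counts instead of relative abundances.
#' @return A `CooccurrenceNetwork` list: `nodes` (otu_id, label), `edges`
#'   (otu_a, otu_b, r, p), `params`, `notes`.
#' @export
build_network <- function(table, alpha = 0.05, r_min = 0,
                          correction = c("none", "bh"), on_counts = FALSE) {
  correction <- match.arg(correction)
  counts <- table$counts
  n <- ncol(counts)
  if (n < 3L) stop("co-occurrence network needs at least 3 samples", call. = FALSE)

  x <- if (on_counts) counts else {
    depth <- colSums(counts)
    sweep(counts, 2, ifelse(depth > 0, depth, 1), "/")
  }
  notes <- character(0)
  vr <- apply(x, 1, stats::var)
  if (any(vr == 0)) {
    notes <- sprintf("zero_variance:%s", rownames(x)[vr == 0])
    ck_msg(sprintf("%d OTU(s) with zero variance skipped", sum(vr == 0)))
  }
  ids <- rownames(x)[vr > 0]
  edges <- data.frame(otu_a = character(0), otu_b = character(0),
                      r = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  if (length(ids) >= 2L) {
    cm <- stats::cor(t(x[ids, , drop = FALSE]))
    iu <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[iu]
    r_cl <- pmin(pmax(r, -1), 1)
    tt <- r_cl * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p[abs(r_cl) == 1] <- 0
    if (correction == "bh") p <- stats::p.adjust(p, method = "BH")
    keep <- p < alpha & abs(r) > r_min
    edges <- data.frame(otu_a = ids[iu[keep, 1]], otu_b = ids[iu[keep, 2]],
                        r = r[keep], p = p[keep], stringsAsFactors = FALSE)
    swap <- edges$otu_a > edges$otu_b
    tmp <- edges$otu_a[swap]
    edges$otu_a[swap] <- edges$otu_b[swap]
    edges$otu_b[swap] <- tmp
    edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(
    nodes = data.frame(otu_id = rownames(counts),
                       label = unname(table$labels[rownames(counts)]),
                       stringsAsFactors = FALSE),
    edges = edges,
    params = list(alpha = alpha, r_min = r_min, correction = correction,
                  on_counts = on_counts, n_samples = n),
    notes = notes), class = "CooccurrenceNetwork")
}

#' Per-node network topology metrics
#'
#' Degree, closeness and betweenness per node. Closeness is harmonic
#' centrality normalized by n-1, which stays well-defined on disconnected
#' graphs (unreachable pairs contribute 0); betweenness is on unweighted
#' shortest paths, normalized. All metrics are deterministic.
#'
#' @param net A `CooccurrenceNetwork`.
#' @return Data frame: `otu_id`, `label`, `degree`, `closeness`,
#'   `betweenness`.
#' @export
topology <- function(net) {
  nodes <- net$nodes
  if (nrow(nodes) == 0L) {
    return(data.frame(otu_id = character(0), label = character(0),
                      degree = integer(0), closeness = numeric(0),
                      betweenness = numeric(0), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("otu_a", "otu_b")],
                                     directed = FALSE, vertices = nodes$otu_id)
  deg <- igraph::degree(g)
  n <- igraph::vcount(g)
  clo <- if (n > 1) igraph::harmonic_centrality(g, normalized = TRUE)
         else stats::setNames(rep(0, n), nodes$otu_id)
  bet <- if (n > 2) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
         else stats::setNames(rep(0, n), nodes$otu_id)
  data.frame(otu_id = nodes$otu_id, label = nodes$label,
             degree = as.integer(deg[nodes$otu_id]),
             closeness = as.numeric(clo[nodes$otu_id]),
             betweenness = as.numeric(bet[nodes$otu_id]),
             stringsAsFactors = FALSE)
}

#' Compare topology metrics between producer label groups
#'
#' For each metric, reports the group medians and a two-sided Mann-Whitney
#' U test between the two label groups (e.g. very-likely producers vs
#' nonproducers), flagging metrics with p < 0.05.
#'
#' @param metrics Data frame from [topology()] (needs a `label` column).
#' @param group_a,group_b Character sets of labels defining the two groups
#'   (defaults `"very_likely"` vs `"nonproducer"`).
#' @param metric_cols Metrics to compare.
#' @return Data frame: `metric`, `median_a`, `median_b`, `statistic`
#'   (Mann-Whitney U for group a), `p_value`, `significant`.
#' @export
compare_groups <- function(metrics, group_a = "very_likely",
                           group_b = "nonproducer",
                           metric_cols = c("degree", "closeness", "betweenness")) {
  a <- metrics[metrics$label %in% group_a, , drop = FALSE]
  b <- metrics[metrics$label %in% group_b, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop(sprintf("group_a (%s) is empty", paste(group_a, collapse = ",")),
         call. = FALSE)
  }
  if (nrow(b) == 0L) {
    stop(sprintf("group_b (%s) is empty", paste(group_b, collapse = ",")),
         call. = FALSE)
  }
  rows <- lapply(metric_cols, function(m) {
    x <- a[[m]]; y <- b[[m]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = NULL))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
    data.frame(metric = m,
               median_a = stats::median(x), median_b = stats::median(y),
               statistic = unname(wt$statistic), p_value = p,
               significant = p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- list(a = group_a, b = group_b,
                              n_a = nrow(a), n_b = nrow(b))
  out
}
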