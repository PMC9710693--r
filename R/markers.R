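#' Per-gene detection fractions inside and outside each cell-type cluster
#'
#' A cell "detects" a gene when its count is greater than zero (the standard
#' percent-detected definition). For each gene g and cell type c, `pct_in`
#' is the detected fraction among cells of type c, and `pct_out` the
#' detected fraction among all other cells.
#'
#' @param sc A [single_cell_dataset()] (counts or CPM; the zero pattern is
#'   scale-invariant).
#' @return A data.frame (the marker table) with columns `gene_id`,
#'   `cell_type`, `pct_in`, `pct_out`; one row per (gene, type) pair.
#' @export
detection_fractions <- function(sc) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  types <- levels(sc$cell_type)
  if (length(types) < 2) stop("need at least 2 cell types")
  det <- sc$expr$values > 0
  n_tot <- ncol(det)
  det_tot <- rowSums(det)
  res <- lapply(types, function(tp) {
    inside <- sc$cell_type == tp
    n_in <- sum(inside)
    d_in <- rowSums(det[, inside, drop = FALSE])
    data.frame(gene_id = rownames(det), cell_type = tp,
               pct_in = d_in / n_in,
               pct_out = (det_tot - d_in) / (n_tot - n_in),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Select cell-type marker genes by detection-percentage difference
#'
#' Two-step rule. Step 1 keeps (gene, type) pairs whose detection fraction
#' inside the cluster exceeds the outside fraction by at least `threshold`
#' (pairs with `|pct_in - pct_out| < threshold` are excluded, and the marker
#' must be enriched in its own cluster, `pct_in > pct_out`; ties at exactly
#' the threshold are kept). Step 2 drops every gene retained for more than
#' one cluster, so surviving genes map to exactly one cell type and the
#' marker sets of any two types share no genes.
#'
#' @param tab Marker table from [detection_fractions()].
#' @param threshold Minimum detection-fraction difference, in (0, 1];
#'   default 0.5. Lowering it only grows the step-1 set.
#' @return A data.frame with columns `gene_id`, `cell_type`, `pct_in`,
#'   `pct_out`, one row per retained marker; attribute `"step1"` holds the
#'   pre-deduplication table.
#' @export
select_markers <- function(tab, threshold = 0.5) {
  stopifnot(is.data.frame(tab),
            all(c("gene_id", "cell_type", "pct_in", "pct_out") %in% colnames(tab)))
  if (!(threshold > 0 && threshold <= 1)) stop("'threshold' must be in (0, 1]")
  keep <- tab$pct_in > tab$pct_out &
    abs(tab$pct_in - tab$pct_out) >= threshold
  step1 <- tab[keep, , drop = FALSE]
  shared <- unique(step1$gene_id[duplicated(step1$gene_id)])
  out <- step1[!(step1$gene_id %in% shared), , drop = FALSE]
  types <- unique(tab$cell_type)
  uncovered <- setdiff(types, out$cell_type)
  if (length(uncovered)) {
    stop("no marker genes survive for cell type(s): ",
         paste(uncovered, collapse = ", "),
         " (closely related types may share all their markers)")
  }
  rownames(out) <- NULL
  attr(out, "step1") <- step1
  out
}

#' Optional rank-sum pre-filter for candidate markers
#'
#' For users wanting a differential-expression screen before the
#' detection-percentage rule: a two-sided Wilcoxon rank-sum test per gene
#' per cluster (cells inside vs outside), Benjamini-Hochberg adjusted;
#' (gene, type) pairs with FDR above `alpha` are removed from the marker
#' table before [select_markers()] is applied.
#'
#' @param sc A [single_cell_dataset()].
#' @param tab Marker table from [detection_fractions()].
#' @param alpha FDR cutoff, default 0.05.
#' @return The marker table restricted to significant (gene, type) pairs.
#' @export
de_prefilter <- function(sc, tab, alpha = 0.05) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  v <- sc$expr$values
  pvals <- mapply(function(g, tp) {
    inside <- sc$cell_type == tp
    x <- v[g, inside]
    y <- v[g, !inside]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, tab$gene_id, tab$cell_type)
  tab[stats::p.adjust(pvals, "BH") <= alpha, , drop = FALSE]
}

#' Restrict an expression matrix to a marker gene list
#'
#' @param m An [expression_matrix()] or plain matrix with gene rownames.
#' @param markers Character vector of gene ids, or a marker data.frame with
#'   a `gene_id` column.
#' @return The row-subset object; row order of `m` is preserved.
#' @export
restrict_to_markers <- function(m, markers) {
  if (is.data.frame(markers)) markers <- markers$gene_id
  markers <- unique(as.character(markers))
  rn <- if (inherits(m, "expression_matrix")) gene_ids(m) else rownames(m)
  missing <- setdiff(markers, rn)
  if (length(missing)) {
    stop("marker gene(s) absent from matrix: ",
         paste(missing[seq_len(min(5, length(missing)))], collapse = ", "))
  }
  keep <- rn[rn %in% markers]
  if (inherits(m, "expression_matrix")) {
    .replace_values(m, m$values[keep, , drop = FALSE])
  } else {
    m[keep, , drop = FALSE]
  }
}
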