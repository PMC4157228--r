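#' Hypergeometric point probability from 2x2 table margins
#'
#' Probability of observing `k` successes in the first row of a 2x2 table
#' with fixed margins: row totals `row1`, `row2` and first-column total
#' `col1`. Computed in log space by binomial-coefficient accumulation
#' (`lchoose`), so genome-scale margins (tens of thousands of background
#' genes) do not overflow. `k` outside the support returns 0.
#'
#' @param k Integer vector of first-cell counts.
#' @param row1,row2,col1 Table margins (scalars).
#' @return Numeric vector of probabilities.
#' @examples
#' hypergeom_pmf(5, 5, 5, 5) # C(5,5) C(5,0) / C(10,5) = 1/252
#' @export
hypergeom_pmf <- function(k, row1, row2, col1) {
  stopifnot(row1 >= 0, row2 >= 0, col1 >= 0, col1 <= row1 + row2)
  lo <- max(0, col1 - row2)
  hi <- min(row1, col1)
  p <- numeric(length(k))
  ok <- k >= lo & k <= hi & k == round(k)
  p[ok] <- exp(lchoose(row1, k[ok]) + lchoose(row2, col1 - k[ok]) - lchoose(row1 + row2, col1))
  p
}

#' Two-tailed Fisher exact test for one 2x2 table
#'
#' Tests whether a pathway is differently represented (enriched or depleted)
#' in the query relative to the reference background. The two-tailed p-value
#' follows the minimum-likelihood ("method of small p-values") definition:
#' the total probability, under the hypergeometric distribution fixed at the
#' observed margins, of every table whose point probability does not exceed
#' the observed one. Point probabilities within a relative tolerance of
#' `1e-7` of the observed probability are counted as ties and included, and
#' the result is clamped to \[0, 1\].
#'
#' In pathway comparison the table is `a` = query ECs in the pathway, `b` =
#' query ECs outside it, `c` = reference genes in the pathway, `d` =
#' remaining genes of the reference genome (see [build_table()]).
#'
#' @param a,b,c,d Non-negative integer cells of the 2x2 table. `a` may also
#'   be a length-4 vector holding all four cells.
#' @return The two-tailed p-value.
#' @examples
#' fisher_two_tailed(5, 0, 0, 5) # 2/252
#' @export
fisher_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b) && length(a) == 4L) {
    d <- a[[4L]]; c <- a[[3L]]; b <- a[[2L]]; a <- a[[1L]]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort_data("contingency table cells must be non-negative integers")
  }
  if (sum(cells) == 0) {
    abort_data("all-zero contingency table: the test is undefined")
  }
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  support <- max(0, col1 - row2):min(row1, col1)
  pmf <- hypergeom_pmf(support, row1, row2, col1)
  p_obs <- pmf[support == a]
  include <- pmf <= p_obs * (1 + 1e-7)
  if (all(include)) {
    return(1) # observed cell is the modal outcome: every table is included
  }
  min(max(sum(pmf[include]), 0), 1)
}

#' Multiple-testing adjustment of pathway p-values
#'
#' `bh_adjust()` applies the Benjamini-Hochberg step-up false discovery rate
#' correction: with p-values sorted ascending, `adj(i) = min(1, min over
#' j >= i of m p(j) / j)`, mapped back to input order. `adjust_pvalues()`
#' exposes the correction method as a configuration point (`"bh"`,
#' `"bonferroni"`, `"none"`); the adjustment is applied over the reported
#' pathway set only, so `m` equals the number of reported rows.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method Correction method.
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  adjust_pvalues(p, "bh")
}

#' @rdname bh_adjust
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1))) {
    abort_data("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = switch(method,
    bh = "BH",
    bonferroni = "bonferroni",
    none = "none"
  ))
}

#' Build the per-pathway 2x2 contingency table
#'
#' The first row counts distinct query ECs in and out of the pathway (a query
#' EC is "in" the pathway when it belongs to the pathway's universal EC set);
#' the second row counts reference genes in the pathway versus the rest of
#' the genome — the background is the entire gene list of the reference
#' genome. The rows are deliberately in different units (ECs vs genes),
#' following how KEGG annotates pathway membership; the report also carries
#' the pure EC counts so an EC-vs-EC table can be recomputed downstream.
#'
#' With `background = "mapped-query"` the first-row total is restricted to
#' query ECs that map to at least one pathway (`mapped_query_size`), an
#' alternative background for queries dominated by non-mapped enzymes.
#'
#' @param partition A [partition_pathway()] result.
#' @param query A query set from [read_query()] or [generate_query()].
#' @param ref An [organism_annotation()].
#' @param pathway_id Pathway identifier.
#' @param background `"all-query"` (default) or `"mapped-query"`.
#' @param mapped_query_size Number of query ECs mapping to any pathway;
#'   required for `background = "mapped-query"`.
#' @return Named integer vector with elements `a`, `b`, `c`, `d`.
#' @export
build_table <- function(partition, query, ref, pathway_id,
                        background = c("all-query", "mapped-query"),
                        mapped_query_size = NULL) {
  background <- match.arg(background)
  a <- length(partition$shared) + length(partition$unique_query)
  n_query <- if (background == "mapped-query") {
    if (is.null(mapped_query_size)) {
      abort_usage("background = 'mapped-query' requires mapped_query_size")
    }
    mapped_query_size
  } else {
    length(query$ecs)
  }
  b <- n_query - a
  cc <- unname(ref$pathway_genes[pathway_id])
  cc <- if (is.na(cc) || is.null(cc)) 0L else cc
  if (ref$total_genes < cc) {
    abort_data(sprintf(
      "corrupt definitions: pathway %s has %d genes but the genome total is %d",
      pathway_id, cc, ref$total_genes
    ))
  }
  d <- ref$total_genes - cc
  if (b < 0) {
    abort_data(sprintf("pathway %s: in-pathway query count %d exceeds the query background %d",
      pathway_id, a, n_query))
  }
  c(a = as.integer(a), b = as.integer(b), c = as.integer(cc), d = as.integer(d))
}
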