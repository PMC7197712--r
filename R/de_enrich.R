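# Differential expression by the overestimated-variance t-test with BH
# correction, and hypergeometric GO term enrichment on the top-ranked
# genes.

#' Rank genes for a group with the overestimated-variance t-test
#'
#' Compares one cell group against the rest with a Welch-style t statistic
#' in which the rest-group variance term is divided by the *group* size
#' rather than the rest size:
#' \deqn{t = (\mu_g - \mu_r) / \sqrt{s_g^2/n_g + s_r^2/n_g}}
#' This deliberately overestimates the standard error whenever the group is
#' smaller than the rest, making the test conservative for small clusters.
#' Degrees of freedom follow the Welch-Satterthwaite formula under the same
#' substitution; two-sided p values come from the t distribution and are
#' adjusted with \code{\link{bh_adjust}}. Genes are ordered by decreasing
#' t.
#'
#' @param lognorm a \code{lognorm_matrix} or matrix, cells x genes, of
#'   log-normalized expression.
#' @param labels per-cell group labels.
#' @param group the label of the group to test (>= 2 cells; the rest must
#'   also have >= 2 cells).
#' @return A data.frame ordered by decreasing t: \code{gene},
#'   \code{mean_group}, \code{mean_rest}, \code{log2_fc}, \code{t},
#'   \code{df}, \code{p_value}, \code{p_adj}.
#' @export
rank_genes <- function(lognorm, labels, group) {
  m <- if (inherits(lognorm, "lognorm_matrix")) lognorm$values else lognorm
  stop_if_not(length(labels) == nrow(m),
              "labels not aligned with cells")
  in_g <- labels == group
  n_g <- sum(in_g)
  n_r <- sum(!in_g)
  stop_if_not(n_g >= 2 && n_r >= 2,
              "group and rest must each have >= 2 cells")
  sg <- sparse_col_stats(m[in_g, , drop = FALSE])
  sr <- sparse_col_stats(m[!in_g, , drop = FALSE])
  # both variance terms divided by the group size: the overestimation
  se2 <- sg$var / n_g + sr$var / n_g
  t_stat <- ifelse(se2 > 0, (sg$mean - sr$mean) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((sg$var / n_g)^2 / (n_g - 1) +
                          (sr$var / n_g)^2 / (n_r - 1)), 1)
  df[!is.finite(df) | df <= 0] <- 1
  p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df), 1)
  # means of log1p data are >= 0; clamp guards callers passing raw values
  lfc <- log2((pmax(expm1(sg$mean), 0) + 1e-9) /
                (pmax(expm1(sr$mean), 0) + 1e-9))
  out <- data.frame(gene = colnames(m), mean_group = sg$mean,
                    mean_rest = sr$mean, log2_fc = lfc, t = t_stat,
                    df = df, p_value = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$t, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with running-minimum enforcement,
#' clipped at 1.
#'
#' @param p numeric vector of p values in [0,1].
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p values outside [0,1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric GO term enrichment on top-ranked genes
#'
#' Takes the top \code{n_top} genes of a DE ranking (ties at the boundary
#' broken by gene name), restricts the annotation to the universe, drops
#' terms outside the size bounds (strict: terms must have more than
#' \code{min_size - 1} and fewer than \code{max_size + 1} genes, i.e.
#' sizes in [\code{min_size}, \code{max_size}] survive), and tests each
#' surviving term with the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} for \eqn{X \sim Hyper(N = |universe|, K = |term|,
#' n = n_{top})}. P values are BH-adjusted across the surviving terms.
#'
#' @param ranked either a character vector of ranked genes (best first) or
#'   a data.frame from \code{\link{rank_genes}}.
#' @param annotations term -> gene mapping: the \code{terms} list from
#'   \code{\link{read_go_table}}, the \code{annotations} data.frame from
#'   \code{\link{simulate_go_universe}}, or any data.frame with columns
#'   \code{term} and \code{gene}.
#' @param universe character vector of background genes (must contain the
#'   top genes), e.g. all genes retained after QC pruning.
#' @param n_top number of top genes tested (default 50).
#' @param min_size,max_size inclusive term-size bounds after restriction to
#'   the universe (defaults 6 and 499: more than five and fewer than five
#'   hundred genes).
#' @param term_names optional named character vector of term names.
#' @return A data.frame ordered by p value: \code{term}, \code{term_name},
#'   \code{term_size}, \code{overlap}, \code{p_value}, \code{p_adj}.
#' @export
go_enrichment <- function(ranked, annotations, universe, n_top = 50,
                          min_size = 6, max_size = 499,
                          term_names = NULL) {
  genes_ranked <- if (is.data.frame(ranked)) ranked$gene else ranked
  stop_if_not(n_top <= length(universe),
              "n_top (%d) exceeds universe size (%d)", n_top,
              length(universe))
  genes_ranked <- genes_ranked[genes_ranked %in% universe]
  # deterministic boundary: order by rank, ties at the cut by gene name
  top <- utils::head(genes_ranked, n_top)
  if (length(genes_ranked) > n_top) {
    # resolve a tie block straddling the boundary by name, if the caller
    # passed a rank_genes frame with tied statistics
    if (is.data.frame(ranked) && "t" %in% names(ranked)) {
      rr <- ranked[ranked$gene %in% genes_ranked, ]
      key <- order(-rr$t, rr$gene)
      top <- rr$gene[key][seq_len(n_top)]
    }
  }
  stop_if_not(all(top %in% universe), "universe must contain the top genes")
  terms <- if (is.data.frame(annotations)) {
    split(annotations$gene, annotations$term)
  } else annotations
  if (is.null(term_names) && is.data.frame(annotations) &&
      "term_name" %in% names(annotations)) {
    term_names <- setNames(annotations$term_name, annotations$term)
    term_names <- term_names[!duplicated(names(term_names))]
  }
  terms <- lapply(terms, function(g) unique(intersect(g, universe)))
  sizes <- lengths(terms)
  keep <- sizes >= min_size & sizes <= max_size
  terms <- terms[keep]
  if (length(terms) == 0) {
    return(data.frame(term = character(0), term_name = character(0),
                      term_size = integer(0), overlap = integer(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(unique(universe))
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, top)), integer(1))
  p <- phyper(k - 1, K, N - K, length(top), lower.tail = FALSE)
  out <- data.frame(term = names(terms),
                    term_name = if (!is.null(term_names)) {
                      unname(term_names[names(terms)])
                    } else NA_character_,
                    term_size = unname(K), overlap = unname(k),
                    p_value = unname(p), p_adj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}
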