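#' Validate an expression matrix
#'
#' Gene-by-sample matrix of nonnegative expression values; gene symbols
#' are uppercase-normalized and must be unique, as must sample ids.
#'
#' @param expr numeric matrix with gene symbols as rownames and sample
#'   ids as colnames.
#' @return the validated matrix with uppercased gene symbols.
#' @export
as_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_validation("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_validation("expression matrix needs gene rownames and sample colnames")
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr)))
    stop_validation("duplicate gene symbols")
  if (anyDuplicated(colnames(expr)))
    stop_validation("duplicate sample ids")
  if (any(expr < 0)) stop_validation("expression values must be >= 0")
  expr
}

#' Cytolytic activity (CYT) score
#'
#' Per-sample geometric mean of `GZMA` and `PRF1` expression, a proxy for
#' cytotoxic lymphocyte effector function; higher CYT indicates greater
#' cytotoxic T cell activity. Computed on linear-scale expression; zeros
#' are an error unless a pseudocount is supplied.
#'
#' @param expr expression matrix (see [as_expression_matrix()]).
#' @param gene_a,gene_b the two effector genes (defaults `GZMA`, `PRF1`).
#' @param pseudocount value added to both genes before the geometric
#'   mean, or `NULL` (default) to error loudly on nonpositive expression.
#' @return named numeric vector of per-sample scores.
#' @examples
#' expr <- rbind(GZMA = c(s1 = 1, s2 = 4), PRF1 = c(s1 = 100, s2 = 4))
#' cyt_score(expr)
#' @export
cyt_score <- function(expr, gene_a = "GZMA", gene_b = "PRF1",
                      pseudocount = NULL) {
  expr <- as_expression_matrix(expr)
  for (g in toupper(c(gene_a, gene_b)))
    if (!g %in% rownames(expr))
      stop_lookup(sprintf("gene '%s' not in expression matrix", g))
  a <- expr[toupper(gene_a), ]
  b <- expr[toupper(gene_b), ]
  if (!is.null(pseudocount)) {
    a <- a + pseudocount
    b <- b + pseudocount
  }
  if (any(a <= 0) || any(b <= 0))
    stop_domain(
      "nonpositive expression; supply a pseudocount to score such samples")
  sqrt(a * b)
}

#' Gene-covariate correlation screen
#'
#' Correlates each gene's expression with a per-sample covariate (e.g.
#' leukocyte fraction or CYT score), classifying genes as `positive` or
#' `negative` when `p < alpha`, else `ns`. Results are ordered by |r|
#' descending (ties by gene symbol) for deterministic output.
#'
#' @param expr expression matrix.
#' @param covariate named numeric vector or data.frame
#'   (`sample_id`, value) matching the matrix samples.
#' @param gene_set genes to screen (default: all rows).
#' @param alpha significance level (default 0.05, unadjusted as in the
#'   source screens; set `adjust = TRUE` for a BH-adjusted gate).
#' @param adjust logical; gate on BH-adjusted p instead of raw p.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame `gene`, `r`, `p` (and `padj` when `adjust`),
#'   `class`.
#' @export
correlate_genes <- function(expr, covariate, gene_set = NULL, alpha = 0.05,
                            adjust = FALSE,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- as_expression_matrix(expr)
  if (is.data.frame(covariate)) {
    cv <- covariate[[2L]]
    names(cv) <- covariate[[1L]]
    covariate <- cv
  }
  if (is.null(names(covariate)))
    stop_validation("covariate must carry sample ids")
  mismatch <- c(setdiff(colnames(expr), names(covariate)),
                setdiff(names(covariate), colnames(expr)))
  if (length(mismatch))
    tcaflux_error("alignment",
                  paste("unmatched sample id(s):",
                        paste(unique(mismatch), collapse = ", ")))
  covariate <- covariate[colnames(expr)]
  gene_set <- toupper(gene_set %||% rownames(expr))
  if (!length(gene_set))
    return(data.frame(gene = character(), r = numeric(), p = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing))
    stop_lookup(paste("gene(s) not in matrix:",
                      paste(missing, collapse = ", ")))
  res <- lapply(gene_set, function(g)
    pearson_r(expr[g, ], covariate, method = method))
  out <- data.frame(gene = gene_set,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  gate <- if (adjust) {
    out$padj <- bh_adjust(out$p)
    out$padj
  } else out$p
  out$class <- ifelse(gate < alpha, ifelse(out$r > 0, "positive", "negative"),
                      "ns")
  out[order(-abs(out$r), out$gene), , drop = FALSE]
}

#' Classify differential-expression results
#'
#' Benjamini-Hochberg-adjusts the p-values of a (gene, log2fc, pvalue)
#' table, then gates on fold change and adjusted significance:
#' `up` requires `log2fc > lfc_cut` and `padj < alpha`; `down` requires
#' `log2fc < -lfc_cut` and `padj < alpha`; all else `not_significant`.
#' Defaults are the melanoma RNA-seq thresholds (|log2 fold change| above
#' 2, BH-corrected p below 0.01).
#'
#' @param de data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @param lfc_cut log2 fold-change magnitude gate (default 2).
#' @param alpha BH-adjusted significance gate (default 0.01).
#' @return data.frame `gene`, `log2fc`, `pvalue`, `padj`, `class`, with a
#'   `counts` attribute (named class counts).
#' @export
classify_de <- function(de, lfc_cut = 2, alpha = 0.01) {
  req <- c("gene", "log2fc", "pvalue")
  miss <- setdiff(req, names(de))
  if (length(miss))
    stop_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(toupper(de$gene)))
    stop_validation("duplicate genes in DE table")
  out <- de[req]
  out$gene <- toupper(out$gene)
  out$padj <- bh_adjust(out$pvalue)
  out$class <- ifelse(out$padj < alpha & out$log2fc > lfc_cut, "up",
               ifelse(out$padj < alpha & out$log2fc < -lfc_cut, "down",
                      "not_significant"))
  counts <- c(up = sum(out$class == "up"),
              down = sum(out$class == "down"),
              not_significant = sum(out$class == "not_significant"))
  structure(out, counts = counts)
}

#' Survival Z score and one-sided p conversions
#'
#' One-sided upper-tail normal convention of prognostic meta-analysis Z
#' scores: `p = 1 - Phi(z)`, so `z = 3.09` corresponds to `p = 0.001` and
#' negative z (beneficial effect of high expression) to `p > 0.5`.
#' `p_to_z()` is the inverse quantile.
#'
#' @param z numeric Z score(s).
#' @return `z_to_p()`: one-sided p in (0, 1); `p_to_z()`: Z score.
#' @examples
#' z_to_p(3.09)
#' p_to_z(0.001)
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop_domain("z must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' @param p one-sided p-value(s) in (0, 1).
#' @rdname z_to_p
#' @export
p_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_domain("p must lie strictly in (0, 1)")
  stats::qnorm(p, lower.tail = FALSE)
}

#' Classify prognostic survival Z scores
#'
#' Three-way classification of per-gene survival Z scores: `detrimental`
#' when `z > z_cut` (high expression associated with worse overall
#' survival), `beneficial` when `z < -z_cut`, else `neutral`. The default
#' cut 3.09 corresponds to a one-sided p of 0.001.
#'
#' @param z_table data.frame with columns `gene`, `zscore`.
#' @param z_cut classification threshold (default 3.09).
#' @return data.frame `gene`, `zscore`, `p_one_sided`, `class`, with a
#'   `counts` attribute.
#' @export
classify_prognostic <- function(z_table, z_cut = 3.09) {
  req <- c("gene", "zscore")
  miss <- setdiff(req, names(z_table))
  if (length(miss))
    stop_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  z <- z_table$zscore
  if (!is.numeric(z) || any(!is.finite(z)))
    stop_validation("zscore must be finite numeric")
  out <- data.frame(gene = toupper(z_table$gene), zscore = z,
                    p_one_sided = z_to_p(z),
                    class = ifelse(z > z_cut, "detrimental",
                            ifelse(z < -z_cut, "beneficial", "neutral")),
                    stringsAsFactors = FALSE)
  counts <- c(detrimental = sum(out$class == "detrimental"),
              beneficial = sum(out$class == "beneficial"),
              neutral = sum(out$class == "neutral"))
  structure(out, counts = counts)
}

#' PCA variance explained
#'
#' Fraction of variance explained by each principal component of the
#' sample-by-gene matrix (samples as observations, genes column-centered;
#' singular-value decomposition). Fractions sum to 1 over all nonzero
#' components.
#'
#' @param expr expression matrix (genes x samples).
#' @return numeric vector of variance fractions per component.
#' @export
pca_variance_explained <- function(expr) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 2L) stop_data("need at least 2 samples")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v[v > max(v) * 1e-12]
  v / sum(v)
}

#' Row clustering with per-row Z scores
#'
#' Standardizes each row to mean 0 and standard deviation 1, computes
#' Euclidean distances between rows, and clusters with average-linkage
#' agglomeration — the standard heatmap row-clustering recipe. Constant
#' rows (undefined after Z-scoring) are dropped with a warning. Leaf
#' order is deterministic: ties in merge height are resolved by the
#' lowest original row index (the agglomeration order of [stats::hclust()]).
#'
#' @param mat numeric matrix with rownames.
#' @return a list with `order` (row labels in leaf order), `hclust` (the
#'   [stats::hclust()] tree), `zmat` (the row-standardized matrix) and
#'   `dropped` (labels of constant rows removed).
#' @export
cluster_rows <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop_data("need a matrix with >= 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  sds <- apply(mat, 1, stats::sd)
  dropped <- rownames(mat)[sds == 0]
  if (length(dropped) == nrow(mat))
    stop_data("all rows are constant; nothing to cluster")
  if (length(dropped)) {
    warning(sprintf("dropping %d constant row(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
    mat <- mat[sds > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop_data("fewer than 2 non-constant rows")
  zmat <- t(scale(t(mat)))
  hc <- stats::hclust(stats::dist(zmat, method = "euclidean"),
                      method = "average")
  list(order = rownames(zmat)[hc$order], hclust = hc, zmat = zmat,
       dropped = dropped)
}
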