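#' Per-sample gene-module score
#'
#' Every member gene is z-scored across samples (mean 0, SD 1, n - 1
#' denominator); the module score of a sample is the mean of the member
#' genes' z-scores. Scores therefore sum to zero across samples for every
#' module. Module genes absent from the matrix are dropped (with a warning
#' when more than half the module is missing); zero-variance genes are
#' excluded with a warning.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param module_genes character vector of member genes.
#' @return named numeric vector of per-sample scores (z units).
#' @export
module_score <- function(expr, module_genes) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), ncol(expr) >= 2)
  if (length(module_genes) == 0) stop("empty module")
  present <- intersect(module_genes, rownames(expr))
  missing <- setdiff(module_genes, rownames(expr))
  if (length(present) == 0)
    stop("no module genes present in matrix; missing: ",
         paste(missing, collapse = ", "))
  if (length(present) < length(module_genes) / 2)
    warning("fewer than 50% of module genes present (",
            length(present), "/", length(module_genes), "); proceeding")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance module gene(s) excluded")
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) stop("all module genes have zero variance")
  }
  z <- t(scale(t(sub)))  # per gene across samples
  colMeans(z)
}

#' Score several modules at once
#'
#' @param expr genes x samples matrix.
#' @param modules named list of gene vectors, or a data.frame with columns
#'   `module_id` and `gene`.
#' @return modules x samples matrix of scores.
#' @export
module_score_table <- function(expr, modules) {
  if (is.data.frame(modules))
    modules <- split(modules$gene, modules$module_id)
  out <- t(vapply(modules, function(g) module_score(expr, g),
                  numeric(ncol(expr))))
  colnames(out) <- colnames(expr)
  out
}

#' Compare module scores between genotypes
#'
#' Two-sided Wilcoxon rank-sum test with the same contract as
#' [compare_groups()].
#'
#' @param scores per-sample module scores.
#' @param genotype genotype labels (2 levels).
#' @return list with `p`, `statistic` and group medians.
#' @export
compare_module <- function(scores, genotype) {
  compare_groups(scores, genotype)
}

#' Generate an expression matrix with planted module shifts
#'
#' Baseline expression is i.i.d. standard normal per gene and sample (in
#' arbitrary normalized-expression units); for each entry of `effects`, the
#' member genes of that module are shifted by the stated amount (in SD
#' units) in the samples of the stated group. Deterministic under the seed.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param module_defs named list of gene vectors; every gene name must be of
#'   the form produced here (`gene_###`) or you may pass your own
#'   `gene_names`.
#' @param effects data.frame with columns `module_id`, `group`, `shift_sd`
#'   (may be empty for a null matrix).
#' @param group_labels character vector of length `n_samples` assigning
#'   samples to groups.
#' @param seed integer seed.
#' @param gene_names optional explicit gene names (length `n_genes`).
#' @return list of class `expr_sim`: `expr` (matrix), `groups`, `modules`,
#'   `effects`.
#' @export
generate_expression_matrix <- function(n_genes, n_samples, module_defs,
                                       effects = NULL, group_labels,
                                       seed = 1, gene_names = NULL) {
  if (is.null(gene_names))
    gene_names <- sprintf("gene_%03d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes, length(group_labels) == n_samples)
  if (any(vapply(module_defs, length, 1L) == 0)) stop("empty module")
  if (!all(unlist(module_defs) %in% gene_names))
    stop("module gene lists must be a subset of generated gene names")
  with_seed(seed, {
    expr <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                   dimnames = list(gene_names,
                                   sprintf("sample_%02d", seq_len(n_samples))))
    if (!is.null(effects) && nrow(effects) > 0) {
      for (i in seq_len(nrow(effects))) {
        genes <- module_defs[[effects$module_id[i]]]
        cols <- group_labels == effects$group[i]
        expr[genes, cols] <- expr[genes, cols] + effects$shift_sd[i]
      }
    }
    structure(list(expr = expr, groups = group_labels,
                   modules = module_defs, effects = effects, seed = seed),
              class = "expr_sim")
  })
}
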