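#' Construct a label-free-quantification table object
#'
#' Couples a proteins x samples matrix of log2 LFQ intensities (NA = not
#' detected) with sample metadata covering every column.
#'
#' @param log2_lfq numeric matrix, rownames = protein accessions, colnames =
#'   sample ids.
#' @param metadata data.frame with one row per sample: `sample`,
#'   `compartment` ("neurite"/"soma"), `genotype`, `clone`, `replicate`.
#' @return object of class `lfq_table`.
#' @export
lfq_table <- function(log2_lfq, metadata) {
  stopifnot(is.matrix(log2_lfq), !is.null(colnames(log2_lfq)),
            all(c("sample", "compartment") %in% names(metadata)))
  if (nrow(log2_lfq) > 0 && is.null(rownames(log2_lfq)))
    stop("protein row names are required")
  if (anyDuplicated(colnames(log2_lfq))) stop("sample ids must be unique")
  if (!all(colnames(log2_lfq) %in% metadata$sample))
    stop("metadata must cover every sample column")
  metadata <- metadata[match(colnames(log2_lfq), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(log2 = log2_lfq, meta = metadata), class = "lfq_table")
}

#' Remove rarely-detected proteins
#'
#' Keeps proteins detected (non-missing) in at least `min_fraction` of the
#' retained samples. Samples listed in `exclude_samples` are removed first,
#' mirroring the removal of low-yield runs before filtering. The operation is
#' idempotent.
#'
#' @param table an [lfq_table()].
#' @param min_fraction detection fraction threshold in (0, 1]; default 0.7.
#' @param exclude_samples character vector of sample ids dropped before
#'   filtering.
#' @return filtered `lfq_table`.
#' @export
filter_detection <- function(table, min_fraction = 0.7,
                             exclude_samples = character()) {
  stopifnot(inherits(table, "lfq_table"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  keep_s <- !(colnames(table$log2) %in% exclude_samples)
  m <- table$log2[, keep_s, drop = FALSE]
  frac <- rowMeans(!is.na(m))
  out <- m[frac >= min_fraction, , drop = FALSE]
  # matrix subsetting drops dimnames on empty results; keep them explicit
  rownames(out) <- rownames(m)[frac >= min_fraction]
  lfq_table(out, table$meta[keep_s, , drop = FALSE])
}

#' Compartment-exclusive protein sets
#'
#' A protein is neurite-exclusive iff it is detected in at least one neurite
#' sample and in no soma sample (and vice versa). Computed on the unfiltered
#' table by default, optionally restricted to a subset of samples (e.g. the
#' wild-type control lines).
#'
#' @param table an [lfq_table()].
#' @param samples optional character vector restricting the analysis.
#' @return list with `neurite_only` and `soma_only` character vectors.
#' @export
exclusive_proteins <- function(table, samples = NULL) {
  stopifnot(inherits(table, "lfq_table"))
  m <- table$log2; meta <- table$meta
  if (!is.null(samples)) {
    keep <- colnames(m) %in% samples
    m <- m[, keep, drop = FALSE]; meta <- meta[keep, , drop = FALSE]
  }
  in_n <- rowSums(!is.na(m[, meta$compartment == "neurite", drop = FALSE])) > 0
  in_s <- rowSums(!is.na(m[, meta$compartment == "soma", drop = FALSE])) > 0
  list(neurite_only = rownames(m)[in_n & !in_s],
       soma_only = rownames(m)[in_s & !in_n])
}

#' Neurite-versus-soma differential abundance
#'
#' Per-protein two-sided pooled-variance t test on log2 LFQ values
#' (pairwise-complete; missing entries treated as non-detections, never
#' imputed), Benjamini-Hochberg adjustment across tested proteins, and pass
#' flags at the stated thresholds. log2FC is mean(group A) - mean(group B)
#' where A is the first factor level of the contrast (default
#' neurite - soma). Proteins with fewer than 2 observed values in either
#' group are reported untested.
#'
#' @param table an [lfq_table()] (usually after [filter_detection()]).
#' @param contrast length-2 character: compartments compared (A, B).
#' @param adj_p_threshold,lfc_threshold pass thresholds; a protein passes iff
#'   adjusted p < `adj_p_threshold` and |log2FC| > `lfc_threshold`.
#' @return data.frame per protein: mean_a, mean_b, log2fc, t, df, p, p_adj,
#'   tested, pass.
#' @export
compartment_de <- function(table, contrast = c("neurite", "soma"),
                           adj_p_threshold = 0.05, lfc_threshold = 1.5) {
  stopifnot(inherits(table, "lfq_table"), length(contrast) == 2)
  m <- table$log2
  ia <- table$meta$compartment == contrast[1]
  ib <- table$meta$compartment == contrast[2]
  res <- t(apply(m, 1, function(x) {
    a <- x[ia]; a <- a[!is.na(a)]
    b <- x[ib]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      return(c(mean_a = if (length(a)) mean(a) else NA_real_,
               mean_b = if (length(b)) mean(b) else NA_real_,
               log2fc = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_))
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
      return(c(mean_a = mean(a), mean_b = mean(b), log2fc = 0,
               t = 0, df = length(a) + length(b) - 2, p = 1))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    c(mean_a = mean(a), mean_b = mean(b), log2fc = mean(a) - mean(b),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }))
  out <- as.data.frame(res)
  out$protein <- rownames(m)
  out$tested <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  out$pass <- out$tested & out$p_adj < adj_p_threshold &
    abs(out$log2fc) > lfc_threshold
  rownames(out) <- NULL
  out[, c("protein", "mean_a", "mean_b", "log2fc", "t", "df", "p", "p_adj",
          "tested", "pass")]
}

#' Per-protein genotype comparison within one compartment
#'
#' Pooled-variance two-sided Student t test on observed log2 LFQ values;
#' degrees of freedom are n1 + n2 - 2 after dropping missing entries.
#'
#' @param table an [lfq_table()].
#' @param protein protein accession (row name).
#' @param compartment compartment to restrict to.
#' @param genotypes length-2 character: genotype levels compared (A, B).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `tested`.
#' @export
genotype_t_test <- function(table, protein, compartment, genotypes) {
  stopifnot(inherits(table, "lfq_table"), length(genotypes) == 2)
  x <- table$log2[protein, ]
  meta <- table$meta
  a <- x[meta$compartment == compartment & meta$genotype == genotypes[1]]
  b <- x[meta$compartment == compartment & meta$genotype == genotypes[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = NA_real_, mean_b = NA_real_, tested = FALSE))
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), mean_b = mean(b), tested = TRUE))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), tested = TRUE)
}

#' Soma/neurite abundance ratios of log2 LFQ values
#'
#' For every (clone, replicate) pair that has both a soma and a neurite
#' sample, the ratio divides the log2-transformed LFQ value in the soma by
#' the value in the matched neurite — a ratio of logs (deliberately not a difference of logs), with a
#' companion difference-of-logs column (`log2_diff`) for interpretability.
#' Values > 1 indicate soma skew, < 1 neurite skew. Replicates missing either
#' compartment value are skipped.
#'
#' @param table an [lfq_table()].
#' @param protein protein accession.
#' @param genotype optional genotype restriction.
#' @return data.frame per matched replicate: clone, replicate, genotype,
#'   soma, neurite, ratio, log2_diff.
#' @export
abundance_ratio <- function(table, protein, genotype = NULL) {
  stopifnot(inherits(table, "lfq_table"))
  x <- table$log2[protein, ]
  meta <- table$meta
  if (!is.null(genotype)) {
    keep <- meta$genotype == genotype
    x <- x[keep]; meta <- meta[keep, , drop = FALSE]
  }
  key <- paste(meta$clone, meta$replicate, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sel <- key == k
    s <- x[sel & meta$compartment == "soma"]
    n <- x[sel & meta$compartment == "neurite"]
    if (length(s) != 1 || length(n) != 1 || is.na(s) || is.na(n)) {
      warning("unmatched or missing replicate skipped for ", protein)
      return(NULL)
    }
    i <- which(sel)[1]
    data.frame(clone = meta$clone[i], replicate = meta$replicate[i],
               genotype = meta$genotype[i],
               soma = unname(s), neurite = unname(n),
               ratio = unname(s / n), log2_diff = unname(s - n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Read an LFQ table and sample metadata from disk
#'
#' @param lfq_path wide TSV, first column protein accession, remaining
#'   columns samples (empty/NA = not detected).
#' @param meta_path CSV with columns sample, compartment, genotype, clone,
#'   replicate.
#' @return an [lfq_table()].
#' @export
read_lfq <- function(lfq_path, meta_path) {
  wide <- utils::read.delim(lfq_path, check.names = FALSE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[1]]
  storage.mode(m) <- "double"
  lfq_table(m, utils::read.csv(meta_path, stringsAsFactors = FALSE))
}

#' Write an LFQ table (and its metadata) to disk
#' @param table an [lfq_table()].
#' @param lfq_path output TSV path.
#' @param meta_path optional output CSV path for the metadata.
#' @return invisibly, the paths written.
#' @export
write_lfq <- function(table, lfq_path, meta_path = NULL) {
  stopifnot(inherits(table, "lfq_table"))
  wide <- data.frame(protein = rownames(table$log2), table$log2,
                     check.names = FALSE)
  utils::write.table(wide, lfq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.csv(table$meta, meta_path, row.names = FALSE)
  invisible(c(lfq_path, meta_path))
}
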