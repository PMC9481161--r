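# Gene co-occurrence profiling: rank genes by similarity of their genomic
# presence/absence profile to a reference gene (the screening logic of
# phylogenomic candidate discovery).

TAXON_COLUMNS <- c("genome", "phylum", "class", "order")

#' Construct a presence/absence matrix object
#'
#' @param values logical or 0/1 matrix, genomes x genes, with genome row
#'   names and gene column names.
#' @param taxa data frame with columns `genome`, `phylum`, `class`, `order`
#'   (one row per genome, same order as `values`).
#' @return object of class `presence_absence_matrix`.
#' @export
presence_absence_matrix <- function(values, taxa) {
  assert_that(is.matrix(values), "values must be a matrix")
  assert_that(all(values %in% c(0, 1)), "values must be 0/1")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "gene names must be unique column names")
  assert_that(is.data.frame(taxa) && all(TAXON_COLUMNS %in% names(taxa)) &&
                nrow(taxa) == nrow(values),
              "taxa must have columns %s, one row per genome",
              paste(TAXON_COLUMNS, collapse = ", "))
  assert_that(!anyDuplicated(taxa$genome), "genome names must be unique")
  storage.mode(values) <- "integer"
  rownames(values) <- taxa$genome
  structure(list(values = values, taxa = taxa[TAXON_COLUMNS]),
            class = "presence_absence_matrix")
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("presence/absence matrix: %d genomes x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat("genes:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Read a presence/absence matrix from TSV
#'
#' Expected layout: taxon columns `genome`, `phylum`, `class`, `order`
#' followed by one 0/1 column per gene; one row per genome. Ragged rows,
#' duplicate names or non-0/1 values are rejected with the offending line or
#' column named.
#'
#' @param path TSV file.
#' @param x a `presence_absence_matrix` (for writing).
#' @return [load_pa_matrix()] returns a `presence_absence_matrix`;
#'   [write_pa_matrix()] invisibly returns `path` (the written file reads
#'   back identically).
#' @export
load_pa_matrix <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 2L, "matrix file needs a header and >= 1 genome")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    stop_pq("ragged row at line %d (%d fields, expected %d)",
            which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L])
  }
  df <- read_tsv_table(path)
  assert_that(all(TAXON_COLUMNS %in% names(df)),
              "matrix must start with taxon columns %s",
              paste(TAXON_COLUMNS, collapse = ", "))
  genes <- setdiff(names(df), TAXON_COLUMNS)
  assert_that(length(genes) >= 1L, "no gene columns found")
  if (anyDuplicated(names(df))) {
    stop_pq("duplicate column name: %s", names(df)[duplicated(names(df))][1L])
  }
  vals <- as.matrix(df[genes])
  bad <- which(!(vals %in% c(0, 1)))
  if (length(bad) > 0L) {
    rowi <- (bad[1L] - 1L) %% nrow(vals) + 1L
    stop_pq("non-0/1 value '%s' at line %d", vals[bad[1L]], rowi + 1L)
  }
  presence_absence_matrix(vals, df[TAXON_COLUMNS])
}

#' @rdname load_pa_matrix
#' @export
write_pa_matrix <- function(x, path) {
  stopifnot(inherits(x, "presence_absence_matrix"))
  write_tsv_table(cbind(x$taxa, as.data.frame(x$values)), path)
}

# Pairwise profile score between two 0/1 vectors.
profile_score <- function(u, v, metric) {
  a <- sum(u == 1 & v == 1)   # both present
  b <- sum(u == 1 & v == 0)   # only first
  c_ <- sum(u == 0 & v == 1)  # only second
  d <- sum(u == 0 & v == 0)   # both absent
  score <- switch(metric,
    jaccard = if (a + b + c_ == 0) 0 else a / (a + b + c_),
    phi = {
      den <- sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
      if (den == 0) 0 else (a * d - b * c_) / den
    })
  list(score = score, counts = c(both_present = a, only_first = b,
                                 only_second = c_, both_absent = d))
}

#' Rank genes by profile similarity to a reference gene
#'
#' Default metric is the Jaccard index,
#' `both_present / (both_present + only_reference + only_gene)`, which
#' ignores genomes lacking both genes - appropriate when most genomes in a
#' broad survey lack the module of interest. The phi (Pearson) coefficient
#' is available as an alternative. Genes are ranked by descending score,
#' ties broken alphabetically; the reference itself is excluded.
#'
#' @param matrix a `presence_absence_matrix`.
#' @param reference_gene gene name present in the matrix.
#' @param metric `"jaccard"` or `"phi"`.
#' @return data frame with columns `gene`, `score`, `both_present`,
#'   `only_reference`, `only_gene`, `both_absent`, ordered by rank.
#' @export
profile_similarity <- function(matrix, reference_gene,
                               metric = c("jaccard", "phi")) {
  stopifnot(inherits(matrix, "presence_absence_matrix"))
  metric <- match.arg(metric)
  genes <- colnames(matrix$values)
  assert_that(reference_gene %in% genes,
              "reference gene '%s' not in matrix", reference_gene)
  ref <- matrix$values[, reference_gene]
  others <- setdiff(genes, reference_gene)
  rows <- lapply(others, function(g) {
    sc <- profile_score(ref, matrix$values[, g], metric)
    data.frame(gene = g, score = sc$score,
               both_present = sc$counts[["both_present"]],
               only_reference = sc$counts[["only_first"]],
               only_gene = sc$counts[["only_second"]],
               both_absent = sc$counts[["both_absent"]])
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' Pairwise co-occurrence table and per-taxon presence summary
#'
#' @param matrix a `presence_absence_matrix`.
#' @param gene_subset genes to include (default: all).
#' @param metric `"jaccard"` or `"phi"`.
#' @param taxon_level `"phylum"`, `"class"` or `"order"`: grouping for the
#'   presence-fraction summary.
#' @return list with `scores` (symmetric gene x gene matrix, unit diagonal
#'   for jaccard) and `taxon_presence` (data frame of per-taxon presence
#'   fractions per gene, with genome counts).
#' @export
cooccurrence_table <- function(matrix, gene_subset = NULL,
                               metric = c("jaccard", "phi"),
                               taxon_level = c("order", "class", "phylum")) {
  stopifnot(inherits(matrix, "presence_absence_matrix"))
  metric <- match.arg(metric)
  taxon_level <- match.arg(taxon_level)
  genes <- gene_subset %||% colnames(matrix$values)
  missing <- setdiff(genes, colnames(matrix$values))
  assert_that(length(missing) == 0L, "unknown gene(s): %s",
              paste(missing, collapse = ", "))
  k <- length(genes)
  scores <- diag(1, k)
  dimnames(scores) <- list(genes, genes)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s <- profile_score(matrix$values[, genes[i]],
                           matrix$values[, genes[j]], metric)$score
        scores[i, j] <- s
        scores[j, i] <- s
      }
    }
  }
  if (metric == "phi") diag(scores) <- 1
  grp <- matrix$taxa[[taxon_level]]
  agg <- do.call(rbind, lapply(split(seq_len(nrow(matrix$values)), grp),
                               function(idx) {
    fr <- colMeans(matrix$values[idx, genes, drop = FALSE])
    cbind(data.frame(taxon = grp[idx[1L]], n_genomes = length(idx)),
          as.data.frame(as.list(fr)))
  }))
  rownames(agg) <- NULL
  list(scores = scores, taxon_presence = agg)
}

#' Generate a synthetic presence/absence matrix
#'
#' The reference gene's profile is Bernoulli(`ref_prevalence`); every other
#' gene matches the reference profile per genome with its co-occurrence
#' probability (and takes the flipped state otherwise). Taxon labels cycle
#' through a small synthetic taxonomy.
#'
#' @param spec a [presence_absence_spec()].
#' @return a `presence_absence_matrix` with the spec attached as attribute
#'   `spec`.
#' @export
gen_presence_absence <- function(spec) {
  stopifnot(inherits(spec, "presence_absence_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  genes <- spec$gene_names
  ref <- as.integer(stats::runif(n) < spec$ref_prevalence)
  vals <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  vals[, spec$reference_gene] <- ref
  for (g in names(spec$co_occurrence_prob)) {
    match_ref <- stats::runif(n) < spec$co_occurrence_prob[[g]]
    vals[, g] <- ifelse(match_ref, ref, 1L - ref)
  }
  phyla <- c("Myxococcota", "Proteobacteria", "Bacteroidota", "Firmicutes")
  taxa <- data.frame(
    genome = sprintf("genome_%04d", seq_len(n)),
    phylum = rep_len(phyla, n),
    class = rep_len(paste0(phyla, "_c"), n),
    order = rep_len(paste0("order_", seq_len(8)), n))
  out <- presence_absence_matrix(vals, taxa)
  attr(out, "spec") <- spec
  out
}
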