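# Candidate-gene screening: threshold a differential-expression table and
# intersect the surviving genes with QTL physical support intervals.

#' Filter a DEG table by fold change and significance
#'
#' Keeps rows with `|log2fc| >= min_abs_log2fc` AND `pvalue < max_p`
#' (the fold-change bound is inclusive, the p-value bound exclusive).
#' Up/down counts are attached as attributes. Idempotent; the output is
#' always a subset of the input.
#'
#' @param table DEG data.frame with `log2fc` and `pvalue` columns (an
#'   optional `padj` column is used instead of `pvalue` when
#'   `use_adjusted = TRUE`).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @param max_p p-value cutoff (default 0.05).
#' @param use_adjusted use the `padj` column if present.
#' @return The filtered data.frame with attributes `n_up` and `n_down`.
#' @export
filter_degs <- function(table, min_abs_log2fc = 1, max_p = 0.05,
                        use_adjusted = FALSE) {
  stopifnot(all(c("log2fc", "pvalue") %in% names(table)))
  pcol <- if (use_adjusted && "padj" %in% names(table)) "padj" else "pvalue"
  keep <- abs(table$log2fc) >= min_abs_log2fc & table[[pcol]] < max_p
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  attr(out, "n_up") <- sum(out$log2fc >= 0)
  attr(out, "n_down") <- sum(out$log2fc < 0)
  out
}

#' Intersect QTL physical intervals with a DEG table
#'
#' A gene is a candidate for every QTL on the same chromosome whose
#' physical interval contains the gene position (closed interval, both
#' endpoints included); one record per (gene, QTL) pair. Chromosome ids
#' present in only one of the two tables trigger a naming-mismatch warning.
#'
#' @param qtls a `qtl_result` data.frame (or any data.frame with columns
#'   `qtl`, `chromosome`, `ci_lo_Mb`, `ci_hi_Mb`).
#' @param degs DEG data.frame with `gene_id`, `chrom`, `pos_mb`, `log2fc`,
#'   `pvalue`.
#' @return data.frame of candidates: gene_id, qtl, chromosome, pos_mb,
#'   log2fc, pvalue.
#' @export
intersect_qtl_degs <- function(qtls, degs) {
  empty <- data.frame(gene_id = character(0), qtl = character(0),
                      chromosome = character(0), pos_mb = numeric(0),
                      log2fc = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(qtls) == 0 || nrow(degs) == 0) return(empty)
  stopifnot(all(c("qtl", "chromosome", "ci_lo_Mb", "ci_hi_Mb") %in% names(qtls)),
            all(c("gene_id", "chrom", "pos_mb") %in% names(degs)))
  only_q <- setdiff(unique(as.character(qtls$chromosome)), unique(as.character(degs$chrom)))
  if (length(only_q))
    warning("naming-mismatch: QTL chromosome(s) absent from the DEG table: ",
            paste(only_q, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(qtls))) {
    hit <- as.character(degs$chrom) == as.character(qtls$chromosome[i]) &
      degs$pos_mb >= qtls$ci_lo_Mb[i] & degs$pos_mb <= qtls$ci_hi_Mb[i]
    if (any(hit)) {
      sub <- degs[hit, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        gene_id = sub$gene_id, qtl = qtls$qtl[i],
        chromosome = as.character(qtls$chromosome[i]),
        pos_mb = sub$pos_mb,
        log2fc = if ("log2fc" %in% names(sub)) sub$log2fc else NA_real_,
        pvalue = if ("pvalue" %in% names(sub)) sub$pvalue else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}
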