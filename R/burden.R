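#' Somatic mutation catalogs and gene-burden comparison
#'
#' Mirrors the COSMIC-style comparison used to ask whether a gene behaves
#' like a tumor suppressor (truncation-enriched, copy-number loss), an
#' oncogene (missense hotspots, copy-number gain), or a neutral background
#' gene (olfactory-receptor-like rates, no skew). A catalog is a flat record
#' table of `(gene, position, consequence, sample)` with protein positions in
#' 1-based codons and consequence in
#' `{synonymous, missense, nonsense, frameshift}`.
#'
#' @name mutation_burden
NULL

CONSEQUENCES <- c("synonymous", "missense", "nonsense", "frameshift")
TRUNCATING <- c("nonsense", "frameshift")

validate_catalog <- function(catalog, gene_lengths) {
  need <- c("gene", "position", "consequence", "sample")
  if (!all(need %in% names(catalog))) {
    stop_invalid("catalog needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(catalog$consequence), CONSEQUENCES)
  if (length(bad)) stop_invalid("unknown consequence value(s): %s", paste(bad, collapse = ", "))
  miss <- setdiff(unique(catalog$gene), names(gene_lengths))
  if (length(miss)) stop_invalid("no length for gene(s): %s", paste(miss, collapse = ", "))
  over <- catalog$position < 1 | catalog$position > gene_lengths[catalog$gene]
  if (any(over)) stop_invalid("record position outside [1, gene length] for %s",
                              paste(unique(catalog$gene[over]), collapse = ", "))
  invisible(catalog)
}

#' Read a mutation catalog from TSV
#'
#' Thin reader for COSMIC-like exports reduced to the four required columns
#' `gene`, `position` (1-based codon), `consequence`
#' (`synonymous`/`missense`/`nonsense`/`frameshift`) and `sample`. Unknown
#' consequence values are rejected at read time.
#'
#' @param path TSV path.
#' @param gene_lengths Named vector of protein lengths (aa) for validation.
#' @return Data frame catalog.
#' @export
read_mutation_catalog <- function(path, gene_lengths) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(cat, gene_lengths)
}

#' Per-gene synonymous and nonsynonymous burden rates
#'
#' Rates are substitutions per 1,000 amino acids: `count * 1000 / length_aa`,
#' with nonsynonymous = missense + nonsense + frameshift and synonymous
#' counted separately; no per-sample normalization. Truncating counts
#' (nonsense + frameshift) and their fraction of nonsynonymous events are
#' reported for downstream classification.
#'
#' @param catalog Catalog data frame (see [read_mutation_catalog()]).
#' @param gene_lengths Named vector of protein lengths in aa; genes listed
#'   here but absent from the catalog get zero rates.
#' @return Data frame: `gene`, `length_aa`, `syn_count`, `nonsyn_count`,
#'   `trunc_count`, `syn_rate`, `nonsyn_rate`, `trunc_fraction`.
#' @export
burden_rates <- function(catalog, gene_lengths) {
  validate_catalog(catalog, gene_lengths)
  genes <- names(gene_lengths)
  count_of <- function(g, what) {
    sum(catalog$gene == g & catalog$consequence %in% what)
  }
  syn <- vapply(genes, count_of, numeric(1), what = "synonymous")
  nonsyn <- vapply(genes, count_of, numeric(1), what = setdiff(CONSEQUENCES, "synonymous"))
  trunc <- vapply(genes, count_of, numeric(1), what = TRUNCATING)
  data.frame(
    gene = genes,
    length_aa = as.integer(gene_lengths[genes]),
    syn_count = as.integer(syn),
    nonsyn_count = as.integer(nonsyn),
    trunc_count = as.integer(trunc),
    syn_rate = syn * 1000 / gene_lengths[genes],
    nonsyn_rate = nonsyn * 1000 / gene_lengths[genes],
    trunc_fraction = ifelse(nonsyn > 0, trunc / nonsyn, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Detect positional mutation hotspots in a gene
#'
#' For each mutated codon carrying k of the gene's m nonsynonymous records
#' over L codons, computes the binomial tail `P[Binomial(m, 1/L) >= k]`
#' against a uniform positional null, adjusts across the gene's mutated
#' codons by Benjamini-Hochberg, and calls a hotspot when `q <= alpha` and
#' `k >= min_count`.
#'
#' @param catalog Catalog data frame.
#' @param gene Gene symbol.
#' @param gene_lengths Named protein lengths (aa).
#' @param alpha FDR level (default 0.05).
#' @param min_count Minimum recurrent count (default 3).
#' @return Data frame of called hotspots: `codon`, `count`, `p`, `q`, sorted
#'   by codon. Zero rows when none pass.
#' @export
detect_hotspots <- function(catalog, gene, gene_lengths, alpha = 0.05, min_count = 3L) {
  validate_catalog(catalog, gene_lengths)
  if (!gene %in% names(gene_lengths)) stop_invalid("gene '%s' not found", gene)
  recs <- catalog[catalog$gene == gene & catalog$consequence != "synonymous", , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(data.frame(codon = integer(0), count = integer(0),
                      p = numeric(0), q = numeric(0)))
  }
  L <- gene_lengths[[gene]]
  m <- nrow(recs)
  tab <- table(recs$position)
  codons <- as.integer(names(tab))
  k <- as.integer(tab)
  p <- stats::pbinom(k - 1L, size = m, prob = 1 / L, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  keep <- q <= alpha & k >= min_count
  out <- data.frame(codon = codons[keep], count = k[keep], p = p[keep], q = q[keep])
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy-number gain/loss skew for a gene
#'
#' @param cnv_table Data frame of per-sample copy-number calls with columns
#'   `sample` and `call` in `{loss, neutral, gain}` (optionally a `gene`
#'   column, filtered via `gene`).
#' @param gene Optional gene to filter on.
#' @return List: `cnl_freq`, `cng_freq` (events per sample) and
#'   `skew = (cng - cnl) / (cng + cnl)` in `[-1, 1]`, 0 when there are no
#'   events.
#' @export
cnv_skew <- function(cnv_table, gene = NULL) {
  if (!is.null(gene)) {
    if (!"gene" %in% names(cnv_table)) stop_invalid("cnv_table has no 'gene' column")
    cnv_table <- cnv_table[cnv_table$gene == gene, , drop = FALSE]
  }
  if (nrow(cnv_table) == 0L) stop_invalid("empty CNV table")
  bad <- setdiff(unique(cnv_table$call), c("loss", "neutral", "gain"))
  if (length(bad)) stop_invalid("unknown CNV call(s): %s", paste(bad, collapse = ", "))
  n <- nrow(cnv_table)
  cnl <- sum(cnv_table$call == "loss")
  cng <- sum(cnv_table$call == "gain")
  skew <- if (cnl + cng > 0) (cng - cnl) / (cng + cnl) else 0
  list(cnl_freq = cnl / n, cng_freq = cng / n, skew = skew)
}

#' Classify a gene as TSG-like, oncogene-like or neutral-like
#'
#' Decision rule over the three burden summaries: `tsg_like` when the
#' truncating fraction of nonsynonymous events is at least `t_trunc` and the
#' CNV skew is at most `-t_skew`; `oncogene_like` when at least one hotspot
#' is called and the skew is at least `+t_skew`; otherwise `neutral_like`.
#' When both rules fire, the oncogene rule (hotspot + positive skew) takes
#' precedence and the conflict is flagged.
#'
#' @param burden One row of [burden_rates()] output for the gene.
#' @param hotspots [detect_hotspots()] output for the gene.
#' @param cnv [cnv_skew()] output for the gene.
#' @param t_trunc Truncating-fraction threshold (default 0.2).
#' @param t_skew Absolute skew threshold (default 0.3).
#' @return List: `class` in `{tsg_like, oncogene_like, neutral_like}` and
#'   `conflict` flag.
#' @export
classify_gene <- function(burden, hotspots, cnv, t_trunc = 0.2, t_skew = 0.3) {
  stopifnot(nrow(burden) == 1L)
  tsg <- burden$trunc_fraction >= t_trunc && cnv$skew <= -t_skew
  onc <- nrow(hotspots) >= 1L && cnv$skew >= t_skew
  cls <- if (onc) "oncogene_like" else if (tsg) "tsg_like" else "neutral_like"
  list(class = cls, conflict = isTRUE(tsg) && isTRUE(onc))
}

#' Full burden report for every gene of a catalog
#'
#' Convenience wrapper combining [burden_rates()], [detect_hotspots()],
#' [cnv_skew()] and [classify_gene()] per gene.
#'
#' @param catalog Mutation catalog.
#' @param cnv_table CNV table with a `gene` column.
#' @param gene_lengths Named protein lengths (aa).
#' @param alpha Hotspot FDR level.
#' @param t_trunc,t_skew Classification thresholds (see [classify_gene()]).
#' @return Data frame, one row per gene, with rates, hotspot count, CNV
#'   frequencies, skew, class and conflict flag.
#' @export
burden_report <- function(catalog, cnv_table, gene_lengths, alpha = 0.05,
                          t_trunc = 0.2, t_skew = 0.3) {
  rates <- burden_rates(catalog, gene_lengths)
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    g <- rates$gene[i]
    hs <- if (rates$nonsyn_count[i] > 0) {
      detect_hotspots(catalog, g, gene_lengths, alpha = alpha)
    } else {
      data.frame(codon = integer(0), count = integer(0), p = numeric(0), q = numeric(0))
    }
    cv <- if (any(cnv_table$gene == g)) cnv_skew(cnv_table, g) else
      list(cnl_freq = 0, cng_freq = 0, skew = 0)
    cl <- classify_gene(rates[i, , drop = FALSE], hs, cv, t_trunc = t_trunc, t_skew = t_skew)
    cbind(rates[i, , drop = FALSE],
          data.frame(n_hotspots = nrow(hs), cnl_freq = cv$cnl_freq,
                     cng_freq = cv$cng_freq, cnv_skew = cv$skew,
                     class = cl$class, conflict = cl$conflict,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
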