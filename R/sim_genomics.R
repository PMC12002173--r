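#' Default gene specifications for mutation-catalog simulation
#'
#' Builds a gene-spec table of the three classes the burden comparison
#' distinguishes. Class defaults emulate aggregated COSMIC-style burdens:
#' neutral genes mutate uniformly at the background rate; TSG-like genes have
#' an elevated nonsynonymous burden enriched for truncating events and skewed
#' toward copy-number loss; oncogene-like genes concentrate missense events
#' at hotspot codons and skew toward copy-number gain.
#'
#' @param n_per_class Genes per class.
#' @param length_aa Protein length in aa (>= 50) used for all genes.
#' @param seed Integer seed (places hotspot codons).
#' @return Data frame: `gene`, `class`, `length_aa`, `hotspots`
#'   (comma-separated codons, empty for non-oncogenes),
#'   `truncating_fraction`, `cnl_prob`, `cng_prob`.
#' @export
default_gene_specs <- function(n_per_class = 10L, length_aa = 500L, seed = 1L) {
  if (length_aa < 50L) stop_invalid("gene lengths must be >= 50 aa")
  with_seed(seed, {
    mk <- function(class, trunc, cnl, cng) {
      data.frame(
        gene = sprintf("%s%02d", toupper(substr(class, 1, 3)), seq_len(n_per_class)),
        class = class, length_aa = as.integer(length_aa),
        hotspots = vapply(seq_len(n_per_class), function(i) {
          if (class == "oncogene") {
            paste(sort(sample.int(length_aa, 2L)), collapse = ",")
          } else ""
        }, character(1)),
        truncating_fraction = trunc, cnl_prob = cnl, cng_prob = cng,
        stringsAsFactors = FALSE
      )
    }
    rbind(
      mk("neutral", 0.0, 0.02, 0.02),
      mk("tsg", 0.4, 0.30, 0.03),
      mk("oncogene", 0.0, 0.03, 0.30)
    )
  })
}

parse_hotspots <- function(s) {
  if (is.na(s) || s == "") return(integer(0))
  as.integer(strsplit(s, ",")[[1]])
}

#' Simulate a COSMIC-like somatic mutation catalog and CNV table
#'
#' Per gene: synonymous and missense counts are Poisson at the background
#' rates (per 1,000 aa, aggregated over the cohort) with uniform codon
#' positions; neutral genes add a small uniform truncating admixture
#' (`neutral_trunc_mix`) as occurs without selection. TSG genes multiply the
#' nonsynonymous rate by `driver_mult` and draw each event as truncating
#' (nonsense/frameshift, 50:50) with probability `truncating_fraction`;
#' oncogene events are missense, landing on a hotspot codon with probability
#' `hotspot_fraction`. Copy-number calls are drawn per sample from each
#' gene's `cnl_prob`/`cng_prob`.
#'
#' @param gene_specs Data frame as from [default_gene_specs()].
#' @param n_samples Cohort size.
#' @param seed Integer seed.
#' @param syn_rate,nonsyn_rate Background rates, substitutions per 1,000 aa
#'   over the whole cohort (defaults 15 and 45).
#' @param driver_mult Burden multiplier for tsg/oncogene classes (default 4).
#' @param hotspot_fraction Fraction of oncogene missense events at hotspots
#'   (default 0.5).
#' @param neutral_trunc_mix Truncating fraction among background
#'   nonsynonymous events (default 0.05).
#' @return List: `catalog` (gene, position, consequence, sample), `cnv`
#'   (gene, sample, call), `gene_lengths` (named), `truth` (the
#'   gene-specification table used).
#' @export
sim_mutation_catalog <- function(gene_specs, n_samples, seed,
                                 syn_rate = 15, nonsyn_rate = 45,
                                 driver_mult = 4, hotspot_fraction = 0.5,
                                 neutral_trunc_mix = 0.05) {
  if (any(gene_specs$length_aa < 50L)) stop_invalid("gene lengths must be >= 50 aa")
  if (syn_rate < 0 || nonsyn_rate < 0) stop_invalid("rates must be nonnegative")
  if (any(gene_specs$cnl_prob + gene_specs$cng_prob > 1)) {
    stop_invalid("cnl_prob + cng_prob must be <= 1")
  }
  hs_list <- lapply(gene_specs$hotspots, parse_hotspots)
  for (i in seq_len(nrow(gene_specs))) {
    if (length(hs_list[[i]]) &&
        any(hs_list[[i]] < 1 | hs_list[[i]] > gene_specs$length_aa[i])) {
      stop_invalid("hotspot codon outside [1, length] for %s", gene_specs$gene[i])
    }
  }
  samples <- sprintf("s%04d", seq_len(n_samples))
  with_seed(seed, {
    recs <- list(); cnvs <- list()
    for (i in seq_len(nrow(gene_specs))) {
      g <- gene_specs$gene[i]; L <- gene_specs$length_aa[i]
      cls <- gene_specs$class[i]
      mult <- if (cls %in% c("tsg", "oncogene")) driver_mult else 1
      n_syn <- stats::rpois(1, syn_rate * L / 1000)
      n_non <- stats::rpois(1, nonsyn_rate * L / 1000 * mult)

      if (n_syn > 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, position = sample.int(L, n_syn, replace = TRUE),
          consequence = "synonymous",
          sample = samples[sample.int(n_samples, n_syn, replace = TRUE)],
          stringsAsFactors = FALSE
        )
      }
      if (n_non > 0) {
        pos <- sample.int(L, n_non, replace = TRUE)
        cons <- rep("missense", n_non)
        if (cls == "tsg") {
          tr <- stats::runif(n_non) < gene_specs$truncating_fraction[i]
          cons[tr] <- sample(TRUNCATING, sum(tr), replace = TRUE)
        } else if (cls == "oncogene") {
          hs <- hs_list[[i]]
          at_hs <- stats::runif(n_non) < hotspot_fraction
          if (any(at_hs) && length(hs)) {
            pos[at_hs] <- hs[sample.int(length(hs), sum(at_hs), replace = TRUE)]
          }
        } else {
          tr <- stats::runif(n_non) < neutral_trunc_mix
          cons[tr] <- sample(TRUNCATING, sum(tr), replace = TRUE)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, position = pos, consequence = cons,
          sample = samples[sample.int(n_samples, n_non, replace = TRUE)],
          stringsAsFactors = FALSE
        )
      }
      u <- stats::runif(n_samples)
      call <- ifelse(u < gene_specs$cnl_prob[i], "loss",
                     ifelse(u < gene_specs$cnl_prob[i] + gene_specs$cng_prob[i],
                            "gain", "neutral"))
      cnvs[[i]] <- data.frame(gene = g, sample = samples, call = call,
                              stringsAsFactors = FALSE)
    }
    catalog <- if (length(recs)) do.call(rbind, recs) else
      data.frame(gene = character(0), position = integer(0),
                 consequence = character(0), sample = character(0))
    list(
      catalog = catalog,
      cnv = do.call(rbind, cnvs),
      gene_lengths = stats::setNames(gene_specs$length_aa, gene_specs$gene),
      truth = gene_specs
    )
  })
}
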