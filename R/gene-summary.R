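#' Read a gene annotation (GFF3)
#'
#' @param gff path to a GFF3 file with `gene` and `mRNA` features.
#' @return list with `genes` (data.frame gene_id, seqnames, start, end,
#'   strand, biotype) and `tx2gene` (named character: transcript ID ->
#'   gene ID).
#' @export
read_gene_annotation <- function(gff) {
  gr <- rtracklayer::import(gff)
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- data.frame(
    gene_id = as.character(md$ID[is_gene]),
    seqnames = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    biotype = if ("biotype" %in% names(md))
      as.character(md$biotype[is_gene]) else NA_character_,
    stringsAsFactors = FALSE)
  is_tx <- md$type %in% c("mRNA", "transcript")
  parent <- md$Parent[is_tx]
  parent <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  tx2gene <- structure(parent, names = as.character(md$ID[is_tx]))
  list(genes = genes, tx2gene = tx2gene)
}

#' Aggregate classified reads per (gene, start position)
#'
#' One row per observed alignment start of each gene, with exact counts
#' by 5'-end class and confident family-unambiguous SL1/SL2 counts
#' (SL2.X counts toward the SL2 family; SL.X is family-ambiguous and
#' excluded from both).
#'
#' @param classified data.frame from [classify_reads()].
#' @param annotation list from [read_gene_annotation()] (or NULL: reads
#'   are binned under their `ref_id`).
#' @param collapse_window collapse start positions within this many nt of
#'   a more frequent one (default 0 = exact-position binning).
#' @return data.frame: `gene_id`, `ref_id`, `start_pos`, `n_total`,
#'   `n_sl` (all SL classes incl. ambiguous), `n_sl_ambiguous`,
#'   `n_hairpin`, `n_unidentified`, `n_sense_untested`,
#'   `n_confident_sl1`, `n_confident_sl2`.
#' @export
aggregate_start_sites <- function(classified, annotation = NULL,
                                  collapse_window = 0L) {
  x <- classified
  if (!is.null(annotation)) {
    g <- unname(annotation$tx2gene[x$ref_id])
    missing_tx <- is.na(g)
    if (any(missing_tx)) {
      warning(sum(missing_tx), " read(s) on transcripts absent from the ",
              "annotation; binned under their ref_id")
      g[missing_tx] <- x$ref_id[missing_tx]
    }
    x$gene_id <- g
  } else {
    x$gene_id <- x$ref_id
  }

  is_sl <- !(x$class %in% c("endogenous_hairpin", "unidentified",
                            "sense_untested"))
  is_amb <- x$class %in% c("SL.X", "SL2.X")
  conf1 <- is_sl & x$confident %in% TRUE & x$sl_family %in% "SL1"
  conf2 <- is_sl & x$confident %in% TRUE & x$sl_family %in% "SL2"

  key <- paste(x$gene_id, x$ref_id, x$start_pos, sep = "\r")
  agg <- function(v) as.vector(rowsum(as.numeric(v), key))
  ord_key <- sort(unique(key))
  m <- match(ord_key, key)
  out <- data.frame(
    gene_id = x$gene_id[m], ref_id = x$ref_id[m],
    start_pos = x$start_pos[m],
    n_total = agg(rep(1, nrow(x))),
    n_sl = agg(is_sl),
    n_sl_ambiguous = agg(is_amb),
    n_hairpin = agg(x$class == "endogenous_hairpin"),
    n_unidentified = agg(x$class == "unidentified"),
    n_sense_untested = agg(x$class == "sense_untested"),
    n_confident_sl1 = agg(conf1),
    n_confident_sl2 = agg(conf2),
    stringsAsFactors = FALSE)
  cnt <- c("n_total", "n_sl", "n_sl_ambiguous", "n_hairpin",
           "n_unidentified", "n_sense_untested", "n_confident_sl1",
           "n_confident_sl2")
  out[cnt] <- lapply(out[cnt], as.integer)
  out <- out[order(out$gene_id, out$ref_id, out$start_pos), , drop = FALSE]
  rownames(out) <- NULL
  if (collapse_window > 0L) out <- collapse_sites(out, collapse_window)
  out
}

# absorb alignment jitter: merge each site into the most supported site
# within `w` nt on the same gene/ref
collapse_sites <- function(sites, w) {
  parts <- split(sites, paste(sites$gene_id, sites$ref_id, sep = "\r"))
  cnt <- c("n_total", "n_sl", "n_sl_ambiguous", "n_hairpin",
           "n_unidentified", "n_sense_untested", "n_confident_sl1",
           "n_confident_sl2")
  res <- lapply(parts, function(p) {
    p <- p[order(-p$n_total, p$start_pos), , drop = FALSE]
    anchor <- integer(0)
    assign_to <- integer(nrow(p))
    for (i in seq_len(nrow(p))) {
      hit <- anchor[abs(p$start_pos[anchor] - p$start_pos[i]) <= w]
      if (length(hit)) assign_to[i] <- hit[1]
      else { anchor <- c(anchor, i); assign_to[i] <- i }
    }
    out <- p[sort(unique(assign_to)), , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      if (assign_to[j] != j) {
        k <- which(sort(unique(assign_to)) == assign_to[j])
        out[k, cnt] <- out[k, cnt] + p[j, cnt]
      }
    }
    out
  })
  out <- do.call(rbind, res)
  out <- out[order(out$gene_id, out$ref_id, out$start_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant start position per gene
#'
#' The most frequently observed alignment start; ties are broken toward
#' the 5'-most (smallest transcript) coordinate.
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @return one row per gene (the dominant row of `sites`).
#' @export
dominant_starts <- function(sites) {
  o <- order(sites$gene_id, -sites$n_total, sites$start_pos)
  s <- sites[o, , drop = FALSE]
  s <- s[!duplicated(s$gene_id), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' SL2 ratio of start sites
#'
#' `SL2 / (SL1 + SL2)` over confident, family-unambiguous matches.
#' Sites with fewer than `min_discriminable` such reads are excluded.
#' Sites with ratio > `hi` are SL2-favored, < `lo` SL1-favored,
#' otherwise intermediate (strict inequalities).
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @param min_discriminable minimum confident SL1+SL2 reads (default 10).
#' @param hi,lo category bounds (defaults 0.60 / 0.40).
#' @return `sites` rows passing the threshold, with `sl2_ratio` and
#'   `sl2_category` (`"SL2"`, `"SL1"`, `"intermediate"`) added.
#' @export
sl2_site_table <- function(sites, min_discriminable = 10L,
                           hi = 0.60, lo = 0.40) {
  n12 <- sites$n_confident_sl1 + sites$n_confident_sl2
  s <- sites[n12 >= min_discriminable, , drop = FALSE]
  if (nrow(s) == 0L) {
    s$sl2_ratio <- numeric(0); s$sl2_category <- character(0)
    return(s)
  }
  s$sl2_ratio <- s$n_confident_sl2 /
    (s$n_confident_sl1 + s$n_confident_sl2)
  s$sl2_category <- ifelse(s$sl2_ratio > hi, "SL2",
                           ifelse(s$sl2_ratio < lo, "SL1", "intermediate"))
  rownames(s) <- NULL
  s
}

#' Strand-aware distance to the closest upstream coding gene
#'
#' For each gene, the distance (nt) from its 5' start (the trans-splice
#' acceptor) to the nearest edge of the closest same-contig coding gene
#' lying upstream in the gene's orientation; 0 when that gene overlaps,
#' `NA` when there is none. Coding genes are features typed `gene` with
#' `biotype=protein_coding` when biotypes are present, else all genes.
#'
#' @param annotation list from [read_gene_annotation()].
#' @return data.frame `gene_id`, `upstream_distance`.
#' @export
upstream_distance <- function(annotation) {
  g <- annotation$genes
  coding <- if (!all(is.na(g$biotype)))
    g[g$biotype %in% "protein_coding", , drop = FALSE] else g
  out <- data.frame(gene_id = g$gene_id,
                    upstream_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    same <- coding[coding$seqnames == g$seqnames[i] &
                   coding$gene_id != g$gene_id[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    if (g$strand[i] == "+") {
      cand <- same[same$start < g$start[i], , drop = FALSE]
      d <- g$start[i] - cand$end
    } else {
      cand <- same[same$end > g$end[i], , drop = FALSE]
      d <- cand$start - g$end[i]
    }
    if (!length(d)) next
    out$upstream_distance[i] <- max(0L, min(d))
  }
  out
}

#' Gene-level trans-splicing call
#'
#' Evaluated at each gene's dominant start position: `sl_fraction` is
#' SL reads over (SL + hairpin + unidentified) reads (sense reads that
#' could not be tested are excluded from the denominator by default).
#' Genes with fewer than `min_reads` reads at the dominant start are
#' `low_coverage`; a gene is `trans_spliced` when `sl_fraction` exceeds
#' `sl_majority`, otherwise `hairpin` when hairpin reads outnumber
#' unidentified ones, else `unidentified`.
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @param annotation optional, to attach upstream distances.
#' @param min_reads minimum dominant-start support (default 20).
#' @param sl_majority SL-fraction threshold for `trans_spliced`
#'   (default 0.5).
#' @param min_discriminable,hi,lo passed to the per-gene SL2 ratio.
#' @param include_unidentified keep unidentified reads in the
#'   `sl_fraction` denominator (default TRUE).
#' @return data.frame: `gene_id`, `dominant_start`, `n_total`, `status`,
#'   `sl_fraction`, `sl2_ratio`, `upstream_distance`.
#' @export
classify_gene <- function(sites, annotation = NULL, min_reads = 20L,
                          sl_majority = 0.5, min_discriminable = 10L,
                          hi = 0.60, lo = 0.40,
                          include_unidentified = TRUE) {
  d <- dominant_starts(sites)
  denom <- d$n_sl + d$n_hairpin +
    if (include_unidentified) d$n_unidentified else 0L
  sl_fraction <- ifelse(denom > 0L, d$n_sl / denom, NA_real_)
  status <- ifelse(d$n_total < min_reads, "low_coverage",
            ifelse(!is.na(sl_fraction) & sl_fraction > sl_majority,
                   "trans_spliced",
            ifelse(d$n_hairpin > d$n_unidentified, "hairpin",
                   "unidentified")))
  n12 <- d$n_confident_sl1 + d$n_confident_sl2
  sl2_ratio <- ifelse(n12 >= min_discriminable,
                      d$n_confident_sl2 / pmax(n12, 1L), NA_real_)
  out <- data.frame(gene_id = d$gene_id, dominant_start = d$start_pos,
                    n_total = d$n_total, status = status,
                    sl_fraction = sl_fraction, sl2_ratio = sl2_ratio,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ud <- upstream_distance(annotation)
    out$upstream_distance <- ud$upstream_distance[match(out$gene_id,
                                                        ud$gene_id)]
  } else {
    out$upstream_distance <- NA_integer_
  }
  out
}

#' Trans-spliced gene fraction across SL-majority thresholds
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @param thresholds SL-majority thresholds to sweep.
#' @param min_reads dominant-start support filter.
#' @param include_unidentified see [classify_gene()].
#' @return data.frame `sl_majority`, `n_genes`, `frac_trans_spliced`.
#' @export
classify_gene_sweep <- function(sites, thresholds = seq(0.1, 0.9, by = 0.1),
                                min_reads = 20L,
                                include_unidentified = TRUE) {
  d <- dominant_starts(sites)
  d <- d[d$n_total >= min_reads, , drop = FALSE]
  denom <- d$n_sl + d$n_hairpin +
    if (include_unidentified) d$n_unidentified else 0L
  fr <- ifelse(denom > 0L, d$n_sl / denom, NA_real_)
  data.frame(sl_majority = thresholds,
             n_genes = nrow(d),
             frac_trans_spliced = vapply(thresholds, function(t)
               if (nrow(d)) mean(fr > t, na.rm = TRUE) else NA_real_,
               numeric(1)))
}

#' Flag well-expressed genes with marginal SL detection
#'
#' Genes whose most represented start position has at least `min_reads`
#' reads but less than `max_sl_frac` SL detection - the endogenous
#' hairpin candidates.
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @param min_reads support threshold (default 100).
#' @param max_sl_frac strict SL-fraction bound (default 0.10).
#' @return character vector of gene IDs.
#' @export
flag_low_sl_genes <- function(sites, min_reads = 100L, max_sl_frac = 0.10) {
  d <- dominant_starts(sites)
  d$gene_id[d$n_total >= min_reads & d$n_sl / d$n_total < max_sl_frac]
}

#' SL variant usage frequencies
#'
#' Counts and fractions per SL over confident matches. Specific
#' (unambiguous) variants get an overall fraction and, for SL2 variants,
#' a within-SL2 fraction (denominator: specific SL2 variants only);
#' confident `SL2.X` reads are tallied as their own row.
#'
#' @param classified data.frame from [classify_reads()].
#' @return data.frame `sl_name`, `family`, `n`, `frac`,
#'   `frac_within_sl2`.
#' @export
sl_variant_usage <- function(classified) {
  x <- classified[classified$confident %in% TRUE &
                  !(classified$class %in% c("SL.X", "endogenous_hairpin",
                                            "unidentified",
                                            "sense_untested")), ,
                  drop = FALSE]
  if (nrow(x) == 0L) {
    return(data.frame(sl_name = character(0), family = character(0),
                      n = integer(0), frac = numeric(0),
                      frac_within_sl2 = numeric(0)))
  }
  tab <- table(x$class)
  out <- data.frame(sl_name = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$family <- ifelse(out$sl_name == "SL2.X", "SL2",
                       sl_family(out$sl_name))
  out$frac <- out$n / sum(out$n)
  spec2 <- out$family == "SL2" & out$sl_name != "SL2.X"
  tot2 <- sum(out$n[spec2])
  out$frac_within_sl2 <- ifelse(spec2 & tot2 > 0, out$n / tot2, NA_real_)
  out[order(-out$n, out$sl_name),
      c("sl_name", "family", "n", "frac", "frac_within_sl2")]
}

#' Per-site SL2 variant frequency matrix
#'
#' For each SL2-favored start site, the frequency of each specific SL2
#' variant among that site's confident unambiguous SL2 reads; rows sum
#' to 1.
#'
#' @param classified data.frame from [classify_reads()].
#' @param site_table data.frame from [sl2_site_table()] (only
#'   `sl2_category == "SL2"` rows are used).
#' @param annotation as in [aggregate_start_sites()].
#' @return numeric matrix, one row per SL2-favored site (rownames
#'   `gene_id:start`), one column per SL2 variant seen.
#' @export
sl2_variant_profile <- function(classified, site_table, annotation = NULL) {
  st <- site_table[site_table$sl2_category == "SL2", , drop = FALSE]
  if (nrow(st) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  x <- classified
  x$gene_id <- if (!is.null(annotation)) {
    g <- unname(annotation$tx2gene[x$ref_id])
    ifelse(is.na(g), x$ref_id, g)
  } else x$ref_id
  x <- x[x$confident %in% TRUE & x$sl_family %in% "SL2" &
         x$class != "SL2.X", , drop = FALSE]
  variants <- sort(unique(x$class))
  rows <- lapply(seq_len(nrow(st)), function(i) {
    sel <- x$gene_id == st$gene_id[i] & x$ref_id == st$ref_id[i] &
      x$start_pos == st$start_pos[i]
    cnt <- table(factor(x$class[sel], levels = variants))
    n <- sum(cnt)
    if (n > 0) as.numeric(cnt) / n else rep(NA_real_, length(variants))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- variants
  rownames(m) <- paste0(st$gene_id, ":", st$start_pos)
  m
}

#' Per-gene start-site report
#'
#' One row per observed alignment start of a gene with read counts and
#' the majority 5'-end class (`SL`, `hairpin` or `no_evidence`), plus
#' genomic coordinates when an annotation is supplied.
#'
#' @param sites data.frame from [aggregate_start_sites()].
#' @param gene gene ID.
#' @param annotation optional [read_gene_annotation()] output for the
#'   genomic lift-over.
#' @return data.frame: `gene_id`, `start_pos`, `genomic_pos`, `n_total`,
#'   `n_sl`, `n_hairpin`, `n_unidentified`, `majority_class`.
#' @export
start_site_report <- function(sites, gene, annotation = NULL) {
  s <- sites[sites$gene_id == gene, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(gene_id = character(0), start_pos = integer(0),
                      genomic_pos = integer(0), n_total = integer(0),
                      n_sl = integer(0), n_hairpin = integer(0),
                      n_unidentified = integer(0),
                      majority_class = character(0)))
  }
  maj <- mapply(function(sl, hp, un) {
    m <- max(sl, hp, un)
    if (m == 0L) "no_evidence"
    else if (sl == m) "SL"
    else if (hp == m) "hairpin"
    else "no_evidence"
  }, s$n_sl, s$n_hairpin, s$n_unidentified)
  gpos <- rep(NA_integer_, nrow(s))
  if (!is.null(annotation)) {
    g <- annotation$genes[match(gene, annotation$genes$gene_id), ]
    if (!is.na(g$gene_id)) {
      gpos <- if (g$strand == "+") g$start + s$start_pos - 1L
              else g$end - s$start_pos + 1L
    }
  }
  data.frame(gene_id = s$gene_id, start_pos = s$start_pos,
             genomic_pos = gpos, n_total = s$n_total, n_sl = s$n_sl,
             n_hairpin = s$n_hairpin, n_unidentified = s$n_unidentified,
             majority_class = maj, stringsAsFactors = FALSE)
}

#' Export a start-site report as BED
#'
#' @param report data.frame from [start_site_report()] (needs
#'   `genomic_pos`).
#' @param contig contig name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_start_site_bed <- function(report, contig, path) {
  r <- report[!is.na(report$genomic_pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t.", contig,
                   r$genomic_pos - 1L, r$genomic_pos,
                   r$gene_id, r$majority_class, r$n_total)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
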