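#' Simulate direct-cDNA reads with the hairpin-cDNA artifact
#'
#' For every read a gene is drawn, then a 5' class (an SL per
#' `sl_weights` restricted to the gene's family, or the gene's endogenous
#' hairpin). With probability `hairpin_artifact_prob` the cDNA self-primes
#' into a hairpin molecule: the first strand (antisense of 5'-end + body
#' + polyA, error rate `err_first_strand`, mean quality `q_aligned`) is
#' followed by the fold-back and a second-strand sense copy (error rate
#' `err_second_strand`, mean quality `q_softclip`), and the whole molecule
#' is emitted as one antisense read. Otherwise a conventional sense read
#' with short clips is emitted. In reference orientation an artifact read
#' therefore carries the layered 5' soft-clip seen in the real libraries:
#' low-quality antisense copy of the transcript, partial antisense SL,
#' then the full SL abutting the alignment start.
#'
#' @param reference output of [generate_reference()].
#' @param config the same [sim_config()].
#' @param outdir optional; when given writes `reads.fastq` and
#'   `truth.tsv`.
#' @return list with `fastq` (data.frame read_id/seq/qual in sequencing
#'   orientation) and `truth` (one row per read; see Details).
#'
#' @details Truth columns: `read_id`, `gene_id`, `transcript_id`,
#' `true_class` (an SL name or `endogenous_hairpin`), `artifact`
#' (`hairpin_cDNA_antisense` or `sense_read`), `segment_spans`
#' (reference-orientation `name:start-end` segments separated by `;`,
#' tiling the read), `true_start_offset` (1-based transcript coordinate
#' of the alignment start), `is_antisense`, `clip5_len`, `clip3_len`,
#' `cigar` (the oracle CIGAR: clips plus M/I/D over the aligned body).
#' @export
simulate_reads <- function(reference, config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_seed(config$seed + 1L, build_reads(reference, config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fq <- file.path(outdir, "reads.fastq")
    tr <- file.path(outdir, "truth.tsv")
    write_fastq(out$fastq, fq)
    write_tsv_plain(out$truth, tr)
    out$files <- list(fastq = fq, truth = tr)
  }
  out
}

build_reads <- function(reference, config) {
  genes <- reference$genes
  n_per_gene <- rpois(nrow(genes), config$reads_per_gene)
  total <- sum(n_per_gene)
  if (total == 0L) {
    empty_fastq <- data.frame(read_id = character(0), seq = character(0),
                              qual = character(0), stringsAsFactors = FALSE)
    return(list(fastq = empty_fastq, truth = empty_truth()))
  }
  gene_idx <- rep(seq_len(nrow(genes)), n_per_gene)

  sls <- config$sl_repertoire
  fam <- ifelse(startsWith(names(sls), "SL2"), "SL2", "SL1")
  w <- config$sl_weights[names(sls)]
  w[is.na(w)] <- 0

  rows <- vector("list", total)
  fq <- vector("list", total)
  for (r in seq_len(total)) {
    gi <- gene_idx[r]
    g <- genes[gi, ]
    tx <- reference$transcripts[[g$tx_id]]
    antisense <- runif(1) < config$hairpin_artifact_prob
    if (g$class == "hairpin") {
      cls <- "endogenous_hairpin"
      sl_seq <- NULL
    } else {
      in_fam <- fam == g$sl_family & w > 0
      wf <- w[in_fam] / sum(w[in_fam])
      cls <- sample(names(sls)[in_fam], 1L, prob = wf)
      sl_seq <- sls[[cls]]
    }
    rd <- build_one_read(tx, sl_seq, cls, antisense, config)
    rd$read_id <- sprintf("r%06d", r)
    rd$gene_id <- g$gene_id
    rd$transcript_id <- g$tx_id
    rows[[r]] <- rd
  }
  assemble_read_tables(rows)
}

empty_truth <- function() {
  data.frame(read_id = character(0), gene_id = character(0),
             transcript_id = character(0), true_class = character(0),
             artifact = character(0), segment_spans = character(0),
             true_start_offset = integer(0), is_antisense = logical(0),
             clip5_len = integer(0), clip3_len = integer(0),
             cigar = character(0), stringsAsFactors = FALSE)
}

assemble_read_tables <- function(rows) {
  chr <- function(f) vapply(rows, `[[`, "", f)
  int <- function(f) vapply(rows, `[[`, 0L, f)
  lgl <- function(f) vapply(rows, `[[`, NA, f)
  truth <- data.frame(
    read_id = chr("read_id"), gene_id = chr("gene_id"),
    transcript_id = chr("transcript_id"), true_class = chr("true_class"),
    artifact = chr("artifact"), segment_spans = chr("segment_spans"),
    true_start_offset = int("true_start_offset"),
    is_antisense = lgl("is_antisense"), clip5_len = int("clip5_len"),
    clip3_len = int("clip3_len"), cigar = chr("cigar"),
    stringsAsFactors = FALSE)
  seqs <- chr("seq_ref")
  quals <- vapply(rows, function(rd) {
    if (rd$is_antisense) int_to_phred(rev(rd$qual_ref))
    else int_to_phred(rd$qual_ref)
  }, character(1))
  anti <- truth$is_antisense
  seqs[anti] <- revcomp(seqs[anti])
  fastq <- data.frame(read_id = truth$read_id, seq = seqs, qual = quals,
                      stringsAsFactors = FALSE)
  list(fastq = fastq, truth = truth)
}

# one read, built in reference orientation; returns sequence, qualities,
# segment spans and the oracle CIGAR
build_one_read <- function(tx, sl_seq, cls, antisense, config) {
  e1 <- config$err_first_strand
  e2 <- config$err_second_strand
  comp <- config$err_composition
  qa <- config$q_aligned; qs <- config$q_softclip; qsd <- config$q_sd
  polya <- strrep("A", config$polya_len)

  segs <- list()   # name -> list(seq, qual)
  if (antisense) {
    if (is.null(sl_seq)) {
      d <- config$hairpin_stem_offset
      copy_len <- as.integer(round(runif(1, config$copy_len_range[1],
                                         config$copy_len_range[2])))
      copy_len <- min(copy_len, nchar(tx) - d)
      copy_len <- max(copy_len, 15L)
      ss <- substr(tx, d + 1L, d + copy_len)
      segs$second_strand_copy <- mutate_segment(revcomp(ss), e2, comp, qs, qsd)
    } else {
      d <- config$sl_foldback_offset
      L <- nchar(sl_seq)
      mrna <- paste0(sl_seq, tx)
      copy_len <- as.integer(round(runif(1, config$copy_len_range[1],
                                         config$copy_len_range[2])))
      copy_len <- min(copy_len, nchar(mrna) - d)
      copy_len <- max(copy_len, L - d)
      ss <- substr(mrna, d + 1L, d + copy_len)     # SL suffix + body prefix
      body_copy <- substr(ss, L - d + 1L, nchar(ss))
      asl <- substr(ss, 1L, L - d)                 # SL[d+1 .. L]
      segs$second_strand_copy <- mutate_segment(revcomp(body_copy), e2, comp, qs, qsd)
      segs$antisense_sl <- mutate_segment(revcomp(asl), e2, comp, qs, qsd)
      segs$sl <- mutate_segment(sl_seq, e1, comp, qa, qsd)
    }
  } else if (!is.null(sl_seq)) {
    segs$sl <- mutate_segment(sl_seq, e1, comp, qa, qsd)
  }
  body <- mutate_segment(tx, e1, comp, qa, qsd, want_cigar = TRUE)
  segs$body <- body
  segs$polyA <- mutate_segment(polya, e1, comp, qa, qsd)

  seq_ref <- paste(vapply(segs, `[[`, "", "seq"), collapse = "")
  qual_ref <- unlist(lapply(segs, `[[`, "qual"), use.names = FALSE)

  lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  spans <- paste(sprintf("%s:%d-%d", names(segs), starts, ends),
                 collapse = ";")

  clip5 <- sum(lens[setdiff(names(segs), c("body", "polyA"))])
  clip3 <- lens[["polyA"]]
  cigar <- paste0(if (clip5 > 0L) paste0(clip5, "S") else "",
                  body$cigar,
                  if (clip3 > 0L) paste0(clip3, "S") else "")

  list(seq_ref = seq_ref, qual_ref = qual_ref, segment_spans = spans,
       true_class = cls,
       artifact = if (antisense) "hairpin_cDNA_antisense" else "sense_read",
       is_antisense = antisense, true_start_offset = 1L,
       clip5_len = as.integer(clip5), clip3_len = as.integer(clip3),
       cigar = cigar)
}

# apply substitutions / insertions / deletions at `rate` and draw per-base
# qualities ~ Normal(qmean, qsd) clamped to [2, 41]. When want_cigar the
# segment is an aligned block: the first and last base are anchored (no
# deletion there, no insertion before the first base) so the CIGAR starts
# and ends with M, and the M/I/D run-length string is returned.
mutate_segment <- function(seq, rate, comp, qmean, qsd, want_cigar = FALSE) {
  n <- nchar(seq)
  if (n == 0L) {
    return(list(seq = "", qual = integer(0),
                cigar = if (want_cigar) "" else NULL))
  }
  if (rate <= 0) {
    qual <- clamp_q(rnorm(n, qmean, qsd))
    return(list(seq = seq, qual = qual,
                cigar = if (want_cigar) paste0(n, "M") else NULL))
  }
  base <- strsplit(seq, "")[[1]]
  u <- runif(n)
  p_sub <- rate * comp[["sub"]]
  p_ins <- rate * comp[["ins"]]
  p_del <- rate * comp[["del"]]
  ev <- rep("M", n)
  ev[u < p_sub + p_ins + p_del] <- "D"
  ev[u < p_sub + p_ins] <- "I"
  ev[u < p_sub] <- "S"
  if (want_cigar) {
    if (ev[1] %in% c("D", "I")) ev[1] <- "M"
    if (ev[n] == "D") ev[n] <- "M"
  }

  alphabet <- c("A", "C", "G", "T")
  idx_s <- which(ev == "S")
  emitted <- base
  if (length(idx_s)) {
    # substitute with one of the three other bases
    shift <- sample.int(3L, length(idx_s), replace = TRUE)
    cur <- match(base[idx_s], alphabet)
    cur[is.na(cur)] <- 1L
    emitted[idx_s] <- alphabet[((cur - 1L + shift) %% 4L) + 1L]
  }
  idx_i <- which(ev == "I")
  ins_chars <- if (length(idx_i))
    alphabet[sample.int(4L, length(idx_i), replace = TRUE)] else character(0)
  keep <- ev != "D"

  pos <- c(idx_i, which(keep))
  val <- c(ins_chars, emitted[keep])
  rank <- c(rep(0L, length(idx_i)), rep(1L, sum(keep)))
  o <- order(pos, rank)
  out_chars <- val[o]
  out_seq <- paste(out_chars, collapse = "")
  qual <- clamp_q(rnorm(length(out_chars), qmean, qsd))

  cigar <- NULL
  if (want_cigar) {
    op_pos <- c(idx_i, seq_len(n))
    op_val <- c(rep("I", length(idx_i)), ifelse(ev == "D", "D", "M"))
    op_rank <- c(rep(0L, length(idx_i)), rep(1L, n))
    oo <- order(op_pos, op_rank)
    ops <- op_val[oo]
    rl <- rle(ops)
    cigar <- paste0(rl$lengths, rl$values, collapse = "")
  }
  list(seq = out_seq, qual = qual, cigar = cigar)
}

clamp_q <- function(x) pmin(41L, pmax(2L, as.integer(round(x))))

write_fastq <- function(fastq, path) {
  if (nrow(fastq) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", fastq$read_id), fastq$seq,
                           "+", fastq$qual))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

read_fastq_plain <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write oracle SAM alignments for simulated reads
#'
#' Replaces an external aligner for testing: each read gets one primary
#' record with the truth CIGAR (soft-clips equal to the truth segment
#' lengths, injected indels as I/D inside the aligned block), the reverse
#' flag for antisense reads, fixed MAPQ 60, and an `@SQ` header carrying
#' the reference lengths.
#'
#' @param fastq data.frame (read_id/seq/qual) or path to a FASTQ file.
#' @param truth truth data.frame from [simulate_reads()] or path to the
#'   TSV.
#' @param reference output of [generate_reference()].
#' @param out_sam path of the SAM file to write.
#' @return `out_sam`, invisibly.
#' @export
emit_oracle_alignments <- function(fastq, truth, reference, out_sam) {
  if (is.character(fastq)) fastq <- read_fastq_plain(fastq)
  if (is.character(truth)) truth <- read_tsv_plain(truth)
  m <- match(fastq$read_id, truth$read_id)
  if (anyNA(m)) stop("read without a truth record: ",
                     fastq$read_id[which(is.na(m))[1]])
  truth <- truth[m, , drop = FALSE]

  txs <- reference$transcripts
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(txs), nchar(txs)))

  flag <- ifelse(truth$is_antisense, 16L, 0L)
  seq_ref <- ifelse(truth$is_antisense, revcomp(fastq$seq), fastq$seq)
  qual_ref <- ifelse(truth$is_antisense,
                     vapply(fastq$qual, function(q)
                       intToUtf8(rev(utf8ToInt(q))), ""),
                     fastq$qual)
  rec <- paste(fastq$read_id, flag, truth$transcript_id,
               truth$true_start_offset, 60L, truth$cigar,
               "*", 0L, 0L, seq_ref, qual_ref, sep = "\t")
  writeLines(c(hdr, rec), out_sam, sep = "\n")
  invisible(out_sam)
}

#' Run the full simulation (reference + reads + oracle alignments)
#'
#' @param config a [sim_config()].
#' @param outdir directory for the output files.
#' @return list with the reference, reads, and file paths (including the
#'   oracle `alignments.sam`).
#' @export
simulate_run <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(config, outdir)
  rds <- simulate_reads(ref, config, outdir)
  sam <- file.path(outdir, "alignments.sam")
  emit_oracle_alignments(rds$fastq, rds$truth, ref, sam)
  list(reference = ref, reads = rds,
       files = c(ref$files, rds$files, list(sam = sam)))
}
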