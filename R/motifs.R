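# Promoter extraction, PWM scanning, motif-set enrichment and motif-to-TF
# association filtering.

#' Extract promoter regions from a genome and gene annotation
#'
#' Plus-strand gene `[s, e)` gets promoter `[s - length, s)`; minus-strand
#' gets `[e, e + length)` reverse-complemented, so the returned sequence is
#' always 5'->3' relative to the gene. Promoters are truncated at contig
#' bounds. Coordinates in the result are 0-based half-open.
#'
#' @param genome named character vector / `DNAStringSet` of contigs, or a
#'   path to a FASTA file.
#' @param annotation data frame with `gene_id, chrom, start, end, strand`
#'   (0-based half-open), or a path to a GFF3 file of gene features
#'   (1-based inclusive, converted internally).
#' @param length promoter length in bp (> 0).
#' @return data frame of class `promoter_set`: gene_id, chrom, start, end,
#'   strand, sequence.
#' @export
extract_promoters <- function(genome, annotation, length = 1000) {
  if (length <= 0) sg_stop("length must be > 0", "solgrn_config_error")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation) && file.exists(annotation)) {
    gr <- rtracklayer::import(annotation)
    gr <- gr[gr$type == "gene"]
    annotation <- data.frame(
      gene_id = gr$ID, chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    if (!g$chrom %in% names(genome)) {
      warning("gene ", g$gene_id, ": contig ", g$chrom, " missing; skipped")
      next
    }
    clen <- Biostrings::width(genome[g$chrom])
    if (g$strand == "+") {
      s <- max(0L, g$start - length); e <- g$start
    } else {
      s <- g$end; e <- min(clen, g$end + length)
    }
    if (e <= s) next
    seq <- Biostrings::subseq(genome[[g$chrom]], s + 1L, e)
    if (g$strand == "-") seq <- Biostrings::reverseComplement(seq)
    rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = as.integer(s), end = as.integer(e),
      strand = g$strand, sequence = unname(as.character(seq)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    sg_stop("no promoters could be extracted", "solgrn_input_error")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("promoter_set", class(out))
  out
}

#' Log-odds scoring matrix from a position probability matrix
#'
#' Adds a pseudocount to every cell, renormalizes rows, and takes
#' log2(p / background).
#'
#' @param pwm position probability matrix (positions x A,C,G,T).
#' @param background length-4 background frequencies.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return positions x 4 log2-odds matrix with attribute `max_score`.
#' @export
pwm_logodds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  m <- pwm + pseudocount
  m <- m / rowSums(m)
  lo <- log2(sweep(m, 2, background, `/`))
  attr(lo, "max_score") <- sum(apply(lo, 1, max))
  lo
}

#' Count PWM hits in one sequence (both strands)
#'
#' Windows scoring at least `threshold` (log2-odds) on either strand are
#' counted. The default threshold is 70% of the motif's maximal score.
#' Windows containing non-ACGT letters are skipped.
#'
#' @param sequence character scalar (promoter, 5'->3').
#' @param pwm position probability matrix.
#' @param threshold absolute log2-odds threshold; `NULL` for the default.
#' @param background length-4 background frequencies.
#' @return integer hit count.
#' @export
scan_pwm <- function(sequence, pwm, threshold = NULL,
                     background = rep(0.25, 4)) {
  if (nchar(sequence) < nrow(pwm))
    sg_stop("promoter shorter than motif", "solgrn_input_error")
  lo <- pwm_logodds(pwm, background)
  if (is.null(threshold)) threshold <- 0.7 * attr(lo, "max_score")
  subject <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N", sequence))
  mat <- t(lo)                      # 4 x w, rows A,C,G,T for countPWM
  rownames(mat) <- c("A", "C", "G", "T")
  fwd <- Biostrings::countPWM(mat, subject, min.score = threshold)
  rev <- Biostrings::countPWM(mat, Biostrings::reverseComplement(subject),
                              min.score = threshold)
  as.integer(fwd + rev)
}

#' Scan a set of promoters against a PWM library
#'
#' @param promoters a [extract_promoters()] result, or any data frame with
#'   `gene_id` and `sequence` columns.
#' @param pwms named list of position probability matrices.
#' @param threshold absolute log2-odds threshold; `NULL` uses 70% of each
#'   motif's maximum.
#' @param background length-4 background frequencies.
#' @return genes x motifs integer hit-count matrix.
#' @export
scan_pwm_set <- function(promoters, pwms, threshold = NULL,
                         background = rep(0.25, 4)) {
  hits <- matrix(0L, nrow(promoters), length(pwms),
                 dimnames = list(promoters$gene_id, names(pwms)))
  for (m in names(pwms)) {
    lo <- pwm_logodds(pwms[[m]], background)
    thr <- if (is.null(threshold)) 0.7 * attr(lo, "max_score") else threshold
    mat <- t(lo); rownames(mat) <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(promoters))) {
      subject <- Biostrings::DNAString(
        gsub("[^ACGTacgt]", "N", promoters$sequence[i]))
      hits[i, m] <- Biostrings::countPWM(mat, subject, min.score = thr) +
        Biostrings::countPWM(mat, Biostrings::reverseComplement(subject),
                             min.score = thr)
    }
  }
  hits
}

#' Motif enrichment in gene sets (Fisher's exact, BH-corrected)
#'
#' Presence/absence (>= 1 hit) per gene enters a 2x2 table per (motif, set):
#' set genes with/without a hit versus remaining background genes
#' with/without. One-sided (enrichment) Fisher's exact test;
#' Benjamini-Hochberg correction jointly across all (motif, set) pairs.
#'
#' @param sets named list of gene-id vectors (each a subset of `background`).
#' @param background gene-id vector (the scanned universe, including sets).
#' @param hits genes x motifs hit-count matrix from [scan_pwm_set()].
#' @param q_cut retention cutoff on the BH q-value (default 0.05).
#' @return data frame motif, set, a, b, c, d, odds_ratio, p, q, retained.
#' @export
enrich_motifs <- function(sets, background, hits, q_cut = 0.05) {
  rows <- list()
  present <- hits[background, , drop = FALSE] >= 1
  for (sid in names(sets)) {
    genes <- intersect(sets[[sid]], background)
    if (length(genes) == 0) {
      warning("set ", sid, " is empty; skipped")
      next
    }
    rest <- setdiff(background, genes)
    for (m in colnames(hits)) {
      a <- sum(present[genes, m])
      b <- length(genes) - a
      c_ <- sum(present[rest, m])
      d <- length(rest) - c_
      p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                       alternative = "greater")$p.value
      or <- (a * d) / max(1e-12, b * c_)
      rows[[paste(m, sid)]] <- data.frame(
        motif = m, set = sid, a = a, b = b, c = c_, d = d,
        odds_ratio = or, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out$retained <- out$q < q_cut
  out
}

#' Filter TF-to-proteome alignment hits and map motifs to TF genes
#'
#' Retains alignment hits with identity >= `min_identity`, relative aligned
#' length difference <= `max_len_diff`, and coverage >= `min_coverage` on
#' both query and target; then joins retained TF hits to their motif ids.
#'
#' @param hits data frame with columns `qseqid` (known TF), `sseqid`
#'   (proteome gene), `pident`, `qlen`, `slen`, `qcovs`, `scovs`
#'   (identities and coverages in percent).
#' @param tf_motif data frame mapping known TFs to motifs: columns
#'   `tf` (matching `qseqid`) and `motif_id`.
#' @param min_identity percent identity cutoff (default 50).
#' @param max_len_diff maximum |qlen - slen| / max(qlen, slen) (default 0.30).
#' @param min_coverage percent coverage cutoff for both sides (default 50).
#' @return data frame motif_id, tf_gene (the matched proteome gene), plus
#'   the filter columns of the retained hits.
#' @export
map_motifs_to_tfs <- function(hits, tf_motif, min_identity = 50,
                              max_len_diff = 0.30, min_coverage = 50) {
  need <- c("qseqid", "sseqid", "pident", "qlen", "slen", "qcovs", "scovs")
  if (!all(need %in% names(hits)))
    sg_stop("alignment table lacks required columns", "solgrn_input_error")
  # relative to the shorter sequence: 100 vs 140 is a 40% difference
  len_diff <- abs(hits$qlen - hits$slen) / pmin(hits$qlen, hits$slen)
  keep <- hits$pident >= min_identity & len_diff <= max_len_diff &
    hits$qcovs >= min_coverage & hits$scovs >= min_coverage
  kept <- hits[keep, , drop = FALSE]
  out <- merge(tf_motif, kept, by.x = "tf", by.y = "qseqid")
  if (nrow(out) == 0)
    return(data.frame(motif_id = character(0), tf_gene = character(0),
                      stringsAsFactors = FALSE))
  data.frame(motif_id = out$motif_id, tf_gene = out$sseqid,
             pident = out$pident, qcovs = out$qcovs, scovs = out$scovs,
             stringsAsFactors = FALSE)
}
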