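# NG86-style Ka/Ks estimation for pairwise aligned coding sequences.
#
# Site counting: every codon position contributes its synonymous fraction
# (number of single-nucleotide changes at that position preserving the amino
# acid, divided by 3); changes creating a stop codon count as nonsynonymous
# sites. Difference counting averages synonymous/nonsynonymous assignments
# over all substitution pathways between the two codons, skipping pathways
# that pass through a stop codon. Jukes-Cantor correction maps proportions
# to rates.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  names(aa) <- codons
  nts <- c("A", "C", "G", "T")
  # synonymous fraction per codon position
  syn_frac <- matrix(0, nrow = length(codons), ncol = 3,
                     dimnames = list(codons, NULL))
  syn_changes <- list()   # per codon: data.frame(pos, alt, syn)
  for (cd in codons) {
    if (aa[cd] == "*") next
    ch <- character(0); pos <- integer(0); syn <- logical(0)
    for (p in 1:3) {
      base <- substr(cd, p, p)
      for (nt in setdiff(nts, base)) {
        alt <- cd
        substr(alt, p, p) <- nt
        is_syn <- aa[alt] == aa[cd] && aa[alt] != "*"
        if (is_syn) syn_frac[cd, p] <- syn_frac[cd, p] + 1 / 3
        pos <- c(pos, p); ch <- c(ch, alt); syn <- c(syn, is_syn)
      }
    }
    syn_changes[[cd]] <- data.frame(pos = pos, alt = ch, syn = syn,
                                    stringsAsFactors = FALSE)
  }
  # per-codon single-nucleotide changes to non-stop codons, by class
  syn_list <- lapply(syn_changes, function(df)
    df[df$syn, , drop = FALSE])
  nonsyn_list <- lapply(syn_changes, function(df)
    df[!df$syn & aa[df$alt] != "*", , drop = FALSE])
  .codon_env$tab <- list(codons = codons, aa = aa, syn_frac = syn_frac,
                         syn_changes = syn_changes,
                         syn_list = syn_list, nonsyn_list = nonsyn_list,
                         syn_n = vapply(syn_list, nrow, 0L),
                         nonsyn_n = vapply(nonsyn_list, nrow, 0L),
                         sense = codons[aa != "*"])
  .codon_env$tab
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# Average syn/nonsyn difference counts between two codons over all valid
# substitution pathways (orders of the differing positions). Pathways through
# stop codons are skipped; if all are blocked the stop restriction is lifted.
.path_cache <- new.env(parent = emptyenv())

codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .path_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- codon_tables()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(pos) else
    if (nd == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  walk <- function(order, allow_stop) {
    cur <- c1; sd <- 0; ndn <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && tab$aa[nxt] == "*") return(NULL)
      if (tab$aa[nxt] == tab$aa[cur] && tab$aa[nxt] != "*") sd <- sd + 1
      else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0)
    res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  out <- c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
  .path_cache[[key]] <- out
  out
}

#' NG86 Ka/Ks for one aligned coding-sequence pair
#'
#' Computes synonymous/nonsynonymous site counts, pathway-averaged difference
#' counts, Jukes-Cantor-corrected rates Ka and Ks, and their ratio omega.
#'
#' @param seq1,seq2 aligned coding sequences (equal length, multiple of 3,
#'   no internal stop codons; gap columns must be removed beforehand).
#' @param min_len minimum alignment length in nucleotides for the pair to
#'   pass filters (default 300).
#' @param ks_band numeric length-2 vector; pairs with Ks outside
#'   `[ks_band[1], ks_band[2]]` fail filters. The default excludes
#'   near-identical pairs (Ks < 0.01) and saturated ones (Ks > 3). Set e.g.
#'   `c(-Inf, 0.01)` for the literal upper-bound-only reading.
#' @return a one-row data frame (class `kaks_record`) with columns
#'   `S, N, Sd, Nd, pS, pN, Ka, Ks, omega, saturated, filters_passed, reason`.
#' @export
ng86_kaks <- function(seq1, seq2, min_len = 300, ks_band = c(0.01, 3)) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2))
    sg_stop("sequences must have equal length", "solgrn_alignment_error")
  if (nchar(seq1) %% 3 != 0)
    sg_stop("alignment length must be a multiple of 3", "solgrn_alignment_error")
  tab <- codon_tables()
  cs1 <- split_codons(seq1); cs2 <- split_codons(seq2)
  if (any(tab$aa[cs1] == "*") || any(tab$aa[cs2] == "*"))
    sg_stop("internal stop codon in input pair", "solgrn_alignment_error")
  S1 <- sum(tab$syn_frac[cs1, ]); S2 <- sum(tab$syn_frac[cs2, ])
  S <- (S1 + S2) / 2
  N <- 3 * length(cs1) - S
  d <- vapply(seq_along(cs1),
              function(i) codon_path_diffs(cs1[i], cs2[i]), c(sd = 0, nd = 0))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- is.na(Ks) || is.na(Ka)
  omega <- if (saturated || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  reason <- ""
  passed <- TRUE
  if (nchar(seq1) < min_len) { passed <- FALSE; reason <- "length<min_len" }
  else if (saturated) { passed <- FALSE; reason <- "saturated" }
  else if (Ks < ks_band[1] || Ks > ks_band[2]) {
    passed <- FALSE; reason <- "ks_outside_band"
  }
  out <- data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                    Ka = Ka, Ks = Ks, omega = omega, saturated = saturated,
                    filters_passed = passed, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("kaks_record", class(out))
  out
}

#' NG86 Ka/Ks over a table of aligned pairs
#'
#' @param pairs named list of `list(seq1=, seq2=)` or a `DNAStringSet` with
#'   interleaved records (pair i = records 2i-1, 2i) as written by
#'   [write_cds_pairs()].
#' @inheritParams ng86_kaks
#' @return data frame, one row per pair, with a `pair` id column.
#' @export
kaks_table <- function(pairs, min_len = 300, ks_band = c(0.01, 3)) {
  if (inherits(pairs, "DNAStringSet")) {
    n <- length(pairs)
    if (n %% 2 != 0)
      sg_stop("interleaved pair file must have an even record count",
              "solgrn_alignment_error")
    ids <- sub("\\|[12]$", "", names(pairs)[seq(1, n, 2)])
    pairs <- lapply(seq(1, n, 2), function(i)
      list(seq1 = as.character(pairs[[i]]), seq2 = as.character(pairs[[i + 1]])))
    names(pairs) <- ids
  }
  rows <- lapply(names(pairs), function(id) {
    r <- ng86_kaks(pairs[[id]]$seq1, pairs[[id]]$seq2,
                   min_len = min_len, ks_band = ks_band)
    cbind(pair = id, r)
  })
  do.call(rbind, rows)
}

#' Pairwise rank-sum comparison of omega distributions
#'
#' Two-sided Mann-Whitney U tests between every pair of groups of Ka/Ks
#' values, plus per-group summaries (median, quartiles, fraction under 0.3
#' signalling purifying selection, fraction in the neutral band 0.7-1.3).
#'
#' @param groups named list of numeric omega vectors.
#' @param min_n groups with fewer finite values are excluded (default 5).
#' @return list with `summary` (per group) and `tests` (per pair) data frames.
#' @export
compare_distributions <- function(groups, min_n = 5) {
  groups <- lapply(groups, function(x) x[is.finite(x)])
  keep <- vapply(groups, length, 0L) >= min_n
  if (any(!keep))
    message("excluding groups with <", min_n, " values: ",
            paste(names(groups)[!keep], collapse = ", "))
  groups <- groups[keep]
  if (length(groups) < 2)
    sg_stop("need at least two groups with enough values", "solgrn_input_error")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), median = median(x),
               q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)),
               frac_purifying = mean(x < 0.3),
               frac_neutral = mean(x >= 0.7 & x <= 1.3),
               stringsAsFactors = FALSE)
  }))
  cmb <- utils::combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    p <- suppressWarnings(
      wilcox.test(groups[[a]], groups[[b]], exact = FALSE)$p.value)
    data.frame(group_a = a, group_b = b, p = p, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
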